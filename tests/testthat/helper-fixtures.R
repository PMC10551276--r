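# Shared fixture builders. Everything is generated in code; no binary
# data ships with the package.

obs_row <- function(position, ref = "G", alt = "A",
                    depth = 5000L, alt_reads = 2500L,
                    ref_reads = depth - alt_reads) {
  data.frame(position = position, ref_base = ref, alt_base = alt,
             total_depth = depth, ref_reads = ref_reads,
             alt_reads = alt_reads, stringsAsFactors = FALSE)
}

make_profile <- function(sample_id, tissue, obs, mean_coverage = 5000) {
  mitosomatic:::new_sample_profile(sample_id, tissue, mean_coverage, obs)
}

# tiny matched pair: tumor carries the normal's variant plus privates
make_pair <- function(private_positions = c(3842L, 7953L),
                      shared_position = 263L) {
  shared <- obs_row(shared_position, "A", "G", alt_reads = 4900L)
  tum_obs <- rbind(shared, do.call(rbind, lapply(private_positions, obs_row)))
  list(
    tumor = make_profile("S-T", "tumor", tum_obs),
    normal = make_profile("S-N", "normal", shared)
  )
}

# a key-only catalog data.frame from vectors of keys like "G3842A"
key_catalog <- function(patient_id, keys) {
  parsed <- mitosomatic:::parse_mutation_key(keys)
  cbind(data.frame(patient_id = patient_id, stringsAsFactors = FALSE), parsed)
}

# the worked-example composition: 168 distinct mutations laid out with
# the published per-gene counts
example_catalog_168 <- function() {
  build_composition_catalog(
    per_gene = c("MT-ND1" = 20, "MT-ND2" = 7, "MT-ND3" = 2, "MT-ND4" = 3,
                 "MT-ND4L" = 9, "MT-ND5" = 29, "MT-ND6" = 4,
                 "MT-CYTB" = 11,
                 "MT-CO1" = 10, "MT-CO2" = 10, "MT-CO3" = 10,
                 "MT-ATP6" = 7, "MT-ATP8" = 1,
                 RNR1 = 12, RNR2 = 13, tRNA = 20),
    n_transversions = 34,
    n_homoplasmic = 31,
    pathogenic_by = c(RCI = 7, RCIV = 4, RCV = 2, tRNA = 2))
}

# 9 patients x 5 tumor mutations = 45 pooled; a chosen subset is
# "detected" in the EVs, spread so every patient has at least one
make_ev_example <- function(n_detected = 17L) {
  keys <- sprintf("G%dA", seq(3310, by = 3, length.out = 45))
  pids <- sprintf("EVP%02d", 1:9)
  tumor <- do.call(rbind, lapply(1:9, function(i)
    key_catalog(pids[i], keys[(5 * i - 4):(5 * i)])))
  det_idx <- unlist(lapply(1:9, function(i) {
    base <- (5 * i - 4):(5 * i)
    base[seq_len(min(2, length(base)))]
  }))[seq_len(n_detected)]
  ev <- do.call(rbind, lapply(1:9, function(i) {
    idx <- intersect(det_idx, (5 * i - 4):(5 * i))
    if (length(idx)) key_catalog(pids[i], keys[idx]) else NULL
  }))
  list(tumor = tumor, ev = ev)
}

# an 11-mutation hotspot panel: the 8 named members plus 3 placeholder
# keys completing the published panel shape (2 more RCI, 1 more RCIV)
example_panel_11 <- function() {
  rbind(default_hotspot_panel()[c("position", "ref_base", "alt_base")],
        data.frame(position = c(13000L, 4500L, 6000L),
                   ref_base = "G", alt_base = "A",
                   stringsAsFactors = FALSE))
}
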