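small_cfg <- function(...) {
  simulation_config(n_patients = 10, seed = 5, ...)
}

test_that("identical seeds give byte-identical cohort output", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(small_cfg()), dir1)
  write_cohort(simulate_cohort(small_cfg()), dir2)
  files <- list.files(dir1)
  expect_equal(sort(files), sort(list.files(dir2)))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  # a different seed changes the cohort
  other <- simulate_cohort(simulation_config(n_patients = 10, seed = 6))
  expect_false(identical(
    other$patients$P01$samples$tumor$observations,
    simulate_cohort(small_cfg())$patients$P01$samples$tumor$observations))
})

test_that("generated VCFs validate under the reader with no skips", {
  co <- simulate_cohort(small_cfg())
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  prof0 <- co$patients$P03$samples$tumor
  prof <- read_vcf_profile(file.path(dir, "P03-T.vcf"), tissue = "tumor")
  expect_equal(unname(prof$skipped["non_snv"]), 0L)
  expect_equal(unname(prof$skipped["other_contig"]), 0L)
  got <- prof$observations[order(prof$observations$position,
                                 prof$observations$alt_base), ]
  want <- prof0$observations[order(prof0$observations$position,
                                   prof0$observations$alt_base), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
  # manifest and known-variant files load through the io module
  man <- read_manifest_tsv(file.path(dir, "manifest.tsv"))
  expect_equal(length(unique(man$patient_id)), 10L)
  kv <- read_known_variants(file.path(dir, "known_variants.tsv"))
  expect_true(all(kv$haplogroup_marker))
  fa <- read_reference_fasta(file.path(dir, "synthetic_reference.fasta"))
  expect_equal(nchar(fa), 16569L)
})

test_that("cohort structure honours the truth ledger", {
  co <- simulate_cohort(small_cfg())
  for (pid in names(co$patients)) {
    p <- co$patients[[pid]]
    led <- co$ledger$patients[[pid]]
    nkeys <- with(p$samples$normal$observations,
                  mitosomatic:::mutation_key(position, ref_base, alt_base))
    tkeys <- with(p$samples$tumor$observations,
                  mitosomatic:::mutation_key(position, ref_base, alt_base))
    expect_setequal(nkeys, led$germline)
    expect_setequal(tkeys, c(led$germline, led$somatic$key))
    expect_length(intersect(led$germline, led$somatic$key), 0L)
    if (!is.null(p$samples$EV)) {
      ekeys <- with(p$samples$EV$observations,
                    mitosomatic:::mutation_key(position, ref_base, alt_base))
      expect_true(all(led$ev_carried %in% led$somatic$key))
      expect_setequal(ekeys, c(led$germline, led$ev_carried,
                               led$ev_exclusive))
    }
    obs <- p$samples$tumor$observations
    expect_true(all(obs$alt_reads + obs$ref_reads <= obs$total_depth))
  }
  # every patient has at least the minimum somatic count
  n_som <- vapply(co$ledger$patients, function(l) nrow(l$somatic), 0L)
  expect_true(all(n_som >= 3L))
})

test_that("well-separated simulations are recovered perfectly", {
  co <- simulate_cohort(small_cfg())
  rec <- evaluate_recovery(co)
  expect_equal(rec$somatic_sensitivity, 1.0)
  expect_equal(rec$somatic_precision, 1.0)
})

test_that("sub-threshold read support is lost at the injected rate", {
  co <- simulate_cohort(simulation_config(n_patients = 30, seed = 9,
                                          hotspot_injection = NULL,
                                          ev_patient_fraction = 0))
  # push ~20% of each tumor's somatic observations below the 100-read
  # filter; expected sensitivity ~ 0.8
  demoted <- 0L
  total <- 0L
  for (pid in names(co$patients)) {
    led <- co$ledger$patients[[pid]]
    obs <- co$patients[[pid]]$samples$tumor$observations
    keys <- mitosomatic:::mutation_key(obs$position, obs$ref_base,
                                       obs$alt_base)
    som_idx <- which(keys %in% led$somatic$key)
    total <- total + length(som_idx)
    down <- som_idx[seq_along(som_idx) %% 5 == 0]
    demoted <- demoted + length(down)
    obs$alt_reads[down] <- 50L
    obs$ref_reads[down] <- obs$total_depth[down] - 50L
    co$patients[[pid]]$samples$tumor$observations <- obs
  }
  rec <- evaluate_recovery(co)
  expect_equal(rec$somatic_sensitivity, (total - demoted) / total,
               tolerance = 1e-9)
  expect_equal(rec$somatic_precision, 1.0)
})

test_that("homoplasmic mixture weight is recovered in the calls", {
  cfg <- simulation_config(n_patients = 60, homoplasmic_weight = 0.18,
                           hotspot_injection = NULL,
                           ev_patient_fraction = 0, seed = 13)
  rec <- evaluate_recovery(simulate_cohort(cfg))
  # ~300 draws: 3 binomial sd of 18% is ~6.7 points
  expect_lt(abs(rec$homoplasmic_share_pct - 18), 7)
})

test_that("injected hotspot frequencies are recovered by the pipeline", {
  hot <- data.frame(position = 7953L, ref_base = "T", alt_base = "G",
                    frequency = 0.38)
  cfg <- simulation_config(n_patients = 800, hotspot_injection = hot,
                           ev_patient_fraction = 0,
                           germline_private_mean = 2,
                           germline_shared_per_ancestry = 5L, seed = 23)
  co <- simulate_cohort(cfg)
  res <- call_cohort(co$patients, known = co$known_variants)
  fr <- mutation_frequency(res$mutations, n_patients = 800)
  got <- fr$frequency[fr$key == "T7953G"]
  # oracle: direct count in the truth ledger
  truth <- mean(vapply(co$ledger$patients, function(l)
    "T7953G" %in% l$somatic$key, TRUE))
  expect_equal(got, truth, tolerance = 1e-9)
  # and the ledger count itself concentrates near the target
  expect_lt(abs(truth - 0.38), 3 * sqrt(0.38 * 0.62 / 800) + 1e-9)
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(hotspot_injection = data.frame(
    position = 100L, ref_base = "G", alt_base = "A", frequency = 1.5)),
    "frequencies")
  expect_error(simulation_config(ev_detection_prob = 2), "ev_detection_prob")
  expect_error(simulation_config(group_load_targets = c(African = 1,
                                                        European = 1)),
               "somatic_min")
})
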