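## Contig names accepted as the mitochondrial genome, matched
## case-insensitively.
MT_CONTIG_ALIASES <- c("chrM", "chrMT", "MT", "M", "NC_012920.1")

new_sample_profile <- function(sample_id, tissue, mean_coverage,
                               observations) {
  tissue <- match.arg(tissue, c("normal", "tumor", "EV"))
  obs <- validate_observations(observations)
  structure(
    list(sample_id = sample_id, tissue = tissue,
         mean_coverage = mean_coverage, observations = obs,
         excluded = FALSE),
    class = "sample_profile"
  )
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s [%s] %.0fx mean coverage, %d observations%s\n",
              x$sample_id, x$tissue,
              ifelse(is.na(x$mean_coverage), NA, x$mean_coverage),
              nrow(x$observations),
              if (isTRUE(x$excluded)) " (excluded)" else ""))
  invisible(x)
}

empty_observations <- function() {
  data.frame(position = integer(), ref_base = character(),
             alt_base = character(), total_depth = integer(),
             ref_reads = integer(), alt_reads = integer(),
             stringsAsFactors = FALSE)
}

validate_observations <- function(obs) {
  need <- c("position", "ref_base", "alt_base", "total_depth",
            "ref_reads", "alt_reads")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    stop("observations lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  obs <- obs[need]
  if (nrow(obs) == 0L) return(empty_observations())
  obs$position <- check_position(obs$position)
  check_bases(obs$ref_base, obs$alt_base)
  for (col in c("total_depth", "ref_reads", "alt_reads")) {
    if (any(obs[[col]] < 0)) stop(col, " must be >= 0", call. = FALSE)
    obs[[col]] <- as.integer(obs[[col]])
  }
  over <- obs$alt_reads + obs$ref_reads > obs$total_depth
  if (any(over)) {
    stop("alt_reads + ref_reads exceed total_depth at row(s) ",
         paste(which(over), collapse = ", "), call. = FALSE)
  }
  rownames(obs) <- NULL
  obs
}

#' Read one sample's variant observations from a VCF
#'
#' Reads single-nucleotide variant records from a VCF (4.x) for one
#' sample. Multi-allelic records are split into one observation per ALT
#' allele; non-SNV (indel/MNV/symbolic) alleles are skipped and counted.
#' Records on contigs other than the mitochondrial genome (aliases
#' chrM/chrMT/MT/M/NC_012920.1, case-insensitive, configurable) are
#' skipped with a warning.
#'
#' Depths are taken from the per-sample FORMAT fields. Two encodings
#' are recognised: GATK-style `AD` = ref,alt1,alt2,... allelic depths,
#' and VarScan-style `RD` (reference depth) + `AD` (alt depth(s) only).
#' When `RD` is present it is used as the reference depth and `AD`
#' entries are alt depths; otherwise the first `AD` entry is the
#' reference depth. A record with neither encoding is a format error
#' naming the record. `DP` gives the total depth; when absent it is
#' taken as the sum of the allelic depths.
#'
#' @param path VCF file (plain text or gzipped).
#' @param sample_id sample column to read; defaults to the first.
#' @param tissue one of `"normal"`, `"tumor"`, `"EV"`.
#' @param mean_coverage fold-coverage of the sample; if `NULL`, the
#'   mean of the per-record `DP` values is used as a proxy.
#' @param contig_aliases accepted mitochondrial contig names.
#' @return a `sample_profile`: list with `sample_id`, `tissue`,
#'   `mean_coverage`, `observations` (data.frame with `position`,
#'   `ref_base`, `alt_base`, `total_depth`, `ref_reads`, `alt_reads`)
#'   and attribute-like counter `skipped` (named: `non_snv`,
#'   `other_contig`).
#' @export
read_vcf_profile <- function(path, sample_id = NULL, tissue,
                             mean_coverage = NULL,
                             contig_aliases = MT_CONTIG_ALIASES) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCFs drop to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (is.null(sample_id)) {
    sample_id <- samples[1L]
  } else if (!sample_id %in% samples) {
    stop("sample ", sample_id, " not in VCF (has: ",
         paste(samples, collapse = ", "), ")", call. = FALSE)
  }

  skipped <- c(non_snv = 0L, other_contig = 0L)
  obs_list <- list()
  if (nrow(fix) > 0L) {
    gt_field <- function(tag) {
      tryCatch(vcfR::extract.gt(vcf, tag)[, sample_id],
               error = function(e) rep(NA_character_, nrow(fix)))
    }
    ad <- gt_field("AD")
    rd <- suppressWarnings(as.integer(gt_field("RD")))
    dp <- suppressWarnings(as.integer(gt_field("DP")))
    on_mt <- tolower(fix$CHROM) %in% tolower(contig_aliases)
    if (any(!on_mt)) {
      skipped["other_contig"] <- sum(!on_mt)
      warning(sum(!on_mt), " record(s) on non-mitochondrial contig(s) skipped",
              call. = FALSE)
    }
    for (i in which(on_mt)) {
      ref <- toupper(fix$REF[i])
      alts <- toupper(strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]])
      if (is.na(ad[i])) {
        stop("record ", fix$CHROM[i], ":", fix$POS[i],
             " lacks the AD depth field for sample ", sample_id,
             call. = FALSE)
      }
      depths <- suppressWarnings(
        as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1L]]))
      varscan_style <- !is.na(rd[i])
      ref_reads <- if (varscan_style) rd[i] else depths[1L]
      alt_depths <- if (varscan_style) depths else depths[-1L]
      total <- if (!is.na(dp[i])) dp[i] else ref_reads + sum(alt_depths, na.rm = TRUE)
      for (j in seq_along(alts)) {
        alt <- alts[j]
        if (nchar(ref) != 1L || nchar(alt) != 1L ||
            !ref %in% c("A", "C", "G", "T") || !alt %in% c("A", "C", "G", "T")) {
          skipped["non_snv"] <- skipped["non_snv"] + 1L
          next
        }
        alt_reads <- if (length(alt_depths) >= j) alt_depths[j] else NA_integer_
        if (is.na(alt_reads)) {
          stop("record ", fix$CHROM[i], ":", fix$POS[i],
               " has no AD entry for ALT allele ", alt, call. = FALSE)
        }
        obs_list[[length(obs_list) + 1L]] <- data.frame(
          position = as.integer(fix$POS[i]), ref_base = ref, alt_base = alt,
          total_depth = total, ref_reads = ref_reads, alt_reads = alt_reads,
          stringsAsFactors = FALSE)
      }
    }
  }
  obs <- if (length(obs_list)) do.call(rbind, obs_list) else empty_observations()
  if (is.null(mean_coverage)) {
    mean_coverage <- if (nrow(obs)) mean(obs$total_depth) else NA_real_
  }
  prof <- new_sample_profile(sample_id, tissue, mean_coverage, obs)
  prof$skipped <- skipped
  prof
}

#' Read a flat variant catalog TSV into sample profiles
#'
#' Expected tab-separated columns: `sample_id`, `tissue`
#' (normal/tumor/EV), `mean_coverage`, `position`, `ref_base`,
#' `alt_base`, `total_depth`, `ref_reads`, `alt_reads`. One row per
#' variant observation; samples with no variants may be listed with
#' `position` `NA` to record their coverage.
#'
#' @param path TSV file with a header row.
#' @return named list of `sample_profile` objects, keyed by sample id.
#' @export
read_catalog_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "mean_coverage", "position",
            "ref_base", "alt_base", "total_depth", "ref_reads", "alt_reads")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_tissue <- !df$tissue %in% c("normal", "tumor", "EV")
  if (any(bad_tissue)) {
    stop("unknown tissue label(s) at row(s) ",
         paste(which(bad_tissue), collapse = ", "), ": ",
         paste(unique(df$tissue[bad_tissue]), collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (sid in unique(df$sample_id)) {
    rows <- df[df$sample_id == sid, , drop = FALSE]
    obs <- rows[!is.na(rows$position),
                c("position", "ref_base", "alt_base", "total_depth",
                  "ref_reads", "alt_reads"), drop = FALSE]
    out[[sid]] <- new_sample_profile(
      sid, unique(rows$tissue)[1L],
      mean_coverage = unique(rows$mean_coverage)[1L],
      observations = obs)
  }
  out
}

#' Read a patient manifest TSV
#'
#' Columns: `patient_id`, `sample_id`, `tissue`, `ancestry`
#' (African/European/other), `stage`, `age` (may be NA/unknown).
#'
#' @param path TSV file.
#' @return data.frame, one row per sample.
#' @export
read_manifest_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("patient_id", "sample_id", "tissue", "ancestry", "stage", "age")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- duplicated(df[c("patient_id", "tissue")])
  if (any(dup)) {
    stop("more than one profile per tissue for patient(s): ",
         paste(unique(df$patient_id[dup]), collapse = ", "), call. = FALSE)
  }
  df
}

#' Assemble patient records from profiles and a manifest
#'
#' @param profiles named list of `sample_profile` objects (names =
#'   sample ids), e.g. from [read_catalog_tsv()] or repeated
#'   [read_vcf_profile()] calls.
#' @param manifest data.frame from [read_manifest_tsv()].
#' @return named list of patient records: each a list with
#'   `patient_id`, `ancestry`, `stage`, `age` and `samples` (a list
#'   keyed by tissue).
#' @export
build_patient_records <- function(profiles, manifest) {
  unknown <- setdiff(manifest$sample_id, names(profiles))
  if (length(unknown)) {
    stop("manifest sample(s) missing from profiles: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (pid in unique(manifest$patient_id)) {
    rows <- manifest[manifest$patient_id == pid, , drop = FALSE]
    samples <- list()
    for (i in seq_len(nrow(rows))) {
      prof <- profiles[[rows$sample_id[i]]]
      if (prof$tissue != rows$tissue[i]) {
        stop("tissue mismatch for sample ", rows$sample_id[i],
             ": manifest says ", rows$tissue[i], ", profile says ",
             prof$tissue, call. = FALSE)
      }
      samples[[rows$tissue[i]]] <- prof
    }
    out[[pid]] <- list(patient_id = pid,
                       ancestry = rows$ancestry[1L],
                       stage = rows$stage[1L],
                       age = rows$age[1L],
                       samples = samples)
  }
  out
}

#' Read a known-variant lookup table
#'
#' Offline stand-in for database interrogation (e.g. Mitomap):
#' tab-separated with columns `position`, `ref_base`, `alt_base`,
#' `reported_in_databases` (yes/no), `pathogenic` (yes/no),
#' `haplogroup_marker` (yes/no). Keys must be unique.
#'
#' @param path TSV file; `NULL` returns an empty table (everything
#'   will be treated as novel, nothing excluded as haplogroup marker).
#' @return data.frame keyed by (position, ref_base, alt_base) with
#'   logical flag columns.
#' @export
read_known_variants <- function(path = NULL) {
  if (is.null(path)) {
    return(data.frame(position = integer(), ref_base = character(),
                      alt_base = character(),
                      reported_in_databases = logical(),
                      pathogenic = logical(), haplogroup_marker = logical(),
                      stringsAsFactors = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "ref_base", "alt_base", "reported_in_databases",
            "pathogenic", "haplogroup_marker")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("known-variant table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[need]
  df$position <- check_position(df$position)
  for (col in c("reported_in_databases", "pathogenic", "haplogroup_marker")) {
    df[[col]] <- tolower(as.character(df[[col]])) %in% c("yes", "true", "1")
  }
  key <- mutation_key(df$position, df$ref_base, df$alt_base)
  if (anyDuplicated(key)) {
    stop("duplicate known-variant key(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }
  df
}

#' Write / read an annotated somatic-mutation catalog
#'
#' One TSV row per (patient, mutation) with the full annotation:
#' `patient_id`, `position`, `ref_base`, `alt_base`, `gene`,
#' `region_class`, `complex`, `substitution_class`, `maf_percent`
#' (`NA` when the site has zero wild-type reads, i.e. fully mutant),
#' `alt_fraction`, `heteroplasmy`, `novel`, `pathogenic`,
#' `ev_exclusive`, `source_tissues` (comma-joined subset of
#' tumor/EV). Round-trips losslessly through [read_annotated_catalog()].
#'
#' @param mutations annotated mutation data.frame (see
#'   [call_somatic()] and [flag_known()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_annotated_catalog <- function(mutations, path) {
  cols <- c("patient_id", "position", "ref_base", "alt_base", "gene",
            "region_class", "complex", "substitution_class", "maf_percent",
            "alt_fraction", "heteroplasmy", "novel", "pathogenic",
            "ev_exclusive", "source_tissues")
  df <- mutations
  for (col in setdiff(cols, names(df))) {
    fill <- switch(col,
      novel = NA, pathogenic = NA, ev_exclusive = FALSE,
      source_tissues = "tumor", NA)
    df[[col]] <- rep(fill, nrow(df))
  }
  df <- df[cols]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_annotated_catalog
#' @export
read_annotated_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = "NA")
  df$position <- as.integer(df$position)
  for (col in c("novel", "pathogenic", "ev_exclusive")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Write a cohort summary as JSON
#'
#' @param summary a `cohort_summary` (see [spectrum_summary()]) or any
#'   list of aggregates.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
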