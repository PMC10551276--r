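#' Read-support filter configuration
#'
#' Defaults follow deep mitochondrial amplicon sequencing practice:
#' samples are usable only above 1000-fold mean coverage (strictly
#' greater), variant calls with fewer than 100 supporting reads are
#' discarded (exactly 100 is kept), and a site is homoplasmic at an
#' alt-allele fraction of 0.95 or more. The homoplasmy cutoff is a
#' documented convention, not a measured constant; see the vignette.
#'
#' @param min_sample_coverage fold-coverage a sample must strictly
#'   exceed to enter somatic calling.
#' @param min_variant_reads minimum alt-read support to keep a variant.
#' @param homoplasmy_threshold alt fraction in (0, 1] at or above which
#'   a mutation is homoplasmic.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_sample_coverage = 1000,
                          min_variant_reads = 100,
                          homoplasmy_threshold = 0.95) {
  stopifnot(min_sample_coverage >= 0, min_variant_reads >= 0,
            homoplasmy_threshold > 0, homoplasmy_threshold <= 1)
  structure(list(min_sample_coverage = min_sample_coverage,
                 min_variant_reads = min_variant_reads,
                 homoplasmy_threshold = homoplasmy_threshold),
            class = "filter_config")
}

#' Apply sample- and variant-level read filters
#'
#' A profile whose mean coverage does not strictly exceed
#' `min_sample_coverage` is marked `excluded` (it keeps its
#' observations but is rejected by [call_somatic()]). Observations with
#' `alt_reads < min_variant_reads` are removed.
#'
#' @param profile a `sample_profile`.
#' @param config a [filter_config()].
#' @return the filtered profile, with a `filter_report` element
#'   counting removals by reason (`low_coverage_sample` 0/1,
#'   `low_read_variants`).
#' @export
apply_read_filters <- function(profile, config = filter_config()) {
  stopifnot(inherits(profile, "sample_profile"))
  report <- c(low_coverage_sample = 0L, low_read_variants = 0L)
  if (is.na(profile$mean_coverage) ||
      profile$mean_coverage <= config$min_sample_coverage) {
    profile$excluded <- TRUE
    report["low_coverage_sample"] <- 1L
  }
  keep <- profile$observations$alt_reads >= config$min_variant_reads
  report["low_read_variants"] <- sum(!keep)
  profile$observations <- profile$observations[keep, , drop = FALSE]
  rownames(profile$observations) <- NULL
  profile$filter_report <- report
  profile
}

#' Mutant-to-wild-type read ratio (MAF), in percent
#'
#' Computed as mutant reads divided by wild-type reads, times 100.
#' Note this ratio is unbounded and is NOT the conventional mutant
#' allele fraction (mutant/total); the fraction is carried separately
#' as `alt_fraction` and used for heteroplasmy classification. A site
#' with zero wild-type reads but mutant support is fully mutant: the
#' ratio is undefined and `NA` is returned (the mutation is retained
#' and classified homoplasmic downstream).
#'
#' @param alt_reads,ref_reads non-negative read counts; vectors recycle.
#' @return percent ratio; `0` when `alt_reads` is 0, `NA` (undefined,
#'   fully mutant) when `ref_reads` is 0 and `alt_reads` > 0.
#' @examples
#' compute_maf(100, 900)  # 11.11...
#' @export
compute_maf <- function(alt_reads, ref_reads) {
  if (any(alt_reads < 0) || any(ref_reads < 0)) {
    stop("read counts must be >= 0", call. = FALSE)
  }
  if (any(alt_reads == 0 & ref_reads == 0)) {
    stop("alt_reads and ref_reads are both 0: no read evidence",
         call. = FALSE)
  }
  ifelse(alt_reads == 0, 0,
         ifelse(ref_reads == 0, NA_real_, alt_reads / ref_reads * 100))
}

#' Classify a mutation as homoplasmic or heteroplasmic
#'
#' @param alt_fraction mutant-read fraction in `[0, 1]` (mutant /
#'   (mutant + wild-type)).
#' @param config a [filter_config()] supplying the threshold.
#' @return `"homoplasmic"` if `alt_fraction >=` threshold, else
#'   `"heteroplasmic"`.
#' @export
classify_heteroplasmy <- function(alt_fraction, config = filter_config()) {
  if (any(is.na(alt_fraction)) || any(alt_fraction < 0) ||
      any(alt_fraction > 1)) {
    stop("alt_fraction must be in [0, 1]", call. = FALSE)
  }
  ifelse(alt_fraction >= config$homoplasmy_threshold,
         "homoplasmic", "heteroplasmic")
}

#' Call somatic mutations from a matched tumor/normal pair
#'
#' A tumor observation is somatic iff no observation with the identical
#' (position, ref, alt) key exists in the filtered matched-normal
#' profile, and its key is not flagged as a haplogroup marker in the
#' known-variant table (inherited haplogroup-defining variants are
#' excluded even if absent from the sequenced normal). Matching is
#' allele-level: a normal-side variant at the same position with a
#' different alt does not suppress the tumor variant.
#'
#' Every call is annotated with its gene (primary feature), region
#' class, respiratory complex, substitution class, MAF, alt fraction
#' and heteroplasmy state.
#'
#' @param tumor,normal `sample_profile`s of the same patient, already
#'   passed through [apply_read_filters()]. A missing or excluded
#'   profile is an error: somatic calling requires the matched normal.
#' @param known known-variant table from [read_known_variants()] (may
#'   be empty).
#' @param config a [filter_config()].
#' @param patient_id patient label attached to the calls.
#' @return data.frame with one row per somatic mutation: `patient_id`,
#'   `position`, `ref_base`, `alt_base`, `gene`, `region_class`,
#'   `complex`, `substitution_class`, `maf_percent`, `alt_fraction`,
#'   `heteroplasmy`, `source_tissues`.
#' @export
call_somatic <- function(tumor, normal, known = read_known_variants(),
                         config = filter_config(), patient_id = NA_character_) {
  if (is.null(normal)) {
    stop("somatic calling requires the matched normal profile",
         call. = FALSE)
  }
  stopifnot(inherits(tumor, "sample_profile"),
            inherits(normal, "sample_profile"))
  if (tumor$tissue != "tumor" || normal$tissue != "normal") {
    stop("profiles must be a (tumor, normal) pair; got (",
         tumor$tissue, ", ", normal$tissue, ")", call. = FALSE)
  }
  if (isTRUE(tumor$excluded) || isTRUE(normal$excluded)) {
    stop("profile(s) excluded by the sample-coverage filter; cannot call",
         call. = FALSE)
  }
  tobs <- tumor$observations
  if (nrow(tobs) == 0L) return(annotate_mutations(empty_observations(),
                                                  patient_id, config))
  tkey <- mutation_key(tobs$position, tobs$ref_base, tobs$alt_base)
  nobs <- normal$observations
  nkey <- mutation_key(nobs$position, nobs$ref_base, nobs$alt_base)
  hkey <- with(known[known$haplogroup_marker, , drop = FALSE],
               mutation_key(position, ref_base, alt_base))
  somatic <- tobs[!(tkey %in% nkey) & !(tkey %in% hkey), , drop = FALSE]
  annotate_mutations(somatic, patient_id, config)
}

## attach gene-map, spectrum and heteroplasmy annotation to raw
## observations (position/ref/alt/read counts)
annotate_mutations <- function(obs, patient_id, config = filter_config(),
                               source_tissues = "tumor") {
  if (nrow(obs) == 0L) {
    out <- data.frame(patient_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      gene = character(), region_class = character(),
                      complex = character(), substitution_class = character(),
                      maf_percent = numeric(), alt_fraction = numeric(),
                      heteroplasmy = character(), source_tissues = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  loc <- locate_position(obs$position)
  if (is.list(loc) && !is.data.frame(loc)) {  # single position
    loc <- data.frame(primary_feature = loc$primary_feature,
                      region_class = loc$region_class,
                      complex = loc$complex, stringsAsFactors = FALSE)
  }
  alt_fraction <- obs$alt_reads / (obs$alt_reads + obs$ref_reads)
  data.frame(
    patient_id = patient_id,
    position = obs$position,
    ref_base = obs$ref_base,
    alt_base = obs$alt_base,
    gene = loc$primary_feature,
    region_class = loc$region_class,
    complex = loc$complex,
    substitution_class = classify_substitution(obs$ref_base, obs$alt_base),
    maf_percent = compute_maf(obs$alt_reads, obs$ref_reads),
    alt_fraction = alt_fraction,
    heteroplasmy = classify_heteroplasmy(alt_fraction, config),
    source_tissues = source_tissues,
    stringsAsFactors = FALSE
  )
}

#' Run somatic calling across a cohort of patient records
#'
#' Applies [apply_read_filters()] to every profile and [call_somatic()]
#' to every patient with both a tumor and a normal profile surviving
#' the sample filter. Patients whose tumor or normal sample fails the
#' coverage filter are dropped with a note in the report.
#'
#' @param patients list of patient records from
#'   [build_patient_records()] (or [simulate_cohort()]).
#' @param known known-variant table.
#' @param config a [filter_config()].
#' @return list with `mutations` (row-bound annotated somatic calls
#'   across patients) and `dropped_patients` (character vector).
#' @export
call_cohort <- function(patients, known = read_known_variants(),
                        config = filter_config()) {
  calls <- list()
  dropped <- character()
  for (p in patients) {
    tum <- p$samples$tumor
    nor <- p$samples$normal
    if (is.null(tum) || is.null(nor)) {
      dropped <- c(dropped, p$patient_id)
      next
    }
    tum <- apply_read_filters(tum, config)
    nor <- apply_read_filters(nor, config)
    if (isTRUE(tum$excluded) || isTRUE(nor$excluded)) {
      dropped <- c(dropped, p$patient_id)
      next
    }
    calls[[p$patient_id]] <- call_somatic(tum, nor, known, config,
                                          patient_id = p$patient_id)
  }
  mutations <- if (length(calls)) do.call(rbind, calls) else
    annotate_mutations(empty_observations(), NA_character_, config)
  rownames(mutations) <- NULL
  list(mutations = mutations, dropped_patients = dropped)
}
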