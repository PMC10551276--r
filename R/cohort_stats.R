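## distinct-mutation view of a per-patient catalog: one row per
## (position, ref, alt) key, keeping the annotation of the first row
## and resolving per-key heteroplasmy (homoplasmic in >= 1 patient)
distinct_mutations <- function(mutations) {
  if (nrow(mutations) == 0L) return(mutations)
  key <- mutation_key(mutations$position, mutations$ref_base,
                      mutations$alt_base)
  first <- !duplicated(key)
  out <- mutations[first, , drop = FALSE]
  if ("heteroplasmy" %in% names(mutations)) {
    hom_keys <- unique(key[mutations$heteroplasmy == "homoplasmic"])
    out$heteroplasmy <- ifelse(key[first] %in% hom_keys,
                               "homoplasmic", "heteroplasmic")
  }
  rownames(out) <- NULL
  out
}

SUBSTITUTION_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                          "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

#' Cohort-level mutation spectrum summary
#'
#' Aggregates an annotated somatic-mutation catalog into the standard
#' cohort report: coding/noncoding split, per-region and per-gene
#' counts, respiratory-complex distribution, the 12 ordered
#' substitution classes with transition/transversion totals,
#' homoplasmy and (when flags are present) novelty/pathogenicity
#' breakdowns. All spectrum counts are over DISTINCT mutation types:
#' a mutation shared by k patients counts once here and contributes k
#' to its patient frequency (see [mutation_frequency()]). Percentages
#' are round-half-up integers.
#'
#' @param mutations annotated catalog (rows = patient-mutation pairs),
#'   e.g. from [call_cohort()] or [build_composition_catalog()].
#' @param n_patients number of patients in the cohort (used for
#'   frequencies; defaults to the number of distinct `patient_id`s).
#' @return a `cohort_summary` list; see Details for fields.
#' @details Fields: `n_patients`, `n_distinct_mutations`,
#' `coding_count`/`noncoding_count` (+ `_pct`), `region_counts`
#' (control, rRNA, tRNA, intergenic), `gene_counts`, `complex_counts`
#' (+ `complex_pct`), `substitution_counts`, `transition_count`,
#' `transversion_count` (+ `_pct`), `homoplasmic_count` (+ `_pct`),
#' and, when `novel`/`pathogenic` columns exist, `novel_count`,
#' `pathogenic_count` with per-complex breakdowns.
#' @export
spectrum_summary <- function(mutations, n_patients = NULL) {
  if (is.null(n_patients)) {
    n_patients <- length(unique(stats::na.omit(mutations$patient_id)))
  }
  dm <- distinct_mutations(mutations)
  n <- nrow(dm)
  out <- list(n_patients = n_patients, n_distinct_mutations = n)
  if (n == 0L) {
    out$coding_count <- out$noncoding_count <- 0L
    class(out) <- "cohort_summary"
    return(out)
  }
  coding <- sum(dm$region_class == "coding")
  noncoding <- n - coding
  out$coding_count <- coding
  out$noncoding_count <- noncoding
  out$coding_pct <- pct(coding, n)
  out$noncoding_pct <- pct(noncoding, n)

  cat_of <- vapply(dm$gene, function(g) {
    if (g == "INTERGENIC") "intergenic" else
      .mito_gene_map$category[match(g, .mito_gene_map$name)]
  }, "")
  out$region_counts <- c(
    control = sum(cat_of == "control"),
    rRNA = sum(cat_of == "rRNA"),
    tRNA = sum(cat_of == "tRNA"),
    intergenic = sum(cat_of == "intergenic")
  )
  gene_tab <- table(dm$gene)
  out$gene_counts <- stats::setNames(as.integer(gene_tab), names(gene_tab))
  cx <- factor(dm$complex, levels = c("RCI", "RCIII", "RCIV", "RCV"))
  out$complex_counts <- stats::setNames(as.integer(table(cx)), levels(cx))
  out$complex_pct <- stats::setNames(
    vapply(out$complex_counts, pct, 0, denom = n), levels(cx))

  sub <- factor(paste0(dm$ref_base, ">", dm$alt_base),
                levels = SUBSTITUTION_CLASSES)
  out$substitution_counts <- stats::setNames(as.integer(table(sub)),
                                             SUBSTITUTION_CLASSES)
  out$transition_count <- sum(dm$substitution_class == "transition")
  out$transversion_count <- sum(dm$substitution_class == "transversion")
  out$transition_pct <- pct(out$transition_count, n)
  out$transversion_pct <- pct(out$transversion_count, n)

  if ("heteroplasmy" %in% names(dm)) {
    out$homoplasmic_count <- sum(dm$heteroplasmy == "homoplasmic")
    out$homoplasmic_pct <- pct(out$homoplasmic_count, n)
  }
  for (flag in c("novel", "pathogenic")) {
    if (flag %in% names(dm)) {
      k <- sum(dm[[flag]], na.rm = TRUE)
      out[[paste0(flag, "_count")]] <- k
      out[[paste0(flag, "_pct")]] <- pct(k, n)
      sel <- dm[which(dm[[flag]]), , drop = FALSE]
      bycx <- stats::setNames(as.integer(table(
        factor(sel$complex, levels = c("RCI", "RCIII", "RCIV", "RCV", "none")))),
        c("RCI", "RCIII", "RCIV", "RCV", "none"))
      out[[paste0(flag, "_by_complex")]] <- bycx
      if (k > 0) {
        out[[paste0(flag, "_by_complex_pct")]] <-
          stats::setNames(vapply(bycx, pct, 0, denom = k), names(bycx))
      }
    }
  }
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_distinct_mutations, "distinct mutations,",
      x$n_patients, "patients\n")
  if (!is.null(x$coding_pct)) {
    cat(sprintf("  coding %d (%d%%) / noncoding %d (%d%%)\n",
                x$coding_count, x$coding_pct,
                x$noncoding_count, x$noncoding_pct))
  }
  if (!is.null(x$transition_pct)) {
    cat(sprintf("  transitions %d (%d%%) / transversions %d (%d%%)\n",
                x$transition_count, x$transition_pct,
                x$transversion_count, x$transversion_pct))
  }
  if (!is.null(x$complex_counts)) {
    cat("  complexes:",
        paste(sprintf("%s=%d", names(x$complex_counts), x$complex_counts),
              collapse = " "), "\n")
  }
  if (!is.null(x$homoplasmic_count)) {
    cat(sprintf("  homoplasmic %d (%d%%)\n", x$homoplasmic_count,
                x$homoplasmic_pct))
  }
  invisible(x)
}

#' Per-mutation patient frequency
#'
#' How many of the cohort's patients carry each distinct mutation, as
#' a count and a round-half-up integer percent of `n_patients`.
#'
#' @param mutations per-patient annotated catalog.
#' @param n_patients cohort size (> 0); a patient carrying a mutation
#'   counts once however many tissues show it.
#' @return data.frame `position`, `ref_base`, `alt_base`, `key`,
#'   `count`, `frequency` (fraction), `percent`, sorted by descending
#'   count then position.
#' @export
mutation_frequency <- function(mutations, n_patients) {
  if (is.null(n_patients) || is.na(n_patients) || n_patients <= 0) {
    stop("n_patients must be > 0", call. = FALSE)
  }
  if (nrow(mutations) == 0L) {
    return(data.frame(position = integer(), ref_base = character(),
                      alt_base = character(), key = character(),
                      count = integer(), frequency = numeric(),
                      percent = numeric(), stringsAsFactors = FALSE))
  }
  key <- mutation_key(mutations$position, mutations$ref_base,
                      mutations$alt_base)
  per <- unique(data.frame(patient_id = mutations$patient_id, key = key,
                           stringsAsFactors = FALSE))
  tab <- table(per$key)
  if (any(tab > n_patients)) {
    stop("a mutation is carried by more patients than n_patients",
         call. = FALSE)
  }
  parsed <- parse_mutation_key(names(tab))
  out <- data.frame(parsed, key = names(tab),
                    count = as.integer(tab),
                    frequency = as.integer(tab) / n_patients,
                    percent = vapply(as.integer(tab), pct, 0,
                                     denom = n_patients),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cohort hotspot panel
#'
#' Mutations recurring in at least `min_frequency` of the patients,
#' ordered by descending frequency then position.
#'
#' @param frequencies output of [mutation_frequency()].
#' @param min_frequency fraction in (0, 1]; default 0.19 (a mutation
#'   seen in 19% or more of patients is a hotspot).
#' @return subset of `frequencies`, same columns.
#' @export
hotspot_panel <- function(frequencies, min_frequency = 0.19) {
  if (!is.numeric(min_frequency) || min_frequency <= 0 || min_frequency > 1) {
    stop("min_frequency must be in (0, 1]", call. = FALSE)
  }
  out <- frequencies[frequencies$frequency >= min_frequency, , drop = FALSE]
  out <- out[order(-out$frequency, out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag mutations as novel / pathogenic against a lookup table
#'
#' Novel means the (position, ref, alt) key is absent from the
#' reported records of the known-variant table; pathogenic means the
#' key is present and flagged pathogenic. With an empty table every
#' mutation is novel and none pathogenic.
#'
#' @param mutations annotated catalog.
#' @param known table from [read_known_variants()].
#' @return `mutations` with logical `novel` and `pathogenic` columns.
#' @export
flag_known <- function(mutations, known = read_known_variants()) {
  if (nrow(mutations) == 0L) {
    mutations$novel <- logical(0)
    mutations$pathogenic <- logical(0)
    return(mutations)
  }
  key <- mutation_key(mutations$position, mutations$ref_base,
                      mutations$alt_base)
  reported <- with(known[known$reported_in_databases, , drop = FALSE],
                   mutation_key(position, ref_base, alt_base))
  patho <- with(known[known$pathogenic, , drop = FALSE],
                mutation_key(position, ref_base, alt_base))
  mutations$novel <- !(key %in% reported)
  mutations$pathogenic <- key %in% patho
  mutations
}

#' Per-group mutational load
#'
#' Number of mutations per patient in each patient group (e.g.
#' ancestry): the count of (patient, mutation) observations in the
#' group — a mutation counted once per patient carrying it — divided
#' by the group size, to 1 decimal. Patients without mutations still
#' count in the denominator, so `groups` must list every patient.
#' The load can be restricted to a genome region: a complex
#' (`"RCI"`...), a gene (`"MT-ND1"`), a feature category (`"tRNA"`,
#' `"rRNA"`, `"control"`), or a region class
#' (`"coding"`/`"noncoding"`).
#'
#' @param mutations per-patient annotated catalog.
#' @param groups data.frame with `patient_id` and `group` columns
#'   covering the whole cohort; every patient in exactly one group.
#' @param region optional restriction (complex, gene or region class).
#' @param digits decimals to report (default 1).
#' @return data.frame `group`, `n_patients`, `n_mutations`, `load`.
#' @export
mutational_load <- function(mutations, groups, region = NULL, digits = 1) {
  if (anyDuplicated(groups$patient_id)) {
    stop("each patient must be assigned to exactly one group", call. = FALSE)
  }
  sizes <- table(groups$group)
  if (any(sizes == 0)) stop("empty group", call. = FALSE)
  m <- mutations
  if (!is.null(region)) {
    category <- vapply(m$gene, function(g) {
      if (g == "INTERGENIC") "intergenic" else
        .mito_gene_map$category[match(g, .mito_gene_map$name)]
    }, "")
    m <- m[m$complex == region | m$gene == region |
             m$region_class == region | category == region, , drop = FALSE]
  }
  key <- if (nrow(m)) mutation_key(m$position, m$ref_base, m$alt_base)
         else character()
  per <- unique(data.frame(patient_id = m$patient_id, key = key,
                           stringsAsFactors = FALSE))
  grp <- groups$group[match(per$patient_id, groups$patient_id)]
  if (anyNA(grp)) {
    stop("mutation(s) from patient(s) missing in groups: ",
         paste(unique(per$patient_id[is.na(grp)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(grp, levels = names(sizes)))
  data.frame(
    group = names(sizes),
    n_patients = as.integer(sizes),
    n_mutations = as.integer(counts),
    load = round_half_up(as.integer(counts) / as.integer(sizes), digits),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
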