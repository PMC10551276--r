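## helper: per-patient sets of mutation keys from a catalog data.frame
keys_by_patient <- function(catalog) {
  if (is.null(catalog) || nrow(catalog) == 0L) return(list())
  key <- mutation_key(catalog$position, catalog$ref_base, catalog$alt_base)
  lapply(split(key, catalog$patient_id), unique)
}

#' Tumor-to-EV traceability of somatic mutations
#'
#' For each patient with an EV profile, intersects the tumor somatic
#' mutation set with the EV mutation set (matching by exact
#' position/ref/alt key). EV or tumor mutations also present in the
#' patient's matched normal are treated as germline carry-over and
#' excluded. The pooled traceability is the share of the union of
#' tumor mutations (across EV-bearing patients) found in the
#' corresponding EVs — a 17-of-45-style percentage — not a mean of
#' per-patient fractions, which are reported alongside.
#'
#' @param tumor_mutations annotated catalog of somatic tumor mutations
#'   (`patient_id`, `position`, `ref_base`, `alt_base`, ...).
#' @param ev_mutations catalog of filtered EV variant observations for
#'   the same patients (same columns; only patients present here count
#'   as EV-bearing).
#' @param normal_mutations optional catalog of matched-normal variants
#'   used to strip germline carry-over from both sides.
#' @return list of class `concordance_result`: `per_patient`
#'   (data.frame with `patient_id`, `tumor_mutation_count`,
#'   `ev_detected_count`, `fraction`, `any_detected`),
#'   `pooled_tumor_count`, `pooled_detected_count`,
#'   `traceability_pct`, `all_patients_detected`, `traceable_keys`.
#' @export
traceability <- function(tumor_mutations, ev_mutations,
                         normal_mutations = NULL) {
  ev_sets <- keys_by_patient(ev_mutations)
  if (length(ev_sets) == 0L) {
    stop("no EV-bearing patients: traceability is undefined", call. = FALSE)
  }
  tumor_sets <- keys_by_patient(tumor_mutations)
  normal_sets <- keys_by_patient(normal_mutations)
  patients <- names(ev_sets)
  rows <- list()
  traceable_all <- character()
  tumor_all <- character()
  for (pid in patients) {
    tum <- setdiff(tumor_sets[[pid]], normal_sets[[pid]])
    ev <- setdiff(ev_sets[[pid]], normal_sets[[pid]])
    tr <- intersect(tum, ev)
    traceable_all <- union(traceable_all, tr)
    tumor_all <- union(tumor_all, tum)
    rows[[pid]] <- data.frame(
      patient_id = pid,
      tumor_mutation_count = length(tum),
      ev_detected_count = length(tr),
      fraction = if (length(tum)) length(tr) / length(tum) else NA_real_,
      any_detected = length(tr) > 0L,
      stringsAsFactors = FALSE)
  }
  per_patient <- do.call(rbind, rows)
  rownames(per_patient) <- NULL
  structure(list(
    per_patient = per_patient,
    pooled_tumor_count = length(tumor_all),
    pooled_detected_count = length(traceable_all),
    traceability_pct = if (length(tumor_all))
      pct(length(traceable_all), length(tumor_all)) else NA_real_,
    all_patients_detected = all(per_patient$any_detected),
    traceable_keys = sort(traceable_all)
  ), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("<concordance_result> %d/%d tumor mutations traceable in EVs (%s%%) across %d patients\n",
              x$pooled_detected_count, x$pooled_tumor_count,
              format(x$traceability_pct), nrow(x$per_patient)))
  invisible(x)
}

#' Hotspot-panel detection rate in EVs
#'
#' Share of panel mutations detectable in at least one EV profile.
#'
#' @param panel data.frame with `position`, `ref_base`, `alt_base`
#'   (e.g. [hotspot_panel()] output or [default_hotspot_panel()]).
#' @param ev_mutations catalog of EV variant observations.
#' @return list `panel_size`, `detected_count`, `detection_pct`,
#'   `detected_keys`.
#' @export
panel_detection_rate <- function(panel, ev_mutations) {
  if (is.null(panel) || nrow(panel) == 0L) {
    stop("panel must be nonempty", call. = FALSE)
  }
  panel_keys <- unique(mutation_key(panel$position, panel$ref_base,
                                    panel$alt_base))
  ev_keys <- if (nrow(ev_mutations))
    unique(mutation_key(ev_mutations$position, ev_mutations$ref_base,
                        ev_mutations$alt_base)) else character()
  detected <- intersect(panel_keys, ev_keys)
  list(panel_size = length(panel_keys),
       detected_count = length(detected),
       detection_pct = pct(length(detected), length(panel_keys)),
       detected_keys = sort(detected))
}

#' EV-exclusive mutations
#'
#' Distinct mutations observed in EV profiles but absent from both the
#' patients' tumor and matched-normal sets, annotated with gene,
#' region class, complex and substitution class, and flagged for
#' novelty/pathogenicity against the known-variant table.
#' Comparison is per patient: an EV mutation is exclusive only if the
#' same patient's tumor and normal lack it; the returned catalog is
#' the per-patient exclusive set (distinct keys may recur across
#' patients).
#'
#' @param ev_mutations,tumor_mutations,normal_mutations catalogs with
#'   `patient_id`, `position`, `ref_base`, `alt_base` (and read
#'   columns for the EV side if available).
#' @param known known-variant table (see [read_known_variants()]).
#' @param config a [filter_config()] for heteroplasmy annotation when
#'   read counts are present.
#' @return annotated catalog of EV-only mutations (possibly 0 rows).
#' @export
ev_exclusive <- function(ev_mutations, tumor_mutations,
                         normal_mutations = NULL,
                         known = read_known_variants(),
                         config = filter_config()) {
  if (nrow(ev_mutations) == 0L) {
    return(flag_known(annotate_mutations(empty_observations(),
                                         NA_character_, config), known))
  }
  tumor_sets <- keys_by_patient(tumor_mutations)
  normal_sets <- keys_by_patient(normal_mutations)
  key <- mutation_key(ev_mutations$position, ev_mutations$ref_base,
                      ev_mutations$alt_base)
  keep <- vapply(seq_len(nrow(ev_mutations)), function(i) {
    pid <- ev_mutations$patient_id[i]
    !(key[i] %in% tumor_sets[[pid]]) && !(key[i] %in% normal_sets[[pid]])
  }, TRUE)
  sel <- ev_mutations[keep, , drop = FALSE]
  sel <- sel[!duplicated(paste(sel$patient_id,
                               mutation_key(sel$position, sel$ref_base,
                                            sel$alt_base))), , drop = FALSE]
  has_reads <- all(c("total_depth", "ref_reads", "alt_reads") %in% names(sel))
  out <- if (has_reads) {
    do.call(rbind, lapply(split(sel, seq_len(nrow(sel))), function(r) {
      annotate_mutations(r[c("position", "ref_base", "alt_base",
                             "total_depth", "ref_reads", "alt_reads")],
                         r$patient_id, config, source_tissues = "EV")
    }))
  } else {
    ann <- annotate_positions(sel)
    ann$source_tissues <- rep("EV", nrow(ann))
    ann
  }
  out <- flag_known(out, known)
  out$ev_exclusive <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

## annotation without read-count fields (for key-only catalogs)
annotate_positions <- function(df) {
  if (nrow(df) == 0L) {
    return(annotate_mutations(empty_observations(), NA_character_))
  }
  loc <- locate_position(df$position)
  if (is.list(loc) && !is.data.frame(loc)) {
    loc <- data.frame(primary_feature = loc$primary_feature,
                      region_class = loc$region_class,
                      complex = loc$complex, stringsAsFactors = FALSE)
  }
  data.frame(
    patient_id = df$patient_id,
    position = df$position,
    ref_base = df$ref_base,
    alt_base = df$alt_base,
    gene = loc$primary_feature,
    region_class = loc$region_class,
    complex = loc$complex,
    substitution_class = classify_substitution(df$ref_base, df$alt_base),
    maf_percent = NA_real_,
    alt_fraction = NA_real_,
    heteroplasmy = NA_character_,
    source_tissues = "EV",
    stringsAsFactors = FALSE
  )
}
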