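#' Build an annotated catalog with a prescribed composition
#'
#' Constructs a deterministic catalog of distinct annotated mutations
#' whose per-region composition, transition/transversion split,
#' homoplasmic count and pathogenicity breakdown are given as counts.
#' Useful for worked examples and tests that start from published
#' aggregate tables rather than raw variant calls: the resulting
#' catalog feeds [spectrum_summary()], [mutational_load()] and friends,
#' which recompute every share from it.
#'
#' Positions are the first coordinates of each gene whose primary
#' feature is that gene (so overlap regions never leak counts into a
#' neighbour). Pseudo-region names `"tRNA"`, `"control"` place counts
#' across tRNA genes (round-robin) or the control region.
#'
#' @param per_gene named integer vector: counts per gene name (e.g.
#'   `c("MT-ND1" = 20, RNR1 = 12, tRNA = 20, control = 4)`).
#' @param n_transversions how many catalog rows are transversions
#'   (assigned to the first rows in map order); the rest are
#'   transitions.
#' @param n_homoplasmic how many rows (first rows in map order) are
#'   homoplasmic; the rest heteroplasmic.
#' @param pathogenic_by optional named vector of counts per label,
#'   where a label is a complex (`"RCI"`), a category (`"tRNA"`) or a
#'   gene name; flags the first matching rows pathogenic.
#' @param novel_by like `pathogenic_by`, for the novel flag.
#' @param patient_id patient label for all rows (spectrum statistics
#'   only use distinct mutations, so one pseudo-patient suffices).
#' @return annotated mutation data.frame as from [call_somatic()],
#'   plus `novel`/`pathogenic` columns when requested.
#' @examples
#' cat168 <- build_composition_catalog(
#'   c("MT-ND1" = 2, "MT-CYTB" = 1, RNR2 = 1), n_transversions = 1)
#' spectrum_summary(cat168, n_patients = 1)
#' @export
build_composition_catalog <- function(per_gene,
                                      n_transversions = 0L,
                                      n_homoplasmic = 0L,
                                      pathogenic_by = NULL,
                                      novel_by = NULL,
                                      patient_id = "COHORT") {
  rows <- list()
  trna_genes <- unique(.mito_gene_map$name[.mito_gene_map$category == "tRNA"])
  for (label in names(per_gene)) {
    k <- per_gene[[label]]
    if (k == 0L) next
    genes <- switch(label,
                    tRNA = rep(trna_genes, length.out = k),
                    control = rep("CONTROL", k),
                    rep(label, k))
    ## spread round-robin, then take positions gene by gene
    for (g in unique(genes)) {
      kk <- sum(genes == g)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, position = gene_positions(g, kk),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  n <- nrow(df)
  stopifnot(n_transversions <= n, n_homoplasmic <= n)
  if (anyDuplicated(df$position)) {
    stop("internal: duplicated positions in composition catalog",
         call. = FALSE)
  }
  is_tv <- seq_len(n) <= n_transversions
  df$ref_base <- ifelse(is_tv, "T", "G")
  df$alt_base <- ifelse(is_tv, "G", "A")
  loc <- locate_position(df$position)
  stopifnot(identical(loc$primary_feature, df$gene))
  hom <- seq_len(n) <= n_homoplasmic
  out <- data.frame(
    patient_id = patient_id,
    position = df$position,
    ref_base = df$ref_base,
    alt_base = df$alt_base,
    gene = loc$primary_feature,
    region_class = loc$region_class,
    complex = loc$complex,
    substitution_class = classify_substitution(df$ref_base, df$alt_base),
    maf_percent = ifelse(hom, NA_real_, 100),
    alt_fraction = ifelse(hom, 1, 0.5),
    heteroplasmy = ifelse(hom, "homoplasmic", "heteroplasmic"),
    source_tissues = "tumor",
    stringsAsFactors = FALSE
  )
  label_of <- function(cat, cx, gene) {
    ifelse(cx != "none", cx,
           ifelse(cat %in% c("tRNA", "rRNA", "control"), cat, gene))
  }
  cat_of <- vapply(out$gene, function(g) {
    if (g == "INTERGENIC") "intergenic" else
      .mito_gene_map$category[match(g, .mito_gene_map$name)]
  }, "")
  for (flag in c("pathogenic", "novel")) {
    spec <- if (flag == "pathogenic") pathogenic_by else novel_by
    if (is.null(spec)) next
    v <- logical(n)
    for (lbl in names(spec)) {
      cand <- which(out$complex == lbl | cat_of == lbl | out$gene == lbl)
      if (length(cand) < spec[[lbl]]) {
        stop("not enough rows in region ", lbl, " to flag ", flag,
             call. = FALSE)
      }
      v[cand[seq_len(spec[[lbl]])]] <- TRUE
    }
    out[[flag]] <- v
  }
  rownames(out) <- NULL
  out
}

## the first k positions of a gene whose primary feature is that gene
gene_positions <- function(gene, k) {
  segs <- .mito_gene_map[.mito_gene_map$name == gene, , drop = FALSE]
  if (nrow(segs) == 0L) stop("unknown gene: ", gene, call. = FALSE)
  cand <- unlist(lapply(seq_len(nrow(segs)),
                        function(i) segs$start[i]:segs$end[i]))
  ## restrict to positions where this gene wins the primary tie-break
  prim <- vapply(cand, function(p) locate_position(p)$primary_feature, "")
  cand <- cand[prim == gene]
  if (length(cand) < k) {
    stop("gene ", gene, " has only ", length(cand),
         " primary positions, need ", k, call. = FALSE)
  }
  cand[seq_len(k)]
}

#' Bundled hotspot-panel fixture
#'
#' The named members of the recurrent ("hotspot") mtDNA mutation panel
#' used in the worked examples, with their cohort frequencies: four
#' MT-ND1 mutations (A3520C, T3572A, T3599A, T3605A), A10935G (MT-ND4),
#' T7953G (MT-CO2), T14894G (MT-CYTB) and T4434G (tRNA-Met). A full
#' panel may add further entries; the table is a plain TSV under
#' `inst/extdata` and can be replaced by the user.
#'
#' @return data.frame `position`, `ref_base`, `alt_base`, `gene`,
#'   `frequency`.
#' @export
default_hotspot_panel <- function() {
  path <- system.file("extdata", "hotspot_panel_tnbc.tsv",
                      package = "mitosomatic", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$position <- as.integer(df$position)
  df
}
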