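#' The rCRS mitochondrial gene map
#'
#' Feature table of the revised Cambridge Reference Sequence
#' (rCRS, NC_012920.1, 16,569 bp): the 13 protein-coding genes, 22 tRNAs,
#' 2 rRNAs and the control region (D-loop), with strand, category and
#' respiratory-complex assignment. Coordinates are 1-based inclusive.
#' The control region wraps the origin and is stored as two segments
#' (16024-16569 and 1-576) sharing the name `CONTROL`. Known gene
#' overlaps (MT-ATP8/MT-ATP6, MT-ND4L/MT-ND4, MT-ATP6/MT-CO3,
#' TRNI/TRNQ, TRNC/TRNY) are preserved.
#'
#' Respiratory complexes: RCI = MT-ND1/2/3/4/4L/5/6, RCIII = MT-CYTB,
#' RCIV = MT-CO1/2/3, RCV = MT-ATP6/8. Non-protein features have
#' complex `none`.
#'
#' @return A data.frame with columns `name`, `start`, `end`, `strand`
#'   (`heavy`/`light`), `category` (`protein`, `tRNA`, `rRNA`,
#'   `control`), and `complex` (`RCI`, `RCIII`, `RCIV`, `RCV`, `none`),
#'   one row per feature segment (39 rows: 37 genes + 2 control-region
#'   segments).
#' @examples
#' map <- mito_gene_map()
#' subset(map, complex == "RCI")
#' @export
mito_gene_map <- function() {
  .mito_gene_map
}

# NC_012920.1 feature coordinates, 1-based inclusive.
.mito_gene_map <- local({
  f <- function(name, start, end, strand, category, complex = "none") {
    data.frame(name = name, start = as.integer(start), end = as.integer(end),
               strand = strand, category = category, complex = complex,
               stringsAsFactors = FALSE)
  }
  rbind(
    f("CONTROL", 16024, 16569, "heavy", "control"),
    f("CONTROL",     1,   576, "heavy", "control"),
    f("TRNF",      577,   647, "heavy", "tRNA"),
    f("RNR1",      648,  1601, "heavy", "rRNA"),
    f("TRNV",     1602,  1670, "heavy", "tRNA"),
    f("RNR2",     1671,  3229, "heavy", "rRNA"),
    f("TRNL1",    3230,  3304, "heavy", "tRNA"),
    f("MT-ND1",   3307,  4262, "heavy", "protein", "RCI"),
    f("TRNI",     4263,  4331, "heavy", "tRNA"),
    f("TRNQ",     4329,  4400, "light", "tRNA"),
    f("TRNM",     4402,  4469, "heavy", "tRNA"),
    f("MT-ND2",   4470,  5511, "heavy", "protein", "RCI"),
    f("TRNW",     5512,  5579, "heavy", "tRNA"),
    f("TRNA",     5587,  5655, "light", "tRNA"),
    f("TRNN",     5657,  5729, "light", "tRNA"),
    f("TRNC",     5761,  5826, "light", "tRNA"),
    f("TRNY",     5826,  5891, "light", "tRNA"),
    f("MT-CO1",   5904,  7445, "heavy", "protein", "RCIV"),
    f("TRNS1",    7446,  7514, "light", "tRNA"),
    f("TRND",     7518,  7585, "heavy", "tRNA"),
    f("MT-CO2",   7586,  8269, "heavy", "protein", "RCIV"),
    f("TRNK",     8295,  8364, "heavy", "tRNA"),
    f("MT-ATP8",  8366,  8572, "heavy", "protein", "RCV"),
    f("MT-ATP6",  8527,  9207, "heavy", "protein", "RCV"),
    f("MT-CO3",   9207,  9990, "heavy", "protein", "RCIV"),
    f("TRNG",     9991, 10058, "heavy", "tRNA"),
    f("MT-ND3",  10059, 10404, "heavy", "protein", "RCI"),
    f("TRNR",    10405, 10469, "heavy", "tRNA"),
    f("MT-ND4L", 10470, 10766, "heavy", "protein", "RCI"),
    f("MT-ND4",  10760, 12137, "heavy", "protein", "RCI"),
    f("TRNH",    12138, 12206, "heavy", "tRNA"),
    f("TRNS2",   12207, 12265, "heavy", "tRNA"),
    f("TRNL2",   12266, 12336, "heavy", "tRNA"),
    f("MT-ND5",  12337, 14148, "heavy", "protein", "RCI"),
    f("MT-ND6",  14149, 14673, "light", "protein", "RCI"),
    f("TRNE",    14674, 14742, "light", "tRNA"),
    f("MT-CYTB", 14747, 15887, "heavy", "protein", "RCIII"),
    f("TRNT",    15888, 15953, "heavy", "tRNA"),
    f("TRNP",    15956, 16023, "light", "tRNA")
  )
})

#' Map an rCRS position to its gene and region class
#'
#' Finds every feature whose interval contains `position`. Positions in
#' none (the short intergenic spacers, e.g. 8270-8294 between MT-CO2 and
#' TRNK) are reported as `INTERGENIC`. Where features overlap (e.g. the
#' MT-ATP8/MT-ATP6 frame overlap at 8527-8572), the primary feature is
#' the one with the smaller start coordinate; all overlapping features
#' are returned so callers can re-count per gene if they wish.
#'
#' The region class follows the coding/noncoding dichotomy used in
#' mtDNA mutation profiling: `coding` only for protein genes;
#' control region, rRNA, tRNA and intergenic positions are `noncoding`.
#'
#' @param position integer rCRS coordinate(s) in 1..16569.
#' @return For a single position, a list with `position`,
#'   `primary_feature`, `all_features`, `category`, `region_class`
#'   (`coding`/`noncoding`), `complex` and `strand`. For a vector, a
#'   data.frame with one row per position (`all_features` collapsed
#'   with `,`).
#' @examples
#' locate_position(3842)   # MT-ND1, coding, RCI
#' locate_position(4434)   # TRNM (tRNA-Met), noncoding
#' locate_position(8550)   # MT-ATP8/MT-ATP6 overlap
#' @export
locate_position <- function(position) {
  position <- check_position(position)
  map <- .mito_gene_map
  one <- function(p) {
    hit <- map[map$start <= p & p <= map$end, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(list(position = p, primary_feature = "INTERGENIC",
                  all_features = "INTERGENIC", category = "noncoding-other",
                  region_class = "noncoding", complex = "none",
                  strand = "heavy"))
    }
    hit <- hit[order(hit$start), , drop = FALSE]
    ## the two CONTROL segments share one name; report it once
    primary <- hit[1L, ]
    list(position = p,
         primary_feature = primary$name,
         all_features = unique(hit$name),
         category = primary$category,
         region_class = if (primary$category == "protein") "coding" else "noncoding",
         complex = primary$complex,
         strand = primary$strand)
  }
  if (length(position) == 1L) return(one(position))
  rows <- lapply(position, one)
  data.frame(
    position = vapply(rows, `[[`, 1L, "position"),
    primary_feature = vapply(rows, `[[`, "", "primary_feature"),
    all_features = vapply(rows, function(r) paste(r$all_features, collapse = ","), ""),
    category = vapply(rows, `[[`, "", "category"),
    region_class = vapply(rows, `[[`, "", "region_class"),
    complex = vapply(rows, `[[`, "", "complex"),
    strand = vapply(rows, `[[`, "", "strand"),
    stringsAsFactors = FALSE
  )
}

#' Respiratory-complex assignment of a gene
#'
#' @param feature_name feature name as in [mito_gene_map()]
#'   (e.g. `"MT-ND5"`, `"MT-CYTB"`, `"RNR2"`).
#' @return `"RCI"`, `"RCIII"`, `"RCIV"` or `"RCV"` for the 13
#'   protein genes; `"none"` for all other features.
#' @examples
#' assign_complex("MT-ND5")   # "RCI"
#' assign_complex("MT-CYTB")  # "RCIII"
#' @export
assign_complex <- function(feature_name) {
  map <- .mito_gene_map
  idx <- match(feature_name, map$name)
  if (anyNA(idx)) {
    stop("unknown feature(s): ",
         paste(feature_name[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  map$complex[idx]
}

#' Classify a substitution as transition or transversion
#'
#' Purine<->purine (A/G) and pyrimidine<->pyrimidine (C/T) changes are
#' transitions; purine<->pyrimidine changes are transversions. Of the 12
#' ordered substitution classes, 4 are transitions and 8 transversions.
#'
#' @param ref_base,alt_base single bases in A/C/G/T; vectors recycle.
#' @return character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("G", "A")  # transition
#' classify_substitution("T", "G")  # transversion
#' @export
classify_substitution <- function(ref_base, alt_base) {
  check_bases(ref_base, alt_base)
  purine <- c("A", "G")
  ifelse((ref_base %in% purine) == (alt_base %in% purine),
         "transition", "transversion")
}

#' Export the gene map as BED intervals
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention. Intended for interoperability with genome
#' browsers and interval tools.
#'
#' @param path optional file to write; when `NULL`, the BED
#'   data.frame is returned invisibly without writing.
#' @return (invisibly) a data.frame with `chrom`, `chromStart`,
#'   `chromEnd`, `name`, `score`, `strand` columns.
#' @export
gene_map_bed <- function(path = NULL) {
  map <- .mito_gene_map
  bed <- data.frame(
    chrom = "chrM",
    chromStart = map$start - 1L,
    chromEnd = map$end,
    name = map$name,
    score = 0L,
    strand = ifelse(map$strand == "heavy", "+", "-"),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(bed)
}

#' Read a mitochondrial reference sequence from FASTA
#'
#' Reads a single-record FASTA and validates that it has the rCRS
#' length (16,569 bp).
#'
#' @param path FASTA file with one 16,569 bp record.
#' @return a character scalar, the uppercase genome sequence.
#' @export
read_reference_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) != 1L) {
    stop("expected a single-record FASTA, found ", length(set), " records",
         call. = FALSE)
  }
  seq <- toupper(as.character(set[[1L]]))
  if (nchar(seq) != MT_GENOME_LENGTH) {
    stop("reference length ", nchar(seq), " != ", MT_GENOME_LENGTH,
         " (rCRS)", call. = FALSE)
  }
  seq
}

#' Synthetic stand-in for the rCRS sequence
#'
#' Generates a deterministic random 16,569 bp sequence as a synthetic
#' stand-in for the true rCRS nucleotide sequence, for tests and
#' simulations that need a concrete reference. It is NOT the real
#' NC_012920.1 sequence; analyses of real data should pass the genuine
#' rCRS FASTA to [read_reference_fasta()] instead. Specific reference
#' bases can be pinned via `constraints` so that named mutation keys
#' (e.g. `T7953G` needing a `T` at 7953) are consistent with it.
#'
#' @param seed integer seed fixing the sequence.
#' @param constraints optional data.frame with columns `position` and
#'   `ref_base`; those positions are set to the given bases.
#' @return a character scalar of length 16,569.
#' @export
synthetic_reference <- function(seed = 101L, constraints = NULL) {
  bases <- c("A", "C", "G", "T")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  s <- sample(bases, MT_GENOME_LENGTH, replace = TRUE,
              prob = c(0.31, 0.31, 0.13, 0.25))  # mtDNA-like base bias
  if (!is.null(constraints)) {
    pos <- check_position(constraints$position)
    s[pos] <- constraints$ref_base
  }
  paste(s, collapse = "")
}

## save/restore the global RNG state so helpers do not disturb callers
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
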