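## Vertebrate mitochondrial genetic code (NCBI translation table 2).
## Differs from the standard code at: AGA/AGG = Stop, ATA = Met, TGA = Trp.
.mito_codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CCWW",   # TTT..TGG
    "LLLLPPPPHHQQRRRR",   # CTT..CGG
    "IIMMTTTTNNKKSS**",   # ATT..AGG (ATA=Met, AGA/AGG=Stop)
    "VVVVAAAADDEEGGGG"),  # GTT..GGG
    "")[[1L]]
  stats::setNames(aa, codons)
})

#' Translate codons with the vertebrate mitochondrial code
#'
#' @param codon character vector of 3-base DNA codons.
#' @return one-letter amino acids; `*` for stop codons.
#' @examples
#' translate_codon_mito(c("ATA", "TGA", "AGA"))  # "M" "W" "*"
#' @export
translate_codon_mito <- function(codon) {
  codon <- toupper(codon)
  bad <- !codon %in% names(.mito_codon_table)
  if (any(bad)) {
    stop("not valid DNA codons: ", paste(codon[bad], collapse = ", "),
         call. = FALSE)
  }
  unname(.mito_codon_table[codon])
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

#' Codon-level effect of a substitution in a protein gene
#'
#' Locates the codon containing `position` within its protein gene,
#' extracts the reference and mutant codons, and translates both with
#' the vertebrate mitochondrial genetic code. For the light-strand gene
#' (MT-ND6) the coding sequence is the reverse complement of the
#' heavy-strand reference, so the codon frame runs from the gene's 3'
#' (heavy-strand `end`) coordinate and input bases — which follow the
#' heavy-strand `<ref><position><alt>` notation — are complemented.
#'
#' Several mitochondrial genes end in an incomplete stop codon completed
#' by polyadenylation of the transcript; a substitution falling in such
#' a partial terminal codon gets `NA` amino-acid fields.
#'
#' When no reference sequence is supplied the call degrades gracefully:
#' gene and codon index are still reported, amino-acid fields are `NA`.
#'
#' @param position rCRS coordinate inside a protein gene.
#' @param ref_base,alt_base heavy-strand bases of the substitution.
#' @param reference_sequence the rCRS sequence as a character scalar
#'   (see [read_reference_fasta()]), or `NULL`.
#' @param gene which gene to use when the position lies in an overlap
#'   (e.g. MT-ATP8/MT-ATP6); default is the primary feature.
#' @return list with `gene`, `codon_index`, `ref_codon`, `alt_codon`,
#'   `ref_aa`, `alt_aa`, `synonymous`.
#' @export
coding_effect <- function(position, ref_base, alt_base,
                          reference_sequence = NULL, gene = NULL) {
  position <- check_position(position)
  stopifnot(length(position) == 1L)
  check_bases(ref_base, alt_base)
  loc <- locate_position(position)
  if (is.null(gene)) {
    if (loc$region_class != "coding") {
      stop("position ", position, " is not in a protein gene (",
           loc$primary_feature, "); no codon effect applies", call. = FALSE)
    }
    gene <- loc$primary_feature
  } else {
    if (!gene %in% loc$all_features) {
      stop("position ", position, " is not inside ", gene, call. = FALSE)
    }
  }
  map <- .mito_gene_map
  feat <- map[map$name == gene, ]
  stopifnot(nrow(feat) == 1L, feat$category == "protein")

  if (feat$strand == "heavy") {
    offset <- position - feat$start           # 0-based within CDS
  } else {
    offset <- feat$end - position
  }
  codon_index <- offset %/% 3L + 1L
  within <- offset %% 3L                      # 0,1,2 position inside codon

  out <- list(gene = gene, codon_index = codon_index,
              ref_codon = NA_character_, alt_codon = NA_character_,
              ref_aa = NA_character_, alt_aa = NA_character_,
              synonymous = NA)
  if (is.null(reference_sequence)) return(out)

  seq <- toupper(reference_sequence)
  if (nchar(seq) != MT_GENOME_LENGTH) {
    stop("reference_sequence must be the full ", MT_GENOME_LENGTH,
         " bp genome", call. = FALSE)
  }
  if (substr(seq, position, position) != ref_base) {
    stop("ref_base ", ref_base, " does not match the reference (",
         substr(seq, position, position), ") at position ", position,
         call. = FALSE)
  }

  if (feat$strand == "heavy") {
    codon_start <- feat$start + 3L * (codon_index - 1L)
    codon_pos <- codon_start + 0:2
  } else {
    codon_hi <- feat$end - 3L * (codon_index - 1L)
    codon_pos <- codon_hi - (0:2)             # genome coords, 5'->3' on light
  }
  if (any(codon_pos < feat$start) || any(codon_pos > feat$end)) {
    ## partial terminal codon (stop completed by polyadenylation)
    return(out)
  }
  fetch <- function(p) substr(seq, p, p)
  ref_codon_bases <- vapply(codon_pos, fetch, "")
  alt_codon_bases <- ref_codon_bases
  slot <- which(codon_pos == position)
  alt_codon_bases[slot] <- alt_base
  if (feat$strand == "light") {
    ref_codon_bases <- chartr("ACGT", "TGCA", ref_codon_bases)
    alt_codon_bases <- chartr("ACGT", "TGCA", alt_codon_bases)
  }
  out$ref_codon <- paste(ref_codon_bases, collapse = "")
  out$alt_codon <- paste(alt_codon_bases, collapse = "")
  out$ref_aa <- translate_codon_mito(out$ref_codon)
  out$alt_aa <- translate_codon_mito(out$alt_codon)
  out$synonymous <- out$ref_aa == out$alt_aa
  out
}
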