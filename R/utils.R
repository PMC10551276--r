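#' Round half away from zero
#'
#' Base `round()` rounds half to even (banker's rounding); cohort reports
#' instead round halves up so that 37.5% prints as 38%.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(37.5)  # 38
#' round_half_up(2.5)   # 3, where round(2.5) is 2
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

## integer percent with the package-wide rounding policy
pct <- function(count, denom) {
  stopifnot(denom > 0)
  round_half_up(count / denom * 100)
}

MT_GENOME_LENGTH <- 16569L

check_position <- function(position) {
  if (!is.numeric(position) || anyNA(position) ||
      any(position < 1) || any(position > MT_GENOME_LENGTH) ||
      any(position != floor(position))) {
    stop("position must be an integer coordinate in 1..", MT_GENOME_LENGTH,
         call. = FALSE)
  }
  as.integer(position)
}

check_bases <- function(ref_base, alt_base) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref_base %in% bases) || !all(alt_base %in% bases)) {
    stop("ref_base and alt_base must be single bases in {A,C,G,T}",
         call. = FALSE)
  }
  if (any(ref_base == alt_base)) {
    stop("ref_base and alt_base must differ", call. = FALSE)
  }
  invisible(TRUE)
}

## canonical string key for a substitution, e.g. "T7953G"
mutation_key <- function(position, ref_base, alt_base) {
  paste0(ref_base, position, alt_base)
}

## split "T7953G"-style keys into their components
parse_mutation_key <- function(key) {
  m <- regmatches(key, regexec("^([ACGT])([0-9]+)([ACGT])$", key))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("malformed mutation key(s): ", paste(key[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    position = as.integer(vapply(m, `[`, "", 3L)),
    ref_base = vapply(m, `[`, "", 2L),
    alt_base = vapply(m, `[`, "", 4L),
    stringsAsFactors = FALSE
  )
}
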