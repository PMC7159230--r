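#' Round half away from zero
#'
#' Fixed-point rounding with ties going up (2.5 -> 3), the convention used for
#' the printed percentages in recombination frequency tables. Base R's
#' `round()` rounds half to even, which disagrees on exact .005 ties.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Union length of a set of 1-based inclusive intervals.
interval_union_bp <- function(start, end) {
  if (length(start) == 0L) return(0L)
  sum(IRanges::width(IRanges::reduce(IRanges::IRanges(start = start, end = end))))
}

# Reduce intervals to disjoint sorted form; returns a tibble(start, end).
interval_reduce <- function(start, end) {
  if (length(start) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  r <- IRanges::reduce(IRanges::IRanges(start = start, end = end))
  tibble::tibble(start = IRanges::start(r), end = IRanges::end(r))
}

# Reverse complement of a plain character DNA string (IUPAC-aware).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
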