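#' Extract intergenic spacers
#'
#' The spacer set is the complement of the union of all annotated gene
#' intervals: every genome position covered by no feature. Exons and introns
#' both count as genic, so spliced genes remove their whole span only if an
#' enclosing `gene` feature (or the intron features) cover the intron too.
#'
#' @param genome an [mt_genome()]
#' @param features feature tibble from [load_features()] (may be empty)
#' @return an object of class `spacer_set`: list with `intervals` (tibble of
#'   disjoint sorted `start`/`end`), `total_bp`, `fraction_of_genome`, and
#'   `genome_length`
#' @export
extract_spacers <- function(genome, features) {
  stopifnot(inherits(genome, "mt_genome"))
  ivs <- feature_intervals(features)
  if (nrow(ivs) > 0 && (min(ivs$start) < 1 || max(ivs$end) > genome$length)) {
    stop("feature intervals extend beyond genome bounds")
  }
  gen <- IRanges::IRanges(start = 1L, end = genome$length)
  if (nrow(ivs) == 0L) {
    sp <- gen
  } else {
    sp <- IRanges::setdiff(gen, IRanges::IRanges(ivs$start, ivs$end))
  }
  total <- sum(IRanges::width(sp))
  structure(
    list(
      intervals = tibble::tibble(
        start = IRanges::start(sp), end = IRanges::end(sp)
      ),
      total_bp = total,
      fraction_of_genome = total / genome$length,
      genome_length = genome$length
    ),
    class = "spacer_set"
  )
}

#' @export
print.spacer_set <- function(x, ...) {
  cat(sprintf(
    "<spacer_set> %d intervals, %s bp (%.1f%% of genome)\n",
    nrow(x$intervals), format(x$total_bp, big.mark = ","),
    100 * x$fraction_of_genome
  ))
  invisible(x)
}

# Flatten the list column of interval matrices into one tibble.
feature_intervals <- function(features) {
  if (nrow(features) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  m <- do.call(rbind, features$intervals)
  tibble::tibble(start = m[, "start"], end = m[, "end"])
}

#' Write a spacer set as TSV
#'
#' @param spacers a `spacer_set`
#' @param path output file
#' @return `path` invisibly
#' @export
write_spacers_tsv <- function(spacers, path) {
  utils::write.table(spacers$intervals, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

#' Extract spacer sequences
#'
#' @param genome an [mt_genome()]
#' @param spacers a `spacer_set` on that genome
#' @return named character vector, one element per spacer interval, names
#'   `start-end`
#' @export
spacer_seqs <- function(genome, spacers) {
  iv <- spacers$intervals
  out <- substring(genome$seq, iv$start, iv$end)
  names(out) <- paste0(iv$start, "-", iv$end)
  out
}
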