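# Long-read support counting for conformation references.
#
# A read supports a reference when a single local alignment (either strand)
# exceeds the identity threshold and covers the repeat plus a window of both
# flanks — reads that stop inside the repeat, or cover only one flank,
# cannot distinguish conformations and count for nothing. Each read is
# assigned to at most one reference per repeat pair: the one with its
# best-scoring qualifying alignment, ties broken toward the master role so
# the recombination call stays conservative.

#' Assemble a read-support result from counts
#'
#' Percentages are computed as `100 * count / (alternative + master)` and
#' rounded half-up to two decimals; both are `NA` when no read qualifies.
#' A pair is recombinationally active when at least one read supports an
#' alternative conformation.
#'
#' @param pair_id repeat pair identifier
#' @param reads_alternative count of reads supporting alternative conformations
#' @param reads_master count of reads supporting master conformations
#' @return one-row tibble: `pair_id`, `reads_alternative`, `reads_master`,
#'   `alt_percent`, `master_percent`, `active`
#' @export
read_support_result <- function(pair_id, reads_alternative, reads_master) {
  stopifnot(reads_alternative >= 0, reads_master >= 0)
  total <- reads_alternative + reads_master
  tibble::tibble(
    pair_id = pair_id,
    reads_alternative = as.integer(reads_alternative),
    reads_master = as.integer(reads_master),
    alt_percent = if (total > 0) round_half_up(100 * reads_alternative / total, 2) else NA_real_,
    master_percent = if (total > 0) round_half_up(100 * reads_master / total, 2) else NA_real_,
    active = reads_alternative >= 1
  )
}

# Qualifying alignments of reads against conformation references: best HSP
# rows passing identity and flank-coverage filters.
qualifying_alignments <- function(confs, reads, config) {
  refs <- confs$references
  if (length(reads) == 0L || nrow(refs) == 0L) {
    return(tibble::tibble(
      qseqid = character(), sseqid = character(), bitscore = numeric()
    ))
  }
  hits <- blast_hits(reads, stats::setNames(refs$seq, refs$name),
    evalue = config$homology_evalue
  )
  if (nrow(hits) == 0L) return(hits)
  w <- config$read_support_flank_cov
  ri <- match(hits$sseqid, refs$name)
  slo <- pmin(hits$sstart, hits$send)
  shi <- pmax(hits$sstart, hits$send)
  ok <- hits$pident > config$read_support_identity &
    slo <= refs$repeat_start[ri] - w &
    shi >= refs$repeat_end[ri] + w
  hits[ok, , drop = FALSE]
}

#' Does a read support a conformation reference?
#'
#' @param read a single DNA sequence (character)
#' @param ref one row of a `conformation_set`'s `references` tibble
#' @param config a [pipeline_config()]
#' @return `TRUE` iff a single local alignment of the read to the reference
#'   (either strand) exceeds `read_support_identity` percent identity and
#'   covers `read_support_flank_cov` bp of both repeat flanks
#' @export
read_supports_reference <- function(read, ref, config = pipeline_config()) {
  confs <- list(references = tibble::as_tibble(as.list(ref)[c(
    "name", "role", "seq", "repeat_start", "repeat_end"
  )]))
  hits <- qualifying_alignments(confs, c(read_1 = unname(read)), config)
  nrow(hits) > 0
}

#' Count reads supporting master vs alternative conformations
#'
#' @param confs a screened `conformation_set`
#' @param reads named character vector of long-read sequences
#' @param config a [pipeline_config()]
#' @return one-row tibble as [read_support_result()]
#' @export
count_read_support <- function(confs, reads, config = pipeline_config()) {
  stopifnot(inherits(confs, "conformation_set"))
  hits <- qualifying_alignments(confs, reads, config)
  if (nrow(hits) == 0L) {
    return(read_support_result(confs$pair$id %||% NA, 0L, 0L))
  }
  refs <- confs$references
  ri <- match(hits$sseqid, refs$name)
  hits$role <- refs$role[ri]
  hits$ref_index <- ri
  # one vote per read: best bitscore, ties toward master then lowest index
  hits <- hits[order(
    hits$qseqid, -hits$bitscore,
    hits$role != "master", hits$ref_index
  ), , drop = FALSE]
  best <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  read_support_result(
    confs$pair$id %||% NA,
    sum(best$role == "alternative"),
    sum(best$role == "master")
  )
}

#' Recombination frequency table for a set of repeat pairs
#'
#' Runs the full per-pair pipeline — conformation construction, genomic
#' screening of recombinants, read-support counting — and returns one row
#' per pair in descending repeat-length order, with the repeat coordinates
#' and direction alongside the read counts, mirroring the standard
#' recombination-frequency table layout.
#'
#' @param pairs a `repeat_pairs` tibble from [find_repeat_pairs()]
#' @param genome the [mt_genome()]
#' @param reads named character vector of long-read sequences
#' @param config a [pipeline_config()]
#' @return tibble with pair columns (`pair_id`, `length`, `identity`,
#'   `start1`, `end1`, `start2`, `end2`, `orientation`), the read-support
#'   columns of [read_support_result()], and `n_references` (post-screening)
#' @export
recombination_table <- function(pairs, genome, reads,
                                config = pipeline_config()) {
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(
      pair_id = integer(), length = integer(), identity = numeric(),
      start1 = integer(), end1 = integer(), start2 = integer(),
      end2 = integer(), orientation = character(),
      reads_alternative = integer(), reads_master = integer(),
      alt_percent = numeric(), master_percent = numeric(),
      active = logical(), n_references = integer()
    ))
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, , drop = FALSE]
    confs <- build_conformation_set(p, genome, config)
    confs <- screen_recombinants(confs, genome, config)
    rs <- count_read_support(confs, reads, config)
    dplyr::bind_cols(
      tibble::tibble(
        pair_id = p$id, length = p$length, identity = p$identity,
        start1 = p$start1, end1 = p$end1, start2 = p$start2, end2 = p$end2,
        orientation = p$orientation
      ),
      rs[, setdiff(names(rs), "pair_id")],
      tibble::tibble(n_references = nrow(confs$references))
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$length, out$start1), , drop = FALSE]
}

#' Write a recombination table as TSV
#'
#' @param tab output of [recombination_table()]
#' @param path output file
#' @return `path` invisibly
#' @export
write_recombination_tsv <- function(tab, path) {
  df <- data.frame(
    `Repeat no.` = tab$pair_id, `Repeat length` = tab$length,
    Identity = tab$identity,
    Start = tab$start1, End = tab$end1,
    Start2 = tab$start2, End2 = tab$end2,
    Direction = ifelse(tab$orientation == "direct", "Direct", "Inverted"),
    `Reads supporting alternative conformation` = sprintf(
      "%d (%.2f%%)", tab$reads_alternative, tab$alt_percent
    ),
    `Reads supporting master conformation` = sprintf(
      "%d (%.2f%%)", tab$reads_master, tab$master_percent
    ),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
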