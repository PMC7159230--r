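# Homology-segment annotation: plastid-derived insertions in mitochondrial
# spacers, inter-genome spacer sharing, and the gene content carried by each
# transferred segment.

#' Find homologous segments between a query genome (or its spacers) and a
#' subject genome
#'
#' Runs a blastn search at the configured e-value cutoff, maps hits to query
#' genome coordinates, and merges hits overlapping on the query into maximal
#' disjoint segments (the convention of plastid-insertion tables). Each
#' merged segment reports its best constituent hit's identity and e-value,
#' and the subject genes its hits overlap — suffixed `"(partial)"` when a
#' gene is not fully covered.
#'
#' @param query an [mt_genome()], or a list with `genome` (an [mt_genome()])
#'   and `spacers` (a `spacer_set`) to restrict the search to spacer regions
#' @param subject an [mt_genome()] (e.g. a plastome)
#' @param subject_features optional feature tibble from [load_features()]
#'   annotating the subject; used for `carried_features`
#' @param config a [pipeline_config()]
#' @return tibble with columns `segment`, `qstart`, `qend` (query genome
#'   coordinates, 1-based inclusive), `length`, `identity`, `evalue`,
#'   `sstart`, `send` (representative hit), `carried_features` (comma-joined
#'   string, `"None"` if empty)
#' @export
find_homologous_segments <- function(query, subject, subject_features = NULL,
                                     config = pipeline_config()) {
  if (inherits(query, "mt_genome")) {
    qseqs <- stats::setNames(query$seq, query$id)
    offsets <- stats::setNames(0L, query$id)
  } else {
    stopifnot(inherits(query$genome, "mt_genome"), inherits(query$spacers, "spacer_set"))
    seqs <- spacer_seqs(query$genome, query$spacers)
    # drop spacers too short to seed an alignment
    seqs <- seqs[nchar(seqs) >= 20]
    qseqs <- stats::setNames(unname(seqs), paste0("spacer_", names(seqs)))
    offsets <- stats::setNames(
      as.integer(sub("-.*", "", names(seqs))) - 1L,
      paste0("spacer_", names(seqs))
    )
  }
  if (nchar(subject$seq) == 0L || length(qseqs) == 0L) {
    return(empty_segments())
  }
  hits <- blast_hits(qseqs, stats::setNames(subject$seq, subject$id),
    evalue = config$homology_evalue
  )
  if (nrow(hits) == 0L) {
    return(empty_segments())
  }
  # map to query genome coordinates
  hits$gstart <- hits$qstart + offsets[hits$qseqid]
  hits$gend <- hits$qend + offsets[hits$qseqid]

  merged <- interval_reduce(hits$gstart, hits$gend)
  segs <- vector("list", nrow(merged))
  for (i in seq_len(nrow(merged))) {
    inseg <- hits$gstart <= merged$end[i] & hits$gend >= merged$start[i]
    h <- hits[inseg, , drop = FALSE]
    best <- h[order(-h$pident, h$evalue), , drop = FALSE][1, ]
    carried <- carried_feature_string(h, subject_features)
    segs[[i]] <- tibble::tibble(
      qstart = merged$start[i], qend = merged$end[i],
      length = merged$end[i] - merged$start[i] + 1L,
      identity = best$pident, evalue = best$evalue,
      sstart = min(best$sstart, best$send),
      send = max(best$sstart, best$send),
      carried_features = carried
    )
  }
  out <- dplyr::bind_rows(segs)
  out <- out[order(-out$length, out$qstart), , drop = FALSE]
  out <- tibble::add_column(out, segment = seq_len(nrow(out)), .before = 1)
  out
}

empty_segments <- function() {
  tibble::tibble(
    segment = integer(), qstart = integer(), qend = integer(),
    length = integer(), identity = numeric(), evalue = numeric(),
    sstart = numeric(), send = numeric(), carried_features = character()
  )
}

# Names of subject genes overlapped by any hit of a merged segment;
# "(partial)" when the union of hit subject-intervals does not cover the
# whole gene.
carried_feature_string <- function(hits, subject_features) {
  if (is.null(subject_features) || nrow(subject_features) == 0L) {
    return("None")
  }
  slo <- pmin(hits$sstart, hits$send)
  shi <- pmax(hits$sstart, hits$send)
  cover <- IRanges::reduce(IRanges::IRanges(slo, shi))
  labels <- character()
  for (i in seq_len(nrow(subject_features))) {
    f <- subject_features[i, ]
    iv <- f$intervals[[1]]
    gene_rng <- IRanges::IRanges(iv[, "start"], iv[, "end"])
    ov <- IRanges::intersect(gene_rng, cover)
    ov_bp <- sum(IRanges::width(ov))
    if (ov_bp == 0L) next
    full <- ov_bp == sum(IRanges::width(gene_rng))
    labels <- c(labels, paste0(f$gene, if (!full) " (partial)" else ""))
  }
  labels <- unique(labels[!is.na(labels)])
  if (length(labels) == 0L) "None" else paste(labels, collapse = ", ")
}

#' Total spacer sequence shared with another genome
#'
#' The union of segment query-intervals is intersected with the spacer set;
#' the result is reported in bp and as a fraction of the spacer total.
#'
#' @param query_spacers a `spacer_set`
#' @param segments tibble from [find_homologous_segments()] in query genome
#'   coordinates
#' @return list with `shared_bp` and `shared_fraction`
#' @export
shared_spacer_total <- function(query_spacers, segments) {
  stopifnot(inherits(query_spacers, "spacer_set"))
  if (nrow(segments) == 0L || query_spacers$total_bp == 0L) {
    return(list(shared_bp = 0L, shared_fraction = 0))
  }
  seg <- IRanges::reduce(IRanges::IRanges(segments$qstart, segments$qend))
  sp <- IRanges::IRanges(
    query_spacers$intervals$start, query_spacers$intervals$end
  )
  shared <- sum(IRanges::width(IRanges::intersect(seg, sp)))
  list(
    shared_bp = shared,
    shared_fraction = shared / query_spacers$total_bp
  )
}

#' Write a homology-segment table as TSV
#'
#' Columns mirror the usual plastid-insertion table: insertion number,
#' minimum/maximum query coordinate, length, genes carried.
#'
#' @param segments tibble from [find_homologous_segments()]
#' @param path output file
#' @return `path` invisibly
#' @export
write_segments_tsv <- function(segments, path) {
  df <- data.frame(
    `Plastid insertion` = segments$segment,
    Minimum = segments$qstart, Maximum = segments$qend,
    Length = segments$length,
    `Plastid genes carried` = segments$carried_features,
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
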