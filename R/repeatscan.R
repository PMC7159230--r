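# Repeat discovery: genome self-comparison.
#
# The scan is a seed-and-extend self-alignment restricted to ungapped
# (same-diagonal) matches: k-mer seeds shared between the genome and itself
# (direct) or its reverse complement (inverted) nominate diagonals; seed runs
# are extended with an X-drop rule under a +1 match / -penalty mismatch
# score, and trimmed to the maximal-scoring segment. With the default
# penalty of 4 a segment is only extended while its local identity stays
# above 80%, and an exact repeat is reported at exactly its maximal exact
# boundaries. Substitution-degraded repeat copies are recovered as single
# pairs; indel-shifted copies fragment into per-diagonal pieces (a documented
# limitation; the synthetic generator degrades repeats by substitution only).

#' Find repeated sequence pairs in a genome
#'
#' Returns every pair of genomic segments of at least
#' `config$min_repeat_len` bp whose ungapped alignment identity exceeds
#' `config$min_repeat_identity` percent, on either strand. Self-hits are
#' excluded; each pair is reported once in canonical order (`copy1` starts
#' first); families with more than two copies appear as all pairwise
#' combinations. `N` and ambiguity bases never count as matches.
#'
#' @param genome an [mt_genome()]
#' @param config a [pipeline_config()]
#' @return tibble of class `repeat_pairs` with columns `id`, `length`,
#'   `identity` (percent, 2 decimals), `start1`, `end1`, `start2`, `end2`,
#'   `orientation` (`"direct"`/`"inverted"`), `size_class`, `n_matches`,
#'   `score`; sorted by descending length
#' @export
find_repeat_pairs <- function(genome, config = pipeline_config()) {
  stopifnot(inherits(genome, "mt_genome"))
  L <- genome$length
  if (L < 2 * config$min_repeat_len) {
    warning("genome shorter than twice the minimum repeat length; no scan")
    return(empty_repeat_pairs())
  }
  x <- genome$seq
  y <- revcomp(x)
  xr <- charToRaw(x)
  yr <- charToRaw(y)
  acgt <- charToRaw("ACGT")
  xa <- xr %in% acgt
  ya <- yr %in% acgt

  k <- as.integer(config$seed_kmer)
  pen <- config$mismatch_penalty
  segs <- list()

  # --- direct: x vs x, diagonals d >= 1 -------------------------------------
  kx <- substring(x, 1:(L - k + 1L), k:L)
  dup <- duplicated(kx) | duplicated(kx, fromLast = TRUE)
  if (any(dup)) {
    groups <- split(which(dup), kx[which(dup)])
    seed_pairs <- seed_pairs_within(groups)
    if (nrow(seed_pairs) > 0) {
      seed_pairs$d <- seed_pairs$j - seed_pairs$i
      seed_pairs <- seed_pairs[seed_pairs$d >= 1L, , drop = FALSE]
      segs <- c(segs, scan_diagonals(
        seed_pairs, xr, xr, xa, xa, k, pen, config,
        map2 = function(s, e, d) c(s + d, e + d), orientation = "direct"
      ))
    }
  }

  # --- inverted: x vs revcomp(x) --------------------------------------------
  ky <- substring(y, 1:(L - k + 1L), k:L)
  # restrict to kmer values present in both sequences
  in_both <- kx %in% ky
  if (any(in_both)) {
    gx <- split(which(in_both), kx[which(in_both)])
    jy <- ky %in% names(gx)
    gy <- split(which(jy), ky[which(jy)])
    seed_pairs <- seed_pairs_across(gx, gy)
    if (nrow(seed_pairs) > 0) {
      seed_pairs$d <- seed_pairs$j - seed_pairs$i
      segs <- c(segs, scan_diagonals(
        seed_pairs, xr, yr, xa, ya, k, pen, config,
        map2 = function(s, e, d) c(L - (e + d) + 1L, L - (s + d) + 1L),
        orientation = "inverted"
      ))
    }
  }

  if (length(segs) == 0L) {
    return(empty_repeat_pairs())
  }
  out <- dplyr::bind_rows(segs)
  # canonical copy order: copy1 starts first
  swap <- out$start2 < out$start1 |
    (out$start2 == out$start1 & out$end2 < out$end1)
  tmp <- out[swap, c("start1", "end1")]
  out[swap, c("start1", "end1")] <- out[swap, c("start2", "end2")]
  out[swap, c("start2", "end2")] <- tmp
  # drop self-hits (identical intervals) and mirror duplicates
  out <- out[!(out$start1 == out$start2 & out$end1 == out$end2), , drop = FALSE]
  out <- out[!duplicated(out[, c("start1", "end1", "start2", "end2", "orientation")]), ,
    drop = FALSE
  ]
  out <- out[out$length >= config$min_repeat_len &
    out$identity > config$min_repeat_identity, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(empty_repeat_pairs())
  }
  out <- out[order(-out$length, out$start1, out$start2), , drop = FALSE]
  out$id <- seq_len(nrow(out))
  out$size_class <- vapply(out$length, classify_size, character(1), config = config)
  class(out) <- c("repeat_pairs", class(tibble::tibble()))
  out[, c(
    "id", "length", "identity", "start1", "end1", "start2", "end2",
    "orientation", "size_class", "n_matches", "score"
  )]
}

empty_repeat_pairs <- function() {
  out <- tibble::tibble(
    id = integer(), length = integer(), identity = numeric(),
    start1 = integer(), end1 = integer(), start2 = integer(),
    end2 = integer(), orientation = character(), size_class = character(),
    n_matches = integer(), score = numeric()
  )
  class(out) <- c("repeat_pairs", class(out))
  out
}

# all i<j pairs within each position group (same sequence)
seed_pairs_within <- function(groups, cap = 64L) {
  big <- vapply(groups, length, integer(1)) > cap
  if (any(big)) {
    warning(sum(big), " high-multiplicity k-mers skipped (low-complexity)")
    groups <- groups[!big]
  }
  ij <- lapply(groups, function(p) {
    if (length(p) < 2L) return(NULL)
    cmb <- utils::combn(sort(p), 2L)
    cbind(i = cmb[1, ], j = cmb[2, ])
  })
  m <- do.call(rbind, ij)
  if (is.null(m)) {
    return(data.frame(i = integer(), j = integer()))
  }
  as.data.frame(m)
}

# all cross pairs between x-groups and y-groups sharing a kmer value
seed_pairs_across <- function(gx, gy, cap = 64L) {
  keys <- intersect(names(gx), names(gy))
  ij <- lapply(keys, function(kv) {
    px <- gx[[kv]]
    py <- gy[[kv]]
    if (length(px) > cap || length(py) > cap) return(NULL)
    expand.grid(i = px, j = py, KEEP.OUT.ATTRS = FALSE)
  })
  m <- do.call(rbind, ij)
  if (is.null(m)) {
    return(data.frame(i = integer(), j = integer()))
  }
  m
}

# Extend merged seed runs per diagonal and trim to maximal-scoring segments.
# map2(s, e, d) maps an aligned segment on diagonal d (positions in the
# second sequence's own axis: s+d..e+d) to genomic copy2 coordinates.
scan_diagonals <- function(seed_pairs, xr, yr, xa, ya, k, pen, config,
                           map2, orientation) {
  Lx <- length(xr)
  Ly <- length(yr)
  out <- list()
  for (d in unique(seed_pairs$d)) {
    lo <- max(1L, 1L - d)           # valid x-index range on this diagonal
    hi <- min(Lx, Ly - d)
    if (hi - lo + 1L < config$min_repeat_len) next
    starts <- sort(unique(seed_pairs$i[seed_pairs$d == d]))
    # merge overlapping/adjacent seed starts into exact seed runs
    runs <- interval_reduce(starts, starts + k - 1L)
    done_upto <- -Inf
    for (r in seq_len(nrow(runs))) {
      s0 <- max(runs$start[r], lo)
      e0 <- min(runs$end[r], hi)
      if (s0 <= done_upto || s0 > e0) next
      left <- xdrop_extend(xr, yr, xa, ya, d, s0, lo, -1L, pen)
      right <- xdrop_extend(xr, yr, xa, ya, d, e0, hi, 1L, pen)
      s1 <- s0 - left
      e1 <- e0 + right
      done_upto <- e1
      n <- e1 - s1 + 1L
      if (n < config$min_repeat_len) next
      idx <- s1:e1
      m <- (xr[idx] == yr[idx + d]) & xa[idx] & ya[idx + d]
      nm <- sum(m)
      ident <- round_half_up(100 * nm / n, 2)
      c2 <- map2(s1, e1, d)
      out[[length(out) + 1L]] <- tibble::tibble(
        length = n, identity = ident,
        start1 = s1, end1 = e1, start2 = c2[1], end2 = c2[2],
        orientation = orientation, n_matches = nm,
        score = nm - pen * (n - nm)
      )
    }
  }
  out
}

# Chunked ungapped X-drop extension along a diagonal; returns the extension
# length (>= 0) from `from` (exclusive) toward `limit` in direction `dir`.
xdrop_extend <- function(xr, yr, xa, ya, d, from, limit, dir, pen,
                         xdrop = 40, chunk = 4096L) {
  best_off <- 0L
  score <- 0
  peak <- 0
  pos <- from
  while (dir * (limit - pos) > 0) {
    nxt <- pos + dir * pmin(chunk, abs(limit - pos))
    idx <- seq.int(pos + dir, nxt, by = dir)
    m <- (xr[idx] == yr[idx + d]) & xa[idx] & ya[idx + d]
    s <- score + cumsum(ifelse(m, 1, -pen))
    cm <- cummax(c(peak, s))[-1]
    dropped <- which(cm - s > xdrop)
    upto <- if (length(dropped) > 0) dropped[1] else length(s)
    seg <- s[seq_len(upto)]
    w <- which.max(seg)
    if (seg[w] > peak) {
      peak <- seg[w]
      best_off <- abs(idx[w] - from)
    }
    if (length(dropped) > 0) break
    score <- s[length(s)]
    pos <- nxt
  }
  best_off
}

#' Classify a repeat by length
#'
#' Size classes follow the usual census of plant mitochondrial repeats:
#' small repeats in `[50, 100)` bp, medium in `[100, 1000]` bp, large above
#' 1000 bp. The exact boundaries (100 and 1000 bp both medium) are set by
#' `config$size_class_bounds`.
#'
#' @param length repeat length in bp (must be >= 50)
#' @param config a [pipeline_config()]
#' @return one of `"small"`, `"medium"`, `"large"`
#' @export
classify_size <- function(length, config = pipeline_config()) {
  if (length < config$min_repeat_len) {
    stop("repeat length ", length, " below the minimum of ", config$min_repeat_len)
  }
  b <- config$size_class_bounds
  if (length < b[1]) "small" else if (length <= b[2]) "medium" else "large"
}

#' Summarise a repeat census
#'
#' @param pairs a `repeat_pairs` tibble from [find_repeat_pairs()]
#' @param genome the scanned [mt_genome()]
#' @return list with `n_pairs`, `per_class` (named counts), `gross_bp`
#'   (genome positions covered by at least one repeat copy, counted once)
#'   and `gross_fraction`
#' @export
repeat_summary <- function(pairs, genome) {
  per_class <- c(small = 0L, medium = 0L, large = 0L)
  if (nrow(pairs) > 0) {
    tab <- table(factor(pairs$size_class, levels = names(per_class)))
    per_class[names(tab)] <- as.integer(tab)
  }
  gross <- interval_union_bp(
    c(pairs$start1, pairs$start2),
    c(pairs$end1, pairs$end2)
  )
  list(
    n_pairs = nrow(pairs),
    per_class = per_class,
    gross_bp = gross,
    gross_fraction = gross / genome$length
  )
}

#' Write a repeat table as TSV
#'
#' Columns mirror the standard recombination-frequency table layout:
#' repeat number, length, identity, both copies' coordinates, direction.
#'
#' @param pairs a `repeat_pairs` tibble
#' @param path output file
#' @return `path` invisibly
#' @export
write_repeats_tsv <- function(pairs, path) {
  df <- data.frame(
    `Repeat no.` = pairs$id, `Repeat length` = pairs$length,
    Identity = pairs$identity, Start = pairs$start1, End = pairs$end1,
    Start2 = pairs$start2, End2 = pairs$end2,
    Direction = ifelse(pairs$orientation == "direct", "Direct", "Inverted"),
    check.names = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
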