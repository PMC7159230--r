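# Independent oracles used across the suite. Each is a deliberately naive
# implementation, structurally unrelated to the package's own code paths.

# ---- maximal exact repeat pairs by full diagonal sweep ----------------------
# Enumerates all maximal exactly-repeated substring pairs >= min_len on both
# strands by comparing the genome against itself (and its reverse
# complement) at every offset. O(L^2); for genomes up to a few kb only.
oracle_exact_repeats <- function(seq, min_len = 50) {
  xc <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(xc)
  yc <- rev(chartr("ACGT", "TGCA", xc))
  rows <- list()
  add <- function(s1, e1, s2, e2, orientation) {
    if (s2 < s1 || (s2 == s1 && e2 < e1)) {
      tmp <- c(s1, e1)
      s1 <- s2
      e1 <- e2
      s2 <- tmp[1]
      e2 <- tmp[2]
    }
    if (s1 == s2 && e1 == e2) return() # self-hit
    rows[[length(rows) + 1L]] <<- data.frame(
      start1 = s1, end1 = e1, start2 = s2, end2 = e2,
      orientation = orientation
    )
  }
  # direct: offset d >= 1
  for (d in 1:(L - 1)) {
    v <- xc[1:(L - d)] == xc[(1 + d):L]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      add(starts[k], ends[k], starts[k] + d, ends[k] + d, "direct")
    }
  }
  # inverted: compare x against revcomp(x) at every offset
  for (d in (1 - L):(L - 1)) {
    i1 <- max(1L, 1L - d)
    i2 <- min(L, L - d)
    if (i2 - i1 + 1L < min_len) next
    idx <- i1:i2
    v <- xc[idx] == yc[idx + d]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      a1 <- idx[starts[k]]
      a2 <- idx[ends[k]]
      add(a1, a2, L - (a2 + d) + 1L, L - (a1 + d) + 1L, "inverted")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(
      start1 = integer(), end1 = integer(), start2 = integer(),
      end2 = integer(), orientation = character()
    ))
  }
  out <- unique(do.call(rbind, rows))
  out[order(out$start1, out$start2, out$orientation), , drop = FALSE]
}

# ---- interval union by position marking -------------------------------------
oracle_union_bp <- function(start, end, L) {
  cover <- logical(L)
  for (i in seq_along(start)) cover[start[i]:end[i]] <- TRUE
  sum(cover)
}

# ---- pairwise identity by Needleman-Wunsch (Biostrings) ---------------------
oracle_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global"
  )
  p <- as.character(Biostrings::alignedPattern(aln))
  s <- as.character(Biostrings::alignedSubject(aln))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  100 * sum(pc == sc & pc != "-") / length(pc)
}

# ---- DCJ: BFS over perfect matchings ---------------------------------------
# Extremity encoding: gene g -> tail 2g-1, head 2g. A telomere-free genome is
# a perfect matching on 1..2n; a DCJ operation cuts two adjacencies and
# rejoins the four extremities the other two ways.
perm_to_matching <- function(genes, strand) {
  n <- length(genes)
  left <- ifelse(strand > 0, 2L * genes - 1L, 2L * genes)
  right <- ifelse(strand > 0, 2L * genes, 2L * genes - 1L)
  partner <- integer(2L * n)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    partner[right[i]] <- left[j]
    partner[left[j]] <- right[i]
  }
  partner
}

matching_key <- function(p) paste(p, collapse = ",")

matching_neighbors <- function(p) {
  anchors <- which(seq_along(p) < p)
  out <- list()
  m <- length(anchors)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      u1 <- anchors[i]
      v1 <- p[u1]
      u2 <- anchors[j]
      v2 <- p[u2]
      q <- p
      q[u1] <- u2
      q[u2] <- u1
      q[v1] <- v2
      q[v2] <- v1
      out[[length(out) + 1L]] <- q
      q <- p
      q[u1] <- v2
      q[v2] <- u1
      q[v1] <- u2
      q[u2] <- v1
      out[[length(out) + 1L]] <- q
    }
  }
  out
}

bfs_dcj_distances <- function(start) {
  dist <- new.env(hash = TRUE)
  assign(matching_key(start), 0L, dist)
  frontier <- list(start)
  d <- 0L
  while (length(frontier) > 0) {
    nxt <- list()
    for (p in frontier) {
      for (q in matching_neighbors(p)) {
        k <- matching_key(q)
        if (!exists(k, dist, inherits = FALSE)) {
          assign(k, d + 1L, dist)
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  dist
}

matching_to_adjacencies <- function(p) {
  anchors <- which(seq_along(p) < p)
  lab <- function(e) {
    paste0("g", (e + 1L) %/% 2L, ".", ifelse(e %% 2L == 1L, "t", "h"))
  }
  lapply(anchors, function(u) c(lab(u), lab(p[u])))
}

random_circular_order <- function(n, organism = "x") {
  genes <- paste0("g", sample.int(n))
  gene_order(organism, list(list(
    genes = genes,
    strand = sample(c(-1L, 1L), n, replace = TRUE),
    circular = TRUE
  )))
}

# ---- parsimony-informative sites by per-column enumeration ------------------
oracle_matrix_stats <- function(alignment, missing = c(
                                  "-", "?", ".", "N", "X", "R", "Y", "S", "W",
                                  "K", "M", "B", "D", "H", "V"
                                )) {
  rows <- strsplit(toupper(alignment), "", fixed = TRUE)
  n_col <- length(rows[[1]])
  pi <- 0L
  n_missing <- 0L
  for (j in seq_len(n_col)) {
    col <- vapply(rows, `[[`, character(1), j)
    miss <- col %in% missing
    n_missing <- n_missing + sum(miss)
    tab <- table(col[!miss])
    if (sum(tab >= 2) >= 2) pi <- pi + 1L
  }
  list(
    pi_sites = pi,
    missing_fraction = n_missing / (n_col * length(alignment))
  )
}

# ---- misc -------------------------------------------------------------------
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
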