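# Conserved gene clusters: maximal runs of genes that appear contiguously,
# with consistent relative orientation, in every organism compared. A run
# and its signed reversal are the same cluster (reading the other strand),
# so candidates are canonicalised before comparison.

#' Find gene clusters conserved across organisms
#'
#' Only genes present exactly once in every organism are considered, so that
#' contiguity is well defined. A cluster is a run of at least `min_len` such
#' genes occurring contiguously (forward, or reversed with flipped strands)
#' in all organisms; reported clusters are maximal — extending them by one
#' neighbouring gene breaks conservation in at least one organism.
#'
#' @param orders list of at least two [gene_order()] objects
#' @param min_len minimum cluster length in genes (default 2)
#' @return tibble with columns `genes` (list of signed label vectors, e.g.
#'   `c("rpl2", "-rps19")`), `length`, and `n_organisms`
#' @export
find_conserved_clusters <- function(orders, min_len = 2) {
  stopifnot(length(orders) >= 2, min_len >= 1)
  counts <- lapply(orders, function(o) {
    table(unlist(lapply(o$chromosomes, `[[`, "genes")))
  })
  shared <- Reduce(intersect, lapply(counts, function(t) names(t)[t == 1]))
  if (length(shared) < min_len) {
    return(tibble::tibble(
      genes = list(), length = integer(), n_organisms = integer()
    ))
  }
  reduced <- lapply(orders, function(o) {
    chroms <- lapply(o$chromosomes, function(chr) {
      keep <- chr$genes %in% shared
      if (!any(keep)) return(NULL)
      list(
        genes = chr$genes[keep], strand = chr$strand[keep],
        circular = chr$circular
      )
    })
    chroms[!vapply(chroms, is.null, logical(1))]
  })

  # signed-token representation of every contiguous window of a chromosome
  signed <- function(genes, strand) paste0(ifelse(strand < 0, "-", ""), genes)
  flip <- function(tokens) {
    rev(ifelse(startsWith(tokens, "-"), sub("^-", "", tokens), paste0("-", tokens)))
  }
  canon <- function(tokens) {
    r <- flip(tokens)
    key_f <- paste(tokens, collapse = " ")
    key_r <- paste(r, collapse = " ")
    if (key_f <= key_r) key_f else key_r
  }
  # all windows of length win_len..max, handling circular wrap by doubling
  windows_of <- function(chroms, min_len) {
    keys <- character()
    for (chr in chroms) {
      n <- length(chr$genes)
      toks <- signed(chr$genes, chr$strand)
      ext <- if (chr$circular) c(toks, toks) else toks
      limit <- length(ext)
      for (w in seq2(min_len, n)) {
        starts <- if (chr$circular) seq_len(n) else seq2(1L, n - w + 1L)
        for (s in starts) {
          if (s + w - 1L > limit) next
          keys <- c(keys, canon(ext[s:(s + w - 1L)]))
        }
      }
      if (chr$circular) {
        # the full circle is rotation-invariant: canonicalise over rotations
        keys <- c(keys, canon_circular(toks, flip, canon))
      }
    }
    unique(keys)
  }

  ref <- reduced[[1]]
  other_sets <- lapply(reduced[-1], windows_of, min_len = min_len)

  present_in_all <- function(key) {
    all(vapply(other_sets, function(s) key %in% s, logical(1)))
  }

  # enumerate candidate runs from the reference organism, longest first,
  # keeping runs present everywhere and not contained in a kept run
  clusters <- list()
  kept_keys <- character()
  for (chr in ref) {
    n <- length(chr$genes)
    toks <- signed(chr$genes, chr$strand)
    ext <- if (chr$circular) c(toks, toks) else toks
    max_w <- n
    for (w in rev(seq2(min_len, max_w))) {
      starts <- if (chr$circular) seq_len(n) else seq2(1L, n - w + 1L)
      for (s in starts) {
        if (s + w - 1L > length(ext)) next
        run <- ext[s:(s + w - 1L)]
        key <- if (w == n && chr$circular) {
          canon_circular(toks, flip, canon)
        } else {
          canon(run)
        }
        if (key %in% kept_keys) next
        if (!present_in_all(key)) next
        # maximality: contained in an already-kept longer cluster?
        contained <- any(vapply(clusters, function(cl) {
          big <- if (isTRUE(cl$circular)) c(cl$run, cl$run) else cl$run
          w < cl$length && is_subrun(run, big, flip)
        }, logical(1)))
        if (contained) next
        clusters[[length(clusters) + 1L]] <- list(
          run = run, length = w, circular = (w == n && chr$circular)
        )
        kept_keys <- c(kept_keys, key)
      }
    }
  }
  if (length(clusters) == 0L) {
    return(tibble::tibble(
      genes = list(), length = integer(), n_organisms = integer()
    ))
  }
  tibble::tibble(
    genes = lapply(clusters, `[[`, "run"),
    length = vapply(clusters, `[[`, "length", FUN.VALUE = integer(1)),
    n_organisms = length(orders)
  )
}

# canonical key of a full circular chromosome: minimum over rotations of
# both readings
canon_circular <- function(toks, flip, canon) {
  n <- length(toks)
  keys <- character()
  for (r in seq_len(n)) {
    rot <- c(toks[r:n], toks[seq2(1L, r - 1L)])
    keys <- c(keys, paste(rot, collapse = " "), paste(flip(rot), collapse = " "))
  }
  min(keys)
}

# is `small` a contiguous subrun of `big` (forward or flipped)?
is_subrun <- function(small, big, flip) {
  k <- length(small)
  n <- length(big)
  if (k > n) return(FALSE)
  key <- paste(small, collapse = " ")
  key_r <- paste(flip(small), collapse = " ")
  for (s in seq2(1L, n - k + 1L)) {
    sub <- paste(big[s:(s + k - 1L)], collapse = " ")
    if (sub == key || sub == key_r) return(TRUE)
  }
  FALSE
}

#' Write a cluster report as TSV
#'
#' @param clusters output of [find_conserved_clusters()]
#' @param path output file
#' @return `path` invisibly
#' @export
write_clusters_tsv <- function(clusters, path) {
  df <- data.frame(
    cluster = vapply(clusters$genes, paste, character(1), collapse = "-"),
    length = clusters$length,
    n_organisms = clusters$n_organisms
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
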