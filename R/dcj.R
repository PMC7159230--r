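# Double-cut-and-join (DCJ) rearrangement distance.
#
# Each gene g has two extremities, tail g.t and head g.h; a signed gene +g
# reads tail->head, -g reads head->tail. A genome is the set of adjacencies
# between consecutive extremities (plus telomeres at linear chromosome
# ends). The DCJ distance between two genomes over the same gene set is
#   d = N - (C + I/2)
# where N is the number of genes, C the number of cycles and I the number of
# odd-length paths in the adjacency graph (vertices: adjacencies and
# telomeres of both genomes; one edge per shared extremity).

#' Restrict two gene orders to their shared single-copy genes
#'
#' Genes present exactly once in each organism are kept, preserving relative
#' order and signs; duplicated genes and genes private to one organism are
#' dropped and reported, so the reconciliation is auditable.
#'
#' @param a,b [gene_order()] objects
#' @return list with elements `a` and `b` (reduced gene orders) and
#'   `dropped` (character vector of removed gene labels)
#' @export
reduce_to_shared_genes <- function(a, b) {
  count <- function(o) table(unlist(lapply(o$chromosomes, `[[`, "genes")))
  ta <- count(a)
  tb <- count(b)
  shared <- intersect(names(ta)[ta == 1], names(tb)[tb == 1])
  if (length(shared) == 0L) {
    stop("no shared single-copy genes between ", a$organism, " and ", b$organism)
  }
  dropped <- setdiff(union(names(ta), names(tb)), shared)
  restrict <- function(o) {
    chroms <- lapply(o$chromosomes, function(chr) {
      keep <- chr$genes %in% shared
      if (!any(keep)) return(NULL)
      list(
        genes = chr$genes[keep], strand = chr$strand[keep],
        circular = chr$circular
      )
    })
    gene_order(o$organism, chroms[!vapply(chroms, is.null, logical(1))])
  }
  list(a = restrict(a), b = restrict(b), dropped = dropped)
}

# Adjacency set of a gene order: list of character vectors, each of length 2
# (adjacency) or 1 (telomere). Extremities are "gene.t" / "gene.h".
adjacency_set <- function(order) {
  adj <- list()
  for (chr in order$chromosomes) {
    n <- length(chr$genes)
    left <- ifelse(chr$strand > 0, paste0(chr$genes, ".t"), paste0(chr$genes, ".h"))
    right <- ifelse(chr$strand > 0, paste0(chr$genes, ".h"), paste0(chr$genes, ".t"))
    if (n > 1) {
      for (i in 1:(n - 1)) {
        adj[[length(adj) + 1L]] <- c(right[i], left[i + 1L])
      }
    }
    if (chr$circular) {
      adj[[length(adj) + 1L]] <- c(right[n], left[1L])
    } else {
      adj[[length(adj) + 1L]] <- left[1L]
      adj[[length(adj) + 1L]] <- right[n]
    }
  }
  adj
}

#' DCJ distance between adjacency sets
#'
#' Low-level entry point: computes `N - (C + I/2)` from two adjacency sets
#' over the same extremities, via the components of the adjacency graph.
#' Exposed so that the formula can be validated directly against
#' breadth-first search over DCJ operations on adjacency sets.
#'
#' @param adj_a,adj_b adjacency sets: lists of length-2 (adjacency) or
#'   length-1 (telomere) character vectors of extremities `"gene.t"` /
#'   `"gene.h"`
#' @return integer DCJ distance
#' @export
dcj_distance_adjacencies <- function(adj_a, adj_b) {
  ext <- sort(unique(unlist(adj_a)))
  if (!setequal(ext, unlist(adj_b))) {
    stop("adjacency sets are over different extremities")
  }
  n_genes <- length(ext) / 2L
  locate <- function(adj) {
    m <- stats::setNames(integer(length(ext)), ext)
    for (i in seq_along(adj)) m[adj[[i]]] <- i
    m
  }
  la <- locate(adj_a)
  lb <- locate(adj_b)

  # union-find over graph nodes: A-adjacencies then B-adjacencies
  na <- length(adj_a)
  parent <- seq_len(na + length(adj_b))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # one edge per extremity, joining its A-node and B-node
  for (e in ext) {
    ra <- find(la[[e]])
    rb <- find(na + lb[[e]])
    if (ra != rb) parent[rb] <- ra
  }
  roots_nodes <- vapply(seq_along(parent), find, integer(1))
  roots_edges <- vapply(ext, function(e) find(la[[e]]), integer(1))
  n_nodes <- table(roots_nodes)
  n_edges <- table(factor(roots_edges, levels = names(n_nodes)))
  n_edges[is.na(n_edges)] <- 0L
  is_cycle <- n_edges == n_nodes          # every node degree 2
  odd_path <- !is_cycle & (n_edges %% 2L == 1L)
  d <- n_genes - sum(is_cycle) - sum(odd_path) / 2
  as.integer(round(d))
}

#' DCJ rearrangement distance between two gene orders
#'
#' Both orders must already be over the same single-copy gene set (apply
#' [reduce_to_shared_genes()] first when gene content differs). The distance
#' is symmetric, zero exactly for identical genomes (up to chromosome
#' rotation and reflection), and counts the minimum number of
#' double-cut-and-join operations — the standard model under which one
#' inversion, one translocation, or one circular excision/reintegration
#' step each cost 1.
#'
#' @param a,b [gene_order()] objects over identical gene sets
#' @return integer DCJ distance
#' @export
dcj_distance <- function(a, b) {
  genes_of <- function(o) sort(unlist(lapply(o$chromosomes, `[[`, "genes")))
  ga <- genes_of(a)
  gb <- genes_of(b)
  if (anyDuplicated(ga) > 0 || anyDuplicated(gb) > 0 || !identical(ga, gb)) {
    stop(
      "gene orders are not reduced to a common single-copy gene set; ",
      "run reduce_to_shared_genes() first"
    )
  }
  dcj_distance_adjacencies(adjacency_set(a), adjacency_set(b))
}

#' Pairwise DCJ distance matrix
#'
#' Each pair of organisms is reduced to its shared single-copy genes before
#' the distance is computed; entries may therefore be based on different
#' gene subsets when gene content varies.
#'
#' @param orders list of [gene_order()] objects
#' @return symmetric integer matrix with organism names as dimnames
#' @export
dcj_distance_matrix <- function(orders) {
  n <- length(orders)
  m <- matrix(0L, n, n)
  nm <- vapply(orders, function(o) o$organism, character(1))
  dimnames(m) <- list(nm, nm)
  for (i in seq2(1L, n - 1L)) {
    for (j in seq2(i + 1L, n)) {
      red <- reduce_to_shared_genes(orders[[i]], orders[[j]])
      m[i, j] <- m[j, i] <- dcj_distance(red$a, red$b)
    }
  }
  m
}
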