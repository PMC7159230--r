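# Alignment-matrix statistics for concatenated phylogenomic datasets:
# missing-data fraction and parsimony-informative sites.

#' Summary statistics of an alignment matrix
#'
#' A column is parsimony-informative when at least two distinct non-missing
#' states each occur in at least two rows. Gap characters and ambiguity
#' codes count as missing, never as states.
#'
#' @param alignment named character vector of aligned sequences (equal
#'   lengths), or a character matrix (rows = taxa)
#' @param missing characters treated as missing; default covers gaps, `?`,
#'   `N`/`X`, and the IUPAC nucleotide ambiguity codes
#' @return list with `n_taxa`, `n_columns`, `missing_fraction`, `pi_sites`,
#'   `pi_fraction`
#' @export
matrix_stats <- function(alignment,
                         missing = c(
                           "-", "?", ".", "N", "X",
                           "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V"
                         )) {
  m <- as_alignment_matrix(alignment)
  n_taxa <- nrow(m)
  n_col <- ncol(m)
  is_missing <- matrix(m %in% toupper(missing), nrow = n_taxa)
  pi <- vapply(seq_len(n_col), function(j) {
    states <- m[, j][!is_missing[, j]]
    if (length(states) < 4L) return(FALSE)
    tab <- table(states)
    sum(tab >= 2L) >= 2L
  }, logical(1))
  list(
    n_taxa = n_taxa,
    n_columns = n_col,
    missing_fraction = mean(is_missing),
    pi_sites = sum(pi),
    pi_fraction = sum(pi) / n_col
  )
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) {
    return(toupper(alignment))
  }
  stopifnot(is.character(alignment), length(alignment) >= 1)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Taxa absent from a gene are filled with the missing symbol; the partition
#' table records each gene's 1-based column range in the concatenation.
#'
#' @param gene_alignments named list of per-gene alignments, each a named
#'   character vector (taxon -> aligned sequence, equal lengths within a
#'   gene)
#' @param taxa taxon universe; defaults to the union over genes
#' @param missing_char fill symbol for absent taxa (default `"-"`)
#' @return list with `alignment` (named character vector over `taxa`) and
#'   `partitions` (tibble: `gene`, `start`, `end`)
#' @export
concat_alignments <- function(gene_alignments, taxa = NULL, missing_char = "-") {
  stopifnot(length(gene_alignments) >= 1)
  if (is.null(names(gene_alignments))) {
    names(gene_alignments) <- paste0("gene", seq_along(gene_alignments))
  }
  if (is.null(taxa)) {
    taxa <- unique(unlist(lapply(gene_alignments, names)))
  }
  pieces <- stats::setNames(rep(list(character(0)), length(taxa)), taxa)
  parts <- vector("list", length(gene_alignments))
  at <- 1L
  for (g in seq_along(gene_alignments)) {
    aln <- gene_alignments[[g]]
    if (anyDuplicated(names(aln)) > 0) {
      stop("duplicate taxon within gene ", names(gene_alignments)[g])
    }
    w <- unique(nchar(aln))
    if (length(w) != 1L) {
      stop("ragged alignment for gene ", names(gene_alignments)[g])
    }
    blank <- strrep(missing_char, w)
    for (t in taxa) {
      pieces[[t]] <- c(pieces[[t]], if (t %in% names(aln)) aln[[t]] else blank)
    }
    parts[[g]] <- tibble::tibble(
      gene = names(gene_alignments)[g], start = at, end = at + w - 1L
    )
    at <- at + w
  }
  list(
    alignment = vapply(pieces, paste, character(1), collapse = ""),
    partitions = dplyr::bind_rows(parts)
  )
}

#' Read an alignment from FASTA
#'
#' @param path FASTA file of aligned sequences
#' @return named character vector
#' @export
load_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*", "", names(ss))
  out
}
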