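# Signed, possibly multichromosomal gene orders and their text dialect.
#
# The dialect: a '>'-prefixed line names an organism; subsequent
# whitespace-separated tokens are signed gene labels ('-' prefix = minus
# strand); a chromosome is terminated by ')' (standalone token or suffix of
# its last gene token) if circular, or by the end of the gene list / the next
# organism line if linear.

#' Construct a gene order
#'
#' @param organism organism name
#' @param chromosomes list of chromosomes; each a list with `genes`
#'   (character vector of labels), `strand` (integer vector of +1/-1), and
#'   `circular` (logical)
#' @return an object of class `gene_order`
#' @export
gene_order <- function(organism, chromosomes) {
  for (chr in chromosomes) {
    stopifnot(
      is.character(chr$genes), all(nzchar(chr$genes)),
      length(chr$genes) == length(chr$strand),
      all(chr$strand %in% c(-1L, 1L)), is.logical(chr$circular)
    )
  }
  structure(list(organism = organism, chromosomes = chromosomes),
    class = "gene_order"
  )
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf(
    "<gene_order> %s: %d chromosome(s), %d genes\n", x$organism,
    length(x$chromosomes),
    sum(vapply(x$chromosomes, function(c) length(c$genes), integer(1)))
  ))
  invisible(x)
}

#' Parse gene orders from the text dialect
#'
#' @param path text file, or a character vector of lines via `text =`
#' @param text optional character vector of lines (overrides `path`)
#' @return list of [gene_order()] objects
#' @export
load_gene_orders <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L || !startsWith(lines[1], ">")) {
    stop("gene-order input must start with a '>' organism line")
  }
  heads <- which(startsWith(lines, ">"))
  orders <- vector("list", length(heads))
  for (k in seq_along(heads)) {
    org <- trimws(sub("^>", "", lines[heads[k]]))
    body_to <- if (k < length(heads)) heads[k + 1L] - 1L else length(lines)
    chroms <- list()
    for (ln in lines[seq2(heads[k] + 1L, body_to)]) {
      tokens <- strsplit(ln, "\\s+")[[1]]
      tokens <- tokens[nzchar(tokens)]
      # ')' as a suffix of the final gene token is split into its own token
      tokens <- unlist(lapply(tokens, function(tok) {
        if (grepl(".\\)$", tok)) c(sub("\\)$", "", tok), ")") else tok
      }))
      genes <- character()
      strand <- integer()
      flush <- function(circular) {
        if (length(genes) > 0L) {
          chroms[[length(chroms) + 1L]] <<- list(
            genes = genes, strand = strand, circular = circular
          )
        } else if (circular) {
          stop("')' with no preceding genes for organism ", org)
        }
        genes <<- character()
        strand <<- integer()
      }
      for (tok in tokens) {
        if (tok == ")") {
          flush(TRUE)
        } else {
          s <- 1L
          if (startsWith(tok, "-")) {
            s <- -1L
            tok <- sub("^-", "", tok)
            if (!nzchar(tok)) stop("gene token of only '-' for organism ", org)
          }
          genes <- c(genes, tok)
          strand <- c(strand, s)
        }
      }
      # end of line closes any open (linear) chromosome
      flush(FALSE)
    }
    orders[[k]] <- gene_order(org, chroms)
  }
  orders
}

#' Write gene orders in the text dialect
#'
#' The writer is the normal form of the dialect: one organism line, one line
#' per chromosome, `')'` emitted as a standalone final token for circular
#' chromosomes. `load_gene_orders(write_gene_orders(x))` is the identity.
#'
#' @param orders a [gene_order()] or list of them
#' @param path output file; `NULL` returns the lines instead
#' @return lines invisibly (or visibly when `path` is `NULL`)
#' @export
write_gene_orders <- function(orders, path = NULL) {
  if (inherits(orders, "gene_order")) orders <- list(orders)
  lines <- unlist(lapply(orders, function(o) {
    c(paste0(">", o$organism), vapply(o$chromosomes, function(chr) {
      toks <- paste0(ifelse(chr$strand < 0, "-", ""), chr$genes)
      if (chr$circular) toks <- c(toks, ")")
      paste(toks, collapse = " ")
    }, character(1)))
  }))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
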