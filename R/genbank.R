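# GenBank flat-file feature parsing.
#
# Only the feature table is consumed: gene/CDS/tRNA/rRNA/intron keys, their
# location strings (ranges, join(), order(), complement(), partial markers
# < and >), and the /gene qualifier. Sequence data and all other record
# sections are ignored.

#' Load gene features from a GenBank flat file
#'
#' Parses the FEATURES table of the first record of a GenBank flat file and
#' returns one row per feature of the recognised kinds. Compound locations
#' (`join`, `order`, possibly inside `complement`) are decomposed into
#' interval lists. Duplicate gene names are preserved; deduplication is the
#' caller's responsibility.
#'
#' @param path GenBank flat file
#' @param kinds feature keys to keep (default gene, CDS, tRNA, rRNA, intron)
#' @return a tibble with columns `gene`, `kind` (`protein_coding`, `tRNA`,
#'   `rRNA`, `intron`, `other`), `strand` (`"+"`/`"-"`), `origin`, and
#'   `intervals` (list column of two-column start/end matrices, 1-based
#'   inclusive)
#' @export
load_features <- function(path, kinds = c("gene", "CDS", "tRNA", "rRNA", "intron")) {
  lines <- readLines(path, warn = FALSE)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0L) stop("no FEATURES section in ", path)
  fstart <- fstart[1]
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- c(fend[fend > fstart], length(lines) + 1L)[1]
  block <- lines[seq(fstart + 1L, fend - 1L)]
  if (length(block) == 0L) {
    return(empty_features())
  }

  # A feature header line has its key in columns 6-20.
  is_header <- grepl("^ {5}\\S", block)
  idx <- which(is_header)
  if (length(idx) == 0L) {
    return(empty_features())
  }
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    j <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    key <- sub("^\\s+", "", substr(block[i], 1, 20))
    key <- sub("\\s.*", "", key)
    body <- c(sub("^ {5}\\S+\\s*", "", block[i]), trimws(block[seq2(i + 1L, j)]))
    # continuation lines of the location precede the first qualifier
    qual_at <- grep("^/", body)
    loc <- paste(body[seq2(1L, (c(qual_at, length(body) + 1L)[1]) - 1L)], collapse = "")
    quals <- paste(body[seq2(c(qual_at, length(body) + 1L)[1], length(body))], collapse = " ")
    if (!key %in% kinds) next
    parsed <- tryCatch(
      parse_genbank_location(loc),
      error = function(e) {
        stop(
          "malformed location for feature '", key, "' (", loc, "): ",
          conditionMessage(e)
        )
      }
    )
    gene <- sub('.*?/gene="([^"]*)".*', "\\1", quals)
    if (identical(gene, quals)) {
      gene <- sub(".*?/gene=([^ /]+).*", "\\1", quals)
      if (identical(gene, quals)) gene <- NA_character_
    }
    kind <- switch(key,
      CDS = "protein_coding", gene = "gene", tRNA = "tRNA",
      rRNA = "rRNA", intron = "intron", "other"
    )
    out[[k]] <- tibble::tibble(
      gene = gene, kind = kind,
      strand = if (parsed$complement) "-" else "+",
      origin = "unknown",
      intervals = list(parsed$intervals)
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(empty_features())
  }
  dplyr::bind_rows(out)
}

empty_features <- function() {
  tibble::tibble(
    gene = character(), kind = character(), strand = character(),
    origin = character(), intervals = list()
  )
}

seq2 <- function(from, to) if (from > to) integer() else seq.int(from, to)

# Parse a GenBank location string into intervals + overall strand.
# Handles N..M, single positions, join(), order(), complement() outside or
# inside join, and partial markers <,>.
parse_genbank_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  complement <- FALSE
  if (grepl("^complement\\(", loc)) {
    complement <- TRUE
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (length(parts) == 0L) stop("empty location")
  ivs <- t(vapply(parts, function(p) {
    if (grepl("^complement\\(", p)) {
      complement <<- TRUE
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    p <- gsub("[<>]", "", p)
    if (grepl("^[0-9]+$", p)) {
      v <- as.integer(p)
      return(c(v, v))
    }
    if (!grepl("^[0-9]+\\.\\.[0-9]+$", p)) stop("unparseable range '", p, "'")
    v <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    if (v[1] > v[2]) stop("start > end in '", p, "'")
    v
  }, integer(2)))
  dimnames(ivs) <- list(NULL, c("start", "end"))
  list(intervals = ivs, complement = complement)
}

#' Deduplicated gene names from a feature table
#'
#' @param features a feature tibble from [load_features()]
#' @param kind restrict to one kind (e.g. `"protein_coding"`); `NULL` keeps all
#' @return character vector of unique gene names (NA names dropped)
#' @export
gene_names <- function(features, kind = NULL) {
  if (!is.null(kind)) features <- features[features$kind %in% kind, ]
  unique(features$gene[!is.na(features$gene)])
}
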