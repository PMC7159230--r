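# Local-alignment search engine interface.
#
# Every homology search in the pipeline (read support counting, recombinant
# screening, plastid/spacer homology annotation, mt-read extraction) goes
# through blast_hits(), a thin wrapper around NCBI BLAST+ blastn. The rest of
# the package depends only on the tabular hit contract below, so the engine
# is replaceable.

#' Run a blastn search between in-memory sequence sets
#'
#' @param query named character vector of DNA sequences
#' @param subject named character vector of DNA sequences
#' @param evalue e-value cutoff
#' @param perc_identity minimum percent identity reported (0 disables)
#' @param task blastn task (`"blastn"` or `"megablast"`)
#' @param dust apply low-complexity masking (off by default: organellar
#'   queries are small and masking costs sensitivity on AT-rich spacers)
#' @return tibble with columns `qseqid`, `sseqid`, `pident`, `length`,
#'   `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send` (s-coordinates
#'   reversed for minus-strand hits), `evalue`, `bitscore`
#' @export
blast_hits <- function(query, subject, evalue = 10, perc_identity = 0,
                       task = "blastn", dust = FALSE) {
  stopifnot(length(query) > 0, length(subject) > 0)
  if (is.null(names(query))) names(query) <- paste0("q", seq_along(query))
  if (is.null(names(subject))) names(subject) <- paste0("s", seq_along(subject))
  check_blast_available()
  dir <- tempfile("blast")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  qf <- file.path(dir, "query.fa")
  sf <- file.path(dir, "subject.fa")
  write_named_fasta(query, qf)
  write_named_fasta(subject, sf)
  db <- file.path(dir, "db")
  status <- system2("makeblastdb",
    c("-in", sf, "-dbtype", "nucl", "-out", db),
    stdout = FALSE, stderr = FALSE
  )
  if (status != 0) stop("makeblastdb failed")
  outf <- file.path(dir, "hits.tsv")
  args <- c(
    "-query", qf, "-db", db, "-task", task,
    "-evalue", format(evalue, scientific = TRUE),
    "-dust", if (dust) "yes" else "no",
    "-soft_masking", "false",
    "-outfmt", shQuote(paste(
      "6 qseqid sseqid pident length mismatch gapopen",
      "qstart qend sstart send evalue bitscore"
    )),
    "-out", outf
  )
  if (perc_identity > 0) args <- c(args, "-perc_identity", perc_identity)
  status <- system2("blastn", args, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("blastn failed (exit ", status, ")")
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  if (file.size(outf) == 0) {
    out <- tibble::as_tibble(stats::setNames(
      c(
        list(character(), character()),
        rep(list(numeric()), 10)
      ), cols
    ))
    return(out)
  }
  df <- utils::read.table(outf,
    sep = "\t", col.names = cols,
    colClasses = c("character", "character", rep("numeric", 10))
  )
  tibble::as_tibble(df)
}

check_blast_available <- function() {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "") {
    stop(
      "NCBI BLAST+ (blastn/makeblastdb) not found on PATH; ",
      "it is required for homology searches"
    )
  }
  invisible(TRUE)
}

write_named_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unname(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract mitochondrial reads from a read database
#'
#' Keeps reads with at least one blastn hit to the reference genome at the
#' configured e-value cutoff — the standard construction of an organellar
#' read database from whole-genome sequencing reads.
#'
#' @param reads named character vector of read sequences
#' @param genome an [mt_genome()]
#' @param config a [pipeline_config()]
#' @return the subset of `reads` with a qualifying hit
#' @export
extract_mt_reads <- function(reads, genome, config = pipeline_config()) {
  if (length(reads) == 0L) return(reads)
  hits <- blast_hits(reads, stats::setNames(genome$seq, genome$id),
    evalue = config$homology_evalue
  )
  reads[names(reads) %in% unique(hits$qseqid)]
}
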