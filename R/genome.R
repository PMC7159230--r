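#' Genome sequence container
#'
#' A light S3 container for a single DNA molecule: an id, an uppercase IUPAC
#' sequence, and a topology flag. Plant mitochondrial assemblies are usually
#' presented as a "master circle" but may be linear contigs; several
#' operations (flank extraction, read simulation) behave differently on
#' circular molecules, so topology is carried explicitly.
#'
#' @param seq DNA string (will be uppercased)
#' @param id sequence label
#' @param topology `"circular"` or `"linear"`
#' @return an object of class `mt_genome` with fields `id`, `seq`,
#'   `topology`, `length`
#' @export
mt_genome <- function(seq, id = "genome", topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  seq <- toupper(as.character(seq))
  if (!grepl("^[ACGTRYSWKMBDHVN]*$", seq)) {
    stop("sequence contains non-IUPAC characters")
  }
  structure(
    list(id = id, seq = seq, topology = topology, length = nchar(seq)),
    class = "mt_genome"
  )
}

#' @export
print.mt_genome <- function(x, ...) {
  cat(sprintf(
    "<mt_genome> %s: %s bp, %s\n", x$id,
    format(x$length, big.mark = ","), x$topology
  ))
  invisible(x)
}

#' Load a genome from a FASTA file
#'
#' Reads one record from a FASTA file and returns it uppercased. Multi-record
#' files require an explicit `record` selector; silently taking the first of
#' several records is refused.
#'
#' @param path FASTA file
#' @param topology `"circular"` or `"linear"`
#' @param record record to take: index or exact name; required when the file
#'   holds more than one record
#' @return an [mt_genome()]
#' @export
load_genome <- function(path, topology = c("circular", "linear"), record = NULL) {
  topology <- match.arg(topology)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  if (length(ss) > 1L && is.null(record)) {
    stop(
      "FASTA file ", path, " has ", length(ss),
      " records; pass `record = ` to select one"
    )
  }
  i <- 1L
  if (!is.null(record)) {
    i <- if (is.numeric(record)) as.integer(record) else {
      m <- match(record, sub("\\s.*", "", names(ss)))
      if (is.na(m)) stop("record '", record, "' not found in ", path)
      m
    }
    if (is.na(i) || i < 1L || i > length(ss)) stop("record selector out of range")
  }
  mt_genome(as.character(ss[[i]]), id = sub("\\s.*", "", names(ss)[i]), topology = topology)
}

#' Extract a subsequence, honouring circular topology
#'
#' 1-based inclusive coordinates. On circular genomes, coordinates outside
#' `[1, length]` wrap around the origin (e.g. `start = -9` reads the last 10
#' bases first). On linear genomes the interval is clipped to the molecule
#' with a warning.
#'
#' @param genome an [mt_genome()]
#' @param start,end 1-based inclusive bounds, `start <= end` on the unwrapped
#'   axis
#' @return character DNA string
#' @export
genome_subseq <- function(genome, start, end) {
  stopifnot(inherits(genome, "mt_genome"), start <= end)
  L <- genome$length
  if (start >= 1 && end <= L) {
    return(substr(genome$seq, start, end))
  }
  if (genome$topology == "circular") {
    len <- end - start + 1L
    if (len > L) stop("requested interval longer than circular genome")
    s0 <- ((start - 1L) %% L) + 1L  # wrapped start
    if (s0 + len - 1L <= L) {
      return(substr(genome$seq, s0, s0 + len - 1L))
    }
    return(paste0(
      substr(genome$seq, s0, L),
      substr(genome$seq, 1L, len - (L - s0 + 1L))
    ))
  }
  warning("interval [", start, ",", end, "] clipped to linear genome bounds")
  substr(genome$seq, max(1L, start), min(L, end))
}

#' GC content of a genome
#'
#' @param genome an [mt_genome()]
#' @return fraction of G+C among unambiguous bases
#' @export
gc_content <- function(genome) {
  counts <- Biostrings::alphabetFrequency(Biostrings::DNAString(genome$seq))
  acgt <- counts[c("A", "C", "G", "T")]
  unname((acgt["G"] + acgt["C"]) / sum(acgt))
}

#' Write genomes to FASTA
#'
#' @param genomes an [mt_genome()] or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genomes, path) {
  if (inherits(genomes, "mt_genome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, function(g) g$seq, character(1)))
  names(ss) <- vapply(genomes, function(g) g$id, character(1))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
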