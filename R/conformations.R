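# Master/alternative conformation references for a repeat pair.
#
# For a repeat pair with copies R1 (flanked by A upstream, B downstream) and
# R2 (flanked by C, D), homologous recombination exchanges the flanks across
# the repeat. The two master references A-R1-B and C-R2-D are genomic
# substrings; the recombinant (alternative) references carry the novel
# flank/repeat junctions. With identical copies there is a single repeat
# version and two distinct recombinants; with diverged copies each
# recombinant junction can carry either repeat version and the repeat can
# also be swapped between its native flanks, giving six recombinants — four
# or eight references in total. For inverted pairs the exchanged flanks enter
# reverse-complemented so that every reference is a contiguous plausible
# molecule.

#' Build the conformation reference set for a repeat pair
#'
#' @param pair one row of a `repeat_pairs` tibble (or an equivalent list with
#'   `start1`, `end1`, `start2`, `end2`, `orientation`, `identity`, `id`)
#' @param genome the [mt_genome()] the pair was found in
#' @param config a [pipeline_config()]; `flank_len` sets the flank size and
#'   `read_support_flank_cov` the minimum usable flank
#' @return an object of class `conformation_set`: list with `pair`,
#'   `references` (tibble: `name`, `role`, `seq`, `repeat_start`,
#'   `repeat_end`, `flank_overlap`), `n_master`, `n_alternative`, `removed`
#' @export
build_conformation_set <- function(pair, genome, config = pipeline_config()) {
  stopifnot(inherits(genome, "mt_genome"))
  p <- as.list(pair)
  f <- config$flank_len
  L <- genome$length
  exact <- p$identity >= 100

  flank <- function(start, end) {
    # clip to the molecule on linear genomes; wrap on circular
    if (genome$topology == "linear") {
      s <- max(1L, start)
      e <- min(L, end)
      if (s > e) return("")
      if (s != start || e != end) {
        warning("flank [", start, ",", end, "] truncated at linear genome end")
      }
      return(substr(genome$seq, s, e))
    }
    genome_subseq(genome, start, end)
  }

  A <- flank(p$start1 - f, p$start1 - 1L)
  B <- flank(p$end1 + 1L, p$end1 + f)
  C <- flank(p$start2 - f, p$start2 - 1L)
  D <- flank(p$end2 + 1L, p$end2 + f)
  if (min(nchar(A), nchar(B), nchar(C), nchar(D)) < config$read_support_flank_cov) {
    stop(
      "a flank of repeat pair ", p$id %||% "?", " is shorter than the ",
      config$read_support_flank_cov, " bp read-support coverage window"
    )
  }
  r1 <- substr(genome$seq, p$start1, p$end1)
  R2g <- substr(genome$seq, p$start2, p$end2)

  ref <- function(name, role, left, mid, right) {
    tibble::tibble(
      name = name, role = role, seq = paste0(left, mid, right),
      repeat_start = nchar(left) + 1L,
      repeat_end = nchar(left) + nchar(mid)
    )
  }

  refs <- list(
    ref("master_1", "master", A, r1, B),
    ref("master_2", "master", C, R2g, D)
  )
  if (p$orientation == "direct") {
    if (exact) {
      refs <- c(refs, list(
        ref("alt_AR1D", "alternative", A, r1, D),
        ref("alt_CR1B", "alternative", C, r1, B)
      ))
    } else {
      refs <- c(refs, list(
        ref("alt_AR1D", "alternative", A, r1, D),
        ref("alt_AR2D", "alternative", A, R2g, D),
        ref("alt_CR1B", "alternative", C, r1, B),
        ref("alt_CR2B", "alternative", C, R2g, B),
        ref("alt_AR2B", "alternative", A, R2g, B),
        ref("alt_CR1D", "alternative", C, r1, D)
      ))
    }
  } else {
    r2i <- revcomp(R2g) # copy2 in copy1 orientation
    rcB <- revcomp(B)
    rcC <- revcomp(C)
    if (exact) {
      refs <- c(refs, list(
        ref("alt_AR1cC", "alternative", A, r1, rcC),
        ref("alt_cBR2D", "alternative", rcB, R2g, D)
      ))
    } else {
      refs <- c(refs, list(
        ref("alt_AR1cC", "alternative", A, r1, rcC),
        ref("alt_AR2cC", "alternative", A, r2i, rcC),
        ref("alt_cBR2D", "alternative", rcB, R2g, D),
        ref("alt_cBR1D", "alternative", rcB, revcomp(r1), D),
        ref("alt_AR2B", "alternative", A, r2i, B),
        ref("alt_CR1D", "alternative", C, revcomp(r1), D)
      ))
    }
  }
  references <- dplyr::bind_rows(refs)

  # record flanks that run into the partner copy (tandem-like pairs)
  overlaps <- function(s1, e1, s2, e2) s1 <= e2 && s2 <= e1
  references$flank_overlap <-
    overlaps(p$end1 + 1L, p$end1 + f, p$start2, p$end2) ||
      overlaps(p$start2 - f, p$start2 - 1L, p$start1, p$end1)

  structure(
    list(
      pair = p,
      references = references,
      n_master = sum(references$role == "master"),
      n_alternative = sum(references$role == "alternative"),
      removed = character()
    ),
    class = "conformation_set"
  )
}

#' @export
print.conformation_set <- function(x, ...) {
  cat(sprintf(
    "<conformation_set> pair %s (%s, %.2f%%): %d master + %d alternative references%s\n",
    x$pair$id %||% "?", x$pair$orientation, x$pair$identity,
    x$n_master, x$n_alternative,
    if (length(x$removed)) paste0(" (", length(x$removed), " screened out)") else ""
  ))
  invisible(x)
}

#' Screen recombinant references against the genome
#'
#' An alternative reference whose sequence is itself present in the genome
#' carries no evidence of recombination: reads matching it may simply come
#' from the master molecule. Such references are removed before read
#' counting. A reference is removed when a single genomic alignment (either
#' strand) covers at least `config$screen_coverage` of its length at
#' `config$screen_identity` percent identity or better, and spans the
#' recombinant junctions (one base beyond each end of the repeat span).
#' Master references are never removed.
#'
#' @param confs a `conformation_set`
#' @param genome the [mt_genome()]
#' @param config a [pipeline_config()]
#' @return the `conformation_set` with screened references dropped and their
#'   names recorded in `$removed`
#' @export
screen_recombinants <- function(confs, genome, config = pipeline_config()) {
  stopifnot(inherits(confs, "conformation_set"))
  refs <- confs$references
  alt <- refs[refs$role == "alternative", , drop = FALSE]
  if (nrow(alt) == 0L) return(confs)
  hits <- blast_hits(
    stats::setNames(alt$seq, alt$name),
    stats::setNames(genome$seq, genome$id),
    evalue = config$homology_evalue,
    perc_identity = config$screen_identity
  )
  drop <- character()
  for (i in seq_len(nrow(alt))) {
    h <- hits[hits$qseqid == alt$name[i], , drop = FALSE]
    if (nrow(h) == 0L) next
    qlen <- nchar(alt$seq[i])
    located <- h$pident >= config$screen_identity &
      (h$qend - h$qstart + 1) >= config$screen_coverage * qlen &
      h$qstart <= alt$repeat_start[i] - 1L &
      h$qend >= alt$repeat_end[i] + 1L
    if (any(located)) drop <- c(drop, alt$name[i])
  }
  confs$references <- refs[!refs$name %in% drop, , drop = FALSE]
  confs$removed <- c(confs$removed, drop)
  confs$n_master <- sum(confs$references$role == "master")
  confs$n_alternative <- sum(confs$references$role == "alternative")
  confs
}
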