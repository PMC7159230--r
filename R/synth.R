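# Synthetic mitochondrial genomes, recombinant conformations, and long reads
# with full ground truth. The generator emulates the inputs of a repeat
# recombination study: a circular (or linear) genome with planted repeat
# pairs of chosen length, identity and orientation; alternative conformations
# obtained by recombining at a planted pair; and a long-read set drawn from a
# weighted mixture of conformations with a simple i.i.d. error model.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(seed)
  expr
}

#' Specify a repeat to plant
#'
#' @param length repeat length in bp (>= 50)
#' @param identity target percent identity between the two copies
#'   (85 < identity <= 100); divergence is realised as uniformly placed
#'   substitutions
#' @param orientation `"direct"` or `"inverted"`
#' @param positions `"random"`, or a two-element integer vector of copy start
#'   positions
#' @return an object of class `repeat_spec`
#' @export
repeat_spec <- function(length, identity = 100,
                        orientation = c("direct", "inverted"),
                        positions = "random") {
  orientation <- match.arg(orientation)
  stopifnot(length >= 50, identity > 85, identity <= 100)
  structure(
    list(
      length = as.integer(length), identity = identity,
      orientation = orientation, positions = positions
    ),
    class = "repeat_spec"
  )
}

#' Generate a random genome with planted repeat pairs
#'
#' The background is i.i.d. random sequence (uniform ACGT by default, or
#' GC-weighted); each spec is realised by copying a source segment to a
#' second location, degrading the copy to the target identity with uniformly
#' placed substitutions, and reverse-complementing it for inverted specs.
#' Copies are placed so that each repeat and its flanks (1000 bp + margin)
#' do not collide with another planted copy.
#'
#' @param length genome length in bp
#' @param specs list of [repeat_spec()] objects (may be empty)
#' @param seed integer RNG seed
#' @param topology genome topology (default circular)
#' @param gc background GC fraction (default 0.5; e.g. 0.466 matches a
#'   typical angiosperm mitochondrial genome)
#' @param margin minimum clearance in bp between planted copies (default
#'   1100, leaving room for 1000-bp conformation flanks)
#' @param min_separation minimum distance in bp between the two copies of a
#'   direct repeat, on both arcs of a circular genome (default
#'   `min(25000, length %/% 4)`), so that recombination sub-circles stay
#'   long enough to draw long reads from
#' @return list with `genome` (an [mt_genome()]) and `truth` (class
#'   `synthetic_truth`: `seed`, `repeats` tibble with realised coordinates
#'   and identities)
#' @export
generate_genome <- function(length, specs = list(), seed = 1,
                            topology = c("circular", "linear"),
                            gc = 0.5, margin = 1100,
                            min_separation = min(25000, length %/% 4)) {
  topology <- match.arg(topology)
  stopifnot(length >= 1000)
  with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    chars <- sample(names(probs), length, replace = TRUE, prob = probs)

    occupied <- matrix(integer(), ncol = 2) # start, end (with margin applied)
    place <- function(len, spec_i, want = NULL, apart_from = NULL) {
      if (!is.null(want)) {
        s <- want
        if (s < margin || s + len - 1L > length - margin) {
          stop("requested position for spec ", spec_i, " does not fit")
        }
        return(s)
      }
      for (try in 1:2000) {
        s <- sample.int(length - len - 2L * margin, 1L) + margin
        e <- s + len - 1L
        clear <- nrow(occupied) == 0L ||
          all(s - margin > occupied[, 2] | e + margin < occupied[, 1])
        if (clear && !is.null(apart_from)) {
          # both arcs between the copies must exceed min_separation
          gap1 <- abs(s - apart_from)
          gap2 <- length - gap1
          clear <- min(gap1, gap2) >= min_separation
        }
        if (clear) return(s)
      }
      stop(
        "could not place repeat spec ", spec_i,
        " (length ", len, "): genome too crowded"
      )
    }

    rows <- vector("list", base::length(specs))
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      s1 <- place(sp$length, i, if (is.numeric(sp$positions)) sp$positions[1] else NULL)
      occupied <- rbind(occupied, c(s1, s1 + sp$length - 1L))
      s2 <- place(sp$length, i,
        if (is.numeric(sp$positions)) sp$positions[2] else NULL,
        apart_from = if (sp$orientation == "direct") s1 else NULL
      )
      occupied <- rbind(occupied, c(s2, s2 + sp$length - 1L))
      src <- chars[s1:(s1 + sp$length - 1L)]
      nsub <- round((100 - sp$identity) / 100 * sp$length)
      copy <- src
      if (nsub > 0) {
        # interior positions only, so the planted boundaries stay exact
        at <- sample.int(sp$length - 2L, nsub) + 1L
        copy[at] <- vapply(copy[at], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
      }
      if (sp$orientation == "inverted") {
        copy <- rev(chartr("ACGT", "TGCA", copy))
      }
      chars[s2:(s2 + sp$length - 1L)] <- copy
      # force the bases just outside the copies to disagree, so the planted
      # coordinates are the maximal repeat coordinates
      e1 <- s1 + sp$length - 1L
      e2 <- s2 + sp$length - 1L
      bases <- c("A", "C", "G", "T")
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      if (sp$orientation == "direct") {
        if (chars[s2 - 1L] == chars[s1 - 1L]) {
          chars[s2 - 1L] <- sample(setdiff(bases, chars[s1 - 1L]), 1L)
        }
        if (chars[e2 + 1L] == chars[e1 + 1L]) {
          chars[e2 + 1L] <- sample(setdiff(bases, chars[e1 + 1L]), 1L)
        }
      } else {
        if (comp[[chars[s2 - 1L]]] == chars[e1 + 1L]) {
          chars[s2 - 1L] <- sample(bases[comp[bases] != chars[e1 + 1L]], 1L)
        }
        if (comp[[chars[e2 + 1L]]] == chars[s1 - 1L]) {
          chars[e2 + 1L] <- sample(bases[comp[bases] != chars[s1 - 1L]], 1L)
        }
      }
      # canonical order: copy1 starts first
      a <- sort(c(s1, s2))
      rows[[i]] <- tibble::tibble(
        spec_id = i, length = sp$length,
        target_identity = sp$identity,
        realized_identity = round_half_up(100 * (sp$length - nsub) / sp$length, 2),
        n_substitutions = as.integer(nsub),
        orientation = sp$orientation,
        start1 = a[1], end1 = a[1] + sp$length - 1L,
        start2 = a[2], end2 = a[2] + sp$length - 1L
      )
    }
    genome <- mt_genome(paste(chars, collapse = ""),
      id = sprintf("synthetic_%d", seed), topology = topology
    )
    truth <- structure(
      list(
        seed = seed,
        repeats = if (base::length(rows)) dplyr::bind_rows(rows) else tibble::tibble(),
        mixture = NULL, reads = NULL
      ),
      class = "synthetic_truth"
    )
    list(genome = genome, truth = truth)
  })
}

#' Apply a recombination event at a repeat pair
#'
#' Recombination between the two copies of a repeat rearranges the molecule:
#' an inverted pair inverts the segment between (and including) the copies,
#' preserving length and base composition; a direct pair on a circular
#' molecule splits it into two sub-circles, each retaining one repeat copy;
#' a direct pair on a linear molecule excises a deletion circle and leaves a
#' shortened linear remainder. Lengths always sum to the parent length.
#'
#' @param genome an [mt_genome()]
#' @param pair one row of a `repeat_pairs` tibble (or equivalent list)
#' @return list of [mt_genome()] products (length 1 for inversions, 2 for
#'   direct-repeat events)
#' @export
apply_recombination <- function(genome, pair) {
  stopifnot(inherits(genome, "mt_genome"))
  p <- as.list(pair)
  L <- genome$length
  if (p$start2 <= p$end1) {
    stop("repeat copies overlap or are nested; recombination product undefined")
  }
  if (p$orientation == "inverted") {
    mid <- revcomp(substr(genome$seq, p$start1, p$end2))
    seq <- paste0(
      substr(genome$seq, 1L, p$start1 - 1L), mid,
      substr(genome$seq, p$end2 + 1L, L)
    )
    return(list(mt_genome(seq,
      id = paste0(genome$id, "_inv"),
      topology = genome$topology
    )))
  }
  if (genome$topology == "circular") {
    sub1 <- substr(genome$seq, p$start1, p$start2 - 1L)
    sub2 <- paste0(
      substr(genome$seq, p$start2, L),
      substr(genome$seq, 1L, p$start1 - 1L)
    )
    return(list(
      mt_genome(sub1, id = paste0(genome$id, "_subA"), topology = "circular"),
      mt_genome(sub2, id = paste0(genome$id, "_subB"), topology = "circular")
    ))
  }
  # linear direct: deletion circle (between-copy segment + one copy) plus
  # the junction-swapped linear remainder
  circle <- substr(genome$seq, p$end1 + 1L, p$end2)
  remainder <- paste0(
    substr(genome$seq, 1L, p$end1),
    substr(genome$seq, p$end2 + 1L, L)
  )
  list(
    mt_genome(remainder, id = paste0(genome$id, "_del"), topology = "linear"),
    mt_genome(circle, id = paste0(genome$id, "_circ"), topology = "circular")
  )
}

#' Conformation mixture for one recombinationally active repeat
#'
#' Builds the molecule pool for a genome in which a fraction `alt_fraction`
#' of molecules have undergone recombination at one repeat pair: the master
#' genome at weight `1 - alt_fraction`, and the recombination products
#' sharing `alt_fraction` in proportion to their lengths (so read coverage
#' per bp is uniform across the alternative pool).
#'
#' @param genome an [mt_genome()]
#' @param pair one row of a `repeat_pairs` tibble
#' @param alt_fraction fraction of molecules carrying the recombinant
#'   arrangement (0 to 1)
#' @param pair_id identifier recorded for the alternative molecules
#'   (default `pair$id`)
#' @return list with `conformations` (list of [mt_genome()]), `weights`, and
#'   `pair_ids` — ready to pass to [simulate_reads()]
#' @export
conformation_mixture <- function(genome, pair, alt_fraction,
                                 pair_id = NULL) {
  stopifnot(alt_fraction >= 0, alt_fraction <= 1)
  if (is.null(pair_id)) pair_id <- as.list(pair)$id
  if (alt_fraction == 0) {
    return(list(
      conformations = list(genome), weights = 1, pair_ids = NA
    ))
  }
  products <- apply_recombination(genome, pair)
  lens <- vapply(products, function(g) g$length, numeric(1))
  list(
    conformations = c(list(genome), products),
    weights = c(1 - alt_fraction, alt_fraction * lens / sum(lens)),
    pair_ids = c(NA, rep(pair_id, base::length(products)))
  )
}

#' Simulate long reads from a weighted mixture of conformations
#'
#' Each read picks a source conformation by the mixture weights, a uniform
#' start (wrapping on circular sources; uniform over fitting positions on
#' linear ones), a lognormal length with the requested mean, a uniform
#' strand, and i.i.d. errors at `error_rate` split
#' substitution:insertion:deletion = 2:1:1.
#'
#' @param conformations list of [mt_genome()] objects
#' @param weights mixture weights (non-negative, summing to 1)
#' @param n_reads number of reads
#' @param mean_len mean read length in bp (default 15000); must be below the
#'   shortest conformation length
#' @param error_rate per-base error probability (default 0)
#' @param seed integer RNG seed
#' @param sigma lognormal sdlog of the length distribution (default 0.5)
#' @param pair_ids optional vector (same length as `conformations`):
#'   identifier of the repeat pair whose recombination produced each
#'   conformation, `NA` for master molecules; recorded in the truth
#' @param genome_truth optional `synthetic_truth` from [generate_genome()];
#'   its planted-repeat table is carried into the returned truth
#' @return list with `reads` (named character vector) and `truth` (class
#'   `synthetic_truth` with `mixture` and per-read `reads` tibbles)
#' @export
simulate_reads <- function(conformations, weights, n_reads, mean_len = 15000,
                           error_rate = 0, seed = 1, sigma = 0.5,
                           pair_ids = NULL, genome_truth = NULL) {
  stopifnot(base::length(conformations) >= 1, n_reads >= 1)
  weights <- as.numeric(weights)
  stopifnot(
    base::length(weights) == base::length(conformations),
    all(weights >= 0), abs(sum(weights) - 1) < 1e-8
  )
  lens <- vapply(conformations, function(g) g$length, numeric(1))
  if (mean_len >= min(lens)) {
    stop("mean_len must be below the shortest conformation length")
  }
  if (is.null(pair_ids)) pair_ids <- rep(NA, base::length(conformations))
  with_seed(seed, {
    src <- sample.int(base::length(conformations), n_reads,
      replace = TRUE, prob = weights
    )
    meanlog <- log(mean_len) - sigma^2 / 2
    rlen <- pmax(50L, as.integer(round(stats::rlnorm(n_reads, meanlog, sigma))))
    reads <- character(n_reads)
    truth_rows <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      g <- conformations[[src[i]]]
      len <- min(rlen[i], g$length)
      start <- if (g$topology == "circular") {
        sample.int(g$length, 1L)
      } else {
        sample.int(g$length - len + 1L, 1L)
      }
      raw_read <- genome_subseq(g, start, start + len - 1L)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") raw_read <- revcomp(raw_read)
      err <- inject_errors(raw_read, error_rate)
      reads[i] <- err$seq
      truth_rows[[i]] <- tibble::tibble(
        read_id = sprintf("read_%05d", i),
        source = g$id, source_index = src[i],
        pair_id = pair_ids[src[i]],
        start = start, strand = strand, length = len,
        n_errors = err$n_errors,
        error_positions = list(err$positions)
      )
    }
    names(reads) <- sprintf("read_%05d", seq_len(n_reads))
    truth <- structure(
      list(
        seed = seed,
        repeats = if (!is.null(genome_truth)) genome_truth$repeats else NULL,
        mixture = tibble::tibble(
          conformation = vapply(conformations, function(g) g$id, character(1)),
          weight = weights,
          pair_id = pair_ids
        ),
        reads = dplyr::bind_rows(truth_rows)
      ),
      class = "synthetic_truth"
    )
    list(reads = reads, truth = truth)
  })
}

# i.i.d. error injection; substitution:insertion:deletion = 2:1:1.
inject_errors <- function(seq, error_rate) {
  if (error_rate <= 0) {
    return(list(seq = seq, n_errors = 0L, positions = integer()))
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- base::length(chars)
  at <- which(stats::runif(n) < error_rate)
  if (base::length(at) == 0L) {
    return(list(seq = seq, n_errors = 0L, positions = integer()))
  }
  type <- sample(c("sub", "ins", "del"), base::length(at),
    replace = TRUE, prob = c(2, 1, 1)
  )
  emit <- chars
  bases <- c("A", "C", "G", "T")
  for (k in seq_along(at)) {
    i <- at[k]
    if (type[k] == "sub") {
      emit[i] <- sample(setdiff(bases, chars[i]), 1L)
    } else if (type[k] == "del") {
      emit[i] <- ""
    } else {
      emit[i] <- paste0(chars[i], sample(bases, 1L))
    }
  }
  list(
    seq = paste(emit, collapse = ""),
    n_errors = base::length(at), positions = at
  )
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads named character vector
#' @param path output file
#' @param qual quality character applied to every base (default `"I"`)
#' @return `path` invisibly
#' @export
write_reads_fastq <- function(reads, path, qual = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(
      paste0("@", names(reads)[i]), reads[[i]], "+",
      strrep(qual, nchar(reads[[i]]))
    ), con)
  }
  invisible(path)
}

#' Load reads from FASTA or FASTQ
#'
#' @param path read file (format detected from the first character)
#' @return named character vector of uppercase read sequences
#' @export
load_reads <- function(path) {
  first <- readChar(path, 1L)
  ss <- if (identical(first, "@")) {
    Biostrings::readDNAStringSet(path, format = "fastq")
  } else {
    Biostrings::readDNAStringSet(path)
  }
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*", "", names(ss))
  out
}

#' Compare read-support results to planted truth
#'
#' Matches each planted repeat to a row of a [recombination_table()] by its
#' copy coordinates, and reports the estimated alternative fraction against
#' the planted mixture weight, plus active-flag confusion counts.
#'
#' @param results a [recombination_table()] output
#' @param truth a `synthetic_truth` from [simulate_reads()] carrying both the
#'   planted-repeat table and the mixture weights
#' @param tol coordinate tolerance in bp when matching repeats (default 10:
#'   a scanned repeat may extend a few bases past its planted boundary when
#'   the adjacent background happens to align profitably)
#' @return list with `per_repeat` (tibble: planted and estimated fractions,
#'   absolute error, flags) and `confusion` (named counts: true/false
#'   active/inactive)
#' @export
evaluate_recovery <- function(results, truth, tol = 10) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(truth$repeats) || is.null(truth$mixture)) {
    stop("truth must carry both planted repeats and mixture weights")
  }
  planted <- truth$repeats
  rows <- vector("list", nrow(planted))
  for (i in seq_len(nrow(planted))) {
    tr <- planted[i, ]
    m <- which(
      abs(results$start1 - tr$start1) <= tol &
        abs(results$end1 - tr$end1) <= tol &
        abs(results$start2 - tr$start2) <= tol &
        abs(results$end2 - tr$end2) <= tol
    )
    if (base::length(m) != 1L) {
      stop(
        "planted repeat ", tr$spec_id, " [", tr$start1, ",", tr$end1,
        "] matched ", base::length(m), " result rows (expected 1)"
      )
    }
    r <- results[m, ]
    planted_frac <- sum(truth$mixture$weight[
      !is.na(truth$mixture$pair_id) & truth$mixture$pair_id == tr$spec_id
    ])
    total <- r$reads_alternative + r$reads_master
    est <- if (total > 0) r$reads_alternative / total else NA_real_
    rows[[i]] <- tibble::tibble(
      spec_id = tr$spec_id, pair_id = r$pair_id, length = tr$length,
      planted_fraction = planted_frac,
      estimated_fraction = est,
      abs_error = abs(est - planted_frac),
      n_reads = as.integer(total),
      active = r$active,
      expected_active = planted_frac > 0
    )
  }
  per_repeat <- dplyr::bind_rows(rows)
  list(
    per_repeat = per_repeat,
    confusion = c(
      true_active = sum(per_repeat$active & per_repeat$expected_active),
      false_active = sum(per_repeat$active & !per_repeat$expected_active),
      false_inactive = sum(!per_repeat$active & per_repeat$expected_active),
      true_inactive = sum(!per_repeat$active & !per_repeat$expected_active)
    )
  )
}
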