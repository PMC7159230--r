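# Synthetic genomes, recombination products, and read simulation.

test_that("identical seeds give byte-identical genomes, truth, and reads", {
  a <- generate_genome(20000, list(repeat_spec(200, 99, "inverted")), seed = 9)
  b <- generate_genome(20000, list(repeat_spec(200, 99, "inverted")), seed = 9)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth$repeats, b$truth$repeats)
  s1 <- simulate_reads(list(a$genome), 1, 50, 3000, 0.05, seed = 4)
  s2 <- simulate_reads(list(a$genome), 1, 50, 3000, 0.05, seed = 4)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth$reads, s2$truth$reads)
})

test_that("planted copies realise the requested identity", {
  gg <- generate_genome(20000, list(repeat_spec(1000, 99, "direct")), seed = 21)
  tr <- gg$truth$repeats
  a <- substr(gg$genome$seq, tr$start1, tr$end1)
  b <- substr(gg$genome$seq, tr$start2, tr$end2)
  expect_lt(abs(oracle_identity(a, b) - 99), 0.2)
  expect_equal(tr$realized_identity, 99)

  # inverted spec: identity holds against the reverse complement
  gi <- generate_genome(20000, list(repeat_spec(1000, 99.5, "inverted")), seed = 22)
  ti <- gi$truth$repeats
  a <- substr(gi$genome$seq, ti$start1, ti$end1)
  b <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    substr(gi$genome$seq, ti$start2, ti$end2)
  )))
  expect_lt(abs(oracle_identity(a, b) - 99.5), 0.2)
})

test_that("a spec-free genome contains no scan-detectable repeat", {
  gg <- generate_genome(50000, list(), seed = 23)
  expect_equal(nrow(gg$truth$repeats), 0L)
  expect_equal(nrow(find_repeat_pairs(gg$genome)), 0L)
})

test_that("infeasible packing errors, naming the offending spec", {
  expect_error(
    generate_genome(8000, list(
      repeat_spec(2000, 100, "direct"), repeat_spec(2000, 100, "direct")
    ), seed = 24),
    "spec"
  )
})

test_that("inversion products conserve length and composition, and invert back", {
  gg <- generate_genome(30000, list(repeat_spec(400, 100, "inverted")), seed = 25)
  pair <- find_repeat_pairs(gg$genome)[1, ]
  prod <- apply_recombination(gg$genome, pair)
  expect_length(prod, 1L)
  expect_equal(prod[[1]]$length, gg$genome$length)
  # composition of the double-stranded molecule is conserved: inverting a
  # segment swaps A<->T and C<->G within it, so A+T and G+C totals hold
  count <- function(s) {
    tab <- table(factor(strsplit(s, "")[[1]], levels = c("A", "C", "G", "T")))
    c(at = tab[["A"]] + tab[["T"]], gc = tab[["G"]] + tab[["C"]])
  }
  expect_equal(count(prod[[1]]$seq), count(gg$genome$seq))
  back <- apply_recombination(prod[[1]], pair)[[1]]
  expect_identical(back$seq, gg$genome$seq)
})

test_that("direct-repeat recombination splits a circle into two sub-circles", {
  gg <- generate_genome(60000, list(repeat_spec(500, 100, "direct")), seed = 26)
  pair <- find_repeat_pairs(gg$genome)[1, ]
  prod <- apply_recombination(gg$genome, pair)
  expect_length(prod, 2L)
  expect_equal(sum(vapply(prod, function(g) g$length, numeric(1))), gg$genome$length)
  expect_true(all(vapply(prod, function(g) g$topology, character(1)) == "circular"))
  # each sub-circle retains exactly one repeat copy
  for (g in prod) {
    hits <- gregexpr(substr(gg$genome$seq, pair$start1, pair$end1),
      paste0(g$seq, g$seq),
      fixed = TRUE
    )[[1]]
    n <- sum(hits > 0 & hits <= g$length)
    expect_equal(n, 1L)
  }
})

test_that("direct-repeat recombination on a linear molecule excises a circle", {
  gg <- generate_genome(60000, list(repeat_spec(500, 100, "direct")),
    seed = 27, topology = "linear"
  )
  pair <- find_repeat_pairs(gg$genome)[1, ]
  prod <- apply_recombination(gg$genome, pair)
  expect_length(prod, 2L)
  expect_equal(sum(vapply(prod, function(g) g$length, numeric(1))), gg$genome$length)
  expect_setequal(vapply(prod, function(g) g$topology, character(1)),
    c("linear", "circular"))
})

test_that("nested or overlapping copies refuse to recombine", {
  g <- mt_genome(random_dna(5000), topology = "circular")
  pair <- tibble::tibble(
    id = 1L, length = 300L, identity = 100,
    start1 = 1000L, end1 = 1299L, start2 = 1200L, end2 = 1499L,
    orientation = "direct"
  )
  expect_error(apply_recombination(g, pair), "overlap")
})

test_that("error-free reads are exact substrings of their source", {
  gg <- generate_genome(30000, list(), seed = 28)
  sim <- simulate_reads(list(gg$genome), 1, 60, mean_len = 4000, seed = 29)
  doubled <- paste0(gg$genome$seq, gg$genome$seq) # circular wrap
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(doubled)))
  for (r in sim$reads) {
    expect_true(grepl(r, doubled, fixed = TRUE) || grepl(r, rc, fixed = TRUE))
  }
})

test_that("mixture source counts follow the weights binomially", {
  gg <- generate_genome(30000, list(), seed = 30)
  g2 <- mt_genome(random_dna(30000), id = "other", topology = "circular")
  sim <- simulate_reads(list(gg$genome, g2), c(0.5, 0.5), 400,
    mean_len = 3000, seed = 31
  )
  n1 <- sum(sim$truth$reads$source_index == 1)
  expect_lt(abs(n1 - 200), 3 * sqrt(400 * 0.25))
})

test_that("read lengths average to the requested mean", {
  gg <- generate_genome(60000, list(), seed = 32)
  sim <- simulate_reads(list(gg$genome), 1, 10000, mean_len = 5000, seed = 33)
  expect_lt(abs(mean(sim$truth$reads$length) - 5000) / 5000, 0.02)
})

test_that("simulate_reads enforces its length precondition", {
  g <- mt_genome(random_dna(2000), topology = "circular")
  expect_error(simulate_reads(list(g), 1, 10, mean_len = 3000, seed = 1), "mean_len")
  expect_error(
    simulate_reads(list(g), c(0.5, 0.6), 10, mean_len = 500, seed = 1)
  )
})

test_that("injected errors change the read at the recorded rate", {
  set.seed(34)
  src <- random_dna(20000)
  err <- mitorecomb:::inject_errors(src, 0.05)
  expect_gt(err$n_errors, 20000 * 0.05 * 0.7)
  expect_lt(err$n_errors, 20000 * 0.05 * 1.3)
  expect_false(identical(err$seq, src))
  # length roughly conserved: insertions and deletions balance in expectation
  expect_lt(abs(nchar(err$seq) - 20000), 20000 * 0.01)
})

test_that("reads round-trip through FASTQ and FASTA", {
  reads <- c(r1 = "ACGTACGTAA", r2 = "GGGTTTCCCA")
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_reads_fastq(reads, fq)
  expect_identical(load_reads(fq), reads)
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(
    list(
      mt_genome("ACGT", id = "r1", topology = "linear"),
      mt_genome("GGCC", id = "r2", topology = "linear")
    ),
    fa
  )
  expect_identical(load_reads(fa), c(r1 = "ACGT", r2 = "GGCC"))
})

test_that("evaluate_recovery reports zero false actives for a master-only mixture", {
  gg <- generate_genome(40000, list(repeat_spec(400, 100, "inverted")), seed = 35)
  pairs <- find_repeat_pairs(gg$genome)
  sim <- simulate_reads(list(gg$genome), 1, 120,
    mean_len = 6000, seed = 36,
    pair_ids = NA, genome_truth = gg$truth
  )
  tab <- recombination_table(pairs, gg$genome, sim$reads)
  rec <- evaluate_recovery(tab, sim$truth)
  expect_equal(unname(rec$confusion["false_active"]), 0L)
  expect_equal(rec$per_repeat$estimated_fraction, 0)
  expect_equal(rec$per_repeat$planted_fraction, 0)
})

test_that("evaluate_recovery errors when a planted repeat has no matching row", {
  gg <- generate_genome(40000, list(repeat_spec(400, 100, "direct")), seed = 37)
  sim <- simulate_reads(list(gg$genome), 1, 10,
    mean_len = 4000, seed = 38,
    genome_truth = gg$truth
  )
  no_pairs <- suppressWarnings(
    find_repeat_pairs(mt_genome(random_dna(200), topology = "linear"))
  )
  empty <- recombination_table(no_pairs, gg$genome, sim$reads)
  expect_equal(nrow(empty), 0L)
  expect_error(evaluate_recovery(empty, sim$truth), "matched 0")
})
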