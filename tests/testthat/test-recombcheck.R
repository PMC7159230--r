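# Conformation references, genomic screening, and read-support counting.

# A hand-built toy genome with explicit flank/repeat blocks, so expected
# reference sequences can be written down as plain string concatenations.
make_block_genome <- function(seed, repeat_len = 300, flank = 1000,
                              orientation = "direct", n_mismatch = 0) {
  set.seed(seed)
  bg1 <- random_dna(2000)
  A <- random_dna(flank)
  R1 <- random_dna(repeat_len)
  B <- random_dna(flank)
  bg2 <- random_dna(2000)
  C <- random_dna(flank)
  D <- random_dna(flank)
  bg3 <- random_dna(2000)
  R2 <- R1
  if (n_mismatch > 0) {
    ch <- strsplit(R2, "")[[1]]
    at <- sample(2:(repeat_len - 1), n_mismatch)
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    R2 <- paste(ch, collapse = "")
  }
  R2g <- if (orientation == "inverted") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(R2)))
  } else {
    R2
  }
  seq <- paste0(bg1, A, R1, B, bg2, C, R2g, D, bg3)
  s1 <- nchar(bg1) + flank + 1L
  s2 <- nchar(bg1) + flank + repeat_len + flank + 2000 + flank + 1L
  pair <- tibble::tibble(
    id = 1L, length = repeat_len,
    identity = round(100 * (repeat_len - n_mismatch) / repeat_len, 2),
    start1 = s1, end1 = s1 + repeat_len - 1L,
    start2 = s2, end2 = s2 + repeat_len - 1L,
    orientation = orientation, size_class = "medium",
    n_matches = repeat_len - n_mismatch, score = 0
  )
  list(
    genome = mt_genome(seq, topology = "linear"), pair = pair,
    A = A, R1 = R1, B = B, C = C, R2 = R2, R2g = R2g, D = D
  )
}

test_that("alternative references equal the string-concatenation oracle (direct, exact)", {
  tg <- make_block_genome(501)
  cs <- build_conformation_set(tg$pair, tg$genome)
  expect_equal(nrow(cs$references), 4L)
  expect_equal(cs$n_master, 2L)
  expect_equal(cs$n_alternative, 2L)
  refs <- cs$references
  expect_equal(
    refs$seq[refs$name == "alt_AR1D"], paste0(tg$A, tg$R1, tg$D)
  )
  expect_equal(
    refs$seq[refs$name == "alt_CR1B"], paste0(tg$C, tg$R1, tg$B)
  )
  # masters are exact genome substrings
  for (s in refs$seq[refs$role == "master"]) {
    expect_true(grepl(s, tg$genome$seq, fixed = TRUE))
  }
  # repeat span bookkeeping
  expect_equal(unique(refs$repeat_start), 1001L)
  expect_equal(unique(refs$repeat_end), 1300L)
})

test_that("two mismatches in copy2 switch the set from 4 to 8 references", {
  tg <- make_block_genome(502, n_mismatch = 2)
  cs <- build_conformation_set(tg$pair, tg$genome)
  expect_equal(nrow(cs$references), 8L)
  expect_equal(cs$n_alternative, 6L)
  refs <- cs$references
  expect_setequal(
    refs$name[refs$role == "alternative"],
    c("alt_AR1D", "alt_AR2D", "alt_CR1B", "alt_CR2B", "alt_AR2B", "alt_CR1D")
  )
  expect_equal(refs$seq[refs$name == "alt_AR2D"], paste0(tg$A, tg$R2, tg$D))
  expect_equal(refs$seq[refs$name == "alt_CR1B"], paste0(tg$C, tg$R1, tg$B))
})

test_that("inverted alternatives carry reverse-complemented exchanged flanks", {
  tg <- make_block_genome(503, orientation = "inverted")
  cs <- build_conformation_set(tg$pair, tg$genome)
  expect_equal(nrow(cs$references), 4L)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  refs <- cs$references
  expect_equal(refs$seq[refs$name == "alt_AR1cC"], paste0(tg$A, tg$R1, rc(tg$C)))
  expect_equal(refs$seq[refs$name == "alt_cBR2D"], paste0(rc(tg$B), tg$R2g, tg$D))
  # and they appear verbatim in the explicit inversion product
  prod <- apply_recombination(tg$genome, tg$pair)[[1]]
  for (s in refs$seq[refs$role == "alternative"]) {
    expect_true(grepl(s, prod$seq, fixed = TRUE))
  }
})

test_that("flanks truncate with a warning at linear genome ends, and short flanks error", {
  g <- mt_genome(random_dna(3000), topology = "linear")
  pair <- tibble::tibble(
    id = 1L, length = 100L, identity = 100,
    start1 = 500L, end1 = 599L, start2 = 2000L, end2 = 2099L,
    orientation = "direct"
  )
  w <- testthat::capture_warnings(cs <- build_conformation_set(pair, g))
  expect_true(all(grepl("truncated", w)))
  expect_gte(length(w), 1L)
  expect_equal(cs$references$repeat_start[1], 500L) # left flank only 499 bp

  pair_edge <- pair
  pair_edge$start1 <- 50L
  pair_edge$end1 <- 149L
  expect_error(
    suppressWarnings(build_conformation_set(pair_edge, g)),
    "coverage window"
  )
})

test_that("circular genomes wrap flanks around the origin", {
  set.seed(504)
  core <- random_dna(8000)
  g <- mt_genome(core, topology = "circular")
  pair <- tibble::tibble(
    id = 1L, length = 100L, identity = 100,
    start1 = 300L, end1 = 399L, start2 = 4000L, end2 = 4099L,
    orientation = "direct"
  )
  cs <- build_conformation_set(pair, g)
  m1 <- cs$references$seq[cs$references$name == "master_1"]
  expect_equal(nchar(m1), 2100L)
  expect_equal(substr(m1, 1, 701), paste0(substr(core, 7300, 8000)))
})

test_that("recombinants present in the genome are screened out", {
  # Period-shifted copies inside a long tandem array: the recombinant
  # junction products are phase-continuous periodic sequence, i.e. exact
  # substrings of the genome, so they carry no recombination evidence.
  set.seed(505)
  unit <- random_dna(60)
  array <- strrep(unit, 80) # 4800 bp tandem array
  bgl <- random_dna(1500)
  bgr <- random_dna(1500)
  g <- mt_genome(paste0(bgl, array, bgr), topology = "linear")
  s <- nchar(bgl) + 2401L # copy1 starts mid-array, phase-aligned
  pair <- tibble::tibble(
    id = 1L, length = 180L, identity = 100,
    start1 = s, end1 = s + 179L, start2 = s + 60L, end2 = s + 239L,
    orientation = "direct"
  )
  cs <- build_conformation_set(pair, g)
  expect_true(cs$references$flank_overlap[1])
  # both recombinants are exact genomic substrings here
  alts <- cs$references[cs$references$role == "alternative", ]
  for (sq in alts$seq) expect_true(grepl(sq, g$seq, fixed = TRUE))
  scr <- screen_recombinants(cs, g)
  expect_setequal(scr$removed, alts$name)
  expect_equal(scr$n_alternative, 0L)
  expect_equal(scr$n_master, 2L) # masters never removed
  # read support is then reported only over the remaining references
  m1 <- scr$references[scr$references$name == "master_1", ]
  reads <- c(r1 = substr(m1$seq, m1$repeat_start - 600, m1$repeat_end + 600))
  rs <- count_read_support(scr, reads)
  expect_false(rs$active)
  expect_equal(rs$reads_master, 1L)
})

test_that("recombinants sharing only flanks with the genome are retained", {
  tg <- make_block_genome(506)
  cs <- build_conformation_set(tg$pair, tg$genome)
  scr <- screen_recombinants(cs, tg$genome)
  expect_equal(length(scr$removed), 0L)
  expect_equal(scr$n_alternative, 2L)
})

test_that("read support needs identity above 95% and 200 bp of both flanks", {
  tg <- make_block_genome(507)
  cs <- build_conformation_set(tg$pair, tg$genome)
  ref <- cs$references[cs$references$name == "master_1", ]
  # perfect read spanning repeat +- 500 bp
  spanning <- substr(ref$seq, ref$repeat_start - 500, ref$repeat_end + 500)
  expect_true(read_supports_reference(spanning, ref))
  # reverse complement also qualifies
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(spanning)))
  expect_true(read_supports_reference(rc, ref))
  # only 150 bp of the left flank
  short <- substr(ref$seq, ref$repeat_start - 150, ref$repeat_end + 500)
  expect_false(read_supports_reference(short, ref))
  # 8% uniform errors push identity below the threshold
  set.seed(508)
  noisy <- mitorecomb:::inject_errors(spanning, 0.08)$seq
  expect_false(read_supports_reference(noisy, ref))
})

test_that("each read is counted once, ties resolved toward master", {
  tg <- make_block_genome(509)
  cs <- build_conformation_set(tg$pair, tg$genome)
  scr <- screen_recombinants(cs, tg$genome)
  m1 <- scr$references[scr$references$name == "master_1", ]
  reads <- stats::setNames(
    rep(substr(m1$seq, m1$repeat_start - 600, m1$repeat_end + 600), 10),
    paste0("r", 1:10)
  )
  rs <- count_read_support(scr, reads)
  expect_equal(rs$reads_master, 10L)
  expect_equal(rs$reads_alternative, 0L)
  expect_false(rs$active)
  expect_equal(rs$master_percent, 100)

  # empty read database: counts 0/0, percentages NA
  rs0 <- count_read_support(scr, character())
  expect_equal(rs0$reads_master + rs0$reads_alternative, 0L)
  expect_true(is.na(rs0$alt_percent))
})

test_that("a planted conformational mixture is recovered within binomial error", {
  gg <- generate_genome(60000, list(repeat_spec(800, 100, "inverted")),
    seed = 510
  )
  pairs <- find_repeat_pairs(gg$genome)
  expect_equal(nrow(pairs), 1L)
  mix <- conformation_mixture(gg$genome, pairs[1, ], 0.5)
  sim <- simulate_reads(mix$conformations, mix$weights, 400,
    mean_len = 8000, error_rate = 0, seed = 511,
    pair_ids = mix$pair_ids, genome_truth = gg$truth
  )
  tab <- recombination_table(pairs, gg$genome, sim$reads)
  n <- tab$reads_alternative + tab$reads_master
  expect_gt(n, 30)
  se <- sqrt(0.25 / n)
  expect_lt(abs(tab$reads_alternative / n - 0.5), 3 * se)
  expect_true(tab$active)
})

test_that("master-only reads flag no repeat as active", {
  gg <- generate_genome(50000, list(
    repeat_spec(500, 100, "direct"), repeat_spec(300, 99, "inverted")
  ), seed = 512)
  pairs <- find_repeat_pairs(gg$genome)
  expect_equal(nrow(pairs), 2L)
  sim <- simulate_reads(list(gg$genome), 1, 150,
    mean_len = 8000,
    error_rate = 0, seed = 513, genome_truth = gg$truth
  )
  tab <- recombination_table(pairs, gg$genome, sim$reads)
  expect_equal(sum(tab$active), 0L)
  expect_equal(sum(tab$reads_alternative), 0L)
  # rows sorted by descending repeat length
  expect_equal(tab$length, sort(tab$length, decreasing = TRUE))
})
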