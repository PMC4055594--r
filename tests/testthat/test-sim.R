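test_that("recommended insert size follows the paired-end formula", {
  expect_equal(recommended_insert_size(150, 50, 100), 300)
  expect_equal(recommended_insert_size(36, 10, 30), 62)
  expect_error(recommended_insert_size(100, 0, 200), "insert size")
  expect_error(recommended_insert_size(-1, 0, 0), "nonnegative")
})

test_that("genome generation plants families faithfully and deterministically", {
  fams <- list(repeat_family(3, 400), repeat_family(2, 600, mode = "tandem"))
  g1 <- make_genome(20000, fams, seed = 42)
  g2 <- make_genome(20000, fams, seed = 42)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotations, g2$annotations)
  expect_equal(nchar(g1$sequence), 20000)
  expect_equal(nrow(g1$annotations), 5)  # 3 interspersed + 2 tandem copies

  # annotated substrings are the family unit; brute-force scan finds >= copies
  for (f in g1$families) {
    ann <- g1$annotations[g1$annotations$family_id == f$family_id, ]
    expect_equal(nrow(ann), f$copies)
    for (i in seq_len(nrow(ann)))
      expect_identical(substr(g1$sequence, ann$start[i] + 1L, ann$end[i]),
                       f$unit)
    hits <- gregexpr(f$unit, g1$sequence, fixed = TRUE)[[1]]
    expect_gte(length(hits), f$copies)
    expect_true(all((ann$start + 1L) %in% as.integer(hits)))
  }

  # tandem copies are contiguous; interspersed ones separated and off the ends
  tand <- g1$annotations[g1$annotations$family_id == "rep02", ]
  expect_equal(tand$start[-1], tand$end[-nrow(tand)])
  intr <- g1$annotations[g1$annotations$family_id == "rep01", ]
  intr <- intr[order(intr$start), ]
  expect_true(all(diff(intr$start) >= 400 + 200))
  expect_gte(min(intr$start), 200)
  expect_lte(max(intr$end), 20000 - 200)
})

test_that("degenerate and invalid genome requests are handled", {
  g <- make_genome(1000, list(), seed = 1)
  expect_equal(nchar(g$sequence), 1000)
  expect_equal(nrow(g$annotations), 0)
  expect_error(make_genome(1000, list(repeat_family(5, 300)), seed = 1),
               "genome too short|must be <")
  fams <- list(repeat_family(2, 100, family_id = "a"),
               repeat_family(2, 100, family_id = "a"))
  expect_error(make_genome(10000, fams, seed = 1), "duplicate")
})

test_that("read sampling conserves depth and is reproducible", {
  g <- make_genome(5000, list(), seed = 3)
  rd <- sample_reads(g, L_r = 60, S_d = 6, seed = 4)
  expect_equal(length(rd$sequence), round(6 * 5000))
  expect_true(all(nchar(rd$sequence) == 60))
  expect_true(all(nchar(rd$quality) == 60))
  rd2 <- sample_reads(g, L_r = 60, S_d = 6, seed = 4)
  expect_identical(rd$sequence, rd2$sequence)

  # fractional expected counts still land on round(S_d * L)
  rd3 <- sample_reads(g, L_r = 36, S_d = 0.33, seed = 5)
  expect_equal(length(rd3$sequence), round(0.33 * 5000))

  expect_equal(length(sample_reads(g, L_r = 60, S_d = 0, seed = 6)$sequence), 0)
  expect_error(sample_reads(g, L_r = 60, S_d = -1, seed = 6), "S_d")
})

test_that("error-free reads are genomic substrings in one orientation", {
  g <- make_genome(3000, list(repeat_family(2, 300)), seed = 9)
  rd <- sample_reads(g, L_r = 40, S_d = 2, seed = 10)
  n <- nchar(g$sequence)
  fwd <- substring(g$sequence, 1:(n - 39), 40:n)
  rc <- revcomp(fwd)
  expect_true(all(rd$sequence %in% c(fwd, rc)))
})

test_that("fragment lengths follow the configured insert distribution", {
  g <- make_genome(100000, list(), seed = 12)
  rd <- sample_reads(g, L_r = 60, S_d = 0.5, insert_mu = 300, insert_sd = 30,
                     seed = 13, keep_fragments = TRUE)
  fr <- rd$provenance$fragments
  expect_gte(nrow(fr), 1e4)
  expect_lt(abs(mean(fr$length) - 300), 1)
  expect_lt(abs(sd(fr$length) - 30), 1)
  expect_true(all(fr$length >= 60))
})

test_that("substitution errors and bias weighting behave as configured", {
  g <- make_genome(2000, list(), seed = 20)
  rd <- sample_reads(g, L_r = 50, S_d = 2, error_rate = 0.05, seed = 21)
  n <- nchar(g$sequence)
  fwd <- substring(g$sequence, 1:(n - 49), 50:n)
  rc <- revcomp(fwd)
  frac_exact <- mean(rd$sequence %in% c(fwd, rc))
  expect_lt(frac_exact, 0.5)  # 1 - (1-.05)^50 ~ 0.92 of reads carry an error
  expect_true(any(grepl("+", rd$quality, fixed = TRUE)))
  rdb <- sample_reads(g, L_r = 50, S_d = 2, bias_sigma = 1, seed = 22)
  expect_equal(length(rdb$sequence), 4000)
})
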