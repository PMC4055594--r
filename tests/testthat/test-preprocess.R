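mk_reads <- function(seqs, quals = NULL) {
  structure(list(id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
                 quality = if (is.null(quals))
                   rep(strrep("I", nchar(seqs[1])), length(seqs)) else quals,
                 L_r = nchar(seqs[1]), S_d = NA_real_, provenance = list()),
            class = "swa_reads")
}

test_that("cleaning drops N-containing and low-quality reads, keeping order", {
  seqs <- c("ACGTACGTAC", "ACGNTACGTA", "TTTTTTTTTT", "GGGGGGGGGG",
            "ACACACACAC", "GTGTGTGTGT", "CCCCCCCCCC", "AAAAAAAAAA",
            "TACGTACGTA", "CGTACGTACG")
  quals <- rep(strrep("I", 10), 10)
  quals[4] <- paste0(strrep("I", 9), "#")          # one base below Q10
  quals[7] <- strrep("5", 10)                       # mean Q20 exactly (kept)
  quals[9] <- strrep("+", 10)                       # mean Q10 < 20
  out <- clean_reads(mk_reads(seqs, quals))
  expect_identical(out$sequence,
                   seqs[-c(2, 4, 9)])               # 3 violations, 7 survive
  # all clean input passes through unchanged
  all_good <- mk_reads(seqs[-2])
  expect_identical(clean_reads(all_good)$sequence, seqs[-2])
  expect_error(clean_reads(mk_reads(c("ACGT", "ACGTA"))), "mixed read lengths")
})

test_that("reverse complement is exact and involutive", {
  expect_identical(revcomp("ACGT"), "ACGT")  # palindrome
  expect_identical(revcomp("AAAC"), "GTTT")
  set.seed(5)
  xs <- replicate(20, random_seq(sample(5:40, 1)))
  expect_identical(revcomp(revcomp(xs)), xs)
  expect_error(revcomp("ACGN"), "non-ACGT")
})

test_that("unique table collapses both orientations and conserves frequency", {
  set.seed(11)
  base <- replicate(5, random_seq(12))
  reads <- rep(base, times = c(2, 3, 2, 4, 2))   # five uniques, each >= twice
  tab <- build_unique_table(mk_reads(reads))
  expect_equal(sum(tab$frequency), 2 * length(reads))
  fwd <- tab[match(base, tab$sequence), ]
  expect_equal(fwd$frequency, c(2, 3, 2, 4, 2))
  expect_true(all(revcomp(base) %in% tab$sequence))
  expect_true(all(!tab$assembled))
  expect_identical(tab$sequence, sort(tab$sequence, method = "radix"))

  # order independence
  tab2 <- build_unique_table(mk_reads(sample(reads)))
  expect_identical(tab$sequence, tab2$sequence)
  expect_identical(tab$frequency, tab2$frequency)

  # all-distinct palindrome-free reads: every frequency 1, 2N entries
  set.seed(12)
  distinct <- unique(replicate(30, random_seq(13)))  # odd length: no palindromes
  t3 <- build_unique_table(mk_reads(distinct))
  expect_true(all(t3$frequency == 1))
  expect_equal(nrow(t3), 2 * length(distinct))

  # a self-reverse-complementary read is counted once per orientation
  t4 <- build_unique_table(mk_reads("AACGTT"))
  expect_equal(nrow(t4), 1)
  expect_equal(t4$frequency, 2L)
})

test_that("mean qualities aggregate over contributing reads", {
  q1 <- strrep("I", 8)            # Q40
  q2 <- strrep("5", 8)            # Q20
  tab <- build_unique_table(mk_reads(c("ACGTACGT", "ACGTACGT"), c(q1, q2)))
  row <- tab[tab$sequence == "ACGTACGT", ]
  expect_equal(row$mean_quality, 30)
})

test_that("marking entries assembled is targeted and idempotent", {
  tab <- build_unique_table(mk_reads(c("ACGTAAGG", "TTCCAAGG")))
  s <- tab$sequence[2]
  t1 <- mark_assembled(tab, s)
  expect_equal(sum(t1$assembled), 1L)
  expect_identical(t1$frequency, tab$frequency)
  expect_identical(mark_assembled(t1, s), t1)
  t_all <- mark_assembled(tab, tab$sequence)
  expect_true(all(t_all$assembled))
  expect_null(select_seed(t_all, "repeat",
                          swa_params(S_d = 1, L_r = 8, L_w = 1,
                                     interval_width = 3, min_contig = 10)))
  expect_error(mark_assembled(tab, "GGGGGGGG"), "unknown sequence")
})

test_that("empty input yields an empty table, not an error", {
  tab <- build_unique_table(character(0))
  expect_equal(nrow(tab), 0)
  expect_s3_class(tab, "swa_table")
})

test_that("the unique table serializes to TSV with a metadata sidecar", {
  d <- withr::local_tempdir()
  tab <- build_unique_table(mk_reads(c("ACGTAAGG", "TTCCAAGG", "ACGTAAGG")))
  write_unique_table(tab, file.path(d, "t.tsv"), file.path(d, "t.json"))
  back <- read.delim(file.path(d, "t.tsv"))
  expect_equal(nrow(back), nrow(tab))
  expect_equal(sum(back$frequency), 6)
  meta <- jsonlite::read_json(file.path(d, "t.json"), simplifyVector = TRUE)
  expect_equal(meta$total_raw_reads, 3)
  expect_equal(meta$L_r, 8)
})
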