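test_that("local alignment matches a full-DP Smith-Waterman oracle", {
  set.seed(91)
  for (i in 1:12) {
    q <- random_seq(sample(5:30, 1))
    r <- random_seq(sample(8:30, 1))
    got <- align_local(q, r)
    oracle <- max(sw_score_oracle(q, r), sw_score_oracle(revcomp(q), r))
    expect_equal(got$score, oracle, info = paste(q, r))
  }
})

test_that("local alignment handles exact and reverse-strand queries", {
  ref <- paste0(random_seq(30), "ACGGTTCAGCATGGA", random_seq(30))
  hit <- align_local("ACGGTTCAGCATGGA", ref)
  expect_equal(hit$identity, 1)
  expect_equal(hit$query_span, 15)
  expect_equal(hit$strand, "+")
  expect_equal(hit$ref_interval, c(30, 45))
  rc <- align_local(revcomp("ACGGTTCAGCATGGA"), ref)
  expect_equal(rc$strand, "-")
  expect_equal(rc$identity, 1)
  expect_error(align_local("", ref), "empty")
})

test_that("size statistics follow their definitions", {
  s <- size_stats(c(100, 300), genome_size = 400)
  expect_equal(s$E_size, 250)  # (100^2 + 300^2) / 400
  expect_equal(s$mean, 200)
  # N50 is computed against the genome size, not assembly size
  one <- size_stats(600, genome_size = 1000)
  expect_equal(one$N50, 600)
  expect_equal(size_stats(400, genome_size = 1000)$N50, 0)
  # coverage can exceed 100 when contigs overlap
  expect_equal(size_stats(c(300000, 205000), genome_size = 500000)$coverage, 101)
  z <- size_stats(integer(0), genome_size = 100)
  expect_equal(z$N50, 0)
  expect_equal(z$E_size, 0)
})

test_that("E-size dominates the mean and N-statistics are ordered", {
  set.seed(92)
  for (i in 1:10) {
    lens <- sample(200:5000, sample(3:20, 1))
    s <- size_stats(lens, genome_size = sum(lens))
    expect_gte(s$E_size, s$mean)
    expect_lte(s$N90, s$N50)
    expect_lte(s$N50, s$max)
  }
})

test_that("CN-accuracy sums absolute copy errors over matched contigs", {
  fams <- list(a = list(family_id = "a", copies = 3, unit_length = 500),
               b = list(family_id = "b", copies = 4, unit_length = 800))
  est_exact <- data.frame(family_id = c("a", "b"), copy_number = c(3L, 4L))
  expect_equal(cn_accuracy(est_exact, fams), 100)
  est_off <- data.frame(family_id = c("a", "b"), copy_number = c(3L, 5L))
  expect_equal(cn_accuracy(est_off, fams), 100 * (1 - 1 / 7))
  expect_true(is.na(cn_accuracy(est_exact[0, ], list())))
})

test_that("Rep-accuracy penalizes missing repeat bases and missing families", {
  fams <- list(a = list(family_id = "a", copies = 2, unit_length = 1000))
  exact <- data.frame(family_id = "a", aligned = 1000)
  expect_equal(rep_accuracy(exact, fams), 100)
  short <- data.frame(family_id = "a", aligned = 990)
  expect_equal(rep_accuracy(short, fams), 99)
  none <- data.frame(family_id = character(0), aligned = numeric(0))
  expect_equal(rep_accuracy(none, fams), 0)
  # redundant fragments beyond the unit length count as error too
  two <- data.frame(family_id = c("a", "a"), aligned = c(1000, 500))
  expect_equal(rep_accuracy(two, fams), 100 * (1 - 500 / 1000))
})

test_that("C-accuracy counts error contigs against the reference", {
  set.seed(93)
  ref <- random_seq(4000)
  good <- substring(ref, seq(1, 3601, by = 400), seq(400, 4000, by = 400))
  expect_equal(c_accuracy(good, reference = ref), 100)
  bad <- c(good[1:9], random_seq(400))
  expect_equal(c_accuracy(bad, reference = ref), 90)
  expect_true(is.na(c_accuracy(data.frame(identity = numeric(0),
                                          coverage = numeric(0)))))
})

test_that("evaluation report is internally consistent on a real assembly", {
  fx <- small_sim(seed = 95, copies = 3, unit = 700, len = 15000, S_d = 4)
  a <- swa_assemble(fx$reads, fx$params)
  ev <- evaluate(a, fx$genome)
  expect_equal(ev$Number_C, ev$TRC + ev$NNC)
  expect_equal(length(ev$CNRC), ev$TRC)
  expect_equal(ev$CN_accuracy, 100)
  expect_equal(ev$C_accuracy, 100)
  expect_gte(ev$Rep_accuracy, 99)
  expect_gte(ev$E_size, ev$mean_contig)
  # fragments of one family each match that family (TRC counts fragments)
  ct <- a$contigs
  ri <- which(ct$contig_class == "repeat")[1]
  unit <- fx$genome$families[[1]]$unit
  frag <- ct[c(ri, ri), ]
  frag$sequence <- c(substr(unit, 1, 400), substr(unit, 301, 700))
  frag$length <- nchar(frag$sequence)
  frag$id <- c("fragA", "fragB")
  m <- classify_and_match(rbind(ct[-ri, ], frag), fx$genome)
  fam <- fx$genome$families[[1]]$family_id
  expect_equal(sum(m$repeat_matches$family_id == fam, na.rm = TRUE), 2)
})

test_that("contigs of novel sequence stay unassigned", {
  g <- make_genome(8000, list(repeat_family(2, 500)), seed = 97)
  set.seed(1234)
  alien <- data.frame(id = "x", sequence = random_seq(400), length = 400L,
                      contig_class = "repeat", copy_number = 2L,
                      stringsAsFactors = FALSE)
  m <- classify_and_match(alien, g)
  expect_true(is.na(m$repeat_matches$family_id[1]))
  expect_lt(m$placements$identity[1] * m$placements$coverage[1], 0.9)
})

test_that("an empty contig set evaluates to a zeroed report", {
  g <- make_genome(5000, list(), seed = 98)
  ev <- evaluate(data.frame(), g)
  expect_equal(ev$Number_C, 0)
  expect_equal(ev$N50, 0)
  expect_true(is.na(ev$CN_accuracy))
})
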