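test_that("derived parameters reproduce the worked threshold example", {
  p <- swa_params(S_d = 2, L_r = 60, L_w = 3, N_f = 1, interval_width = 10)
  expect_equal(p$S_fd, 6)   # S_fd = S_d * L_w^N_f = 2 * 3
  expect_equal(p$H_p, 5)
  expect_equal(p$L_p, 1)
  expect_equal(p$T_1, 8)
  expect_equal(p$T_2, 10)
  # identity cases of the compensation formula
  expect_equal(swa_params(S_d = 3, L_r = 60, L_w = 1, N_f = 1,
                          interval_width = 10)$S_fd, 3)
  expect_equal(swa_params(S_d = 4, L_r = 60, L_w = 3, N_f = 2,
                          interval_width = 10)$S_fd, 36)
})

test_that("invalid parameter combinations are rejected", {
  expect_error(swa_params(S_d = 0, L_r = 60), "positive")
  expect_error(swa_params(S_d = 2, L_r = 60, min_ov = 20), "L_r / 2")
  expect_error(swa_params(S_d = 2, L_r = 60, L_w = 4, interval_width = 10),
               "odd")
  expect_error(swa_params(S_d = 2, L_r = 60, interval_width = 10, L_k = 55),
               "L_k")
  expect_warning(swa_params(S_d = 0.5, L_r = 60, L_w = 11, interval_width = 20),
                 "L_d/2")
})

test_that("seed selection honors the count thresholds and quality tie-break", {
  p <- swa_params(S_d = 2, L_r = 12, L_w = 1, N_f = 1, interval_width = 5,
                  min_contig = 30)
  set.seed(51)
  seqs <- replicate(6, random_seq(12))
  tab <- toy_table(seqs, freq = c(12, 6, 2, 1, 12, 3),
                   mq = c(38, 40, 40, 40, 40, 40))
  # repeats: both 12-count entries qualify (H_p = 5); Q40 beats Q38
  i <- select_seed(tab, "repeat", p)
  expect_equal(tab$frequency[i], 12L)
  expect_equal(tab$mean_quality[i], 40)
  # nonrepeats: L_p = 1, effective floor 1 -> the 1-count entry
  j <- select_seed(tab, "nonrepeat", p)
  expect_equal(tab$frequency[j], 1L)
  # exhausted pool
  tab2 <- tab; tab2$assembled[] <- TRUE
  expect_null(select_seed(tab2, "repeat", p))
  # middle counts (L_p < f <= H_p) are never seeds
  tab3 <- toy_table(seqs[1:3], freq = c(4, 3, 2))
  expect_null(select_seed(tab3, "repeat", p))
  expect_null(select_seed(tab3, "nonrepeat", p))
})

test_that("optimal-read choice follows the documented strategies", {
  cands <- data.frame(sequence = c("TTTT", "AAAA"), overlap = c(59L, 55L),
                      frequency = c(2L, 9L), count = c(2, 9))
  expect_equal(choose_optimal_read(cands, "longest_overlap"), 1L)
  # nearest depth prefers the candidate whose count is closest to S_d
  expect_equal(choose_optimal_read(cands, "nearest_depth", S_d = 8), 2L)
  expect_equal(choose_optimal_read(cands[2, ], "longest_overlap"), 1L)
  expect_equal(choose_optimal_read(cands[2, ], "nearest_depth", S_d = 4), 1L)
  expect_null(choose_optimal_read(cands[0, ], "longest_overlap"))
})

test_that("copy numbers round half-up from the M_n trace", {
  expect_equal(estimate_copy_number(c(6, 6, 6), S_fd = 6), 1L)
  expect_equal(estimate_copy_number(12.2, S_fd = 6), 2L)   # 2.03 -> 2
  expect_equal(estimate_copy_number(18.1, S_fd = 6), 3L)   # 3.02 -> 3
  expect_equal(estimate_copy_number(15, S_fd = 6), 3L)     # 2.5 rounds up
  expect_equal(estimate_copy_number(0.5, S_fd = 6), 1L)    # floored at 1
  expect_error(estimate_copy_number(numeric(0), S_fd = 6), "empty")
})

test_that("a seed with no overlaps returns itself as the contig", {
  set.seed(52)
  p <- swa_params(S_d = 2, L_r = 20, L_w = 3, N_f = 1, interval_width = 8,
                  L_k = 5, min_contig = 50)
  tab <- toy_table(replicate(5, random_seq(20)))
  out <- extend_contig(1L, "nonrepeat", tab, p)
  expect_identical(out$contig$sequence, tab$sequence[1])
  expect_equal(length(out$contig$M_n), 0)
  expect_true(out$table$assembled[1])
  expect_error(extend_contig(1L, "nonrepeat", out$table, p),
               "already assembled")
})

test_that("extension separates a planted repeat from its flanks", {
  fx <- small_sim(seed = 61, copies = 2, unit = 1000, len = 20000, S_d = 4)
  a <- swa_assemble(fx$reads, fx$params)
  ct <- a$contigs
  expect_equal(sum(ct$contig_class == "repeat"), 1)
  expect_equal(ct$copy_number[ct$contig_class == "repeat"], 2L)
  expect_equal(sum(ct$contig_class == "nonrepeat"), 3)

  # boundary containment: each nonrepeat contig stays within a nonrepeat
  # interval extended by at most max_ov bases into a repeat
  ann <- fx$genome$annotations
  bounds <- rbind(c(0, ann$start[1]), c(ann$end[1], ann$start[2]),
                  c(ann$end[2], fx$genome$length))
  for (i in which(ct$contig_class == "nonrepeat")) {
    loc <- regexpr(ct$sequence[i], fx$genome$sequence, fixed = TRUE)
    if (loc < 0)
      loc <- regexpr(revcomp(ct$sequence[i]), fx$genome$sequence, fixed = TRUE)
    expect_gte(loc, 0)
    s0 <- as.integer(loc) - 1L
    e0 <- s0 + ct$length[i]
    ok <- any(s0 >= bounds[, 1] - fx$params$max_ov &
                e0 <= bounds[, 2] + fx$params$max_ov)
    expect_true(ok, info = sprintf("contig %d at [%d, %d)", i, s0, e0))
  }
})

test_that("planted copy numbers are recovered across copy counts", {
  for (cc in c(2L, 3L, 5L, 10L)) {
    correct <- 0L
    for (s in 1:3) {
      fx <- small_sim(seed = 700 + 10 * cc + s, copies = cc, unit = 600,
                      len = 15000 + 600 * cc, S_d = 4)
      a <- swa_assemble(fx$reads, fx$params)
      rep_ct <- a$contigs[a$contigs$contig_class == "repeat", ]
      if (nrow(rep_ct) == 1 && rep_ct$copy_number == cc)
        correct <- correct + 1L
    }
    expect_gte(correct, 3L)
  }
})

test_that("assembly is deterministic and the repeat pass skips clean genomes", {
  fx <- small_sim(seed = 71, copies = 2, unit = 800, len = 12000, S_d = 4)
  a1 <- swa_assemble(fx$reads, fx$params)
  a2 <- swa_assemble(fx$reads, fx$params)
  expect_identical(a1$contigs, a2$contigs)

  g <- make_genome(12000, list(), seed = 72)
  rd <- sample_reads(g, L_r = 60, S_d = 4, seed = 73)
  a <- swa_assemble(rd, fx$params)
  expect_equal(sum(a$contigs$contig_class == "repeat"), 0)
  expect_gte(sum(a$contigs$contig_class == "nonrepeat"), 1)
})

test_that("the per-step threshold rule leaves an M_n trace above T_2", {
  fx <- small_sim(seed = 81, copies = 3, unit = 800, len = 15000, S_d = 4,
                  stop_rule = "threshold")
  tab <- build_unique_table(clean_reads(fx$reads))
  i <- select_seed(tab, "repeat", fx$params)
  expect_false(is.null(i))
  out <- extend_contig(i, "repeat", tab, fx$params)
  mn <- out$contig$M_n
  expect_gt(length(mn), 0)
  # every accepted step passed the repeat threshold
  expect_true(all(mn > fx$params$T_2))
  expect_equal(out$contig$copy_number, 3L)
})

test_that("empty read sets assemble to empty output", {
  p <- swa_params(S_d = 2, L_r = 20, L_w = 3, N_f = 1, interval_width = 8,
                  L_k = 5)
  a <- swa_assemble(character(0), p)
  expect_equal(nrow(a$contigs), 0)
})
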