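# Brute-force oracles and small fixture builders, independent of the
# package's hash-accelerated code paths.

# All entries of `table` whose first t bases equal the last t bases of
# `contig_end`, by direct all-pairs comparison.
bf_overlap_candidates <- function(table, contig_end, t) {
  n <- nchar(contig_end)
  if (t > n) return(integer(0))
  suffix <- substr(contig_end, n - t + 1L, n)
  which(substr(table$sequence, 1L, t) == suffix)
}

# Overlap profile by brute force (unassembled entries only).
bf_overlap_profile <- function(contig_end, table, params) {
  x <- numeric(params$L_d)
  tmax <- min(params$max_ov, nchar(contig_end))
  for (t in seq_len(params$L_d) + params$min_ov) {
    if (t > tmax) next
    ids <- bf_overlap_candidates(table, contig_end, t)
    ids <- ids[!table$assembled[ids]]
    x[params$max_ov - t + 1L] <- sum(table$frequency[ids])
  }
  x
}

# Full-matrix Smith-Waterman score, linear gap penalty: match +2,
# mismatch -1, gap -2 (single strand).
sw_score_oracle <- function(q, r) {
  qa <- strsplit(q, "")[[1]]
  ra <- strsplit(r, "")[[1]]
  n <- length(qa); m <- length(ra)
  H <- matrix(0, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qa[i] == ra[j]) 2 else -1
      H[i + 1, j + 1] <- max(0, H[i, j] + s, H[i, j + 1] - 2, H[i + 1, j] - 2)
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A tiny sorted unique-read table built directly from given sequences.
toy_table <- function(seqs, freq = NULL, mq = NULL) {
  o <- order(seqs, method = "radix")
  seqs <- seqs[o]
  tab <- data.frame(sequence = seqs,
                    frequency = if (is.null(freq)) rep(1L, length(seqs))
                                else as.integer(freq[o]),
                    mean_quality = if (is.null(mq)) rep(40, length(seqs))
                                   else mq[o],
                    assembled = rep(FALSE, length(seqs)),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("swa_table", "data.frame"),
            L_r = nchar(seqs[1]), total_raw_reads = NA_integer_)
}

# Standard small planted-repeat simulation used across assembler tests.
small_sim <- function(seed, copies = 2L, unit = 1000L, len = 20000L,
                      S_d = 4, L_r = 60L, ...) {
  g <- make_genome(len, list(repeat_family(copies, unit)), seed = seed)
  rd <- sample_reads(g, L_r = L_r, S_d = S_d, seed = seed + 1L)
  p <- swa_params(S_d = S_d, L_r = L_r, L_w = 3, N_f = 1, interval_width = 10, ...)
  list(genome = g, reads = rd, params = p)
}
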