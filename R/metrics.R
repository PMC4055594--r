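swa_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                           baseOnly = TRUE)
}

align_one <- function(q, r) {
  pa <- Biostrings::pairwiseAlignment(pattern = q, subject = r, type = "local",
                                      substitutionMatrix = swa_submat(),
                                      gapOpening = 0, gapExtension = 2)
  nm <- Biostrings::nmatch(pa)
  nmm <- Biostrings::nmismatch(pa)
  ind <- Biostrings::nindel(pa)
  gapcols <- Biostrings::insertion(ind)[1, "WidthSum"] +
    Biostrings::deletion(ind)[1, "WidthSum"]
  alen <- as.numeric(nm + nmm + gapcols)
  sub <- Biostrings::subject(pa)
  pat <- Biostrings::pattern(pa)
  list(score = Biostrings::score(pa),
       identity = if (alen > 0) nm / alen else 0,
       query_span = BiocGenerics::width(pat),
       query_interval = c(BiocGenerics::start(pat) - 1L,
                          BiocGenerics::end(pat)),
       ref_interval = c(BiocGenerics::start(sub) - 1L,
                        BiocGenerics::end(sub)),
       subject_span = BiocGenerics::width(sub))
}

#' Optimal local alignment of two DNA sequences
#'
#' Smith-Waterman local alignment under the scoring match +2, mismatch -1,
#' gap -2 (linear). Both strands of the query are tried and the better one is
#' kept.
#'
#' @param query,reference nonempty ACGT strings.
#' @return List with \code{score}, \code{identity} (matches over alignment
#'   columns), \code{query_span} (aligned query bases), \code{ref_interval}
#'   (0-based half-open interval on the reference) and \code{strand}
#'   (\code{"+"} or \code{"-"}).
#' @export
align_local <- function(query, reference) {
  if (!nzchar(query) || !nzchar(reference)) stop("empty sequence")
  fwd <- align_one(query, reference)
  rev <- align_one(revcomp(query), reference)
  if (rev$score > fwd$score) {
    out <- rev
    out$strand <- "-"
  } else {
    out <- fwd
    out$strand <- "+"
  }
  out[c("score", "identity", "query_span", "ref_interval", "strand")]
}

# Exact-substring fast path: locate `q` (either strand) in `ref_dna`
# (a DNAString). Long queries are located by a leading anchor and verified by
# direct comparison (Boyer-Moore caps pattern length). Returns NULL or
# list(start0, strand).
exact_locate <- function(q, ref_dna) {
  L <- length(ref_dna)
  for (strand in c("+", "-")) {
    full <- if (strand == "+") q else revcomp(q)
    n <- nchar(full)
    if (n > L) next
    if (n <= 10000L) {
      m <- Biostrings::matchPattern(full, ref_dna)
      if (length(m) > 0)
        return(list(start0 = BiocGenerics::start(m)[1] - 1L, strand = strand))
    } else {
      m <- Biostrings::matchPattern(substr(full, 1L, 1000L), ref_dna)
      for (s in BiocGenerics::start(m)) {
        if (s + n - 1L > L) next
        if (as.character(Biostrings::subseq(ref_dna, s, s + n - 1L)) == full)
          return(list(start0 = s - 1L, strand = strand))
      }
    }
  }
  NULL
}

# Best reference placement of a contig: exact search first (identity 1 over
# the full length), then exact search of end-trimmed versions (repeat contigs
# legitimately carry up to ~max_ov foreign-flank bases per end), then anchored
# Smith-Waterman around exact 60-mer anchor hits. Returns list(identity,
# coverage) of the best placement found (identity of the aligned region,
# coverage = aligned query fraction of the full contig).
best_ref_placement <- function(contig, ref_dna, max_trim = 150L) {
  n <- nchar(contig)
  hit <- exact_locate(contig, ref_dna)
  if (!is.null(hit)) return(list(identity = 1, coverage = 1))
  for (tr in unique(pmin(c(10L, 30L, 60L, max_trim), (n - 1L) %/% 2L))) {
    if (tr <= 0) next
    core <- substr(contig, tr + 1L, n - tr)
    if (!is.null(exact_locate(core, ref_dna)))
      return(list(identity = 1, coverage = nchar(core) / n))
  }
  # anchored alignment fallback
  best <- list(identity = 0, coverage = 0)
  plen <- min(60L, n)
  L <- length(ref_dna)
  for (frac in c(0.5, 0.25, 0.75)) {
    p0 <- max(1L, min(n - plen + 1L, as.integer(frac * n)))
    probe <- substr(contig, p0, p0 + plen - 1L)
    for (strand in c("+", "-")) {
      pr <- if (strand == "+") probe else revcomp(probe)
      m <- Biostrings::matchPattern(pr, ref_dna)
      if (length(m) == 0) next
      starts <- utils::head(BiocGenerics::start(m), 8L)
      for (s in starts) {
        w1 <- max(1L, s - n - 100L)
        w2 <- min(L, s + n + 100L)
        win <- as.character(Biostrings::subseq(ref_dna, w1, w2))
        q <- if (strand == "+") contig else revcomp(contig)
        al <- align_one(q, win)
        cov <- al$query_span / n
        if (al$identity * cov > best$identity * best$coverage)
          best <- list(identity = al$identity, coverage = cov)
        if (best$identity >= 0.99 && best$coverage >= 0.9) return(best)
      }
    }
    if (best$identity >= 0.99 && best$coverage >= 0.9) break
  }
  best
}

# Alignment of a repeat contig against a family unit: aligned length on the
# unit, identity. Exact containment (either direction, either strand) short-
# circuits the dynamic programming.
unit_alignment <- function(contig, unit) {
  ud <- Biostrings::DNAString(unit)
  if (!is.null(exact_locate(contig, ud)))
    return(list(aligned = nchar(contig), identity = 1))
  if (!is.null(exact_locate(unit, Biostrings::DNAString(contig))))
    return(list(aligned = nchar(unit), identity = 1))
  best <- NULL
  for (q in c(contig, revcomp(contig))) {
    al <- align_one(q, unit)
    if (is.null(best) || al$score > best$score) best <- al
  }
  list(aligned = best$subject_span, identity = best$identity)
}

#' Match contigs to the simulation truth
#'
#' Repeat-class contigs are assigned to the repeat family whose unit sequence
#' they align to best (identity at least 0.95 over at least 90% of the shorter
#' of contig and unit); fragments of one family all match that family.
#' Nonrepeat contigs are placed on the reference by exact search with an
#' anchored Smith-Waterman fallback.
#'
#' @param contigs a \code{swa_assembly} or its \code{contigs} data.frame.
#' @param truth a \code{\link{make_genome}} result.
#' @return List with \code{repeat_matches} (one row per repeat contig:
#'   \code{family_id} or NA, aligned length, identity, copy estimate) and
#'   \code{placements} (one row per contig: best reference identity and
#'   coverage).
#' @export
classify_and_match <- function(contigs, truth) {
  ct <- if (inherits(contigs, "swa_assembly")) contigs$contigs else contigs
  ref_dna <- Biostrings::DNAString(truth$sequence)
  fams <- truth$families

  rep_idx <- which(ct$contig_class == "repeat")
  repeat_matches <- data.frame(id = character(0), family_id = character(0),
                               aligned = numeric(0), identity = numeric(0),
                               copy_number = integer(0),
                               stringsAsFactors = FALSE)
  for (i in rep_idx) {
    best_fam <- NA_character_; best_al <- 0; best_id <- 0
    for (f in fams) {
      al <- unit_alignment(ct$sequence[i], f$unit)
      need <- 0.9 * min(nchar(ct$sequence[i]), f$unit_length)
      ok <- al$identity >= 0.95 && al$aligned >= need
      if (ok && (is.na(best_fam) || al$identity * al$aligned >
                 best_id * best_al)) {
        best_fam <- f$family_id; best_al <- al$aligned; best_id <- al$identity
      }
    }
    repeat_matches <- rbind(repeat_matches, data.frame(
      id = ct$id[i], family_id = best_fam, aligned = best_al,
      identity = best_id, copy_number = ct$copy_number[i],
      stringsAsFactors = FALSE))
  }

  placements <- data.frame(id = ct$id,
                           contig_class = ct$contig_class,
                           identity = NA_real_, coverage = NA_real_,
                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(ct))) {
    pl <- best_ref_placement(ct$sequence[i], ref_dna)
    placements$identity[i] <- pl$identity
    placements$coverage[i] <- pl$coverage
  }
  list(repeat_matches = repeat_matches, placements = placements)
}

#' Copy-number estimation accuracy (CN-accuracy)
#'
#' \code{100 * (1 - sum(N_error) / N_total)} where \code{N_total} is the sum
#' of true copy numbers over all repeat families and \code{N_error} the sum of
#' absolute errors of the matched repeat contigs (a fragment inherits its
#' family's true copies as truth).
#'
#' @param estimates data.frame with \code{family_id} and \code{copy_number}
#'   (matched repeat contigs; unmatched rows with NA family are ignored).
#' @param truth a \code{swa_genome} (or list of families).
#' @return Percentage, or \code{NA} when there are no true repeats.
#' @export
cn_accuracy <- function(estimates, truth) {
  fams <- if (inherits(truth, "swa_genome")) truth$families else truth
  true_copies <- vapply(fams, function(f) f$copies, numeric(1))
  N_total <- sum(true_copies)
  if (N_total == 0) return(NA_real_)
  est <- estimates[!is.na(estimates$family_id), , drop = FALSE]
  N_error <- 0
  if (nrow(est)) {
    truth_map <- stats::setNames(true_copies,
                                 vapply(fams, function(f) f$family_id,
                                        character(1)))
    N_error <- sum(abs(est$copy_number - truth_map[est$family_id]))
  }
  100 * (1 - N_error / N_total)
}

#' Repeat assembly accuracy (Rep-accuracy)
#'
#' \code{100 * (1 - sum(|L_a - L_true|) / sum(L_true))} over repeat families,
#' with \code{L_true} the unit length and \code{L_a} the total aligned length
#' of the contigs matched to the family (capped at the unit length per
#' contig); an unassembled family contributes its full unit length as error.
#'
#' @param matches data.frame with \code{family_id} and \code{aligned} (from
#'   \code{\link{classify_and_match}}).
#' @param truth a \code{swa_genome} (or list of families).
#' @return Percentage, or \code{NA} when there are no true repeats.
#' @export
rep_accuracy <- function(matches, truth) {
  fams <- if (inherits(truth, "swa_genome")) truth$families else truth
  if (!length(fams)) return(NA_real_)
  err <- 0; tot <- 0
  for (f in fams) {
    L_true <- f$unit_length
    rows <- matches[!is.na(matches$family_id) &
                      matches$family_id == f$family_id, , drop = FALSE]
    L_a <- sum(pmin(rows$aligned, L_true))
    err <- err + abs(L_a - L_true)
    tot <- tot + L_true
  }
  100 * (1 - err / tot)
}

#' Overall contig accuracy (C-accuracy)
#'
#' A contig is an error contig when no reference alignment reaches identity
#' 0.99 over at least 90% of its length (repeat contigs legitimately carry up
#' to a read length of one copy's flanking sequence at each end, which the
#' coverage margin absorbs). Returns \code{100 * (1 - errors / total)}.
#'
#' @param placements data.frame with \code{identity} and \code{coverage} per
#'   contig (from \code{\link{classify_and_match}}), or a contig data.frame
#'   plus \code{reference}.
#' @param reference reference sequence, required when raw contigs are given.
#' @return Percentage, or \code{NA} for an empty contig set.
#' @export
c_accuracy <- function(placements, reference = NULL) {
  if (!is.null(reference)) {
    ref_dna <- Biostrings::DNAString(
      if (inherits(reference, "swa_genome")) reference$sequence else reference)
    seqs <- if (is.data.frame(placements)) placements$sequence else placements
    placements <- do.call(rbind, lapply(seqs, function(s) {
      pl <- best_ref_placement(s, ref_dna)
      data.frame(identity = pl$identity, coverage = pl$coverage)
    }))
  }
  n <- nrow(placements)
  if (!n) return(NA_real_)
  err <- sum(!(placements$identity >= 0.99 & placements$coverage >= 0.9))
  100 * (1 - err / n)
}

#' Contig size statistics: N50, N90, E-size, coverage
#'
#' N50 (N90) is the largest length L such that contigs of length at least L
#' together cover half (90%) of the genome size -- computed against the genome
#' size, not the assembly size. The E-size, the expected length of the contig
#' covering a random base, is \code{sum(l^2) / G} with \code{G} the assembly
#' size (sum of contig lengths). Coverage is the assembly size as a percentage
#' of the genome size (it can exceed 100 when contigs overlap at repeat
#' boundaries).
#'
#' @param lengths contig lengths (or a contig data.frame / assembly).
#' @param genome_size reference genome size in bases.
#' @return List with \code{N50}, \code{N90}, \code{mean}, \code{max},
#'   \code{E_size}, \code{coverage}.
#' @examples
#' size_stats(c(100, 300), genome_size = 400)$E_size  # 250
#' @export
size_stats <- function(lengths, genome_size) {
  if (inherits(lengths, "swa_assembly")) lengths <- lengths$contigs$length
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (genome_size <= 0) stop("genome_size must be positive")
  if (!length(lengths))
    return(list(N50 = 0, N90 = 0, mean = 0, max = 0, E_size = 0, coverage = 0))
  l <- sort(lengths, decreasing = TRUE)
  cs <- cumsum(l)
  nxx <- function(frac) {
    i <- which(cs >= frac * genome_size)
    if (length(i)) l[i[1]] else 0
  }
  list(N50 = nxx(0.5), N90 = nxx(0.9), mean = mean(l), max = max(l),
       E_size = sum(l^2) / sum(l), coverage = 100 * sum(l) / genome_size)
}

#' Evaluate an assembly against the simulation truth
#'
#' Computes the full repeat-aware report: TRC (number of repeat contigs
#' emitted), CNRC (their copy estimates), NNC (nonrepeat contigs), contig size
#' statistics against the true genome size, and the CN-/Rep-/C-accuracy
#' percentages.
#'
#' @param contigs a \code{swa_assembly} or contig data.frame (already length-
#'   filtered).
#' @param truth a \code{\link{make_genome}} result.
#' @return An object of class \code{"swa_eval"}.
#' @export
evaluate <- function(contigs, truth) {
  ct <- if (inherits(contigs, "swa_assembly")) contigs$contigs else contigs
  if (!nrow(ct)) {
    out <- list(TRC = 0L, CNRC = integer(0), NNC = 0L, Number_C = 0L,
                N50 = 0, N90 = 0, mean_contig = 0, max_contig = 0,
                E_size = 0, CN_accuracy = NA_real_, Rep_accuracy = NA_real_,
                C_accuracy = NA_real_, genome_coverage = 0)
    class(out) <- "swa_eval"
    return(out)
  }
  m <- classify_and_match(ct, truth)
  ss <- size_stats(ct$length, truth$length)
  out <- list(
    TRC = sum(ct$contig_class == "repeat"),
    CNRC = ct$copy_number[ct$contig_class == "repeat"],
    NNC = sum(ct$contig_class == "nonrepeat"),
    Number_C = nrow(ct),
    N50 = ss$N50, N90 = ss$N90, mean_contig = ss$mean, max_contig = ss$max,
    E_size = ss$E_size,
    CN_accuracy = cn_accuracy(m$repeat_matches, truth),
    Rep_accuracy = rep_accuracy(m$repeat_matches, truth),
    C_accuracy = c_accuracy(m$placements),
    genome_coverage = ss$coverage,
    matches = m)
  class(out) <- "swa_eval"
  out
}

#' @export
print.swa_eval <- function(x, ...) {
  cat("Assembly evaluation\n")
  cat(sprintf("  TRC %d | NNC %d | Number C %d\n", x$TRC, x$NNC, x$Number_C))
  if (length(x$CNRC))
    cat(sprintf("  CNRC: %s\n", paste(x$CNRC, collapse = ", ")))
  cat(sprintf("  N50 %s | N90 %s | mean %.1f | max %s | E-size %.1f\n",
              x$N50, x$N90, x$mean_contig, x$max_contig, x$E_size))
  cat(sprintf("  CN-accuracy %.1f%% | Rep-accuracy %.1f%% | C-accuracy %.1f%%\n",
              x$CN_accuracy, x$Rep_accuracy, x$C_accuracy))
  cat(sprintf("  genome coverage %.1f%%\n", x$genome_coverage))
  invisible(x)
}

# One-row report in the canonical column order.
report_row <- function(ev) {
  data.frame(TRC = ev$TRC,
             CNRC = paste(ev$CNRC, collapse = ", "),
             NNC = ev$NNC,
             N50 = ev$N50, Max = ev$max_contig,
             CN_accuracy = ev$CN_accuracy,
             Rep_accuracy = ev$Rep_accuracy,
             C_accuracy = ev$C_accuracy,
             Genome_coverage = ev$genome_coverage,
             stringsAsFactors = FALSE)
}
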