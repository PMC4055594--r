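#' Overlap-count profile over the dynamic overlapping interval
#'
#' For a contig 3' end, records at position \code{j} (j = 1..L_d) the summed
#' frequency of unassembled entries whose prefix of \code{max_ov - j + 1}
#' bases equals the contig-end suffix of the same length, i.e. read counts for
#' overlap lengths \code{max_ov} down to \code{min_ov + 1}. When the contig is
#' shorter than \code{max_ov} the contig length caps the longest overlap
#' considered. Candidates come from the hash index and are verified exactly.
#'
#' @param contig_end the working contig (its 3' end is profiled).
#' @param table a \code{swa_table}.
#' @param index a \code{\link{build_index}} of the table (built with
#'   \code{L_k <= min_ov}); rebuilt on the fly when \code{NULL}.
#' @param params a \code{\link{swa_params}} object.
#' @return Numeric vector of length \code{L_d}; attribute \code{"overlap"}
#'   gives the overlap length for each position.
#' @export
overlap_profile <- function(contig_end, table, index = NULL, params) {
  if (is.null(index)) index <- build_index(table, params$L_k)
  L_d <- params$L_d
  x <- numeric(L_d)
  tmax <- min(params$max_ov, nchar(contig_end))
  for (t in seq_len(L_d) + params$min_ov) {
    if (t > tmax) next
    j <- params$max_ov - t + 1L
    ids <- overlap_candidates(index, contig_end, t)
    ids <- ids[!table$assembled[ids]]
    if (length(ids)) x[j] <- sum(table$frequency[ids])
  }
  attr(x, "overlap") <- params$max_ov - seq_len(L_d) + 1L
  x
}

#' Sliding-window filtering of an overlap profile
#'
#' Applies \code{N_f} passes of a rectangular window of length \code{L_w}
#' (odd) as a windowed SUM with edge-replication padding, so that a constant
#' profile \code{c} maps exactly to \code{c * L_w^N_f} -- the identity that
#' puts the extension thresholds on the filtered-depth scale
#' \code{S_fd = S_d * L_w^N_f}. The filtered interval mean \code{m_y} is the
#' statistic recorded in the M_n trace at each extension step.
#'
#' @param x numeric profile (length \code{L_d}).
#' @param L_w window length (odd, at most \code{length(x)}).
#' @param N_f number of passes.
#' @return List with \code{y} (filtered profile) and \code{m_y} (its mean).
#' @examples
#' smooth_profile(c(0, 0, 6, 0, 0), L_w = 3)$y  # 0 6 6 6 0
#' @export
smooth_profile <- function(x, L_w, N_f = 1L) {
  if (L_w %% 2L == 0L || L_w < 1L) stop("L_w must be odd and >= 1")
  if (L_w > length(x)) stop("L_w exceeds profile length")
  y <- as.numeric(x)
  hw <- (L_w - 1L) %/% 2L
  n <- length(y)
  for (pass in seq_len(N_f)) {
    padded <- c(rep(y[1], hw), y, rep(y[n], hw))
    y <- vapply(seq_len(n), function(i) sum(padded[i:(i + L_w - 1L)]),
                numeric(1))
  }
  list(y = y, m_y = mean(y))
}
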