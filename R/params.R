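#' Assembly parameters for the sliding-window assembler
#'
#' Constructs the full parameter set of the assembly kernel from the sequencing
#' depth and the window/filter settings, deriving every threshold the way the
#' method prescribes. The central quantities are:
#'
#' \itemize{
#'   \item \code{S_d}, sequencing depth in reads per base (the number of reads
#'     divided by genome length; note this is not coverage, which is
#'     \code{S_d * L_r}).
#'   \item \code{S_fd = S_d * L_w^N_f}, the depth after \code{N_f} passes of a
#'     rectangular sliding-window sum of length \code{L_w} -- the scale on
#'     which all extension thresholds live.
#'   \item \code{H_p = 2 * S_d + 1}, the minimum read count (exclusive) for a
#'     repeat seed, and \code{L_p = max(1, ceiling(S_d) - 1)}, the maximum
#'     count (inclusive) for a nonrepeat seed.
#'   \item \code{T_1 = S_fd + delta} and \code{T_2 = 2 * S_fd - delta} with
#'     \code{delta = min(ceiling(S_fd / 3), S_fd / 2)}: nonrepeat extension
#'     continues while the filtered interval mean stays below \code{T_1},
#'     repeat extension while it stays above \code{T_2}.
#' }
#'
#' The dynamic overlapping interval has width
#' \code{interval_width = max_ov - min_ov} (the method's "k-mer", which is an
#' interval width, not a substring length): at each extension step read counts
#' are collected for overlap lengths \code{max_ov} down to \code{min_ov + 1}.
#'
#' @param S_d sequencing depth in reads per base; must be positive.
#' @param L_r read length in bases.
#' @param L_w sliding-window length (odd number of profile positions).
#' @param N_f number of successive sliding-window passes (the compensation
#'   mechanism for low depth).
#' @param interval_width width of the dynamic overlapping interval
#'   (\code{max_ov - min_ov}); \code{k_mer} is accepted as an alias.
#' @param max_ov maximal overlap length; defaults to \code{L_r - 1}.
#' @param min_ov minimal overlap length; defaults to
#'   \code{max_ov - interval_width}.
#' @param H_p,L_p,T_1,T_2 seed-count and extension thresholds; derived from
#'   \code{S_d}, \code{L_w}, \code{N_f} when \code{NULL}.
#' @param count_floor minimum frequency for a nonrepeat seed (guards against
#'   seeding on sequencing errors). The effective floor is
#'   \code{min(count_floor, L_p)} so the nonrepeat pool is never structurally
#'   empty at low depth.
#' @param min_contig contigs shorter than this many bases are dropped from the
#'   final output.
#' @param strategy optimal-read choice: \code{"longest_overlap"} (default;
#'   deepest overlap, ties by frequency then table order) or
#'   \code{"nearest_depth"} (profile count closest to \code{S_d}).
#' @param stop_rule boundary decision: \code{"confidence"} (default) stops an
#'   end when a one-sided CUSUM of the filtered-mean deviations exceeds
#'   \code{h}, then trims the contig back to the change point;
#'   \code{"threshold"} stops the moment a single filtered mean crosses
#'   \code{T_1}/\code{T_2}.
#' @param h CUSUM decision limit for \code{stop_rule = "confidence"}; default
#'   \code{3 * S_fd}.
#' @param L_k hash keyword length in bases; default \code{min(12, min_ov)}.
#' @param k_mer alias for \code{interval_width}.
#'
#' @return An object of class \code{"swa_params"}: a list with the supplied
#'   and derived parameters (\code{L_d}, \code{S_fd}, \code{delta}, thresholds).
#' @examples
#' p <- swa_params(S_d = 2, L_r = 60, L_w = 3, N_f = 1)
#' p$S_fd  # 6
#' p$T_1   # 8
#' p$T_2   # 10
#' @export
swa_params <- function(S_d, L_r, L_w = 3, N_f = 1, interval_width = 10,
                       max_ov = NULL, min_ov = NULL,
                       H_p = NULL, L_p = NULL, T_1 = NULL, T_2 = NULL,
                       count_floor = 2, min_contig = 200,
                       strategy = c("longest_overlap", "nearest_depth"),
                       stop_rule = c("confidence", "threshold"),
                       h = NULL, L_k = NULL, k_mer = NULL) {
  strategy <- match.arg(strategy)
  stop_rule <- match.arg(stop_rule)
  if (!is.numeric(S_d) || length(S_d) != 1L || S_d <= 0)
    stop("S_d must be a single positive number")
  if (!is.numeric(L_r) || L_r < 2) stop("L_r must be >= 2")
  if (!is.null(k_mer)) interval_width <- k_mer
  if (is.null(max_ov)) max_ov <- L_r - 1L
  if (is.null(min_ov)) min_ov <- max_ov - interval_width
  max_ov <- as.integer(max_ov); min_ov <- as.integer(min_ov)
  if (!(min_ov < max_ov && max_ov <= L_r - 1L))
    stop("need min_ov < max_ov <= L_r - 1")
  if (min_ov < L_r / 2)
    stop("min_ov must be >= L_r / 2")
  L_d <- max_ov - min_ov
  L_w <- as.integer(L_w); N_f <- as.integer(N_f)
  if (L_w < 1L || L_w %% 2L == 0L) stop("L_w must be odd and >= 1")
  if (N_f < 1L) stop("N_f must be >= 1")
  if (L_w > L_d) stop("L_w cannot exceed the interval width L_d")
  if (L_w > 1L && L_w > L_d / 2)
    warning("L_w exceeds L_d/2; the recommended range is 2 <= L_w <= L_d/2")

  S_fd <- S_d * L_w^N_f
  delta <- min(ceiling(S_fd / 3), S_fd / 2)
  if (is.null(H_p)) H_p <- 2 * S_d + 1
  if (is.null(L_p)) L_p <- max(1, ceiling(S_d) - 1)
  if (is.null(T_1)) T_1 <- S_fd + delta
  if (is.null(T_2)) T_2 <- 2 * S_fd - delta
  if (is.null(h)) h <- 3 * S_fd
  if (is.null(L_k)) L_k <- min(12L, min_ov)
  L_k <- as.integer(L_k)
  if (L_k > min_ov)
    stop("L_k must not exceed min_ov (hash lookup would miss legal overlaps)")
  if (T_1 > T_2) stop("need T_1 <= T_2")
  if (L_p >= H_p) stop("need L_p < H_p")

  structure(list(
    L_r = as.integer(L_r), max_ov = max_ov, min_ov = min_ov, L_d = L_d,
    L_w = L_w, N_f = N_f, S_d = S_d, S_fd = S_fd, delta = delta,
    H_p = H_p, L_p = L_p, T_1 = T_1, T_2 = T_2, h = h,
    count_floor = as.integer(count_floor), min_contig = as.integer(min_contig),
    strategy = strategy, stop_rule = stop_rule, L_k = L_k
  ), class = "swa_params")
}

#' @export
print.swa_params <- function(x, ...) {
  cat("Sliding-window assembly parameters\n")
  cat(sprintf("  read length L_r        : %d\n", x$L_r))
  cat(sprintf("  overlap interval       : [%d, %d] (L_d = %d)\n",
              x$min_ov + 1L, x$max_ov, x$L_d))
  cat(sprintf("  window / passes        : L_w = %d, N_f = %d\n", x$L_w, x$N_f))
  cat(sprintf("  depth S_d / S_fd       : %g / %g\n", x$S_d, x$S_fd))
  cat(sprintf("  seed thresholds        : H_p = %g, L_p = %g (floor %d)\n",
              x$H_p, x$L_p, x$count_floor))
  cat(sprintf("  extension thresholds   : T_1 = %g, T_2 = %g (delta = %g)\n",
              x$T_1, x$T_2, x$delta))
  cat(sprintf("  stop rule              : %s (h = %g)\n", x$stop_rule, x$h))
  cat(sprintf("  strategy / min contig  : %s / %d\n", x$strategy, x$min_contig))
  invisible(x)
}

# Parameter list handed to the C++ kernel.
params_for_kernel <- function(p) {
  list(L_r = p$L_r, max_ov = p$max_ov, min_ov = p$min_ov, L_w = p$L_w,
       N_f = p$N_f, L_k = p$L_k, S_d = p$S_d, S_fd = p$S_fd, H_p = p$H_p,
       L_p = p$L_p, T_1 = p$T_1, T_2 = p$T_2, h = p$h,
       count_floor = as.integer(min(p$count_floor, floor(p$L_p))),
       strategy = p$strategy, stop_rule = p$stop_rule)
}
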