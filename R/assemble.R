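#' Select the next seed from a pool
#'
#' Repeat seeds are unassembled entries with frequency above \code{H_p},
#' highest count first; nonrepeat seeds have frequency between the count floor
#' and \code{L_p}, lowest count first (reads with middle counts sit near
#' repeat boundaries and are avoided). Equal counts are resolved by higher
#' mean quality (higher base quality means fewer errors), then table order.
#'
#' @param table a \code{swa_table}.
#' @param pool \code{"repeat"} or \code{"nonrepeat"}.
#' @param params a \code{\link{swa_params}}.
#' @return The 1-based row index of the chosen entry, or \code{NULL} when the
#'   pool is exhausted.
#' @export
select_seed <- function(table, pool = c("repeat", "nonrepeat"), params) {
  pool <- match.arg(pool)
  floor_eff <- min(params$count_floor, floor(params$L_p))
  cand <- if (pool == "repeat")
    which(!table$assembled & table$frequency > params$H_p)
  else
    which(!table$assembled & table$frequency >= floor_eff &
            table$frequency <= params$L_p)
  if (!length(cand)) return(NULL)
  o <- order(if (pool == "repeat") -table$frequency[cand]
             else table$frequency[cand],
             -table$mean_quality[cand], cand)
  cand[o[1L]]
}

#' Choose the optimal extension read among profile candidates
#'
#' \code{"longest_overlap"} picks the candidate overlapping the contig end by
#' the most bases (ties: higher frequency, then lexicographic order);
#' \code{"nearest_depth"} picks the candidate whose profile count is closest
#' to the theoretical sequencing depth (ties: longer overlap, then frequency,
#' then order).
#'
#' @param candidates data.frame with columns \code{sequence}, \code{overlap},
#'   \code{frequency} and \code{count} (the profile value at the candidate's
#'   overlap position).
#' @param strategy \code{"longest_overlap"} or \code{"nearest_depth"}.
#' @param S_d theoretical sequencing depth (needed for
#'   \code{"nearest_depth"}).
#' @return The row index of the chosen candidate, or \code{NULL} if there are
#'   none.
#' @export
choose_optimal_read <- function(candidates,
                                strategy = c("longest_overlap", "nearest_depth"),
                                S_d = NULL) {
  strategy <- match.arg(strategy)
  if (!nrow(candidates)) return(NULL)
  o <- if (strategy == "longest_overlap") {
    order(-candidates$overlap, -candidates$frequency, candidates$sequence)
  } else {
    if (is.null(S_d)) stop("nearest_depth requires S_d")
    order(abs(candidates$count - S_d), -candidates$overlap,
          -candidates$frequency, candidates$sequence)
  }
  o[1L]
}

#' Estimate the copy number of an assembled contig
#'
#' The filtered interval means recorded at every accepted extension step (the
#' M_n trace) average to (copy number) x S_fd inside a repeat, so the copy
#' number is mean(M_n) / S_fd rounded half-up to the nearest integer, floored
#' at 1.
#'
#' @param M_n numeric trace of filtered interval means (nonempty).
#' @param S_fd filtered sequencing depth \code{S_d * L_w^N_f}.
#' @return Positive integer copy-number estimate.
#' @examples
#' estimate_copy_number(c(12.1, 12.3), 6)  # 2
#' @export
estimate_copy_number <- function(M_n, S_fd) {
  if (!length(M_n)) stop("empty M_n trace: contig was never extended")
  if (S_fd <= 0) stop("S_fd must be positive")
  max(1L, as.integer(floor(mean(M_n) / S_fd + 0.5)))
}

#' Extend a single seed into a contig
#'
#' Greedy seed-and-extend: the seed is extended at its 3' end, then (via the
#' reverse complement of the working contig) at its 5' end. Each step profiles
#' the overlap interval, filters it with the sliding window, records the
#' filtered mean in the M_n trace, applies the boundary stop rule, and appends
#' the optimal extendable read, which is marked assembled along with the seed.
#'
#' @param seed seed sequence (must be an unassembled table entry) or its row
#'   index.
#' @param contig_class \code{"repeat"} or \code{"nonrepeat"}.
#' @param table a \code{swa_table}.
#' @param params a \code{\link{swa_params}}.
#' @return List with \code{contig} (a contig record: \code{sequence},
#'   \code{contig_class}, \code{M_n}, \code{copy_number}, \code{seed}, stop
#'   reasons per end) and \code{table} (the table with consumed entries marked
#'   assembled).
#' @export
extend_contig <- function(seed, contig_class = c("repeat", "nonrepeat"),
                          table, params) {
  contig_class <- match.arg(contig_class)
  idx <- if (is.character(seed)) match(seed, table$sequence) else as.integer(seed)
  if (is.na(idx) || idx < 1L || idx > nrow(table)) stop("seed not found in table")
  if (table$assembled[idx]) stop("seed is already assembled")
  res <- cpp_extend_contig(table$sequence, table$frequency, table$mean_quality,
                           table$assembled, idx,
                           contig_class == "repeat", params_for_kernel(params))
  table$assembled <- res$assembled
  record <- list(sequence = res$sequence, contig_class = contig_class,
                 M_n = res$mn,
                 copy_number = if (length(res$mn))
                   estimate_copy_number(res$mn, params$S_fd) else NA_integer_,
                 seed = table$sequence[idx],
                 stop3 = res$stop3, stop5 = res$stop5)
  list(contig = record, table = table)
}

#' Assemble repeats and nonrepeats from a read set
#'
#' Runs the full serial pipeline: read cleaning, unique-read table
#' construction (reads plus reverse complements), hash indexing, then a repeat
#' pass (seeds with count above \code{H_p}) followed by a nonrepeat pass
#' (seeds with count at most \code{L_p}), each extending seeds until its pool
#' is exhausted. When a contig is finished, all unique entries occurring as a
#' read-length substring of it (either orientation) are retired, so repeat
#' copies are represented once and nonrepeat regions cannot re-seed. Contigs
#' shorter than \code{min_contig} are dropped; every contig carries its
#' estimated copy number.
#'
#' @param reads a \code{swa_reads} object, character vector of read sequences,
#'   or a prebuilt \code{swa_table}.
#' @param params a \code{\link{swa_params}}.
#' @param policy cleaning policy applied when \code{reads} carries qualities.
#' @return An object of class \code{"swa_assembly"}: list with \code{contigs}
#'   (data.frame: \code{id}, \code{sequence}, \code{length},
#'   \code{contig_class}, \code{copy_number}, \code{mn_mean},
#'   \code{n_steps}, \code{stop3}, \code{stop5}, \code{seed}), \code{M_n}
#'   (list of traces), \code{params}, and bookkeeping counts.
#' @export
swa_assemble <- function(reads, params, policy = clean_policy()) {
  if (inherits(reads, "swa_table")) {
    table <- reads
    n_clean <- NA_integer_
  } else {
    reads <- clean_reads(reads, policy)
    n_clean <- length(reads$sequence)
    table <- build_unique_table(reads)
  }
  L_r <- attr(table, "L_r")
  if (!is.na(L_r) && L_r != params$L_r)
    stop("params$L_r (", params$L_r, ") differs from read length (", L_r, ")")
  if (!nrow(table)) {
    return(new_assembly(empty_contigs_df(), list(), params, 0L, 0L, 0L))
  }
  res <- cpp_assemble(table$sequence, table$frequency, table$mean_quality,
                      table$assembled, params_for_kernel(params))
  lens <- nchar(res$sequence)
  copies <- vapply(res$mn, function(m)
    if (length(m)) estimate_copy_number(m, params$S_fd) else NA_integer_,
    integer(1))
  keep <- lens >= params$min_contig
  contigs <- data.frame(
    id = sprintf("contig_%d", seq_len(sum(keep))),
    sequence = res$sequence[keep],
    length = lens[keep],
    contig_class = res$contig_class[keep],
    copy_number = copies[keep],
    mn_mean = vapply(res$mn[keep], function(m)
      if (length(m)) mean(m) else NA_real_, numeric(1)),
    n_steps = vapply(res$mn[keep], length, integer(1)),
    stop3 = res$stop3[keep], stop5 = res$stop5[keep],
    seed = res$seed[keep],
    stringsAsFactors = FALSE)
  new_assembly(contigs, res$mn[keep], params, n_clean, nrow(table),
               sum(!keep))
}

empty_contigs_df <- function() {
  data.frame(id = character(0), sequence = character(0), length = integer(0),
             contig_class = character(0), copy_number = integer(0),
             mn_mean = numeric(0), n_steps = integer(0), stop3 = character(0),
             stop5 = character(0), seed = character(0),
             stringsAsFactors = FALSE)
}

new_assembly <- function(contigs, mn, params, n_clean, table_size, dropped) {
  structure(list(contigs = contigs, M_n = mn, params = params,
                 n_clean_reads = n_clean, table_size = table_size,
                 n_dropped_short = dropped),
            class = "swa_assembly")
}

#' @export
print.swa_assembly <- function(x, ...) {
  ct <- x$contigs
  cat(sprintf("Assembly: %d contigs (%d repeat, %d nonrepeat), %d short contig%s dropped\n",
              nrow(ct), sum(ct$contig_class == "repeat"),
              sum(ct$contig_class == "nonrepeat"),
              x$n_dropped_short, if (x$n_dropped_short == 1) "" else "s"))
  if (nrow(ct)) {
    rep_ct <- ct[ct$contig_class == "repeat", ]
    if (nrow(rep_ct))
      cat(sprintf("  repeat copy numbers: %s\n",
                  paste(rep_ct$copy_number, collapse = ", ")))
    cat(sprintf("  total length %d, max %d\n", sum(ct$length), max(ct$length)))
  }
  invisible(x)
}

#' @export
summary.swa_assembly <- function(object, ...) {
  ct <- object$contigs
  out <- list(n_contigs = nrow(ct),
              TRC = sum(ct$contig_class == "repeat"),
              NNC = sum(ct$contig_class == "nonrepeat"),
              CNRC = ct$copy_number[ct$contig_class == "repeat"],
              total_length = sum(ct$length),
              max_length = if (nrow(ct)) max(ct$length) else 0L,
              params = object$params)
  class(out) <- "summary.swa_assembly"
  out
}

#' @export
print.summary.swa_assembly <- function(x, ...) {
  cat(sprintf("Contigs: %d (TRC %d, NNC %d); total %d bp, max %d bp\n",
              x$n_contigs, x$TRC, x$NNC, x$total_length, x$max_length))
  if (length(x$CNRC))
    cat(sprintf("CNRC: %s\n", paste(x$CNRC, collapse = ", ")))
  invisible(x)
}
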