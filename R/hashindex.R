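#' Quaternary keyword encoding
#'
#' Maps a DNA keyword to its integer key under A=0, C=1, G=2, T=3 with the
#' most significant digit first: \code{encode_key("ACGT")} is
#' \code{0*64 + 1*16 + 2*4 + 3 = 27}. The map is a bijection between
#' length-\code{L_k} strings and \code{[0, 4^L_k)}.
#'
#' @param s DNA string (alphabet ACGT).
#' @return Integer key (double for keywords longer than 15 bases).
#' @examples
#' encode_key("TT")  # 15
#' @export
encode_key <- function(s) {
  if (length(s) != 1L || !nzchar(s)) stop("s must be a single nonempty string")
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  digits <- match(chars, c("A", "C", "G", "T")) - 1L
  if (anyNA(digits)) stop("keyword contains non-ACGT characters")
  sum(digits * 4^(rev(seq_along(digits)) - 1))
}

#' Decode an integer key back to its DNA keyword
#'
#' @param key integer key in \code{[0, 4^L_k)}.
#' @param L_k keyword length in bases.
#' @return DNA string of length \code{L_k}.
#' @export
decode_key <- function(key, L_k) {
  if (key < 0 || key >= 4^L_k) stop("key out of range [0, 4^L_k)")
  out <- character(L_k)
  for (i in L_k:1) {
    out[i] <- c("A", "C", "G", "T")[key %% 4 + 1]
    key <- key %/% 4
  }
  paste(out, collapse = "")
}

#' Build the prefix/suffix hash index of a unique-read table
#'
#' Every unassembled entry is bucketed twice: by the integer key of its first
#' \code{L_k} bases (forward map, used when a read's 5' end must match a
#' contig's 3' end) and of its last \code{L_k} bases (backward map). Keys index
#' entry ids, not strings, so lookup reduces overlap search to a small bucket
#' that is then verified exactly.
#'
#' @param table a \code{\link{build_unique_table}} result.
#' @param L_k keyword length in bases; must not exceed the read length.
#' @return An object of class \code{"swa_index"} with \code{forward} and
#'   \code{backward} maps (named lists keyed by integer key), \code{L_k}, and
#'   a snapshot of the entry sequences for verification.
#' @export
build_index <- function(table, L_k = 12L) {
  L_r <- attr(table, "L_r")
  if (!is.na(L_r) && L_k > L_r) stop("L_k cannot exceed the read length")
  live <- which(!table$assembled)
  fseq <- substr(table$sequence[live], 1L, L_k)
  bseq <- substr(table$sequence[live], nchar(table$sequence[live]) - L_k + 1L,
                 nchar(table$sequence[live]))
  fkey <- vapply(fseq, encode_key, numeric(1), USE.NAMES = FALSE)
  bkey <- vapply(bseq, encode_key, numeric(1), USE.NAMES = FALSE)
  structure(list(
    L_k = as.integer(L_k),
    forward = split(live, sprintf("%.0f", fkey)),
    backward = split(live, sprintf("%.0f", bkey)),
    sequences = table$sequence
  ), class = "swa_index")
}

#' @export
print.swa_index <- function(x, ...) {
  cat(sprintf("Hash index: L_k = %d, %d forward / %d backward buckets\n",
              x$L_k, length(x$forward), length(x$backward)))
  invisible(x)
}

#' Entries overlapping a contig end by exactly t bases
#'
#' Hash lookup of the overlap window's leading keyword followed by exact
#' verification of the full \code{t}-base overlap: returns precisely the
#' entries whose first \code{t} bases equal the last \code{t} bases of
#' \code{contig_end}.
#'
#' @param index a \code{\link{build_index}} result.
#' @param contig_end contig (or its 3'-end suffix), at least \code{t} bases.
#' @param t overlap length; must be at least \code{L_k}, otherwise the hash
#'   lookup could miss legal overlaps.
#' @return Integer vector of table entry ids (possibly empty).
#' @export
overlap_candidates <- function(index, contig_end, t) {
  if (t < index$L_k)
    stop("unsupported overlap: t must be >= the keyword length L_k")
  n <- nchar(contig_end)
  if (t > n) return(integer(0))
  suffix <- substr(contig_end, n - t + 1L, n)
  key <- sprintf("%.0f", encode_key(substr(suffix, 1L, index$L_k)))
  ids <- index$forward[[key]]
  if (is.null(ids)) return(integer(0))
  ids[substr(index$sequences[ids], 1L, t) == suffix]
}
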