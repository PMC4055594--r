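#' Read-cleaning policy
#'
#' Raw reads containing any \code{N} (uninformative) or any low-quality region
#' are discarded before assembly. "Low quality" is made concrete as: any base
#' below \code{min_base_quality}, or a read mean below \code{min_mean_quality}
#' (Phred scale).
#'
#' @param drop_if_contains_N drop reads containing \code{N}.
#' @param min_base_quality minimum per-base Phred score.
#' @param min_mean_quality minimum read-mean Phred score.
#' @return An object of class \code{"clean_policy"}.
#' @export
clean_policy <- function(drop_if_contains_N = TRUE, min_base_quality = 10,
                         min_mean_quality = 20) {
  if (min_base_quality < 0 || min_mean_quality < 0)
    stop("quality thresholds must be >= 0")
  structure(list(drop_if_contains_N = isTRUE(drop_if_contains_N),
                 min_base_quality = min_base_quality,
                 min_mean_quality = min_mean_quality),
            class = "clean_policy")
}

#' Filter raw reads by the cleaning policy
#'
#' Keeps exactly the reads with no \code{N}, no base below the per-base
#' threshold, and mean quality at or above the mean threshold; input order is
#' preserved. All reads must share one length (the assembler is a fixed-read-
#' length algorithm).
#'
#' @param reads a \code{swa_reads} object (or character vector of sequences,
#'   in which case quality checks are skipped, as for FASTA input).
#' @param policy a \code{\link{clean_policy}}.
#' @return A \code{swa_reads} object with the surviving reads.
#' @export
clean_reads <- function(reads, policy = clean_policy()) {
  if (is.character(reads))
    reads <- structure(list(id = sprintf("read%d", seq_along(reads)),
                            sequence = reads,
                            quality = rep(NA_character_, length(reads)),
                            L_r = if (length(reads)) nchar(reads[1]) else NA_integer_,
                            S_d = NA_real_, provenance = list()),
                       class = "swa_reads")
  lens <- nchar(reads$sequence)
  if (length(unique(lens)) > 1L)
    stop("mixed read lengths: the algorithm requires a fixed L_r")
  keep <- rep(TRUE, length(reads$sequence))
  if (policy$drop_if_contains_N)
    keep <- keep & !grepl("N", reads$sequence, fixed = TRUE)
  have_qual <- length(reads$quality) > 0 && !anyNA(reads$quality)
  if (have_qual) {
    qs <- cpp_quality_stats(reads$quality)
    keep <- keep & qs$min >= policy$min_base_quality &
      qs$mean >= policy$min_mean_quality
  }
  out <- reads
  out$id <- reads$id[keep]
  out$sequence <- reads$sequence[keep]
  out$quality <- reads$quality[keep]
  out
}

#' Reverse complement of DNA sequences
#'
#' Strict ACGT alphabet; vectorised. The operation is an involution:
#' \code{revcomp(revcomp(x)) == x}.
#'
#' @param x character vector of ACGT sequences.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("AAAC")  # "GTTT"
#' @export
revcomp <- function(x) cpp_revcomp(x)

#' Build the unique-read frequency table (table R)
#'
#' Each cleaned read and its reverse complement are pooled; identical sequences
#' are collapsed into one entry carrying the multiplicity, the mean of the
#' contributing reads' mean qualities, and an assembled/unassembled state. The
#' table is sorted lexicographically; the sum of all frequencies equals twice
#' the number of cleaned reads (a self-reverse-complementary read is counted
#' once per orientation to preserve this conservation).
#'
#' @param reads a \code{swa_reads} object or character vector of equal-length
#'   ACGT sequences.
#' @return An object of class \code{"swa_table"}: a data.frame with columns
#'   \code{sequence}, \code{frequency}, \code{mean_quality}, \code{assembled},
#'   plus attributes \code{L_r} and \code{total_raw_reads}.
#' @export
build_unique_table <- function(reads) {
  if (is.character(reads)) {
    seqs <- reads
    mqs <- rep(40, length(seqs))
  } else {
    seqs <- reads$sequence
    mqs <- if (length(reads$quality) && !anyNA(reads$quality))
      cpp_quality_stats(reads$quality)$mean else rep(40, length(seqs))
  }
  if (length(seqs) == 0L) {
    tab <- data.frame(sequence = character(0), frequency = integer(0),
                      mean_quality = numeric(0), assembled = logical(0),
                      stringsAsFactors = FALSE)
    return(structure(tab, class = c("swa_table", "data.frame"),
                     L_r = NA_integer_, total_raw_reads = 0L))
  }
  lens <- unique(nchar(seqs))
  if (length(lens) > 1L) stop("reads must share one length")
  u <- cpp_unique_table(seqs, mqs)
  tab <- data.frame(sequence = u$sequence, frequency = u$frequency,
                    mean_quality = u$mean_quality,
                    assembled = rep(FALSE, length(u$sequence)),
                    stringsAsFactors = FALSE)
  structure(tab, class = c("swa_table", "data.frame"),
            L_r = as.integer(lens), total_raw_reads = length(seqs))
}

#' @export
print.swa_table <- function(x, ...) {
  cat(sprintf("Unique-read table: %d entries (L_r = %s), %d raw reads, %d assembled\n",
              nrow(x), attr(x, "L_r"), attr(x, "total_raw_reads"),
              sum(x$assembled)))
  if (nrow(x)) {
    print.data.frame(utils::head(as.data.frame(x), 6))
    if (nrow(x) > 6) cat("  ...\n")
  }
  invisible(x)
}

#' Serialize a unique-read table for inspection
#'
#' Writes the table as a two-column TSV (sequence, frequency) plus a JSON
#' metadata sidecar (read length, raw read count, entry count).
#'
#' @param table a \code{swa_table}.
#' @param tsv_path,json_path output files (either may be \code{NULL}).
#' @return Invisibly, the paths written.
#' @export
write_unique_table <- function(table, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(table[, c("sequence", "frequency")], tsv_path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(L_r = attr(table, "L_r"),
                              total_raw_reads = attr(table, "total_raw_reads"),
                              entries = nrow(table)),
                         json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv = tsv_path, json = json_path))
}

#' Mark table entries as assembled
#'
#' Flips the state of the listed sequences to assembled; frequencies are
#' unchanged and the operation is idempotent.
#'
#' @param table a \code{swa_table}.
#' @param sequences character vector of entry sequences present in the table.
#' @return The updated table.
#' @export
mark_assembled <- function(table, sequences) {
  idx <- match(sequences, table$sequence)
  if (anyNA(idx))
    stop("unknown sequence(s): ", paste(utils::head(sequences[is.na(idx)], 3),
                                        collapse = ", "))
  table$assembled[idx] <- TRUE
  table
}
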