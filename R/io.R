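#' Write a simulated genome as FASTA
#' @param genome a \code{swa_genome} (or named character vector).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- if (inherits(genome, "swa_genome"))
    stats::setNames(genome$sequence, "genome") else genome
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write reads as FASTQ (Sanger Phred+33)
#' @param reads a \code{swa_reads}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  qual <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(x, filepath = path, format = "fastq",
                              qualities = qual)
  invisible(path)
}

#' Read a FASTQ or FASTA file into a read set
#'
#' Format is taken from the extension (\code{.fastq}/\code{.fq} vs
#' \code{.fasta}/\code{.fa}); FASTA reads carry no qualities and quality
#' filters are skipped downstream.
#'
#' @param path input file.
#' @return A \code{swa_reads} object.
#' @export
read_reads <- function(path) {
  is_fastq <- grepl("\\.(fastq|fq)$", path, ignore.case = TRUE)
  if (is_fastq) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  } else {
    x <- Biostrings::readDNAStringSet(path)
    qual <- rep(NA_character_, length(x))
  }
  lens <- unique(BiocGenerics::width(x))
  structure(list(id = names(x), sequence = unname(as.character(x)),
                 quality = unname(qual),
                 L_r = if (length(lens) == 1L) lens else NA_integer_,
                 S_d = NA_real_, provenance = list(path = path)),
            class = "swa_reads")
}

#' Write the repeat annotation truth as BED and JSON
#'
#' BED intervals are 0-based half-open with the name column
#' \code{family_id.copy_index}; the JSON file carries each family's unit
#' sequence, copy count, mode and loci.
#'
#' @param genome a \code{swa_genome}.
#' @param bed_path,json_path output files (either may be \code{NULL}).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(genome, bed_path = NULL, json_path = NULL) {
  ann <- genome$annotations
  if (!is.null(bed_path)) {
    bed <- if (NROW(ann)) {
      data.frame(chrom = "genome", start = ann$start, end = ann$end,
                 name = paste0(ann$family_id, ".", ann$copy_index))
    } else {
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 name = character(0))
    }
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(json_path)) {
    fams <- unname(lapply(genome$families, function(f) {
      loci <- ann[ann$family_id == f$family_id, c("start", "end", "copy_index")]
      list(family_id = f$family_id, unit = f$unit,
           unit_length = f$unit_length, copies = f$copies, mode = f$mode,
           loci = loci)
    }))
    jsonlite::write_json(list(genome_length = genome$length, families = fams),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(bed = bed_path, json = json_path))
}

#' Read a truth JSON file back into a minimal genome object
#'
#' Restores the fields evaluation needs (length, families, annotations); the
#' genome sequence must be supplied separately from its FASTA.
#'
#' @param json_path truth JSON written by \code{\link{write_truth}}.
#' @param genome_fasta optional genome FASTA to attach the sequence.
#' @return A \code{swa_genome} object.
#' @export
read_truth <- function(json_path, genome_fasta = NULL) {
  tr <- jsonlite::read_json(json_path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  if (!NROW(tr$families)) {
    seq <- if (!is.null(genome_fasta))
      as.character(Biostrings::readDNAStringSet(genome_fasta)[[1]]) else NA_character_
    return(structure(list(sequence = seq, length = tr$genome_length,
                          annotations = NULL, families = list(),
                          provenance = list(json = json_path)),
                     class = "swa_genome"))
  }
  fams <- lapply(seq_len(nrow(tr$families)), function(i) {
    f <- tr$families[i, ]
    list(family_id = f$family_id, unit = f$unit, unit_length = f$unit_length,
         copies = f$copies, mode = f$mode)
  })
  names(fams) <- tr$families$family_id
  ann <- do.call(rbind, lapply(seq_len(nrow(tr$families)), function(i) {
    loci <- tr$families$loci[[i]]
    if (is.null(loci) || !NROW(loci)) return(NULL)
    data.frame(family_id = tr$families$family_id[i], start = loci$start,
               end = loci$end, copy_index = loci$copy_index,
               stringsAsFactors = FALSE)
  }))
  seq <- if (!is.null(genome_fasta))
    as.character(Biostrings::readDNAStringSet(genome_fasta)[[1]]) else NA_character_
  structure(list(sequence = seq, length = tr$genome_length,
                 annotations = ann, families = fams,
                 provenance = list(json = json_path)),
            class = "swa_genome")
}

#' Write assembled contigs as FASTA
#'
#' Headers carry the contig class, the copy estimate and the M_n summary,
#' e.g. \code{>contig_3 class=repeat copies=3 mn_mean=53.9}.
#'
#' @param assembly a \code{swa_assembly}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_contigs_fasta <- function(assembly, path) {
  ct <- assembly$contigs
  x <- Biostrings::DNAStringSet(ct$sequence)
  names(x) <- sprintf("%s class=%s copies=%s mn_mean=%.1f", ct$id,
                      ct$contig_class, ct$copy_number, ct$mn_mean)
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

#' Write an evaluation report as TSV and JSON
#'
#' The TSV is one row in the canonical column order (TRC, CNRC, NNC, N50,
#' Max, CN-accuracy, Rep-accuracy, C-accuracy, Genome coverage); the JSON
#' carries the same values plus N90, mean and E-size.
#'
#' @param ev a \code{\link{evaluate}} result.
#' @param tsv_path,json_path output files (either may be \code{NULL}).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(ev, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(report_row(ev), tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json_path)) {
    payload <- ev[c("TRC", "CNRC", "NNC", "Number_C", "N50", "N90",
                    "mean_contig", "max_contig", "E_size", "CN_accuracy",
                    "Rep_accuracy", "C_accuracy", "genome_coverage")]
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(tsv = tsv_path, json = json_path))
}
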