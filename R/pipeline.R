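#' Load a run configuration
#'
#' A configuration is a named list (or YAML/JSON file) with components
#' \code{seed}, \code{outdir}, \code{genome} (length, families, each with
#' copies/unit_length/mode, min_separation), \code{reads} (L_r, S_d,
#' insert_mu, insert_sd, error_rate, bias_sigma) and \code{params} (any
#' \code{\link{swa_params}} argument). Unspecified values fall back to
#' defaults; the seed governs every stochastic step and is recorded in each
#' output artifact.
#'
#' @param config named list, or path to a YAML or JSON file.
#' @return The normalised configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config must provide a seed")
  config$seed <- as.integer(config$seed)
  if (is.null(config$outdir)) config$outdir <- "."
  config
}

config_genome <- function(config) {
  g <- config$genome
  fams <- lapply(g$families, function(f)
    repeat_family(copies = f$copies, unit_length = f$unit_length,
                  mode = if (is.null(f$mode)) "interspersed" else f$mode,
                  family_id = f$family_id))
  make_genome(length = g$length, families = fams, seed = config$seed,
              min_separation = if (is.null(g$min_separation)) 200L
                               else g$min_separation)
}

config_params <- function(config) {
  p <- config$params
  if (is.null(p)) p <- list()
  p$S_d <- config$reads$S_d
  p$L_r <- config$reads$L_r
  do.call(swa_params, p)
}

#' Run the simulation stage of the pipeline
#'
#' Writes the genome FASTA, reads FASTQ, truth BED and truth JSON into the
#' output directory, along with a manifest carrying the configuration and the
#' MD5 checksum of every file (identical config + seed reproduces identical
#' checksums).
#'
#' @param config configuration (see \code{\link{load_config}}).
#' @return Invisibly, a list with the file paths and the genome object.
#' @export
run_simulate <- function(config) {
  config <- load_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- config_genome(config)
  r <- config$reads
  reads <- sample_reads(genome, L_r = r$L_r, S_d = r$S_d,
                        insert_mu = if (is.null(r$insert_mu)) 300 else r$insert_mu,
                        insert_sd = if (is.null(r$insert_sd)) 30 else r$insert_sd,
                        error_rate = if (is.null(r$error_rate)) 0 else r$error_rate,
                        bias_sigma = if (is.null(r$bias_sigma)) 0 else r$bias_sigma,
                        seed = config$seed + 1L)
  paths <- file.path(config$outdir,
                     c("genome.fasta", "reads.fastq", "truth.bed", "truth.json"))
  names(paths) <- c("genome", "reads", "bed", "json")
  write_genome_fasta(genome, paths["genome"])
  write_reads_fastq(reads, paths["reads"])
  write_truth(genome, paths["bed"], paths["json"])
  manifest <- list(seed = config$seed, config = config,
                   files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, genome = genome, reads = reads))
}

#' Run the assembly stage of the pipeline
#'
#' Reads the FASTQ produced by \code{\link{run_simulate}} (or any fixed-length
#' read set), assembles it, and writes the contig FASTA plus a JSON sidecar
#' echoing every parameter (explicit config values override the derived
#' defaults).
#'
#' @param config configuration (see \code{\link{load_config}}).
#' @param reads optional in-memory \code{swa_reads}, bypassing the FASTQ.
#' @return Invisibly, a list with the paths and the \code{swa_assembly}.
#' @export
run_assemble <- function(config, reads = NULL) {
  config <- load_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(reads))
    reads <- read_reads(file.path(config$outdir, "reads.fastq"))
  params <- config_params(config)
  assembly <- swa_assemble(reads, params)
  contig_path <- file.path(config$outdir, "contigs.fasta")
  write_contigs_fasta(assembly, contig_path)
  params_path <- file.path(config$outdir, "params.json")
  jsonlite::write_json(c(unclass(params), list(seed = config$seed)),
                       params_path, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = c(contigs = contig_path, params = params_path),
                 assembly = assembly))
}

#' Run the evaluation stage of the pipeline
#'
#' Evaluates the contigs against the simulation truth and writes the report
#' as TSV (canonical column order) and JSON with identical values.
#'
#' @param config configuration (see \code{\link{load_config}}).
#' @param assembly optional in-memory \code{swa_assembly}.
#' @param truth optional in-memory \code{swa_genome}.
#' @return Invisibly, a list with the paths and the \code{swa_eval}.
#' @export
run_evaluate <- function(config, assembly = NULL, truth = NULL) {
  config <- load_config(config)
  if (is.null(truth)) {
    json_path <- file.path(config$outdir, "truth.json")
    if (!file.exists(json_path)) stop("missing truth.json; run simulate first")
    truth <- read_truth(json_path, file.path(config$outdir, "genome.fasta"))
  }
  if (is.null(assembly)) {
    cpath <- file.path(config$outdir, "contigs.fasta")
    if (!file.exists(cpath)) stop("missing contigs.fasta; run assemble first")
    x <- Biostrings::readDNAStringSet(cpath)
    hdr <- names(x)
    cls <- sub(".*class=([a-z]+).*", "\\1", hdr)
    cp <- suppressWarnings(as.integer(sub(".*copies=([0-9NA]+).*", "\\1", hdr)))
    assembly <- data.frame(id = sub(" .*", "", hdr),
                           sequence = as.character(x),
                           length = BiocGenerics::width(x),
                           contig_class = cls, copy_number = cp,
                           stringsAsFactors = FALSE)
  }
  ev <- evaluate(assembly, truth)
  paths <- file.path(config$outdir, c("report.tsv", "report.json"))
  write_report(ev, paths[1], paths[2])
  invisible(list(paths = c(tsv = paths[1], json = paths[2]), report = ev))
}

#' Run simulate, assemble and evaluate end to end
#'
#' @param config configuration (see \code{\link{load_config}}).
#' @return Invisibly, a list with the genome, assembly and report.
#' @export
run_all <- function(config) {
  config <- load_config(config)
  sim <- run_simulate(config)
  asm <- run_assemble(config, reads = sim$reads)
  ev <- run_evaluate(config, assembly = asm$assembly, truth = sim$genome)
  invisible(list(genome = sim$genome, assembly = asm$assembly,
                 report = ev$report))
}
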