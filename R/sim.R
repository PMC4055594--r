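#' Describe a repeat family to plant in a simulated genome
#'
#' @param copies number of identical copies (>= 1).
#' @param unit_length length of the repeat unit in bases; ignored when
#'   \code{unit} is given. When \code{NULL}, \code{make_genome()} draws a
#'   length uniformly from 500 to 5000 bases under its seed.
#' @param mode \code{"interspersed"} (copies scattered at separated loci) or
#'   \code{"tandem"} (copies cascaded head-to-tail at one locus).
#' @param family_id label; defaults are assigned by \code{make_genome()}.
#' @param unit optional explicit unit sequence (ACGT string).
#' @return An object of class \code{"repeat_family"}.
#' @export
repeat_family <- function(copies, unit_length = NULL,
                          mode = c("interspersed", "tandem"),
                          family_id = NULL, unit = NULL) {
  mode <- match.arg(mode)
  if (!is.null(unit)) {
    check_dna(unit)
    unit_length <- nchar(unit)
  }
  if (!is.null(unit_length) && unit_length < 1) stop("unit_length must be >= 1")
  if (copies < 1) stop("copies must be >= 1")
  structure(list(family_id = family_id,
                 unit_length = if (is.null(unit_length)) NULL
                               else as.integer(unit_length),
                 copies = as.integer(copies), mode = mode, unit = unit),
            class = "repeat_family")
}

check_dna <- function(x) {
  if (any(grepl("[^ACGT]", x))) stop("sequence contains non-ACGT characters")
  invisible(TRUE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

kmer_set <- function(s, k = 31L) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1L), k:n))
}

#' Simulate a genome with planted repeat families
#'
#' Generates a uniformly random ACGT background and plants each repeat family
#' according to its mode: interspersed copies are scattered at loci separated
#' by at least \code{min_separation} nonrepeat bases (and kept off the genome
#' ends), tandem copies form one head-to-tail cascade. All copies of a family
#' are exact. Unit sequences are drawn at random and screened so that no two
#' families share a 31-base substring, preventing accidental cross-family
#' repeats.
#'
#' @param length genome length in bases.
#' @param families list of \code{\link{repeat_family}} objects.
#' @param seed integer RNG seed (required: the genome is part of a reproducible
#'   experiment).
#' @param min_separation minimum number of nonrepeat bases between planted
#'   blocks and at both genome ends.
#' @return An object of class \code{"swa_genome"}: list with \code{sequence}
#'   (character scalar), \code{length}, \code{annotations} (data.frame with
#'   0-based half-open \code{start}, \code{end}, plus \code{family_id} and
#'   \code{copy_index}), and \code{families} (unit sequence, copies, mode per
#'   family).
#' @examples
#' g <- make_genome(10000, list(repeat_family(3, 500)), seed = 1)
#' nchar(g$sequence)
#' @export
make_genome <- function(length, families = list(), seed,
                        min_separation = 200L) {
  if (missing(seed)) stop("a seed is required")
  length <- as.integer(length)
  if (inherits(families, "repeat_family")) families <- list(families)
  ids <- vapply(seq_along(families), function(i) {
    fid <- families[[i]]$family_id
    if (is.null(fid)) sprintf("rep%02d", i) else fid
  }, character(1))
  if (anyDuplicated(ids)) stop("duplicate family_id")

  with_seed(seed, {
    # draw unit sequences, screened against shared 31-mers across families
    units <- character(length(families))
    seen <- character(0)
    for (i in seq_along(families)) {
      f <- families[[i]]
      if (!is.null(f$unit)) {
        units[i] <- f$unit
      } else {
        ul <- if (is.null(f$unit_length)) sample(500:5000, 1L) else f$unit_length
        repeat {
          u <- random_dna(ul)
          if (!any(kmer_set(u) %in% seen)) break
        }
        units[i] <- u
      }
      seen <- c(seen, kmer_set(units[i]))
    }

    # one placement block per interspersed copy; one block per tandem cascade
    blocks <- list()
    for (i in seq_along(families)) {
      f <- families[[i]]
      if (f$mode == "interspersed") {
        for (ci in seq_len(f$copies))
          blocks[[length(blocks) + 1L]] <-
            list(fam = i, seq = units[i], copies = 1L, first_copy = ci)
      } else {
        blocks[[length(blocks) + 1L]] <-
          list(fam = i, seq = strrep(units[i], f$copies), copies = f$copies,
               first_copy = 1L)
      }
    }
    total_rep <- sum(vapply(blocks, function(b) nchar(b$seq), numeric(1)))
    if (total_rep >= length)
      stop("planted repeat bases (", total_rep, ") must be < genome length")
    nb <- length(blocks)
    free <- length - total_rep
    slack <- free - (nb + 1L) * min_separation
    if (nb > 0L && slack < 0L)
      stop("genome too short for the requested repeat content and separation")

    if (nb > 0L) blocks <- blocks[sample.int(nb)]
    # gap lengths: min_separation each plus a random split of the slack
    gaps <- rep(min_separation, nb + 1L)
    if (nb > 0L && slack > 0L) {
      cuts <- sort(sample.int(slack + 1L, nb, replace = TRUE) - 1L)
      gaps <- gaps + diff(c(0L, cuts, slack))
    } else if (nb == 0L) {
      gaps <- free
    }

    pieces <- character(2L * nb + 1L)
    ann <- list()
    pos <- 0L
    for (i in seq_len(nb + 1L)) {
      pieces[2L * i - 1L] <- random_dna(gaps[i])
      pos <- pos + gaps[i]
      if (i <= nb) {
        b <- blocks[[i]]
        pieces[2L * i] <- b$seq
        ul <- nchar(units[b$fam])
        for (ci in seq_len(b$copies)) {
          ann[[length(ann) + 1L]] <- data.frame(
            family_id = ids[b$fam],
            start = pos + (ci - 1L) * ul,
            end = pos + ci * ul,
            copy_index = b$first_copy + ci - 1L,
            stringsAsFactors = FALSE)
        }
        pos <- pos + nchar(b$seq)
      }
    }
    annotations <- if (length(ann)) do.call(rbind, ann) else
      data.frame(family_id = character(0), start = integer(0),
                 end = integer(0), copy_index = integer(0),
                 stringsAsFactors = FALSE)

    fam_out <- lapply(seq_along(families), function(i) {
      f <- families[[i]]
      list(family_id = ids[i], unit = units[i],
           unit_length = nchar(units[i]), copies = f$copies, mode = f$mode)
    })
    names(fam_out) <- ids

    structure(list(sequence = paste(pieces, collapse = ""),
                   length = length, annotations = annotations,
                   families = fam_out,
                   provenance = list(seed = seed,
                                     min_separation = min_separation)),
              class = "swa_genome")
  })
}

#' @export
print.swa_genome <- function(x, ...) {
  cat(sprintf("Simulated genome: %d bp, %d repeat famil%s, %d planted cop%s\n",
              x$length, length(x$families),
              if (length(x$families) == 1) "y" else "ies",
              nrow(x$annotations),
              if (nrow(x$annotations) == 1) "y" else "ies"))
  for (f in x$families)
    cat(sprintf("  %s: %d x %d bp (%s)\n", f$family_id, f$copies,
                f$unit_length, f$mode))
  invisible(x)
}

#' Recommended paired-end insert size for overlapping libraries
#'
#' For a library whose two reads are meant to overlap, the recommended insert
#' size is \code{(l + m) * 2 - n}, with read length \code{l}, maximum error
#' tolerance \code{m} and maximum overlap length \code{n} (all in bases).
#'
#' @param l read length (bases).
#' @param m maximum error tolerance (bases).
#' @param n maximum overlap length (bases).
#' @return Insert size in bases.
#' @examples
#' recommended_insert_size(150, 50, 100)  # 300
#' @export
recommended_insert_size <- function(l, m, n) {
  if (any(c(l, m, n) < 0)) stop("l, m, n must be nonnegative")
  out <- (l + m) * 2 - n
  if (out <= 0) stop("non-positive insert size; check l, m, n")
  out
}

#' Sample paired-end reads from a simulated genome
#'
#' Fragments start uniformly over the genome (or weighted by a lognormal
#' per-position bias when \code{bias_sigma > 0}) with lengths drawn from
#' Normal(\code{insert_mu}, \code{insert_sd}) truncated to at least \code{L_r};
#' both fragment ends are read (the second end reverse-complemented) and pooled
#' into a single-read set, with pairing retained only in the read ids. The
#' total read count is exactly \code{round(S_d * genome length)}. Substitution
#' errors are applied independently per base at \code{error_rate}; bases carry
#' constant Q40 qualities except erroneous bases, which are downgraded to Q10
#' with probability 0.5.
#'
#' @param genome a \code{\link{make_genome}} result (or ACGT string).
#' @param L_r read length in bases.
#' @param S_d sequencing depth in reads per base (not coverage).
#' @param insert_mu,insert_sd fragment length distribution parameters (bases).
#' @param error_rate substitution error probability per base, in [0, 1).
#' @param bias_sigma lognormal sigma for per-position sampling weights
#'   (0 = uniform).
#' @param seed integer RNG seed.
#' @param keep_fragments record the sampled fragment starts and lengths in
#'   \code{provenance$fragments} (for diagnostics).
#' @return An object of class \code{"swa_reads"}: list with \code{id},
#'   \code{sequence}, \code{quality} (parallel character vectors), \code{L_r},
#'   \code{S_d} and \code{provenance}.
#' @export
sample_reads <- function(genome, L_r, S_d, insert_mu = 300, insert_sd = 30,
                         error_rate = 0, bias_sigma = 0, seed,
                         keep_fragments = FALSE) {
  if (missing(seed)) stop("a seed is required")
  gseq <- if (inherits(genome, "swa_genome")) genome$sequence else genome
  L <- nchar(gseq)
  if (S_d < 0) stop("S_d must be >= 0")
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)")
  if (L_r > L) stop("read length exceeds genome length")
  N_r <- round(S_d * L)
  prov <- list(L_r = L_r, S_d = S_d, insert_mu = insert_mu,
               insert_sd = insert_sd, error_rate = error_rate,
               bias_sigma = bias_sigma, seed = seed, genome_length = L)
  if (N_r == 0)
    return(structure(list(id = character(0), sequence = character(0),
                          quality = character(0), L_r = as.integer(L_r),
                          S_d = S_d, provenance = prov),
                     class = "swa_reads"))
  with_seed(seed, {
    n_frag <- ceiling(N_r / 2)
    flen <- pmin(L, pmax(L_r, round(stats::rnorm(n_frag, insert_mu, insert_sd))))
    if (bias_sigma > 0) {
      w <- stats::rlnorm(L, 0, bias_sigma)
      starts <- sample.int(L, n_frag, replace = TRUE, prob = w)
      starts <- pmin(starts, L - flen + 1L)
    } else {
      starts <- floor(stats::runif(n_frag) * (L - flen + 1)) + 1L
    }
    if (keep_fragments)
      prov$fragments <- data.frame(start = starts, length = flen)
    r1 <- substring(gseq, starts, starts + L_r - 1L)
    r2 <- cpp_revcomp(substring(gseq, starts + flen - L_r, starts + flen - 1L))
    seqs <- character(2L * n_frag)
    seqs[c(TRUE, FALSE)] <- r1
    seqs[c(FALSE, TRUE)] <- r2
    ids <- character(2L * n_frag)
    ids[c(TRUE, FALSE)] <- sprintf("frag%07d/1", seq_len(n_frag))
    ids[c(FALSE, TRUE)] <- sprintf("frag%07d/2", seq_len(n_frag))
    seqs <- seqs[seq_len(N_r)]
    ids <- ids[seq_len(N_r)]
    quals <- rep(strrep("I", L_r), N_r)
    if (error_rate > 0) {
      nerr <- stats::rbinom(N_r, L_r, error_rate)
      for (i in which(nerr > 0)) {
        pos <- sample.int(L_r, nerr[i])
        s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
        q <- strsplit(quals[i], "", fixed = TRUE)[[1]]
        for (p in pos) {
          s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
          if (stats::runif(1) < 0.5) q[p] <- "+"  # Q10
        }
        seqs[i] <- paste(s, collapse = "")
        quals[i] <- paste(q, collapse = "")
      }
    }
    structure(list(id = ids, sequence = seqs, quality = quals,
                   L_r = as.integer(L_r), S_d = S_d, provenance = prov),
              class = "swa_reads")
  })
}

#' @export
print.swa_reads <- function(x, ...) {
  cat(sprintf("Read set: %d reads of length %d (S_d = %g)\n",
              length(x$sequence), x$L_r, x$S_d))
  invisible(x)
}

#' Number of reads in a read set
#' @param x a \code{swa_reads} object.
#' @export
length.swa_reads <- function(x) length(x$sequence)
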