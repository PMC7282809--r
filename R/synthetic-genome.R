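#' Generate a synthetic experimental + calibration genome pair
#'
#' Draws random nucleotide sequences for two species so that no subsequence of
#' length `read_length` occurs in both species on either strand. This mirrors
#' the spike-in calibration setting, where reads are assigned to one of two
#' genomes by sequential alignment: with disjoint read-length k-mer spectra
#' every simulated read has exactly one correct assignment, so the partition
#' step can be checked against ground truth.
#'
#' The disjointness audit compares k-mers of length `min(read_length, 31)`:
#' two genomes sharing a read-length subsequence necessarily share all its
#' k-mers, so an empty shared k-mer set is sufficient. For random sequences of
#' desk scale the audit essentially never fails; if it does, the pair is
#' redrawn up to `max_tries` times and then an error is raised.
#'
#' @param seed Integer seed; regeneration with the same seed is byte-identical.
#' @param n_chrom Number of chromosomes per species (>= 1).
#' @param chrom_len Chromosome length in bases (>= `read_length`).
#' @param read_length Read length in bases (>= 20) used for the uniqueness
#'   audit and by [sample_experiment()]. The default of 190 bases matches a
#'   typical single-end semiconductor-sequencing library.
#' @param max_tries Redraw attempts before the audit failure is reported.
#'
#' @return A `genome_pair`: list with `experimental` and `calibration` (named
#'   character vectors of chromosome sequences) and `read_length`.
#' @examples
#' pair <- gen_genome_pair(seed = 1, n_chrom = 2, chrom_len = 2000,
#'                         read_length = 50)
#' chrom_lengths(pair)
#' @export
gen_genome_pair <- function(seed, n_chrom = 2L, chrom_len = 20000L,
                            read_length = 190L, max_tries = 20L) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_chrom < 1L) abort("`n_chrom` must be >= 1 per species.")
  if (read_length < 20L) abort("`read_length` must be >= 20.")
  if (chrom_len < read_length) {
    abort(sprintf("`chrom_len` (%d) must be >= `read_length` (%d).",
                  chrom_len, read_length))
  }
  withr::local_seed(as.integer(seed))

  draw_species <- function(prefix) {
    seqs <- vapply(seq_len(n_chrom), function(i) {
      paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- sprintf("%s_chr%d", prefix, seq_len(n_chrom))
    seqs
  }

  k <- min(read_length, 31L)
  for (try in seq_len(max_tries)) {
    experimental <- draw_species("exp")
    calibration  <- draw_species("cal")
    if (.kmer_spectra_disjoint(experimental, calibration, k)) {
      out <- structure(
        list(experimental = experimental, calibration = calibration,
             read_length = as.integer(read_length)),
        class = "genome_pair")
      return(out)
    }
  }
  abort(sprintf(
    "Could not construct genomes with disjoint %d-mer spectra in %d attempts.",
    k, max_tries))
}

# Sufficient audit: a shared read-length subsequence implies a shared k-mer,
# so disjoint k-mer sets (experimental forward vs calibration both strands)
# certify disjoint read-length spectra on all strand combinations.
.kmer_spectra_disjoint <- function(experimental, calibration, k) {
  kmers <- function(seqs) {
    unlist(lapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      unique(stringi::stri_sub(s, 1:(n - k + 1L), length = k))
    }), use.names = FALSE)
  }
  cal_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(calibration)))
  !any(kmers(experimental) %in% c(kmers(calibration), kmers(cal_rc)))
}

#' @export
print.genome_pair <- function(x, ...) {
  cat("<genome_pair>\n")
  cat("  experimental:", length(x$experimental), "chromosome(s),",
      sum(nchar(x$experimental)), "bp total\n")
  cat("  calibration: ", length(x$calibration), "chromosome(s),",
      sum(nchar(x$calibration)), "bp total\n")
  cat("  read_length: ", x$read_length, "bp\n")
  invisible(x)
}

#' Chromosome lengths of a genome pair
#'
#' @param pair A `genome_pair`.
#' @param species `"experimental"`, `"calibration"`, or `"both"`.
#' @return Named integer vector of chromosome lengths.
#' @export
chrom_lengths <- function(pair, species = c("both", "experimental", "calibration")) {
  stopifnot(inherits(pair, "genome_pair"))
  species <- match.arg(species)
  seqs <- switch(species,
                 both          = c(pair$experimental, pair$calibration),
                 experimental  = pair$experimental,
                 calibration   = pair$calibration)
  vapply(seqs, nchar, integer(1))
}

#' Define a relative occupancy landscape over the experimental genome
#'
#' The landscape is the ground-truth protein occupancy used by
#' [sample_experiment()] to place immunoprecipitated (IP) reads: the
#' probability that an IP read starts at a position is proportional to the
#' landscape weight there. A constant `baseline` models dispersed background
#' occupancy; Gaussian `peaks` model focal enrichment such as the
#' pericentromeric cohesin domain.
#'
#' @param chrom_lengths Named integer vector of experimental chromosome
#'   lengths (as from `chrom_lengths(pair, "experimental")`).
#' @param baseline Non-negative baseline weight applied everywhere.
#' @param peaks Optional data frame with columns `chrom`, `center`, `width`
#'   (Gaussian standard deviation, bases) and `height` (weight added at the
#'   peak center).
#'
#' @return An `occupancy_landscape`: list of per-chromosome weight vectors
#'   plus the parameters used.
#' @examples
#' ls <- occupancy_landscape(c(chrA = 1000), baseline = 1,
#'   peaks = data.frame(chrom = "chrA", center = 500, width = 50, height = 10))
#' @export
occupancy_landscape <- function(chrom_lengths, baseline = 1, peaks = NULL) {
  stopifnot(is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  if (baseline < 0) abort("`baseline` must be non-negative.")
  weights <- lapply(chrom_lengths, function(len) rep(baseline, len))
  if (!is.null(peaks)) {
    peaks <- as_tibble(peaks)
    stopifnot(all(c("chrom", "center", "width", "height") %in% names(peaks)))
    if (any(peaks$height < 0)) abort("Peak heights must be non-negative.")
    for (i in seq_len(nrow(peaks))) {
      ch <- peaks$chrom[i]
      if (!ch %in% names(weights)) {
        abort(sprintf("Peak chromosome '%s' not in `chrom_lengths`.", ch))
      }
      x <- seq_along(weights[[ch]])
      weights[[ch]] <- weights[[ch]] +
        peaks$height[i] * exp(-0.5 * ((x - peaks$center[i]) / peaks$width[i])^2)
    }
  }
  if (any(vapply(weights, function(w) all(w <= 0), logical(1)))) {
    abort("Every chromosome needs at least one position with positive weight.")
  }
  structure(list(weights = weights, baseline = baseline, peaks = peaks),
            class = "occupancy_landscape")
}

#' Multiply an occupancy landscape by a constant factor
#'
#' Used to simulate global occupancy changes (e.g. eviction of half the
#' protein from every position between two conditions).
#'
#' @param landscape An `occupancy_landscape`.
#' @param factor Non-negative multiplier.
#' @return A rescaled `occupancy_landscape`.
#' @export
scale_landscape <- function(landscape, factor) {
  stopifnot(inherits(landscape, "occupancy_landscape"))
  if (factor < 0) abort("`factor` must be non-negative.")
  if (factor == 0) abort("`factor` = 0 would give an all-zero landscape.")
  landscape$weights <- lapply(landscape$weights, function(w) w * factor)
  landscape$baseline <- landscape$baseline * factor
  if (!is.null(landscape$peaks)) {
    landscape$peaks$height <- landscape$peaks$height * factor
  }
  landscape
}

#' @export
print.occupancy_landscape <- function(x, ...) {
  cat("<occupancy_landscape>\n")
  cat("  chromosomes:", paste(names(x$weights), collapse = ", "), "\n")
  cat("  baseline:", x$baseline, "\n")
  cat("  peaks:", if (is.null(x$peaks)) 0L else nrow(x$peaks), "\n")
  invisible(x)
}
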