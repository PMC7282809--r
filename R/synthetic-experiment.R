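#' Simulate a spike-in calibrated ChIP-seq experiment
#'
#' Draws paired whole-cell-extract (WCE) and immunoprecipitated (IP) read sets
#' from a two-species genome pair, emulating the mixing of experimental cells
#' with calibration-species cells before chromatin immunoprecipitation:
#'
#' * WCE reads sample both genomes uniformly; each read comes from the
#'   calibration species with probability `spike_fraction_wce` (the default
#'   0.25 corresponds to mixing experimental and calibration cells 3:1).
#' * IP experimental reads start at a position with probability proportional
#'   to the occupancy `landscape` weight there; IP calibration reads are
#'   uniform, with the calibration share of the IP library governed by
#'   `ip_calibration_efficiency`.
#'
#' Writing `f` for the WCE spike fraction, `kappa` for
#' `ip_calibration_efficiency` and `m` for the mean landscape weight over
#' valid read start positions, a read in the IP library is from the
#' calibration genome with probability `q = f*kappa / (f*kappa + (1-f)*m)`.
#' The analytic expectation of the occupancy ratio
#' `(Wc * IPx) / (Wx * IPc)` under this model is `m / kappa`; it is computed
#' from the parameters and recorded as `truth$true_or` *before* any read is
#' drawn. With a uniform landscape of weight `w` and `kappa = w` the IP and
#' WCE species shares coincide and the true occupancy ratio is 1.
#'
#' Reads are taken from both strands with equal probability and carry their
#' true origin (species, chromosome, start, strand), so downstream assignment
#' can be audited read by read. There is no sequencing-error model.
#'
#' @param pair A `genome_pair` from [gen_genome_pair()].
#' @param landscape An `occupancy_landscape` over the experimental
#'   chromosomes of `pair`.
#' @param n_ip,n_wce Number of IP / WCE reads to draw (> 0).
#' @param spike_fraction_wce Probability in (0, 1) that a WCE read is from
#'   the calibration species.
#' @param ip_calibration_efficiency Positive pull-down propensity of the
#'   calibration species relative to one unit of landscape weight.
#' @param seed Integer seed; the draw is byte-identical under a fixed seed.
#'
#' @return A `synthetic_experiment`: list with `reads_ip` and `reads_wce`
#'   (tibbles with columns `id`, `sample`, `sequence`, `origin`, `chrom`,
#'   `start`, `strand`) and `truth` (spike fraction, efficiency, landscape,
#'   mean landscape weight, IP calibration share, `true_or`, seed).
#' @examples
#' pair <- gen_genome_pair(seed = 1, n_chrom = 1, chrom_len = 2000,
#'                         read_length = 50)
#' ls <- occupancy_landscape(chrom_lengths(pair, "experimental"))
#' ex <- sample_experiment(pair, ls, n_ip = 200, n_wce = 200, seed = 2)
#' ex$truth$true_or
#' @export
sample_experiment <- function(pair, landscape, n_ip, n_wce,
                              spike_fraction_wce = 0.25,
                              ip_calibration_efficiency = 1,
                              seed = 1L) {
  stopifnot(inherits(pair, "genome_pair"),
            inherits(landscape, "occupancy_landscape"))
  if (n_ip <= 0L || n_wce <= 0L) abort("`n_ip` and `n_wce` must be > 0.")
  if (spike_fraction_wce <= 0 || spike_fraction_wce >= 1) {
    abort("`spike_fraction_wce` must lie strictly between 0 and 1.")
  }
  if (ip_calibration_efficiency <= 0) {
    abort("`ip_calibration_efficiency` must be > 0.")
  }
  exp_chroms <- names(pair$experimental)
  if (!all(exp_chroms %in% names(landscape$weights))) {
    abort("`landscape` must cover every experimental chromosome.")
  }
  rl <- pair$read_length

  # landscape weights restricted to valid read start positions
  start_w <- lapply(exp_chroms, function(ch) {
    w <- landscape$weights[[ch]]
    n_start <- length(w) - rl + 1L
    if (n_start < 1L) abort(sprintf("Chromosome '%s' shorter than one read.", ch))
    w[seq_len(n_start)]
  })
  names(start_w) <- exp_chroms
  total_w <- sum(unlist(start_w, use.names = FALSE))
  if (total_w <= 0) abort("Landscape is all-zero over valid start positions.")
  n_starts <- sum(lengths(start_w))
  mean_w <- total_w / n_starts

  f <- spike_fraction_wce
  kappa <- ip_calibration_efficiency
  q_ip_cal <- f * kappa / (f * kappa + (1 - f) * mean_w)
  true_or <- mean_w / kappa

  withr::local_seed(as.integer(seed))

  wce <- .draw_reads(pair, start_w, n = n_wce, p_cal = f,
                     landscape_weighted = FALSE, sample = "WCE")
  ip  <- .draw_reads(pair, start_w, n = n_ip, p_cal = q_ip_cal,
                     landscape_weighted = TRUE, sample = "IP")

  structure(list(
    reads_ip = ip, reads_wce = wce,
    truth = list(spike_fraction_wce = f,
                 ip_calibration_efficiency = kappa,
                 landscape = landscape,
                 mean_landscape_weight = mean_w,
                 ip_calibration_share = q_ip_cal,
                 true_or = true_or,
                 seed = as.integer(seed))),
    class = "synthetic_experiment")
}

# Draw one read set. Calibration reads and (optionally) experimental reads are
# uniform over valid starts; landscape_weighted experimental reads use the
# per-start landscape weights.
.draw_reads <- function(pair, start_w, n, p_cal, landscape_weighted, sample) {
  rl <- pair$read_length
  origin <- ifelse(rbinom(n, 1L, p_cal) == 1L, "calibration", "experimental")
  chrom <- character(n)
  start <- integer(n)

  # calibration: uniform over (chrom, start)
  idx_c <- which(origin == "calibration")
  if (length(idx_c)) {
    n_start_cal <- nchar(pair$calibration) - rl + 1L
    flat <- sample.int(sum(n_start_cal), length(idx_c), replace = TRUE)
    pos <- .unflatten(flat, n_start_cal)
    chrom[idx_c] <- pos$chrom
    start[idx_c] <- pos$start
  }

  idx_x <- which(origin == "experimental")
  if (length(idx_x)) {
    n_start_exp <- lengths(start_w)
    if (landscape_weighted) {
      w <- unlist(start_w, use.names = FALSE)
      flat <- sample.int(length(w), length(idx_x), replace = TRUE, prob = w)
    } else {
      flat <- sample.int(sum(n_start_exp), length(idx_x), replace = TRUE)
    }
    pos <- .unflatten(flat, n_start_exp)
    chrom[idx_x] <- pos$chrom
    start[idx_x] <- pos$start
  }

  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- character(n)
  genome <- c(pair$experimental, pair$calibration)
  seqs <- stringi::stri_sub(genome[chrom], from = start, length = rl)
  minus <- strand == "-"
  if (any(minus)) {
    seqs[minus] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[minus])))
  }
  tibble(id = sprintf("%s_%06d", tolower(sample), seq_len(n)),
         sample = sample, sequence = seqs, origin = origin,
         chrom = chrom, start = start, strand = strand)
}

# Map flat indices over concatenated per-chromosome start ranges back to
# (chromosome, start) pairs.
.unflatten <- function(flat, n_start) {
  offsets <- cumsum(c(0L, n_start[-length(n_start)]))
  bin <- findInterval(flat, offsets + 1L)
  list(chrom = names(n_start)[bin], start = flat - offsets[bin])
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat("<synthetic_experiment>\n")
  cat("  IP reads: ", nrow(x$reads_ip), " WCE reads: ", nrow(x$reads_wce), "\n")
  cat("  spike fraction (WCE):", x$truth$spike_fraction_wce, "\n")
  cat("  true occupancy ratio:", signif(x$truth$true_or, 6), "\n")
  invisible(x)
}
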