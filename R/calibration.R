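#' Occupancy ratio from partition counts
#'
#' The occupancy ratio (OR) is the scalar that converts raw IP read depth on
#' the experimental genome into calibrated occupancy, computed from the four
#' partition counts as
#'
#' \deqn{OR = \frac{W_c \cdot IP_x}{W_x \cdot IP_c}}
#'
#' where `Wc`/`Wx` are whole-cell-extract reads aligned to the calibration /
#' experimental genome and `IPc`/`IPx` the same for the IP sample. In this
#' orientation a higher experimental IP yield relative to the spike-in raises
#' occupancy, and swapping the IP and WCE samples inverts the value. The
#' complementary orientation is available via `invert = TRUE`.
#'
#' @param counts A `partition_result`, or a list/vector with named elements
#'   `Wc`, `Wx`, `IPc`, `IPx` (all > 0).
#' @param invert If `TRUE`, return the reciprocal orientation
#'   `(Wx * IPc) / (Wc * IPx)`.
#' @return An `occupancy_ratio`: list with `value` and the four `components`.
#' @examples
#' occupancy_ratio(list(Wc = 2000, Wx = 8000, IPc = 1000, IPx = 9000))
#' @export
occupancy_ratio <- function(counts, invert = FALSE) {
  comp <- c(Wc = as.numeric(counts[["Wc"]]), Wx = as.numeric(counts[["Wx"]]),
            IPc = as.numeric(counts[["IPc"]]),
            IPx = as.numeric(counts[["IPx"]]))
  zero <- names(comp)[comp <= 0]
  if (length(zero)) {
    abort(paste0("Occupancy ratio undefined: no reads in class ",
                 paste(zero, collapse = ", "),
                 ". All four partition counts must be positive."))
  }
  value <- (comp[["Wc"]] * comp[["IPx"]]) / (comp[["Wx"]] * comp[["IPc"]])
  if (invert) value <- 1 / value
  structure(list(value = value, components = as.list(comp), invert = invert),
            class = "occupancy_ratio")
}

#' @export
print.occupancy_ratio <- function(x, ...) {
  cat("<occupancy_ratio> value =", signif(x$value, 6),
      if (x$invert) "(inverted orientation)" else "", "\n")
  cat(sprintf("  Wc = %.0f, Wx = %.0f, IPc = %.0f, IPx = %.0f\n",
              x$components$Wc, x$components$Wx,
              x$components$IPc, x$components$IPx))
  invisible(x)
}

#' @rdname occupancy_ratio
#' @param x An `occupancy_ratio`.
#' @param ... Unused.
#' @method tidy occupancy_ratio
#' @export
tidy.occupancy_ratio <- function(x, ...) {
  tibble(value = x$value, Wc = x$components$Wc, Wx = x$components$Wx,
         IPc = x$components$IPc, IPx = x$components$IPx)
}

.or_value <- function(or_) {
  if (inherits(or_, "occupancy_ratio")) or_$value
  else if (is.numeric(or_) && length(or_) == 1L && or_ > 0) as.numeric(or_)
  else abort("`or_` must be an `occupancy_ratio` or a positive number.")
}

#' Scale a depth track to calibrated occupancy
#'
#' Converts raw per-base read depth into calibrated occupancy by multiplying
#' every value by the occupancy ratio and normalising to 1 million reads:
#' `value = depth * OR * 1e6 / total_reads`. `total_reads` should be the
#' experimental-genome-aligned read count of the IP library the track was
#' built from (`IPx`), so that tracks from libraries of different depths are
#' on a common scale.
#'
#' @param depth A depth track as returned by [pileup()] or [fill_gaps()]:
#'   a data frame with columns `chrom`, `pos`, `depth`, dense over each
#'   chromosome.
#' @param or_ An `occupancy_ratio` or a positive scalar.
#' @param total_reads Positive read count used for the per-million
#'   normalisation.
#' @return A `scaled_track` tibble with columns `chrom`, `pos`, `value` and
#'   attributes `or_value` and `total_reads`.
#' @examples
#' dt <- fill_gaps(tibble::tibble(pos = 3, depth = 7), chrom_length = 5)
#' scale_track(dt, or_ = 2.25, total_reads = 5e5)
#' @export
scale_track <- function(depth, or_, total_reads) {
  depth <- as_tibble(depth)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)))
  if (total_reads <= 0) abort("`total_reads` must be > 0.")
  orv <- .or_value(or_)
  lens <- attr(depth, "chrom_lengths")
  if (!is.null(lens)) {
    got <- table(depth$chrom)
    bad <- names(got)[as.integer(got) != lens[names(got)]]
    if (length(bad)) {
      abort(paste0("Track length does not match declared chromosome length for: ",
                   paste(bad, collapse = ", ")))
    }
  }
  out <- tibble(chrom = depth$chrom, pos = depth$pos,
                value = depth$depth * orv * 1e6 / total_reads)
  attr(out, "chrom_lengths") <- lens
  attr(out, "or_value") <- orv
  attr(out, "total_reads") <- total_reads
  class(out) <- c("scaled_track", class(out))
  out
}
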