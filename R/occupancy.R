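#' Per-base read depth from placed reads
#'
#' Builds a dense per-base depth track: the depth at position `p` of a
#' chromosome is the number of reads whose interval `[start, start + len - 1]`
#' contains `p` (1-based, inclusive coordinates, the mpileup convention).
#' Positions never covered are reported with depth 0, so every chromosome in
#' `chrom_lengths` yields a vector of exactly its length.
#'
#' @param reads Data frame with columns `chrom`, `start` (1-based) and a read
#'   length given either as a `width` column or via `read_length`.
#' @param chrom_lengths Named integer vector of chromosome lengths; every
#'   read's chromosome must appear here and its interval must lie within
#'   `[1, length]`.
#' @param read_length Read length applied to all reads when `reads` has no
#'   `width` column.
#' @return A `depth_track` tibble with columns `chrom`, `pos`, `depth`,
#'   dense over every chromosome, with attribute `chrom_lengths`.
#' @examples
#' pileup(tibble::tibble(chrom = "c1", start = 11), c(c1 = 100),
#'        read_length = 50)
#' @export
pileup <- function(reads, chrom_lengths, read_length = NULL) {
  reads <- as_tibble(reads)
  stopifnot(all(c("chrom", "start") %in% names(reads)),
            is.numeric(chrom_lengths), !is.null(names(chrom_lengths)))
  width <- if ("width" %in% names(reads)) reads$width
           else if (!is.null(read_length)) rep(as.integer(read_length), nrow(reads))
           else abort("Provide a `width` column or `read_length`.")
  missing_chr <- setdiff(unique(reads$chrom), names(chrom_lengths))
  if (length(missing_chr)) {
    abort(paste0("Reads on chromosome(s) absent from `chrom_lengths`: ",
                 paste(missing_chr, collapse = ", ")))
  }
  end <- reads$start + width - 1L
  bad <- which(reads$start < 1L | end > chrom_lengths[reads$chrom])
  if (length(bad)) {
    id <- if ("id" %in% names(reads)) reads$id[bad[1]] else paste("row", bad[1])
    abort(paste0("Read interval outside [1, chromosome length]: ", id))
  }

  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    sel <- reads$chrom == ch
    depth <- if (any(sel)) {
      cov <- IRanges::coverage(IRanges::IRanges(start = reads$start[sel],
                                                width = width[sel]),
                               width = len)
      as.integer(cov)
    } else {
      integer(len)
    }
    tibble(chrom = ch, pos = seq_len(len), depth = depth)
  })
  out <- bind_rows(out)
  attr(out, "chrom_lengths") <-
    stats::setNames(as.integer(chrom_lengths), names(chrom_lengths))
  class(out) <- c("depth_track", class(out))
  out
}

#' Fill coverage gaps with explicit zeros
#'
#' Converts a sparse pileup (only covered positions listed) into a dense
#' per-base track in which every unlisted position of the chromosome carries
#' a read depth of 0. Total depth is conserved and the output always has
#' exactly `chrom_length` rows.
#'
#' @param sparse_depth Data frame with columns `pos` (1-based, within
#'   `[1, chrom_length]`, no duplicates) and `depth`; may have zero rows.
#' @param chrom_length Chromosome length (>= 1).
#' @param chrom Chromosome name for the output (default `"chr"`).
#' @return A `depth_track` tibble with columns `chrom`, `pos`, `depth`.
#' @examples
#' fill_gaps(tibble::tibble(pos = 3, depth = 7), chrom_length = 5)
#' @export
fill_gaps <- function(sparse_depth, chrom_length, chrom = "chr") {
  sparse_depth <- as_tibble(sparse_depth)
  if (nrow(sparse_depth) > 0L) {
    stopifnot(all(c("pos", "depth") %in% names(sparse_depth)))
    if (any(sparse_depth$pos < 1L | sparse_depth$pos > chrom_length)) {
      abort("Position outside [1, chrom_length].")
    }
    if (anyDuplicated(sparse_depth$pos)) {
      abort("Duplicate positions in sparse pileup.")
    }
  }
  depth <- numeric(chrom_length)
  if (nrow(sparse_depth) > 0L) depth[sparse_depth$pos] <- sparse_depth$depth
  out <- tibble(chrom = chrom, pos = seq_len(as.integer(chrom_length)),
                depth = depth)
  attr(out, "chrom_lengths") <- stats::setNames(as.integer(chrom_length), chrom)
  class(out) <- c("depth_track", class(out))
  out
}

#' Anchor-centred meta-profile of calibrated occupancy
#'
#' Averages per-base read depth as a function of signed offset from a set of
#' anchor positions (here, centromeric CDEIII elements), one anchor per
#' chromosome or several, and calibrates the averaged profile by multiplying
#' by the occupancy ratio and normalising to 1 million reads.
#'
#' For each offset `o` in `[-window, +window]`, the profile is the mean of
#' `depth(anchor + o)` over all anchors for which `anchor + o` lies inside
#' the chromosome; anchors whose window is truncated by a chromosome end
#' simply do not contribute at the offsets they cannot reach, and the
#' divisor is the number of contributing anchors (reported per offset in
#' `n_contributing` so the truncation is auditable).
#'
#' @param track A dense `depth_track` (from [pileup()] or [fill_gaps()])
#'   covering every anchor's chromosome.
#' @param anchors Data frame with columns `chrom` and `anchor` (1-based
#'   anchor position, e.g. the CDEIII midpoint; see [read_anchors_bed()]).
#' @param window Half-width of the profile in bases (>= 1); offsets run from
#'   `-window` to `+window`. The default 60000 covers the pericentromeric
#'   cohesin domain.
#' @param or_ An `occupancy_ratio` or positive scalar used for calibration
#'   (default 1, i.e. uncalibrated).
#' @param total_reads Read count for the per-million normalisation (default
#'   `1e6`, i.e. no depth normalisation).
#' @return A `meta_profile` tibble with columns `offset`, `mean_depth`
#'   (calibrated), `n_contributing`, and attributes `or_value`,
#'   `total_reads`, `window`.
#' @export
meta_profile <- function(track, anchors, window = 60000L, or_ = 1,
                         total_reads = 1e6) {
  track <- as_tibble(track)
  anchors <- as_tibble(anchors)
  stopifnot(all(c("chrom", "pos", "depth") %in% names(track)),
            all(c("chrom", "anchor") %in% names(anchors)))
  if (window < 1L) abort("`window` must be >= 1.")
  if (nrow(anchors) == 0L) abort("No anchors supplied.")
  orv <- .or_value(or_)
  if (total_reads <= 0) abort("`total_reads` must be > 0.")

  depth_by_chrom <- split(track$depth, track$chrom)
  missing_chr <- setdiff(unique(anchors$chrom), names(depth_by_chrom))
  if (length(missing_chr)) {
    abort(paste0("Anchor chromosome(s) without a depth track: ",
                 paste(missing_chr, collapse = ", ")))
  }

  offsets <- seq.int(-window, window)
  total <- numeric(length(offsets))
  n_contrib <- integer(length(offsets))
  for (i in seq_len(nrow(anchors))) {
    v <- depth_by_chrom[[anchors$chrom[i]]]
    a <- anchors$anchor[i]
    if (a < 1L || a > length(v)) {
      abort(sprintf("Anchor at %d outside chromosome '%s' (length %d).",
                    a, anchors$chrom[i], length(v)))
    }
    p <- a + offsets
    inside <- p >= 1L & p <= length(v)
    total[inside] <- total[inside] + v[p[inside]]
    n_contrib <- n_contrib + inside
  }
  mean_depth <- ifelse(n_contrib > 0L, total / n_contrib, NA_real_)
  out <- tibble(offset = offsets,
                mean_depth = mean_depth * orv * 1e6 / total_reads,
                n_contributing = n_contrib)
  attr(out, "or_value") <- orv
  attr(out, "total_reads") <- total_reads
  attr(out, "window") <- as.integer(window)
  class(out) <- c("meta_profile", class(out))
  out
}

#' Median occupancy across an entire chromosome
#'
#' The median of the per-base values over all positions `1..length` of one
#' chromosome, zeros included; the track must be dense. For an even number
#' of positions the median is the mean of the two central values.
#'
#' @param track A dense `scaled_track` or `depth_track`.
#' @param chromosome Chromosome name.
#' @return The median as a single number.
#' @export
chromosome_median <- function(track, chromosome) {
  track <- as_tibble(track)
  val_col <- if ("value" %in% names(track)) "value" else "depth"
  sel <- track$chrom == chromosome
  if (!any(sel)) abort(paste0("Chromosome '", chromosome, "' not in track."))
  median(track[[val_col]][sel])
}

#' Chromosome-median occupancy change between two conditions
#'
#' Compares calibrated occupancy between two conditions (e.g. before and
#' after DNA replication) chromosome by chromosome: for each chromosome the
#' ratio of whole-chromosome median occupancy `after / before`, plus a
#' genome-wide summary defined as the median of the per-chromosome ratios.
#' A chromosome whose `before` median is zero has an undefined ratio and is
#' reported as `NA` (excluded from the genome-wide median) with a warning.
#'
#' @param before,after Dense `scaled_track`s covering the same chromosomes.
#' @return An `occupancy_change` tibble with columns `chrom`,
#'   `median_before`, `median_after`, `ratio`; the genome-wide median ratio
#'   is in attribute `genome_wide` and via [glance()].
#' @export
occupancy_change <- function(before, after) {
  b <- as_tibble(before)
  a <- as_tibble(after)
  chroms <- unique(b$chrom)
  if (!setequal(chroms, unique(a$chrom))) {
    abort("`before` and `after` must cover the same chromosomes.")
  }
  out <- purrr::map_dfr(chroms, function(ch) {
    mb <- chromosome_median(before, ch)
    ma <- chromosome_median(after, ch)
    tibble(chrom = ch, median_before = mb, median_after = ma,
           ratio = if (mb > 0) ma / mb else NA_real_)
  })
  if (anyNA(out$ratio)) {
    warn(paste0("Undefined occupancy ratio (zero `before` median) on: ",
                paste(out$chrom[is.na(out$ratio)], collapse = ", ")))
  }
  attr(out, "genome_wide") <- median(out$ratio, na.rm = TRUE)
  class(out) <- c("occupancy_change", class(out))
  out
}

#' @rdname occupancy_change
#' @param x An `occupancy_change`.
#' @param ... Unused.
#' @method glance occupancy_change
#' @export
glance.occupancy_change <- function(x, ...) {
  tibble(genome_wide_ratio = attr(x, "genome_wide"),
         n_chromosomes = nrow(x),
         n_undefined = sum(is.na(x$ratio)))
}
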