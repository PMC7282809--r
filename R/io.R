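#' Write genome sequences as FASTA
#'
#' @param seqs Named character vector of sequences (e.g. `pair$experimental`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write reads as FASTQ (Phred 33, constant quality)
#'
#' @param reads Data frame with `id` and `sequence` columns.
#' @param path Output FASTQ path.
#' @param quality_char Constant per-base quality character (default `"I"`,
#'   Phred 40).
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  reads <- as_tibble(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' @param path FASTQ path.
#' @param sample Value for the `sample` column (`"IP"` or `"WCE"`).
#' @return Tibble with columns `id`, `sample`, `sequence`.
#' @export
read_reads_fastq <- function(path, sample = NA_character_) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(id = sub("\\s.*$", "", names(x)), sample = sample,
         sequence = unname(as.character(x)))
}

#' Read CDEIII/centromere anchors from a BED file
#'
#' BED intervals are 0-based half-open; the anchor is taken as the midpoint
#' of each element in 1-based coordinates:
#' `floor((start0 + end0 + 1) / 2)`. For a 1 bp element `[s, s+1)` this is
#' the 1-based position `s + 1` of that base.
#'
#' @param path BED path (at least 3 columns).
#' @return Tibble with columns `chrom`, `anchor` (1-based midpoint),
#'   `start`, `end` (the original 0-based half-open interval) and `name`
#'   when present.
#' @export
read_anchors_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  start0 <- GenomicRanges::start(gr) - 1L  # back to 0-based
  end0 <- GenomicRanges::end(gr)           # half-open end
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                anchor = as.integer(floor((start0 + end0 + 1) / 2)),
                start = start0, end = end0)
  nm <- gr$name
  if (!is.null(nm)) out$name <- nm
  out
}

#' Write CDEIII/centromere anchors as BED
#'
#' Each anchor position `p` (1-based) is written as the 0-based half-open
#' 1 bp interval `[p - 1, p)`, the exact inverse of [read_anchors_bed()] for
#' point anchors.
#'
#' @param anchors Tibble with `chrom` and `anchor` columns.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_anchors_bed <- function(anchors, path) {
  anchors <- as_tibble(anchors)
  gr <- GenomicRanges::GRanges(
    seqnames = anchors$chrom,
    ranges = IRanges::IRanges(start = anchors$anchor, width = 1L),
    name = if ("name" %in% names(anchors)) anchors$name
           else sprintf("anchor_%d", seq_len(nrow(anchors))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a track as bedGraph
#'
#' Runs of equal value are merged into 0-based half-open intervals.
#'
#' @param track A `depth_track` or `scaled_track` (columns `chrom`, `pos`
#'   and `depth` or `value`).
#' @param path Output bedGraph path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as_tibble(track)
  val_col <- if ("value" %in% names(df)) "value" else "depth"
  merged <- lapply(unique(df$chrom), function(ch) {
    sel <- df$chrom == ch
    v <- as.numeric(df[[val_col]][sel])[order(df$pos[sel])]
    r <- rle(v)
    ends <- df$pos[sel][1] - 1L + cumsum(r$lengths)
    GenomicRanges::GRanges(
      seqnames = ch,
      ranges = IRanges::IRanges(end = ends, width = r$lengths),
      score = r$values)
  })
  gr <- do.call(c, merged)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a track as fixed-step wiggle
#'
#' @inheritParams write_bedgraph
#' @export
write_wig <- function(track, path) {
  df <- as_tibble(track)
  val_col <- if ("value" %in% names(df)) "value" else "depth"
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in unique(df$chrom)) {
    sel <- df$chrom == ch
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1", ch,
                       min(df$pos[sel])), con)
    writeLines(format(df[[val_col]][sel], trim = TRUE, scientific = FALSE),
               con)
  }
  invisible(path)
}

#' Write placed reads as a minimal SAM text file
#'
#' Fixture writer for the SAM ingestion path: emits a header (`@HD`, `@SQ`
#' for every chromosome of both genomes) and one primary single-end record
#' per read, using the read's true placement. Minus-strand reads get flag
#' 16; reads with `chrom = NA` are written as unmapped (flag 4).
#'
#' @param reads Tibble with `id`, `sequence`, `chrom`, `start`, `strand`.
#' @param pair A `genome_pair` supplying the `@SQ` header lines.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, pair, path) {
  reads <- as_tibble(reads)
  lens <- chrom_lengths(pair)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), lens))
  unmapped <- is.na(reads$chrom)
  flag <- ifelse(unmapped, 4L, ifelse(reads$strand == "-", 16L, 0L))
  seq_out <- reads$sequence
  rc <- !unmapped & reads$strand == "-"
  if (any(rc)) {
    # SAM stores the sequence as aligned to the forward strand
    seq_out[rc] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq_out[rc])))
  }
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*",
                  reads$id, flag,
                  ifelse(unmapped, "*", reads$chrom),
                  ifelse(unmapped, 0L, reads$start),
                  ifelse(unmapped, 0L, 60L),
                  ifelse(unmapped, "*", sprintf("%dM", nchar(seq_out))),
                  seq_out)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write a competition series / cytology table as TSV
#'
#' Plain tab-delimited round-trip for the tabular assay inputs.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @return The tibble (readers) or `path` invisibly (writers).
#' @name assay_tables
NULL

#' @rdname assay_tables
#' @export
write_competition_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path)
  invisible(path)
}

#' @rdname assay_tables
#' @export
read_competition_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write the ground-truth manifest of a synthetic experiment
#'
#' Records the simulation parameters and the analytic true occupancy ratio
#' (everything except the landscape weight vectors) as JSON, so a fixture
#' directory is self-describing.
#'
#' @param experiment A `synthetic_experiment`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_manifest <- function(experiment, path) {
  stopifnot(inherits(experiment, "synthetic_experiment"))
  tr <- experiment$truth
  jsonlite::write_json(
    list(spike_fraction_wce = tr$spike_fraction_wce,
         ip_calibration_efficiency = tr$ip_calibration_efficiency,
         mean_landscape_weight = tr$mean_landscape_weight,
         ip_calibration_share = tr$ip_calibration_share,
         true_or = tr$true_or,
         seed = tr$seed,
         n_ip = nrow(experiment$reads_ip),
         n_wce = nrow(experiment$reads_wce),
         origin_counts = list(
           ip = as.list(table(experiment$reads_ip$origin)),
           wce = as.list(table(experiment$reads_wce$origin)))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a complete fixture directory for a synthetic experiment
#'
#' Emits genomes (FASTA), reads (FASTQ), true-placement alignments (SAM)
#' and the truth manifest (JSON) into `dir`, the on-disk form of everything
#' [sample_experiment()] generated.
#'
#' @param experiment A `synthetic_experiment`.
#' @param pair The `genome_pair` it was drawn from.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(experiment, pair, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(pair$experimental, file.path(dir, "experimental.fa"))
  write_genome_fasta(pair$calibration, file.path(dir, "calibration.fa"))
  write_reads_fastq(experiment$reads_ip, file.path(dir, "ip.fastq"))
  write_reads_fastq(experiment$reads_wce, file.path(dir, "wce.fastq"))
  write_sam(experiment$reads_ip, pair, file.path(dir, "ip.sam"))
  write_sam(experiment$reads_wce, pair, file.path(dir, "wce.sam"))
  write_truth_manifest(experiment, file.path(dir, "truth.json"))
  invisible(dir)
}
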