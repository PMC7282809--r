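#' Positional trimming and length filtering of reads
#'
#' Applies the fixed positional trimming rule used before alignment: the
#' first `head_trim` bases and any bases after position `max_keep` are
#' removed, and reads whose trimmed length falls below `min_len` are dropped.
#' With the defaults, a 250-base read becomes the 190 bases originally at
#' positions 11–200, and any read of 59 or fewer bases is discarded
#' (59 - 10 < 50). Read order is preserved.
#'
#' @param reads Data frame with at least a `sequence` column (additional
#'   columns such as `id` and `sample` are carried through).
#' @param head_trim Bases removed from the 5' end (>= 0).
#' @param max_keep Last retained base position (1-based, > `head_trim`).
#' @param min_len Minimum trimmed length to keep a read (>= 1).
#' @return A tibble of surviving reads with trimmed `sequence`.
#' @examples
#' trim_reads(tibble::tibble(sequence = strrep("ACGT", 70)))
#' @export
trim_reads <- function(reads, head_trim = 10L, max_keep = 200L, min_len = 50L) {
  reads <- as_tibble(reads)
  stopifnot("sequence" %in% names(reads))
  if (head_trim < 0L) abort("`head_trim` must be >= 0.")
  if (max_keep <= head_trim) abort("`max_keep` must exceed `head_trim`.")
  if (min_len < 1L) abort("`min_len` must be >= 1.")
  trimmed <- stringi::stri_sub(reads$sequence, from = head_trim + 1L,
                               to = max_keep)
  trimmed[is.na(trimmed)] <- ""
  keep <- nchar(trimmed) >= min_len
  reads$sequence <- trimmed
  reads[keep, , drop = FALSE]
}

#' Assign one read to the calibration genome, the experimental genome, or neither
#'
#' Reproduces the sequential two-genome alignment strategy used for spike-in
#' calibration: the read is first sought in the calibration genome and, only
#' if absent there, in the experimental genome. Matching is exact full-length
#' matching on either strand; a read found in both genomes is therefore
#' assigned to the calibration genome, and reads containing `N` never match.
#'
#' @param sequence A single read sequence (character).
#' @param pair A `genome_pair`.
#' @return One of `"calibration"`, `"experimental"`, `"unaligned"`.
#' @examples
#' pair <- gen_genome_pair(seed = 1, n_chrom = 1, chrom_len = 500,
#'                         read_length = 30)
#' assign_read(substr(pair$calibration[[1]], 11, 40), pair)
#' @export
assign_read <- function(sequence, pair) {
  stopifnot(is.character(sequence), length(sequence) == 1L,
            inherits(pair, "genome_pair"))
  if (nchar(sequence) == 0L) abort("Read sequence is empty.")
  if (grepl("N", sequence, fixed = TRUE)) return("unaligned")
  if (.matches_genome(sequence, pair$calibration)) return("calibration")
  if (.matches_genome(sequence, pair$experimental)) return("experimental")
  "unaligned"
}

.matches_genome <- function(sequence, genome_chr) {
  subject <- Biostrings::DNAStringSet(genome_chr)
  subject <- c(subject, Biostrings::reverseComplement(subject))
  hits <- Biostrings::vcountPattern(sequence, subject)
  any(hits > 0)
}

# Vectorised exact matcher: logical hit per read against one genome (both
# strands). Uses an Aho-Corasick dictionary scan for large equal-width
# batches and a per-read scan otherwise.
.match_reads <- function(sequences, genome_chr) {
  n <- length(sequences)
  hit <- logical(n)
  if (n == 0L) return(hit)
  has_n <- stringi::stri_detect_fixed(sequences, "N")
  ok <- which(!has_n & nchar(sequences) > 0L)
  if (!length(ok)) return(hit)

  subject <- Biostrings::DNAStringSet(genome_chr)
  subject <- c(subject, Biostrings::reverseComplement(subject))

  widths <- nchar(sequences[ok])
  for (w in unique(widths)) {
    idx <- ok[widths == w]
    if (length(idx) >= 200L && w >= 12L) {
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sequences[idx]),
                              tb.start = 1L, tb.end = min(w, 30L))
      m <- Biostrings::vcountPDict(pd, subject)
      hit[idx] <- rowSums(m) > 0L
    } else {
      hit[idx] <- vapply(sequences[idx], .matches_genome, logical(1),
                         genome_chr = genome_chr)
    }
  }
  hit
}

#' Partition IP and WCE read sets between the two genomes
#'
#' Assigns every read of the immunoprecipitated (IP) and whole-cell-extract
#' (WCE) samples with the sequential rule of [assign_read()] (calibration
#' genome first) and tallies the four counts that feed the occupancy ratio:
#' `Wc`/`Wx`, the WCE reads aligned to the calibration / experimental genome,
#' and `IPc`/`IPx`, the same for the IP sample. Assignment classes partition
#' each read set exactly, so `Wc + Wx + unaligned(WCE)` equals the WCE total
#' (and likewise for IP).
#'
#' @param ip_reads,wce_reads Data frames of trimmed reads with a `sequence`
#'   column (and optionally `id`).
#' @param pair A `genome_pair`.
#' @return A `partition_result`: list with `assignments` (tibble: `id`,
#'   `sample`, `assignment`) and counts `Wc`, `Wx`, `IPc`, `IPx`,
#'   `unaligned_wce`, `unaligned_ip`.
#' @examples
#' pair <- gen_genome_pair(seed = 1, n_chrom = 1, chrom_len = 500,
#'                         read_length = 30)
#' ls <- occupancy_landscape(chrom_lengths(pair, "experimental"))
#' ex <- sample_experiment(pair, ls, n_ip = 50, n_wce = 50, seed = 2)
#' partition_reads(ex$reads_ip, ex$reads_wce, pair)
#' @export
partition_reads <- function(ip_reads, wce_reads, pair) {
  stopifnot(inherits(pair, "genome_pair"))
  ip_reads <- as_tibble(ip_reads)
  wce_reads <- as_tibble(wce_reads)
  if (nrow(ip_reads) == 0L || nrow(wce_reads) == 0L) {
    abort("Both the IP and the WCE read set must be non-empty.")
  }
  assign_set <- function(reads, sample) {
    cal <- .match_reads(reads$sequence, pair$calibration)
    exp_hit <- logical(nrow(reads))
    exp_hit[!cal] <- .match_reads(reads$sequence[!cal], pair$experimental)
    assignment <- rep("unaligned", nrow(reads))
    assignment[cal] <- "calibration"
    assignment[!cal & exp_hit] <- "experimental"
    ids <- if ("id" %in% names(reads)) reads$id
           else sprintf("%s_%06d", tolower(sample), seq_len(nrow(reads)))
    tibble(id = ids, sample = sample, assignment = assignment)
  }
  a_ip <- assign_set(ip_reads, "IP")
  a_wce <- assign_set(wce_reads, "WCE")
  new_partition_result(
    assignments = bind_rows(a_wce, a_ip),
    Wc = sum(a_wce$assignment == "calibration"),
    Wx = sum(a_wce$assignment == "experimental"),
    IPc = sum(a_ip$assignment == "calibration"),
    IPx = sum(a_ip$assignment == "experimental"),
    unaligned_wce = sum(a_wce$assignment == "unaligned"),
    unaligned_ip = sum(a_ip$assignment == "unaligned"))
}

new_partition_result <- function(assignments, Wc, Wx, IPc, IPx,
                                 unaligned_wce = 0L, unaligned_ip = 0L,
                                 skipped = 0L) {
  structure(list(assignments = assignments,
                 Wc = as.integer(Wc), Wx = as.integer(Wx),
                 IPc = as.integer(IPc), IPx = as.integer(IPx),
                 unaligned_wce = as.integer(unaligned_wce),
                 unaligned_ip = as.integer(unaligned_ip),
                 skipped = as.integer(skipped)),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("<partition_result>\n")
  cat(sprintf("  WCE: Wc = %d, Wx = %d, unaligned = %d\n",
              x$Wc, x$Wx, x$unaligned_wce))
  cat(sprintf("  IP:  IPc = %d, IPx = %d, unaligned = %d\n",
              x$IPc, x$IPx, x$unaligned_ip))
  if (x$skipped > 0L) {
    cat(sprintf("  (%d secondary/supplementary records ignored)\n", x$skipped))
  }
  invisible(x)
}

#' @rdname partition_reads
#' @param x A `partition_result`.
#' @param ... Unused.
#' @method tidy partition_result
#' @export
tidy.partition_result <- function(x, ...) {
  tibble(sample = c("WCE", "WCE", "WCE", "IP", "IP", "IP"),
         assignment = rep(c("calibration", "experimental", "unaligned"), 2),
         n = c(x$Wc, x$Wx, x$unaligned_wce, x$IPc, x$IPx, x$unaligned_ip))
}

#' Tally partition counts from externally aligned reads (SAM text)
#'
#' Ingestion path for data aligned outside the package: reads one SAM file
#' per sample and counts primary alignments by reference name. A record
#' mapped to a reference in `calibration_names` counts toward `Wc`/`IPc`,
#' one mapped to any other known reference toward `Wx`/`IPx`, and unmapped
#' records toward the unaligned class. Secondary (0x100) and supplementary
#' (0x800) records are ignored and their number reported.
#'
#' @param sam_ip,sam_wce Paths to SAM files (text, with `@SQ` headers) for
#'   the IP and WCE samples.
#' @param calibration_names Character vector of calibration-genome reference
#'   (chromosome) names.
#' @param experimental_names Optional character vector of experimental
#'   reference names; when supplied, a mapped record whose reference is in
#'   neither set raises an error naming it.
#' @return A `partition_result` (without per-read assignments).
#' @export
load_alignment_counts <- function(sam_ip, sam_wce, calibration_names,
                                  experimental_names = NULL) {
  count_one <- function(path) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
    rec <- Rsamtools::scanBam(
      bam, param = Rsamtools::ScanBamParam(what = c("flag", "rname")))[[1]]
    flag <- rec$flag
    secondary <- bitwAnd(flag, 0x100L) != 0L | bitwAnd(flag, 0x800L) != 0L
    flag <- flag[!secondary]
    rname <- as.character(rec$rname)[!secondary]
    unmapped <- bitwAnd(flag, 0x4L) != 0L
    mapped_ref <- rname[!unmapped]
    if (!is.null(experimental_names)) {
      unknown <- setdiff(mapped_ref, c(calibration_names, experimental_names))
      if (length(unknown)) {
        abort(paste0("Unknown reference name(s) in '", path, "': ",
                     paste(unique(unknown), collapse = ", ")))
      }
    }
    list(cal = sum(mapped_ref %in% calibration_names),
         exp = sum(!mapped_ref %in% calibration_names),
         unaligned = sum(unmapped),
         skipped = sum(secondary))
  }
  ip <- count_one(sam_ip)
  wce <- count_one(sam_wce)
  res <- new_partition_result(
    assignments = tibble(id = character(), sample = character(),
                         assignment = character()),
    Wc = wce$cal, Wx = wce$exp, IPc = ip$cal, IPx = ip$exp,
    unaligned_wce = wce$unaligned, unaligned_ip = ip$unaligned,
    skipped = ip$skipped + wce$skipped)
  if (res$skipped > 0L) {
    message(res$skipped, " secondary/supplementary record(s) ignored.")
  }
  res
}
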