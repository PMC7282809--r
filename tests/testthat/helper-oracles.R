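# Independent oracles and small fixture builders shared across tests.
# Every oracle is a deliberately naive re-computation (double loops, full
# strand scans) kept separate from the package's vectorised code paths.

# Brute-force strand-aware assignment: scan every chromosome of both genomes
# (forward and reverse complement strings) for the read as a plain substring.
oracle_assign <- function(sequence, pair) {
  if (grepl("N", sequence, fixed = TRUE)) return("unaligned")
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  in_genome <- function(genome) {
    any(vapply(genome, function(chr) {
      grepl(sequence, chr, fixed = TRUE) || grepl(revcomp(sequence), chr,
                                                  fixed = TRUE)
    }, logical(1)))
  }
  if (in_genome(pair$calibration)) return("calibration")
  if (in_genome(pair$experimental)) return("experimental")
  "unaligned"
}

# Per-position membership count: depth(p) = number of reads covering p.
oracle_pileup <- function(reads, chrom_lengths, read_length) {
  out <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    depth <- integer(len)
    sel <- which(reads$chrom == ch)
    for (p in seq_len(len)) {
      for (i in sel) {
        if (p >= reads$start[i] && p <= reads$start[i] + read_length - 1L) {
          depth[p] <- depth[p] + 1L
        }
      }
    }
    out[[ch]] <- depth
  }
  out
}

# Double loop over (anchor, offset); mean over anchors whose offset position
# lies inside the chromosome, then OR / per-million scaling.
oracle_meta_profile <- function(depth_by_chrom, anchors, window,
                                or_value = 1, total_reads = 1e6) {
  offsets <- seq.int(-window, window)
  mean_depth <- rep(NA_real_, length(offsets))
  n_contrib <- integer(length(offsets))
  for (j in seq_along(offsets)) {
    vals <- c()
    for (i in seq_len(nrow(anchors))) {
      v <- depth_by_chrom[[anchors$chrom[i]]]
      p <- anchors$anchor[i] + offsets[j]
      if (p >= 1 && p <= length(v)) vals <- c(vals, v[p])
    }
    n_contrib[j] <- length(vals)
    if (length(vals)) mean_depth[j] <- mean(vals) * or_value * 1e6 / total_reads
  }
  list(offset = offsets, mean_depth = mean_depth, n_contributing = n_contrib)
}

# Hand-evaluated Welch statistic and Welch-Satterthwaite df.
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df)
}

# Small genome pair reused by partition/calibration tests.
tiny_pair <- function(seed = 11L) {
  gen_genome_pair(seed = seed, n_chrom = 2L, chrom_len = 1500L,
                  read_length = 40L)
}

# Substring of a chromosome, 1-based.
chrom_substr <- function(pair, species, chrom_idx, start, len) {
  substr(pair[[species]][[chrom_idx]], start, start + len - 1L)
}

string_revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}
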