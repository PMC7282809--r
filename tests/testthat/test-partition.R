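test_that("positional trimming keeps bases (head_trim+1)..max_keep and drops short reads", {
  mk <- function(n) paste(rep(c("A", "C", "G", "T"), length.out = n),
                          collapse = "")
  reads <- tibble::tibble(id = c("long", "boundary_drop", "boundary_keep"),
                          sequence = c(mk(250), mk(55), mk(60)))
  out <- trim_reads(reads)
  # 250-base read -> the 190 bases at original positions 11..200
  expect_equal(out$sequence[out$id == "long"],
               substr(reads$sequence[1], 11, 200))
  expect_equal(nchar(out$sequence[out$id == "long"]), 190)
  # 55 bases: 55 - 10 = 45 < 50, dropped; 60 bases: exactly 50 kept
  expect_false("boundary_drop" %in% out$id)
  expect_equal(nchar(out$sequence[out$id == "boundary_keep"]), 50)
  # order preserved
  expect_equal(out$id, c("long", "boundary_keep"))
  expect_equal(nrow(trim_reads(tibble::tibble(sequence = mk(30)))), 0)
  expect_error(trim_reads(reads, head_trim = 10, max_keep = 5), "max_keep")
})

test_that("single-read assignment follows the sequential strand-aware rule", {
  pair <- tiny_pair()
  cal_read <- chrom_substr(pair, "calibration", 1, 101, 40)
  exp_read <- chrom_substr(pair, "experimental", 2, 501, 40)
  expect_equal(assign_read(cal_read, pair), "calibration")
  expect_equal(assign_read(exp_read, pair), "experimental")
  # reverse complement of an experimental substring still maps there
  expect_equal(assign_read(string_revcomp(exp_read), pair), "experimental")
  # N-containing and alien reads are unaligned
  expect_equal(assign_read(paste0("N", substr(exp_read, 2, 40)), pair),
               "unaligned")
  expect_equal(assign_read(strrep("A", 40), pair), "unaligned")

  # agreement with the brute-force oracle on random-ish probes
  probes <- c(cal_read, exp_read, string_revcomp(cal_read),
              strrep("ACGT", 10), chrom_substr(pair, "experimental", 1, 7, 40))
  for (p in probes) expect_equal(assign_read(p, pair), oracle_assign(p, pair))
})

test_that("a read present in both genomes takes calibration precedence", {
  # hand-built pair sharing a sequence: constructed directly, bypassing the
  # audited generator, to probe the two-pass precedence rule
  shared <- strrep("ACGTTGCA", 5)
  pair <- structure(list(
    experimental = c(exp_chr1 = paste0(strrep("A", 30), shared,
                                       strrep("C", 30))),
    calibration = c(cal_chr1 = paste0(strrep("G", 30), shared,
                                      strrep("T", 30))),
    read_length = 40L), class = "genome_pair")
  expect_equal(assign_read(shared, pair), "calibration")
  # removing it from the calibration genome moves the assignment
  pair2 <- pair
  pair2$calibration <- c(cal_chr1 = strrep("G", 100))
  expect_equal(assign_read(shared, pair2), "experimental")
})

test_that("partition counts classes exactly and matches simulator ground truth", {
  pair <- tiny_pair()
  cal_reads <- tibble::tibble(
    sequence = vapply(1:10, function(i)
      chrom_substr(pair, "calibration", 1, i * 20, 40), character(1)))
  exp_reads <- tibble::tibble(
    sequence = vapply(1:30, function(i)
      chrom_substr(pair, "experimental", 1 + i %% 2, i * 20, 40),
      character(1)))
  wce <- dplyr::bind_rows(cal_reads, exp_reads)
  res <- partition_reads(ip_reads = exp_reads, wce_reads = wce, pair = pair)
  expect_equal(res$Wc, 10)
  expect_equal(res$Wx, 30)
  expect_equal(res$IPx, 30)
  expect_equal(res$IPc, 0)
  # conservation: classes partition each read set
  tt <- tidy(res)
  expect_equal(sum(tt$n[tt$sample == "WCE"]), 40)
  expect_equal(sum(tt$n[tt$sample == "IP"]), 30)

  # strand symmetry: reverse-complementing every read leaves counts unchanged
  rc <- function(df) dplyr::mutate(df, sequence = vapply(sequence,
                                                         string_revcomp,
                                                         character(1)))
  res_rc <- partition_reads(rc(exp_reads), rc(wce), pair)
  expect_equal(tidy(res_rc)$n, tt$n)

  expect_error(partition_reads(exp_reads[0, ], wce, pair), "non-empty")

  # simulator round trip: assignment equals true origin for every read
  ls <- occupancy_landscape(chrom_lengths(pair, "experimental"))
  ex <- sample_experiment(pair, ls, n_ip = 400, n_wce = 400, seed = 5)
  res2 <- partition_reads(ex$reads_ip, ex$reads_wce, pair)
  got <- res2$assignments
  truth <- dplyr::bind_rows(ex$reads_wce, ex$reads_ip)
  expect_equal(got$assignment, truth$origin)
  expect_equal(res2$unaligned_ip + res2$unaligned_wce, 0)
})

test_that("large equal-width batches use the dictionary path consistently", {
  withr::local_seed(99L)
  pair <- tiny_pair()
  n <- 600  # above the dictionary-scan threshold
  starts <- sample(1400, n, replace = TRUE)
  seqs <- substr(rep(pair$experimental[[1]], n), starts, starts + 39L)
  alien <- replicate(50, paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                               collapse = ""))
  batch <- c(seqs, alien)
  hits <- cohesr:::.match_reads(batch, pair$experimental)
  slow <- vapply(batch, cohesr:::.matches_genome, logical(1),
                 genome_chr = pair$experimental)
  expect_equal(unname(hits), unname(slow))
  expect_true(all(hits[1:n]))
})

test_that("SAM ingestion tallies primary records by reference name", {
  pair <- tiny_pair()
  ls <- occupancy_landscape(chrom_lengths(pair, "experimental"))
  ex <- sample_experiment(pair, ls, n_ip = 120, n_wce = 150, seed = 9)
  dir <- withr::local_tempdir()
  write_fixture_dir(ex, pair, dir)
  res <- load_alignment_counts(file.path(dir, "ip.sam"),
                               file.path(dir, "wce.sam"),
                               calibration_names = names(pair$calibration),
                               experimental_names = names(pair$experimental))
  manifest <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(res$Wc, manifest$origin_counts$wce$calibration)
  expect_equal(res$Wx, manifest$origin_counts$wce$experimental)
  expect_equal(res$IPc, manifest$origin_counts$ip$calibration)
  expect_equal(res$IPx, manifest$origin_counts$ip$experimental)

  # unmapped flag and unknown reference handling
  sam <- file.path(dir, "edge.sam")
  writeLines(c("@HD\tVN:1.6",
               sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths(pair)),
                       chrom_lengths(pair)),
               "r1\t4\t*\t0\t0\t*\t*\t0\t0\tACGTACGTACGT\t*",
               sprintf("r2\t0\t%s\t5\t60\t12M\t*\t0\t0\tACGTACGTACGT\t*",
                       names(pair$calibration)[1]),
               sprintf("r3\t256\t%s\t9\t60\t12M\t*\t0\t0\tACGTACGTACGT\t*",
                       names(pair$calibration)[1])),
             sam)
  suppressMessages(res2 <- load_alignment_counts(sam, sam,
                                names(pair$calibration)))
  expect_equal(res2$Wc, 1)           # one primary mapped record
  expect_equal(res2$unaligned_wce, 1)  # flag-4 record
  expect_equal(res2$skipped, 2)      # secondary record in each file
})
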