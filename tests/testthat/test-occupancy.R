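test_that("pileup counts interval membership densely with zeros elsewhere", {
  one <- pileup(tibble::tibble(chrom = "c1", start = 11),
                c(c1 = 100), read_length = 50)
  expect_equal(nrow(one), 100)
  expect_equal(one$depth, c(rep(0, 10), rep(1, 50), rep(0, 40)))

  two <- pileup(tibble::tibble(chrom = c("c1", "c1"), start = c(11, 11)),
                c(c1 = 100), read_length = 50)
  expect_equal(two$depth[11:60], rep(2, 50))

  # random fixture vs the double-loop oracle
  withr::local_seed(31L)
  lens <- c(a = 120L, b = 90L)
  reads <- tibble::tibble(chrom = sample(names(lens), 200, replace = TRUE))
  reads$start <- vapply(reads$chrom,
                        function(ch) sample.int(lens[[ch]] - 14L, 1L),
                        integer(1))
  pu <- pileup(reads, lens, read_length = 15)
  oracle <- oracle_pileup(reads, lens, 15L)
  expect_equal(pu$depth[pu$chrom == "a"], oracle$a)
  expect_equal(pu$depth[pu$chrom == "b"], oracle$b)

  expect_error(pileup(tibble::tibble(chrom = "c1", start = 90, id = "bad"),
                      c(c1 = 100), read_length = 50), "bad")
  expect_error(pileup(tibble::tibble(chrom = "nope", start = 1),
                      c(c1 = 100), read_length = 10), "nope")
})

test_that("gap filling densifies, keeps listed depths, and conserves totals", {
  expect_equal(fill_gaps(tibble::tibble(pos = 3, depth = 7), 5)$depth,
               c(0, 0, 7, 0, 0))
  expect_equal(fill_gaps(tibble::tibble(pos = integer(), depth = integer()),
                         4)$depth, rep(0, 4))
  dense <- tibble::tibble(pos = 1:6, depth = c(1, 0, 2, 5, 0, 3))
  expect_equal(fill_gaps(dense, 6)$depth, dense$depth)
  expect_error(fill_gaps(tibble::tibble(pos = 9, depth = 1), 5), "outside")
  expect_error(fill_gaps(tibble::tibble(pos = c(2, 2), depth = c(1, 1)), 5),
               "Duplicate")

  withr::local_seed(41L)
  for (i in 1:200) {
    len <- sample(5:400, 1)
    k <- sample(0:min(len, 30), 1)
    sp <- tibble::tibble(pos = sample.int(len, k),
                         depth = sample.int(50, k, replace = TRUE))
    out <- fill_gaps(sp, len)
    expect_equal(nrow(out), len)
    expect_equal(sum(out$depth), sum(sp$depth))
  }
})

test_that("meta-profiles equal the brute-force oracle and respect boundaries", {
  # hand-listed toy: 2 chromosomes, window 2
  track <- dplyr::bind_rows(
    tibble::tibble(chrom = "a", pos = 1:7, depth = c(1, 2, 3, 4, 5, 6, 7)),
    tibble::tibble(chrom = "b", pos = 1:5, depth = c(10, 0, 20, 0, 30)))
  anchors <- tibble::tibble(chrom = c("a", "b"), anchor = c(4, 3))
  mp <- meta_profile(track, anchors, window = 2)
  oracle <- oracle_meta_profile(list(a = c(1:7), b = c(10, 0, 20, 0, 30)),
                                anchors, window = 2)
  expect_equal(mp$offset, -2:2)
  expect_equal(mp$mean_depth, oracle$mean_depth)
  expect_equal(mp$mean_depth, c((2 + 10) / 2, (3 + 0) / 2, (4 + 20) / 2,
                                (5 + 0) / 2, (6 + 30) / 2))
  expect_equal(mp$n_contributing, rep(2L, 5))

  # anchor near the chromosome start: truncated offsets lose one contributor
  anchors2 <- tibble::tibble(chrom = c("a", "b"), anchor = c(4, 2))
  mp2 <- meta_profile(track, anchors2, window = 3)
  expect_equal(mp2$n_contributing, c(1L, 1L, 2L, 2L, 2L, 2L, 2L))
  oracle2 <- oracle_meta_profile(list(a = c(1:7), b = c(10, 0, 20, 0, 30)),
                                 anchors2, window = 3)
  expect_equal(mp2$mean_depth, oracle2$mean_depth)

  # uniform depth stays constant at every offset after calibration identity
  flat <- tibble::tibble(chrom = "a", pos = 1:50, depth = 3)
  mpf <- meta_profile(flat, tibble::tibble(chrom = "a", anchor = 25),
                      window = 10, or_ = 1, total_reads = 1e6)
  expect_equal(mpf$mean_depth, rep(3, 21))

  # calibration scaling applies OR * 1e6 / total_reads
  mpc <- meta_profile(flat, tibble::tibble(chrom = "a", anchor = 25),
                      window = 2, or_ = 2, total_reads = 5e5)
  expect_equal(mpc$mean_depth, rep(12, 5))

  expect_error(meta_profile(track, tibble::tibble(chrom = "zz", anchor = 1),
                            window = 2), "zz")
  expect_error(meta_profile(track, tibble::tibble(chrom = "a", anchor = 99),
                            window = 2), "outside")
})

test_that("meta-profiles are equivariant under a joint coordinate shift", {
  withr::local_seed(51L)
  depth <- sample.int(20, 60, replace = TRUE)
  k <- 7L
  t1 <- tibble::tibble(chrom = "a", pos = 1:60, depth = depth)
  t2 <- tibble::tibble(chrom = "a", pos = 1:67,
                       depth = c(rep(0, k), depth))
  a1 <- tibble::tibble(chrom = "a", anchor = 30)
  a2 <- tibble::tibble(chrom = "a", anchor = 30 + k)
  m1 <- meta_profile(t1, a1, window = 20)
  m2 <- meta_profile(t2, a2, window = 20)
  expect_equal(m1$mean_depth, m2$mean_depth)
})

test_that("chromosome medians use the stated conventions and scale linearly", {
  tr <- tibble::tibble(chrom = "c", pos = 1:5, depth = c(1, 2, 3, 4, 100))
  expect_equal(chromosome_median(tr, "c"), 3)
  even <- tibble::tibble(chrom = "c", pos = 1:4, depth = c(1, 2, 3, 4))
  expect_equal(chromosome_median(even, "c"), 2.5)
  const <- tibble::tibble(chrom = "c", pos = 1:9, depth = 7)
  expect_equal(chromosome_median(const, "c"), 7)
  # permutation invariance and linearity
  withr::local_seed(61L)
  shuffled <- tr[sample(5), ]
  expect_equal(chromosome_median(shuffled, "c"), 3)
  tr2 <- tr; tr2$depth <- tr$depth * 4
  expect_equal(chromosome_median(tr2, "c"), 12)
  expect_error(chromosome_median(tr, "missing"), "missing")
})

test_that("occupancy change reports per-chromosome ratios and a genome-wide median", {
  before <- tibble::tibble(chrom = rep(c("a", "b"), each = 6),
                           pos = rep(1:6, 2),
                           value = c(2, 4, 6, 8, 10, 12, 1, 1, 1, 1, 1, 5))
  oc <- occupancy_change(before, before)
  expect_equal(oc$ratio, c(1, 1))
  after <- before
  after$value <- before$value * 0.5
  oc2 <- occupancy_change(before, after)
  expect_equal(oc2$ratio, c(0.5, 0.5))
  expect_equal(glance(oc2)$genome_wide_ratio, 0.5)

  # zero median before -> undefined ratio, reported and excluded
  b0 <- tibble::tibble(chrom = rep(c("a", "z"), each = 5), pos = rep(1:5, 2),
                       value = c(1, 2, 3, 4, 5, 0, 0, 0, 1, 0))
  a0 <- b0
  a0$value <- b0$value * 2
  expect_warning(oc3 <- occupancy_change(b0, a0), "Undefined")
  expect_true(is.na(oc3$ratio[oc3$chrom == "z"]))
  expect_equal(glance(oc3)$genome_wide_ratio, 2)

  expect_error(occupancy_change(before, before[before$chrom == "a", ]),
               "same chromosomes")
})
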