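test_that("read QC removes exactly the reads violating each rule, in order", {
  p <- qc_params()
  ad3 <- p$adapter_3p
  good_q <- function(n) strrep(I_to_q(40), n)
  I_to_q <- function(q) intToUtf8(q + 33L)
  mk <- function(seq) data.frame(seq = seq, qual = strrep(I_to_q(40), nchar(seq)),
                                 stringsAsFactors = FALSE)
  # 17-nt insert -> min_length
  r <- filter_raw_reads(mk(paste0(strrep("ACGT", 4), "A", ad3)), p)
  expect_equal(unname(r$removed["min_length"]), 1L)
  # homopolymer A insert
  r <- filter_raw_reads(mk(paste0(strrep("A", 20), ad3)), p)
  expect_equal(unname(r$removed["homopolymer_A"]), 1L)
  # missing 3' adapter
  r <- filter_raw_reads(mk(strrep("ACGT", 10)), p)
  expect_equal(unname(r$removed["no_3p_adapter"]), 1L)
  # quality rules: 5 bases below Q10 fails, 4 passes q10 but may trip q13
  seq <- paste0(strrep("ACGT", 5), ad3)
  lowq <- function(nlow, q) {
    qual <- rep(40L, 20); qual[seq_len(nlow)] <- q
    data.frame(seq = seq, qual = paste0(intToUtf8(qual + 33L, multiple = FALSE),
                                        strrep(intToUtf8(73L), nchar(ad3))),
               stringsAsFactors = FALSE)
  }
  r <- filter_raw_reads(lowq(5, 5), p)
  expect_equal(unname(r$removed["low_quality_q10"]), 1L)
  r <- filter_raw_reads(lowq(7, 12), p)
  expect_equal(unname(r$removed["low_quality_q13"]), 1L)
  r <- filter_raw_reads(lowq(4, 5), p)   # 4 bases < Q10: tolerated by q10 rule
  expect_equal(unname(r$removed["low_quality_q10"]), 0L)

  # constructed 10-read fixture: 3 violations, 7 survivors
  recs <- rbind(
    mk(paste0(strrep("ACGT", 8), ad3)),          # ok
    mk(paste0(strrep("GA", 12), ad3)),           # ok
    mk(paste0(strrep("A", 16), "C", ad3)),       # 17 nt -> min_length
    mk(paste0(strrep("A", 22), ad3)),            # homopolymer
    mk(strrep("ACGTT", 8)),                      # no adapter
    mk(paste0(strrep("TTGCA", 4), ad3)),         # ok
    mk(paste0(strrep("CCGA", 6), ad3)),          # ok
    mk(paste0(strrep("GTCA", 7), ad3)),          # ok
    mk(paste0(strrep("ACCA", 5), ad3)),          # ok
    mk(paste0(strrep("TGGA", 6), ad3)))          # ok
  r <- filter_raw_reads(recs, p)
  expect_equal(nrow(r$reads), 7L)
  expect_equal(sum(r$removed), 3L)
  expect_error(filter_raw_reads(data.frame(seq = "ACGT", qual = "II")),
               "malformed")
})

test_that("site assembly matches the single-read and no-conversion closed cases", {
  reads <- data.frame(chrom = "chrI", start = c(100L, 500L),
                      end = c(130L, 530L), name = c("a", "b"),
                      conversion_count = c(1L, 1L), strand = "+",
                      read_length = 30L, dataset = "d")
  s <- assemble_binding_sites(reads, total_mapped = 1e6)
  expect_equal(nrow(s), 2L)
  expect_equal(s$rpm, c(1, 1))
  # 10 identical reads, no conversions -> no high-confidence sites
  r0 <- reads[rep(1, 10), ]; r0$conversion_count <- 0L
  expect_equal(nrow(assemble_binding_sites(r0, 1e6)), 0L)
  # >2 conversions excluded before aggregation
  r3 <- reads; r3$conversion_count <- c(3L, 1L)
  expect_equal(nrow(assemble_binding_sites(r3, 1e6)), 1L)
  # empty input is fine; negative coordinates are not
  expect_equal(nrow(assemble_binding_sites(reads[0, ], 1e6)), 0L)
  rneg <- reads; rneg$start[1] <- -5L
  expect_error(assemble_binding_sites(rneg, 1e6), "negative")
  expect_error(assemble_binding_sites(reads, total_mapped = 1),
               "total_mapped")
})

test_that("site assembly equals the brute-force per-position coverage oracle", {
  for (seed in c(2, 13, 77)) {
    reads <- random_reads(200, seed = seed)
    got <- assemble_binding_sites(reads, total_mapped = 1e6)
    want <- oracle_sites(reads, total_mapped = 1e6)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$rpm, want$rpm, tolerance = 1e-12)
    expect_equal(got$n_conversion_reads, want$n_conversion_reads)
  }
})

test_that("site assembly is invariant to read order", {
  reads <- random_reads(150, seed = 4)
  set.seed(1)
  shuffled <- reads[sample.int(nrow(reads)), ]
  expect_equal(assemble_binding_sites(reads, 1e6),
               assemble_binding_sites(shuffled, 1e6))
})

test_that("K-S statistic matches closed cases, the brute-force oracle and stats::ks.test", {
  expect_equal(ks_two_sample(1:10, 1:10), 0)
  expect_equal(ks_two_sample(0, 1), 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
  set.seed(9)
  for (i in 1:25) {
    x <- rnorm(50); y <- rnorm(50, mean = runif(1, -1, 1))
    d <- ks_two_sample(x, y)
    expect_equal(d, oracle_ks(x, y), tolerance = 1e-14)
    expect_equal(d, unname(stats::ks.test(x, y)$statistic),
                 tolerance = 1e-14)
  }
  # ties are handled like the ECDF supremum demands
  x <- c(1, 1, 2, 3); y <- c(1, 2, 2, 4)
  expect_equal(ks_two_sample(x, y), oracle_ks(x, y))
})

test_that("threshold selection is deterministic, degenerate-safe and errors on tiny inputs", {
  mix <- simulate_rpm_mixture(seed = 5)
  t1 <- empirical_rpm_threshold(mix$rpm, n_iter = 300, seed = 11)
  t2 <- empirical_rpm_threshold(mix$rpm, n_iter = 300, seed = 11)
  expect_identical(t1$mean_stat, t2$mean_stat)
  expect_identical(t1$chosen, t2$chosen)
  expect_true(t1$chosen %in% t1$grid)
  expect_true(all(t1$mean_stat >= 0 & t1$mean_stat <= 1, na.rm = TRUE))

  # all-equal RPMs: D = 0 at every evaluable threshold, minimum chosen
  tdeg <- empirical_rpm_threshold(rep(3, 100), grid = seq(0, 3, length.out = 8),
                                  n_iter = 100, seed = 1)
  expect_true(all(tdeg$mean_stat[!is.na(tdeg$mean_stat)] == 0))
  expect_equal(tdeg$chosen, 0)

  expect_error(empirical_rpm_threshold(runif(10), n_iter = 10),
               "smallest grid value")
  w <- capture_warnings(empirical_rpm_threshold(mix$rpm, n_iter = 10, seed = 1))
  expect_true(any(grepl("unstable", w)))
})

test_that("identical forced subsamples give a zero K-S statistic", {
  # frac = 1 makes both subsamples the whole set: D must be exactly 0
  tc <- suppressWarnings(
    empirical_rpm_threshold(runif(60, 1, 5), grid = c(0, 0.5, 1),
                            n_iter = 50, frac = 1, window = 1, seed = 2))
  expect_true(all(tc$mean_stat == 0, na.rm = TRUE))
})

test_that("RPM filtering is monotone and the chosen threshold separates the planted mixture", {
  mix <- simulate_rpm_mixture(seed = 21)
  sites <- data.frame(rpm = mix$rpm)
  n_prev <- Inf
  for (t in c(0, 1, 2.5, 5, 10)) {
    kept <- filter_sites_rpm(sites, t)
    expect_true(all(kept$rpm >= t))
    expect_lte(nrow(kept), n_prev)
    n_prev <- nrow(kept)
  }
  # default settings (n_iter = 10,000): >= 95% of signal above, >= 95% of
  # noise below the chosen threshold
  tc <- empirical_rpm_threshold(mix$rpm, seed = 22)
  expect_gte(mean(mix$rpm[mix$is_signal] >= tc$chosen), 0.95)
  expect_gte(mean(mix$rpm[!mix$is_signal] < tc$chosen), 0.95)
})
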