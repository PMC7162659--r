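test_that("toy annotations echo inputs, are deterministic, and reject impossible layouts", {
  ann <- make_annotation(1, 10000, utr_lengths = c(100, 200), seed = 1)
  expect_equal(nrow(ann), 1L)
  expect_equal(ann$utr5_end - ann$utr5_start, 100L)
  expect_equal(ann$utr3_end - ann$utr3_start, 200L)
  expect_true(ann$end <= attr(ann, "chrom_lengths")[["chrI"]])

  a1 <- make_annotation(20, 100000, seed = 7)
  a2 <- make_annotation(20, 100000, seed = 7)
  expect_identical(a1, a2)
  expect_setequal(unique(a1$strand), c("+", "-"))
  # genes never overlap
  ord <- order(a1$start)
  expect_true(all(a1$start[ord][-1] >= a1$end[ord][-20]))

  expect_error(make_annotation(50, 1000), "cannot place")
})

test_that("planted-site read simulation honors conversion probabilities and coverage", {
  ann <- make_annotation(10, 30000, seed = 2)
  tr1 <- plant_site_truth(ann, n_signal = 1, n_noise = 1, conv_prob = 1,
                          signal_coverage = 30, noise_coverage = 2, seed = 3)
  reads <- simulate_parclip_reads(ann, tr1, total_reads = 10000,
                                  bg_coverage = 0, seed = 4)
  sig <- tr1$sites[tr1$sites$kind == "signal", ]
  on_site <- reads$start >= sig$start & reads$end <= sig$end &
    reads$strand == sig$strand
  expect_true(sum(on_site) > 0)
  expect_true(all(reads$conversion_count[on_site] >= 1))

  # conversion probability 0 everywhere -> no high-confidence sites
  tr0 <- plant_site_truth(ann, n_signal = 2, n_noise = 2, conv_prob = 0,
                          bg_conv_prob = 0, seed = 5)
  reads0 <- simulate_parclip_reads(ann, tr0, total_reads = 10000,
                                   bg_coverage = 0, seed = 6)
  expect_equal(nrow(assemble_binding_sites(reads0, 10000)), 0L)

  expect_error(simulate_parclip_reads(ann, tr1, read_length = 100L),
               "read_length")
})

test_that("planted mean coverage is recovered by direct per-position counting", {
  ann <- make_annotation(20, 100000, seed = 11)
  truth <- plant_site_truth(ann, n_signal = 15, n_noise = 10,
                            signal_coverage = 50, noise_coverage = 2,
                            seed = 3)
  reads <- simulate_parclip_reads(ann, truth, total_reads = 100000,
                                  seed = 3)
  sig <- truth$sites[truth$sites$kind == "signal", ]
  mean_cov <- vapply(seq_len(nrow(sig)), function(i) {
    pos <- (sig$start[i] + 1):sig$end[i]
    cov <- vapply(pos, function(p)
      sum(reads$start < p & reads$end >= p &
            reads$chrom == sig$chrom[i] & reads$strand == sig$strand[i]),
      numeric(1))
    mean(cov)
  }, numeric(1))
  # Poisson read counts: SE of the mean over sites ~ sqrt(50 * L/S / n)
  se <- sd(mean_cov) / sqrt(length(mean_cov))
  expect_lt(abs(mean(mean_cov) - 50), 3 * se)
})

test_that("RIP-seq simulation gives the planted fold in the noiseless limit and honors totals", {
  ann <- make_annotation(100, 300000, seed = 8)
  enriched <- ann$gene_id[1:5]
  sim <- simulate_ripseq_counts(ann, enriched, fold = 2, n_reps = 3,
                                dispersion = 0, lib_size = 1e6, seed = 9)
  cols <- function(a) grep(paste0("^", a, "_"), names(sim$counts))
  totals <- colSums(sim$counts[-1])
  expect_true(all(abs(totals - 1e6) / 1e6 < 0.1))
  rpm_ip <- rowMeans(sim$counts[cols("IP")]) / sum(sim$counts[[cols("IP")[1]]]) * 1e6
  rpm_ft <- rowMeans(sim$counts[cols("FT")]) / sum(sim$counts[[cols("FT")[1]]]) * 1e6
  ratio <- rpm_ip[ann$gene_id %in% enriched] / rpm_ft[ann$gene_id %in% enriched]
  # Poisson-only noise at mu ~ thousands: realized RPM ratio -> fold
  expect_equal(mean(ratio), 2, tolerance = 0.05)
  bg <- rpm_ip[!ann$gene_id %in% enriched] / rpm_ft[!ann$gene_id %in% enriched]
  expect_equal(median(bg), sim$background_ratio, tolerance = 0.05)
  expect_error(simulate_ripseq_counts(ann, "nope", seed = 1),
               "not in annotation")
})

test_that("image stacks render exact Gaussian peaks and respect rotation symmetry", {
  p <- data.frame(x0 = 20, y0 = 24, slice = 1, A = 1000, sx = 3, sy = 5,
                  theta = 0.6)
  img <- simulate_image_stack(dim = c(48, 48, 1), puncta = p,
                              baseline = 100, noise_sd = 0, seed = 1)
  expect_equal(img$stack[24, 20, 1], 1100)   # b + A at the center pixel
  p2 <- p; p2$theta <- p$theta + pi
  img2 <- simulate_image_stack(dim = c(48, 48, 1), puncta = p2,
                               baseline = 100, noise_sd = 0, seed = 1)
  expect_equal(img$stack, img2$stack)
  expect_error(simulate_image_stack(puncta = transform(p, sx = -1)),
               "sigma")
  expect_error(simulate_image_stack(puncta = transform(p, A = -5)),
               "amplitude")

  # integrated background-subtracted intensity ~ 2*pi*A*sx*sy
  imgn <- simulate_image_stack(dim = c(64, 64, 1),
                               puncta = transform(p, x0 = 32, y0 = 32),
                               baseline = 100, noise_sd = 5, seed = 2)
  integ <- sum(imgn$stack[, , 1] - 100)
  expect_equal(integ, 2 * pi * 1000 * 3 * 5, tolerance = 0.02)
})

test_that("FRAP traces reduce to the closed-form recovery when uncorrupted", {
  tr <- simulate_frap_trace(A_true = 0.3, tau_true = log(2) / 10,
                            acquisition_bleach_rate = 0, noise_sd = 0,
                            seed = 1)
  tr <- correct_trace(tr)
  t_post <- tr$times[tr$bleach_index:length(tr$times)] -
    tr$times[tr$bleach_index]
  expect_equal(tr$normalized[tr$bleach_index:length(tr$times)],
               0.3 * (1 - exp(-log(2) / 10 * t_post)), tolerance = 1e-12)

  tr0 <- simulate_frap_trace(A_true = 0, noise_sd = 0, seed = 2)
  tr0 <- correct_trace(tr0)
  expect_true(all(abs(tr0$normalized[tr0$bleach_index:41]) < 1e-12))

  expect_error(simulate_frap_trace(bleach_depth = 0), "bleach_depth")
  expect_error(simulate_frap_trace(bleach_depth = 1.2), "bleach_depth")
})

test_that("competition draws have the mixing-law expectation", {
  obs1 <- simulate_competition(1, 90, 10, n_cells = 200000, seed = 3)
  expect_equal(obs1$pct_mix, 90, tolerance = 0.01)
  obs5 <- simulate_competition(0.5, 90, 10, n_cells = 200000, seed = 4)
  expect_equal(obs5$pct_mix, 50, tolerance = 0.02)
  expect_error(simulate_competition(0.5, 50, 50), "identifiable")
  expect_error(simulate_competition(0.5, 90, 10, n_cells = 0), "n_cells")
})

test_that("generators are bit-reproducible given a seed", {
  ann <- make_annotation(10, 30000, seed = 2)
  tr <- plant_site_truth(ann, seed = 3)
  expect_identical(simulate_parclip_reads(ann, tr, 50000, seed = 5),
                   simulate_parclip_reads(ann, tr, 50000, seed = 5))
  expect_identical(simulate_ripseq_counts(ann, ann$gene_id[1], seed = 6),
                   simulate_ripseq_counts(ann, ann$gene_id[1], seed = 6))
  p <- data.frame(x0 = 10, y0 = 10, slice = 1, A = 100, sx = 2, sy = 2,
                  theta = 0)
  expect_identical(
    simulate_image_stack(dim = c(32, 32, 2), puncta = p, noise_sd = 3,
                         poisson = TRUE, seed = 7),
    simulate_image_stack(dim = c(32, 32, 2), puncta = p, noise_sd = 3,
                         poisson = TRUE, seed = 7))
  expect_identical(simulate_frap_trace(seed = 8),
                   simulate_frap_trace(seed = 8))
  expect_identical(simulate_competition(seed = 9),
                   simulate_competition(seed = 9))
})
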