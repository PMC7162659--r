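#!/usr/bin/env Rscript
# Generate every synthetic input the downstream analyses consume, with the
# planted ground truth saved alongside. All later scripts read from
# results/data/, so the whole workflow runs without any external download.

library(gbodykit)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

message("-- toy genome annotation (60 genes on a 120 kb chromosome)")
annot <- make_annotation(60L, 120000L, seed = stage_seed(seed, "annotation"))
write.table(annot, file.path(out, "annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("-- PAR-CLIP read tables for three enzyme datasets")
# three datasets sharing many planted sites, mimicking the shared substrate
# binding of the three glycolysis enzymes
for (ds in c("pfk2", "eno1", "fba1")) {
  truth <- plant_site_truth(annot, n_signal = 25L, n_noise = 50L,
                            signal_coverage = 50, noise_coverage = 2,
                            dataset_id = ds,
                            seed = stage_seed(seed, paste0("truth_", ds)))
  reads <- simulate_parclip_reads(annot, truth, total_reads = 200000L,
                                  seed = stage_seed(seed, paste0("reads_", ds)))
  write_reads_tsv(reads, file.path(out, sprintf("parclip_%s_reads.tsv", ds)))
  jsonlite::write_json(truth$sites,
                       file.path(out, sprintf("parclip_%s_truth.json", ds)))
}

message("-- RIP-seq count tables (20 genes planted 4-fold enriched)")
rip_annot <- make_annotation(300L, 600000L, seed = stage_seed(seed, "rip_annot"))
write.table(rip_annot, file.path(out, "rip_annotation.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
sim <- simulate_ripseq_counts(rip_annot, rip_annot$gene_id[1:20], fold = 4,
                              n_reps = 3L, dispersion = 0.1, lib_size = 1e6,
                              seed = stage_seed(seed, "rip_counts"))
write_gene_table(sim$counts, file.path(out, "ripseq_counts.tsv"))
writeLines(sim$enriched, file.path(out, "ripseq_enriched_truth.txt"))

message("-- qPCR Cq table (planted percent-of-input between 2.4 and 7)")
probes <- data.frame(probe_id = sprintf("probe%02d", 1:6),
                     cq_eluate = c(24.9, 24.2, 23.8, 25.6, 24.4, 23.5),
                     cq_ft = rep(21.5, 6), fraction = 0.25)
write_cq_table(probes, file.path(out, "qpcr_cq.tsv"))

message("-- image stacks: untreated vs hexanediol-like (shrunken) puncta")
px <- 0.13
for (cond in c("untreated", "hexanediol")) {
  sg <- if (cond == "untreated") 1.1 / px else 0.72 / px
  A <- if (cond == "untreated") 18519 else 12054
  set.seed(stage_seed(seed, paste0("img_", cond)))
  centers <- expand.grid(x = c(40, 110, 180), y = c(40, 110, 180))
  puncta <- data.frame(x0 = centers$x + runif(9, -3, 3),
                       y0 = centers$y + runif(9, -3, 3), slice = 1L,
                       A = A * runif(9, 0.85, 1.15),
                       sx = sg * runif(9, 0.9, 1.1),
                       sy = sg * runif(9, 0.9, 1.1),
                       theta = runif(9, 0, pi))
  cells <- data.frame(cell_id = 1:9, cx = centers$x, cy = centers$y, r = 30)
  img <- simulate_image_stack(dim = c(220L, 220L, 1L), cells = cells,
                              puncta = puncta, baseline = 100,
                              noise_sd = 100, poisson = TRUE,
                              pixel_size = px,
                              seed = stage_seed(seed, paste0("stack_", cond)))
  write_image_stack(img$stack, file.path(out, sprintf("puncta_%s.tif", cond)),
                    pixel_size = px)
  write.table(puncta, file.path(out, sprintf("puncta_%s_truth.tsv", cond)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cells, file.path(out, sprintf("cells_%s.tsv", cond)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message("-- smFISH stacks: one enriched mRNA, one control-like mRNA")
for (tgt in c("enriched", "control")) {
  s <- stage_seed(seed, paste0("fish_", tgt))
  set.seed(s)
  n <- 150L
  if (tgt == "enriched") {
    ang <- runif(n, 0, 2 * pi)
    rad <- c(abs(rnorm(n / 2, 0, 3)), runif(n / 2, 0, 25))
    spots <- data.frame(x = 45 + rad * cos(ang), y = 38 + rad * sin(ang),
                        z = sample(1:3, n, replace = TRUE))
  } else {
    spots <- data.frame(x = 40 + runif(n, -25, 25),
                        y = 40 + runif(n, -25, 25),
                        z = sample(1:3, n, replace = TRUE))
  }
  spots <- spots[(spots$x - 40)^2 + (spots$y - 40)^2 < 30^2, ]
  # two channels: GFP carries the granule, the FISH channel the spots
  gfp <- simulate_image_stack(
    dim = c(80L, 80L, 3L),
    cells = data.frame(cell_id = 1L, cx = 40, cy = 40, r = 32),
    puncta = data.frame(x0 = 45, y0 = 38, slice = 2L, A = 2000, sx = 4,
                        sy = 4, theta = 0),
    baseline = 50, noise_sd = 2, pixel_size = px, seed = s)
  fish <- simulate_image_stack(dim = c(80L, 80L, 3L), spots = spots,
                               baseline = 30, noise_sd = 2,
                               pixel_size = px, seed = s + 1L)
  write_image_stack(gfp$stack, file.path(out, sprintf("fish_%s_gfp.tif", tgt)),
                    pixel_size = px)
  write_image_stack(fish$stack, file.path(out, sprintf("fish_%s_fish.tif", tgt)),
                    pixel_size = px)
  write.table(spots, file.path(out, sprintf("fish_%s_spots.tsv", tgt)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

message("-- FRAP traces for three fusion-protein conditions")
frap_design <- data.frame(condition = c("pfk2", "fba1", "rnase_targeted"),
                          A = c(0.095, 0.28, 0.13),
                          half_time = c(10.6, 25, 5.7))
write.table(frap_design, file.path(out, "frap_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
for (i in seq_len(nrow(frap_design))) for (r in 1:5) {
  tr <- simulate_frap_trace(
    A_true = frap_design$A[i],
    tau_true = log(2) / frap_design$half_time[i],
    bleach_depth = 0.8, acquisition_bleach_rate = 0.01, noise_sd = 0.02,
    seed = stage_seed(seed, sprintf("frap_%s_%d", frap_design$condition[i], r)))
  write_trace_tsv(tr, file.path(out, sprintf("frap_%s_rep%d.tsv",
                                             frap_design$condition[i], r)))
}

message("-- competition observations over increasing generations")
set.seed(stage_seed(seed, "competition"))
for (g in 1:3) {
  obs <- simulate_competition(f_true = 0.65, pct_gb_plus = 90,
                              pct_gb_minus = 10, n_cells = 10000L,
                              seed = stage_seed(seed, paste0("comp", g)))
  write_competition_tsv(obs, file.path(out, sprintf("competition_t%d.tsv", g)))
}

message("done: inputs in ", out)
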