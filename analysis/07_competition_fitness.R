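#!/usr/bin/env Rscript
# Growth-competition fitness: invert the G-body phenotype frequencies of
# mixed cultures to the fraction of G-body-forming cells, with bootstrap
# intervals, against generations of hypoxic growth.

library(gbodykit)

data_dir <- "results/data"
out <- "results/competition"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# OD series: serial 1:8 dilutions regrown to OD ~ 3.2 each round
od <- data.frame(t = 1:3, od_start = 0.05, od_end = c(3.2, 3.2, 3.2))
gen_per_round <- generations(od$od_start[1], od$od_end[1])

rows <- list()
for (g in 1:3) {
  obs <- read_competition_tsv(file.path(data_dir,
                                        sprintf("competition_t%d.tsv", g)))
  est <- fraction_gb_plus(obs, seed = stage_seed(1L, paste0("boot", g)))
  rows[[g]] <- data.frame(round = g,
                          generations = g * gen_per_round,
                          pct_mix = obs$pct_mix,
                          pct_gb_plus = obs$pct_gb_plus,
                          pct_gb_minus = obs$pct_gb_minus,
                          f_gb_plus = est$estimate,
                          ci_lo = est$ci[1], ci_hi = est$ci[2])
}
res <- do.call(rbind, rows)
message(sprintf("%.1f generations per growth round (OD %.2f -> %.1f)",
                gen_per_round, od$od_start[1], od$od_end[1]))
message("fraction of G-body-forming cells in the mixed culture:")
print(res, digits = 3, row.names = FALSE)
write.table(res, file.path(out, "fraction_gb_plus.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("done: ", out)
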