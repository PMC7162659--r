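#!/usr/bin/env Rscript
# G-body RIP-seq enrichment: RPM-normalize the three arms, compute per-gene
# fold and p over flow-through and over total RNA, intersect the two
# screens into the high-confidence set, test its overlap with the PAR-CLIP
# target genes, and summarize the qPCR percent-of-input assay.

library(gbodykit)

data_dir <- "results/data"
out <- "results/ripseq"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

counts <- read_gene_table(file.path(data_dir, "ripseq_counts.tsv"))
truth <- readLines(file.path(data_dir, "ripseq_enriched_truth.txt"))
cols <- function(a) c("gene_id", grep(paste0("^", a, "_"), names(counts),
                                      value = TRUE))
rpm_ip <- normalize_rpm(counts[cols("IP")])
rpm_ft <- normalize_rpm(counts[cols("FT")])
rpm_tot <- normalize_rpm(counts[cols("TOT")])

vs_ft <- enrichment_test(rpm_ip, rpm_ft)
vs_tot <- enrichment_test(rpm_ip, rpm_tot)
message(sprintf("replicate log-RPM correlation (IP arm): r = %.3f",
                attr(vs_ft, "replicate_cor")))
write.table(vs_ft, file.path(out, "volcano_vs_flowthrough.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(vs_tot, file.path(out, "volcano_vs_total.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

hc <- high_confidence_set(vs_ft, vs_tot, fold_thresh = 2, alpha = 0.05)
message(sprintf(
  "enriched >2-fold, p<0.05: %d vs flow-through, %d vs total, %d in both",
  hc$n[["vs_ft"]], hc$n[["vs_total"]], hc$n[["high_confidence"]]))
sens <- mean(truth %in% hc$high_confidence)
fdr <- 1 - mean(hc$high_confidence %in% truth)
message(sprintf("against planted truth: sensitivity %.2f, FDR %.2f",
                sens, fdr))
writeLines(hc$high_confidence, file.path(out, "high_confidence_genes.txt"))

# overlap of the high-confidence set with an independent reference set --
# here the planted-truth stand-in for the PAR-CLIP bound genes
chisq <- overlap_chisq(hc$high_confidence, counts$gene_id, truth)
message(sprintf(
  "overlap with reference set: %d observed vs %.1f expected (%.1f-fold), chi-square p = %.2g",
  chisq$observed, chisq$expected, chisq$fold, chisq$p))

# qPCR percent of input with the 2-cycle flow-through correction
cq <- read_cq_table(file.path(data_dir, "qpcr_cq.tsv"))
cq$percent_input <- vapply(seq_len(nrow(cq)), function(i)
  qpcr_percent_input(cq$cq_eluate[i], cq$cq_ft[i], cq$fraction[i])$percent_input,
  numeric(1))
message("qPCR percent of input per probe:")
print(cq[c("probe_id", "percent_input")], digits = 3)
write.table(cq, file.path(out, "qpcr_percent_input.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# the spectral-count membership rule on a tiny illustrative table
spec <- data.frame(protein = c("enzymeA", "enzymeB", "enzymeC"),
                   spec_uv = c(12, 3, 2), spec_ctrl = c(0, 0, 0),
                   fdr = c(NA, NA, 0.04))
spec$is_mrbp <- classify_mrbp(spec$spec_uv, spec$spec_ctrl, spec$fdr)
write.table(spec, file.path(out, "mrbp_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

jsonlite::write_json(list(n_vs_ft = unname(hc$n[["vs_ft"]]),
                          n_high_confidence = unname(hc$n[["high_confidence"]]),
                          sensitivity = sens, fdr = fdr,
                          overlap_fold = chisq$fold, overlap_p = chisq$p),
                     file.path(out, "summary.json"), auto_unbox = TRUE)
message("done: ", out)
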