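#' Normalize a gene count table to reads per million (RPM)
#'
#' `RPM_g = count_g * 1e6 / sum(counts)` within each library (column).
#' Replicate averaging is a separate, explicit step downstream.
#'
#' @param counts `data.frame` with `gene_id` plus one integer count column
#'   per library.
#' @return a `data.frame` of the same shape with RPM values.
#' @export
normalize_rpm <- function(counts) {
  stopifnot("gene_id" %in% names(counts))
  libs <- setdiff(names(counts), "gene_id")
  out <- counts
  for (lib in libs) {
    tot <- sum(counts[[lib]])
    if (tot == 0) .fail("library %s has all-zero counts", lib)
    if (any(counts[[lib]] < 0)) .fail("library %s has negative counts", lib)
    out[[lib]] <- counts[[lib]] * 1e6 / tot
  }
  out
}

# internal: vectorized two-sided unpaired t-test across rows of two
# matrices (Welch or pooled). Zero-variance rows with equal means get p = 1
# (flagged), keeping the pipeline total.
.row_t_test <- function(a, b, pooled_var = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
  if (pooled_var) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(ma))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
  }
  t <- (ma - mb) / se
  p <- 2 * stats::pt(-abs(t), df)
  zero_var <- se == 0
  # zero variance: identical replicates give p = 1 (conservative); a
  # noiseless mean shift is unambiguous evidence, p -> 0
  p[zero_var & ma == mb] <- 1
  t[zero_var & ma == mb] <- 0
  p[zero_var & ma != mb] <- 0
  list(t = t, p = p, zero_variance = zero_var)
}

#' Per-gene enrichment of IP RPM over a reference arm
#'
#' Fold change = (mean IP RPM + pseudo) / (mean reference RPM + pseudo);
#' the p-value is a two-sided unpaired t-test on log2(RPM + pseudo) across
#' replicates. The default is the classic pooled-variance (Student) form,
#' appropriate for the equal-replicate designs used here and correctly
#' calibrated under the null; `pooled_var = FALSE` switches to Welch and
#' `linear = TRUE` tests raw RPMs instead.
#' Identical replicate sets (zero variance, equal means) yield p = 1 with
#' a flag rather than NaN.
#'
#' @param ip,ref RPM tables (`gene_id` + one column per replicate) over
#'   the same gene universe.
#' @param pseudo pseudocount in RPM units added before folds and logs
#'   (default 0.5).
#' @param pooled_var pooled-variance (Student) t-test; `FALSE` for Welch.
#' @param linear t-test on linear instead of log2 RPM.
#' @return `data.frame`: `gene_id`, `fold`, `log2_fold`, `t`, `p`,
#'   `zero_variance`, plus `mean_ip`, `mean_ref` (RPM), and a reported
#'   Pearson correlation of log RPM between replicates in
#'   `attr(, "replicate_cor")`.
#' @export
enrichment_test <- function(ip, ref, pseudo = 0.5, pooled_var = TRUE,
                            linear = FALSE) {
  if (!setequal(ip$gene_id, ref$gene_id) ||
      nrow(ip) != nrow(ref))
    .fail("mismatched gene universes; symmetric difference: %s",
          paste(union(setdiff(ip$gene_id, ref$gene_id),
                      setdiff(ref$gene_id, ip$gene_id)), collapse = ", "))
  ref <- ref[match(ip$gene_id, ref$gene_id), , drop = FALSE]
  a <- as.matrix(ip[setdiff(names(ip), "gene_id")])
  b <- as.matrix(ref[setdiff(names(ref), "gene_id")])
  if (ncol(a) < 2 || ncol(b) < 2) .fail("need >= 2 replicates per arm")
  fold <- (rowMeans(a) + pseudo) / (rowMeans(b) + pseudo)
  ta <- if (linear) a else log2(a + pseudo)
  tb <- if (linear) b else log2(b + pseudo)
  tt <- .row_t_test(ta, tb, pooled_var)
  out <- data.frame(gene_id = ip$gene_id, fold = fold,
                    log2_fold = log2(fold), t = tt$t, p = tt$p,
                    zero_variance = tt$zero_variance,
                    mean_ip = rowMeans(a), mean_ref = rowMeans(b),
                    stringsAsFactors = FALSE)
  la <- log10(a + pseudo)
  cors <- if (ncol(la) >= 2) stats::cor(la)[upper.tri(diag(ncol(la)))] else NA
  attr(out, "replicate_cor") <- mean(cors)
  out
}

#' High-confidence enriched gene set
#'
#' Genes passing both screens: fold > `fold_thresh` and p < `alpha` against
#' flow-through AND against total RNA.
#'
#' @param vs_ft,vs_total [enrichment_test()] results on the same universe.
#' @param fold_thresh,alpha thresholds (defaults 2 and 0.05).
#' @return list with `high_confidence` (gene ids), `vs_ft_only`,
#'   `vs_total_only` (single-screen sets) and their counts.
#' @export
high_confidence_set <- function(vs_ft, vs_total, fold_thresh = 2,
                                alpha = 0.05) {
  stopifnot(setequal(vs_ft$gene_id, vs_total$gene_id))
  pass <- function(res) res$gene_id[res$fold > fold_thresh & res$p < alpha]
  s_ft <- pass(vs_ft); s_tot <- pass(vs_total)
  hc <- intersect(s_ft, s_tot)
  list(high_confidence = hc, vs_ft_only = s_ft, vs_total_only = s_tot,
       n = c(high_confidence = length(hc), vs_ft = length(s_ft),
             vs_total = length(s_tot)))
}

#' Chi-square test of overlap between a hit set and a reference set
#'
#' Expected overlap = |hits| * |reference| / |universe|; the statistic is
#' the 1-df chi-square on the 2x2 membership table (no continuity
#' correction by default).
#'
#' @param hits,reference gene sets, both subsets of `universe`.
#' @param universe the gene universe.
#' @param correct apply the Yates continuity correction.
#' @return list: `observed`, `expected`, `fold`, `chisq`, `p`.
#' @export
overlap_chisq <- function(hits, universe, reference, correct = FALSE) {
  if (!length(universe)) .fail("empty universe")
  if (!all(hits %in% universe) || !all(reference %in% universe))
    .fail("hits and reference must be subsets of the universe")
  n <- length(universe)
  obs <- length(intersect(hits, reference))
  expected <- length(hits) * length(reference) / n
  o <- matrix(c(obs, length(hits) - obs,
                length(reference) - obs,
                n - length(hits) - length(reference) + obs), 2, 2)
  e <- outer(rowSums(o), colSums(o)) / n
  adj <- if (correct) pmin(abs(o - e), 0.5) else 0
  chisq <- sum((abs(o - e) - adj)^2 / e)
  list(observed = obs, expected = expected,
       fold = if (expected > 0) obs / expected else NA_real_,
       chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Percent of input from qPCR Cq values
#'
#' When only a fraction of the flow-through was assayed, the flow-through
#' Cq is corrected by subtracting `log2(1/fraction)` cycles (2 cycles for
#' the default 25% fraction), then
#' `percent = 100 * 2^(Cq_ft_corrected - Cq_eluate)` assuming doubling per
#' cycle.
#'
#' @param cq_eluate,cq_ft Cq of the eluate and flow-through reactions.
#' @param fraction assayed fraction of the flow-through, in (0, 1]
#'   (default 0.25).
#' @return list: `percent_input`, `correction_cycles`.
#' @export
qpcr_percent_input <- function(cq_eluate, cq_ft, fraction = 0.25) {
  if (fraction <= 0 || fraction > 1) .fail("fraction must be in (0, 1]")
  if (!all(is.finite(c(cq_eluate, cq_ft)))) .fail("non-finite Cq value")
  corr <- log2(1 / fraction)
  list(percent_input = 100 * 2^((cq_ft - corr) - cq_eluate),
       correction_cycles = corr)
}

#' mRNA-binding-protein membership rule from spectral counts
#'
#' A protein is called an mRBP iff it has more than 2 spectral counts in
#' the crosslinked (+UV) sample and 0 in the -UV control, or a reported
#' FDR below 10%.
#'
#' @param spec_uv,spec_ctrl spectral counts in +UV and -UV runs.
#' @param fdr optional FDR (NA when not computed).
#' @return logical vector.
#' @export
classify_mrbp <- function(spec_uv, spec_ctrl, fdr = NA_real_) {
  stopifnot(all(spec_uv >= 0), all(spec_ctrl >= 0))
  (spec_uv > 2 & spec_ctrl == 0) | (!is.na(fdr) & fdr < 0.10)
}
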