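#' Simulate RIP-seq count tables with planted G-body enrichment
#'
#' Generates negative-binomial (gamma-Poisson) raw counts for three arms of
#' a G-body RIP experiment: immunoprecipitate (IP), flow-through (FT) and
#' total RNA. A chosen gene set is enriched `fold`-fold in the IP arm
#' relative to flow-through; flow-through and total share the baseline
#' abundance profile. Enrichment is compensated compositionally: the
#' non-enriched genes are deflated by a common factor so that the expected
#' IP/FT RPM ratio of every enriched gene is exactly `fold` while expected
#' library totals stay at `lib_size` (an IP that concentrates some RNAs
#' necessarily dilutes the rest). The deflation factor is reported as
#' `background_ratio`.
#'
#' @param annot a [make_annotation()] table supplying the gene universe.
#' @param enriched_genes character vector of gene ids to enrich; must be a
#'   subset of the annotation.
#' @param fold enrichment ratio (> 0).
#' @param n_reps replicates per arm (>= 2).
#' @param dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   0 gives Poisson-only noise.
#' @param lib_size expected reads per library.
#' @param abund_sdlog sd of the log-normal baseline abundance profile.
#' @param seed integer seed.
#' @return a list with `counts` (data.frame: `gene_id` plus columns
#'   `IP_1..`, `FT_1..`, `TOT_1..`), `enriched` (the planted set), `fold`,
#'   and `background_ratio` (expected IP/FT RPM ratio of non-enriched
#'   genes, < 1 when anything is enriched).
#' @export
simulate_ripseq_counts <- function(annot, enriched_genes, fold = 2,
                                   n_reps = 2L, dispersion = 0.1,
                                   lib_size = 1e6, abund_sdlog = 1,
                                   seed = 1L) {
  stopifnot(fold > 0, n_reps >= 2)
  genes <- annot$gene_id
  if (!all(enriched_genes %in% genes))
    .fail("enriched_genes not in annotation: %s",
          paste(setdiff(enriched_genes, genes), collapse = ", "))
  .with_seed(seed)
  n <- length(genes)
  w <- stats::rlnorm(n, meanlog = 0, sdlog = abund_sdlog)
  w <- w / sum(w)                          # baseline abundance profile
  is_enr <- genes %in% enriched_genes
  w_enr <- sum(w[is_enr])
  f_mass <- sum(w[is_enr] * fold)
  if (f_mass >= 1)
    .fail(paste("enriched mass x fold (%.2f) reaches the whole library;",
                "reduce fold or the enriched set"), f_mass)
  # deflate the background so enriched genes keep an IP/FT RPM ratio of
  # exactly `fold` while the expected IP total stays at lib_size
  bg_ratio <- (1 - f_mass) / (1 - w_enr)
  ip_w <- ifelse(is_enr, w * fold, w * bg_ratio)
  mu <- list(IP = ip_w * lib_size,
             FT = w * lib_size,
             TOT = w * lib_size)
  draw <- function(mu_arm) {
    m <- vapply(seq_len(n_reps), function(r) {
      if (dispersion > 0)
        stats::rnbinom(n, mu = mu_arm, size = 1 / dispersion)
      else stats::rpois(n, mu_arm)
    }, numeric(n))
    storage.mode(m) <- "integer"
    m
  }
  counts <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (arm in names(mu)) {
    m <- draw(mu[[arm]])
    colnames(m) <- sprintf("%s_%d", arm, seq_len(n_reps))
    counts <- cbind(counts, as.data.frame(m))
  }
  list(counts = counts, enriched = enriched_genes, fold = fold,
       background_ratio = bg_ratio)
}
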