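#' Fraction of G-body-forming cells in a mixed competition culture
#'
#' Inverts the mixing relation
#' `%mix = f * %GB+ + (1 - f) * %GB-` to
#' `f_GB+ = (%mix - %GB-) / (%GB+ - %GB-)`. Estimates pushed outside
#' `[0, 1]` by sampling noise are clipped with a flag. When cell-level
#' counts are available (as from [simulate_competition()]), a bootstrap
#' interval over resampled binomial counts is attached.
#'
#' @param obs a `competition_obs` or list with `pct_mix`, `pct_gb_plus`,
#'   `pct_gb_minus` and optionally `counts`/`n_cells`.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the interval).
#' @param conf interval coverage (default 0.95).
#' @param seed integer seed for the bootstrap.
#' @return list: `estimate`, `clipped`, `ci` (or `NULL`), `n_boot`.
#' @export
fraction_gb_plus <- function(obs, n_boot = 1000L, conf = 0.95, seed = 1L) {
  denom <- obs$pct_gb_plus - obs$pct_gb_minus
  if (denom == 0) .fail("non-identifiable: pct_gb_plus equals pct_gb_minus")
  f_raw <- (obs$pct_mix - obs$pct_gb_minus) / denom
  clipped <- f_raw < 0 || f_raw > 1
  if (clipped)
    warning(sprintf("estimate %.4f outside [0, 1]; clipped", f_raw))
  est <- min(max(f_raw, 0), 1)
  ci <- NULL
  if (n_boot > 0 && !is.null(obs$counts) && !is.null(obs$n_cells)) {
    .with_seed(seed)
    n <- obs$n_cells
    p <- obs$counts / n
    fb <- vapply(seq_len(n_boot), function(i) {
      k <- stats::rbinom(3L, n, p)
      d <- (k[2] - k[3])
      if (d == 0) return(NA_real_)
      min(max((k[1] - k[3]) / d, 0), 1)
    }, numeric(1))
    ci <- stats::quantile(fb, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE)
  }
  list(estimate = est, raw = f_raw, clipped = clipped, ci = ci,
       n_boot = n_boot)
}

#' Generations of growth from optical density
#'
#' `n = log2(OD_end / OD_start)`.
#'
#' @param od_start,od_end optical densities; both must be positive and
#'   `od_end >= od_start`.
#' @return number of generations.
#' @export
generations <- function(od_start, od_end) {
  if (any(od_start <= 0) || any(od_end <= 0))
    .fail("optical densities must be positive")
  if (any(od_end < od_start)) .fail("od_end must be >= od_start")
  log2(od_end / od_start)
}
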