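#' Two-sample Kolmogorov-Smirnov statistic
#'
#' \eqn{D = \sup_t |ECDF_x(t) - ECDF_y(t)|} evaluated over the pooled
#' sample points (tie-safe). This is the statistic driving the empirical
#' RPM threshold selection; no p-value is attached because the procedure
#' only tracks the statistic's plateau.
#'
#' @param x,y non-empty numeric samples.
#' @return the statistic `D` in `[0, 1]`.
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y)) .fail("both samples must be non-empty")
  ks_stat_cpp(as.numeric(x), as.numeric(y))
}

#' Assemble PAR-CLIP binding sites from aligned reads
#'
#' Reads carrying more than two T-to-C conversions are discarded, then
#' maximal sets of transitively overlapping same-strand reads are merged
#' into one site spanning their union. Each site's RPM is the mean
#' per-position read coverage over the site, divided by `total_mapped/1e6`.
#' Sites without a single conversion-bearing read are dropped (the
#' high-confidence requirement).
#'
#' @param reads aligned-read table (`chrom`, `start`, `end`,
#'   `conversion_count`, `strand`, ...), 0-based half-open.
#' @param total_mapped total mapped reads in the library; defaults to
#'   `attr(reads, "total_mapped")`.
#' @param max_conversions reads with more conversions are excluded before
#'   aggregation (default 2).
#' @param dataset_id label attached to the sites.
#' @return `data.frame` of binding sites: `chrom`, `start`, `end`,
#'   `strand`, `rpm`, `n_conversion_reads`, `n_reads`, `dataset`.
#' @export
assemble_binding_sites <- function(reads, total_mapped = NULL,
                                   max_conversions = 2L,
                                   dataset_id = NULL) {
  if (is.null(total_mapped)) total_mapped <- attr(reads, "total_mapped")
  if (is.null(total_mapped)) .fail("total_mapped must be supplied")
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      rpm = numeric(), n_conversion_reads = integer(),
                      n_reads = integer(), dataset = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(reads)) return(empty)
  if (any(reads$start < 0)) .fail("reads: negative coordinates")
  if (total_mapped < nrow(reads))
    .fail("total_mapped (%s) is smaller than the number of reads (%d)",
          format(total_mapped), nrow(reads))
  if (is.null(dataset_id))
    dataset_id <- if ("dataset" %in% names(reads) && nrow(reads))
      reads$dataset[1] else "ds"
  reads <- reads[reads$conversion_count <= max_conversions, , drop = FALSE]
  if (!nrow(reads)) return(empty)
  out <- list()
  for (key in unique(paste(reads$chrom, reads$strand))) {
    sel <- paste(reads$chrom, reads$strand) == key
    r <- reads[sel, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end) # to 1-based closed
    red <- IRanges::reduce(ir)
    comp <- S4Vectors::subjectHits(IRanges::findOverlaps(ir, red))
    width_sum <- tapply(IRanges::width(ir), comp, sum)
    conv_n <- tapply(r$conversion_count >= 1L, comp, sum)
    n_reads <- tabulate(comp, nbins = length(red))
    idx <- as.integer(names(width_sum))
    mean_cov <- as.numeric(width_sum) / IRanges::width(red)[idx]
    out[[key]] <- data.frame(
      chrom = r$chrom[1],
      start = IRanges::start(red)[idx] - 1L,
      end = IRanges::end(red)[idx],
      strand = r$strand[1],
      rpm = mean_cov / (total_mapped / 1e6),
      n_conversion_reads = as.integer(conv_n),
      n_reads = n_reads[idx],
      dataset = dataset_id,
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, out)
  sites <- sites[sites$n_conversion_reads >= 1L, , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$start, sites$end), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Empirical RPM threshold by subsampling K-S stabilization
#'
#' For each candidate threshold `t` in `grid`, the sites with `rpm >= t` are
#' kept and two independent subsamples, each containing `frac` of the
#' surviving sites, are drawn `n_iter` times; the mean two-sample K-S
#' statistic between the subsample RPM distributions is recorded. The
#' chosen threshold is the first grid value at which the mean statistic has
#' stabilized: it changes by less than `rel_tol` (relative) over each of
#' the next `window` grid steps. Subsamples are drawn without replacement
#' and independently of each other (they may overlap).
#'
#' @param rpm numeric vector of binding-site RPM values (or a site table
#'   with an `rpm` column).
#' @param grid candidate thresholds; default 36 values spanning 0-25.
#' @param n_iter subsampling repeats per threshold (default 10000).
#' @param frac subsample fraction (default 0.20).
#' @param rel_tol,window stabilization tolerance and look-ahead (defaults
#'   2% over 3 grid steps).
#' @param min_pass minimum sites that must pass the smallest grid value
#'   (default 25, so a 20% subsample has at least 5 elements).
#' @param seed integer seed; the curve is deterministic given
#'   `(grid, n_iter, frac, seed)`.
#' @return a list of class `threshold_curve`: `grid`, `mean_stat`,
#'   `n_sites`, `chosen`, `n_iter`, `frac`, `rel_tol`, `window`, `seed`.
#' @export
empirical_rpm_threshold <- function(rpm, grid = seq(0, 25, length.out = 36),
                                    n_iter = 10000L, frac = 0.20,
                                    rel_tol = 0.02, window = 3L,
                                    min_pass = 25L, seed = 1L) {
  if (is.data.frame(rpm)) rpm <- rpm$rpm
  stopifnot(is.numeric(rpm), all(diff(grid) > 0), frac > 0, frac <= 1)
  n0 <- sum(rpm >= grid[1])
  if (n0 < min_pass)
    .fail("only %d sites pass the smallest grid value (%.3g); need >= %d",
          n0, grid[1], min_pass)
  if (n_iter < 100)
    warning(sprintf(
      "n_iter = %d: the mean K-S curve will be unstable; interpret the chosen threshold with caution",
      n_iter))
  .with_seed(seed)
  res <- ks_subsample_curve_cpp(sort(as.numeric(rpm)), as.numeric(grid),
                                as.integer(n_iter), frac)
  mean_stat <- res[, 1]
  n_sites <- as.integer(res[, 2])
  chosen <- NA_real_
  for (i in seq_along(grid)) {
    if (is.na(mean_stat[i])) next
    js <- i + seq_len(window)
    if (max(js) > length(grid) || anyNA(mean_stat[js])) next # window incomplete
    base <- mean_stat[i]
    if (base == 0 || all(abs(mean_stat[js] - base) / base < rel_tol)) {
      chosen <- grid[i]; break
    }
  }
  if (is.na(chosen)) {
    warning("K-S statistic never stabilized on the grid; using last valid value")
    chosen <- grid[max(which(!is.na(mean_stat)))]
  }
  structure(list(grid = grid, mean_stat = mean_stat, n_sites = n_sites,
                 chosen = chosen, n_iter = n_iter, frac = frac,
                 rel_tol = rel_tol, window = window, seed = seed),
            class = "threshold_curve")
}

#' Apply an RPM threshold to a site table
#'
#' Keeps sites with `rpm >= threshold`. Filtering is monotone: raising the
#' threshold never adds a site.
#'
#' @param sites a binding-site table with an `rpm` column.
#' @param threshold RPM threshold.
#' @return the filtered site table.
#' @export
filter_sites_rpm <- function(sites, threshold) {
  sites[sites$rpm >= threshold, , drop = FALSE]
}
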