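#' Plant ground-truth PAR-CLIP binding sites on a toy annotation
#'
#' Chooses signal and noise site intervals inside genes and records the
#' per-class coverage scales and per-read crosslink conversion probabilities.
#' Signal coverage must exceed noise coverage so that the planted truth is
#' separable by construction.
#'
#' @param annot a [make_annotation()] table.
#' @param n_signal,n_noise numbers of signal / noise sites.
#' @param site_length site length in nt.
#' @param signal_coverage,noise_coverage mean per-position read coverage of
#'   signal and noise sites (signal > noise required).
#' @param conv_prob probability that a read over a planted site carries at
#'   least one T-to-C conversion (crosslink signature).
#' @param bg_conv_prob per-read conversion probability for background reads.
#'   The study does not report a background conversion rate; the default
#'   corresponds to a 0.5% per-T error over a 30 nt read with ~25% T content.
#' @param dataset_id label stored with the reads.
#' @param seed integer seed.
#' @return a list of class `site_truth` with elements `sites` (data.frame of
#'   planted intervals with a `kind` column), `signal_coverage`,
#'   `noise_coverage`, `conv_prob`, `bg_conv_prob`, `dataset_id`.
#' @export
plant_site_truth <- function(annot, n_signal = 20L, n_noise = 40L,
                             site_length = 40L,
                             signal_coverage = 50, noise_coverage = 2,
                             conv_prob = 0.8,
                             bg_conv_prob = 1 - (1 - 0.005)^7.5,
                             dataset_id = "ds1", seed = 1L) {
  stopifnot(signal_coverage > noise_coverage, conv_prob >= 0, conv_prob <= 1)
  .with_seed(seed)
  n <- n_signal + n_noise
  genes <- annot[sample.int(nrow(annot), n, replace = TRUE), ]
  usable <- (genes$end - genes$start) - site_length
  if (any(usable < 1)) .fail("site_length %d exceeds some gene lengths", site_length)
  off <- vapply(usable, function(u) sample.int(u, 1L), integer(1))
  sites <- data.frame(
    chrom = genes$chrom,
    start = genes$start + off,
    end = genes$start + off + site_length,
    strand = genes$strand,
    kind = rep(c("signal", "noise"), c(n_signal, n_noise)),
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, signal_coverage = signal_coverage,
                 noise_coverage = noise_coverage, conv_prob = conv_prob,
                 bg_conv_prob = bg_conv_prob, dataset_id = dataset_id),
            class = "site_truth")
}

#' Simulate an aligned PAR-CLIP read table with planted binding sites
#'
#' Reads over planted sites are placed uniformly inside the site interval
#' (so the mean per-position coverage over the site equals the planted
#' coverage scale in expectation) and carry T-to-C conversions with the
#' planted per-read probability; conversion-bearing reads record 1-3
#' conversions. Remaining reads up to `total_reads` are scattered uniformly
#' over the chromosome on random strands with the background conversion
#' rate. The output is coordinate-sorted.
#'
#' @param annot a [make_annotation()] table.
#' @param truth a [plant_site_truth()] record.
#' @param total_reads total mapped reads in the library, the denominator of
#'   all RPM values. The toy annotation is one window of the genome, so only
#'   the planted and background reads land on it; `total_reads` must be at
#'   least that number.
#' @param read_length read length in nt; must not exceed the site length.
#' @param bg_coverage mean background read coverage over the chromosome
#'   (default 0.1x, a sparse non-specific floor).
#' @param seed integer seed.
#' @return a `data.frame` with the 8 columns of the aligned-read dialect:
#'   `chrom`, `start`, `end`, `name`, `conversion_count`, `strand`,
#'   `read_length`, `dataset`, plus `attr(, "total_mapped")`.
#' @export
simulate_parclip_reads <- function(annot, truth, total_reads = 1e6L,
                                   read_length = 30L, bg_coverage = 0.1,
                                   seed = 1L) {
  stopifnot(inherits(truth, "site_truth"))
  sites <- truth$sites
  site_len <- sites$end - sites$start
  if (any(read_length > site_len))
    .fail("read_length %d exceeds a planted site length %d",
          read_length, min(site_len))
  .with_seed(seed)
  cov_scale <- ifelse(sites$kind == "signal",
                      truth$signal_coverage, truth$noise_coverage)
  # n reads per site so that E[mean coverage over site positions] = cov_scale:
  # contained reads give mean coverage n * L / S over the S site positions
  n_per_site <- stats::rpois(nrow(sites), cov_scale * site_len / read_length)
  rows <- vector("list", nrow(sites) + 1L)
  for (i in seq_len(nrow(sites))) {
    n <- n_per_site[i]
    if (n == 0L) { rows[[i]] <- NULL; next }
    start <- sites$start[i] +
      sample.int(site_len[i] - read_length + 1L, n, replace = TRUE) - 1L
    has_conv <- stats::rbinom(n, 1L, truth$conv_prob)
    conv <- has_conv * (1L + stats::rbinom(n, 2L, 0.15))
    rows[[i]] <- data.frame(chrom = sites$chrom[i], start = start,
                            end = start + read_length,
                            conversion_count = conv,
                            strand = sites$strand[i],
                            stringsAsFactors = FALSE)
  }
  n_planted <- sum(n_per_site)
  clen <- attr(annot, "chrom_lengths")[[1]]
  n_bg <- stats::rpois(1, bg_coverage * clen / read_length)
  if (n_planted + n_bg > total_reads)
    .fail("planted + background reads (%d) exceed total_reads = %d",
          n_planted + n_bg, total_reads)
  if (n_bg > 0) {
    start <- sample.int(clen - read_length, n_bg, replace = TRUE) - 1L
    conv <- stats::rbinom(n_bg, 1L, truth$bg_conv_prob)
    rows[[nrow(sites) + 1L]] <- data.frame(
      chrom = names(attr(annot, "chrom_lengths"))[1], start = start,
      end = start + read_length, conversion_count = conv,
      strand = sample(c("+", "-"), n_bg, replace = TRUE),
      stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  reads <- reads[order(reads$chrom, reads$start, reads$end), , drop = FALSE]
  reads <- data.frame(chrom = reads$chrom, start = reads$start,
                      end = reads$end,
                      name = sprintf("read%07d", seq_len(nrow(reads))),
                      conversion_count = reads$conversion_count,
                      strand = reads$strand,
                      read_length = as.integer(read_length),
                      dataset = truth$dataset_id,
                      stringsAsFactors = FALSE)
  attr(reads, "total_mapped") <- as.integer(total_reads)
  reads
}

#' Planted RPM mixture for threshold-selection experiments
#'
#' Draws binding-site RPM values from a two-component mixture: low-coverage
#' noise sites with RPM ~ Exp(mean `noise_mean`) and genuine signal sites
#' with RPM ~ `signal_offset` + Exp(mean `signal_mean`). The defaults give a
#' background-dominated site list (most called sites are low-coverage), the
#' regime the empirical RPM threshold exists to clean up.
#'
#' @param n_noise,n_signal component sizes.
#' @param noise_mean exponential mean of the noise component (RPM).
#' @param signal_offset,signal_mean offset and exponential mean of the
#'   signal component (RPM).
#' @param seed integer seed.
#' @return a list with `rpm` (numeric vector), `is_signal` (logical vector)
#'   and the component parameters.
#' @export
simulate_rpm_mixture <- function(n_noise = 400L, n_signal = 100L,
                                 noise_mean = 1, signal_offset = 10,
                                 signal_mean = 5, seed = 1L) {
  .with_seed(seed)
  rpm <- c(stats::rexp(n_noise, 1 / noise_mean),
           signal_offset + stats::rexp(n_signal, 1 / signal_mean))
  list(rpm = rpm,
       is_signal = rep(c(FALSE, TRUE), c(n_noise, n_signal)),
       noise_mean = noise_mean, signal_offset = signal_offset,
       signal_mean = signal_mean)
}
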