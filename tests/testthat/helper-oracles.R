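# Independent brute-force oracles used to check the fast implementations.
# These deliberately avoid IRanges / sorting tricks: per-position arrays,
# connected components by scanning, and double-loop ECDF suprema.

# per-position coverage oracle for binding-site assembly
oracle_sites <- function(reads, total_mapped, max_conversions = 2L) {
  reads <- reads[reads$conversion_count <= max_conversions, , drop = FALSE]
  out <- list()
  for (chrom in unique(reads$chrom)) for (strand in c("+", "-")) {
    r <- reads[reads$chrom == chrom & reads$strand == strand, , drop = FALSE]
    if (!nrow(r)) next
    lim <- max(r$end) + 1L
    cov <- integer(lim)
    conv <- integer(lim)   # conversion-read starts, for site attribution
    for (i in seq_len(nrow(r))) {
      span <- (r$start[i] + 1L):r$end[i]   # 1-based positions
      cov[span] <- cov[span] + 1L
    }
    # connected components of covered positions
    covered <- which(cov > 0)
    if (!length(covered)) next
    brk <- c(0L, which(diff(covered) > 1L), length(covered))
    for (k in seq_len(length(brk) - 1L)) {
      span <- covered[(brk[k] + 1L):brk[k + 1L]]
      s0 <- span[1] - 1L; e0 <- span[length(span)]
      inside <- r$start >= s0 & r$end <= e0
      n_conv <- sum(inside & r$conversion_count >= 1L)
      if (n_conv < 1L) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = s0, end = e0, strand = strand,
        rpm = mean(cov[span]) / (total_mapped / 1e6),
        n_conversion_reads = n_conv, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      rpm = numeric(), n_conversion_reads = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

# double-loop ECDF supremum oracle for the two-sample K-S statistic
oracle_ks <- function(x, y) {
  pts <- c(x, y)
  max(vapply(pts, function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# random aligned-read fixture (contained reads, both strands, 2 chroms)
random_reads <- function(n = 200L, seed = 1L) {
  set.seed(seed)
  start <- sample.int(2000L, n, replace = TRUE) - 1L
  len <- sample(20:40, n, replace = TRUE)
  data.frame(chrom = sample(c("chrI", "chrII"), n, replace = TRUE),
             start = start, end = start + len,
             name = sprintf("r%04d", seq_len(n)),
             conversion_count = sample(0:4, n, replace = TRUE,
                                       prob = c(.4, .3, .15, .1, .05)),
             strand = sample(c("+", "-"), n, replace = TRUE),
             read_length = len, dataset = "fx",
             stringsAsFactors = FALSE)
}

# noiseless rendered patch for fit tests
render_patch <- function(side, b, A, x0, y0, sx, sy, theta) {
  xs <- rep(seq_len(side), each = side)
  ys <- rep(seq_len(side), side)
  matrix(gaussian2d(xs, ys, b, A, x0, y0, sx, sy, theta), side, side)
}
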