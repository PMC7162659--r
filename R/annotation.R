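#' Build a toy genome annotation
#'
#' Places `n_genes` non-overlapping genes on a single chromosome, each with a
#' 5'UTR, CDS and 3'UTR contiguous in transcription order on the annotated
#' strand. A fraction of genes are flagged as non-coding RNAs (their whole
#' span counts as the ncRNA category; UTR/CDS subdivision is ignored for
#' them). All coordinates are 0-based half-open.
#'
#' @param n_genes number of genes to place (>= 1).
#' @param chrom_length chromosome length in nt.
#' @param utr_lengths length-2 vector: 5'UTR and 3'UTR lengths in nt.
#' @param cds_range range the CDS length is drawn from, in nt.
#' @param ncrna_frac fraction of genes flagged as ncRNA.
#' @param seed integer seed; the annotation is deterministic given the seed.
#' @return a `data.frame` of class `toy_annotation` with one row per gene and
#'   columns `gene_id`, `chrom`, `strand`, `start`, `end`, `utr5_start`,
#'   `utr5_end`, `cds_start`, `cds_end`, `utr3_start`, `utr3_end`,
#'   `is_ncRNA`; chromosome lengths are stored in `attr(, "chrom_lengths")`.
#' @export
make_annotation <- function(n_genes, chrom_length,
                            utr_lengths = c(100L, 200L),
                            cds_range = c(300L, 1500L),
                            ncrna_frac = 0.1,
                            seed = 1L) {
  stopifnot(n_genes >= 1, chrom_length > 0, length(utr_lengths) == 2)
  .with_seed(seed)
  u5 <- as.integer(utr_lengths[1]); u3 <- as.integer(utr_lengths[2])
  cds_len <- sample(seq(cds_range[1], cds_range[2]), n_genes, replace = TRUE)
  gene_len <- u5 + cds_len + u3
  min_gap <- 10L
  need <- sum(gene_len) + (n_genes + 1L) * min_gap
  if (need > chrom_length)
    .fail("cannot place %d genes (need %d nt) on a %d nt chromosome",
          n_genes, need, chrom_length)
  # distribute the slack uniformly over the n_genes + 1 gaps
  slack <- chrom_length - need
  extra <- if (slack > 0) {
    cuts <- sort(sample.int(slack + 1L, n_genes + 1L, replace = TRUE) - 1L)
    diff(c(0L, cuts, slack))[seq_len(n_genes + 1L)]
  } else rep(0L, n_genes + 1L)
  gaps <- min_gap + extra
  starts <- cumsum(gaps[seq_len(n_genes)]) + c(0L, cumsum(gene_len))[seq_len(n_genes)]
  ends <- starts + gene_len
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  if (n_genes >= 2 && length(unique(strand)) == 1L)
    strand[1] <- setdiff(c("+", "-"), strand[1])   # both strands represented
  is_nc <- stats::runif(n_genes) < ncrna_frac
  # genomic extents of each region; on the minus strand the 5'UTR is rightmost
  utr5_start <- ifelse(strand == "+", starts, ends - u5)
  utr5_end <- ifelse(strand == "+", starts + u5, ends)
  cds_start <- ifelse(strand == "+", starts + u5, starts + u3)
  cds_end <- ifelse(strand == "+", ends - u3, ends - u5)
  utr3_start <- ifelse(strand == "+", ends - u3, starts)
  utr3_end <- ifelse(strand == "+", ends, starts + u3)
  ann <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(n_genes)),
    chrom = "chrI", strand = strand,
    start = as.integer(starts), end = as.integer(ends),
    utr5_start = as.integer(utr5_start), utr5_end = as.integer(utr5_end),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    utr3_start = as.integer(utr3_start), utr3_end = as.integer(utr3_end),
    is_ncRNA = is_nc,
    stringsAsFactors = FALSE
  )
  attr(ann, "chrom_lengths") <- c(chrI = as.integer(chrom_length))
  class(ann) <- c("toy_annotation", "data.frame")
  ann
}

#' Genic region of a genomic position
#'
#' Maps 0-based positions to `{5'UTR, CDS, 3'UTR, ncRNA, intergenic}` against
#' a toy annotation. Assignment is strand-aware: a position only annotates to
#' a gene on the same strand.
#'
#' @param annot a [make_annotation()] table.
#' @param chrom,pos,strand vectors describing the positions.
#' @param utr_fallback length-2 UTR extents (nt) granted to genes whose
#'   annotated UTR length is zero, mirroring the hierarchical UTR fallback
#'   used for ORFs lacking UTR annotation.
#' @return character vector of region labels.
#' @export
region_of_position <- function(annot, chrom, pos, strand,
                               utr_fallback = c(50L, 100L)) {
  n <- length(pos)
  out <- rep("intergenic", n)
  for (i in seq_len(n)) {
    g <- annot[annot$chrom == chrom[i] & annot$strand == strand[i] &
                 annot$start <= pos[i] & pos[i] < annot$end, , drop = FALSE]
    if (nrow(g) == 0L) next
    g <- g[1L, ]
    if (isTRUE(g$is_ncRNA)) { out[i] <- "ncRNA"; next }
    u5 <- c(g$utr5_start, g$utr5_end); u3 <- c(g$utr3_start, g$utr3_end)
    if (u5[2] - u5[1] <= 0) {                     # fallback 5'UTR extent
      u5 <- if (g$strand == "+") c(g$cds_start - utr_fallback[1], g$cds_start)
            else c(g$cds_end, g$cds_end + utr_fallback[1])
    }
    if (u3[2] - u3[1] <= 0) {
      u3 <- if (g$strand == "+") c(g$cds_end, g$cds_end + utr_fallback[2])
            else c(g$cds_start - utr_fallback[2], g$cds_start)
    }
    out[i] <- if (pos[i] >= u5[1] && pos[i] < u5[2]) "5'UTR"
      else if (pos[i] >= g$cds_start && pos[i] < g$cds_end) "CDS"
      else if (pos[i] >= u3[1] && pos[i] < u3[2]) "3'UTR"
      else "CDS" # interior positions not captured by extents collapse to CDS
  }
  out
}

# internal: gene id containing a midpoint (same strand), NA if none
.gene_of_position <- function(annot, chrom, pos, strand) {
  out <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    hit <- which(annot$chrom == chrom[i] & annot$strand == strand[i] &
                   annot$start <= pos[i] & pos[i] < annot$end)
    if (length(hit)) out[i] <- annot$gene_id[hit[1]]
  }
  out
}
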