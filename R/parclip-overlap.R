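#' Classify binding sites by cross-dataset overlap
#'
#' Each site is labeled `identical` if another dataset contains a
#' same-strand site whose both endpoints match within `identical_tol` nt,
#' else `overlapping` if it intersects at least 1 nt of any other dataset's
#' same-strand site, else `unique`. The three labels partition every site.
#'
#' @param site_sets named list of binding-site tables (one per dataset).
#' @param identical_tol endpoint tolerance in nt for the `identical` class
#'   (default 0 = exact endpoint equality).
#' @return a list with `labels` (the input tables with a `overlap_class`
#'   column added) and `percentages` (per dataset x class table).
#' @export
classify_site_overlap <- function(site_sets, identical_tol = 0L) {
  stopifnot(is.list(site_sets), !is.null(names(site_sets)))
  if (length(site_sets) < 2)
    warning("single dataset: every site is 'unique'")
  labels <- lapply(names(site_sets), function(ds) {
    s <- site_sets[[ds]]
    any_ident <- logical(nrow(s))
    any_olap <- logical(nrow(s))
    for (other in setdiff(names(site_sets), ds)) {
      o <- site_sets[[other]]
      for (key in unique(paste(s$chrom, s$strand))) {
        qi <- which(paste(s$chrom, s$strand) == key)
        sj <- which(paste(o$chrom, o$strand) == key)
        if (!length(qi) || !length(sj)) next
        qr <- IRanges::IRanges(s$start[qi] + 1L, s$end[qi])
        sr <- IRanges::IRanges(o$start[sj] + 1L, o$end[sj])
        hits <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
        qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
        ident <- abs(s$start[qi][qh] - o$start[sj][sh]) <= identical_tol &
          abs(s$end[qi][qh] - o$end[sj][sh]) <= identical_tol
        any_ident[qi[qh[ident]]] <- TRUE
        any_olap[qi[qh]] <- TRUE
      }
    }
    s$overlap_class <- ifelse(any_ident, "identical",
                              ifelse(any_olap, "overlapping", "unique"))
    s
  })
  names(labels) <- names(site_sets)
  pct <- t(vapply(labels, function(s) {
    tab <- table(factor(s$overlap_class,
                        levels = c("identical", "overlapping", "unique")))
    100 * as.numeric(tab) / max(1L, nrow(s))
  }, numeric(3)))
  colnames(pct) <- c("identical", "overlapping", "unique")
  list(labels = labels, percentages = pct)
}

#' Annotate binding sites with genic regions
#'
#' Assigns each site to `{5'UTR, CDS, 3'UTR, ncRNA, intergenic}` by its
#' midpoint (strand-aware) and reports the RPM-weighted fraction of signal
#' in each annotated category, normalized to sum to 1 over the four
#' annotated categories (intergenic signal is reported separately).
#'
#' @param sites binding-site table.
#' @param annot a [make_annotation()] table.
#' @param utr_fallback UTR extents for genes lacking annotated UTRs.
#' @return a list with `sites` (input plus `region` and `gene_id` columns)
#'   and `region_fractions` (named numeric over the annotated categories).
#' @export
annotate_sites <- function(sites, annot, utr_fallback = c(50L, 100L)) {
  clen <- attr(annot, "chrom_lengths")
  bad <- !(sites$chrom %in% names(clen)) |
    sites$end > clen[sites$chrom]
  if (any(bad, na.rm = TRUE)) .fail("site beyond all chromosomes")
  mid <- .midpoint(sites$start, sites$end)
  sites$region <- region_of_position(annot, sites$chrom, mid, sites$strand,
                                     utr_fallback)
  sites$gene_id <- .gene_of_position(annot, sites$chrom, mid, sites$strand)
  cats <- c("5'UTR", "CDS", "3'UTR", "ncRNA")
  w <- tapply(sites$rpm, factor(sites$region, levels = cats), sum)
  w[is.na(w)] <- 0
  frac <- if (sum(w) > 0) w / sum(w) else w
  list(sites = sites, region_fractions = frac)
}

#' Binding-site RPM vs gene-expression RPKM enrichment
#'
#' Computes per-site `log10(site RPM / gene RPKM)` and compares the ratios
#' between overlap classes with two-sided unpaired t-tests (Welch by
#' default). Sites mapping to genes with missing or non-positive RPKM are
#' excluded and counted.
#'
#' @param sites annotated site table with `gene_id`, `rpm` and (optionally)
#'   `overlap_class` columns.
#' @param rpkm `data.frame` with `gene_id` and `rpkm` columns.
#' @param pooled_var use the pooled-variance (classic Student) t-test
#'   instead of Welch.
#' @return list with `per_site` (sites plus `log_ratio`), `n_excluded`,
#'   and `tests` (data.frame of pairwise class comparisons, when classes
#'   are present).
#' @export
site_expression_enrichment <- function(sites, rpkm, pooled_var = FALSE) {
  if (!all(c("gene_id", "rpkm") %in% names(rpkm)))
    .fail("rpkm table must have gene_id and rpkm columns")
  m <- match(sites$gene_id, rpkm$gene_id)
  g_rpkm <- rpkm$rpkm[m]
  ok <- !is.na(g_rpkm) & g_rpkm > 0 & !is.na(sites$gene_id)
  n_excluded <- sum(!ok)
  per <- sites[ok, , drop = FALSE]
  per$log_ratio <- log10(per$rpm / g_rpkm[ok])
  tests <- NULL
  if ("overlap_class" %in% names(per) &&
      length(unique(per$overlap_class)) >= 2) {
    cl <- unique(per$overlap_class)
    pairs <- utils::combn(cl, 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(p) {
      a <- per$log_ratio[per$overlap_class == p[1]]
      b <- per$log_ratio[per$overlap_class == p[2]]
      if (length(a) < 2 || length(b) < 2)
        return(data.frame(class_a = p[1], class_b = p[2],
                          t = NA_real_, p = NA_real_))
      tt <- stats::t.test(a, b, var.equal = pooled_var)
      data.frame(class_a = p[1], class_b = p[2],
                 t = unname(tt$statistic), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
  }
  list(per_site = per, n_excluded = n_excluded, tests = tests)
}

#' Bound-gene target sets and their intersections
#'
#' A gene is a target of a dataset iff at least one (thresholded,
#' high-confidence) site annotates to it. Reports every Venn region count
#' for two or three datasets.
#'
#' @param site_sets named list of annotated site tables (with `gene_id`).
#' @return list with `targets` (named list of gene-id vectors) and
#'   `venn` (named counts of each exclusive region plus the full
#'   intersection/union).
#' @export
target_gene_sets <- function(site_sets) {
  targets <- lapply(site_sets, function(s)
    sort(unique(stats::na.omit(s$gene_id))))
  nms <- names(targets)
  k <- length(targets)
  venn <- list()
  if (k >= 2) {
    all_genes <- unique(unlist(targets))
    member <- vapply(targets, function(t) all_genes %in% t, logical(length(all_genes)))
    if (length(all_genes) == 1L) member <- matrix(member, nrow = 1)
    pattern <- apply(member, 1, function(r) paste(nms[r], collapse = "&"))
    venn <- as.list(table(pattern))
    venn[["union"]] <- length(all_genes)
    venn[["intersection_all"]] <- sum(rowSums(member) == k)
  }
  list(targets = targets, venn = venn)
}
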