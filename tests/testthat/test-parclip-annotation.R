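mk_sites <- function(start, end, strand = "+", rpm = 1, chrom = "chrI",
                     dataset = "d") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), strand = strand, rpm = rpm,
             n_conversion_reads = 1L, dataset = dataset,
             stringsAsFactors = FALSE)
}

test_that("overlap classes cover the identical / overlapping / unique cases", {
  a <- mk_sites(100, 150)
  b <- mk_sites(100, 150)
  res <- classify_site_overlap(list(A = a, B = b), identical_tol = 0)
  expect_equal(res$labels$A$overlap_class, "identical")
  expect_equal(res$labels$B$overlap_class, "identical")

  a <- mk_sites(100, 150); b <- mk_sites(140, 190)
  res <- classify_site_overlap(list(A = a, B = b))
  expect_equal(res$labels$A$overlap_class, "overlapping")
  expect_equal(res$labels$B$overlap_class, "overlapping")

  # same interval, opposite strands: unique (strand-aware)
  b2 <- mk_sites(100, 150, strand = "-")
  res <- classify_site_overlap(list(A = a, B = b2))
  expect_equal(res$labels$A$overlap_class, "unique")
  expect_warning(classify_site_overlap(list(A = a)), "single dataset")
})

test_that("overlap labels equal an all-pairs brute-force comparison on random fixtures", {
  set.seed(31)
  rand_sites <- function(n) {
    st <- sample.int(1000, n) - 1L
    mk_sites(st, st + sample(20:60, n, replace = TRUE),
             strand = sample(c("+", "-"), n, replace = TRUE))
  }
  sets <- list(A = rand_sites(40), B = rand_sites(40), C = rand_sites(40))
  res <- classify_site_overlap(sets, identical_tol = 0)
  for (ds in names(sets)) {
    s <- sets[[ds]]
    for (i in seq_len(nrow(s))) {
      ident <- FALSE; olap <- FALSE
      for (other in setdiff(names(sets), ds)) {
        o <- sets[[other]]
        for (j in seq_len(nrow(o))) {
          if (s$strand[i] != o$strand[j] || s$chrom[i] != o$chrom[j]) next
          if (s$start[i] == o$start[j] && s$end[i] == o$end[j]) ident <- TRUE
          if (min(s$end[i], o$end[j]) - max(s$start[i], o$start[j]) >= 1)
            olap <- TRUE
        }
      }
      want <- if (ident) "identical" else if (olap) "overlapping" else "unique"
      expect_equal(res$labels[[ds]]$overlap_class[i], want)
    }
  }
})

test_that("genic-region annotation assigns by midpoint and weights fractions by RPM", {
  ann <- make_annotation(8, 40000, utr_lengths = c(100, 200),
                         ncrna_frac = 0, seed = 3)
  g <- ann[ann$strand == "+", ][1, ]
  in_utr3 <- mk_sites(g$utr3_start + 10, g$utr3_start + 40, strand = g$strand)
  res <- annotate_sites(in_utr3, ann)
  expect_equal(res$sites$region, "3'UTR")
  expect_equal(res$sites$gene_id, g$gene_id)

  # all-ncRNA fixture: ncRNA fraction is exactly 1
  annN <- make_annotation(4, 20000, ncrna_frac = 1, seed = 4)
  sN <- mk_sites(annN$start + 50, annN$start + 90, strand = annN$strand)
  resN <- annotate_sites(sN, annN)
  expect_equal(unname(resN$region_fractions[["ncRNA"]]), 1)
  expect_equal(sum(resN$region_fractions), 1, tolerance = 1e-9)

  expect_error(annotate_sites(mk_sites(1e6, 1e6 + 50), ann), "beyond")
})

test_that("RPM-weighted region fractions equal a hand tally and sum to one", {
  ann <- make_annotation(12, 60000, utr_lengths = c(150, 250),
                         ncrna_frac = 0.25, seed = 9)
  set.seed(10)
  gidx <- sample.int(nrow(ann), 30, replace = TRUE)
  off <- vapply(gidx, function(i)
    sample.int(ann$end[i] - ann$start[i] - 30L, 1L), integer(1))
  sites <- mk_sites(ann$start[gidx] + off, ann$start[gidx] + off + 30L,
                    strand = ann$strand[gidx], rpm = runif(30, 0.5, 20))
  res <- annotate_sites(sites, ann)
  tal <- tapply(res$sites$rpm,
                factor(res$sites$region,
                       levels = c("5'UTR", "CDS", "3'UTR", "ncRNA")), sum)
  tal[is.na(tal)] <- 0
  expect_equal(as.numeric(res$region_fractions),
               as.numeric(tal / sum(tal)), tolerance = 1e-12)
  expect_equal(sum(res$region_fractions), 1, tolerance = 1e-9)
})

test_that("site/gene expression ratios hit the closed forms and power the class t-test", {
  s <- mk_sites(c(0, 100), c(50, 150))
  s$gene_id <- c("g1", "g2"); s$rpm <- c(5, 50)
  rpkm <- data.frame(gene_id = c("g1", "g2"), rpkm = c(5, 5))
  res <- site_expression_enrichment(s, rpkm)
  expect_equal(res$per_site$log_ratio, c(0, 1))
  expect_error(site_expression_enrichment(s, data.frame(x = 1)), "gene_id")

  # planted class difference: 0 vs 0.5 in log10 ratio, sd 0.3, n = 100
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 100
    sd0 <- 0.3
    sA <- mk_sites(seq_len(n) * 100, seq_len(n) * 100 + 50)
    sA$gene_id <- sprintf("a%03d", 1:n); sA$overlap_class <- "unique"
    sB <- sA; sB$gene_id <- sprintf("b%03d", 1:n); sB$overlap_class <- "identical"
    rpkm <- data.frame(gene_id = c(sA$gene_id, sB$gene_id), rpkm = 1)
    sA$rpm <- 10^rnorm(n, 0, sd0); sB$rpm <- 10^rnorm(n, 0.5, sd0)
    res <- site_expression_enrichment(rbind(sA, sB), rpkm)
    if (res$tests$p[1] < 1e-9) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.95)
})

test_that("target gene sets and Venn counts follow set algebra", {
  s1 <- mk_sites(c(0, 100), c(50, 150)); s1$gene_id <- c("g1", "g2")
  s2 <- mk_sites(c(0, 100), c(50, 150)); s2$gene_id <- c("g1", "g2")
  res <- target_gene_sets(list(A = s1, B = s2))
  expect_equal(res$venn$intersection_all, 2L)
  expect_equal(res$venn$union, 2L)

  s3 <- s2; s3$gene_id <- c("g3", "g4")
  res2 <- target_gene_sets(list(A = s1, B = s3))
  expect_equal(res2$venn$intersection_all, 0L)

  set.seed(12)
  pools <- lapply(1:3, function(i) sample(sprintf("g%02d", 1:30), 15))
  sets <- lapply(pools, function(g) {
    s <- mk_sites(seq_along(g) * 10, seq_along(g) * 10 + 5)
    s$gene_id <- g; s
  })
  names(sets) <- c("A", "B", "C")
  res3 <- target_gene_sets(sets)
  expect_equal(res3$venn$intersection_all,
               length(Reduce(intersect, pools)))
  expect_equal(res3$venn$union, length(Reduce(union, pools)))
  # every exclusive region adds up to the union
  excl <- res3$venn[setdiff(names(res3$venn), c("union", "intersection_all"))]
  expect_equal(sum(unlist(excl)), res3$venn$union)
})
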