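# Overlap, distance and enrichment statistics.

test_that("overlap fractions and matched-null p-values behave at the extremes", {
  sizes <- c(chr1 = 100000L)
  q <- gintervals("chr1", c(1000L, 21000L, 41000L, 61000L),
                  c(2000L, 22000L, 42000L, 62000L))
  feats <- gintervals("chr1", 1500L, 1600L)
  r <- overlap_fraction_with_null(q, feats, sizes, n_random = 99, seed = 1)
  expect_equal(r$fraction, 0.25)
  expect_equal(r$n_overlapping, 1L)

  # features covering almost everything: observed 1, enrichment p maximal...
  dense <- gintervals("chr1", seq(0L, 99000L, 500L), seq(400L, 99400L, 500L))
  r2 <- overlap_fraction_with_null(q, dense, sizes, n_random = 99, seed = 1)
  expect_equal(r2$fraction, 1)
  # ...and a feature-free query set is maximally depleted
  far <- gintervals("chr1", 90000L, 90100L)
  r3 <- overlap_fraction_with_null(q, far, sizes, n_random = 199, seed = 1)
  expect_equal(r3$fraction, 0)
  expect_lte(r3$p_deplete, 1)
  expect_gte(r3$p_enrich, 0.5)

  # slop extends the features symmetrically
  near <- gintervals("chr1", 2300L, 2400L)  # 300 bp beyond the first query
  expect_equal(overlap_fraction_with_null(q, near, sizes, n_random = 9,
                                          slop = 0, seed = 1)$n_overlapping, 0L)
  expect_equal(overlap_fraction_with_null(q, near, sizes, n_random = 9,
                                          slop = 500, seed = 1)$n_overlapping, 1L)

  # random intervals avoid the exclusion set
  excl <- gintervals("chr1", 0L, 95000L)
  r4 <- overlap_fraction_with_null(q, feats, sizes, n_random = 19,
                                   exclude = excl, seed = 2)
  expect_equal(r4$expected_fraction, 0)   # only [95000,100000) is free
  expect_error(overlap_fraction_with_null(q, feats, sizes, n_random = 0))
})

test_that("clusters are assigned to the nearest gene below the distance cap", {
  genes <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                      start = c(10000L, 60000L, 200000L),
                      end = c(15000L, 65000L, 205000L),
                      strand = "+", is_protein_coding = TRUE)
  genes$tss <- genes$start; genes$tes <- genes$end - 1L
  cl <- gintervals("chr1", c(20000L, 110000L, 230000L),
                   c(21000L, 111000L, 231000L))
  a <- assign_to_genes(cl, genes, max_dist = 20000L)
  expect_equal(a$gene_id, c("gA", NA, NA))     # 5 kb vs 39 kb; desert; 25 kb
  expect_equal(a$distance[1], 5000L)
  expect_false(a$assigned[3])                  # 25 kb > cap (strict <)

  # equidistant genes: nearer TSS wins, then the smaller id
  g2 <- data.frame(gene_id = c("gZ", "gA2"), chrom = "chr1",
                   start = c(1000L, 21000L), end = c(6000L, 26000L),
                   strand = c("-", "+"), is_protein_coding = TRUE)
  g2$tss <- ifelse(g2$strand == "+", g2$start, g2$end - 1L)
  g2$tes <- ifelse(g2$strand == "+", g2$end - 1L, g2$start)
  mid <- gintervals("chr1", 11000L, 16000L)    # 5 kb from both bodies
  a2 <- assign_to_genes(mid, g2, max_dist = 20000L)
  # gZ TSS at 5999 is 7.5 kb from the midpoint; gA2 TSS at 21000 is 7.5 kb:
  # TSS tie too -> lexicographically smaller id
  expect_equal(a2$gene_id, "gA2")

  # deterministic and stable under permutation of the gene table
  a3 <- assign_to_genes(mid, g2[2:1, ], max_dist = 20000L)
  expect_equal(a3$gene_id, a2$gene_id)
})

test_that("gene-class enrichment matches the exact binomial oracle", {
  # 9 of 10 assignments inducible against an expected fraction of 0.3
  g <- gene_class_enrichment(rep(c("inducible", "constitutive"), c(9, 1)),
                             rep(c("inducible", "constitutive", "repressed"),
                                 c(30, 40, 30)))
  row <- g[g$class == "inducible", ]
  expect_equal(row$direction, "over")
  expect_equal(row$p_one_sided, 1.436859e-4, tolerance = 1e-6)
  expect_equal(row$expected_fraction, 0.3)

  # observed equal to expected: non-significant
  e <- gene_class_enrichment(rep(c("a", "b"), c(3, 7)),
                             rep(c("a", "b"), c(30, 70)))
  expect_equal(e$direction, c("n.s.", "n.s."))
  expect_true(all(e$p_two_sided > 0.5))

  # oracle equivalence across many small configurations
  set.seed(19)
  for (rep in 1:60) {
    n <- sample(5:30, 1); k <- sample(0:n, 1); p0 <- runif(1, 0.05, 0.95)
    labels <- rep(c("x", "y"), c(k, n - k))
    pos <- rep(c("x", "y"), round(c(p0, 1 - p0) * 1000))
    got <- gene_class_enrichment(labels, pos)
    p0r <- sum(pos == "x") / length(pos)
    expect_equal(got$p_two_sided[got$class == "x"],
                 oracle_binom_two_sided(k, n, p0r), tolerance = 1e-12)
  }
  expect_error(gene_class_enrichment(character(), "a"))
})

test_that("nearest-peak distance distributions match an exhaustive scan", {
  cl <- gintervals("chr1", 1000L, 1100L)
  pk <- gintervals("chr1", 1350L, 1400L)
  d <- distance_to_nearest_distribution(cl, pk)
  expect_equal(d$median, 250)

  ov <- distance_to_nearest_distribution(gintervals("chr1", c(0L, 100L),
                                                    c(50L, 150L)),
                                         gintervals("chr1", 0L, 200L))
  expect_equal(ov$median, 0)

  set.seed(29)
  cls <- gintervals(sample(c("chr1", "chr2"), 40, TRUE),
                    s <- as.integer(runif(40, 0, 1e5)), s + 200L)
  pks <- gintervals("chr1", t <- as.integer(runif(25, 0, 1e5)), t + 100L)
  got <- distance_to_nearest_distribution(cls, pks)
  for (i in seq_len(40)) {
    if (cls$chrom[i] != "chr1") { expect_true(is.na(got$distances[i])); next }
    gaps <- pmax(0L, pmax(pks$start - cls$end[i], cls$start[i] - pks$end))
    expect_equal(got$distances[i], min(gaps))
  }
  expect_equal(got$n_none, sum(cls$chrom == "chr2"))
})

test_that("intra-region CAGE spacing takes the median of consecutive midpoints", {
  region <- gintervals("chr1", 0L, 2000L)
  cage <- gintervals("chr1", c(90L, 290L, 890L), c(110L, 310L, 910L))
  r <- median_intra_region_cage_distance(region, cage)
  expect_equal(r$status, "ok")
  expect_equal(r$median, 400)   # consecutive distances 200 and 600

  one <- median_intra_region_cage_distance(region, cage[1, ])
  expect_equal(one$status, "single")
  none <- median_intra_region_cage_distance(region,
                                            gintervals("chr1", 5000L, 5100L))
  expect_equal(none$status, "none")

  # sort-and-diff oracle on random placements
  set.seed(37)
  for (rep in 1:40) {
    k <- sample(2:12, 1)
    mids <- sort(sample(seq(10L, 1990L, 2L), k))
    cc <- gintervals("chr1", mids - 5L, mids + 5L)
    got <- median_intra_region_cage_distance(region, cc)
    expect_equal(got$median, median(diff(sort(mids))))
  }

  s <- cage_spacing_summary(rbind(region, gintervals("chr1", 5000L, 6000L)),
                            cage)
  expect_equal(s$status, c("ok", "none"))
})

test_that("RNA-seq support splits clusters and recovers a planted Pol II ratio", {
  cl <- gintervals("chr1", seq(0L, 99000L, 1000L)[1:80],
                   seq(0L, 99000L, 1000L)[1:80] + 800L)
  supported <- rep(c(TRUE, FALSE), 40)
  set.seed(47)
  # supported clusters get 30x the Pol II tag rate
  pol_tags <- unlist(lapply(seq_len(80), function(i) {
    n <- rpois(1, if (supported[i]) 300 else 10)
    as.integer(runif(n, cl$start[i], cl$end[i]))
  }))
  rna_tags <- unlist(lapply(which(supported), function(i)
    as.integer(runif(3, cl$start[i], cl$end[i]))))
  r <- tag_support_comparison(cl, tt1(rna_tags), tt1(pol_tags))
  expect_equal(r$supported, supported)
  expect_equal(r$log10_ratio, log10(30), tolerance = 0.08)

  nos <- tag_support_comparison(cl[2, ], tt1(rna_tags), tt1(pol_tags))
  expect_false(nos$supported)
})
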