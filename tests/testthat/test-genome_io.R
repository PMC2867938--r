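test_that("read_bed parses BED records, skips headers and keeps half-open coordinates", {
  p <- tmp_text(c("track name=test", "# a comment",
                  "chr1\t100\t200", "chr1\t300\t450\tx\t7\t-"))
  bed <- read_bed(p)
  expect_equal(nrow(bed), 2L)
  expect_equal(bed$start, c(100L, 300L))
  expect_equal(bed$end, c(200L, 450L))
  expect_equal(bed$strand, c(".", "-"))
  expect_equal(bed$score[2], 7)

  expect_equal(nrow(read_bed(tmp_text(character()))), 0L)
  expect_error(read_bed(tmp_text("chr1\t200\t100")), "line 1")
  expect_error(read_bed(tmp_text("chr1\tabc\t100")), "line 1")
  expect_error(read_bed(tmp_text("chr1\t100\t200"), min_columns = 6), "field")
})

test_that("write_bed / read_bed round-trip is the identity on coordinates", {
  set.seed(42)
  s <- sort(sample.int(1e6, 30))
  x <- gintervals(sample(c("chr1", "chr2"), 30, TRUE), s, s + sample(1e4, 30),
                  strand = sample(c("+", "-", "."), 30, TRUE),
                  name = sprintf("r%d", 1:30), score = runif(30))
  p <- tempfile(fileext = ".bed")
  write_bed(x, p, comment = "round trip")
  y <- read_bed(p, min_columns = 6)
  expect_equal(y[, c("chrom", "start", "end", "strand")],
               x[, c("chrom", "start", "end", "strand")])
})

test_that("gene tables apply strand-aware TSS/TES rules and reject duplicates", {
  p <- tmp_text(c("gene_id\tchrom\tstart\tend\tstrand\tis_protein_coding",
                  "g1\tchr1\t1000\t2000\t+\t1",
                  "g2\tchr1\t1000\t2000\t-\t1"))
  g <- read_gene_table(p)
  expect_equal(g$tss, c(1000L, 1999L))
  expect_equal(g$tes, c(1999L, 1000L))
  expect_equal(g$is_protein_coding, c(TRUE, TRUE))

  dup <- tmp_text(c("gene_id\tchrom\tstart\tend\tstrand\tis_protein_coding",
                    "g1\tchr1\t0\t10\t+\t1", "g1\tchr1\t50\t60\t-\t0"))
  expect_error(read_gene_table(dup), "duplicate")
  expect_error(read_gene_table(p, dialect = "nope"))

  ens <- tmp_text(c("gene_id\tchrom\tstart\tend\tstrand\tbiotype",
                    "E1\tchr2\t101\t200\t1\tprotein_coding",
                    "E2\tchr2\t301\t400\t-1\tlincRNA"))
  e <- read_gene_table(ens, dialect = "ensembl")
  expect_equal(e$start, c(100L, 300L))  # converted to 0-based
  expect_equal(e$is_protein_coding, c(TRUE, FALSE))
  expect_equal(e$strand, c("+", "-"))
})

test_that("tag tracks take the strand-aware 5' position and stay sorted", {
  p <- tmp_text(c("chr1\t500\t536\t.\t0\t-",
                  "chr1\t100\t136\t.\t0\t+",
                  "chr1\t50\t86\t.\t0\t+"))
  tr <- read_tag_track(p)
  expect_equal(tr$library_size, 3L)
  expect_equal(tr$positions$chr1, c(50L, 100L, 535L))  # sorted; minus-strand 5' = end-1
  expect_error(read_tag_track(tmp_text(character())), "no tags")
})

test_that("count_tags respects half-open bounds and is additive over partitions", {
  tr <- tt1(c(100L, 150L, 200L))
  expect_equal(count_tags(tr, gintervals("chr1", 100, 200)), 2L)
  expect_equal(count_tags(tr, gintervals("chr1", 100, 201)), 3L)
  expect_equal(count_tags(tt1(integer()), gintervals("chr1", 0, 10)), 0L)
  expect_message(
    expect_equal(count_tags(tr, gintervals("chrX", 0, 1000)), 0L),
    "chrX")

  set.seed(7)
  pos <- sort(as.integer(runif(5000, 0, 1e6)))
  tr <- tt1(pos)
  cuts <- sort(as.integer(runif(9, 1, 1e6 - 1)))
  parts <- gintervals("chr1", c(0L, cuts), c(cuts, 1e6L))
  expect_equal(sum(count_tags(tr, parts)),
               count_tags(tr, gintervals("chr1", 0, 1e6)))
})

test_that("count_tags matches a linear-scan oracle on random instances", {
  set.seed(11)
  pos <- sort(as.integer(runif(10000, 0, 1e6)))
  tr <- tt1(pos)
  for (rep in 1:120) {
    a <- as.integer(runif(1, 0, 9e5)); b <- a + as.integer(runif(1, 1, 1e5))
    expect_identical(count_tags(tr, gintervals("chr1", a, b)),
                     sum(pos >= a & pos < b))
  }
})

test_that("merge_intervals honours the boundary gap and matches the quadratic oracle", {
  x <- gintervals("chr1", c(100L, 250L), c(200L, 300L))
  expect_equal(nrow(merge_intervals(x, max_gap = 50L)), 1L)
  expect_equal(merge_intervals(x, max_gap = 50L)$end, 300L)
  expect_equal(nrow(merge_intervals(x, max_gap = 49L)), 2L)

  set.seed(3)
  for (rep in 1:5) {
    n <- 100L
    s <- as.integer(runif(n, 0, 5e4))
    x <- gintervals(sample(c("chr1", "chr2"), n, TRUE), s,
                    s + as.integer(runif(n, 1, 800)))
    gap <- sample(c(0L, 10L, 100L, 1000L), 1)
    got <- merge_intervals(x, max_gap = gap)
    exp <- oracle_merge(as.data.frame(x), gap)
    expect_equal(got$chrom, exp$chrom)
    expect_equal(got$start, exp$start)
    expect_equal(got$end, exp$end)
    # idempotence
    again <- merge_intervals(got, max_gap = gap)
    expect_equal(again[, c("chrom", "start", "end")],
                 got[, c("chrom", "start", "end")])
    # every input contained in exactly one output
    hits <- vapply(seq_len(n), function(i)
      sum(got$chrom == x$chrom[i] & got$start <= x$start[i] &
            got$end >= x$end[i]), integer(1))
    expect_true(all(hits == 1L))
  }
})

test_that("merge_intervals with members partitions the inputs", {
  x <- gintervals("chr1", c(0L, 50L, 500L), c(40L, 100L, 600L))
  m <- merge_intervals(x, max_gap = 10L, with_members = TRUE)
  expect_equal(nrow(m), 2L)
  expect_equal(sort(unlist(m$members)), 1:3)
  expect_equal(sort(m$members[[1]]), c(1L, 2L))
})

test_that("nearest_distance gives boundary gaps, zero on overlap, NA off-chromosome", {
  q <- gintervals("chr1", 1000, 1100)
  expect_equal(nearest_distance(q, gintervals("chr1", 1300, 1400)), 200L)
  expect_equal(nearest_distance(q, gintervals("chr1", 1050, 1500)), 0L)
  expect_true(is.na(nearest_distance(q, gintervals("chr9", 0, 10))))

  set.seed(5)
  subs <- gintervals("chr1", s <- as.integer(runif(50, 0, 1e5)),
                     s + as.integer(runif(50, 1, 500)))
  for (rep in 1:100) {
    a <- as.integer(runif(1, 0, 1e5)); q <- gintervals("chr1", a, a + 200L)
    gaps <- pmax(0L, pmax(subs$start - q$end, q$start - subs$end))
    expect_equal(nearest_distance(q, subs), min(gaps))
  }
})

test_that("JASPAR matrices parse into unit-sum probability columns", {
  p <- tmp_text(c(">M1 testmotif", "A [ 10 0 0 5 ]", "C [ 0 10 0 5 ]",
                  "G [ 0 0 10 5 ]", "T [ 0 0 0 5 ]"))
  pw <- read_jaspar(p)
  expect_equal(names(pw), "M1")
  expect_equal(ncol(pw$M1$prob), 4L)
  expect_true(all(abs(colSums(pw$M1$prob) - 1) < 1e-9))
  expect_equal(unname(pw$M1$prob["A", 1]), 10.01 / 10.04)
  expect_error(read_jaspar(tmp_text(c(">M1", "A [ 1 1 1 ]", "C [ 1 1 1 ]",
                                      "G [ 1 1 1 ]", "T [ 1 1 1 ]"))),
               "length >= 4")
})

test_that("conservation tracks validate scores and average regions correctly", {
  bg <- tmp_text(c("chr1\t0\t10\t0.8", "chr1\t10\t20\t0.4"))
  tr <- read_conservation(bg, c(chr1 = 30L))
  expect_equal(region_mean_conservation(tr, gintervals("chr1", 0, 10)), 0.8)
  expect_equal(region_mean_conservation(tr, gintervals("chr1", 5, 15)), 0.6)
  # bases 20-30 are missing: excluded from the mean
  expect_equal(region_mean_conservation(tr, gintervals("chr1", 10, 30)), 0.4)
  expect_true(is.na(region_mean_conservation(tr, gintervals("chr1", 20, 30))))
  expect_error(read_conservation(tmp_text("chr1\t0\t10\t1.5"), c(chr1 = 30L)),
               "\\[0, 1\\]")
})
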