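# Profile extraction and the enhancer/promoter signature classifier.

test_that("profiles bin tags around the summit with unit-sum normalisation", {
  me1 <- tt1(c(1500L))          # single tag exactly at the summit
  me3 <- tt1(integer())
  p <- extract_profile(me1, me3, "chr1", 1500L)
  expect_length(p$me1_bins, 50L)
  expect_equal(p$me1_bins[26], 1)   # bin 26 covers [summit, summit+100)
  expect_equal(sum(p$me1_bins), 1)
  expect_true(p$zero_me3)
  expect_false(p$zero_me1)

  z <- extract_profile(tt1(integer()), tt1(integer()), "chr1", 5000L)
  expect_true(z$zero_me1 && z$zero_me3)
  expect_equal(sum(z$me1_bins) + sum(z$me3_bins), 0)

  near_edge <- extract_profile(me1, me3, "chr1", 1000L)
  expect_true(near_edge$truncated)
})

test_that("binned profiles equal a per-tag assignment oracle", {
  set.seed(41)
  pos <- as.integer(runif(1000, 0, 10000))
  me1 <- tt1(pos)
  summit <- 5000L
  p <- extract_profile(me1, tt1(integer()), "chr1", summit)
  oracle <- numeric(50)
  for (t in pos) {
    b <- (t - (summit - 2500L)) %/% 100L + 1L
    if (b >= 1 && b <= 50) oracle[b] <- oracle[b] + 1
  }
  oracle <- oracle / me1$library_size * 1e6
  oracle <- oracle / sum(oracle)
  expect_equal(p$me1_bins, oracle, tolerance = 1e-12)
})

test_that("profile extraction is translation-equivariant and depth-invariant", {
  set.seed(43)
  pos <- as.integer(runif(300, 2000, 8000))
  delta <- 12345L
  a <- extract_profile(tt1(pos), tt1(pos + 3L), "chr1", 5000L)
  b <- extract_profile(tt1(pos + delta), tt1(pos + 3L + delta), "chr1",
                       5000L + delta)
  expect_equal(a$me1_bins, b$me1_bins)
  expect_equal(a$me3_bins, b$me3_bins)
  # doubling every tag leaves the unit-sum shape unchanged
  dbl <- extract_profile(tt1(rep(pos, 2)), tt1(rep(pos + 3L, 2)), "chr1", 5000L)
  expect_equal(a$me1_bins, dbl$me1_bins, tolerance = 1e-12)
})

# seeded synthetic training profiles: enhancers have broad bimodal me1 and
# weak me3; promoters a sharp central me3 with flanking me1
make_profiles <- function(n_per_class, seed, n_tags = 40) {
  withr::with_seed(seed, {
    mk <- function(class) {
      center <- 50000
      if (class == "enhancer") {
        me1 <- rnorm(n_tags, center + sample(c(-1000, 1000), n_tags, TRUE), 500)
        me3 <- rnorm(max(1, rpois(1, n_tags * 0.15)),
                     center + sample(c(-1000, 1000), 3, TRUE), 600)
      } else {
        me3 <- rnorm(n_tags, center, 300)
        me1 <- rnorm(max(1, rpois(1, n_tags * 0.4)),
                     center + sample(c(-800, 800), n_tags, TRUE), 400)
      }
      p <- extract_profile(tt1(as.integer(me1)), tt1(as.integer(me3)),
                           "chr1", center)
      c(p$me1_bins, p$me3_bins)
    }
    X <- rbind(t(vapply(seq_len(n_per_class), function(i) mk("enhancer"),
                        numeric(100))),
               t(vapply(seq_len(n_per_class), function(i) mk("promoter"),
                        numeric(100))))
    colnames(X) <- c(sprintf("me1_%02d", 1:50), sprintf("me3_%02d", 1:50))
    list(X = X, labels = factor(rep(c("enhancer", "promoter"),
                                    each = n_per_class)))
  })
}

test_that("linearly separable me1- vs me3-dominant profiles give perfect CV accuracy", {
  sep <- withr::with_seed(12, {
    mk <- function(mark) {
      tags <- as.integer(rnorm(40, 50000, 600))
      p <- extract_profile(tt1(if (mark == "me1") tags else integer()),
                           tt1(if (mark == "me3") tags else integer()),
                           "chr1", 50000L)
      c(p$me1_bins, p$me3_bins)
    }
    X <- rbind(t(replicate(30, mk("me1"))), t(replicate(30, mk("me3"))))
    colnames(X) <- c(sprintf("me1_%02d", 1:50), sprintf("me3_%02d", 1:50))
    list(X = X, labels = factor(rep(c("enhancer", "promoter"), each = 30)))
  })
  m <- train_signature_classifier(sep, seed = 1)
  expect_equal(mean(m$cv_accuracy, na.rm = TRUE), 1)
})

test_that("held-out profiles with Poisson noise are classified accurately with few abstentions", {
  tr <- make_profiles(40, seed = 2)
  m <- train_signature_classifier(tr, seed = 1)
  held <- make_profiles(30, seed = 99)
  pr <- predict_signature(m, held$X)
  decided <- pr$class != "unpredictable"
  expect_gte(mean(pr$class[decided] == as.character(held$labels)[decided]), 0.95)
  expect_lte(mean(pr$class == "unpredictable"), 0.10)
})

test_that("training is deterministic and permuted labels give chance accuracy", {
  tr <- make_profiles(30, seed = 3)
  m1 <- train_signature_classifier(tr, seed = 7)
  m2 <- train_signature_classifier(tr, seed = 7)
  expect_identical(m1$w, m2$w)
  expect_identical(m1$band, m2$band)

  accs <- vapply(1:20, function(s) {
    perm <- tr
    perm$labels <- withr::with_seed(1000 + s, sample(tr$labels))
    mean(train_signature_classifier(perm, seed = s)$cv_accuracy, na.rm = TRUE)
  }, numeric(1))
  expect_equal(mean(accs), 0.5, tolerance = 0.06)
})

test_that("degenerate training sets are rejected", {
  X <- rbind(matrix(0.02, 10, 100), matrix(runif(1000), 10, 100))
  colnames(X) <- sprintf("f%03d", 1:100)
  tr <- list(X = X, labels = factor(rep(c("enhancer", "promoter"), each = 10)))
  expect_error(train_signature_classifier(tr), "degenerate")
})

test_that("prediction applies the abstention band and zero-signal rule", {
  tr <- make_profiles(40, seed = 5)
  m <- train_signature_classifier(tr, seed = 1)
  expect_gt(m$band, 0)
  # class centroids are confidently classified
  enh_centroid <- colMeans(tr$X[tr$labels == "enhancer", ])
  prom_centroid <- colMeans(tr$X[tr$labels == "promoter", ])
  expect_equal(predict_signature(m, rbind(enh_centroid))$class, "enhancer")
  expect_equal(predict_signature(m, rbind(prom_centroid))$class, "promoter")
  # all-zero profile: zero-signal rule
  expect_equal(predict_signature(m, rbind(rep(0, 100)),
                                 zero_signal = TRUE)$class, "unpredictable")
  # a score exactly at the decision boundary falls inside the band
  hand <- m
  hand$w <- rep(0, 100); hand$b <- 0
  expect_equal(predict_signature(hand, rbind(enh_centroid))$class,
               "unpredictable")
  expect_error(predict_signature(m, matrix(0, 1, 10)), "features")
})

test_that("model serialisation round-trips predictions exactly", {
  tr <- make_profiles(25, seed = 6)
  m <- train_signature_classifier(tr, seed = 1)
  f <- tempfile(fileext = ".tsv")
  write_signature_model(m, f)
  m2 <- read_signature_model(f)
  expect_equal(m2$w, m$w)
  expect_equal(m2$band, m$band)
  probe <- make_profiles(10, seed = 55)$X
  expect_identical(predict_signature(m, probe)$class,
                   predict_signature(m2, probe)$class)
  expect_equal(predict_signature(m, probe)$score,
               predict_signature(m2, probe)$score, tolerance = 1e-12)
})

test_that("balanced training sets are sampled reproducibly from candidate pools", {
  set.seed(8)
  centers <- as.integer(seq(20000, 380000, length.out = 30))
  p300 <- gintervals("chr1", centers - 150L, centers + 150L)
  tss <- data.frame(chrom = "chr1",
                    pos = as.integer(seq(10000, 390000, length.out = 25)) + 3L)
  me1 <- tt1(as.integer(runif(5000, 0, 4e5)))
  me3 <- tt1(as.integer(runif(5000, 0, 4e5)))
  tr1 <- build_training_set(p300, tss, me1, me3, n_per_class = 10,
                            min_tss_dist = 0L, seed = 3)
  tr2 <- build_training_set(p300, tss, me1, me3, n_per_class = 10,
                            min_tss_dist = 0L, seed = 3)
  expect_equal(table(tr1$labels), table(factor(rep(c("enhancer", "promoter"),
                                                   each = 10))))
  expect_identical(tr1$X, tr2$X)
  expect_error(build_training_set(p300, tss, me1, me3, n_per_class = 100),
               "informative|exemplars")
  # informative filter: p300 peaks near a TSS are excluded from the pool
  near_tss <- gintervals("chr1", tss$pos - 100L, tss$pos + 100L)
  expect_error(build_training_set(near_tss, tss, me1, me3, n_per_class = 5,
                                  min_tss_dist = 2500L), "informative")
})

test_that("predicted promoters are validated against annotated TSSs", {
  preds <- data.frame(chrom = "chr1",
                      summit = c(1000L, 1200L, 50000L, 90000L),
                      class = c("promoter", "promoter", "enhancer", "promoter"))
  tss <- data.frame(chrom = "chr1", pos = c(1100L, 89000L))
  fr <- validate_against_tss(preds, tss, half_window = 2500L)
  expect_equal(unname(fr["promoter"]), 1)
  expect_equal(unname(fr["enhancer"]), 0)
  none <- validate_against_tss(preds, data.frame(chrom = "chrX", pos = 1L))
  expect_equal(unname(none["promoter"]), 0)
})
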