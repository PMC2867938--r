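# Enhancer-vs-promoter classification from H3K4me1/H3K4me3 shapes in a 5 kb
# summit-centred window. Profiles are binned tag densities normalised to
# tags-per-million then unit sum per mark: the discriminative feature is the
# me1/me3 *pattern* (broad me1-high domains at enhancers versus a sharp
# me3-dominant peak at TSSs), not its amplitude. The decision function is a
# linear max-margin classifier with an abstention band that produces the
# third, "unpredictable" class.

#' Extract a binned H3K4me1/H3K4me3 profile around a summit
#'
#' Bin `i` (0-based) covers `[summit - window_half_bp + i * bin_bp, ... +
#' bin_bp)`. Counts are scaled to tags-per-million of each mark's library and
#' then rescaled to unit sum per mark; a mark without any signal in the
#' window stays all-zero and is flagged.
#'
#' @param me1,me3 [tag_track] objects for H3K4me1 and H3K4me3.
#' @param chrom,summit Chromosome and summit position (0-based) of the peak.
#' @param window_half_bp Half-window (bp); window is `2 * window_half_bp`.
#' @param bin_bp Bin width (bp); must divide `window_half_bp`.
#' @return List with `me1_bins`, `me3_bins` (numeric vectors of
#'   `2 * window_half_bp / bin_bp` entries each), `zero_me1`, `zero_me3`
#'   flags and a `truncated` flag (window crossing the chromosome start).
#' @export
extract_profile <- function(me1, me3, chrom, summit, window_half_bp = 2500L,
                            bin_bp = 100L) {
  stopifnot(window_half_bp %% bin_bp == 0L)
  nb <- 2L * window_half_bp %/% bin_bp
  bounds <- summit - window_half_bp + (0:nb) * bin_bp
  one <- function(track) {
    pos <- track$positions[[chrom]]
    if (is.null(pos) || track$library_size == 0L) return(numeric(nb))
    diff(findInterval(bounds - 1L, pos)) / track$library_size * 1e6
  }
  v1 <- one(me1); v3 <- one(me3)
  s1 <- sum(v1); s3 <- sum(v3)
  if (s1 > 0) v1 <- v1 / s1
  if (s3 > 0) v3 <- v3 / s3
  list(me1_bins = v1, me3_bins = v3, zero_me1 = s1 == 0, zero_me3 = s3 == 0,
       truncated = summit - window_half_bp < 0L)
}

#' Profile matrix for a set of summits
#'
#' @param me1,me3 [tag_track] objects.
#' @param summits Data frame with columns `chrom` and `summit`.
#' @inheritParams extract_profile
#' @return List with `X` (n x 2*nbins matrix, columns `me1_*` then `me3_*`)
#'   and `zero_signal` (logical: both marks empty in the window).
#' @export
profile_matrix <- function(me1, me3, summits, window_half_bp = 2500L,
                           bin_bp = 100L) {
  nb <- 2L * window_half_bp %/% bin_bp
  n <- nrow(summits)
  X <- matrix(0, n, 2L * nb,
              dimnames = list(NULL, c(sprintf("me1_%02d", seq_len(nb)),
                                      sprintf("me3_%02d", seq_len(nb)))))
  zero <- logical(n)
  for (i in seq_len(n)) {
    p <- extract_profile(me1, me3, summits$chrom[i], summits$summit[i],
                         window_half_bp, bin_bp)
    X[i, ] <- c(p$me1_bins, p$me3_bins)
    zero[i] <- p$zero_me1 && p$zero_me3
  }
  list(X = X, zero_signal = zero)
}

#' Assemble a balanced enhancer/promoter training set
#'
#' Enhancer exemplars are "informative" p300 peaks — those at least
#' `min_tss_dist` bp from any annotated TSS, so that their window cannot
#' overlap promoter chromatin. Promoter exemplars are sampled uniformly
#' (seeded) from the supplied TSS list. Both classes contribute exactly
#' `n_per_class` profiles.
#'
#' @param p300_peaks A [gintervals] frame of p300 peaks.
#' @param tss Data frame with columns `chrom` and `pos` (annotated TSSs).
#' @param me1,me3 [tag_track] objects.
#' @param n_per_class Profiles per class.
#' @param min_tss_dist Minimum p300-to-TSS distance (bp) for "informative".
#' @param seed Integer seed for the (uniform) sampling of both classes.
#' @inheritParams extract_profile
#' @return List with `X`, `labels` (factor enhancer/promoter), `zero_signal`,
#'   and the sampled exemplar coordinates.
#' @export
build_training_set <- function(p300_peaks, tss, me1, me3, n_per_class,
                               min_tss_dist = 2500L, seed = 1L,
                               window_half_bp = 2500L, bin_bp = 100L) {
  stopifnot(nrow(tss) > 0L)
  centers <- p300_peaks$start + (p300_peaks$end - p300_peaks$start) %/% 2L
  informative <- vapply(seq_len(nrow(p300_peaks)), function(i) {
    tt <- tss[tss$chrom == p300_peaks$chrom[i], , drop = FALSE]
    !nrow(tt) || min(abs(tt$pos - centers[i])) >= min_tss_dist
  }, logical(1))
  enh_pool <- data.frame(chrom = p300_peaks$chrom[informative],
                         summit = centers[informative])
  tss_pool <- data.frame(chrom = tss$chrom, summit = tss$pos)
  if (nrow(enh_pool) < n_per_class)
    stop(sprintf("only %d informative p300 peaks for n_per_class = %d",
                 nrow(enh_pool), n_per_class))
  if (nrow(tss_pool) < n_per_class)
    stop(sprintf("only %d TSS exemplars for n_per_class = %d",
                 nrow(tss_pool), n_per_class))
  sel <- withr::with_seed(seed, list(
    enh = sample(nrow(enh_pool), n_per_class),
    tss = sample(nrow(tss_pool), n_per_class)))
  exemplars <- rbind(enh_pool[sel$enh, ], tss_pool[sel$tss, ])
  pm <- profile_matrix(me1, me3, exemplars, window_half_bp, bin_bp)
  list(X = pm$X,
       labels = factor(rep(c("enhancer", "promoter"), each = n_per_class),
                       levels = c("enhancer", "promoter")),
       zero_signal = pm$zero_signal,
       exemplars = exemplars)
}

#' Train the linear max-margin signature classifier
#'
#' Fits a linear-kernel support-vector machine on the concatenated
#' `[me1 bins, me3 bins]` features, records 5-fold cross-validation
#' accuracies (seeded fold assignment), and calibrates the abstention band
#' as the `band_quantile` quantile of the absolute decision scores of
#' correctly classified training profiles: test profiles scoring inside
#' `(-band, +band)` are left "unpredictable". The calibration scores are
#' taken out-of-fold (each profile scored by the model that did not see
#' it): in-sample scores of a max-margin fit concentrate at the margin
#' (+-1) and misstate the spread that held-out profiles actually have.
#'
#' @param training Output of [build_training_set] (or a list with `X` and
#'   `labels`).
#' @param seed Integer seed (fold assignment).
#' @param nfolds Number of cross-validation folds.
#' @param cost SVM cost parameter. Profiles have unit sum, so individual
#'   bins are of order `1/nbins`; the default keeps the margin penalty from
#'   dominating at that feature scale.
#' @param band_quantile Quantile defining the abstention band.
#' @return Object of class `"signature_model"`: weights `w`, intercept `b`,
#'   `band`, `positive_class`, `cv_accuracy` per fold, `seed`.
#' @export
train_signature_classifier <- function(training, seed = 1L, nfolds = 5L,
                                       cost = 100, band_quantile = 0.05) {
  X <- training$X
  y <- droplevels(factor(training$labels))
  if (nlevels(y) != 2L) stop("training set must contain exactly two classes")
  constant_class <- vapply(split(seq_along(y), y), function(i)
    nrow(unique(X[i, , drop = FALSE])) == 1L, logical(1))
  if (any(constant_class))
    stop("degenerate training set: class ",
         paste(names(constant_class)[constant_class], collapse = ", "),
         " has a constant profile")
  positive_class <- levels(y)[1L]
  # oriented linear weights: positive decision score <=> positive_class
  oriented_wb <- function(fit, Xfit) {
    w <- as.vector(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    s <- as.vector(Xfit %*% w) + b
    pred <- as.character(stats::predict(fit, Xfit))
    other <- setdiff(levels(y), positive_class)
    agree <- mean(ifelse(s >= 0, positive_class, other) == pred)
    if (agree < 0.5) {
      w <- -w; b <- -b
    }
    list(w = w, b = b)
  }
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = cost,
                    scale = FALSE)
  wb <- oriented_wb(fit, X)
  w <- wb$w; b <- wb$b
  names(w) <- colnames(X)
  folds <- withr::with_seed(seed, sample(rep_len(seq_len(nfolds), nrow(X))))
  oof <- rep(NA_real_, nrow(X))
  cv_acc <- rep(NA_real_, nfolds)
  for (k in seq_len(nfolds)) {
    tr <- folds != k
    if (nlevels(droplevels(y[tr])) < 2L) next
    f <- e1071::svm(x = X[tr, , drop = FALSE], y = y[tr], kernel = "linear",
                    cost = cost, scale = FALSE)
    fwb <- oriented_wb(f, X[tr, , drop = FALSE])
    s <- as.vector(X[!tr, , drop = FALSE] %*% fwb$w) + fwb$b
    oof[!tr] <- s
    cv_acc[k] <- mean(ifelse(s >= 0, positive_class, levels(y)[2L]) ==
                        as.character(y[!tr]))
  }
  cal <- if (all(is.na(oof))) as.vector(X %*% w) + b else oof
  correct <- !is.na(cal) &
    ifelse(cal >= 0, positive_class, levels(y)[2L]) == as.character(y)
  band <- as.numeric(stats::quantile(abs(cal[correct]), band_quantile))
  structure(list(w = w, b = b, band = band, positive_class = positive_class,
                 classes = levels(y), cv_accuracy = cv_acc, seed = seed,
                 n_train = nrow(X)),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf(
    "signature_model: %d features, band %.4g, CV accuracy %.3f (%d folds)\n",
    length(x$w), x$band, mean(x$cv_accuracy, na.rm = TRUE),
    length(x$cv_accuracy)))
  invisible(x)
}

#' Predict enhancer / promoter / unpredictable classes
#'
#' @param model A [train_signature_classifier] model.
#' @param X Profile matrix (columns matching the model's features).
#' @param zero_signal Optional logical vector: profiles with no signal in
#'   either mark are forced to "unpredictable".
#' @return List with `class` (character vector: `enhancer`, `promoter` or
#'   `unpredictable`) and `score` (signed decision values; positive side is
#'   `model$positive_class`).
#' @export
predict_signature <- function(model, X, zero_signal = NULL) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != length(model$w))
    stop(sprintf("profile has %d features; model expects %d",
                 ncol(X), length(model$w)))
  s <- as.vector(X %*% model$w) + model$b
  negative_class <- setdiff(model$classes, model$positive_class)
  cls <- rep("unpredictable", length(s))
  cls[s >= model$band] <- model$positive_class
  cls[s <= -model$band] <- negative_class
  if (model$band == 0) cls[s == 0] <- "unpredictable"
  if (!is.null(zero_signal)) cls[zero_signal] <- "unpredictable"
  list(class = cls, score = s)
}

#' Serialise / restore a signature model as TSV
#'
#' One `feature<TAB>weight` row per feature plus `.bias`, `.band`,
#' `.positive_class`, `.classes` and `.seed` metadata rows, after `#` header
#' comments.
#'
#' @param model A signature model.
#' @param path Output path.
#' @export
write_signature_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# extrapol signature model",
               sprintf("# trained on %d profiles; CV accuracy %s", model$n_train,
                       paste(sprintf("%.4f", model$cv_accuracy), collapse = ","))),
             con)
  df <- data.frame(key = c(names(model$w), ".bias", ".band", ".positive_class",
                           ".classes", ".seed", ".n_train"),
                   value = c(sprintf("%.17g", model$w),
                             sprintf("%.17g", model$b),
                             sprintf("%.17g", model$band),
                             model$positive_class,
                             paste(model$classes, collapse = ","),
                             as.character(model$seed),
                             as.character(model$n_train)))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_signature_model
#' @export
read_signature_model <- function(path) {
  tab <- .read_text_table(path, "model file")
  kv <- data.table::fread(text = tab$lines, header = FALSE, sep = "\t",
                          colClasses = "character")
  keys <- kv$V1; vals <- kv$V2
  meta <- startsWith(keys, ".")
  w <- as.numeric(vals[!meta])
  names(w) <- keys[!meta]
  get <- function(k) vals[keys == k][1]
  structure(list(w = w, b = as.numeric(get(".bias")),
                 band = as.numeric(get(".band")),
                 positive_class = get(".positive_class"),
                 classes = strsplit(get(".classes"), ",")[[1]],
                 cv_accuracy = NA_real_, seed = as.integer(get(".seed")),
                 n_train = as.integer(get(".n_train"))),
            class = "signature_model")
}

#' Fraction of predicted classes overlapping annotated TSSs
#'
#' For each predicted class, the fraction of peak summits lying within
#' `half_window` bp of any annotated TSS — the consistency check used to
#' validate signature predictions against independent annotation.
#'
#' @param predictions Data frame with columns `chrom`, `summit`, `class`.
#' @param tss Data frame with columns `chrom` and `pos`.
#' @param half_window Distance threshold (bp).
#' @return Named numeric vector: per-class fraction near a TSS.
#' @export
validate_against_tss <- function(predictions, tss, half_window = 2500L) {
  near <- vapply(seq_len(nrow(predictions)), function(i) {
    tt <- tss[tss$chrom == predictions$chrom[i], , drop = FALSE]
    nrow(tt) > 0L && min(abs(tt$pos - predictions$summit[i])) <= half_window
  }, logical(1))
  vapply(split(near, predictions$class), mean, numeric(1))
}
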