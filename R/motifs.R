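# Clover-style PWM scanning and group-level TFBS enrichment. A window is
# scored by its likelihood ratio against the background model, a sequence by
# the arithmetic mean of its window ratios over both strands, and a group of
# sequences by the mean log sequence score (geometric-mean aggregation).
# Significance comes from randomisation: length-matched fragments drawn from
# a background pool (group-level enrichment) or mononucleotide shuffles of
# the sequence itself (per-region match probability).

# A, C, G, T -> 1..4; anything else (incl. N) -> NA. Complement is 5 - code.
.DNA_CODE <- local({
  v <- rep(NA_integer_, 127)
  v[utf8ToInt("A")] <- 1L; v[utf8ToInt("a")] <- 1L
  v[utf8ToInt("C")] <- 2L; v[utf8ToInt("c")] <- 2L
  v[utf8ToInt("G")] <- 3L; v[utf8ToInt("g")] <- 3L
  v[utf8ToInt("T")] <- 4L; v[utf8ToInt("t")] <- 4L
  v
})

#' Encode a DNA string as integer codes
#'
#' @param seq Character scalar (A/C/G/T; other letters become `NA`, scored
#'   as neutral positions).
#' @return Integer vector (A=1, C=2, G=3, T=4, `NA` otherwise).
#' @export
encode_dna <- function(seq) {
  .DNA_CODE[utf8ToInt(seq)]
}

.log_ratio_matrix <- function(pwm) log(pwm$prob / pwm$background)

# scores of all windows of one strand; codes NA contribute factor 1
.window_scores <- function(lrm, codes) {
  L <- ncol(lrm)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(numeric(0))
  acc <- numeric(nw)
  for (j in seq_len(L)) {
    contrib <- unname(lrm[, j])[codes[j:(j + nw - 1L)]]
    contrib[is.na(contrib)] <- 0
    acc <- acc + contrib
  }
  exp(acc)
}

#' Likelihood ratio of one sequence window under a PWM
#'
#' Product over motif positions of `P_pwm(base) / P_background(base)`; an
#' `N` (or any non-ACGT base) contributes a neutral factor of 1.
#'
#' @param pwm A `"pwm"` object from [read_jaspar].
#' @param window Character scalar of length equal to the motif length.
#' @return Non-negative likelihood ratio.
#' @export
window_likelihood_ratio <- function(pwm, window) {
  codes <- encode_dna(window)
  if (length(codes) != ncol(pwm$prob))
    stop(sprintf("window length %d does not match motif length %d",
                 length(codes), ncol(pwm$prob)))
  .window_scores(.log_ratio_matrix(pwm), codes)
}

#' Clover-style score of a sequence under a PWM
#'
#' Arithmetic mean of the window likelihood ratios over all windows on both
#' strands (the reverse complement is scanned with the same matrix).
#'
#' @param pwm A `"pwm"` object.
#' @param seq Character scalar, or a pre-encoded integer vector from
#'   [encode_dna].
#' @return Mean likelihood ratio (strictly positive).
#' @export
sequence_score <- function(pwm, seq) {
  codes <- if (is.character(seq)) encode_dna(seq) else seq
  L <- ncol(pwm$prob)
  if (length(codes) < L)
    stop("sequence shorter than the motif")
  .seq_score_cpp(as.integer(codes), .log_ratio_matrix(pwm))
}

# pure-R window scan over both strands (kept for the single-window scorer)
.sequence_score_r <- function(pwm, codes) {
  lrm <- .log_ratio_matrix(pwm)
  fwd <- .window_scores(lrm, codes)
  rc <- rev(5L - codes)  # complement then reverse; NA stays NA
  rev_ <- .window_scores(lrm, rc)
  mean(c(fwd, rev_))
}

#' Group-level raw motif score
#'
#' Mean over sequences of `log(sequence_score)`: a geometric-mean
#' aggregation of the per-sequence Clover-style scores. A PWM identical to
#' the background scores exactly 0 on any group.
#'
#' @param pwm A `"pwm"` object.
#' @param sequences Character vector or list of encoded integer vectors.
#' @return Real group score.
#' @export
group_raw_score <- function(pwm, sequences) {
  if (!length(sequences)) stop("at least one sequence required")
  if (is.character(sequences)) sequences <- lapply(sequences, encode_dna)
  sequences <- lapply(sequences, as.integer)
  mean(log(.seq_scores_cpp(sequences, .log_ratio_matrix(pwm))))
}

#' Randomisation p-value for group-level motif enrichment
#'
#' The observed [group_raw_score] of the target set is compared with
#' `n_draws` null sets, each assembled by drawing one length-matched
#' fragment per target sequence uniformly from the background pool.
#' p = (1 + #{null >= observed}) / (1 + n_draws).
#'
#' @param pwm A `"pwm"` object.
#' @param target_seqs Character vector of target sequences.
#' @param background_seqs Character vector of background sequences; every
#'   target must fit inside at least one background sequence.
#' @param n_draws Number of null sets.
#' @param seed Optional integer seed.
#' @return List: `p_value`, `observed`, `null_scores`.
#' @export
enrichment_p <- function(pwm, target_seqs, background_seqs, n_draws = 1000L,
                         seed = NULL) {
  stopifnot(n_draws >= 1L, length(target_seqs) > 0L)
  targets <- lapply(target_seqs, encode_dna)
  pool <- lapply(background_seqs, encode_dna)
  pool_len <- lengths(pool)
  tlens <- lengths(targets)
  if (max(tlens) > max(pool_len))
    stop("background pool holds no sequence as long as the longest target")
  targets <- lapply(targets, as.integer)
  pool <- lapply(pool, as.integer)
  obs <- group_raw_score(pwm, targets)
  lrm <- .log_ratio_matrix(pwm)
  eligible <- lapply(tlens, function(l) which(pool_len >= l))
  run <- function() {
    vapply(seq_len(n_draws), function(d) {
      frags <- lapply(seq_along(targets), function(i) {
        j <- eligible[[i]][sample.int(length(eligible[[i]]), 1L)]
        off <- sample.int(pool_len[j] - tlens[i] + 1L, 1L)
        pool[[j]][off:(off + tlens[i] - 1L)]
      })
      mean(log(.seq_scores_cpp(frags, lrm)))
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(p_value = (1 + sum(null >= obs)) / (1 + n_draws), observed = obs,
       null_scores = null)
}

#' Per-region match probability against composition-preserving shuffles
#'
#' Probability (with +1 smoothing) that a mononucleotide shuffle of the
#' region scores below the observed [sequence_score]: values near 1 indicate
#' a match far stronger than expected from base composition alone. Shuffles
#' tied with the observed score count one half, so a matrix that cannot
#' distinguish the region from its shuffles sits near 0.5.
#'
#' @param pwm A `"pwm"` object.
#' @param seq Character scalar.
#' @param n_shuffles Number of shuffles.
#' @param seed Optional integer seed.
#' @return Probability in `[0, 1]`.
#' @export
region_match_probability <- function(pwm, seq, n_shuffles = 100L, seed = NULL) {
  codes <- as.integer(encode_dna(seq))
  obs <- sequence_score(pwm, codes)
  lrm <- .log_ratio_matrix(pwm)
  run <- function() {
    .seq_scores_cpp(lapply(seq_len(n_shuffles), function(i) sample(codes)),
                    lrm)
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  # ties (e.g. a background-equal matrix) count half: a score
  # indistinguishable from its shuffles sits mid-distribution
  (1 + sum(null < obs) + 0.5 * sum(null == obs)) / (1 + n_shuffles)
}

#' Motif-by-group enrichment table
#'
#' Runs [enrichment_p] for every PWM on every group of sequences against one
#' or more background pools.
#'
#' @param pwms List of `"pwm"` objects (e.g. [read_jaspar] output).
#' @param groups Named list of character vectors of sequences.
#' @param backgrounds Named list of background pools (character vectors).
#' @param n_draws Null sets per test.
#' @param seed Optional integer seed (advanced per test, deterministically).
#' @return Data frame: `motif_id`, `group`, `background`, `raw_score`,
#'   `p_value`.
#' @export
motif_enrichment_table <- function(pwms, groups, backgrounds, n_draws = 1000L,
                                   seed = NULL) {
  combos <- expand.grid(m = seq_along(pwms), g = seq_along(groups),
                        b = seq_along(backgrounds))
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    m <- combos$m[k]; g <- combos$g[k]; b <- combos$b[k]
    s <- if (is.null(seed)) NULL else seed + k
    res <- enrichment_p(pwms[[m]], groups[[g]], backgrounds[[b]],
                        n_draws = n_draws, seed = s)
    data.frame(motif_id = pwms[[m]]$id, group = names(groups)[g],
               background = names(backgrounds)[b], raw_score = res$observed,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Motif-by-region match-probability matrix
#'
#' The heat-table companion of [motif_enrichment_table]: for each PWM and
#' each region sequence, the [region_match_probability].
#'
#' @param pwms List of `"pwm"` objects.
#' @param sequences Character vector of region sequences.
#' @param n_shuffles Shuffles per cell.
#' @param seed Optional integer seed.
#' @return Numeric matrix (motifs x regions) of probabilities in `[0, 1]`.
#' @export
region_probability_matrix <- function(pwms, sequences, n_shuffles = 100L,
                                      seed = NULL) {
  out <- matrix(NA_real_, length(pwms), length(sequences),
                dimnames = list(vapply(pwms, `[[`, "", "id"), NULL))
  k <- 0L
  for (m in seq_along(pwms)) {
    for (i in seq_along(sequences)) {
      k <- k + 1L
      s <- if (is.null(seed)) NULL else seed + k
      out[m, i] <- region_match_probability(pwms[[m]], sequences[[i]],
                                            n_shuffles = n_shuffles, seed = s)
    }
  }
  out
}
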