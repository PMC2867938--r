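# Small in-code fixtures shared across tests.

# tag track from bare positions on one chromosome
tt1 <- function(pos, chrom = "chr1") tag_track(stats::setNames(list(pos), chrom))

# write a temporary text file and return its path
tmp_text <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# a background-equal PWM (every position uniform): scores 1 on any window
uniform_pwm <- function(len = 4L) {
  structure(list(id = "UNIF", name = "UNIF",
                 prob = matrix(0.25, 4, len,
                               dimnames = list(c("A", "C", "G", "T"), NULL)),
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudocount = 0),
            class = "pwm")
}

# sharp PWM from a consensus string (dominant probability p_hi)
consensus_pwm <- function(consensus, p_hi = 0.85, id = "CONS") {
  bases <- strsplit(consensus, "")[[1]]
  prob <- matrix((1 - p_hi) / 3, 4, length(bases),
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) prob[bases[j], j] <- p_hi
  structure(list(id = id, name = id, prob = prob,
                 background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                 pseudocount = 0),
            class = "pwm")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# brute-force interval merge: repeated pairwise merging to a fixed point
oracle_merge <- function(df, max_gap) {
  items <- lapply(seq_len(nrow(df)), function(i)
    list(chrom = df$chrom[i], start = df$start[i], end = df$end[i]))
  repeat {
    merged_any <- FALSE
    for (i in seq_along(items)) {
      for (j in seq_along(items)) {
        if (i >= j) next
        a <- items[[i]]; b <- items[[j]]
        if (a$chrom != b$chrom) next
        gap <- max(b$start - a$end, a$start - b$end, 0)
        if (gap <= max_gap) {
          items[[i]] <- list(chrom = a$chrom, start = min(a$start, b$start),
                             end = max(a$end, b$end))
          items[[j]] <- NULL
          merged_any <- TRUE
          break
        }
      }
      if (merged_any) break
    }
    if (!merged_any) break
  }
  out <- do.call(rbind, lapply(items, as.data.frame))
  out[order(out$chrom, out$start), , drop = FALSE]
}

# exact two-sided binomial p by direct summation (the small-sample oracle,
# matching the "sum of outcomes no more likely than the observed" definition)
oracle_binom_two_sided <- function(k, n, p) {
  d <- stats::dbinom(0:n, n, p)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}
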