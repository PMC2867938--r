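# Curation of extragenic Pol II peaks: a minimal sliding-window Poisson peak
# caller (external callers are expected for real data; this one serves the
# synthetic pipeline), summit finding, gene-overlap / 3'-flank / continuity
# filtering, condition-comparison regulation classes, and clustering.

#' Call enriched regions from a tag track
#'
#' Minimal sliding-window caller: tag counts in fixed-width windows are
#' compared against a global Poisson background rate (library_size / genome
#' length); significant windows are merged and short regions dropped. This is
#' a deliberately simple stand-in for a dedicated ChIP-seq peak caller, meant
#' for data of synthetic-genome scale.
#'
#' @param track A [tag_track].
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param window_bp,step_bp Window width and step (bp).
#' @param p_cutoff Poisson upper-tail cutoff per window.
#' @param min_width Minimum width (bp) of a reported region.
#' @param merge_gap_bp Significant windows closer than this are joined into
#'   one region; broad, low occupancy domains (the typical enhancer shape)
#'   show local dips that would otherwise fragment them.
#' @return A [gintervals] frame; `score` holds the peak's best
#'   `-log10` window p-value.
#' @export
call_peaks <- function(track, chrom_sizes, window_bp = 200L, step_bp = 50L,
                       p_cutoff = 1e-5, min_width = 200L, merge_gap_bp = 500L) {
  stopifnot(inherits(track, "tag_track"))
  genome_len <- sum(as.numeric(chrom_sizes))
  lambda <- track$library_size / genome_len * window_bp
  res <- list()
  for (ch in names(chrom_sizes)) {
    pos <- track$positions[[ch]]
    if (is.null(pos) || length(pos) == 0L) next
    starts <- seq.int(0L, max(0L, chrom_sizes[[ch]] - window_bp), by = step_bp)
    cnt <- findInterval(starts + window_bp - 1L, pos) - findInterval(starts - 1L, pos)
    p <- stats::ppois(cnt - 1L, lambda, lower.tail = FALSE)
    sig <- which(p < p_cutoff)
    if (!length(sig)) next
    wins <- gintervals(ch, starts[sig], starts[sig] + window_bp,
                       score = -log10(pmax(p[sig], 1e-300)))
    merged <- merge_intervals(wins, max_gap = merge_gap_bp, with_members = TRUE)
    merged$score <- vapply(merged$members, function(m) max(wins$score[m]), 0)
    merged$members <- NULL
    res[[ch]] <- merged
  }
  if (!length(res)) return(gintervals(character(), integer(), integer()))
  out <- .as_gintervals(do.call(rbind, res))
  out <- out[out$end - out$start >= min_width, , drop = FALSE]
  rownames(out) <- NULL
  out$name <- sprintf("peak_%04d", seq_len(nrow(out)))
  .as_gintervals(out)
}

#' Locate the summit of a peak
#'
#' The summit is the position maximising the tag count in a sliding window of
#' width `smooth_bp` centred on it. Maximal positions typically form a
#' contiguous run (a plateau); the summit is the midpoint of the leftmost
#' such run, so a single pile of tags maps to its own position. A peak
#' without any signal returns its midpoint.
#'
#' @param track A [tag_track].
#' @param intervals A [gintervals] frame of peaks.
#' @param smooth_bp Sliding-window width (bp).
#' @return Integer vector of summit positions (0-based), one per peak.
#' @export
find_summit <- function(track, intervals, smooth_bp = 50L) {
  stopifnot(smooth_bp >= 1L)
  h1 <- smooth_bp %/% 2L
  h2 <- smooth_bp - h1
  vapply(seq_len(nrow(intervals)), function(i) {
    s <- intervals$start[i]; e <- intervals$end[i]
    pos <- track$positions[[intervals$chrom[i]]]
    if (is.null(pos)) return(s + (e - s) %/% 2L)
    x <- s:(e - 1L)
    cnt <- findInterval(x + h2 - 1L, pos) - findInterval(x - h1 - 1L, pos)
    if (max(cnt) == 0L) return(s + (e - s) %/% 2L)
    top <- which(cnt == max(cnt))
    run_end <- if (any(diff(top) > 1L)) top[min(which(diff(top) > 1L))] else
      top[length(top)]
    x[(top[1L] + run_end) %/% 2L]
  }, integer(1))
}

#' Retain extragenic peaks
#'
#' Removes peaks that (a) overlap any annotated gene body by at least 1 bp,
#' (b) fall within `flank3_bp` downstream of a gene's 3' end (strand-aware),
#' or (c) show continuous Pol II coverage connecting them to the 3' end of
#' the nearest gene transcribing towards them — no window of
#' `continuity_gap_bp` with zero tags over the intervening gap (rule (c) is
#' only applied when a tag track is supplied).
#'
#' @param peaks A [gintervals] frame.
#' @param genes Gene table from [read_gene_table].
#' @param track Optional [tag_track] used for the continuity rule.
#' @param flank3_bp Width of the 3' exclusion flank (bp).
#' @param continuity_gap_bp Zero-coverage window (bp) that breaks continuity.
#' @return List with `retained` (a [gintervals] frame) and `rejected`
#'   (data frame of removed peaks with the rule that fired).
#' @export
filter_extragenic <- function(peaks, genes, track = NULL, flank3_bp = 10000L,
                              continuity_gap_bp = 500L) {
  stopifnot(flank3_bp >= 0L)
  n <- nrow(peaks)
  rule <- rep(NA_character_, n)
  if (n > 0L && nrow(genes) > 0L) {
    bodies <- gintervals(genes$chrom, genes$start, genes$end)
    rule[overlaps_feature(peaks, bodies)] <- "gene_overlap"
    if (flank3_bp > 0L) {
      fs <- ifelse(genes$strand == "+", genes$end, pmax(0L, genes$start - flank3_bp))
      fe <- ifelse(genes$strand == "+", genes$end + flank3_bp, genes$start)
      keepf <- fe > fs
      flanks <- gintervals(genes$chrom[keepf], fs[keepf], fe[keepf])
      rule[is.na(rule) & overlaps_feature(peaks, flanks)] <- "flank3"
    }
    if (!is.null(track)) {
      for (i in which(is.na(rule))) {
        if (.continuous_with_upstream(peaks[i, ], genes, track, continuity_gap_bp))
          rule[i] <- "continuity"
      }
    }
  }
  keep <- is.na(rule)
  rejected <- as.data.frame(peaks)[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$rule <- rule[!keep]
  else rejected$rule <- character(0)
  rownames(rejected) <- NULL
  list(retained = .as_gintervals(as.data.frame(peaks)[keep, , drop = FALSE]),
       rejected = rejected)
}

# Is the gap between the peak and the nearest gene 3' end pointing at it
# covered without any zero-tag window of width gap_bp?
.continuous_with_upstream <- function(peak, genes, track, gap_bp) {
  g <- genes[genes$chrom == peak$chrom, , drop = FALSE]
  if (!nrow(g)) return(FALSE)
  spans <- list()
  left <- g[g$strand == "+" & g$end <= peak$start, , drop = FALSE]
  if (nrow(left)) {
    tes <- max(left$end)
    spans <- c(spans, list(c(tes, peak$start)))
  }
  right <- g[g$strand == "-" & g$start >= peak$end, , drop = FALSE]
  if (nrow(right)) {
    tes <- min(right$start)
    spans <- c(spans, list(c(peak$end, tes)))
  }
  for (sp in spans) {
    len <- sp[2] - sp[1]
    nw <- len %/% gap_bp
    if (nw < 1L) return(TRUE)  # no room for a zero-coverage window
    ws <- sp[1] + (seq_len(nw) - 1L) * gap_bp
    wins <- gintervals(peak$chrom, ws, ws + gap_bp)
    if (all(count_tags(track, wins) > 0L)) return(TRUE)
  }
  FALSE
}

#' Classify the regulation of peaks between two conditions
#'
#' Tag counts in the two conditions are compared with a conditional exact
#' binomial test: given `n = tags_ut + tags_lps` tags, the stimulated count
#' is binomial with success probability `lib_lps / (lib_ut + lib_lps)` under
#' no change. The library-size-normalised fold change (with pseudocount 1)
#' decides the direction. A peak is `inducible` when fold `>= fold_min` and
#' `p <= p_max`, `repressed` in the mirrored case, else `constitutive`.
#'
#' @param tags_ut,tags_lps Integer vectors of per-peak tag counts in the
#'   untreated and stimulated conditions.
#' @param lib_ut,lib_lps Library sizes (total tags) of the two conditions.
#' @param fold_min Minimum normalised fold change.
#' @param p_max Maximum exact binomial p-value.
#' @return Data frame with `regulation` (factor: constitutive / inducible /
#'   repressed), `p_value` and `fold` (lps/ut, normalised).
#' @export
classify_regulation <- function(tags_ut, tags_lps, lib_ut, lib_lps,
                                fold_min = 2, p_max = 1e-3) {
  stopifnot(lib_ut > 0, lib_lps > 0, length(tags_ut) == length(tags_lps))
  p0 <- lib_lps / (lib_ut + lib_lps)
  fold <- ((tags_lps + 1) / lib_lps) / ((tags_ut + 1) / lib_ut)
  pv <- vapply(seq_along(tags_ut), function(i) {
    tot <- tags_ut[i] + tags_lps[i]
    if (tot == 0L) return(1)
    stats::binom.test(tags_lps[i], tot, p = p0)$p.value
  }, numeric(1))
  reg <- rep("constitutive", length(tags_ut))
  reg[fold >= fold_min & pv <= p_max] <- "inducible"
  reg[(1 / fold) >= fold_min & pv <= p_max] <- "repressed"
  data.frame(regulation = factor(reg, levels = c("constitutive", "inducible",
                                                 "repressed")),
             p_value = pv, fold = fold)
}

#' Cluster peaks and filter against protein-coding genes
#'
#' Peaks closer than `cluster_gap_bp` are merged into clusters; clusters
#' overlapping any protein-coding gene body are discarded. Cluster-level
#' regulation is the majority label of the members (ties go to
#' `constitutive`) and the cluster signature class is the majority member
#' class (ties go to `unpredictable`).
#'
#' @param peaks A [gintervals] frame with columns `regulation` and
#'   `signature_class` (missing columns are treated as `constitutive` /
#'   `unassigned`).
#' @param genes Gene table; only rows with `is_protein_coding` are used.
#' @param cluster_gap_bp Maximum gap (bp) between peaks in one cluster.
#' @return Data frame of clusters: `chrom`, `start`, `end`, `n_members`,
#'   `members` (list of member row indices), `regulation`, `signature_class`.
#' @export
cluster_and_filter <- function(peaks, genes, cluster_gap_bp = 2000L) {
  if (!"regulation" %in% names(peaks)) peaks$regulation <- "constitutive"
  if (!"signature_class" %in% names(peaks)) peaks$signature_class <- "unassigned"
  cl <- merge_intervals(.as_gintervals(peaks[, c("chrom", "start", "end",
                                                 "strand", "name", "score")]),
                        max_gap = cluster_gap_bp, with_members = TRUE)
  if (nrow(cl) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_members = integer(), regulation = character(),
                      signature_class = character()))
  }
  cl$n_members <- lengths(cl$members)
  cl$regulation <- vapply(cl$members, function(m)
    .majority(as.character(peaks$regulation[m]), tie = "constitutive"),
    character(1))
  cl$signature_class <- vapply(cl$members, function(m)
    .majority(as.character(peaks$signature_class[m]), tie = "unpredictable"),
    character(1))
  pc <- genes[genes$is_protein_coding, , drop = FALSE]
  if (nrow(pc)) {
    drop <- overlaps_feature(.as_gintervals(as.data.frame(cl)), gintervals(pc$chrom, pc$start, pc$end))
    cl <- cl[!drop, , drop = FALSE]
  }
  rownames(cl) <- NULL
  cl$name <- sprintf("cluster_%04d", seq_len(nrow(cl)))
  cl
}

.majority <- function(labels, tie) {
  tab <- table(labels)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) tie else top
}
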