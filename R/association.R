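# Overlap, distance and enrichment statistics relating classified clusters to
# CpG islands, genes, Ser5-P Pol II peaks, CAGE clusters, ncRNA catalogues,
# RNA-seq support and PU.1 binding. Empirical p-values from randomisation
# nulls use +1 smoothing: p = (1 + #{null >= observed}) / (1 + n_random).

# Place length-matched random intervals on the same chromosome as each
# template, uniformly, optionally avoiding an exclusion set (rejection
# sampling, capped). Returns a plain data frame (chrom/start/end).
.random_matched_intervals <- function(template, chrom_sizes, exclude_idx = NULL,
                                      max_tries = 50L) {
  n <- nrow(template)
  lens <- template$end - template$start
  chroms <- template$chrom
  hi <- unname(chrom_sizes[chroms]) - lens
  if (anyNA(hi) || any(hi < 0L))
    stop("chromosome too short for a length-matched interval")
  starts <- as.integer(floor(stats::runif(n, 0, hi + 1)))
  if (!is.null(exclude_idx)) {
    redo <- which(.overlap_flags(exclude_idx, data.frame(
      chrom = chroms, start = starts, end = starts + lens)))
    tries <- 0L
    while (length(redo) && tries < max_tries) {
      starts[redo] <- as.integer(floor(stats::runif(length(redo), 0,
                                                    hi[redo] + 1)))
      keep <- .overlap_flags(exclude_idx, data.frame(
        chrom = chroms[redo], start = starts[redo],
        end = starts[redo] + lens[redo]))
      redo <- redo[keep]
      tries <- tries + 1L
    }
  }
  data.frame(chrom = chroms, start = starts, end = starts + lens,
             stringsAsFactors = FALSE)
}

# Sorted per-chromosome merged feature index for O(log n) overlap queries.
.overlap_index <- function(features, slop = 0L) {
  if (nrow(features) == 0L) return(list())
  f <- features
  f$start <- pmax(0L, f$start - as.integer(slop))
  f$end <- f$end + as.integer(slop)
  m <- merge_intervals(.as_gintervals(data.frame(
    chrom = f$chrom, start = f$start, end = f$end, strand = ".",
    name = NA_character_, score = NA_real_, stringsAsFactors = FALSE)), 0L)
  lapply(split(m[, c("start", "end")], m$chrom), function(d)
    list(starts = d$start, ends = d$end))
}

.any_overlap_sorted <- function(index, chrom, start, end) {
  ix <- index[[chrom]]
  if (is.null(ix)) return(FALSE)
  k <- findInterval(end - 1L, ix$starts)  # last feature starting before `end`
  k >= 1L && ix$ends[k] > start
}

.overlap_flags <- function(index, intervals) {
  vapply(seq_len(nrow(intervals)), function(i)
    .any_overlap_sorted(index, intervals$chrom[i], intervals$start[i],
                        intervals$end[i]), logical(1))
}

#' Overlap fraction with a matched random null
#'
#' Observed fraction of query intervals overlapping at least one feature
#' (after symmetric `slop` extension of the features), compared against
#' `n_random` sets of length-matched intervals placed uniformly on the same
#' chromosomes — excluding a given region set (typically gene bodies, when
#' the query set is extragenic). Empirical p-values use +1 smoothing.
#'
#' @param query A [gintervals] frame (e.g. Pol II clusters).
#' @param features A [gintervals] frame (e.g. CpG islands, PU.1 peaks).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param n_random Number of random sets.
#' @param slop Symmetric extension (bp) applied to features.
#' @param exclude Optional [gintervals] frame the random intervals must avoid.
#' @param seed Optional integer seed for the randomisation.
#' @return Object of class `"overlap_null"`: `n_query`, `n_overlapping`,
#'   `fraction`, `expected_fraction` (mean of the null), `p_enrich`,
#'   `p_deplete`, `null_fractions`.
#' @export
overlap_fraction_with_null <- function(query, features, chrom_sizes,
                                       n_random = 1000L, slop = 0L,
                                       exclude = NULL, seed = NULL) {
  stopifnot(n_random >= 1L, nrow(query) > 0L)
  idx <- .overlap_index(features, slop)
  obs_flags <- .overlap_flags(idx, query)
  obs <- mean(obs_flags)
  excl_idx <- if (!is.null(exclude) && nrow(exclude)) .overlap_index(exclude)
  run <- function() {
    vapply(seq_len(n_random), function(r) {
      rnd <- .random_matched_intervals(query, chrom_sizes, excl_idx)
      mean(.overlap_flags(idx, rnd))
    }, numeric(1))
  }
  null <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(n_query = nrow(query), n_overlapping = sum(obs_flags),
                 fraction = obs, expected_fraction = mean(null),
                 p_enrich = (1 + sum(null >= obs)) / (1 + n_random),
                 p_deplete = (1 + sum(null <= obs)) / (1 + n_random),
                 n_random = n_random, null_fractions = null),
            class = "overlap_null")
}

#' @export
print.overlap_null <- function(x, ...) {
  cat(sprintf(
    "overlap: %d/%d (%.1f%%) vs expected %.1f%%; p_enrich=%.3g p_deplete=%.3g\n",
    x$n_overlapping, x$n_query, 100 * x$fraction, 100 * x$expected_fraction,
    x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Assign clusters to nearby genes
#'
#' Each cluster is assigned to the nearest gene (boundary distance) if that
#' distance is strictly below `max_dist`; ties are broken by the nearer TSS,
#' then by the lexicographically smaller gene id.
#'
#' @param clusters A [gintervals]-like frame.
#' @param genes Gene table from [read_gene_table].
#' @param max_dist Maximum assignment distance (bp, strict).
#' @return Data frame with one row per cluster: `gene_id` (`NA` when
#'   unassigned), `distance`, `assigned`.
#' @export
assign_to_genes <- function(clusters, genes, max_dist = 20000L) {
  n <- nrow(clusters)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    distance = rep(NA_integer_, n),
                    assigned = rep(FALSE, n), stringsAsFactors = FALSE)
  if (n == 0L || nrow(genes) == 0L) return(out)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == clusters$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    # boundary gap in bp between half-open intervals (0 when overlapping)
    d <- pmax(0L, pmax(g$start - clusters$end[i], clusters$start[i] - g$end))
    best <- which(d == min(d))
    if (length(best) > 1L) {
      mid <- clusters$start[i] + (clusters$end[i] - clusters$start[i]) %/% 2L
      dt <- abs(g$tss[best] - mid)
      best <- best[dt == min(dt)]
      if (length(best) > 1L) best <- best[order(g$gene_id[best])][1L]
    }
    if (d[best] < max_dist) {
      out$gene_id[i] <- g$gene_id[best]
      out$distance[i] <- d[best]
      out$assigned[i] <- TRUE
    }
  }
  out
}

#' Gene-class enrichment among assigned genes
#'
#' Compares the observed distribution of assigned genes over regulation
#' classes with the expected fractions, defined as each class's relative
#' frequency among all Pol II-positive genes. Per class, the p-value is the
#' exact binomial tail of the observed count at the expected fraction; raw
#' two-sided and directional one-sided p-values are reported together with a
#' Benjamini-Hochberg column over the classes.
#'
#' @param assigned_labels Character vector: regulation class of each assigned
#'   gene (one entry per assignment).
#' @param positive_labels Character vector: regulation class of every
#'   Pol II-positive gene (defines the expected fractions).
#' @return Data frame with one row per class: `observed_n`,
#'   `observed_fraction`, `expected_fraction`, `p_two_sided`, `p_one_sided`,
#'   `direction` (`over` / `under` / `n.s.`), `p_bh`.
#' @export
gene_class_enrichment <- function(assigned_labels, positive_labels) {
  if (!length(assigned_labels)) stop("no assigned genes")
  if (!length(positive_labels)) stop("no Pol II-positive genes")
  classes <- sort(unique(c(assigned_labels, positive_labels)))
  n <- length(assigned_labels)
  exp_frac <- as.numeric(table(factor(positive_labels, classes))) /
    length(positive_labels)
  obs_n <- as.numeric(table(factor(assigned_labels, classes)))
  rows <- lapply(seq_along(classes), function(i) {
    k <- obs_n[i]; p0 <- exp_frac[i]
    p2 <- if (p0 %in% c(0, 1)) as.numeric(k == n * p0) else
      stats::binom.test(k, n, p = p0)$p.value
    if (k / n > p0) {
      p1 <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
      dir <- "over"
    } else if (k / n < p0) {
      p1 <- stats::pbinom(k, n, p0)
      dir <- "under"
    } else {
      p1 <- 1
      dir <- "n.s."
    }
    if (p2 > 0.05) dir <- "n.s."
    data.frame(class = classes[i], observed_n = k, observed_fraction = k / n,
               expected_fraction = p0, p_two_sided = p2, p_one_sided = p1,
               direction = dir, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_two_sided, method = "BH")
  out
}

#' Distances from clusters to the nearest peak
#'
#' Per-cluster [nearest_distance] to a second peak set, with summary
#' statistics over clusters that have a peak on their chromosome.
#'
#' @param clusters,peaks [gintervals] frames.
#' @return List: `distances` (integer, `NA` = no peak on chromosome),
#'   `median`, `q25`, `q75`, `n_none`.
#' @export
distance_to_nearest_distribution <- function(clusters, peaks) {
  stopifnot(nrow(clusters) > 0L, nrow(peaks) > 0L)
  d <- nearest_distance(clusters, peaks)
  ok <- !is.na(d)
  qs <- if (any(ok)) stats::quantile(d[ok], c(0.25, 0.5, 0.75)) else
    rep(NA_real_, 3)
  list(distances = d, median = unname(qs[2]), q25 = unname(qs[1]),
       q75 = unname(qs[3]), n_none = sum(!ok))
}

#' Median spacing of CAGE clusters inside one region
#'
#' Collects the CAGE tag clusters overlapping a region; with two or more,
#' returns the median of consecutive midpoint-to-midpoint distances. A
#' region with a single overlapping cluster reports status `"single"`, one
#' with none reports `"none"`.
#'
#' @param region Single-row [gintervals] frame.
#' @param cage_clusters A [gintervals] frame of CAGE tag clusters.
#' @return List with `status` (`"ok"`, `"single"`, `"none"`) and `median`
#'   (`NA` unless status is `"ok"`).
#' @export
median_intra_region_cage_distance <- function(region, cage_clusters) {
  stopifnot(nrow(region) == 1L)
  cc <- cage_clusters[cage_clusters$chrom == region$chrom &
                        cage_clusters$start < region$end &
                        cage_clusters$end > region$start, , drop = FALSE]
  if (nrow(cc) == 0L) return(list(status = "none", median = NA_real_))
  if (nrow(cc) == 1L) return(list(status = "single", median = NA_real_))
  mids <- sort(cc$start + (cc$end - cc$start) %/% 2L)
  list(status = "ok", median = stats::median(diff(mids)))
}

#' CAGE spacing summary over a set of regions
#'
#' @param regions A [gintervals] frame.
#' @param cage_clusters A [gintervals] frame.
#' @return Data frame with per-region `status` and `median_spacing`.
#' @export
cage_spacing_summary <- function(regions, cage_clusters) {
  res <- lapply(seq_len(nrow(regions)), function(i)
    median_intra_region_cage_distance(regions[i, , drop = FALSE], cage_clusters))
  data.frame(status = vapply(res, `[[`, "", "status"),
             median_spacing = vapply(res, `[[`, 0, "median"))
}

#' RNA-seq support versus Pol II occupancy
#'
#' Flags each cluster as supported when it contains at least one RNA-seq tag,
#' and compares Pol II occupancy (tags per million) between supported and
#' unsupported clusters.
#'
#' @param clusters A [gintervals] frame.
#' @param rnaseq,polII [tag_track] objects.
#' @return List: `supported` (logical per cluster), `median_tpm_supported`,
#'   `median_tpm_unsupported`, `log10_ratio`.
#' @export
tag_support_comparison <- function(clusters, rnaseq, polII) {
  supported <- count_tags(rnaseq, clusters) > 0L
  tpm <- count_tags(polII, clusters) / polII$library_size * 1e6
  ms <- if (any(supported)) stats::median(tpm[supported]) else NA_real_
  mu <- if (any(!supported)) stats::median(tpm[!supported]) else NA_real_
  list(supported = supported, median_tpm_supported = ms,
       median_tpm_unsupported = mu,
       log10_ratio = if (!is.na(ms) && !is.na(mu) && mu > 0) log10(ms / mu)
       else NA_real_)
}
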