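# Interval container and readers for the external formats used throughout the
# pipeline. All coordinates are 0-based half-open (BED convention); gene-table
# dialects with other conventions are converted on read. GRanges/IRanges do
# the interval arithmetic behind these wrappers (conversion adds 1 to starts).

#' Construct a set of genomic intervals
#'
#' Creates the plain data-frame interval container used across the package:
#' one row per interval with `chrom`, `start`, `end` (0-based half-open),
#' `strand` (`"+"`, `"-"` or `"."`), and optional `name` and `score` columns.
#'
#' @param chrom Character vector of chromosome names (non-empty).
#' @param start,end Integer vectors; `start >= 0`, `end > start`, half-open.
#' @param strand Strand per interval; recycled. Default unstranded (`"."`).
#' @param name Optional label per interval.
#' @param score Optional numeric score per interval.
#' @return A `data.frame` with class `"gintervals"`.
#' @examples
#' gintervals("chr1", c(100L, 300L), c(200L, 450L))
#' @export
gintervals <- function(chrom, start, end, strand = ".", name = NA_character_,
                       score = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  if (n == 0L) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), name = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("gintervals", "data.frame")
    return(out)
  }
  chrom <- as.character(rep_len(chrom, n))
  start <- as.integer(rep_len(start, n))
  end <- as.integer(rep_len(end, n))
  strand <- as.character(rep_len(strand, n))
  name <- as.character(rep_len(name, n))
  score <- as.numeric(rep_len(score, n))
  if (anyNA(start) || anyNA(end)) stop("interval coordinates must be integer")
  if (any(!nzchar(chrom)) || anyNA(chrom)) stop("chrom names must be non-empty")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (!all(strand %in% c("+", "-", "."))) stop("strand must be one of '+', '-', '.'")
  out <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                    name = name, score = score, stringsAsFactors = FALSE)
  class(out) <- c("gintervals", "data.frame")
  out
}

#' @rdname gintervals
#' @param x Object to test.
#' @export
is_gintervals <- function(x) inherits(x, "gintervals")

.as_gintervals <- function(df) {
  # trust columns already validated
  class(df) <- c("gintervals", "data.frame")
  rownames(df) <- NULL
  df
}

# 0-based half-open data frame -> GRanges (1-based closed)
.gi2gr <- function(x, use_strand = FALSE) {
  strand <- if (use_strand) ifelse(x$strand == ".", "*", x$strand) else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = strand)
}

.gr2gi <- function(gr, name = NA_character_, score = NA_real_) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  gintervals(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             strand = s, name = name, score = score)
}

.read_text_table <- function(path, what = "file") {
  if (!file.exists(path)) stop(sprintf("%s not found: %s", what, path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(lines) & !grepl("^(track|browser|#)", lines)
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a BED file
#'
#' Parses BED3+ records into a [gintervals] frame, preserving the half-open
#' 0-based convention. `track`, `browser`, `#`-comment and blank lines are
#' skipped. Malformed coordinates raise an error naming the offending line.
#'
#' @param path Path to a BED file.
#' @param min_columns Minimum number of tab-separated fields required per line.
#' @return A [gintervals] frame in file order; columns 4-6 populate `name`,
#'   `score`, `strand` when present.
#' @export
read_bed <- function(path, min_columns = 3L) {
  tab <- .read_text_table(path, "BED file")
  if (length(tab$lines) == 0L) return(gintervals(character(), integer(), integer()))
  fields <- strsplit(tab$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < min_columns)) {
    i <- which(nf < min_columns)[1L]
    stop(sprintf("line %d of %s has %d field(s); %d required",
                 tab$lineno[i], path, nf[i], min_columns))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0L)
  if (length(bad)) {
    stop(sprintf("malformed coordinates at line %d of %s: '%s'",
                 tab$lineno[bad[1L]], path, tab$lines[bad[1L]]))
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
                 NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5L, vapply(fields, function(f) f[min(5L, length(f))], ""),
                      NA_character_)))
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  gintervals(chrom, start, end, strand = strand, name = name, score = score)
}

#' Write intervals as BED
#'
#' Emits BED6 (or BED3 when no name/score/strand information is present).
#' Coordinates are written unchanged (0-based half-open).
#'
#' @param x A [gintervals] frame.
#' @param path Output path.
#' @param comment Optional `#`-prefixed header comment line(s).
#' @export
write_bed <- function(x, path, comment = NULL) {
  stopifnot(is.data.frame(x))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  has_extra <- nrow(x) > 0L &&
    (any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != "."))
  if (has_extra) {
    out <- data.frame(x$chrom, x$start, x$end,
                      ifelse(is.na(x$name), ".", x$name),
                      ifelse(is.na(x$score), 0, x$score),
                      x$strand)
  } else {
    out <- data.frame(x$chrom, x$start, x$end)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene table
#'
#' Reads gene models into a data frame with strand-aware `tss`/`tes` columns
#' (0-based positions of the 5' and 3' ends). Supported dialects:
#' `simple_tsv` (columns `gene_id`, `chrom`, `start`, `end`, `strand`,
#' `is_protein_coding`; 0-based half-open), `ucsc_known` (`name`, `chrom`,
#' `strand`, `txStart`, `txEnd`; 0-based half-open) and `ensembl`
#' (`gene_id`, `chrom`, `start`, `end`, `strand` as 1/-1, `biotype`;
#' 1-based inclusive, converted on read).
#'
#' @param path Path to a tab-separated gene table. A header line is required
#'   for `simple_tsv`; `#` comment lines are skipped.
#' @param dialect One of `"simple_tsv"`, `"ucsc_known"`, `"ensembl"`.
#' @return Data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `is_protein_coding`, `tss`, `tes`.
#' @export
read_gene_table <- function(path, dialect = c("simple_tsv", "ucsc_known", "ensembl")) {
  dialect <- match.arg(dialect)
  tab <- .read_text_table(path, "gene table")
  if (length(tab$lines) == 0L) stop("gene table is empty: ", path)
  dt <- data.table::fread(text = tab$lines, header = TRUE, sep = "\t",
                          colClasses = list(character = 1))
  df <- as.data.frame(dt)
  g <- switch(dialect,
    simple_tsv = {
      req <- c("gene_id", "chrom", "start", "end", "strand", "is_protein_coding")
      if (!all(req %in% names(df)))
        stop("simple_tsv gene table must have columns: ", paste(req, collapse = ", "))
      data.frame(gene_id = df$gene_id, chrom = as.character(df$chrom),
                 start = as.integer(df$start), end = as.integer(df$end),
                 strand = as.character(df$strand),
                 is_protein_coding = as.logical(as.integer(df$is_protein_coding)),
                 stringsAsFactors = FALSE)
    },
    ucsc_known = {
      req <- c("name", "chrom", "strand", "txStart", "txEnd")
      if (!all(req %in% names(df)))
        stop("ucsc_known gene table must have columns: ", paste(req, collapse = ", "))
      data.frame(gene_id = df$name, chrom = as.character(df$chrom),
                 start = as.integer(df$txStart), end = as.integer(df$txEnd),
                 strand = as.character(df$strand), is_protein_coding = TRUE,
                 stringsAsFactors = FALSE)
    },
    ensembl = {
      req <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
      if (!all(req %in% names(df)))
        stop("ensembl gene table must have columns: ", paste(req, collapse = ", "))
      data.frame(gene_id = df$gene_id, chrom = as.character(df$chrom),
                 start = as.integer(df$start) - 1L, end = as.integer(df$end),
                 strand = ifelse(as.character(df$strand) %in% c("1", "+"), "+", "-"),
                 is_protein_coding = df$biotype == "protein_coding",
                 stringsAsFactors = FALSE)
    })
  if (anyDuplicated(g$gene_id))
    stop("duplicate gene_id in gene table: ",
         g$gene_id[anyDuplicated(g$gene_id)])
  if (any(g$end <= g$start)) stop("gene table has end <= start")
  if (!all(g$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  g$tss <- ifelse(g$strand == "+", g$start, g$end - 1L)
  g$tes <- ifelse(g$strand == "+", g$end - 1L, g$start)
  g
}

# ---- tag tracks -------------------------------------------------------------

#' Build a tag track from 5' tag positions
#'
#' A tag track stores per-chromosome sorted vectors of ChIP-seq tag 5'
#' positions together with the library size (total tag count). Duplicate
#' positions are kept by default (the counting is directional-read based).
#'
#' @param positions Named list of integer vectors (one per chromosome) or a
#'   data frame with columns `chrom` and `pos`.
#' @return An object of class `"tag_track"`.
#' @export
tag_track <- function(positions) {
  if (is.data.frame(positions)) {
    positions <- split(as.integer(positions$pos), as.character(positions$chrom))
  }
  positions <- lapply(positions, function(p) sort(as.integer(p)))
  positions <- positions[order(names(positions))]
  structure(list(positions = positions,
                 library_size = sum(lengths(positions))),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("tag_track: %d tags on %d chromosome(s)\n",
              x$library_size, length(x$positions)))
  invisible(x)
}

#' Read a BED6 tag file as a tag track
#'
#' Each BED6 line is one sequenced tag; its 5' position is `start` on the
#' `+` strand (and for unstranded records) and `end - 1` on the `-` strand.
#'
#' @param path Path to a BED6 file of tags.
#' @return A [tag_track].
#' @export
read_tag_track <- function(path) {
  bed <- read_bed(path, min_columns = 3L)
  if (nrow(bed) == 0L) stop("tag file contains no tags: ", path)
  pos <- ifelse(bed$strand == "-", bed$end - 1L, bed$start)
  tag_track(data.frame(chrom = bed$chrom, pos = pos))
}

#' Count tags falling in intervals
#'
#' Number of tag 5' positions `p` with `start <= p < end`, per interval, by
#' binary search on the sorted per-chromosome position vectors. Chromosomes
#' absent from the track contribute zero counts (sparse genomes are normal).
#'
#' @param track A [tag_track].
#' @param intervals A [gintervals] frame (or any data frame with `chrom`,
#'   `start`, `end`).
#' @return Integer vector of counts, one per interval row.
#' @export
count_tags <- function(track, intervals) {
  stopifnot(inherits(track, "tag_track"))
  n <- nrow(intervals)
  out <- integer(n)
  if (n == 0L) return(out)
  missing_chroms <- character()
  for (ch in unique(intervals$chrom)) {
    idx <- which(intervals$chrom == ch)
    pos <- track$positions[[ch]]
    if (is.null(pos)) {
      missing_chroms <- c(missing_chroms, ch)
      next
    }
    out[idx] <- findInterval(intervals$end[idx] - 1L, pos) -
      findInterval(intervals$start[idx] - 1L, pos)
  }
  if (length(missing_chroms))
    message("count_tags: no tags on chromosome(s) ",
            paste(missing_chroms, collapse = ", "), "; counting 0")
  out
}

# ---- interval arithmetic ----------------------------------------------------

#' Merge intervals closer than a gap
#'
#' Single-linkage merge of intervals whose boundary gap is `<= max_gap` bp
#' (overlapping and book-ended intervals always merge). Strand is ignored.
#'
#' @param x A [gintervals] frame.
#' @param max_gap Maximum boundary gap (bp) across which to merge.
#' @param with_members If `TRUE`, attach a list column `members` with the row
#'   indices of `x` merged into each output interval.
#' @return A sorted [gintervals] frame of merged spans.
#' @export
merge_intervals <- function(x, max_gap = 0L, with_members = FALSE) {
  stopifnot(max_gap >= 0L)
  if (nrow(x) == 0L) return(x[0, , drop = FALSE])
  red <- GenomicRanges::reduce(.gi2gr(x), min.gapwidth = max_gap + 1L,
                               with.revmap = TRUE, ignore.strand = TRUE)
  out <- .gr2gi(red)
  members <- as.list(red$revmap)
  ord <- order(out$chrom, out$start)  # deterministic chrom-then-start order
  out <- .as_gintervals(as.data.frame(out)[ord, , drop = FALSE])
  if (with_members) out$members <- I(members[ord])
  out
}

#' Distance to the nearest subject interval
#'
#' Boundary-gap distance in bp from each query interval to its nearest
#' subject on the same chromosome: 0 when any subject overlaps (or touches)
#' the query, `NA` when the query's chromosome holds no subject.
#'
#' @param query,subjects [gintervals] frames.
#' @return Integer vector of distances (`NA` = no subject on that chromosome).
#' @export
nearest_distance <- function(query, subjects) {
  n <- nrow(query)
  out <- rep(NA_integer_, n)
  if (n == 0L || nrow(subjects) == 0L) return(out)
  qgr <- .gi2gr(query)
  sgr <- .gi2gr(subjects)
  # disjoint seqlevel sets are expected (sparse genomes) -> no warning
  hits <- suppressWarnings(
    GenomicRanges::distanceToNearest(qgr, sgr, ignore.strand = TRUE))
  out[S4Vectors_queryHits(hits)] <- as.integer(S4Vectors_mcols_distance(hits))
  out
}

# minimal accessors to avoid importing S4Vectors wholesale
S4Vectors_queryHits <- function(h) methods::slot(h, "from")
S4Vectors_mcols_distance <- function(h) methods::slot(h, "elementMetadata")$distance

#' Fraction / count of queries overlapping features
#'
#' @param query,features [gintervals] frames.
#' @param slop Symmetric extension (bp) applied to features before overlap.
#' @return Logical vector: does each query overlap any (slopped) feature?
#' @export
overlaps_feature <- function(query, features, slop = 0L) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(features) == 0L) return(rep(FALSE, nrow(query)))
  f <- features
  f$start <- pmax(0L, f$start - as.integer(slop))
  f$end <- f$end + as.integer(slop)
  suppressWarnings(
    GenomicRanges::countOverlaps(.gi2gr(query), .gi2gr(f))) > 0L
}

# ---- chromosome sizes, conservation, PWMs -----------------------------------

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns `chrom` and `length` (comment lines allowed).
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- .read_text_table(path, "chrom sizes")
  dt <- data.table::fread(text = tab$lines, header = TRUE, sep = "\t")
  stats::setNames(as.integer(dt$length), as.character(dt$chrom))
}

#' Read a bedGraph conservation track
#'
#' Loads per-base conservation scores (each in `[0, 1]`) into dense
#' per-chromosome vectors; bases not covered by any bedGraph record are
#' missing (`NA`) and excluded from all averages downstream.
#'
#' @param path bedGraph file (`chrom start end score`, 0-based half-open).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return Object of class `"conservation_track"` with per-chromosome score
#'   vectors and precomputed cumulative sums for O(1) interval means.
#' @export
read_conservation <- function(path, chrom_sizes) {
  tab <- .read_text_table(path, "bedGraph")
  dt <- data.table::fread(text = tab$lines, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "score"))
  if (any(dt$score < 0 | dt$score > 1))
    stop("conservation scores must lie in [0, 1]")
  if (any(dt$end <= dt$start)) stop("bedGraph has end <= start")
  scores <- lapply(names(chrom_sizes), function(ch) {
    v <- rep(NA_real_, chrom_sizes[[ch]])
    sub <- dt[dt$chrom == ch, ]
    if (nrow(sub)) {
      for (i in seq_len(nrow(sub))) {
        v[(sub$start[i] + 1L):min(sub$end[i], length(v))] <- sub$score[i]
      }
    }
    v
  })
  names(scores) <- names(chrom_sizes)
  .conservation_track(scores)
}

.conservation_track <- function(scores) {
  # cum_s[[ch]][k + 1] = sum of scores over the first k bases (NA as 0)
  cum_s <- lapply(scores, function(v) c(0, cumsum(ifelse(is.na(v), 0, v))))
  cum_n <- lapply(scores, function(v) c(0, cumsum(!is.na(v))))
  structure(list(scores = scores, cum_s = cum_s, cum_n = cum_n),
            class = "conservation_track")
}

# per-interval sum of defined-base scores and count of defined bases
.region_score_sums <- function(track, chrom, start, end) {
  n <- length(chrom)
  s_tot <- numeric(n); n_tot <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    cs0 <- track$cum_s[[ch]]; cn0 <- track$cum_n[[ch]]
    if (is.null(cs0)) { s_tot[idx] <- 0; n_tot[idx] <- 0; next }
    L <- length(cs0) - 1L
    lo <- pmin(pmax(start[idx], 0L), L)
    hi <- pmin(pmax(end[idx], 0L), L)
    s_tot[idx] <- cs0[hi + 1L] - cs0[lo + 1L]
    n_tot[idx] <- cn0[hi + 1L] - cn0[lo + 1L]
  }
  list(s = s_tot, n = n_tot)
}

# mean defined-base score over [start, end) per interval; NA if no defined base
.region_mean_scores <- function(track, chrom, start, end) {
  sums <- .region_score_sums(track, chrom, start, end)
  ifelse(sums$n > 0, sums$s / sums$n, NA_real_)
}

#' Mean conservation per interval
#'
#' @param track A [read_conservation] track.
#' @param intervals A [gintervals] frame.
#' @return Numeric vector of per-interval mean scores over defined bases
#'   (`NA` when an interval covers no scored base).
#' @export
region_mean_conservation <- function(track, intervals) {
  stopifnot(inherits(track, "conservation_track"))
  .region_mean_scores(track, intervals$chrom, intervals$start, intervals$end)
}

#' Read a JASPAR plain-text PWM library
#'
#' Parses JASPAR-style count matrices (`>ID name` header followed by four
#' rows `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]`; bracket-less rows
#' are accepted). Counts are converted to per-position probabilities with a
#' pseudocount added to every cell.
#'
#' @param path Path to the matrix file.
#' @param pseudocount Pseudocount added per cell before normalisation.
#' @param background Base frequencies over A, C, G, T (must sum to 1).
#' @return A list of `"pwm"` objects (`id`, `name`, `prob` 4 x L probability
#'   matrix, `background`, `pseudocount`), named by motif id.
#' @export
read_jaspar <- function(path, pseudocount = 0.01,
                        background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(abs(sum(background) - 1) < 1e-9, pseudocount > 0)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' motif headers in ", path)
  pwms <- lapply(seq_along(hdr), function(i) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) < 4L)
      stop("motif block under header '", lines[hdr[i]], "' has fewer than 4 rows")
    head_parts <- strsplit(sub("^>\\s*", "", lines[hdr[i]]), "\\s+")[[1]]
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", " ", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    base_labels <- toupper(substr(trimws(block[1:4]), 1, 1))
    if (!identical(base_labels, c("A", "C", "G", "T")))
      stop("motif rows must be ordered A, C, G, T under '", lines[hdr[i]], "'")
    len <- unique(lengths(rows))
    if (length(len) != 1L)
      stop("ragged count rows under '", lines[hdr[i]], "'")
    if (len < 4L) stop("PWM must have length >= 4: ", head_parts[1])
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    prob <- sweep(counts + pseudocount, 2, colSums(counts) + 4 * pseudocount, "/")
    structure(list(id = head_parts[1],
                   name = if (length(head_parts) > 1) head_parts[2] else head_parts[1],
                   prob = prob, background = background,
                   pseudocount = pseudocount),
              class = "pwm")
  })
  stats::setNames(pwms, vapply(pwms, `[[`, "", "id"))
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s (%s), length %d\n", x$id, x$name, ncol(x$prob)))
  invisible(x)
}

#' Extract interval sequences from a genome
#'
#' @param genome A `Biostrings::DNAStringSet` (e.g. from
#'   `Biostrings::readDNAStringSet`) named by chromosome.
#' @param intervals A [gintervals] frame.
#' @return Character vector of sequences (half-open intervals).
#' @export
get_sequences <- function(genome, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    ch <- intervals$chrom[i]
    if (!ch %in% names(genome)) stop("chromosome missing from genome: ", ch)
    as.character(Biostrings::subseq(genome[[ch]],
                                    start = intervals$start[i] + 1L,
                                    end = intervals$end[i]))
  }, character(1))
}
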