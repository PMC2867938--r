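# Seeded generator of a toy genome with the statistical structure the
# analysis assumes: genes with elongating Pol II and sharp H3K4me3 TSS
# chromatin; extragenic enhancers with broad, low, often condition-dependent
# Pol II and an H3K4me1-high/H3K4me3-low signature; extragenic ncRNA
# promoters with the inverse signature; p300/PU.1 binding, CAGE clusters,
# Ser5-P Pol II, RNA-seq tags, promoter-biased CpG islands, elevated
# conservation at functional elements, and motif instances planted in
# inducible enhancers. Every planted element is recorded in a truth table.

#' Specification of a synthetic dataset
#'
#' Defaults mirror the structure of the stimulated-macrophage study the
#' pipeline is designed around: regulation-class fractions follow the
#' reported constitutive/inducible/repressed split of extragenic Pol II
#' peaks (~20/32/48%), enhancer Pol II is low (mean 60 tags) and broad while
#' gene bodies are tag-dense, the stimulated:unstimulated fold at regulated
#' elements is 4, CpG islands sit at ~72% of coding-gene promoters, ~21% of
#' ncRNA promoters and ~0.5% of enhancers, and p300/PU.1 mark 80%/85% of
#' enhancers (PU.1 also 70% of promoters).
#'
#' @param n_chroms,chrom_length Genome shape.
#' @param n_genes,n_enhancers,n_promoter_ncrna Element counts.
#' @param frac_constitutive,frac_inducible,frac_repressed Regulation-class
#'   fractions (must sum to 1).
#' @param polII_mean_tags Mean Pol II tags of an element in its low
#'   condition.
#' @param gene_body_mean_tags Mean Pol II tags over a gene body (low
#'   condition).
#' @param inducible_fold Expected stimulated/unstimulated tag ratio at
#'   regulated elements.
#' @param me1_mean_tags,me3_mean_tags Mean H3K4me1 tags at an enhancer and
#'   H3K4me3 tags at a TSS.
#' @param me3_me1_ratio_enh H3K4me3 level at enhancers relative to their
#'   H3K4me1 (kept well below 1: the enhancer signature).
#' @param me1_me3_ratio_prom Flanking H3K4me1 at promoters relative to their
#'   H3K4me3.
#' @param background_tag_rate Uniform background tags per bp per track.
#' @param cpg_prob_gene,cpg_prob_promoter,cpg_prob_enhancer CpG island
#'   probabilities per element class.
#' @param p300_frac,pu1_frac_enh,pu1_frac_prom Binding fractions.
#' @param cons_background,cons_functional Mean conservation score of
#'   background and of functional elements.
#' @param rnaseq_rate RNA-seq tags per expected untreated Pol II tag.
#' @param motifs_per_enhancer Planted motif instances per inducible enhancer.
#' @param n_decoy_pwms Decoy matrices written alongside the planted one.
#' @param seed Integer seed driving all sampling.
#' @return A `"synthetic_spec"` list.
#' @export
synthetic_spec <- function(n_chroms = 2L, chrom_length = 5e6L, n_genes = 60L,
                           n_enhancers = 120L, n_promoter_ncrna = 40L,
                           frac_constitutive = 0.20, frac_inducible = 0.32,
                           frac_repressed = 0.48, polII_mean_tags = 60,
                           gene_body_mean_tags = 400, inducible_fold = 4,
                           me1_mean_tags = 150, me3_mean_tags = 150,
                           me3_me1_ratio_enh = 0.15, me1_me3_ratio_prom = 0.4,
                           background_tag_rate = 1e-4,
                           cpg_prob_gene = 0.72, cpg_prob_promoter = 0.21,
                           cpg_prob_enhancer = 0.005, p300_frac = 0.80,
                           pu1_frac_enh = 0.85, pu1_frac_prom = 0.70,
                           cons_background = 0.10, cons_functional = 0.60,
                           rnaseq_rate = 1 / 60, motifs_per_enhancer = 3L,
                           n_decoy_pwms = 10L, seed = 1L) {
  spec <- as.list(environment())
  fr <- frac_constitutive + frac_inducible + frac_repressed
  if (abs(fr - 1) > 1e-9) stop("regulation fractions must sum to 1")
  counts <- c(n_chroms, chrom_length, n_genes, n_enhancers, n_promoter_ncrna)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (n_chroms < 1L || chrom_length < 1e5)
    stop("need at least one chromosome of >= 100 kb")
  if (inducible_fold <= 1) stop("inducible_fold must exceed 1")
  structure(spec, class = "synthetic_spec")
}

.draw_regulation <- function(n, spec) {
  sample(c("constitutive", "inducible", "repressed"), n, replace = TRUE,
         prob = c(spec$frac_constitutive, spec$frac_inducible,
                  spec$frac_repressed))
}

.condition_means <- function(base, regulation, fold) {
  ut <- ifelse(regulation == "repressed", base * fold, base)
  lps <- ifelse(regulation == "inducible", base * fold, base)
  list(ut = ut, lps = lps)
}

.clamp <- function(x, lo, hi) pmin(pmax(as.integer(round(x)), lo), hi)

# the planted inflammatory motif: a strong NF-kB-like site (GGGACTTTCC)
.planted_counts <- function() {
  consensus <- c("G", "G", "G", "A", "C", "T", "T", "T", "C", "C")
  m <- matrix(5, 4, length(consensus), dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) m[consensus[j], j] <- 85
  m
}

.random_decoy_counts <- function(len) {
  m <- matrix(5, 4, len, dimnames = list(c("A", "C", "G", "T"), NULL))
  dom <- sample(4, len, replace = TRUE)
  for (j in seq_len(len)) m[dom[j], j] <- 85
  m
}

# A decoy must be insensitive to the planted motif: scoring random sequence
# with and without planted instances must not shift its mean log score.
# (Partial consensus overlap, e.g. a shared GGG run, would otherwise make a
# "decoy" respond to the planted sites.)
.decoy_ok <- function(counts, planted, n_seqs = 16L, tol = 0.05) {
  dec <- list(prob = sweep(counts + 0.01, 2, colSums(counts) + 0.04, "/"),
              background = rep(0.25, 4))
  plain <- replicate(n_seqs, sample(c("A", "C", "G", "T"), 400, TRUE),
                     simplify = FALSE)
  with_motif <- lapply(plain, function(s) {
    for (at in c(50L, 180L, 310L)) {
      inst <- strsplit(.sample_pwm_instance(planted), "")[[1]]
      s[at:(at + length(inst) - 1L)] <- inst
    }
    s
  })
  sc <- function(seqs) mean(vapply(seqs, function(s)
    log(sequence_score(structure(dec, class = "pwm"),
                       paste(s, collapse = ""))), numeric(1)))
  sc(with_motif) - sc(plain) < tol
}

.make_decoys <- function(n, planted, max_tries = 60L) {
  lapply(seq_len(n), function(i) {
    for (t in seq_len(max_tries)) {
      cand <- .random_decoy_counts(sample(8:12, 1))
      if (.decoy_ok(cand, planted)) return(cand)
    }
    stop("could not generate a planted-motif-insensitive decoy")
  })
}

.write_jaspar <- function(mats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(mats)) {
    writeLines(sprintf(">%s %s", id, id), con)
    m <- mats[[id]]
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b, paste(m[b, ], collapse = " ")), con)
    }
  }
  invisible(path)
}

.sample_pwm_instance <- function(counts) {
  paste(apply(counts, 2, function(col)
    sample(c("A", "C", "G", "T"), 1, prob = col)), collapse = "")
}

.write_tags <- function(pos_df, path) {
  # BED6, one width-1 '+' record per tag (5' position == start)
  dt <- data.table::data.table(chrom = pos_df$chrom, start = pos_df$pos,
                               end = pos_df$pos + 1L, name = ".", score = 0L,
                               strand = "+")
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Generate a synthetic dataset
#'
#' Writes every input the pipeline consumes (gene table, chromosome sizes,
#' Pol II tag BEDs for both conditions, H3K4me1/me3/Ser5/RNA-seq tag BEDs,
#' p300/PU.1/CAGE/CpG BEDs, a conservation bedGraph, the genome FASTA with
#' planted motif instances, a JASPAR matrix file) plus a truth table, and
#' returns a manifest. Running twice with the same spec produces
#' byte-identical files.
#'
#' @param spec A [synthetic_spec].
#' @param out_dir Output directory (created if missing).
#' @return List with `dir`, `manifest` (named paths), `truth` (element truth
#'   table), `genes_truth`, and the `spec`.
#' @export
generate_dataset <- function(spec, out_dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr::with_seed(spec$seed, .generate_dataset_impl(spec, out_dir))
}

.generate_dataset_impl <- function(spec, out_dir) {
  chroms <- sprintf("chr%d", seq_len(spec$n_chroms))
  L <- as.integer(spec$chrom_length)
  chrom_sizes <- stats::setNames(rep(L, spec$n_chroms), chroms)
  fold <- spec$inducible_fold

  # ---- element placement: shuffled types, evenly spaced slots per chrom ----
  types <- c(rep("gene", spec$n_genes), rep("enhancer", spec$n_enhancers),
             rep("promoter", spec$n_promoter_ncrna))
  types <- sample(types)
  chrom_of <- chroms[(seq_along(types) - 1L) %% spec$n_chroms + 1L]
  margin <- 50000L
  centers <- integer(length(types))
  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    n_i <- length(idx)
    if (!n_i) next
    slot <- (L - 2 * margin) / n_i
    centers[idx] <- as.integer(margin + (seq_len(n_i) - 0.5) * slot +
                                 round(stats::runif(n_i, -0.04, 0.04) * slot))
  }
  el <- data.frame(type = types, chrom = chrom_of, center = centers,
                   stringsAsFactors = FALSE)

  # ---- genes ---------------------------------------------------------------
  gi <- which(el$type == "gene")
  glen <- sample(2000:8000, length(gi), replace = TRUE)
  gstrand <- sample(c("+", "-"), length(gi), replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_along(gi)),
    chrom = el$chrom[gi],
    start = .clamp(el$center[gi] - glen %/% 2L, 0L, L - 1L),
    end = .clamp(el$center[gi] + glen %/% 2L, 1L, L),
    strand = gstrand, is_protein_coding = 1L, stringsAsFactors = FALSE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes$tes <- ifelse(genes$strand == "+", genes$end - 1L, genes$start)
  gene_reg <- .draw_regulation(nrow(genes), spec)
  gmeans <- .condition_means(spec$gene_body_mean_tags, gene_reg, fold)

  # ---- extragenic elements -------------------------------------------------
  ei <- which(el$type != "gene")
  elem <- data.frame(
    element_id = sprintf("e%03d", seq_along(ei)),
    class = el$type[ei], chrom = el$chrom[ei], center = el$center[ei],
    stringsAsFactors = FALSE)
  half_span <- ifelse(elem$class == "enhancer", 1750L, 750L)
  elem$start <- .clamp(elem$center - half_span, 0L, L - 1L)
  elem$end <- .clamp(elem$center + half_span, 1L, L)
  elem$regulation <- .draw_regulation(nrow(elem), spec)
  emeans <- .condition_means(spec$polII_mean_tags, elem$regulation, fold)

  # ---- Pol II tags ---------------------------------------------------------
  gene_tags <- function(mean_vec) {
    res <- list()
    for (i in seq_len(nrow(genes))) {
      n <- stats::rpois(1, mean_vec[i])
      n_tss <- stats::rbinom(1, n, 0.3)
      body <- stats::runif(n - n_tss, genes$start[i], genes$end[i])
      tssp <- stats::rnorm(n_tss, genes$tss[i], 100)
      n_off <- stats::rpois(1, 0.15 * mean_vec[i])
      dir <- if (genes$strand[i] == "+") 1 else -1
      runoff <- genes$tes[i] + dir * stats::rexp(n_off, 1 / 2000)
      res[[i]] <- data.frame(chrom = genes$chrom[i],
                             pos = .clamp(c(body, tssp, runoff), 0L, L - 1L))
    }
    do.call(rbind, res)
  }
  elem_tags <- function(mean_vec, sd_enh = 700, sd_prom = 150) {
    res <- list()
    for (i in seq_len(nrow(elem))) {
      n <- stats::rpois(1, mean_vec[i])
      sd <- if (elem$class[i] == "enhancer") sd_enh else sd_prom
      p <- stats::rnorm(n, elem$center[i], sd)
      res[[i]] <- data.frame(chrom = elem$chrom[i],
                             pos = .clamp(p, elem$start[i], elem$end[i] - 1L))
    }
    do.call(rbind, res)
  }
  bg_tags <- function() {
    res <- lapply(chroms, function(ch) {
      n <- stats::rpois(1, spec$background_tag_rate * L)
      data.frame(chrom = ch, pos = .clamp(stats::runif(n, 0, L - 1), 0L, L - 1L))
    })
    do.call(rbind, res)
  }
  # Sequencing depth is matched between conditions, as in a real experiment:
  # the condition with less planted signal mass receives compensating uniform
  # background tags (bulk transcription unchanged by stimulation), so that
  # library normalisation leaves the planted per-element folds intact.
  exp_mass <- function(g, e) 1.15 * sum(g) + sum(e)  # genes incl. 3' runoff
  mass_ut <- exp_mass(gmeans$ut, emeans$ut)
  mass_lps <- exp_mass(gmeans$lps, emeans$lps)
  depth_pad <- function(short_by) {
    if (short_by <= 0) return(NULL)
    per_chrom <- short_by / spec$n_chroms
    res <- lapply(chroms, function(ch) {
      n <- stats::rpois(1, per_chrom)
      data.frame(chrom = ch, pos = .clamp(stats::runif(n, 0, L - 1), 0L, L - 1L))
    })
    do.call(rbind, res)
  }
  polII_ut <- rbind(gene_tags(gmeans$ut), elem_tags(emeans$ut), bg_tags(),
                    depth_pad(mass_lps - mass_ut))
  polII_lps <- rbind(gene_tags(gmeans$lps), elem_tags(emeans$lps), bg_tags(),
                     depth_pad(mass_ut - mass_lps))

  # ---- H3K4me1 / H3K4me3 (untreated chromatin) -----------------------------
  bimodal <- function(n, center, mode_bp, sd) {
    side <- sample(c(-1, 1), n, replace = TRUE)
    stats::rnorm(n, center + side * mode_bp, sd)
  }
  me1 <- list(); me3 <- list()
  for (i in seq_len(nrow(elem))) {
    if (elem$class[i] == "enhancer") {
      n1 <- stats::rpois(1, spec$me1_mean_tags)
      n3 <- stats::rpois(1, spec$me1_mean_tags * spec$me3_me1_ratio_enh)
      p1 <- bimodal(n1, elem$center[i], 1000, 500)
      p3 <- bimodal(n3, elem$center[i], 1000, 600)
    } else {
      n3 <- stats::rpois(1, spec$me3_mean_tags)
      n1 <- stats::rpois(1, spec$me3_mean_tags * spec$me1_me3_ratio_prom)
      p3 <- stats::rnorm(n3, elem$center[i], 300)
      p1 <- bimodal(n1, elem$center[i], 800, 400)
    }
    me1[[length(me1) + 1L]] <- data.frame(chrom = elem$chrom[i],
                                          pos = .clamp(p1, 0L, L - 1L))
    me3[[length(me3) + 1L]] <- data.frame(chrom = elem$chrom[i],
                                          pos = .clamp(p3, 0L, L - 1L))
  }
  for (i in seq_len(nrow(genes))) {  # promoter chromatin at coding TSSs
    n3 <- stats::rpois(1, spec$me3_mean_tags)
    n1 <- stats::rpois(1, spec$me3_mean_tags * spec$me1_me3_ratio_prom)
    me3[[length(me3) + 1L]] <- data.frame(
      chrom = genes$chrom[i],
      pos = .clamp(stats::rnorm(n3, genes$tss[i], 300), 0L, L - 1L))
    me1[[length(me1) + 1L]] <- data.frame(
      chrom = genes$chrom[i],
      pos = .clamp(bimodal(n1, genes$tss[i], 800, 400), 0L, L - 1L))
  }
  me1 <- rbind(do.call(rbind, me1), bg_tags())
  me3 <- rbind(do.call(rbind, me3), bg_tags())

  # ---- Ser5-P Pol II and nuclear RNA-seq -----------------------------------
  ser5 <- list()
  for (i in seq_len(nrow(elem))) {
    n <- stats::rpois(1, 50)
    ser5[[length(ser5) + 1L]] <- data.frame(
      chrom = elem$chrom[i],
      pos = .clamp(stats::rnorm(n, elem$center[i], 300), 0L, L - 1L))
  }
  for (i in seq_len(nrow(genes))) {
    n <- stats::rpois(1, 50)
    ser5[[length(ser5) + 1L]] <- data.frame(
      chrom = genes$chrom[i],
      pos = .clamp(stats::runif(n, genes$start[i], genes$end[i]), 0L, L - 1L))
  }
  ser5 <- rbind(do.call(rbind, ser5), bg_tags())

  rnaseq <- list()
  for (i in seq_len(nrow(elem))) {
    n <- stats::rpois(1, emeans$ut[i] * spec$rnaseq_rate)
    if (n > 0) rnaseq[[length(rnaseq) + 1L]] <- data.frame(
      chrom = elem$chrom[i],
      pos = .clamp(stats::runif(n, elem$start[i], elem$end[i]), 0L, L - 1L))
  }
  for (i in seq_len(nrow(genes))) {
    n <- stats::rpois(1, gmeans$ut[i] * spec$rnaseq_rate * 5)
    if (n > 0) rnaseq[[length(rnaseq) + 1L]] <- data.frame(
      chrom = genes$chrom[i],
      pos = .clamp(stats::runif(n, genes$start[i], genes$end[i]), 0L, L - 1L))
  }
  rnaseq <- rbind(do.call(rbind, rnaseq), bg_tags())

  # ---- p300, PU.1, CAGE, CpG ----------------------------------------------
  enh <- elem$class == "enhancer"
  p300_sel <- which(enh)[stats::runif(sum(enh)) < spec$p300_frac]
  p300 <- gintervals(elem$chrom[p300_sel], elem$center[p300_sel] - 150L,
                     elem$center[p300_sel] + 150L,
                     name = elem$element_id[p300_sel])
  pu1_sel <- c(which(enh)[stats::runif(sum(enh)) < spec$pu1_frac_enh],
               which(!enh)[stats::runif(sum(!enh)) < spec$pu1_frac_prom])
  pu1_sel <- sort(pu1_sel)
  pu1 <- gintervals(elem$chrom[pu1_sel], elem$center[pu1_sel] - 100L,
                    elem$center[pu1_sel] + 100L,
                    name = elem$element_id[pu1_sel])
  cage <- list()
  cage_one <- function(chrom, center, k, spread) {
    mid <- center + round(stats::runif(k, -spread, spread))
    w <- sample(20:50, k, replace = TRUE)
    data.frame(chrom = chrom, start = .clamp(mid - w %/% 2L, 0L, L - 1L),
               end = .clamp(mid + w %/% 2L + 1L, 1L, L))
  }
  for (i in seq_len(nrow(elem))) {
    k <- sample(2:5, 1)
    spread <- if (elem$class[i] == "enhancer") 1500 else 100
    cage[[length(cage) + 1L]] <- cage_one(elem$chrom[i], elem$center[i], k, spread)
  }
  for (i in seq_len(nrow(genes))) {
    cage[[length(cage) + 1L]] <- cage_one(genes$chrom[i], genes$tss[i],
                                          sample(2:4, 1), 80)
  }
  cage <- do.call(rbind, cage)

  elem$cpg <- stats::runif(nrow(elem)) <
    ifelse(enh, spec$cpg_prob_enhancer, spec$cpg_prob_promoter)
  gene_cpg <- stats::runif(nrow(genes)) < spec$cpg_prob_gene
  cpg <- rbind(
    data.frame(chrom = elem$chrom[elem$cpg],
               start = elem$center[elem$cpg] - 300L,
               end = elem$center[elem$cpg] + 500L),
    data.frame(chrom = genes$chrom[gene_cpg],
               start = genes$tss[gene_cpg] - 300L,
               end = genes$tss[gene_cpg] + 500L))
  # a few background islands
  bg_cpg <- do.call(rbind, lapply(chroms, function(ch)
    data.frame(chrom = ch,
               start = as.integer(sort(round(stats::runif(3, 0, L - 1000)))),
               end = NA_integer_)))
  bg_cpg$end <- bg_cpg$start + 600L
  cpg <- rbind(cpg, bg_cpg)
  cpg$start <- .clamp(cpg$start, 0L, L - 1L)
  cpg$end <- .clamp(cpg$end, 1L, L)

  # ---- conservation --------------------------------------------------------
  elem$conserved <- TRUE
  cons <- list()
  for (ch in chroms) {
    tile_starts <- seq.int(0L, L - 1000L, by = 1000L)
    keep <- stats::runif(length(tile_starts)) > 0.03  # leave gaps (missing)
    tile_starts <- tile_starts[keep]
    func <- elem[elem$chrom == ch, , drop = FALSE]
    fs <- func$center - 500L; fe <- func$center + 500L
    hit <- vapply(tile_starts, function(s)
      any(fs < s + 1000L & fe > s), logical(1))
    bgt <- tile_starts[!hit]
    bg_scores <- pmin(pmax(stats::rnorm(length(bgt), spec$cons_background,
                                        0.03), 0), 1)
    ft <- unlist(lapply(seq_len(nrow(func)), function(i)
      seq.int(fs[i], fe[i] - 100L, by = 100L)))
    f_scores <- pmin(pmax(stats::rnorm(length(ft), spec$cons_functional,
                                       0.08), 0), 1)
    d <- rbind(data.frame(start = bgt, end = bgt + 1000L, score = bg_scores),
               data.frame(start = ft, end = ft + 100L, score = f_scores))
    d <- d[d$start >= 0 & d$end <= L, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    cons[[ch]] <- data.frame(chrom = ch, d)
  }
  cons <- do.call(rbind, cons)
  cons$score <- round(cons$score, 4)

  # ---- genome sequence with planted motifs ---------------------------------
  planted <- .planted_counts()
  pwm_mats <- c(list(NFKB_SYN = planted),
                stats::setNames(.make_decoys(spec$n_decoy_pwms, planted),
                                sprintf("DECOY_%02d", seq_len(spec$n_decoy_pwms))))
  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(seqs) <- chroms
  elem$motifs <- ""
  ind_enh <- which(enh & elem$regulation == "inducible")
  for (i in ind_enh) {
    offs <- sort(sample(seq.int(-500L, 490L, by = 10L), spec$motifs_per_enhancer))
    for (o in offs) {
      inst <- strsplit(.sample_pwm_instance(planted), "")[[1]]
      at <- elem$center[i] + o
      if (at >= 0 && at + length(inst) <= L)
        seqs[[elem$chrom[i]]][(at + 1):(at + length(inst))] <- inst
    }
    elem$motifs[i] <- "NFKB_SYN"
  }

  # ---- write everything ----------------------------------------------------
  path <- function(f) file.path(out_dir, f)
  files <- list()
  utils::write.table(genes[, c("gene_id", "chrom", "start", "end", "strand",
                               "is_protein_coding")],
                     path("genes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$genes <- "genes.tsv"
  utils::write.table(data.frame(chrom = chroms, length = L),
                     path("chrom_sizes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files$chrom_sizes <- "chrom_sizes.tsv"
  .write_tags(polII_ut, path("polII_ut.bed"));  files$polII_ut <- "polII_ut.bed"
  .write_tags(polII_lps, path("polII_lps.bed")); files$polII_lps <- "polII_lps.bed"
  .write_tags(me1, path("h3k4me1.bed"));        files$me1 <- "h3k4me1.bed"
  .write_tags(me3, path("h3k4me3.bed"));        files$me3 <- "h3k4me3.bed"
  .write_tags(ser5, path("ser5.bed"));          files$ser5 <- "ser5.bed"
  .write_tags(rnaseq, path("rnaseq.bed"));      files$rnaseq <- "rnaseq.bed"
  write_bed(p300, path("p300.bed"));            files$p300 <- "p300.bed"
  write_bed(pu1, path("pu1.bed"));              files$pu1 <- "pu1.bed"
  write_bed(gintervals(cage$chrom, cage$start, cage$end), path("cage.bed"))
  files$cage <- "cage.bed"
  write_bed(gintervals(cpg$chrom, cpg$start, cpg$end), path("cpg.bed"))
  files$cpg <- "cpg.bed"
  data.table::fwrite(cons, path("conservation.bedgraph"), sep = "\t",
                     col.names = FALSE)
  files$conservation <- "conservation.bedgraph"
  fa <- Biostrings::DNAStringSet(vapply(seqs, paste, "", collapse = ""))
  Biostrings::writeXStringSet(fa, path("genome.fa"))
  files$genome_fasta <- "genome.fa"
  .write_jaspar(pwm_mats, path("pwms.jaspar.txt"))
  files$pwms <- "pwms.jaspar.txt"

  truth <- elem[, c("element_id", "class", "chrom", "start", "end", "center",
                    "regulation", "cpg", "conserved", "motifs")]
  utils::write.table(truth, path("truth_elements.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$truth <- "truth_elements.tsv"
  genes_truth <- data.frame(gene_id = genes$gene_id, regulation = gene_reg,
                            stringsAsFactors = FALSE)
  utils::write.table(genes_truth, path("truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files$truth_genes <- "truth_genes.tsv"
  manifest <- data.frame(role = names(files),
                         path = unlist(files, use.names = FALSE))
  utils::write.table(manifest, path("manifest.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(dir = out_dir,
       manifest = stats::setNames(file.path(out_dir, manifest$path),
                                  manifest$role),
       truth = truth, genes_truth = genes_truth, spec = spec)
}

#' Match discovered clusters to planted truth elements
#'
#' Each cluster is matched to the truth element whose interval it overlaps
#' (the one with the largest overlap when several do). Reports per-cluster
#' matches plus recovery and agreement summaries.
#'
#' @param clusters Cluster frame from [cluster_and_filter] (columns `chrom`,
#'   `start`, `end`, `regulation`, `signature_class`).
#' @param truth Truth table from [generate_dataset].
#' @return List: `matches` (per-cluster truth id, `NA` if unmatched),
#'   `regulation_accuracy`, `class_accuracy`, `unpredictable_fraction`,
#'   `recovery` (fraction of truth elements matched by some cluster).
#' @export
evaluate_against_truth <- function(clusters, truth) {
  n <- nrow(clusters)
  match_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    tt <- truth[truth$chrom == clusters$chrom[i] &
                  truth$start < clusters$end[i] &
                  truth$end > clusters$start[i], , drop = FALSE]
    if (!nrow(tt)) next
    ov <- pmin(tt$end, clusters$end[i]) - pmax(tt$start, clusters$start[i])
    match_id[i] <- tt$element_id[which.max(ov)]
  }
  matched <- !is.na(match_id)
  tm <- truth[match(match_id[matched], truth$element_id), , drop = FALSE]
  cm <- clusters[matched, , drop = FALSE]
  decided <- cm$signature_class %in% c("enhancer", "promoter")
  list(matches = match_id,
       regulation_accuracy = if (any(matched))
         mean(cm$regulation == tm$regulation) else NA_real_,
       class_accuracy = if (any(decided))
         mean(cm$signature_class[decided] == tm$class[decided]) else NA_real_,
       unpredictable_fraction = if (n > 0)
         mean(clusters$signature_class == "unpredictable") else NA_real_,
       recovery = mean(truth$element_id %in% match_id))
}
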