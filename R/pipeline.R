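# End-to-end orchestration: filter -> regulation -> profiles -> classify ->
# cluster -> associations -> conservation -> motifs, with a flat key=value
# config, per-stage TSV/BED outputs, a summary table and a run log.

.CONFIG_DEFAULTS <- list(
  flank3_bp = 10000, continuity_gap_bp = 500, cluster_gap_bp = 2000,
  window_half_bp = 2500, bin_bp = 100, gene_assign_max = 20000,
  pu1_slop = 500, fold_min = 2, p_max = 1e-3, n_random = 1000, alpha = 0.01,
  peak_window_bp = 200, peak_step_bp = 50, peak_p_cutoff = 1e-5,
  peak_min_width = 200, peak_merge_gap_bp = 500, summit_smooth_bp = 500,
  gene_polii_min = 20,
  motif_n_draws = 199, motif_region_half_bp = 500, seed = 1)

#' Pipeline configuration
#'
#' All tunables of the pipeline with their defaults. The constants mirror
#' the analysis design: a 10 kb 3' exclusion flank, +/-2.5 kb signature
#' windows with 100 bp bins, 2 kb peak clustering, gene assignment below
#' 20 kb, +/-500 bp PU.1 search space, fold >= 2 at p <= 1e-3 regulation
#' calls, 1000-set randomisation nulls at alpha = 0.01.
#'
#' @param ... Overrides of the defaults (unknown keys are rejected).
#' @return Named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, over)
  if (any(vapply(cfg, function(v) !is.numeric(v) || v <= 0, logical(1))))
    stop("all config values must be positive numbers")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a flat key=value config file
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Unknown keys raise an error naming the key.
#'
#' @param path Config file path.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: '", lines[bad][1], "'")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[[`, "", 2L)))
  if (anyNA(vals))
    stop("non-numeric config value for key: ", keys[is.na(vals)][1])
  do.call(pipeline_config, stats::setNames(as.list(vals), keys))
}

.read_manifest <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    tab <- .read_text_table(x, "manifest")
    dt <- data.table::fread(text = tab$lines, header = TRUE, sep = "\t")
    paths <- file.path(dirname(x), dt$path)
    # manifest paths may already be absolute or relative to the manifest
    paths <- ifelse(file.exists(dt$path), dt$path, paths)
    return(stats::setNames(paths, dt$role))
  }
  unlist(x)
}

.need <- function(manifest, role) {
  if (!role %in% names(manifest))
    stop("missing input role in manifest: ", role)
  p <- manifest[[role]]
  if (!file.exists(p)) stop(sprintf("input '%s' not found: %s", role, p))
  p
}

#' Run the full discovery pipeline
#'
#' Executes every stage on a set of input files (a manifest: named list or a
#' two-column `role<TAB>path` TSV) or on a freshly generated synthetic
#' dataset, writing per-stage outputs, a summary table and a run log into
#' `out_dir`.
#'
#' Required manifest roles: `genes`, `chrom_sizes`, `polII_ut`, `polII_lps`,
#' `me1`, `me3`, `p300`. Optional roles (stages are skipped without them):
#' `ser5`, `pu1`, `cage`, `cpg`, `rnaseq`, `conservation`, `genome_fasta`,
#' `pwms`, `peaks` (pre-called Pol II peak intervals; otherwise the built-in
#' caller runs on the pooled tag tracks).
#'
#' @param config A [pipeline_config].
#' @param inputs Manifest (named list/vector of paths, or path to a
#'   manifest TSV). Ignored when `simulate` is given.
#' @param simulate Optional [synthetic_spec]; the dataset is generated under
#'   `out_dir/data` and then analysed.
#' @param out_dir Report directory (created).
#' @return Invisibly, a list with the main per-stage results and the
#'   `summary` data frame.
#' @export
run_pipeline <- function(config = pipeline_config(), inputs = NULL,
                         simulate = NULL, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  cat("# extrapol run log\n", file = log_path)
  logf("package version: %s", as.character(utils::packageVersion("extrapol")))
  logf("config: %s", paste(sprintf("%s=%g", names(config), unlist(config)),
                           collapse = " "))
  truth <- NULL
  if (!is.null(simulate)) {
    logf("stage simulate: generating synthetic dataset (seed %d)",
         simulate$seed)
    gen <- generate_dataset(simulate, file.path(out_dir, "data"))
    manifest <- gen$manifest
    truth <- gen$truth
  } else {
    if (is.null(inputs)) stop("either 'inputs' or 'simulate' must be given")
    manifest <- .read_manifest(inputs)
  }
  res <- list(manifest = manifest, truth = truth)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # ---- load core inputs ----------------------------------------------------
  genes <- stage("inputs", read_gene_table(.need(manifest, "genes")))
  chrom_sizes <- stage("inputs", read_chrom_sizes(.need(manifest, "chrom_sizes")))
  ut <- stage("inputs", read_tag_track(.need(manifest, "polII_ut")))
  lps <- stage("inputs", read_tag_track(.need(manifest, "polII_lps")))
  me1 <- stage("inputs", read_tag_track(.need(manifest, "me1")))
  me3 <- stage("inputs", read_tag_track(.need(manifest, "me3")))
  pooled <- tag_track(stats::setNames(lapply(
    union(names(ut$positions), names(lps$positions)),
    function(ch) c(ut$positions[[ch]], lps$positions[[ch]])),
    union(names(ut$positions), names(lps$positions))))
  gene_bodies <- gintervals(genes$chrom, genes$start, genes$end)

  # ---- peaks ---------------------------------------------------------------
  peaks <- stage("peaks", {
    if ("peaks" %in% names(manifest)) read_bed(manifest[["peaks"]])
    else call_peaks(pooled, chrom_sizes, window_bp = config$peak_window_bp,
                    step_bp = config$peak_step_bp,
                    p_cutoff = config$peak_p_cutoff,
                    min_width = config$peak_min_width,
                    merge_gap_bp = config$peak_merge_gap_bp)
  })
  logf("stage peaks: %d candidate regions", nrow(peaks))

  # ---- extragenic filtering ------------------------------------------------
  filt <- stage("filter", filter_extragenic(
    peaks, genes, track = pooled, flank3_bp = config$flank3_bp,
    continuity_gap_bp = config$continuity_gap_bp))
  exg <- filt$retained
  logf("stage filter: %d extragenic peaks retained, %d rejected",
       nrow(exg), nrow(filt$rejected))
  if (nrow(filt$rejected))
    utils::write.table(filt$rejected, file.path(out_dir, "rejected_peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(exg) == 0L) stop("stage 'filter' failed: no extragenic peaks left")

  # ---- summits + regulation ------------------------------------------------
  exg$summit <- stage("summits",
                      find_summit(pooled, exg, config$summit_smooth_bp))
  reg <- stage("regulation", {
    tu <- count_tags(ut, exg); tl <- count_tags(lps, exg)
    cbind(tags_ut = tu, tags_lps = tl,
          classify_regulation(tu, tl, ut$library_size, lps$library_size,
                              fold_min = config$fold_min,
                              p_max = config$p_max))
  })
  exg <- cbind(exg, reg)
  exg$regulation <- as.character(exg$regulation)
  logf("stage regulation: %s",
       paste(sprintf("%s=%d", names(table(exg$regulation)),
                     as.integer(table(exg$regulation))), collapse = " "))

  # ---- signature classification --------------------------------------------
  p300 <- stage("inputs", read_bed(.need(manifest, "p300")))
  tss <- data.frame(chrom = genes$chrom, pos = genes$tss)
  model <- stage("classify", {
    n_per_class <- min(nrow(p300), nrow(tss))
    training <- build_training_set(p300, tss, me1, me3,
                                   n_per_class = n_per_class,
                                   min_tss_dist = config$window_half_bp,
                                   seed = config$seed,
                                   window_half_bp = config$window_half_bp,
                                   bin_bp = config$bin_bp)
    train_signature_classifier(training, seed = config$seed)
  })
  write_signature_model(model, file.path(out_dir, "signature_model.tsv"))
  pred <- stage("classify", {
    pm <- profile_matrix(me1, me3,
                         data.frame(chrom = exg$chrom, summit = exg$summit),
                         config$window_half_bp, config$bin_bp)
    predict_signature(model, pm$X, pm$zero_signal)
  })
  exg$signature_class <- pred$class
  exg$signature_score <- pred$score
  logf("stage classify: CV accuracy %.3f; %s",
       mean(model$cv_accuracy, na.rm = TRUE),
       paste(sprintf("%s=%d", names(table(exg$signature_class)),
                     as.integer(table(exg$signature_class))), collapse = " "))
  utils::write.table(as.data.frame(exg), file.path(out_dir, "extragenic_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # ---- clustering ----------------------------------------------------------
  clusters <- stage("cluster",
                    cluster_and_filter(exg, genes, config$cluster_gap_bp))
  clusters$summit <- stage("cluster", find_summit(pooled, clusters,
                                                  config$summit_smooth_bp))
  logf("stage cluster: %d clusters (%s)", nrow(clusters),
       paste(sprintf("%s=%d", names(table(clusters$signature_class)),
                     as.integer(table(clusters$signature_class))),
             collapse = " "))
  res$peaks <- exg
  res$clusters <- clusters
  res$model <- model
  cl_by <- split(seq_len(nrow(clusters)), clusters$signature_class)
  cl_gi <- .as_gintervals(data.frame(
    chrom = clusters$chrom, start = clusters$start, end = clusters$end,
    strand = ".", name = clusters$name, score = NA_real_,
    stringsAsFactors = FALSE))
  utils::write.table(
    data.frame(clusters[, c("chrom", "start", "end", "name", "n_members",
                            "regulation", "signature_class", "summit")]),
    file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # ---- associations --------------------------------------------------------
  assoc <- list()
  if ("cpg" %in% names(manifest)) {
    cpg <- read_bed(manifest[["cpg"]])
    assoc$cpg <- stage("associate", lapply(cl_by[c("enhancer", "promoter")],
      function(ix) {
        if (!length(ix)) return(NULL)
        overlap_fraction_with_null(cl_gi[ix, ], cpg, chrom_sizes,
                                   n_random = config$n_random,
                                   exclude = gene_bodies,
                                   seed = config$seed)
      }))
  }
  pc_genes <- genes[genes$is_protein_coding, , drop = FALSE]
  assoc$gene_regulation <- stage("associate", {
    tssw <- gintervals(pc_genes$chrom, pmax(0L, pc_genes$tss - 500L),
                       pc_genes$tss + 501L)
    tu <- count_tags(ut, tssw); tl <- count_tags(lps, tssw)
    gr <- classify_regulation(tu, tl, ut$library_size, lps$library_size,
                              fold_min = config$fold_min, p_max = config$p_max)
    data.frame(gene_id = pc_genes$gene_id,
               regulation = as.character(gr$regulation),
               polII_positive = tu + tl >= config$gene_polii_min)
  })
  assoc$enhancer_gene <- stage("associate", {
    eix <- cl_by[["enhancer"]]
    if (!length(eix)) NULL else {
      asg <- assign_to_genes(clusters[eix, ], pc_genes,
                             max_dist = config$gene_assign_max)
      asg$cluster <- clusters$name[eix]
      asg$enhancer_regulation <- clusters$regulation[eix]
      asg
    }
  })
  assoc$gene_class_enrichment <- stage("associate", {
    ag <- assoc$enhancer_gene
    greg <- assoc$gene_regulation
    pos_labels <- greg$regulation[greg$polII_positive]
    if (is.null(ag) || !any(ag$assigned) || !length(pos_labels)) NULL
    else {
      lab <- function(sel) {
        ids <- ag$gene_id[sel & ag$assigned]
        greg$regulation[match(ids, greg$gene_id)]
      }
      out <- list()
      for (r in c("inducible", "repressed")) {
        al <- lab(ag$enhancer_regulation == r)
        if (length(al))
          out[[r]] <- gene_class_enrichment(al, pos_labels)
      }
      out
    }
  })
  if ("pu1" %in% names(manifest)) {
    pu1 <- read_bed(manifest[["pu1"]])
    assoc$pu1 <- stage("associate", lapply(cl_by, function(ix) {
      if (!length(ix)) return(NULL)
      overlap_fraction_with_null(cl_gi[ix, ], pu1, chrom_sizes,
                                 n_random = max(100L, config$n_random %/% 10L),
                                 slop = config$pu1_slop,
                                 exclude = gene_bodies, seed = config$seed)
    }))
  }
  if ("cage" %in% names(manifest)) {
    cage <- read_bed(manifest[["cage"]])
    assoc$cage <- stage("associate", {
      sp <- cage_spacing_summary(cl_gi, cage)
      sp$signature_class <- clusters$signature_class
      sp
    })
  }
  if ("ser5" %in% names(manifest)) {
    ser5 <- read_tag_track(manifest[["ser5"]])
    assoc$ser5 <- stage("associate", {
      sp <- call_peaks(ser5, chrom_sizes, window_bp = config$peak_window_bp,
                       step_bp = config$peak_step_bp,
                       p_cutoff = config$peak_p_cutoff,
                       min_width = config$peak_min_width)
      eix <- cl_by[["enhancer"]]
      list(peaks = sp,
           peak_lengths = sp$end - sp$start,
           enhancer_distances = if (length(eix))
             distance_to_nearest_distribution(cl_gi[eix, ], sp) else NULL)
    })
  }
  if ("rnaseq" %in% names(manifest)) {
    rna <- read_tag_track(manifest[["rnaseq"]])
    assoc$rnaseq <- stage("associate",
                          tag_support_comparison(cl_gi, rna, ut))
  }
  res$assoc <- assoc

  # ---- conservation --------------------------------------------------------
  if ("conservation" %in% names(manifest)) {
    cons <- stage("conserve",
                  read_conservation(manifest[["conservation"]], chrom_sizes))
    res$conservation <- stage("conserve", lapply(
      cl_by[intersect(c("enhancer", "promoter", "unpredictable"),
                      names(cl_by))],
      function(ix) {
        if (!length(ix)) return(NULL)
        su <- data.frame(chrom = clusters$chrom[ix],
                         summit = clusters$summit[ix])
        list(profile = conservation_profile(cons, su, config$window_half_bp),
             test = conservation_significance(
               cl_gi[ix, ], cons, chrom_sizes, exclude = gene_bodies,
               n_random = config$n_random, seed = config$seed,
               alpha = config$alpha))
      }))
    for (grp in names(res$conservation)) {
      t <- res$conservation[[grp]]$test
      logf("stage conserve: %s observed %.3f p=%.3g", grp, t$observed,
           t$p_value)
    }
  }

  # ---- motifs --------------------------------------------------------------
  if (all(c("genome_fasta", "pwms") %in% names(manifest))) {
    res$motifs <- stage("motifs", {
      genome <- Biostrings::readDNAStringSet(manifest[["genome_fasta"]])
      names(genome) <- sub("\\s.*$", "", names(genome))
      pwms <- read_jaspar(manifest[["pwms"]])
      hw <- config$motif_region_half_bp
      groups <- list()
      eix <- cl_by[["enhancer"]]
      for (r in c("constitutive", "inducible", "repressed")) {
        ix <- eix[clusters$regulation[eix] == r]
        if (length(ix) >= 3L) {
          ri <- gintervals(clusters$chrom[ix],
                           pmax(0L, clusters$summit[ix] - hw),
                           clusters$summit[ix] + hw)
          groups[[paste0(r, "_enhancers")]] <- get_sequences(genome, ri)
        }
      }
      # background 1: the whole last chromosome, in 5 kb pieces;
      # background 2: the 5 kb upstream of every coding-gene TSS
      bgchr <- names(genome)[length(genome)]
      bglen <- Biostrings::width(genome[bgchr])
      starts <- seq.int(0L, bglen - 5000L, by = 5000L)
      bg1 <- get_sequences(genome, gintervals(bgchr, starts, starts + 5000L))
      up <- ifelse(pc_genes$strand == "+",
                   pmax(0L, pc_genes$tss - 5000L), pc_genes$tss + 1L)
      bg2 <- get_sequences(genome, gintervals(pc_genes$chrom, up, up + 5000L))
      backgrounds <- list(genome_bg = bg1, upstream5k_bg = bg2)
      tab <- motif_enrichment_table(pwms, groups, backgrounds,
                                    n_draws = config$motif_n_draws,
                                    seed = config$seed)
      utils::write.table(tab, file.path(out_dir, "motif_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(table = tab, groups = names(groups))
    })
    hits <- with(res$motifs$table, unique(motif_id[p_value < 0.01]))
    logf("stage motifs: %d motif(s) enriched at p<0.01: %s", length(hits),
         paste(hits, collapse = ", "))
  }

  # ---- summary -------------------------------------------------------------
  reg_tab <- table(factor(exg$regulation, c("constitutive", "inducible",
                                            "repressed")))
  cls_tab <- table(factor(clusters$signature_class,
                          c("enhancer", "promoter", "unpredictable")))
  summary_df <- rbind(
    data.frame(key = paste0("peaks_", names(reg_tab)),
               value = as.numeric(reg_tab)),
    data.frame(key = "peaks_total", value = nrow(exg)),
    data.frame(key = paste0("clusters_", names(cls_tab)),
               value = as.numeric(cls_tab)),
    data.frame(key = "clusters_total", value = nrow(clusters)),
    data.frame(key = paste0("clusters_pct_", names(cls_tab)),
               value = as.numeric(100 * cls_tab / max(1, sum(cls_tab)))),
    data.frame(key = "classifier_cv_accuracy",
               value = mean(model$cv_accuracy, na.rm = TRUE)))
  if (!is.null(truth)) {
    ev <- evaluate_against_truth(clusters, truth)
    res$evaluation <- ev
    summary_df <- rbind(summary_df, data.frame(
      key = c("truth_recovery", "truth_regulation_accuracy",
              "truth_class_accuracy", "truth_unpredictable_fraction"),
      value = c(ev$recovery, ev$regulation_accuracy, ev$class_accuracy,
                ev$unpredictable_fraction)))
    logf("stage evaluate: recovery %.3f, class accuracy %.3f, regulation accuracy %.3f",
         ev$recovery, ev$class_accuracy, ev$regulation_accuracy)
  }
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$summary <- summary_df
  logf("pipeline complete: %d peaks, %d clusters", nrow(exg), nrow(clusters))
  invisible(res)
}

#' Class counts as shares
#'
#' Turns a named vector of per-class counts into a share table (fractions
#' and percentages) — the tabular analogue of the dataset pie charts.
#'
#' @param counts Named numeric vector of counts.
#' @return Data frame with `class`, `n`, `fraction`, `pct`.
#' @export
summarize_class_counts <- function(counts) {
  stopifnot(length(counts) > 0, all(counts >= 0), sum(counts) > 0)
  data.frame(class = names(counts), n = as.numeric(counts),
             fraction = as.numeric(counts) / sum(counts),
             pct = 100 * as.numeric(counts) / sum(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
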