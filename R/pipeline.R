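#' Analysis options for the UV-response pipeline
#'
#' All thresholds default to the standard choices for this analysis: 2-fold
#' repression/induction calls, a +/-10% dependency band at the 24.5 h
#' recovery timepoint, 5 kb promoter extension, peak filters FDR < 1 and
#' fold enrichment > 10, and a 10 J/m2 dose for the lesion model.
#'
#' @param control control condition name.
#' @param threshold_fold fold-change for repression/induction calls.
#' @param band half-width of the independent dependency band.
#' @param recovery_timepoint hours post UVC for recovery calls.
#' @param upstream promoter extension in bp.
#' @param fdr_max,fold_enrichment_min peak filters.
#' @param dose UVC dose (J/m2) for the lesion model.
#' @param mode replicate handling for ratios: "replicate_mean" (default for
#'   summary-level classification) or "per_replicate" (classify one chosen
#'   replicate; see `replicate`).
#' @param replicate replicate used when `mode = "per_replicate"`.
#' @return list of class `uv_options`.
#' @export
uv_options <- function(control = "control", threshold_fold = 2, band = 0.10,
                       recovery_timepoint = 24.5, upstream = 5000,
                       fdr_max = 1, fold_enrichment_min = 10, dose = 10,
                       mode = c("replicate_mean", "per_replicate"),
                       replicate = 1L) {
  mode <- match.arg(mode)
  stopifnot(threshold_fold > 0, band > 0, band < 1, upstream >= 0, dose > 0)
  structure(list(control = control, threshold_fold = threshold_fold,
                 band = band, recovery_timepoint = recovery_timepoint,
                 upstream = upstream, fdr_max = fdr_max,
                 fold_enrichment_min = fold_enrichment_min, dose = dose,
                 mode = mode, replicate = replicate),
            class = "uv_options")
}

#' Run the full UV-response analysis
#'
#' Executes quantification (RPKM, biological scaling normalisation,
#' baseline ratios), UV-response and kinetics classification, dependency
#' calls per knockdown, gene partitions, the Poisson lesion-load model with
#' the predicted-damaged vs observed-dependent contrast on the shortest
#' quartile of UV-repressed genes, and (if peaks are given) promoter-extended
#' peak intersection with Fisher overlap tests against the UV-repressed set.
#'
#' @param x input: a `uv_simulation` (from [simulate_uv_experiment()]), a
#'   `cohort_config` (simulated on the fly), or a `bru_experiment` in state
#'   "counts" or "rpkm" (supply `factors`).
#' @param factors `scaling_factor_table`; taken from the simulation when
#'   `x` is one.
#' @param peaks optional peak data.frame (BED-like with fdr and
#'   fold_enrichment) or the result of [generate_peaks()].
#' @param options `uv_options`.
#' @return object of class `uv_run`.
#' @export
run_pipeline <- function(x, factors = NULL, peaks = NULL,
                         options = uv_options()) {
  UseMethod("run_pipeline")
}

#' @export
run_pipeline.cohort_config <- function(x, factors = NULL, peaks = NULL,
                                       options = uv_options()) {
  run_pipeline(simulate_uv_experiment(x), factors, peaks, options)
}

#' @export
run_pipeline.uv_simulation <- function(x, factors = NULL, peaks = NULL,
                                       options = uv_options()) {
  analyse_uv_experiment(x$experiment, factors %||% x$factors, peaks, options,
                        truth = x$truth)
}

#' @export
run_pipeline.bru_experiment <- function(x, factors = NULL, peaks = NULL,
                                        options = uv_options()) {
  if (is.null(factors)) stop("a scaling-factor table is required")
  analyse_uv_experiment(x, factors, peaks, options)
}

#' Run the pipeline from TSV/BED input files
#'
#' @param counts,samples,factors,annotation input paths (see the readers).
#' @param peaks optional BED6+ peak path.
#' @param options `uv_options`.
#' @param state state of the matrix file.
#' @param one_based annotation coordinates are 1-based inclusive.
#' @return `uv_run`.
#' @export
run_pipeline_files <- function(counts, samples, factors, annotation,
                               peaks = NULL, options = uv_options(),
                               state = "counts", one_based = FALSE) {
  ann <- read_annotation(annotation, one_based = one_based)
  exp <- read_bru_experiment(counts, samples, ann, state = state)
  fac <- read_factor_table(factors)
  pk <- if (!is.null(peaks)) read_peaks_bed(peaks)
  analyse_uv_experiment(exp, fac, pk, options)
}

analyse_uv_experiment <- function(experiment, factors, peaks = NULL,
                                  options = uv_options(), truth = NULL) {
  stopifnot(inherits(experiment, "bru_experiment"),
            inherits(options, "uv_options"))
  opt <- options
  if (experiment$state == "counts") experiment <- compute_rpkm(experiment)
  annotation <- experiment$annotation
  if (is.null(annotation)) stop("a gene annotation is required")
  rpkm <- experiment
  scaled <- apply_scaling(rpkm, factors)
  ratios <- relative_to_baseline(scaled, mode = opt$mode)
  replicate <- if (opt$mode == "per_replicate") opt$replicate

  response <- call_uv_response(ratios, opt$control, opt$threshold_fold,
                               replicate)
  response <- call_kinetics(response, ratios)
  repressed <- response$gene_id[response$response == "repressed"]

  # baseline expression: mean unirradiated RPKM over replicates (control)
  base_cols <- rpkm$samples$sample_id[
    rpkm$samples$condition == opt$control & rpkm$samples$timepoint == 0]
  baseline <- rowMeans(rpkm$values[, base_cols, drop = FALSE])
  analysed <- names(baseline)[baseline > 0]
  partitions <- partition_genes(annotation, baseline[analysed])

  knockdowns <- setdiff(unique(experiment$samples$condition), opt$control)
  dependency <- lapply(stats::setNames(knockdowns, knockdowns), function(kd) {
    call_dependency(ratios, repressed, kd, opt$control,
                    opt$recovery_timepoint, opt$band, replicate)
  })
  dep_summary <- lapply(dependency, summarize_dependency)

  params <- lesion_params(dose = opt$dose)
  damage <- damage_table(annotation, params, analysed)

  # predicted damage vs observed dependence on the shortest quartile of
  # UV-repressed genes (the genes least likely to carry a lesion)
  fig_pair <- NULL
  short_cutoff <- NA_real_
  if (length(repressed) >= 4 && length(knockdowns)) {
    rep_len <- gene_lengths(annotation, repressed)
    short_cutoff <- unname(stats::quantile(rep_len, 0.25, type = 1))
    short_rep <- rep_len[rep_len <= short_cutoff]
    fig_pair <- damage_vs_dependency(short_rep, dependency[[1]], params)
  }

  targets <- NULL
  overlaps <- NULL
  if (!is.null(peaks)) {
    if (is.list(peaks) && !is.data.frame(peaks)) peaks <- peaks$peaks
    kept <- filter_peaks(peaks, opt$fdr_max, opt$fold_enrichment_min)
    ext <- extend_upstream(annotation[annotation$gene_id %in% analysed, ,
                                      drop = FALSE], opt$upstream)
    targets <- intersect_targets(ext, kept)
    overlaps <- list(
      targets_vs_repressed = overlap_fisher(
        names(targets)[targets], intersect(repressed, analysed), analysed))
  }

  curves <- lapply(stats::setNames(nm = unique(experiment$samples$condition)),
                   function(cond) {
                     if (!length(repressed)) return(NULL)
                     mean_response_curve(ratios, repressed, cond, replicate)
                   })

  counts_tab <- table(factor(response$response,
                             c("repressed", "induced", "unchanged",
                               "excluded")))
  summary <- list(
    n_genes = nrow(experiment$values),
    n_analysed = length(analysed),
    response_counts = as.list(counts_tab),
    kinetics_fractions = if (length(repressed)) {
      k <- response$kinetics[response$response == "repressed"]
      list(fast = mean(k == "fast"), slow = mean(k == "slow"))
    },
    dependency = lapply(dep_summary, function(s)
      list(fractions = as.list(s$fractions), n = s$n,
           n_excluded = s$n_excluded)),
    length_median = attr(partitions, "length_median"),
    rpkm_median = attr(partitions, "rpkm_median"),
    short_repressed_cutoff = short_cutoff,
    damage_vs_dependency = fig_pair,
    overlap = if (!is.null(overlaps))
      lapply(overlaps, unclass)
  )

  structure(list(options = opt, ratios = ratios, response = response,
                 dependency = dependency, partitions = partitions,
                 damage = damage, targets = targets, overlaps = overlaps,
                 curves = curves, summary = summary, truth = truth,
                 experiment = scaled),
            class = "uv_run")
}

#' @export
print.uv_run <- function(x, ...) {
  s <- x$summary
  cat("UV-response run: ", s$n_genes, " genes, ", s$n_analysed,
      " analysed (baseline RPKM > 0)\n", sep = "")
  cat("  repressed ", s$response_counts$repressed,
      " | induced ", s$response_counts$induced,
      " | unchanged ", s$response_counts$unchanged,
      " | excluded ", s$response_counts$excluded, "\n", sep = "")
  if (!is.null(s$kinetics_fractions)) {
    cat(sprintf("  kinetics: %.1f%% fast / %.1f%% slow\n",
                100 * s$kinetics_fractions$fast,
                100 * s$kinetics_fractions$slow))
  }
  for (kd in names(s$dependency)) {
    f <- s$dependency[[kd]]$fractions
    cat(sprintf("  %s: stimulated %.1f%% / independent %.1f%% / inhibited %.1f%% (n = %d)\n",
                kd, 100 * f$stimulated, 100 * f$independent,
                100 * f$inhibited, s$dependency[[kd]]$n))
  }
  if (!is.null(s$damage_vs_dependency)) {
    cat(sprintf("  shortest-quartile repressed genes (<= %s bp): %.0f%% predicted damaged vs %.0f%% knockdown-dependent\n",
                format(s$short_repressed_cutoff, big.mark = ","),
                100 * s$damage_vs_dependency$predicted_damaged_fraction,
                100 * s$damage_vs_dependency$observed_dependent_fraction))
  }
  if (!is.null(x$overlaps)) {
    cat("  peak targets vs repressed: p = ",
        format(x$overlaps$targets_vs_repressed$p_value, digits = 3), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
summary.uv_run <- function(object, ...) object$summary

#' Ratio heatmap matrix for export
#'
#' Genes x (condition, timepoint) matrix of baseline-normalised ratios for
#' the UV-repressed genes, after the complete-case filter (genes with
#' RPKM = 0 in any condition excluded), ranked by gene length. Restrict with
#' `max_length` for the short-gene view.
#'
#' @param run `uv_run`.
#' @param max_length optional gene-length cutoff in bp.
#' @return numeric matrix; rownames gene ids (shortest first), colnames
#'   "condition@timepoint".
#' @export
heatmap_matrix <- function(run, max_length = NULL) {
  stopifnot(inherits(run, "uv_run"))
  repressed <- run$response$gene_id[run$response$response == "repressed"]
  conds <- unique(run$experiment$samples$condition)
  keep <- intersect(repressed, filter_complete_cases(run$experiment, conds))
  len <- gene_lengths(run$experiment$annotation, keep)
  if (!is.null(max_length)) keep <- keep[len[keep] <= max_length]
  keep <- keep[order(len[keep])]
  rep_arg <- if (run$options$mode == "per_replicate") run$options$replicate
  cols <- do.call(cbind, lapply(conds, function(cond) {
    m <- ratio_matrix(run$ratios, cond, rep_arg)
    m <- m[keep, , drop = FALSE]
    colnames(m) <- paste0(cond, "@", colnames(m))
    m
  }))
  cols
}

#' Plot a UV-response run
#'
#' Base-graphics panels: mean transcription curves of UV-repressed genes
#' per condition (mean +/- sd), the dependency pie, and the predicted
#' damaged vs observed dependent bar pair for the shortest repressed
#' quartile. Empty panels are skipped with a warning.
#'
#' @param x `uv_run`.
#' @param which subset of panels (1:3).
#' @param ... ignored.
#' @export
plot.uv_run <- function(x, which = 1:3, ...) {
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  if (1 %in% which) {
    curves <- Filter(Negate(is.null), x$curves)
    if (!length(curves)) {
      warning("no UV-repressed genes; curve panel omitted")
    } else {
      cols <- seq_along(curves)
      ylim <- c(0, max(vapply(curves, function(d) max(d$mean + d$sd), 0), 1))
      graphics::plot(NA, xlim = range(curves[[1]]$timepoint), ylim = ylim,
                     xlab = "time post UVC (h)",
                     ylab = "nascent transcription (relative to no UV)",
                     main = sprintf("UV-repressed genes (n = %d)",
                                    curves[[1]]$n[1]))
      graphics::abline(h = 1, lty = 3, col = "grey")
      for (i in seq_along(curves)) {
        d <- curves[[i]]
        graphics::lines(d$timepoint, d$mean, type = "b", col = cols[i],
                        pch = 16)
        has_sd <- d$sd > 0
        if (any(has_sd)) {
          graphics::arrows(d$timepoint[has_sd], (d$mean - d$sd)[has_sd],
                           d$timepoint[has_sd], (d$mean + d$sd)[has_sd],
                           angle = 90, code = 3, length = 0.03,
                           col = cols[i])
        }
      }
      graphics::legend("bottomright", names(curves), col = cols, lty = 1,
                       bty = "n")
    }
  }
  if (2 %in% which) {
    if (!length(x$dependency)) {
      warning("no knockdown condition; dependency panel omitted")
    } else {
      s <- summarize_dependency(x$dependency[[1]])
      graphics::pie(s$fractions,
                    labels = sprintf("%s (%.1f%%)", names(s$fractions),
                                     100 * s$fractions),
                    main = paste0("recovery dependency: ",
                                  names(x$dependency)[1]))
    }
  }
  if (3 %in% which) {
    p <- x$summary$damage_vs_dependency
    if (is.null(p)) {
      warning("no damage-vs-dependency contrast; panel omitted")
    } else {
      graphics::barplot(
        c(predicted = p$predicted_damaged_fraction,
          observed = p$observed_dependent_fraction),
        ylim = c(0, 1), ylab = "fraction of short repressed genes",
        main = "predicted damaged vs knockdown-dependent")
    }
  }
  invisible(x)
}

#' Write the machine-readable run report
#'
#' Writes the per-gene classification TSV (response, kinetics, dependency
#' per knockdown with relative recovery, partitions, damage probability,
#' peak-target flag, exclusion reason), the heatmap matrix TSV, and a
#' summary JSON with class fractions, curves, the damage-vs-dependency
#' pair, overlap tests and provenance (options, package version).
#'
#' @param run `uv_run`.
#' @param dir output directory.
#' @return invisibly, paths written.
#' @export
write_run_report <- function(run, dir) {
  stopifnot(inherits(run, "uv_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- run$response
  cls <- merge(cls, run$partitions[, c("gene_id", "length", "baseline_rpkm",
                                       "length_class", "length_quartile",
                                       "expression_class", "biotype_class")],
               by = "gene_id", all.x = TRUE)
  for (kd in names(run$dependency)) {
    d <- run$dependency[[kd]][, c("gene_id", "relative_recovery",
                                  "dependency")]
    names(d)[-1] <- paste0(names(d)[-1], ".", kd)
    cls <- merge(cls, d, by = "gene_id", all.x = TRUE)
  }
  cls <- merge(cls, run$damage[, c("gene_id", "lambda", "prob_damaged")],
               by = "gene_id", all.x = TRUE)
  if (!is.null(run$targets)) {
    cls$peak_target <- unname(run$targets[cls$gene_id])
  }
  tsv <- function(df, file, ...) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, ...)
    file.path(dir, file)
  }
  paths <- c(classification = tsv(cls, "classification.tsv"))
  hm <- heatmap_matrix(run)
  paths <- c(paths, heatmap = tsv(
    data.frame(gene_id = rownames(hm), hm, check.names = FALSE),
    "heatmap.tsv"))
  report <- c(run$summary,
              list(curves = run$curves,
                   provenance = list(
                     package = "nascentUV",
                     version = as.character(utils::packageVersion("nascentUV")),
                     options = unclass(run$options))))
  jsonlite::write_json(report, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(paths, summary = file.path(dir, "summary.json")))
}
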