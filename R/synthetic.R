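#' Configuration for a synthetic Bru-seq cohort
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: a gene population with a log-normal length distribution (default
#' median 48,667 bp) and log-normal baseline expression (default median
#' 0.279766 RPKM); UV lesions placed per gene as Poisson draws with mean
#' proportional to gene length (transcribed strand, 1/12 kb at 10 J/m2);
#' damaged genes repressed fast (in cis, from 30 min), a configurable
#' fraction of undamaged genes repressed slowly (in trans, from 2 h 30 min);
#' a small immediate-early induced set; condition-dependent recovery at
#' 24.5 h controlled by a planted dependency plan; and global-transcription
#' scaling factors equal to the cohort-mean signal change.
#'
#' @param n_genes number of genes.
#' @param seed integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @param length_meanlog,length_sdlog log-normal gene-length parameters (bp).
#' @param expr_meanlog,expr_sdlog log-normal baseline RPKM parameters.
#' @param coding_fraction fraction of protein-coding genes.
#' @param dose UVC dose in J/m2 (0 = unirradiated control cohort, no damage).
#' @param trans_repressed_fraction fraction of undamaged genes repressed in
#'   trans.
#' @param induced_fraction fraction of unaffected genes induced at 30 min.
#' @param cis_floor transcription ratio of damaged genes at 0.5 and 2.5 h.
#' @param trans_level_0p5,trans_floor trans-repressed gene ratios at 0.5 h
#'   (mild, above the 2-fold threshold) and 2.5 h (full repression).
#' @param induced_peak induced-gene ratio at 0.5 h.
#' @param recovery_control mean 24.5 h ratio in the control condition.
#' @param dependency_plan named fractions over stimulated / independent /
#'   inhibited (must sum to 1); class drawn per gene.
#' @param dependency_effects multiplicative effect of each class on the
#'   24.5 h recovery ratio under knockdown, relative to control.
#' @param timepoints labelled timepoints in hours (must contain 0, 0.5, 2.5
#'   and the recovery timepoint 24.5).
#' @param conditions condition names; the first is the control.
#' @param n_replicates biological replicates per condition.
#' @param count_depth reads per sample; the default 2500 x n_genes matches
#'   a ~50 million read library spread over a ~20,000-gene transcriptome.
#' @param count_noise "poisson" (counting noise), "none" (expected counts,
#'   noiseless), or "lognormal_poisson" (Poisson with log-normal
#'   mean perturbation of sd `overdispersion_sd`, mean-preserving).
#' @param overdispersion_sd sd (log scale) of the mean perturbation.
#' @param factor_sd sd (log scale) of multiplicative noise on the reported
#'   scaling factors (0 = report the exact cohort-mean factors).
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 2000, seed = 1L,
                          length_meanlog = log(48667), length_sdlog = 1.1,
                          expr_meanlog = log(0.279766), expr_sdlog = 1.5,
                          coding_fraction = 0.75,
                          dose = 10,
                          trans_repressed_fraction = 0.4,
                          induced_fraction = 0.02,
                          cis_floor = 0.3,
                          trans_level_0p5 = 0.85, trans_floor = 0.35,
                          induced_peak = 3.0,
                          recovery_control = 1.0,
                          dependency_plan = c(stimulated = 0.88,
                                              independent = 0.043,
                                              inhibited = 0.077),
                          dependency_effects = c(stimulated = 0.5,
                                                 independent = 1.0,
                                                 inhibited = 1.3),
                          timepoints = c(0, 0.5, 2.5, 24.5),
                          conditions = c("control", "knockdown_A"),
                          n_replicates = 3,
                          count_depth = 2500 * n_genes,
                          count_noise = c("poisson", "none",
                                          "lognormal_poisson"),
                          overdispersion_sd = 0.1,
                          factor_sd = 0) {
  count_noise <- match.arg(count_noise)
  cls <- c("stimulated", "independent", "inhibited")
  if (!setequal(names(dependency_plan), cls)) {
    stop("dependency_plan needs fractions named ", paste(cls, collapse = ", "))
  }
  dependency_plan <- dependency_plan[cls]
  dependency_effects <- dependency_effects[cls]
  stopifnot(
    n_genes >= 1, dose >= 0,
    trans_repressed_fraction >= 0, trans_repressed_fraction <= 1,
    induced_fraction >= 0, induced_fraction <= 1,
    coding_fraction >= 0, coding_fraction <= 1,
    all(dependency_plan >= 0), abs(sum(dependency_plan) - 1) < 1e-9,
    dependency_effects["stimulated"] <= 0.9,
    dependency_effects["inhibited"] >= 1.1,
    cis_floor > 0, cis_floor <= 0.5, trans_floor > 0, trans_floor <= 0.5,
    trans_level_0p5 > 0.5, induced_peak >= 2,
    recovery_control > 0, count_depth > 0, n_replicates >= 1,
    0 %in% timepoints, all(c(0.5, 2.5, 24.5) %in% timepoints),
    length(conditions) >= 1, !anyDuplicated(conditions)
  )
  structure(as.list(environment()), class = "cohort_config")
}

#' Generate a gene cohort with planted truth
#'
#' Draws gene lengths, baseline expression, biotypes and per-gene truth
#' labels (damage status from Poisson lesion counts, repression and
#' kinetics, dependency class), and lays the genes out without overlap on
#' synthetic chromosomes with intergenic gaps wide enough for promoter
#' extension and decoy-peak placement.
#'
#' @param config `cohort_config`.
#' @return object of class `uv_cohort`: list with `annotation`
#'   (`gene_annotation`), `truth` (per-gene data.frame) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_genes
  gene_id <- sprintf("G%05d", seq_len(n))
  len <- pmax(200, round(stats::rlnorm(n, config$length_meanlog,
                                       config$length_sdlog)))
  baseline <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  biotype <- ifelse(stats::runif(n) < config$coding_fraction,
                    "protein_coding", "noncoding")
  strand <- sample(c("+", "-"), n, replace = TRUE)

  lambda <- if (config$dose > 0) {
    expected_lesions(len, lesion_params(dose = config$dose), "transcribed")
  } else rep(0, n)
  lesions <- stats::rpois(n, lambda)
  damaged <- lesions >= 1
  trans_repressed <- !damaged &
    stats::runif(n) < config$trans_repressed_fraction
  induced <- !damaged & !trans_repressed &
    stats::runif(n) < config$induced_fraction
  response_truth <- ifelse(damaged | trans_repressed, "repressed",
                           ifelse(induced, "induced", "unchanged"))
  kinetics_truth <- ifelse(damaged, "fast",
                           ifelse(trans_repressed, "slow", "not_applicable"))
  dependency_truth <- sample(names(config$dependency_plan), n, replace = TRUE,
                             prob = config$dependency_plan)

  # genome layout: spread over 8 chromosomes, gaps wide enough that 5 kb
  # promoter extensions never touch and decoy peaks fit between genes
  chrom <- paste0("chr", rep_len(seq_len(8), n))
  start <- numeric(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gaps <- round(stats::runif(length(idx), 15000, 60000))
    start[idx] <- cumsum(gaps) + c(0, cumsum(len[idx]))[seq_along(idx)]
  }
  annotation <- gene_annotation(data.frame(
    gene_id = gene_id, chrom = chrom, start = start, end = start + len,
    strand = strand, biotype = biotype, stringsAsFactors = FALSE))
  truth <- data.frame(
    gene_id = gene_id, length = len, baseline_rpkm = baseline,
    lesions = lesions, damaged = damaged,
    trans_repressed = trans_repressed,
    response_truth = response_truth, kinetics_truth = kinetics_truth,
    dependency_truth = dependency_truth, stringsAsFactors = FALSE)
  structure(list(annotation = annotation, truth = truth, config = config),
            class = "uv_cohort")
}

#' @export
print.uv_cohort <- function(x, ...) {
  cat("uv_cohort: ", nrow(x$truth), " genes (seed ", x$config$seed, "); ",
      sum(x$truth$damaged), " damaged, ",
      sum(x$truth$response_truth == "repressed"), " repressed (",
      sum(x$truth$kinetics_truth == "fast"), " fast / ",
      sum(x$truth$kinetics_truth == "slow"), " slow), ",
      sum(x$truth$response_truth == "induced"), " induced\n", sep = "")
  invisible(x)
}

# true mean signal (RPKM scale) per gene for one condition/timepoint
true_signal <- function(cohort, condition, timepoint) {
  cfg <- cohort$config
  tr <- cohort$truth
  is_control <- condition == cfg$conditions[1]
  shape <- rep(1, nrow(tr))
  t <- timepoint
  recovery <- rep(cfg$recovery_control, nrow(tr))
  if (!is_control) {
    recovery <- recovery * unname(cfg$dependency_effects[tr$dependency_truth])
  }
  fast <- tr$kinetics_truth == "fast"
  slow <- tr$kinetics_truth == "slow"
  ind <- tr$response_truth == "induced"
  if (t == 0) {
    shape[] <- 1
  } else if (t <= 0.5) {
    shape[fast] <- cfg$cis_floor
    shape[slow] <- cfg$trans_level_0p5
    shape[ind] <- cfg$induced_peak
  } else if (t <= 2.5) {
    shape[fast] <- cfg$cis_floor
    shape[slow] <- cfg$trans_floor
    shape[ind] <- 1.2
  } else if (t <= 6.5) {
    # partial recovery / decay, interpolated between trough and 24.5 h
    shape[fast] <- cfg$cis_floor + 0.4 * (recovery[fast] - cfg$cis_floor)
    shape[slow] <- cfg$trans_floor + 0.4 * (recovery[slow] - cfg$trans_floor)
    shape[ind] <- 1.05
  } else {
    shape[fast] <- recovery[fast]
    shape[slow] <- recovery[slow]
    shape[ind] <- 1
  }
  tr$baseline_rpkm * shape
}

#' Simulate a Bru-seq count time course from a cohort
#'
#' True per-gene signal follows the planted kinetics (cis repression of
#' damaged genes from 30 min, trans repression from 2 h 30 min, recovery at
#' 24.5 h modulated by the planted dependency class under knockdown).
#' Read counts allocate a fixed sequencing depth across genes proportionally
#' to signal x length (longer nascent transcripts yield more reads), with
#' the configured count noise. The returned scaling-factor table holds the
#' true global-transcription factors: the cohort total signal x length at
#' each (condition, timepoint) relative to the same condition's baseline —
#' exactly what sequencing-depth normalisation erases — optionally
#' perturbed by log-normal factor noise.
#'
#' @param cohort `uv_cohort` from [generate_cohort()].
#' @param seed seed for the noise draws (default `config$seed + 1`).
#' @return list of class `uv_simulation`: `experiment` (`bru_experiment`,
#'   state counts), `factors` (`scaling_factor_table`), `truth`, `config`.
#' @export
simulate_timecourse <- function(cohort, seed = cohort$config$seed + 1L) {
  stopifnot(inherits(cohort, "uv_cohort"))
  cfg <- cohort$config
  set.seed(seed)
  len <- cohort$truth$length
  n <- nrow(cohort$truth)
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      timepoint = cfg$timepoints,
                      condition = cfg$conditions,
                      stringsAsFactors = FALSE)
  grid$sample_id <- sprintf("%s_t%g_r%d", grid$condition, grid$timepoint,
                            grid$replicate)
  counts <- matrix(0, n, nrow(grid),
                   dimnames = list(cohort$truth$gene_id, grid$sample_id))
  lib <- numeric(nrow(grid))
  totals <- list()  # total signal x length per (condition, timepoint)
  for (j in seq_len(nrow(grid))) {
    s <- true_signal(cohort, grid$condition[j], grid$timepoint[j])
    w <- s * len
    totals[[paste(grid$condition[j], grid$timepoint[j])]] <- sum(w)
    mu <- w / sum(w) * cfg$count_depth
    x <- switch(cfg$count_noise,
      none = mu,
      poisson = stats::rpois(n, mu),
      lognormal_poisson = stats::rpois(n, mu * stats::rlnorm(
        n, -cfg$overdispersion_sd^2 / 2, cfg$overdispersion_sd)))
    counts[, j] <- x
    lib[j] <- if (cfg$count_noise == "none") cfg$count_depth else sum(x)
  }
  grid$library_size <- lib
  experiment <- bru_experiment(counts, grid, cohort$annotation, "counts")
  fac <- expand.grid(timepoint = cfg$timepoints, condition = cfg$conditions,
                     stringsAsFactors = FALSE)
  fac$factor <- vapply(seq_len(nrow(fac)), function(i) {
    totals[[paste(fac$condition[i], fac$timepoint[i])]] /
      totals[[paste(fac$condition[i], 0)]]
  }, 0)
  if (cfg$factor_sd > 0) {
    post <- fac$timepoint != 0
    fac$factor[post] <- fac$factor[post] *
      stats::rlnorm(sum(post), 0, cfg$factor_sd)
  }
  factors <- scaling_factor_table(fac[, c("condition", "timepoint", "factor")])
  structure(list(experiment = experiment, factors = factors,
                 truth = cohort$truth, annotation = cohort$annotation,
                 config = cfg),
            class = "uv_simulation")
}

#' One-call synthetic experiment
#'
#' [generate_cohort()] followed by [simulate_timecourse()].
#'
#' @param config `cohort_config`.
#' @return `uv_simulation`.
#' @export
simulate_uv_experiment <- function(config = cohort_config()) {
  simulate_timecourse(generate_cohort(config))
}

#' Generate a synthetic ChIP-seq peak set with planted targets
#'
#' Places one passing peak (FDR < 1, fold enrichment > 10) inside the
#' 5 kb-upstream-extended interval of each designated target gene, decoy
#' passing peaks in intergenic space, and low-quality peaks (failing either
#' filter) on non-target genes, so that the stated filters retain exactly
#' the planted target set.
#'
#' @param annotation `gene_annotation` (cohort layout guarantees the
#'   intergenic room the decoys need).
#' @param genes candidate genes for targeting (default all).
#' @param target_fraction fraction of `genes` receiving a passing peak.
#' @param decoy_fraction intergenic decoys relative to the target count.
#' @param low_quality_fraction fraction of non-target genes receiving a
#'   filter-failing peak.
#' @param width_meanlog,width_sdlog log-normal peak width (bp), capped at
#'   2 kb.
#' @param upstream promoter extension used for placement (bp).
#' @param seed integer seed.
#' @return list: `peaks` (BED-like data.frame with fdr, fold_enrichment and
#'   a truth `role` column), `target_genes` (character).
#' @export
generate_peaks <- function(annotation, genes = annotation$gene_id,
                           target_fraction = 0.62, decoy_fraction = 0.3,
                           low_quality_fraction = 0.2,
                           width_meanlog = log(300), width_sdlog = 0.4,
                           upstream = 5000, seed = 1L) {
  stopifnot(target_fraction >= 0, target_fraction <= 1,
            decoy_fraction >= 0, low_quality_fraction >= 0,
            low_quality_fraction <= 1)
  set.seed(seed)
  ext <- extend_upstream(annotation, upstream)
  draw_width <- function(k) {
    pmin(2000, pmax(50, round(stats::rlnorm(k, width_meanlog, width_sdlog))))
  }
  place_in_gene <- function(ids, role, fdr, fe) {
    if (!length(ids)) return(NULL)
    i <- match(ids, ext$gene_id)
    w <- draw_width(length(ids))
    w <- pmin(w, ext$end[i] - ext$start[i])
    s <- ext$start[i] + floor(stats::runif(length(ids)) *
                                (ext$end[i] - ext$start[i] - w + 1))
    data.frame(chrom = ext$chrom[i], start = s, end = s + w,
               name = paste0("peak_", role, "_", seq_along(ids)),
               score = 0, strand = ".", fdr = fdr, fold_enrichment = fe,
               role = role, stringsAsFactors = FALSE)
  }
  n_t <- round(target_fraction * length(genes))
  targets <- if (n_t) sort(sample(genes, n_t)) else character()
  pk_t <- place_in_gene(targets, "target",
                        stats::runif(n_t, 0, 0.9),
                        stats::runif(n_t, 10.5, 50))
  nontarget <- setdiff(genes, targets)
  n_lq <- round(low_quality_fraction * length(nontarget))
  lq <- if (n_lq) sample(nontarget, n_lq) else character()
  fail_fe <- seq_len(n_lq) %% 2 == 0
  pk_lq <- place_in_gene(lq, "low_quality",
                         ifelse(fail_fe, stats::runif(n_lq, 0, 0.9),
                                stats::runif(n_lq, 1, 5)),
                         ifelse(fail_fe, stats::runif(n_lq, 2, 10),
                                stats::runif(n_lq, 10.5, 50)))
  # decoys: centred in gaps between consecutive extended intervals
  n_d <- round(decoy_fraction * n_t)
  pk_d <- NULL
  if (n_d > 0) {
    gaps <- do.call(rbind, lapply(split(ext, ext$chrom), function(e) {
      e <- e[order(e$start), ]
      if (nrow(e) < 2) return(NULL)
      data.frame(chrom = e$chrom[-nrow(e)], lo = e$end[-nrow(e)],
                 hi = e$start[-1], stringsAsFactors = FALSE)
    }))
    gaps <- gaps[gaps$hi - gaps$lo > 2100, , drop = FALSE]
    pick <- gaps[sample(nrow(gaps), min(n_d, nrow(gaps))), , drop = FALSE]
    w <- draw_width(nrow(pick))
    mid <- floor((pick$lo + pick$hi) / 2)
    pk_d <- data.frame(chrom = pick$chrom, start = mid - floor(w / 2),
                       end = mid - floor(w / 2) + w,
                       name = paste0("peak_decoy_", seq_len(nrow(pick))),
                       score = 0, strand = ".",
                       fdr = stats::runif(nrow(pick), 0, 0.9),
                       fold_enrichment = stats::runif(nrow(pick), 10.5, 50),
                       role = "decoy", stringsAsFactors = FALSE)
  }
  peaks <- do.call(rbind, Filter(Negate(is.null), list(pk_t, pk_lq, pk_d))) %||%
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               name = character(), score = numeric(), strand = character(),
               fdr = numeric(), fold_enrichment = numeric(),
               role = character())
  rownames(peaks) <- NULL
  list(peaks = peaks, target_genes = targets)
}

#' Write synthetic inputs as the plain-text files the pipeline reads
#'
#' Writes the counts matrix, sample sheet, scaling-factor table, annotation
#' (TSV and BED6), and truth table into a directory; a peak set from
#' [generate_peaks()] can be written alongside.
#'
#' @param sim `uv_simulation`.
#' @param dir output directory (created if needed).
#' @param peaks optional result of [generate_peaks()].
#' @return invisibly, the named vector of file paths written.
#' @export
write_synthetic_inputs <- function(sim, dir, peaks = NULL) {
  stopifnot(inherits(sim, "uv_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file, ...) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE, ...)
    file.path(dir, file)
  }
  counts <- data.frame(gene_id = rownames(sim$experiment$values),
                       sim$experiment$values, check.names = FALSE)
  ann <- sim$annotation
  bed <- data.frame(ann$chrom, ann$start, ann$end, ann$gene_id, 0, ann$strand)
  paths <- c(
    counts = tsv(counts, "counts.tsv"),
    samples = tsv(sim$experiment$samples, "samples.tsv"),
    factors = tsv(sim$factors, "factors.tsv"),
    annotation = tsv(as.data.frame(ann), "annotation.tsv"),
    annotation_bed = tsv(bed, "annotation.bed", col.names = FALSE),
    truth = tsv(sim$truth, "truth.tsv"))
  if (!is.null(peaks)) {
    pk <- peaks$peaks
    bed8 <- pk[, c("chrom", "start", "end", "name", "score", "strand",
                   "fdr", "fold_enrichment")]
    paths <- c(paths, peaks = tsv(bed8, "peaks.bed", col.names = FALSE))
  }
  invisible(paths)
}
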