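#' Classify genes as UV-repressed or UV-induced
#'
#' In control conditions, a gene is UV-repressed if its nascent transcription
#' 2 h 30 min post UVC is reduced at least `threshold_fold`-fold relative to
#' the unirradiated baseline (ratio <= 1/threshold_fold, inclusive), and
#' UV-induced if its transcription 30 min post UVC is increased at least
#' `threshold_fold`-fold (ratio >= threshold_fold, inclusive). A gene meeting
#' both definitions is excluded as a conflict rather than double-counted.
#' Genes excluded upstream (zero baseline) are carried through as excluded.
#'
#' @param ratios `ratio_table` with ratios at 0.5 h and 2.5 h.
#' @param condition the control condition name (default "control").
#' @param threshold_fold fold-change threshold (default 2).
#' @param replicate see [ratio_matrix()].
#' @return data.frame of class `uv_response`: gene_id, response
#'   (repressed / induced / unchanged / excluded), kinetics (filled by
#'   [call_kinetics()], `not_applicable` here), repression_ratio_2p5h,
#'   induction_ratio_0p5h, reason.
#' @export
call_uv_response <- function(ratios, condition = "control",
                             threshold_fold = 2, replicate = NULL) {
  stopifnot(threshold_fold > 0)
  m <- ratio_matrix(ratios, condition, replicate)
  tps <- as.numeric(colnames(m))
  i05 <- tp_match(0.5, tps)
  i25 <- tp_match(2.5, tps)
  if (is.na(i05) || is.na(i25)) {
    stop("ratios at 0.5 h and 2.5 h are required for UV-response calls; ",
         "found timepoints: ", paste(tps, collapse = ", "))
  }
  r05 <- m[, i05]
  r25 <- m[, i25]
  repressed <- r25 <= 1 / threshold_fold
  induced <- r05 >= threshold_fold
  response <- ifelse(repressed & induced, "excluded",
              ifelse(repressed, "repressed",
              ifelse(induced, "induced", "unchanged")))
  out <- data.frame(
    gene_id = rownames(m), response = response,
    kinetics = "not_applicable",
    repression_ratio_2p5h = r25, induction_ratio_0p5h = r05,
    reason = ifelse(repressed & induced, "conflict", ""),
    stringsAsFactors = FALSE, row.names = NULL)
  excl <- ratios$excluded[ratios$excluded$condition == condition, , drop = FALSE]
  if (nrow(excl)) {
    out <- rbind(out, data.frame(
      gene_id = excl$gene_id, response = "excluded",
      kinetics = "not_applicable",
      repression_ratio_2p5h = NA_real_, induction_ratio_0p5h = NA_real_,
      reason = excl$reason, stringsAsFactors = FALSE))
  }
  class(out) <- c("uv_response", "data.frame")
  out
}

#' Call repression kinetics (fast vs slow) for UV-repressed genes
#'
#' Fast repression is at least 2-fold inhibition already detectable 30 min
#' post UVC (ratio at 0.5 h <= 0.5, inclusive); slow repression appears only
#' by 2 h 30 min. Fast repression is the expected signature of a direct,
#' cis-acting lesion block on the gene; slow repression of (mostly short,
#' likely undamaged) genes points to trans-acting inhibition.
#'
#' @param responses `uv_response` table.
#' @param ratios the `ratio_table` the responses were called from (only the
#'   0.5 h ratio is used, already stored in `responses`).
#' @param genes genes to call; defaults to all repressed genes. Passing a
#'   non-repressed gene is an error.
#' @param threshold_fold fold threshold defining "detectable" inhibition.
#' @return `responses` with `kinetics` set to fast/slow for repressed genes.
#' @export
call_kinetics <- function(responses, ratios = NULL, genes = NULL,
                          threshold_fold = 2) {
  stopifnot(inherits(responses, "uv_response"))
  rep_set <- responses$gene_id[responses$response == "repressed"]
  if (is.null(genes)) {
    genes <- rep_set
  } else if (length(bad <- setdiff(genes, rep_set))) {
    stop("kinetics are defined for UV-repressed genes only; not repressed: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  idx <- match(genes, responses$gene_id)
  fast <- responses$induction_ratio_0p5h[idx] <= 1 / threshold_fold
  responses$kinetics[idx] <- ifelse(fast, "fast", "slow")
  responses
}

#' Dependency of transcription recovery on a knockdown
#'
#' Transcription recovery is the 24 h 30 min nascent level normalised to the
#' same condition's pre-irradiation level. For each UV-repressed gene the
#' relative recovery is recovery(knockdown) / recovery(control);
#' the gene is `stimulated` by the knocked-down factor (i.e. requires it)
#' when relative recovery <= 0.90, `inhibited` (recovers better without it)
#' when >= 1.10, and `independent` in the open band in between. Genes with
#' zero control recovery or a zero baseline in either condition are excluded.
#'
#' @param ratios `ratio_table` holding both conditions.
#' @param genes gene ids to call (typically the UV-repressed set).
#' @param knockdown knockdown condition name.
#' @param control control condition name.
#' @param recovery_timepoint hours post UVC (default 24.5).
#' @param band half-width of the independent band (default 0.10).
#' @param replicate see [ratio_matrix()].
#' @return data.frame of class `uv_dependency`: gene_id, knockdown,
#'   recovery_control, recovery_knockdown, relative_recovery, dependency,
#'   reason.
#' @export
call_dependency <- function(ratios, genes, knockdown, control = "control",
                            recovery_timepoint = 24.5, band = 0.10,
                            replicate = NULL) {
  stopifnot(band > 0, band < 1)
  mc <- ratio_matrix(ratios, control, replicate)
  mk <- ratio_matrix(ratios, knockdown, replicate)
  ic <- tp_match(recovery_timepoint, as.numeric(colnames(mc)))
  ik <- tp_match(recovery_timepoint, as.numeric(colnames(mk)))
  if (is.na(ic) || is.na(ik)) {
    stop("no ratios at the recovery timepoint (", recovery_timepoint, " h)")
  }
  rc <- rk <- rep(NA_real_, length(genes))
  in_c <- match(genes, rownames(mc))
  in_k <- match(genes, rownames(mk))
  rc[!is.na(in_c)] <- mc[in_c[!is.na(in_c)], ic]
  rk[!is.na(in_k)] <- mk[in_k[!is.na(in_k)], ik]
  rel <- rk / rc
  dependency <- character(length(genes))
  reason <- character(length(genes))
  baseline_miss <- is.na(rc) | is.na(rk)
  ctrl_zero <- !baseline_miss & rc == 0
  ok <- !baseline_miss & !ctrl_zero
  dependency[baseline_miss] <- "excluded"
  reason[baseline_miss] <- "baseline_zero"
  dependency[ctrl_zero] <- "excluded"
  reason[ctrl_zero] <- "control_recovery_zero"
  dependency[ok] <- classify_recovery_band(rel[ok], band)
  out <- data.frame(
    gene_id = genes, knockdown = knockdown,
    recovery_control = rc, recovery_knockdown = rk,
    relative_recovery = rel, dependency = dependency, reason = reason,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("uv_dependency", "data.frame")
  out
}

#' Map relative recovery onto dependency classes
#'
#' The bands tile the positive axis: stimulated (0, 1 - band\],
#' independent (1 - band, 1 + band), inhibited \[1 + band, Inf). Both
#' boundaries are assigned to the outer classes ("at most 90%" and
#' "at least 110%" read inclusively).
#'
#' @param rel positive numeric vector of relative recoveries.
#' @param band half-width of the independent band.
#' @return character vector of classes.
#' @export
classify_recovery_band <- function(rel, band = 0.10) {
  stopifnot(all(rel >= 0, na.rm = TRUE))
  ifelse(rel <= 1 - band, "stimulated",
         ifelse(rel >= 1 + band, "inhibited", "independent"))
}

#' Partition analysed genes by length, expression and coding potential
#'
#' Cutoffs are always recomputed from the analysed gene set itself: short
#' vs long at the median gene length, low vs high at the median baseline
#' RPKM (ties go to the lower class), and length quartiles with quartile 1
#' the shortest 25% (ties broken by (length, gene_id) rank for determinism).
#'
#' @param annotation `gene_annotation`.
#' @param baseline_rpkm named numeric vector of unirradiated RPKM for the
#'   analysed genes (names = gene_id).
#' @return data.frame of class `gene_partitions`: gene_id, length,
#'   baseline_rpkm, length_class, length_quartile, expression_class,
#'   biotype_class; attributes `length_median` and `rpkm_median`.
#' @export
partition_genes <- function(annotation, baseline_rpkm) {
  genes <- names(baseline_rpkm)
  if (!length(genes)) stop("empty gene set")
  len <- gene_lengths(annotation, genes)
  med_len <- stats::median(len)
  med_expr <- stats::median(baseline_rpkm)
  ord <- order(len, genes)             # deterministic tie-break
  qrt <- integer(length(genes))
  qrt[ord] <- ceiling(seq_along(ord) * 4 / length(ord))
  bio <- annotation$biotype[match(genes, annotation$gene_id)]
  out <- data.frame(
    gene_id = genes, length = unname(len),
    baseline_rpkm = unname(baseline_rpkm),
    length_class = ifelse(len <= med_len, "short", "long"),
    length_quartile = qrt,
    expression_class = ifelse(baseline_rpkm <= med_expr, "low", "high"),
    biotype_class = ifelse(bio == "protein_coding", "coding", "noncoding"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "length_median") <- med_len
  attr(out, "rpkm_median") <- med_expr
  class(out) <- c("gene_partitions", "data.frame")
  out
}

#' Dependency-class fractions
#'
#' @param dependency `uv_dependency` table.
#' @return list with `fractions` (named numeric over stimulated /
#'   independent / inhibited, summing to 1 over non-excluded genes), `n`
#'   (non-excluded count), `n_excluded`, and `genes` (gene ids per class).
#' @export
summarize_dependency <- function(dependency) {
  stopifnot(inherits(dependency, "uv_dependency"))
  ok <- dependency[dependency$dependency != "excluded", , drop = FALSE]
  if (!nrow(ok)) stop("no non-excluded dependency calls to summarise")
  classes <- c("stimulated", "independent", "inhibited")
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(ok$dependency == cl), 0), classes)
  list(fractions = counts / nrow(ok), n = nrow(ok),
       n_excluded = sum(dependency$dependency == "excluded"),
       genes = lapply(stats::setNames(classes, classes),
                      function(cl) ok$gene_id[ok$dependency == cl]))
}

#' Mean transcription curve over a gene set
#'
#' Arithmetic mean and sample standard deviation of the baseline-normalised
#' ratios over the genes of a set, per timepoint (the summary behind the
#' gene-set recovery curves).
#'
#' @param ratios `ratio_table`.
#' @param genes nonempty character vector of gene ids.
#' @param condition condition to summarise.
#' @param replicate see [ratio_matrix()].
#' @return data.frame: timepoint, mean, sd, n (genes contributing).
#' @export
mean_response_curve <- function(ratios, genes, condition, replicate = NULL) {
  if (!length(genes)) stop("empty gene set")
  m <- ratio_matrix(ratios, condition, replicate)
  genes <- intersect(genes, rownames(m))
  if (!length(genes)) stop("none of the genes have ratios in ", condition)
  m <- m[genes, , drop = FALSE]
  data.frame(
    timepoint = as.numeric(colnames(m)),
    mean = colMeans(m),
    sd = if (length(genes) == 1) 0 else apply(m, 2, stats::sd),
    n = length(genes), row.names = NULL)
}
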