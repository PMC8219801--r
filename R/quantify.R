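#' Gene-body RPKM from read counts
#'
#' RPKM(g, s) = counts(g, s) / (length_kb(g) x library_size_millions(s)),
#' with the full annotated gene-body length in the denominator (nascent
#' transcripts retain introns). No pseudo-counts are added anywhere; zeros
#' propagate and are handled downstream by the RPKM > 0 exclusion rules.
#'
#' @param x `bru_experiment` in state "counts".
#' @param annotation `gene_annotation`; defaults to the one stored in `x`.
#' @return `bru_experiment` in state "rpkm".
#' @export
compute_rpkm <- function(x, annotation = x$annotation) {
  stopifnot(inherits(x, "bru_experiment"))
  if (x$state != "counts") stop("compute_rpkm expects count input, got ", x$state)
  if (is.null(annotation)) stop("gene annotation with lengths is required")
  len <- gene_lengths(annotation, rownames(x$values))
  if (any(len <= 0)) {
    stop("non-positive gene length for: ",
         paste(names(len)[len <= 0], collapse = ", "))
  }
  lib <- x$samples$library_size
  if (any(lib <= 0)) stop("library_size must be positive")
  x$values <- x$values / (len / 1000) /
    rep(lib / 1e6, each = nrow(x$values))
  x$annotation <- annotation
  x$state <- "rpkm"
  x
}

#' Biological scaling normalisation
#'
#' Multiplies every RPKM value by the global-transcription correction factor
#' of its sample's (condition, timepoint). Sequencing depth normalisation
#' erases genome-wide shifts in transcription output (such as global
#' post-UV silencing); the factors, measured externally per condition and
#' timepoint relative to the unirradiated sample (e.g. by EU incorporation
#' imaging), restore that global scale. Baseline samples have factor 1 and
#' are unchanged.
#'
#' @param x `bru_experiment` in state "rpkm".
#' @param factors `scaling_factor_table` (or a data.frame coercible to one)
#'   covering every (condition, timepoint) present in `x`.
#' @return `bru_experiment` in state "scaled_rpkm".
#' @export
apply_scaling <- function(x, factors) {
  stopifnot(inherits(x, "bru_experiment"))
  if (x$state != "rpkm") stop("apply_scaling expects rpkm input, got ", x$state)
  if (!inherits(factors, "scaling_factor_table")) {
    factors <- scaling_factor_table(factors)
  }
  key_s <- paste(x$samples$condition, x$samples$timepoint)
  key_f <- paste(factors$condition, factors$timepoint)
  idx <- match(key_s, key_f)
  if (anyNA(idx)) {
    stop("no scaling factor for (condition, timepoint): ",
         paste(unique(key_s[is.na(idx)]), collapse = "; "))
  }
  f <- factors$factor[idx]
  x$values <- x$values * rep(f, each = nrow(x$values))
  x$state <- "scaled_rpkm"
  x
}

#' Per-gene transcription relative to the unirradiated baseline
#'
#' ratio(g, c, t) = scaled_rpkm(g, c, t) / scaled_rpkm(g, c, 0), computed
#' within each replicate. Genes with a zero baseline in any replicate of a
#' condition are excluded for that condition with reason `baseline_zero`
#' (the RPKM > 0 analysed-gene filter). In `replicate_mean` mode the
#' per-replicate ratios are averaged per (gene, condition, timepoint).
#'
#' @param x `bru_experiment` in state "scaled_rpkm" (or "rpkm", accepted so
#'   unscaled ratios can be inspected).
#' @param mode "per_replicate" keeps one ratio per replicate;
#'   "replicate_mean" averages the per-replicate ratios.
#' @return object of class `ratio_table`: list with `ratios` (data.frame
#'   gene_id, condition, timepoint, \[replicate,\] ratio), `excluded`
#'   (gene_id, condition, reason) and `mode`.
#' @export
relative_to_baseline <- function(x, mode = c("per_replicate", "replicate_mean")) {
  stopifnot(inherits(x, "bru_experiment"))
  mode <- match.arg(mode)
  if (!x$state %in% c("scaled_rpkm", "rpkm")) {
    stop("relative_to_baseline expects (scaled) rpkm input, got ", x$state)
  }
  sm <- x$samples
  out <- vector("list", 0L)
  excl <- vector("list", 0L)
  for (cond in unique(sm$condition)) {
    sc <- sm[sm$condition == cond, , drop = FALSE]
    reps <- sort(unique(sc$replicate))
    base_ok <- rep(TRUE, nrow(x$values))
    for (r in reps) {
      b <- sc$sample_id[sc$timepoint == 0 & sc$replicate == r]
      base_ok <- base_ok & x$values[, b] > 0
    }
    if (any(!base_ok)) {
      excl[[length(excl) + 1L]] <- data.frame(
        gene_id = rownames(x$values)[!base_ok], condition = cond,
        reason = "baseline_zero", stringsAsFactors = FALSE)
    }
    keep <- rownames(x$values)[base_ok]
    if (!length(keep)) next
    for (r in reps) {
      b <- sc$sample_id[sc$timepoint == 0 & sc$replicate == r]
      post <- sc[sc$timepoint != 0 & sc$replicate == r, , drop = FALSE]
      for (i in seq_len(nrow(post))) {
        out[[length(out) + 1L]] <- data.frame(
          gene_id = keep, condition = cond, timepoint = post$timepoint[i],
          replicate = r,
          ratio = x$values[keep, post$sample_id[i]] / x$values[keep, b],
          stringsAsFactors = FALSE)
      }
    }
  }
  ratios <- do.call(rbind, out) %||% data.frame(
    gene_id = character(), condition = character(), timepoint = numeric(),
    replicate = integer(), ratio = numeric())
  rownames(ratios) <- NULL
  if (mode == "replicate_mean" && nrow(ratios)) {
    agg <- stats::aggregate(
      ratio ~ gene_id + condition + timepoint, data = ratios, FUN = mean)
    ratios <- agg[order(agg$condition, agg$timepoint, agg$gene_id), ]
    rownames(ratios) <- NULL
  }
  excluded <- do.call(rbind, excl) %||% data.frame(
    gene_id = character(), condition = character(), reason = character())
  rownames(excluded) <- NULL
  structure(list(ratios = ratios, excluded = excluded, mode = mode),
            class = "ratio_table")
}

#' @export
print.ratio_table <- function(x, ...) {
  cat("ratio_table [", x$mode, "]: ", length(unique(x$ratios$gene_id)),
      " genes, conditions: ",
      paste(unique(x$ratios$condition), collapse = ", "),
      "; ", nrow(x$excluded), " (gene, condition) exclusions\n", sep = "")
  invisible(x)
}

#' Genes detected in every listed condition
#'
#' Complete-case filter used before heatmap export: keeps genes whose value
#' is strictly positive in every sample of every listed condition (genes
#' with RPKM = 0 in one of the conditions are excluded).
#'
#' @param x `bru_experiment` in state "rpkm" or "scaled_rpkm".
#' @param conditions character vector of conditions to require; empty vector
#'   imposes no constraint and retains all genes.
#' @return character vector of retained gene ids.
#' @export
filter_complete_cases <- function(x, conditions) {
  stopifnot(inherits(x, "bru_experiment"))
  if (!x$state %in% c("rpkm", "scaled_rpkm")) {
    stop("filter_complete_cases expects (scaled) rpkm input")
  }
  if (!length(conditions)) return(rownames(x$values))
  miss <- setdiff(conditions, x$samples$condition)
  if (length(miss)) stop("unknown condition(s): ", paste(miss, collapse = ", "))
  cols <- x$samples$sample_id[x$samples$condition %in% conditions]
  keep <- rowSums(x$values[, cols, drop = FALSE] <= 0) == 0
  rownames(x$values)[keep]
}

#' Extract ratios for one condition as a genes x timepoints matrix
#'
#' Convenience accessor used by the classifiers; requires a unique ratio per
#' (gene, timepoint), i.e. a `replicate_mean` table or a single replicate.
#'
#' @param ratios `ratio_table`.
#' @param condition condition to extract.
#' @param replicate replicate to extract from a `per_replicate` table with
#'   several replicates (default: error if ambiguous).
#' @return numeric matrix, genes x timepoints (column names = hours).
#' @export
ratio_matrix <- function(ratios, condition, replicate = NULL) {
  stopifnot(inherits(ratios, "ratio_table"))
  df <- ratios$ratios[ratios$ratios$condition == condition, , drop = FALSE]
  if (!nrow(df)) stop("no ratios for condition ", condition)
  if (!is.null(df$replicate)) {
    if (!is.null(replicate)) df <- df[df$replicate == replicate, , drop = FALSE]
    if (length(unique(df$replicate)) > 1) {
      stop("several replicates present; pass `replicate` or use ",
           "relative_to_baseline(mode = 'replicate_mean')")
    }
  }
  tps <- sort(unique(df$timepoint))
  genes <- sort(unique(df$gene_id))
  m <- matrix(NA_real_, length(genes), length(tps),
              dimnames = list(genes, as.character(tps)))
  m[cbind(match(df$gene_id, genes), match(df$timepoint, tps))] <- df$ratio
  m
}
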