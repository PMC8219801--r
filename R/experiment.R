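#' Bru-seq experiment container
#'
#' Bundles a genes x samples value matrix with per-sample metadata and a gene
#' annotation, and tracks the normalisation state. State moves only forward:
#' `counts` -> `rpkm` (via [compute_rpkm()]) -> `scaled_rpkm` (via
#' [apply_scaling()]).
#'
#' @param values numeric matrix, genes in rows (rownames = gene_id), samples
#'   in columns (colnames = sample_id); non-negative.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `timepoint` (hours post UVC, 0 = unirradiated; label aliases like
#'   "2h30" are accepted), `replicate`, and `library_size` (total uniquely
#'   mapped reads; required when `state = "counts"`).
#' @param annotation `gene_annotation` covering at least the genes in
#'   `values` (may be NULL for RPKM input whose lengths are no longer needed).
#' @param state one of "counts", "rpkm", "scaled_rpkm".
#' @return object of class `bru_experiment`.
#' @export
bru_experiment <- function(values, samples, annotation = NULL,
                           state = c("counts", "rpkm", "scaled_rpkm")) {
  state <- match.arg(state)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene_id rownames and sample_id colnames")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  stop_if_not_df_cols(samples,
                      c("sample_id", "condition", "timepoint", "replicate"),
                      "sample sheet")
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  samples$timepoint <- normalize_timepoint(samples$timepoint)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) stop("sample_id must be unique")
  if (!setequal(samples$sample_id, colnames(values))) {
    stop("sample sheet and value matrix name different samples")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (state == "counts") {
    if (is.null(samples$library_size)) {
      stop("library_size is required for count input")
    }
    samples$library_size <- as.numeric(samples$library_size)
    if (any(!is.finite(samples$library_size) | samples$library_size <= 0)) {
      stop("library_size must be positive for every sample")
    }
  }
  # each (condition, replicate) needs exactly one unirradiated baseline
  base <- samples[samples$timepoint == 0, , drop = FALSE]
  key <- interaction(samples$condition, samples$replicate, drop = TRUE)
  bkey <- interaction(base$condition, base$replicate, drop = TRUE)
  if (anyDuplicated(bkey)) {
    stop("more than one timepoint-0 baseline for a (condition, replicate)")
  }
  if (!all(levels(key) %in% as.character(bkey))) {
    stop("missing timepoint-0 baseline for: ",
         paste(setdiff(levels(key), as.character(bkey)), collapse = ", "))
  }
  if (!is.null(annotation)) {
    miss <- setdiff(rownames(values), annotation$gene_id)
    if (length(miss)) {
      stop("genes absent from annotation: ",
           paste(utils::head(miss, 5), collapse = ", "),
           if (length(miss) > 5) ", ...")
    }
  }
  structure(list(values = values, samples = samples,
                 annotation = annotation, state = state),
            class = "bru_experiment")
}

#' @export
print.bru_experiment <- function(x, ...) {
  cat("bru_experiment: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples [", x$state, "]\n", sep = "")
  cat("  conditions: ", paste(unique(x$samples$condition), collapse = ", "),
      "\n  timepoints (h): ",
      paste(sort(unique(x$samples$timepoint)), collapse = ", "),
      "\n  replicates: ", max(x$samples$replicate), "\n", sep = "")
  invisible(x)
}

#' @export
dim.bru_experiment <- function(x) dim(x$values)

#' Subset a Bru-seq experiment by gene
#'
#' @param x `bru_experiment`.
#' @param genes character vector of gene ids to keep.
#' @return `bru_experiment` restricted to `genes`, in the given order.
#' @export
subset_genes <- function(x, genes) {
  stopifnot(inherits(x, "bru_experiment"))
  miss <- setdiff(genes, rownames(x$values))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  x$values <- x$values[genes, , drop = FALSE]
  x
}

#' Read a Bru-seq experiment from TSV files
#'
#' The matrix TSV has gene ids in the first column and one column per sample;
#' the sample sheet TSV has columns sample_id, condition, timepoint_h (or
#' timepoint; bench labels like "2h30" are accepted), replicate, and
#' library_size for count input.
#'
#' @param matrix_path path to the counts or RPKM matrix TSV.
#' @param samples_path path to the sample sheet TSV.
#' @param annotation optional `gene_annotation`.
#' @param state state of the matrix values ("counts" or "rpkm").
#' @return `bru_experiment`.
#' @export
read_bru_experiment <- function(matrix_path, samples_path, annotation = NULL,
                                state = c("counts", "rpkm")) {
  state <- match.arg(state)
  mat <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  values <- as.matrix(mat[, -1, drop = FALSE])
  rownames(values) <- mat[[1]]
  samples <- utils::read.delim(samples_path, stringsAsFactors = FALSE)
  if (is.null(samples$timepoint) && !is.null(samples$timepoint_h)) {
    samples$timepoint <- samples$timepoint_h
  }
  bru_experiment(values, samples, annotation, state)
}

#' Read a scaling-factor table TSV
#'
#' Columns: condition, timepoint_h (or timepoint), factor. Factors are
#' global-transcription correction factors relative to the unirradiated
#' sample of the same condition (factor at timepoint 0 is 1 by definition;
#' a missing baseline row is filled in).
#'
#' @param path TSV path.
#' @return validated factor table (see [scaling_factor_table()]).
#' @export
read_factor_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(df$timepoint) && !is.null(df$timepoint_h)) {
    df$timepoint <- df$timepoint_h
  }
  scaling_factor_table(df)
}

#' Validate a scaling-factor table
#'
#' @param df data.frame with columns condition, timepoint, factor.
#' @return data.frame of class `scaling_factor_table`; baseline rows
#'   (timepoint 0, factor 1) are added for any condition lacking one.
#' @export
scaling_factor_table <- function(df) {
  stop_if_not_df_cols(df, c("condition", "timepoint", "factor"),
                      "factor table")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$timepoint <- normalize_timepoint(df$timepoint)
  df$factor <- as.numeric(df$factor)
  if (any(!is.finite(df$factor) | df$factor <= 0)) {
    stop("all scaling factors must be positive")
  }
  base <- df$timepoint == 0
  if (any(df$factor[base] != 1)) {
    stop("baseline (timepoint 0) factor must be exactly 1; factors are ",
         "defined relative to each condition's own unirradiated sample")
  }
  for (cond in setdiff(unique(df$condition), df$condition[base])) {
    df <- rbind(df[, c("condition", "timepoint", "factor")],
                data.frame(condition = cond, timepoint = 0, factor = 1))
  }
  if (anyDuplicated(df[, c("condition", "timepoint")])) {
    stop("duplicated (condition, timepoint) in factor table")
  }
  rownames(df) <- NULL
  class(df) <- c("scaling_factor_table", "data.frame")
  df
}
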