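#' Gene annotation table
#'
#' Validates and normalises a transcription-unit annotation. Coordinates are
#' 0-based half-open (BED dialect) throughout the package; use
#' `one_based = TRUE` for 1-based inclusive input (e.g. GTF-derived tables),
#' which is converted on the way in.
#'
#' Gene length is the full annotated gene-body length (`end - start`), not an
#' exonic length: Bru-seq captures intron-containing nascent transcripts, and
#' both RPKM and the lesion-load model are defined on the gene body.
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` and optionally `biotype` (`protein_coding` or anything else,
#'   grouped as non-coding).
#' @param one_based logical; input coordinates are 1-based inclusive.
#' @return data.frame of class `gene_annotation` with an added `length`
#'   column (bp).
#' @export
gene_annotation <- function(df, one_based = FALSE) {
  stop_if_not_df_cols(df, c("gene_id", "chrom", "start", "end", "strand"),
                      "annotation")
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) {
    stop("duplicated gene_id in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  if (one_based) df$start <- df$start - 1
  if (any(df$start < 0)) stop("negative start coordinate in annotation")
  if (any(df$end <= df$start)) {
    stop("annotation has end <= start for: ",
         paste(df$gene_id[df$end <= df$start], collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (is.null(df$biotype)) df$biotype <- "protein_coding"
  df$length <- df$end - df$start
  class(df) <- c("gene_annotation", "data.frame")
  df
}

#' Read a gene annotation TSV
#'
#' @param path TSV with header columns gene_id, chrom, start, end, strand
#'   and optionally biotype.
#' @inheritParams gene_annotation
#' @return `gene_annotation` data.frame.
#' @export
read_annotation <- function(path, one_based = FALSE) {
  gene_annotation(utils::read.delim(path, stringsAsFactors = FALSE),
                  one_based = one_based)
}

#' Look up gene lengths
#'
#' @param annotation `gene_annotation`.
#' @param gene_ids character vector; every id must be annotated.
#' @return named numeric vector of gene-body lengths in bp.
#' @export
gene_lengths <- function(annotation, gene_ids = annotation$gene_id) {
  idx <- match(gene_ids, annotation$gene_id)
  if (anyNA(idx)) {
    stop("no annotated length for gene(s): ",
         paste(gene_ids[is.na(idx)], collapse = ", "))
  }
  stats::setNames(annotation$length[idx], gene_ids)
}
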