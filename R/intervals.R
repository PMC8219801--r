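#' Extend intervals upstream of the transcription start
#'
#' Strand-aware promoter extension: on the + strand the start moves upstream
#' (clipped at 0), on the - strand the end moves upstream (to the right).
#' Coordinates are 0-based half-open; the interval grows by exactly
#' `distance_bp` unless clipped at the chromosome origin.
#'
#' @param intervals data.frame with columns chrom, start, end, strand
#'   (+ or -; "." is an error since upstream is undefined).
#' @param distance_bp extension distance (default 5000, to take in promoter
#'   regions).
#' @return the data.frame with adjusted start/end.
#' @export
extend_upstream <- function(intervals, distance_bp = 5000) {
  stop_if_not_df_cols(intervals, c("chrom", "start", "end", "strand"),
                      "intervals")
  stopifnot(distance_bp >= 0)
  if (any(intervals$strand == ".")) {
    stop("upstream is undefined for unstranded interval(s): ",
         paste(utils::head(which(intervals$strand == "."), 5), collapse = ", "))
  }
  plus <- intervals$strand == "+"
  intervals$start[plus] <- pmax(0, intervals$start[plus] - distance_bp)
  intervals$end[!plus] <- intervals$end[!plus] + distance_bp
  intervals
}

#' Filter ChIP-seq peaks on FDR and fold enrichment
#'
#' Keeps peaks with fdr strictly below `fdr_max` and fold_enrichment
#' strictly above `fold_enrichment_min` (both inequalities strict).
#'
#' @param peaks data.frame with columns fdr and fold_enrichment.
#' @param fdr_max FDR cutoff (default 1).
#' @param fold_enrichment_min fold-enrichment cutoff (default 10).
#' @return the retained rows.
#' @export
filter_peaks <- function(peaks, fdr_max = 1.0, fold_enrichment_min = 10.0) {
  stop_if_not_df_cols(peaks, c("chrom", "start", "end"), "peaks")
  for (col in c("fdr", "fold_enrichment")) {
    if (is.null(peaks[[col]]) || anyNA(peaks[[col]])) {
      bad <- if (is.null(peaks[[col]])) "all" else
        paste(utils::head(which(is.na(peaks[[col]])), 5), collapse = ", ")
      stop("peak(s) missing attribute '", col, "': ", bad)
    }
  }
  peaks[peaks$fdr < fdr_max & peaks$fold_enrichment > fold_enrichment_min, ,
        drop = FALSE]
}

#' Flag genes whose (extended) interval overlaps a peak
#'
#' A gene is a peak target if at least one peak overlaps its interval by at
#' least 1 bp under half-open semantics. Peak strand is ignored (ChIP peaks
#' are unstranded); apply [extend_upstream()] beforehand for promoter
#' inclusion.
#'
#' @param transcripts data.frame with chrom, start, end and gene_id
#'   (0-based half-open; typically already extended upstream).
#' @param peaks data.frame with chrom, start, end (typically already
#'   filtered).
#' @return named logical vector over `transcripts$gene_id`.
#' @export
intersect_targets <- function(transcripts, peaks) {
  stop_if_not_df_cols(transcripts, c("gene_id", "chrom", "start", "end"),
                      "transcripts")
  stop_if_not_df_cols(peaks, c("chrom", "start", "end"), "peaks")
  hit <- rep(FALSE, nrow(transcripts))
  if (nrow(peaks)) {
    # 0-based half-open -> 1-based closed for IRanges; shared seqlevels so
    # chromosomes present on only one side compare cleanly
    chroms <- union(transcripts$chrom, peaks$chrom)
    gr_t <- GenomicRanges::GRanges(
      factor(transcripts$chrom, chroms),
      IRanges::IRanges(transcripts$start + 1, transcripts$end))
    gr_p <- GenomicRanges::GRanges(
      factor(peaks$chrom, chroms),
      IRanges::IRanges(peaks$start + 1, peaks$end))
    hit <- GenomicRanges::countOverlaps(gr_t, gr_p, minoverlap = 1L,
                                        ignore.strand = TRUE) > 0
  }
  stats::setNames(hit, transcripts$gene_id)
}

#' Fisher's exact test for the overlap of two gene lists
#'
#' Builds the 2x2 table (in both, A only, B only, neither) over a finite
#' gene universe and applies the two-sided Fisher's exact test (summing all
#' hypergeometric tables no more probable than the observed one). The
#' universe should be the analysed gene set the lists were drawn from, not
#' the whole annotation.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of analysed genes; nonempty.
#' @return object of class `overlap_result`: set sizes, universe size,
#'   overlap size, odds_ratio (conditional MLE, Inf allowed), p_value.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) || length(setdiff(set_b, universe))) {
    stop("set_a and set_b must be subsets of the universe")
  }
  n11 <- length(intersect(set_a, set_b))
  n12 <- length(set_a) - n11
  n21 <- length(set_b) - n11
  n22 <- length(universe) - n11 - n12 - n21
  ft <- stats::fisher.test(matrix(c(n11, n21, n12, n22), 2),
                           alternative = "two.sided")
  structure(list(set_a_size = length(set_a), set_b_size = length(set_b),
                 universe_size = length(universe), overlap_size = n11,
                 odds_ratio = unname(ft$estimate), p_value = ft$p.value),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("overlap: ", x$overlap_size, " of |A|=", x$set_a_size, ", |B|=",
      x$set_b_size, " in universe ", x$universe_size,
      "; OR = ", format(x$odds_ratio, digits = 4),
      ", p = ", format(x$p_value, digits = 4), " (Fisher, two-sided)\n",
      sep = "")
  invisible(x)
}

#' Read a BED6+ peak file
#'
#' BED columns chrom, start, end, name, score, strand, with `fdr` and
#' `fold_enrichment` in configurable extra columns (7 and 8 by default).
#'
#' @param path BED-like TSV without header.
#' @param fdr_col,fold_enrichment_col 1-based column indices of the two
#'   attributes.
#' @return data.frame: chrom, start, end, name, score, strand, fdr,
#'   fold_enrichment.
#' @export
read_peaks_bed <- function(path, fdr_col = 7, fold_enrichment_col = 8) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < max(fdr_col, fold_enrichment_col)) {
    stop("peak file has ", ncol(df), " columns; fdr/fold_enrichment expected",
         " in columns ", fdr_col, "/", fold_enrichment_col)
  }
  out <- data.frame(chrom = df[[1]], start = as.numeric(df[[2]]),
                    end = as.numeric(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else "",
                    score = if (ncol(df) >= 5) df[[5]] else 0,
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else ".",
                    fdr = as.numeric(df[[fdr_col]]),
                    fold_enrichment = as.numeric(df[[fold_enrichment_col]]),
                    stringsAsFactors = FALSE)
  if (any(out$start < 0 | out$end <= out$start)) {
    stop("invalid peak coordinates (need 0 <= start < end)")
  }
  out
}
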