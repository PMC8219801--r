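# Independent oracles and small fixture builders shared across the suite.

# Exhaustive two-sided Fisher p for a 2x2 table by minimum-likelihood
# summation over every table with the observed margins (dhyper enumeration,
# with the conventional 1e-7 relative tolerance at the probability boundary).
fisher_enum_p <- function(n11, n12, n21, n22) {
  m <- n11 + n12          # size of set A
  n <- n21 + n22          # complement of A
  k <- n11 + n21          # size of set B
  support <- max(0, k - n):min(k, m)
  d <- stats::dhyper(support, m, n, k)
  d0 <- stats::dhyper(n11, m, n, k)
  sum(d[d <= d0 * (1 + 1e-7)])
}

# naive all-pairs interval intersection (0-based half-open)
brute_overlap <- function(transcripts, peaks) {
  hits <- vapply(seq_len(nrow(transcripts)), function(i) {
    any(peaks$chrom == transcripts$chrom[i] &
          peaks$start < transcripts$end[i] &
          peaks$end > transcripts$start[i])
  }, logical(1))
  stats::setNames(hits, transcripts$gene_id)
}

# ratio_table wrapper around a genes x timepoints matrix for one condition
ratio_table_from_matrix <- function(m, condition = "control",
                                    excluded = NULL) {
  tps <- as.numeric(colnames(m))
  df <- data.frame(
    gene_id = rep(rownames(m), times = ncol(m)),
    condition = condition,
    timepoint = rep(tps, each = nrow(m)),
    ratio = as.vector(m), stringsAsFactors = FALSE)
  excluded <- excluded %||% data.frame(
    gene_id = character(), condition = character(), reason = character())
  structure(list(ratios = df, excluded = excluded, mode = "replicate_mean"),
            class = "ratio_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-condition count experiment with one replicate
make_quant_experiment <- function(counts, lengths, library_size = 1e6,
                                  condition = "control",
                                  timepoints = c(0, 0.5, 2.5, 24.5)) {
  genes <- rownames(counts)
  samples <- data.frame(
    sample_id = colnames(counts), condition = condition,
    timepoint = timepoints[seq_len(ncol(counts))], replicate = 1L,
    library_size = library_size, stringsAsFactors = FALSE)
  ann <- gene_annotation(data.frame(
    gene_id = genes, chrom = "chr1",
    start = seq(0, by = 1e6, length.out = length(genes)),
    end = seq(0, by = 1e6, length.out = length(genes)) + lengths,
    strand = "+", stringsAsFactors = FALSE))
  bru_experiment(counts, samples, ann, state = "counts")
}

# random interval fixture for intersection tests
random_interval_fixture <- function(n_genes, n_peaks, span = 1e5) {
  gs <- sort(sample.int(span, n_genes))
  transcripts <- data.frame(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    start = gs, end = gs + sample.int(5000, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  ps <- sample.int(span, n_peaks)
  peaks <- data.frame(
    chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
    start = ps, end = ps + sample.int(800, n_peaks),
    stringsAsFactors = FALSE)
  list(transcripts = transcripts, peaks = peaks)
}
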