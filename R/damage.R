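#' UV lesion-load model parameters
#'
#' UVC photoproducts (mostly cyclobutane pyrimidine dimers) are distributed
#' essentially uniformly along the genome, so the expected lesion count of a
#' transcription unit is proportional to its length and to the dose. At the
#' reference dose of 10 J/m2, UVC generates about 1 lesion per 6 kb of
#' double-stranded DNA; only lesions on the transcribed (template) strand
#' block RNA polymerase II, halving the rate to 1 per 12 kb. Dose scaling is
#' linear.
#'
#' @param dose UVC dose in J/m2 (default 10).
#' @param reference_dose dose at which `ds_rate_per_bp` is defined (10 J/m2).
#' @param ds_rate_per_bp lesions per bp of double-stranded DNA at the
#'   reference dose (default 1/6000).
#' @param strand_factor fraction of lesions on the transcribed strand
#'   (default 0.5).
#' @return object of class `lesion_params`.
#' @examples
#' p <- lesion_params()
#' expected_lesions(12000, p)                      # 1 lesion per 12 kb
#' prob_damaged(12000, p)                          # 1 - exp(-1)
#' @export
lesion_params <- function(dose = 10, reference_dose = 10,
                          ds_rate_per_bp = 1 / 6000, strand_factor = 0.5) {
  stopifnot(dose > 0, reference_dose > 0, ds_rate_per_bp > 0,
            strand_factor > 0, strand_factor <= 1)
  structure(list(dose = dose, reference_dose = reference_dose,
                 ds_rate_per_bp = ds_rate_per_bp,
                 strand_factor = strand_factor),
            class = "lesion_params")
}

#' @export
print.lesion_params <- function(x, ...) {
  cat("UV lesion model: ", format(1 / x$ds_rate_per_bp / 1000),
      " kb/lesion (ds DNA) at ", x$reference_dose, " J/m2; dose ", x$dose,
      " J/m2; transcribed-strand factor ", x$strand_factor, "\n", sep = "")
  invisible(x)
}

#' Expected number of UV lesions on a transcription unit
#'
#' lambda = length_bp x (dose / reference_dose) x ds_rate_per_bp
#' x strand_factor (transcribed strand) or x 1 (both strands).
#'
#' @param length_bp gene-body length(s) in bp (non-negative).
#' @param params `lesion_params`.
#' @param strand "transcribed" (default; lesions that block RNAPII) or
#'   "double_stranded".
#' @return expected lesion count(s), same length as `length_bp`.
#' @export
expected_lesions <- function(length_bp, params = lesion_params(),
                             strand = c("transcribed", "double_stranded")) {
  strand <- match.arg(strand)
  if (any(length_bp < 0)) stop("gene length must be non-negative")
  sf <- if (strand == "transcribed") params$strand_factor else 1
  length_bp * (params$dose / params$reference_dose) * params$ds_rate_per_bp * sf
}

#' Probability that a gene carries at least one transcribed-strand lesion
#'
#' Lesion counts are modelled as Poisson with mean lambda from
#' [expected_lesions()] on the transcribed strand, so
#' P(damaged) = 1 - exp(-lambda).
#'
#' @inheritParams expected_lesions
#' @return probabilities in \[0, 1).
#' @export
prob_damaged <- function(length_bp, params = lesion_params()) {
  -expm1(-expected_lesions(length_bp, params, "transcribed"))
}

#' @export
predict.lesion_params <- function(object, length_bp, ...) {
  prob_damaged(length_bp, object)
}

#' Expected fraction of damaged genes in a set
#'
#' Mean over genes of the per-gene probability of carrying at least one
#' transcribed-strand lesion (each gene's own length enters; no single
#' representative length is used).
#'
#' @param length_bp lengths of the genes in the set (bp); nonempty.
#' @param params `lesion_params`.
#' @return scalar expected damaged fraction.
#' @export
fraction_damaged <- function(length_bp, params = lesion_params()) {
  if (!length(length_bp)) stop("empty gene set")
  mean(prob_damaged(length_bp, params))
}

#' Predicted damage load vs observed knockdown dependence
#'
#' For a gene set (typically UV-repressed genes below a length cutoff),
#' contrasts the Poisson-predicted fraction of genes with at least one
#' transcribed-strand lesion against the observed fraction whose recovery
#' requires the knocked-down factor (dependency class "stimulated"). An
#' observed fraction well above the predicted one indicates recovery control
#' beyond damaged genes.
#'
#' @param length_bp named numeric vector of gene lengths (names = gene_id).
#' @param dependency `uv_dependency` covering the same genes.
#' @param params `lesion_params`.
#' @return list: predicted_damaged_fraction, observed_dependent_fraction,
#'   excess (observed - predicted), n.
#' @export
damage_vs_dependency <- function(length_bp, dependency,
                                 params = lesion_params()) {
  stopifnot(inherits(dependency, "uv_dependency"))
  idx <- match(names(length_bp), dependency$gene_id)
  if (anyNA(idx)) {
    stop("no dependency call for gene(s): ",
         paste(utils::head(names(length_bp)[is.na(idx)], 5), collapse = ", "))
  }
  cls <- dependency$dependency[idx]
  keep <- cls != "excluded"
  predicted <- fraction_damaged(length_bp[keep], params)
  observed <- mean(cls[keep] == "stimulated")
  list(predicted_damaged_fraction = predicted,
       observed_dependent_fraction = observed,
       excess = observed - predicted, n = sum(keep))
}

#' Per-gene damage table
#'
#' @param annotation `gene_annotation`.
#' @param params `lesion_params`.
#' @param genes gene ids (default: all annotated).
#' @return data.frame: gene_id, length, lambda (transcribed strand),
#'   prob_damaged.
#' @export
damage_table <- function(annotation, params = lesion_params(),
                         genes = annotation$gene_id) {
  len <- gene_lengths(annotation, genes)
  data.frame(gene_id = genes, length = unname(len),
             lambda = unname(expected_lesions(len, params, "transcribed")),
             prob_damaged = unname(prob_damaged(len, params)),
             stringsAsFactors = FALSE, row.names = NULL)
}
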