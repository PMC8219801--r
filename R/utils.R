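#' Normalise timepoint labels to hours post UVC
#'
#' Bru-seq samples are labelled with a 30-min bromouridine pulse starting 0,
#' 2, 6 or 24 h after irradiation, so the effective (midpoint-convention)
#' timepoints are 0.5, 2.5, 6.5 and 24.5 h. Input tables may carry either the
#' recovery-time names used at the bench ("30min", "2h30", "24h30") or the
#' numeric labelled timepoints; this resolves both to numeric hours.
#'
#' @param x character or numeric vector of timepoint labels.
#' @return numeric vector of hours post UVC (0 = unirradiated).
#' @examples
#' normalize_timepoint(c("0", "30min", "2h30", "24h30"))
#' normalize_timepoint(c(0, 0.5, 2.5, 24.5))
#' @export
normalize_timepoint <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  key <- tolower(gsub("[[:space:]_]", "", as.character(x)))
  alias <- c(
    "0" = 0, "0h" = 0, "noUV" = 0, "nouv" = 0, "untreated" = 0,
    "30min" = 0.5, "0h30" = 0.5, "0.5" = 0.5, "0.5h" = 0.5,
    "2h30" = 2.5, "2.5" = 2.5, "2.5h" = 2.5, "150min" = 2.5,
    "6h30" = 6.5, "6.5" = 6.5, "6.5h" = 6.5,
    "24h30" = 24.5, "24.5" = 24.5, "24.5h" = 24.5
  )
  out <- unname(alias[key])
  bad <- is.na(out)
  if (any(bad)) {
    num <- suppressWarnings(as.numeric(key[bad]))
    out[bad] <- num
    if (anyNA(out)) {
      stop("unrecognised timepoint label(s): ",
           paste(unique(x[is.na(out)]), collapse = ", "))
    }
  }
  out
}

# float-safe matching of timepoints (tables may round-trip through text)
tp_match <- function(x, table, tol = 1e-6) {
  idx <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    hit <- which(abs(table - x[i]) < tol)
    if (length(hit)) idx[i] <- hit[1L]
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_df_cols <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data.frame")
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}
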