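#' Write a cue-by-outcome weight matrix to TSV
#'
#' Rows are cues, columns are outcomes, cells are association strengths.
#' The first column is headed `Cue`. With `digits = NULL` values are
#' written with full `as.character()` precision so the file round-trips
#' bit-exactly through [read_weights()].
#'
#' @param weights Numeric matrix with cue rownames and outcome colnames,
#'   or an `ndl_fit` object.
#' @param path Output path.
#' @param digits Decimal places, or `NULL` for full precision.
#' @param header_lines Optional `#%` provenance header lines.
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path, digits = NULL, header_lines = NULL) {
  w <- as_weight_matrix(weights)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_lines)) {
    writeLines(paste0(header_prefix, " ", header_lines), con)
  }
  writeLines(paste(c("Cue", colnames(w)), collapse = "\t"), con)
  fmt <- if (is.null(digits)) {
    function(x) sprintf("%.17g", x)
  } else {
    function(x) formatC(x, digits = digits, format = "f")
  }
  for (i in seq_len(nrow(w))) {
    writeLines(paste(c(rownames(w)[i], fmt(w[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a cue-by-outcome weight matrix from TSV
#'
#' @param path Path written by [write_weights()] (or any TSV whose first
#'   column `Cue` holds cue labels and remaining columns hold per-outcome
#'   association strengths). `#%` header lines are skipped.
#' @return Numeric matrix, rownames = cues, colnames = outcomes.
#' @export
read_weights <- function(path) {
  raw <- read_tsv_skipping_header(path)
  require_columns(raw, "Cue", path)
  if (ncol(raw) < 2L) rlang::abort(sprintf("'%s' has no outcome columns.", path))
  w <- as.matrix(as.data.frame(lapply(raw[-1], as.numeric)))
  colnames(w) <- names(raw)[-1]
  rownames(w) <- raw$Cue
  if (any(!is.finite(w))) rlang::abort(sprintf("non-numeric weight cell in '%s'.", path))
  w
}

# accept an ndl_fit or a bare matrix wherever weights are needed
as_weight_matrix <- function(weights) {
  if (inherits(weights, "ndl_fit")) {
    return(weights$weights)
  }
  if (is.matrix(weights) && is.numeric(weights) &&
    !is.null(rownames(weights)) && !is.null(colnames(weights))) {
    return(weights)
  }
  rlang::abort("`weights` must be an ndl_fit or a numeric matrix with cue rownames and outcome colnames.")
}
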