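#' Fluorescence trace matrix
#'
#' A numeric matrix of fluorescence traces, one ROI per row and one imaging
#' frame per column, with the volume rate attached. Row names are ROI ids and
#' must match the ROI table. Frames are 0-based throughout the package and
#' all frame windows are half-open `[start, end)`. Censored frames are `NA`.
#'
#' @param values Numeric matrix (ROIs x frames); row names are ROI ids.
#' @param rate_hz Volumes per second (typically 2 or 4).
#' @param roi_ids Optional ROI ids overriding the row names.
#' @return A `trace_matrix`.
#' @export
trace_matrix <- function(values, rate_hz, roi_ids = rownames(values)) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), rate_hz > 0)
  if (is.null(roi_ids)) stop("trace matrix needs ROI ids as row names", call. = FALSE)
  if (anyDuplicated(roi_ids)) stop("duplicate ROI ids in trace matrix", call. = FALSE)
  if (any(!is.finite(values) & !is.na(values))) {
    stop("trace values must be finite or NA", call. = FALSE)
  }
  rownames(values) <- roi_ids
  structure(values, rate_hz = rate_hz, class = c("trace_matrix", "matrix", "array"))
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat("<trace_matrix> ", nrow(x), " ROIs x ", ncol(x), " frames at ",
      attr(x, "rate_hz"), " Hz\n", sep = "")
  invisible(x)
}

# keep class and rate when subsetting rows/columns
#' @export
`[.trace_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    out <- structure(out, rate_hz = attr(x, "rate_hz"),
                     class = c("trace_matrix", "matrix", "array"))
  }
  out
}

#' Rate of a trace matrix, volumes per second
#' @param traces A [trace_matrix].
#' @return Numeric scalar.
#' @export
trace_rate <- function(traces) attr(traces, "rate_hz")

#' Z-score every trace
#'
#' Transforms each row to mean 0, SD 1 (ignoring censored frames). A constant
#' row carries no signal and is an error, reported by ROI id.
#'
#' @param traces A [trace_matrix].
#' @return A z-scored [trace_matrix].
#' @export
zscore_traces <- function(traces) {
  m <- rowMeans(traces, na.rm = TRUE)
  s <- apply(traces, 1, sd, na.rm = TRUE)
  bad <- which(!is.finite(s) | s == 0)
  if (length(bad)) {
    stop("degenerate (constant) trace for ROI: ",
         paste(head(rownames(traces)[bad], 5), collapse = ", "), call. = FALSE)
  }
  trace_matrix((traces - m) / s, rate_hz = trace_rate(traces))
}

#' Check that a trace matrix is z-scored
#'
#' @param traces A [trace_matrix].
#' @param tol Tolerance on the row means and SDs.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
assert_zscored <- function(traces, tol = 1e-9) {
  m <- rowMeans(traces, na.rm = TRUE)
  s <- apply(traces, 1, sd, na.rm = TRUE)
  if (any(abs(m) > tol) || any(abs(s - 1) > tol)) {
    stop("trace matrix is not z-scored", call. = FALSE)
  }
  invisible(TRUE)
}
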