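#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Rent fit
#' @param x A `rent_fit`.
#' @param ... Ignored.
#' @return One-row tibble with `exponent`, `exponent_sd`, `intercept`.
#' @export
tidy.rent_fit <- function(x, ...) {
  tibble::tibble(exponent = x$exponent, exponent_sd = x$exponent_sd,
                 intercept = x$intercept)
}

#' Glance at a Rent fit
#' @param x A `rent_fit`.
#' @param ... Ignored.
#' @return One-row tibble with sample counts.
#' @export
glance.rent_fit <- function(x, ...) {
  tibble::tibble(n_valid = x$n_valid, n_boxes = x$n_boxes)
}

#' Tidy a decode result
#' @param x A `decode_result`.
#' @param ... Ignored.
#' @return Tibble with one row per subset.
#' @export
tidy.decode_result <- function(x, ...) {
  tibble::tibble(subset = seq_along(x$subset_r2), r2 = x$subset_r2)
}

#' Glance at a decode result
#' @param x A `decode_result`.
#' @param ... Ignored.
#' @return One-row tibble with the mean validation r-squared.
#' @export
glance.decode_result <- function(x, ...) {
  tibble::tibble(mean_r2 = x$mean_r2, n_subsets = x$n_subsets)
}

#' Tidy a cluster model
#' @param x A `cluster_model`.
#' @param ... Ignored.
#' @return The assignments tibble.
#' @export
tidy.cluster_model <- function(x, ...) x$assignments

#' Glance at a cluster model
#' @param x A `cluster_model`.
#' @param ... Ignored.
#' @return One-row tibble with `k`, cost, and member counts.
#' @export
glance.cluster_model <- function(x, ...) {
  tibble::tibble(k = x$k, l1_cost = x$cost,
                 n_rois = nrow(x$assignments),
                 n_retained = sum(x$assignments$retained))
}
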