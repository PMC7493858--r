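#' Topological Rentian scaling of a physically embedded network
#'
#' Random axis-aligned boxes are placed over the node cloud (coordinates
#' z-scored per axis) and, for each box, the number of nodes strictly inside
#' (N) and the number of edges crossing the box boundary (E, exactly one
#' endpoint inside) are counted. The Rent exponent is the slope of a robust
#' regression of log(E) on log(N): higher exponents indicate more long-range,
#' less spatially modular wiring.
#'
#' @name rentian
NULL

#' Sample random boxes over an embedded graph
#'
#' Coordinates are z-scored per axis. Each box has its corner drawn uniformly
#' within the coordinate bounding volume and its per-axis size drawn
#' uniformly in (0, axis range]; membership uses half-open intervals
#' `[corner, corner + size)` so boundary nodes are never double-counted.
#'
#' @param coords Numeric matrix (nodes x 3) of node coordinates.
#' @param adj Logical/0-1 adjacency matrix (undirected, zero diagonal).
#' @param n_boxes Number of boxes (default 5000).
#' @param seed Integer seed.
#' @return Tibble with `n_inside` and `e_crossing`, one row per box.
#' @export
sample_boxes <- function(coords, adj, n_boxes = 5000, seed = 1L) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2, ncol(coords) == 3, nrow(adj) == nrow(coords))
  z <- scale(coords)
  z[is.nan(z)] <- 0  # degenerate axis (no spread)
  lo <- apply(z, 2, min)
  hi <- apply(z, 2, max)
  set.seed(child_seed(seed, "boxes"))
  corner <- sapply(1:3, function(a) runif(n_boxes, lo[a], hi[a]))
  size <- sapply(1:3, function(a) runif(n_boxes, 0, hi[a] - lo[a]))
  inside <- matrix(TRUE, n_boxes, nrow(z))
  for (a in 1:3) {
    if (hi[a] - lo[a] <= 0) next  # degenerate axis constrains nothing
    inside <- inside &
      outer(corner[, a], z[, a], `<=`) &
      outer(corner[, a] + size[, a], z[, a], `>`)
  }
  A <- (adj | t(adj))
  eidx <- which(A & upper.tri(A), arr.ind = TRUE)
  n_inside <- rowSums(inside)
  if (nrow(eidx)) {
    e_crossing <- rowSums(inside[, eidx[, 1], drop = FALSE] !=
                            inside[, eidx[, 2], drop = FALSE])
  } else {
    e_crossing <- rep(0L, n_boxes)
  }
  tibble::tibble(n_inside = as.integer(n_inside),
                 e_crossing = as.integer(e_crossing))
}

#' Fit the Rent exponent by robust regression
#'
#' Boxes with fewer than 2 nodes inside or no crossing edges are excluded
#' (their logs are undefined or degenerate). The slope of log(E) on log(N) is
#' estimated by iteratively reweighted least squares with Tukey bisquare
#' weights (tuning constant 4.685) to limit the influence of outliers; when
#' the samples are an exact power law (zero residual scale) the ordinary
#' least-squares fit is returned.
#'
#' @param samples Tibble from [sample_boxes()].
#' @param min_samples Minimum number of valid samples (default 10).
#' @return A `rent_fit`: list with `exponent`, `exponent_sd`, `intercept`,
#'   `n_valid`, `n_boxes`.
#' @export
fit_rent <- function(samples, min_samples = 10) {
  ok <- samples$n_inside >= 2 & samples$e_crossing >= 1
  d <- data.frame(ln = log(samples$n_inside[ok]), le = log(samples$e_crossing[ok]))
  if (nrow(d) < min_samples) {
    stop("only ", nrow(d), " valid box samples; need at least ", min_samples,
         call. = FALSE)
  }
  if (length(unique(d$ln)) < 3) {
    stop("insufficient variation in box occupancy to fit a slope", call. = FALSE)
  }
  ols <- stats::lm(le ~ ln, data = d)
  if (sqrt(mean(stats::residuals(ols)^2)) < 1e-8) {
    # this branch exists for exact power laws, where summary.lm warns
    sm <- suppressWarnings(summary(ols))$coefficients
    fit <- list(exponent = unname(coef(ols)[2]),
                exponent_sd = unname(sm[2, 2]),
                intercept = unname(coef(ols)[1]))
  } else {
    rfit <- MASS::rlm(le ~ ln, data = d, psi = MASS::psi.bisquare, c = 4.685,
                      maxit = 100)
    sm <- summary(rfit)$coefficients
    fit <- list(exponent = unname(coef(rfit)[2]),
                exponent_sd = unname(sm[2, 2]),
                intercept = unname(coef(rfit)[1]))
  }
  structure(c(fit, list(n_valid = nrow(d), n_boxes = nrow(samples))),
            class = "rent_fit")
}

#' @export
print.rent_fit <- function(x, ...) {
  cat("<rent_fit> exponent ", format(x$exponent, digits = 4), " +/- ",
      format(x$exponent_sd, digits = 3), " (", x$n_valid, "/", x$n_boxes,
      " valid boxes)\n", sep = "")
  invisible(x)
}

#' Rentian scaling of a correlation graph
#'
#' Convenience wrapper: samples boxes over the graph's node coordinates and
#' fits the Rent exponent.
#'
#' @param graph A `corr_graph` (nodes must carry `x`, `y`, `z`).
#' @param n_boxes Number of random boxes.
#' @param seed Integer seed.
#' @return A `rent_fit`.
#' @export
rent_scaling <- function(graph, n_boxes = 5000, seed = 1L) {
  coords <- as.matrix(graph$nodes[, c("x", "y", "z")])
  fit <- fit_rent(sample_boxes(coords, graph$adj, n_boxes = n_boxes, seed = seed))
  fit$amplitude_db <- graph$amplitude_db
  fit
}

#' Compare two Rent exponents
#'
#' Difference of exponents with the pooled (root-sum-square) SD. No
#' hypothesis test is attached; group-level testing is left to downstream
#' statistics.
#'
#' @param fit_a,fit_b Two `rent_fit`s.
#' @return Tibble with `difference` (`a - b`) and `pooled_sd`.
#' @export
compare_exponents <- function(fit_a, fit_b) {
  tibble::tibble(
    exponent_a = fit_a$exponent, exponent_b = fit_b$exponent,
    difference = fit_a$exponent - fit_b$exponent,
    pooled_sd = sqrt(fit_a$exponent_sd^2 + fit_b$exponent_sd^2)
  )
}
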