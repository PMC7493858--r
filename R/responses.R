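#' Regression-based detection of stimulus-responsive ROIs
#'
#' Each z-scored trace is modeled by multivariate ordinary least squares
#' against the full regressor set plus an intercept. The coefficient of each
#' regressor reads out response strength in z-score units. Because a single
#' whole-model r-squared cannot be stimulus-specific, the per-regressor
#' r-squared is taken from the univariate fit of that regressor alone (the
#' squared Pearson correlation between trace and regressor).
#'
#' Censored frames (`NA`) are dropped pairwise: ROIs sharing a censoring
#' pattern are fitted together on their uncensored frames.
#'
#' @param traces A z-scored [trace_matrix].
#' @param regs A regressor set from [make_regressors()].
#' @return Tibble with one row per (ROI, regressor): `roi_id`, `regressor`,
#'   `beta`, `r2`.
#' @export
fit_regression <- function(traces, regs) {
  R <- regs$matrix
  if (ncol(traces) != ncol(R)) {
    stop("trace and regressor frame counts differ", call. = FALSE)
  }
  cr <- cor(t(R))
  if (any(abs(cr[upper.tri(cr)]) > 0.999)) {
    stop("near-collinear regressor pair (|correlation| > 0.999)", call. = FALSE)
  }
  n <- nrow(traces)
  p <- nrow(R)
  X <- cbind(1, t(R))
  nas <- is.na(unclass(traces))
  if (any(nas)) {
    key <- vapply(seq_len(n), function(i) paste(which(nas[i, ]), collapse = ","), "")
  } else {
    key <- rep("", n)
  }
  beta <- matrix(NA_real_, p, n)
  r2 <- matrix(NA_real_, p, n)
  for (k in unique(key)) {
    rows <- which(key == k)
    ok <- !nas[rows[1], ]
    Xk <- X[ok, , drop = FALSE]
    Yk <- t(unclass(traces)[rows, ok, drop = FALSE])
    B <- solve(crossprod(Xk), crossprod(Xk, Yk))
    beta[, rows] <- B[-1, , drop = FALSE]
    r2[, rows] <- cor(Xk[, -1, drop = FALSE], Yk)^2
  }
  tibble::tibble(
    roi_id = rep(rownames(traces), each = p),
    regressor = rep(regs$labels, times = n),
    beta = as.numeric(beta),
    r2 = as.numeric(r2)
  )
}

#' Multisensory responsiveness thresholds
#'
#' For each stimulus regressor the cutoff is the mean plus two SD of the
#' wild-type coefficient distribution; the same cutoffs are applied to every
#' genotype. An ROI is responsive to a stimulus when its coefficient strictly
#' exceeds the cutoff and its per-regressor r-squared strictly exceeds
#' `r2_min`.
#'
#' @param records Regression records ([fit_regression()] output) to classify.
#' @param reference_records Wild-type regression records defining the cutoffs.
#' @param r2_min Minimum r-squared (default 0.1).
#' @return `records` with a logical `responsive` column; the per-regressor
#'   cutoffs are attached as the `cutoffs` attribute.
#' @export
threshold_multisensory <- function(records, reference_records, r2_min = 0.1) {
  stopifnot(nrow(reference_records) > 0)
  cuts <- dplyr::summarise(
    dplyr::group_by(reference_records, .data$regressor),
    cutoff = mean(.data$beta) + 2 * sd(.data$beta), .groups = "drop"
  )
  out <- dplyr::left_join(records, cuts, by = "regressor")
  out <- dplyr::mutate(out,
                       responsive = .data$beta > .data$cutoff & .data$r2 > r2_min)
  out$cutoff <- NULL
  attr(out, "cutoffs") <- cuts
  out
}

#' Auditory-sensitivity candidate threshold
#'
#' An ROI is a candidate auditory responder to an amplitude when its
#' coefficient is strictly positive and its r-squared strictly exceeds
#' `r2_min`. Candidates are finalized downstream by functional clustering.
#'
#' @param records Regression records.
#' @param r2_min Minimum r-squared (default 0.05).
#' @return `records` with a logical `responsive` column.
#' @export
threshold_auditory <- function(records, r2_min = 0.05) {
  dplyr::mutate(records, responsive = .data$beta > 0 & .data$r2 > r2_min)
}

#' Censor frames around startle events
#'
#' Marks the frames flanking a startle-contaminated stimulus as missing for
#' every ROI of the affected larva: frames `[onset_frame - flank,
#' onset_frame + flank)`, clipped to the recording.
#'
#' @param traces A [trace_matrix].
#' @param larva_of_roi Character vector, the larva id of each trace row.
#' @param censor Tibble with `larva_id` and `onset_s` of the events to censor.
#' @param flank_frames Number of frames to remove on each side (default 50).
#' @return The trace matrix with censored frames set to `NA`.
#' @export
exclude_startle_frames <- function(traces, larva_of_roi, censor, flank_frames = 50) {
  stopifnot(length(larva_of_roi) == nrow(traces))
  rate <- trace_rate(traces)
  nf <- ncol(traces)
  vals <- unclass(traces)
  for (i in seq_len(nrow(censor))) {
    if (!censor$larva_id[i] %in% larva_of_roi) {
      stop("censored event names unknown larva: ", censor$larva_id[i], call. = FALSE)
    }
    f <- floor(censor$onset_s[i] * rate)
    lo <- f - flank_frames
    hi <- f + flank_frames  # half-open [lo, hi)
    if (lo < 0 || hi > nf) {
      message("censor window clipped to the recording for larva ", censor$larva_id[i])
    }
    span <- seq.int(max(0L, lo), min(nf, hi) - 1L) + 1L
    vals[larva_of_roi == censor$larva_id[i], span] <- NA_real_
  }
  trace_matrix(vals, rate_hz = rate)
}

#' Detect spontaneous calcium events in one trace
#'
#' Finds local maxima rising at least `sd_mult` SD above a running-median
#' local baseline (10-s window by default), then greedily enforces a minimum
#' separation between accepted peaks, keeping larger peaks first.
#'
#' @param trace Numeric z-scored trace (one ROI).
#' @param rate_hz Volumes per second.
#' @param min_sep_s Minimum separation between events (s).
#' @param sd_mult SD multiple above the local baseline.
#' @param baseline_window_s Running-median window (s).
#' @return List with `n_events`, `rate_per_min`, `frames` (0-based).
#' @export
detect_events <- function(trace, rate_hz, min_sep_s = 2, sd_mult = 1,
                          baseline_window_s = 10) {
  x <- as.numeric(trace)
  n <- length(x)
  if (anyNA(x)) {
    x <- stats::approx(seq_len(n)[!is.na(x)], x[!is.na(x)], xout = seq_len(n),
                       rule = 2)$y
  }
  k <- max(3L, round(baseline_window_s * rate_hz) %/% 2L * 2L + 1L)
  k <- min(k, (n - 1L) %/% 2L * 2L + 1L)
  baseline <- runmed(x, k)
  sdv <- sd(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L  # strict-then-nonstrict local maxima
  cand <- cand[x[cand] > baseline[cand] + sd_mult * sdv]
  sep <- min_sep_s * rate_hz
  accepted <- integer(0)
  for (f in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(accepted) || all(abs(f - accepted) >= sep)) {
      accepted <- c(accepted, f)
    }
  }
  accepted <- sort(accepted)
  list(n_events = length(accepted),
       rate_per_min = length(accepted) / (n / rate_hz / 60),
       frames = accepted - 1L)
}

#' Per-ROI spontaneous event rates
#'
#' @param traces A z-scored [trace_matrix].
#' @inheritParams detect_events
#' @return Tibble with `roi_id`, `n_events`, `rate_per_min`.
#' @export
event_rates <- function(traces, min_sep_s = 2, sd_mult = 1, baseline_window_s = 10) {
  res <- lapply(seq_len(nrow(traces)), function(i) {
    detect_events(unclass(traces)[i, ], trace_rate(traces), min_sep_s, sd_mult,
                  baseline_window_s)
  })
  tibble::tibble(
    roi_id = rownames(traces),
    n_events = vapply(res, `[[`, 0L, "n_events"),
    rate_per_min = vapply(res, `[[`, 0, "rate_per_min")
  )
}

#' Pairwise correlation versus 3D distance
#'
#' Pearson correlation (pairwise-complete over censored frames) and Euclidean
#' distance in micrometres for every pair of ROIs within each larva.
#'
#' @param traces A [trace_matrix].
#' @param rois ROI tibble (`roi_id`, `larva_id`, `x`, `y`, `z`).
#' @param max_rois_per_larva Optional cap: larger larvae are deterministically
#'   subsampled to this many ROIs to bound the pair count.
#' @return Tibble with `larva_id`, `roi_a`, `roi_b`, `distance_um`,
#'   `correlation`.
#' @export
correlation_vs_distance <- function(traces, rois, max_rois_per_larva = Inf) {
  stopifnot(nrow(rois) >= 2)
  out <- lapply(split(rois, rois$larva_id), function(rl) {
    if (nrow(rl) > max_rois_per_larva) {
      rl <- rl[round(seq(1, nrow(rl), length.out = max_rois_per_larva)), ]
    }
    if (nrow(rl) < 2) return(NULL)
    tr <- unclass(traces)[rl$roi_id, , drop = FALSE]
    cm <- cor(t(tr), use = "pairwise.complete.obs")
    dm <- as.matrix(stats::dist(rl[, c("x", "y", "z")]))
    iu <- which(upper.tri(cm), arr.ind = TRUE)
    tibble::tibble(
      larva_id = rl$larva_id[1],
      roi_a = rl$roi_id[iu[, 1]], roi_b = rl$roi_id[iu[, 2]],
      distance_um = dm[iu], correlation = cm[iu]
    )
  })
  dplyr::bind_rows(out)
}

#' Bin correlation/distance pairs into a heat-map table
#'
#' @param pairs Output of [correlation_vs_distance()].
#' @param dist_width_um Distance bin width (micrometres).
#' @param corr_width Correlation bin width.
#' @return Tibble with bin midpoints and pair counts.
#' @export
bin_correlation_distance <- function(pairs, dist_width_um = 20, corr_width = 0.1) {
  dplyr::count(
    dplyr::mutate(pairs,
                  dist_bin = (floor(.data$distance_um / dist_width_um) + 0.5) * dist_width_um,
                  corr_bin = (floor(.data$correlation / corr_width) + 0.5) * corr_width),
    .data$dist_bin, .data$corr_bin, name = "n_pairs"
  )
}

# correlation between matched rows of two matrices; rows with any NA give NA
row_cor <- function(A, B) {
  ok <- rowSums(is.na(A)) == 0 & rowSums(is.na(B)) == 0
  out <- rep(NA_real_, nrow(A))
  if (any(ok)) {
    Ac <- A[ok, , drop = FALSE] - rowMeans(A[ok, , drop = FALSE])
    Bc <- B[ok, , drop = FALSE] - rowMeans(B[ok, , drop = FALSE])
    out[ok] <- rowSums(Ac * Bc) /
      sqrt(rowSums(Ac^2) * rowSums(Bc^2))
  }
  out
}

#' Inter-repetition response consistency
#'
#' For every discrete amplitude at or above `min_amplitude_db`, correlates
#' each ROI's response snippets (`[onset, onset + window_s)`) across the
#' three repetitions and averages over repetition pairs and amplitudes.
#' Pairs touching censored frames are skipped.
#'
#' @param traces A z-scored [trace_matrix].
#' @param train The auditory [stim_train].
#' @param min_amplitude_db Quietest amplitude included (default -21 dB).
#' @param window_s Snippet length after onset (s).
#' @return Tibble with `roi_id` and `consistency` (mean correlation).
#' @export
response_consistency <- function(traces, train, min_amplitude_db = -21,
                                 window_s = 5) {
  rate <- trace_rate(traces)
  w <- round(window_s * rate)
  sound <- dplyr::filter(train, .data$modality == "sound",
                         .data$block %in% c("ascending", "quasirandom", "descending"),
                         .data$amplitude_db >= min_amplitude_db)
  acc <- matrix(0, nrow(traces), 2)  # sum of correlations, count
  for (amp in unique(sound$amplitude_db)) {
    ev <- sound[sound$amplitude_db == amp, ]
    snips <- lapply(ev$onset_s, function(o) {
      f0 <- floor(o * rate)
      unclass(traces)[, (f0 + 1L):(f0 + w), drop = FALSE]
    })
    for (i in seq_along(snips)) for (j in seq_len(i - 1)) {
      r <- row_cor(snips[[i]], snips[[j]])
      ok <- !is.na(r)
      acc[ok, 1] <- acc[ok, 1] + r[ok]
      acc[ok, 2] <- acc[ok, 2] + 1
    }
  }
  tibble::tibble(roi_id = rownames(traces),
                 consistency = ifelse(acc[, 2] > 0, acc[, 1] / acc[, 2], NA_real_))
}

#' Region-level response summary
#'
#' Summarizes responsiveness per region and genotype: the fraction of ROIs
#' responsive to at least one regressor, and the mean coefficient and mean
#' r-squared of the responsive records. With `by_larva = TRUE` the same
#' summary is computed per larva; pooled values equal the ROI-count-weighted
#' average of the per-larva values.
#'
#' @param records Thresholded regression records (with `responsive`).
#' @param rois ROI tibble.
#' @param by_larva Summarize per larva instead of pooled.
#' @return Tibble keyed by region and genotype (and larva).
#' @export
region_summary <- function(records, rois, by_larva = FALSE) {
  roi_level <- dplyr::summarise(
    dplyr::group_by(records, .data$roi_id),
    responsive = any(.data$responsive),
    beta = ifelse(any(.data$responsive),
                  mean(.data$beta[.data$responsive]), NA_real_),
    r2 = ifelse(any(.data$responsive),
                mean(.data$r2[.data$responsive]), NA_real_),
    .groups = "drop"
  )
  d <- dplyr::inner_join(roi_level, rois, by = "roi_id")
  keys <- if (by_larva) c("region", "genotype", "larva_id") else c("region", "genotype")
  dplyr::summarise(
    dplyr::group_by(d, dplyr::across(dplyr::all_of(keys))),
    n_rois = dplyr::n(),
    responsive_fraction = mean(.data$responsive),
    mean_beta = mean(.data$beta[.data$responsive]),
    mean_r2 = mean(.data$r2[.data$responsive]),
    .groups = "drop"
  )
}
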