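#' Head-motion quantification
#'
#' A larva's per-frame Y-axis displacement (pixels) is smoothed with a
#' 5-point linear moving-average filter (to remove non-linearity from larvae
#' not returning to their original position) and motion is quantified as the
#' trapezoidal integral of the rectified filtered displacement, in
#' pixel-seconds.
#'
#' @name motion
NULL

#' Centered moving-average filter
#'
#' Mean over a centered window, with shrinking windows at the edges so the
#' output has the same length as the input. Never increases the maximum
#' absolute displacement.
#'
#' @param y_px Numeric displacement series (pixels).
#' @param window Window size in frames (default 5).
#' @return Filtered series of the same length.
#' @export
moving_average <- function(y_px, window = 5) {
  n <- length(y_px)
  if (n < window) stop("series shorter than the filter window", call. = FALSE)
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    mean(y_px[max(1, i - half):min(n, i + half)])
  }, 0)
}

#' Motion area over a time window
#'
#' Trapezoidal integral of the rectified (absolute) filtered displacement
#' over `[from_s, to_s)`, in pixel-seconds.
#'
#' @param filtered Filtered displacement series (pixels).
#' @param rate_hz Frames per second.
#' @param from_s,to_s Window bounds in seconds (defaults: the whole series).
#' @return Area in pixel-seconds (non-negative).
#' @export
motion_area <- function(filtered, rate_hz, from_s = 0,
                        to_s = length(filtered) / rate_hz) {
  n <- length(filtered)
  f0 <- max(0L, floor(from_s * rate_hz))
  f1 <- min(n - 1L, floor(to_s * rate_hz))  # frames f0..f1 inclusive
  if (f1 <= f0) return(0)
  idx <- seq.int(f0 + 1L, f1 + 1L)
  pracma::trapz((idx - 1L) / rate_hz, abs(filtered[idx]))
}

#' Baseline and stimulus-locked motion summary
#'
#' Total motion area over the whole train plus, for each discrete amplitude,
#' the area over `[onset, onset + window_s)` summed across its repetitions.
#'
#' @param motion Tibble with `frame` and `y_px` (see
#'   [generate_motion_trace()]) or a numeric displacement vector.
#' @param train The auditory [stim_train].
#' @param rate_hz Frames per second.
#' @param window_s Stimulus-locked window (s, default 2).
#' @param filter_window Moving-average window (frames).
#' @return List with `total_area_pxs` and `per_amplitude` tibble
#'   (`amplitude_db`, `area_pxs`, `n_events`).
#' @export
motion_summary <- function(motion, train, rate_hz, window_s = 2,
                           filter_window = 5) {
  y <- if (is.data.frame(motion)) motion$y_px else as.numeric(motion)
  filt <- moving_average(y, filter_window)
  total <- motion_area(filt, rate_hz)
  sound <- dplyr::filter(train, .data$modality == "sound",
                         .data$block %in% c("ascending", "quasirandom",
                                            "descending", "none"))
  per_amp <- dplyr::summarise(
    dplyr::group_by(sound, .data$amplitude_db),
    area_pxs = sum(vapply(.data$onset_s, function(o) {
      motion_area(filt, rate_hz, from_s = o, to_s = o + window_s)
    }, 0)),
    n_events = dplyr::n(),
    .groups = "drop"
  )
  list(total_area_pxs = total, per_amplitude = dplyr::arrange(per_amp, .data$amplitude_db))
}
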