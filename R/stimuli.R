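#' Stimulus trains and GCaMP regressors
#'
#' A stimulus train is a tibble with one row per stimulus event and columns
#' `modality` (`flow`, `loom`, `sound`, `ramp`), `onset_s`, `duration_s`,
#' `amplitude_db` (dB re full scale, non-positive; `NA` for visual stimuli),
#' `block` (`none`, `ascending`, `quasirandom`, `descending`, `ramp1`,
#' `ramp2`) and `repetition`. The tibble carries a `total_s` attribute giving
#' the recording length the train is designed for.
#'
#' @name stim_train
NULL

STIM_MODALITIES <- c("flow", "loom", "sound", "ramp")
STIM_BLOCKS <- c("none", "ascending", "quasirandom", "descending", "ramp1", "ramp2")

#' The twelve discrete sound amplitudes, in dB re full scale
#' @format Integer vector, 0 to -33 dB in 3-dB steps.
#' @export
DISCRETE_AMPLITUDES_DB <- seq(-33, 0, by = 3)

# printed quasi-random presentation order of the second block
QUASIRANDOM_ORDER_DB <- c(-21, -27, -12, -33, -9, -18, -6, -24, 0, -15, -30, -3)

new_stim_train <- function(events, total_s) {
  ev <- dplyr::arrange(tibble::as_tibble(events), .data$onset_s)
  stopifnot(all(ev$modality %in% STIM_MODALITIES),
            all(ev$block %in% STIM_BLOCKS),
            all(ev$duration_s > 0),
            all(is.na(ev$amplitude_db) | ev$amplitude_db <= 0))
  # events must not overlap
  if (nrow(ev) > 1) {
    offs <- ev$onset_s + ev$duration_s
    if (any(ev$onset_s[-1] < offs[-nrow(ev)] - 1e-9)) {
      stop("stimulus events overlap within the train", call. = FALSE)
    }
  }
  attr(ev, "total_s") <- total_s
  class(ev) <- c("stim_train", class(ev))
  ev
}

#' Total designed recording length of a train, in seconds
#' @param train A stimulus train.
#' @return Length in seconds.
#' @export
train_total_s <- function(train) {
  tot <- attr(train, "total_s")
  if (is.null(tot)) max(train$onset_s + train$duration_s) + 12 else tot
}

#' Number of frames a train occupies at a given volume rate
#' @param train A stimulus train.
#' @param rate_hz Volumes per second (2 or 4).
#' @return Integer frame count.
#' @export
n_frames_for <- function(train, rate_hz) as.integer(ceiling(train_total_s(train) * rate_hz))

#' Build the multisensory stimulus train
#'
#' Three presentations each of visual flow (28 s including pre/post luminance
#' ramps), visual loom (18 s including post-loom brightening) and a 1-s white
#' noise burst, in a seeded semi-random order in which consecutive events
#' never share a modality, separated by at least a 3-s inter-stimulus
#' interval and preceded by 40 s of rest.
#'
#' @param seed Integer seed controlling the event order.
#' @param rest_s Initial rest period (s).
#' @param isi_s Inter-stimulus interval between consecutive events (s).
#' @return A [stim_train] tibble of 9 events.
#' @export
build_multisensory_train <- function(seed = 1L, rest_s = 40, isi_s = 3) {
  stopifnot(isi_s >= 3)
  durations <- c(flow = 28, loom = 18, sound = 1)
  pool <- rep(names(durations), times = 3)
  set.seed(child_seed(seed, "multisensory"))
  order <- sample(pool)
  # semi-random: re-draw until no modality repeats back-to-back
  while (any(order[-1] == order[-length(order)])) order <- sample(pool)
  onset <- numeric(9)
  t <- rest_s
  for (i in seq_along(order)) {
    onset[i] <- t
    t <- t + durations[[order[i]]] + isi_s
  }
  rep_idx <- stats::ave(seq_along(order), order, FUN = seq_along)
  new_stim_train(tibble::tibble(
    modality = order,
    onset_s = onset,
    duration_s = unname(durations[order]),
    amplitude_db = ifelse(order == "sound", 0, NA_real_),
    block = "none",
    repetition = as.integer(rep_idx)
  ), total_s = t + 9)
}

#' Build the auditory-sensitivity stimulus train
#'
#' Two 30-s white-noise amplitude ramps (to 0 dB) bracket three blocks of
#' twelve discrete 1-s white-noise amplitudes spanning 0 to -33 dB re full
#' scale in 3-dB steps. Block 1 is ascending, block 2 follows the fixed
#' quasi-random order (-21, -27, -12, -33, -9, -18, -6, -24, 0, -15, -30,
#' -3 dB), block 3 is descending. The within-block inter-stimulus interval is
#' 14 s and blocks are separated by 30 s. The first ramp sits inside the
#' initial 90-s segment of the recording.
#'
#' @param ramp_lead_s Onset of the first ramp (s); the ramp must end within
#'   the first 90 s.
#' @param block_start_s Onset of the first discrete block (s).
#' @param isi_s Silent gap between discrete events within a block (s).
#' @param block_gap_s Gap between the end of one block and the start of the
#'   next, and before the final ramp (s).
#' @param lead_out_s Recording time after the final ramp (s).
#' @return A [stim_train] tibble of 36 discrete events plus 2 ramps.
#' @export
build_auditory_train <- function(ramp_lead_s = 30, block_start_s = 90,
                                 isi_s = 14, block_gap_s = 30, lead_out_s = 12) {
  stopifnot(ramp_lead_s + 30 <= 90, block_start_s >= 90)
  blocks <- list(
    ascending = DISCRETE_AMPLITUDES_DB,
    quasirandom = QUASIRANDOM_ORDER_DB,
    descending = rev(DISCRETE_AMPLITUDES_DB)
  )
  events <- list(tibble::tibble(
    modality = "ramp", onset_s = ramp_lead_s, duration_s = 30,
    amplitude_db = 0, block = "ramp1", repetition = 1L
  ))
  t <- block_start_s
  for (bi in seq_along(blocks)) {
    amps <- blocks[[bi]]
    onsets <- t + (seq_along(amps) - 1) * (1 + isi_s)
    events[[length(events) + 1L]] <- tibble::tibble(
      modality = "sound", onset_s = onsets, duration_s = 1,
      amplitude_db = amps, block = names(blocks)[bi], repetition = bi
    )
    t <- max(onsets) + 1 + block_gap_s
  }
  events[[length(events) + 1L]] <- tibble::tibble(
    modality = "ramp", onset_s = t, duration_s = 30,
    amplitude_db = 0, block = "ramp2", repetition = 2L
  )
  ev <- dplyr::bind_rows(events)
  new_stim_train(ev, total_s = t + 30 + lead_out_s)
}

#' Convert dB re full scale to linear amplitude
#'
#' `10^(dB/20)`: 0 dB maps to 1 (full scale) and every 6-dB step very nearly
#' doubles (or halves) the linear amplitude.
#'
#' @param amplitude_db Amplitude in dB re full scale (non-positive).
#' @return Dimensionless linear amplitude in (0, 1].
#' @export
db_to_linear <- function(amplitude_db) {
  stopifnot(all(amplitude_db <= 0))
  10^(amplitude_db / 20)
}

#' A GCaMP6 impulse-response kernel
#'
#' Linear rise to unit peak followed by exponential decay, sampled at the
#' imaging rate. The `fast` variant models a nuclear-targeted GCaMP6f
#' (rise 0.1 s, decay 1.5 s); the `slow` variant GCaMP6s (rise 0.2 s, decay
#' 3.5 s). Constants are configurable.
#'
#' @param variant `"fast"` or `"slow"`.
#' @param rate_hz Sampling rate (volumes per second).
#' @param rise_s,decay_s Optional overrides of the rise time and decay time
#'   constant (s).
#' @return Numeric vector, non-negative, single-peaked, unit peak; classed
#'   `gcamp_kernel` with `rate_hz`, `rise_s`, `decay_s` attributes.
#' @export
gcamp_kernel <- function(variant = c("fast", "slow"), rate_hz = 4,
                         rise_s = NULL, decay_s = NULL) {
  variant <- match.arg(variant)
  defaults <- list(fast = c(0.1, 1.5), slow = c(0.2, 3.5))[[variant]]
  rise_s <- rise_s %||% defaults[1]
  decay_s <- decay_s %||% defaults[2]
  stopifnot(rise_s >= 0, decay_s > 0, rate_hz > 0)
  t <- seq(0, rise_s + 8 * decay_s, by = 1 / rate_hz)
  k <- ifelse(t <= rise_s,
              if (rise_s > 0) t / rise_s else 1,
              exp(-(t - rise_s) / decay_s))
  k <- k / max(k)
  structure(k, class = "gcamp_kernel", rate_hz = rate_hz,
            rise_s = rise_s, decay_s = decay_s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact discrete convolution (no FFT ripple), truncated to length(x)
convolve_trunc <- function(x, k) {
  n <- length(x)
  m <- length(k)
  y <- stats::filter(c(numeric(m - 1), x), k, method = "convolution", sides = 1)
  as.numeric(y)[m:(m - 1 + n)]
}

#' Build stimulus regressors by kernel convolution
#'
#' Each regressor is the boxcar time course of a group of events convolved
#' with a GCaMP kernel and normalized to unit maximum. Ramp events use a
#' linearly increasing boxcar (linear amplitude 0 to 1). Grouping
#' `by_modality_repetition` yields one regressor per (modality, repetition)
#' pair (nine for the multisensory train); `by_amplitude` pools the three
#' repetitions of each discrete sound amplitude into a single regressor
#' (twelve for the auditory train), ignoring ramps.
#'
#' @param train A [stim_train].
#' @param grouping `"by_modality_repetition"` or `"by_amplitude"`.
#' @param kernel A [gcamp_kernel()].
#' @param rate_hz Volumes per second of the paired trace matrix.
#' @param n_frames Number of frames in the paired trace matrix; defaults to
#'   [n_frames_for()].
#' @return A `regressor_set`: list with `matrix` (regressors x frames),
#'   `labels`, `rate_hz`.
#' @export
make_regressors <- function(train,
                            grouping = c("by_modality_repetition", "by_amplitude"),
                            kernel = gcamp_kernel("fast", rate_hz = rate_hz),
                            rate_hz = 4,
                            n_frames = n_frames_for(train, rate_hz)) {
  grouping <- match.arg(grouping)
  ev <- train
  if (grouping == "by_amplitude") {
    ev <- dplyr::filter(ev, .data$modality == "sound",
                        .data$block %in% c("ascending", "quasirandom", "descending"))
    groups <- split(seq_len(nrow(ev)), format(ev$amplitude_db))
    groups <- groups[order(as.numeric(names(groups)))]
    labels <- names(groups)
  } else {
    key <- paste(ev$modality, ev$repetition, sep = "_")
    groups <- split(seq_len(nrow(ev)), key)
    # stable order: by first onset
    groups <- groups[order(vapply(groups, function(i) min(ev$onset_s[i]), 0))]
    labels <- names(groups)
  }
  if (any(ceiling((ev$onset_s + ev$duration_s) * rate_hz) > n_frames)) {
    stop("stimulus event extends beyond the end of the recording", call. = FALSE)
  }
  mat <- matrix(0, nrow = length(groups), ncol = n_frames)
  for (gi in seq_along(groups)) {
    box <- numeric(n_frames)
    for (i in groups[[gi]]) {
      f0 <- floor(ev$onset_s[i] * rate_hz)
      f1 <- floor((ev$onset_s[i] + ev$duration_s[i]) * rate_hz)
      idx <- seq.int(f0, f1 - 1L) + 1L  # half-open [f0, f1), 0-based frames
      w <- if (ev$modality[i] == "ramp") seq_along(idx) / length(idx) else 1
      box[idx] <- box[idx] + w
    }
    r <- convolve_trunc(box, as.numeric(kernel))
    mat[gi, ] <- r / max(r)
  }
  structure(list(matrix = mat, labels = labels, rate_hz = rate_hz),
            class = "regressor_set")
}
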