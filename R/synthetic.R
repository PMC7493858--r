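#' Synthetic cohort configuration
#'
#' Describes a synthetic light-sheet cohort: larvae per genotype, ROIs per
#' region, the functional cluster layout per region, the genotype sensitivity
#' shift, and noise levels. Each cluster spec row gives the `region`, the
#' `fraction` of that region's ROIs belonging to the cluster, a sensitivity
#' threshold `theta_db` (dB re full scale), a logistic `slope_db` (dB; 0
#' gives a hard threshold) and a response `gain` (peak fluorescence in
#' pre-z-score units). ROIs not claimed by any cluster are non-responsive.
#'
#' The homozygous-mutant (HOM) genotype hears every sound effectively
#' `genotype_shift_db` dB louder, the minimal mechanism for a pure
#' sensitivity shift; heterozygotes are generated unshifted.
#'
#' @param n_larvae_per_genotype Larvae per genotype.
#' @param rois_per_region ROIs per region per larva.
#' @param genotypes Subset of `c("WT", "HET", "HOM")`.
#' @param cluster_specs Tibble (`region`, `fraction`, `theta_db`, `slope_db`,
#'   `gain`); defaults to one auditory cluster per region with
#'   region-specific thresholds ([default_cluster_specs()]).
#' @param genotype_shift_db Sensitivity shift applied to HOM (dB, >= 0).
#' @param noise_sd Gaussian noise SD (pre-z-score units).
#' @param spont_rate_hz Poisson rate of spontaneous unit-amplitude calcium
#'   events per ROI.
#' @param rate_hz Imaging rate (volumes per second).
#' @param kernel_variant GCaMP kernel variant, `"fast"` or `"slow"`.
#' @param coord_sd Spatial SD of each region's ROI cloud (micrometres).
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_larvae_per_genotype = 3,
                         rois_per_region = 50,
                         genotypes = GENOTYPES,
                         cluster_specs = default_cluster_specs(),
                         genotype_shift_db = 6,
                         noise_sd = 0.25,
                         spont_rate_hz = 0.03,
                         rate_hz = 4,
                         kernel_variant = "fast",
                         coord_sd = 12,
                         seed = 1L) {
  stopifnot(genotype_shift_db >= 0, noise_sd > 0, spont_rate_hz >= 0,
            all(genotypes %in% GENOTYPES),
            all(cluster_specs$region %in% BRAIN_REGIONS),
            all(cluster_specs$fraction >= 0), all(cluster_specs$slope_db >= 0))
  frac_tot <- tapply(cluster_specs$fraction, cluster_specs$region, sum)
  if (any(frac_tot > 1 + 1e-9)) {
    stop("cluster fractions within a region must sum to at most 1", call. = FALSE)
  }
  structure(list(
    n_larvae_per_genotype = n_larvae_per_genotype,
    rois_per_region = rois_per_region,
    genotypes = genotypes,
    cluster_specs = tibble::as_tibble(cluster_specs),
    genotype_shift_db = genotype_shift_db,
    noise_sd = noise_sd,
    spont_rate_hz = spont_rate_hz,
    rate_hz = rate_hz,
    kernel_variant = kernel_variant,
    coord_sd = coord_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default per-region auditory cluster layout
#'
#' One auditory cluster per region covering 40% of its ROIs, with sensitivity
#' thresholds graded along the ascending auditory pathway: the
#' octavolateralis nucleus most sensitive, forebrain structures least.
#'
#' @return Tibble with columns `region`, `fraction`, `theta_db`, `slope_db`,
#'   `gain`.
#' @export
default_cluster_specs <- function() {
  tibble::tibble(
    region = BRAIN_REGIONS,
    fraction = 0.4,
    theta_db = c(ON = -24, Cb = -12, rHB = -15, Teg = -9, TS = -18,
                 TeO = -12, Pr = -9, Th = -15, Ha = -6, Tel = -6)[BRAIN_REGIONS],
    slope_db = 2,
    gain = 2
  )
}

# bilateral region centroid layout (micrometres; x lateral from midline,
# y rostro-caudal, z dorso-ventral) -- a plausible desk-scale geometry
region_centers <- function() {
  tibble::tibble(
    region = BRAIN_REGIONS,
    cx = c(60, 50, 70, 40, 55, 90, 45, 35, 20, 50),
    cy = c(150, 120, 180, 60, 70, 60, 30, 20, -10, -40),
    cz = c(-40, -10, -30, -30, -15, 0, -10, -25, 5, -5)
  )
}

logistic_peak <- function(amps_db, shift_db, theta_db, slope_db, gain) {
  a <- amps_db + shift_db
  if (slope_db <= 1e-9) gain * as.numeric(a >= theta_db)
  else gain * plogis((a - theta_db) / slope_db)
}

#' Generate a synthetic cohort with recorded ground truth
#'
#' Draws bilateral 3D ROI clouds per region, synthesizes amplitude-tuned
#' auditory responses (peak `gain * logistic((a + shift - theta)/slope)` per
#' discrete sound event, convolved with the GCaMP kernel), adds spontaneous
#' unit-amplitude calcium events at a Poisson rate and Gaussian noise, and
#' z-scores every trace. Amplitude ramps evoke no synthetic response. The
#' returned ground truth is sufficient to reconstruct every noiseless trace.
#'
#' @param cfg A [synth_config()].
#' @param train A [stim_train]; must contain discrete sound events when
#'   auditory clusters are requested.
#' @return A `larvanet_cohort` list: `rois` (tibble), `traces`
#'   ([trace_matrix]), `train`, `truth` (tibble with per-ROI cluster id,
#'   `theta_db`, `gain`, plus cohort-level attributes `genotype_shift_db`,
#'   `noise_sd`, `spont_rate_hz`, `seed`).
#' @export
generate_cohort <- function(cfg, train = build_auditory_train()) {
  stopifnot(inherits(cfg, "synth_config"))
  sound <- dplyr::filter(train, .data$modality == "sound",
                         .data$block %in% c("ascending", "quasirandom", "descending", "none"))
  if (nrow(sound) == 0 && nrow(cfg$cluster_specs) > 0 && any(cfg$cluster_specs$fraction > 0)) {
    stop("train has no sound events but auditory clusters were requested", call. = FALSE)
  }
  set.seed(child_seed(cfg$seed, "cohort"))
  rate <- cfg$rate_hz
  nf <- n_frames_for(train, rate)
  kern <- as.numeric(gcamp_kernel(cfg$kernel_variant, rate_hz = rate))
  onset_frames <- floor(sound$onset_s * rate)
  centers <- region_centers()

  # roster: cluster membership is assigned deterministically within a region
  roster <- tidyr::expand_grid(
    genotype = cfg$genotypes,
    larva = seq_len(cfg$n_larvae_per_genotype),
    region = BRAIN_REGIONS,
    idx = seq_len(cfg$rois_per_region)
  )
  specs <- dplyr::group_by(cfg$cluster_specs, .data$region)
  specs <- dplyr::mutate(specs, cluster = dplyr::row_number(),
                         hi = cumsum(.data$fraction),
                         lo = .data$hi - .data$fraction)
  specs <- dplyr::ungroup(specs)
  roster$frac_pos <- (roster$idx - 0.5) / cfg$rois_per_region
  roster <- dplyr::left_join(roster, specs,
                             by = dplyr::join_by("region",
                                                 "frac_pos" >= "lo",
                                                 "frac_pos" < "hi"))
  roster$cluster[is.na(roster$cluster)] <- 0L
  n <- nrow(roster)
  roster$larva_id <- paste0(roster$genotype, "_L", roster$larva)
  roster$roi_id <- sprintf("%s_%s_%03d", roster$larva_id, roster$region, roster$idx)

  # bilateral coordinate clouds
  ctr <- centers[match(roster$region, centers$region), ]
  side <- sample(c(-1, 1), n, replace = TRUE)
  roster$x <- side * ctr$cx + rnorm(n, 0, cfg$coord_sd)
  roster$y <- ctr$cy + rnorm(n, 0, cfg$coord_sd)
  roster$z <- ctr$cz + rnorm(n, 0, cfg$coord_sd)

  # evoked signal is shared within (genotype, region, cluster)
  traces <- matrix(0, nrow = n, ncol = nf)
  grp_key <- paste(roster$genotype, roster$region, roster$cluster)
  for (key in unique(grp_key)) {
    rows <- which(grp_key == key)
    cl <- roster$cluster[rows[1]]
    if (cl == 0L || nrow(sound) == 0) next
    shift <- if (roster$genotype[rows[1]] == "HOM") cfg$genotype_shift_db else 0
    peaks <- logistic_peak(sound$amplitude_db, shift,
                           roster$theta_db[rows[1]], roster$slope_db[rows[1]],
                           roster$gain[rows[1]])
    impulse <- numeric(nf)
    impulse[onset_frames + 1L] <- impulse[onset_frames + 1L] + peaks
    sig <- convolve_trunc(impulse, kern)
    traces[rows, ] <- matrix(sig, nrow = length(rows), ncol = nf, byrow = TRUE)
  }

  # spontaneous events and noise
  lambda_total <- cfg$spont_rate_hz * nf / rate
  n_ev <- rpois(n, lambda_total)
  lk <- length(kern)
  for (i in which(n_ev > 0)) {
    at <- sample.int(nf, n_ev[i], replace = TRUE)
    for (f in at) {
      span <- f:min(nf, f + lk - 1L)
      traces[i, span] <- traces[i, span] + kern[seq_along(span)]
    }
  }
  traces <- traces + matrix(rnorm(n * nf, 0, cfg$noise_sd), n, nf)
  rownames(traces) <- roster$roi_id

  rois <- tibble::tibble(
    roi_id = roster$roi_id, larva_id = roster$larva_id,
    genotype = roster$genotype, region = roster$region,
    x = roster$x, y = roster$y, z = roster$z
  )
  truth <- tibble::tibble(
    roi_id = roster$roi_id, cluster = roster$cluster,
    theta_db = ifelse(roster$cluster > 0, roster$theta_db, NA_real_),
    gain = ifelse(roster$cluster > 0, roster$gain, NA_real_)
  )
  attr(truth, "genotype_shift_db") <- cfg$genotype_shift_db
  attr(truth, "noise_sd") <- cfg$noise_sd
  attr(truth, "spont_rate_hz") <- cfg$spont_rate_hz
  attr(truth, "seed") <- cfg$seed

  structure(list(
    rois = rois,
    traces = zscore_traces(trace_matrix(traces, rate_hz = rate)),
    train = train,
    truth = truth,
    config = cfg
  ), class = "larvanet_cohort")
}

#' @export
print.larvanet_cohort <- function(x, ...) {
  cat("<larvanet_cohort> ", nrow(x$rois), " ROIs, ",
      ncol(x$traces), " frames at ", attr(x$traces, "rate_hz"), " Hz, ",
      length(unique(x$rois$larva_id)), " larvae\n", sep = "")
  invisible(x)
}

#' Generate a synthetic per-frame head-displacement trace
#'
#' Baseline Gaussian jitter plus optional rectangular startle transients
#' time-locked to discrete sound events, with a startle probability that
#' grows with amplitude.
#'
#' @param cfg A [synth_config()] (supplies rate and seed).
#' @param train A [stim_train].
#' @param jitter_sd Baseline jitter SD (pixels).
#' @param startle_amp_px Displacement amplitude of a startle (pixels).
#' @param startle_width_s Startle duration (s).
#' @param startle_prob Function mapping amplitude (dB) to startle
#'   probability; the default rises steeply above about -9 dB.
#' @return Tibble with `frame` (0-based), `t_s`, `y_px`.
#' @export
generate_motion_trace <- function(cfg, train,
                                  jitter_sd = 0.1,
                                  startle_amp_px = 5,
                                  startle_width_s = 1,
                                  startle_prob = function(db) plogis((db + 9) / 3)) {
  set.seed(child_seed(cfg$seed, "motion"))
  rate <- cfg$rate_hz
  nf <- n_frames_for(train, rate)
  y <- rnorm(nf, 0, jitter_sd)
  sound <- dplyr::filter(train, .data$modality == "sound")
  for (i in seq_len(nrow(sound))) {
    if (runif(1) < startle_prob(sound$amplitude_db[i])) {
      f0 <- floor(sound$onset_s[i] * rate)
      f1 <- min(nf, f0 + round(startle_width_s * rate))
      y[(f0 + 1L):f1] <- y[(f0 + 1L):f1] + startle_amp_px
    }
  }
  tibble::tibble(frame = seq_len(nf) - 1L, t_s = (seq_len(nf) - 1L) / rate, y_px = y)
}
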