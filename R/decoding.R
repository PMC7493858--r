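#' Population decoding of sound amplitude
#'
#' Patterns of auditory-responsive activity are used to decode the discrete
#' sound amplitude (dB re full scale) with gradient-boosted regression trees.
#' Following the three-block protocol, models are trained on the ascending
#' block, tuned (early stopping) on the quasi-random block, and validated on
#' the descending block; r-squared is computed between predicted and actual
#' amplitudes on the validation block only.
#'
#' @name decoding
NULL

#' Per-event feature blocks for decoding
#'
#' For every discrete sound event, the feature vector is each ROI's mean
#' z-scored activity over `[onset, onset + window_s)`; the target is the
#' event's amplitude in dB. Events are grouped by presentation block. Events
#' whose window touches censored frames for all ROIs are dropped.
#'
#' @param traces Z-scored [trace_matrix] of the region's auditory ROIs.
#' @param train The auditory [stim_train].
#' @param window_s Feature window (s, default 5).
#' @return A `decode_features`: list with `features` (events x ROIs matrix),
#'   `targets` (dB), `block` (character), `roi_ids`.
#' @export
make_feature_blocks <- function(traces, train, window_s = 5) {
  rate <- trace_rate(traces)
  nf <- ncol(traces)
  w <- round(window_s * rate)
  sound <- dplyr::filter(train, .data$modality == "sound",
                         .data$block %in% c("ascending", "quasirandom", "descending"))
  f0 <- floor(sound$onset_s * rate)
  if (any(f0 + w > nf)) {
    stop("feature window extends beyond the end of the recording", call. = FALSE)
  }
  feats <- t(vapply(seq_along(f0), function(i) {
    rowMeans(unclass(traces)[, (f0[i] + 1L):(f0[i] + w), drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(traces))))
  keep <- rowSums(is.finite(feats)) > 0
  if (any(!keep)) message(sum(!keep), " fully censored event(s) dropped")
  structure(list(features = feats[keep, , drop = FALSE],
                 targets = sound$amplitude_db[keep],
                 block = sound$block[keep],
                 roi_ids = rownames(traces)),
            class = "decode_features")
}

# r-squared between predictions and truth (1 - SS_res/SS_tot; at most 1,
# negative when predictions are worse than the mean)
r_squared <- function(pred, truth) {
  1 - sum((pred - truth)^2) / sum((truth - mean(truth))^2)
}

#' Decode amplitude from one region's population
#'
#' The region's ROIs are randomly divided into `n_subsets` subsets. For each
#' subset, a gradient-boosted tree regressor is fitted on the ascending-block
#' rows of that subset's features, early-stopped against the quasi-random
#' block, and scored by r-squared on the descending block. Descending rows
#' are never used for fitting or tuning.
#'
#' @param feats A [make_feature_blocks()] object.
#' @param n_subsets Number of ROI subsets (default 10; reduced with a message
#'   when there are fewer ROIs than subsets).
#' @param seed Integer seed (subset partition and model fit).
#' @param nrounds,max_depth,eta,early_stopping_rounds Boosting
#'   hyperparameters (defaults: 200 rounds, depth 3, learning rate 0.1,
#'   stop after 20 stagnant rounds).
#' @return A `decode_result`: list with `subset_r2` (one value per subset),
#'   `mean_r2`, `n_subsets`, `seed`, `params`.
#' @export
decode_region <- function(feats, n_subsets = 10, seed = 1L,
                          nrounds = 200, max_depth = 3, eta = 0.1,
                          early_stopping_rounds = 20) {
  stopifnot(inherits(feats, "decode_features"))
  blocks <- c("ascending", "quasirandom", "descending")
  if (!all(blocks %in% feats$block)) {
    stop("all three presentation blocks are required", call. = FALSE)
  }
  n_rois <- ncol(feats$features)
  if (n_rois < n_subsets) {
    message("only ", n_rois, " ROIs; reducing subsets from ", n_subsets)
    n_subsets <- max(1L, n_rois)
  }
  set.seed(child_seed(seed, "decode"))
  part <- sample(rep(seq_len(n_subsets), length.out = n_rois))
  is_tr <- feats$block == "ascending"
  is_tu <- feats$block == "quasirandom"
  is_va <- feats$block == "descending"
  r2 <- vapply(seq_len(n_subsets), function(s) {
    cols <- which(part == s)
    X <- feats$features[, cols, drop = FALSE]
    dtrain <- xgboost::xgb.DMatrix(X[is_tr, , drop = FALSE],
                                   label = feats$targets[is_tr])
    dtune <- xgboost::xgb.DMatrix(X[is_tu, , drop = FALSE],
                                  label = feats$targets[is_tu])
    fit <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror", max_depth = max_depth,
                    eta = eta, nthread = 1, seed = child_seed(seed, paste0("xgb", s))),
      data = dtrain, nrounds = nrounds,
      evals = list(tune = dtune),
      early_stopping_rounds = early_stopping_rounds, verbose = 0
    )
    pred <- stats::predict(fit, xgboost::xgb.DMatrix(X[is_va, , drop = FALSE]))
    r_squared(pred, feats$targets[is_va])
  }, 0)
  structure(list(subset_r2 = r2, mean_r2 = mean(r2), n_subsets = n_subsets,
                 seed = seed,
                 params = list(nrounds = nrounds, max_depth = max_depth,
                               eta = eta,
                               early_stopping_rounds = early_stopping_rounds)),
            class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat("<decode_result> mean r2 ", format(x$mean_r2, digits = 4), " over ",
      x$n_subsets, " subsets\n", sep = "")
  invisible(x)
}

#' Decode every region of a cohort, per genotype
#'
#' @param cohort A `larvanet_cohort`.
#' @param aud ROI tibble of the auditory-responsive set (with `region`,
#'   `genotype`).
#' @param window_s Feature window (s).
#' @param min_rois Minimum auditory ROIs for a region to be decoded.
#' @param n_subsets,seed See [decode_region()].
#' @return Tibble with `region`, `genotype`, `subset`, `r2`.
#' @export
decode_cohort <- function(cohort, aud, window_s = 5, min_rois = 10,
                          n_subsets = 10, seed = 1L) {
  groups <- split(aud, paste(aud$region, aud$genotype, sep = "."))
  rows <- lapply(sort(names(groups)), function(key) {
    g <- groups[[key]]
    if (nrow(g) < min_rois) {
      message("skipping decode for ", key, ": only ", nrow(g), " auditory ROIs")
      return(NULL)
    }
    feats <- make_feature_blocks(cohort$traces[g$roi_id, ], cohort$train,
                                 window_s = window_s)
    res <- decode_region(feats, n_subsets = n_subsets,
                         seed = child_seed(seed, key))
    tibble::tibble(region = g$region[1], genotype = g$genotype[1],
                   subset = seq_along(res$subset_r2), r2 = res$subset_r2)
  })
  dplyr::bind_rows(rows)
}

#' Per-region decoding comparison between genotypes
#'
#' Mean validation r-squared difference per region (alternative minus
#' reference genotype), with the per-subset values carried along for
#' downstream testing. Regions are ordered along the ascending auditory
#' pathway.
#'
#' @param decode_tbl Output of [decode_cohort()].
#' @param ref_genotype,alt_genotype Genotypes compared.
#' @return Tibble with `region`, `mean_r2_ref`, `mean_r2_alt`, `difference`,
#'   and list-columns of the per-subset values.
#' @export
compare_decoding <- function(decode_tbl, ref_genotype = "WT", alt_genotype = "HOM") {
  pathway <- c("ON", "rHB", "Cb", "TS", "Teg", "TeO", "Pr", "Th", "Ha", "Tel")
  d <- dplyr::filter(decode_tbl, .data$genotype %in% c(ref_genotype, alt_genotype))
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$region),
    mean_r2_ref = mean(.data$r2[.data$genotype == ref_genotype]),
    mean_r2_alt = mean(.data$r2[.data$genotype == alt_genotype]),
    subset_r2_ref = list(.data$r2[.data$genotype == ref_genotype]),
    subset_r2_alt = list(.data$r2[.data$genotype == alt_genotype]),
    .groups = "drop"
  )
  out$difference <- out$mean_r2_alt - out$mean_r2_ref
  out[order(match(out$region, pathway)), ]
}
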