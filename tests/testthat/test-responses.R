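test_that("fit_regression recovers known coefficients and univariate r2", {
  set.seed(42)
  n_frames <- 400
  r1 <- convolve_trunc(as.numeric(rep(c(1, 0), each = 10))[sample(20, n_frames, TRUE)],
                       as.numeric(gcamp_kernel("fast", rate_hz = 4)))
  r2v <- as.numeric(stats::filter(rnorm(n_frames), rep(1 / 5, 5), sides = 2))
  r2v[is.na(r2v)] <- 0
  regs <- structure(list(matrix = rbind(r1 / max(r1), r2v / max(abs(r2v))),
                         labels = c("a", "b"), rate_hz = 4),
                    class = "regressor_set")
  true_beta <- rbind(c(2, -1), c(0.5, 3))
  y <- true_beta %*% regs$matrix + 0.7   # noiseless, arbitrary intercept
  rownames(y) <- c("roiA", "roiB")
  rec <- fit_regression(trace_matrix(y, rate_hz = 4), regs)
  expect_equal(nrow(rec), 4)
  got <- matrix(rec$beta, nrow = 2)  # regressors x rois
  expect_equal(t(got), true_beta, tolerance = 1e-8, ignore_attr = TRUE)
  # per-regressor r2 equals the squared Pearson correlation of the univariate fit
  manual <- cor(y["roiA", ], regs$matrix[1, ])^2
  expect_equal(rec$r2[rec$roi_id == "roiA" & rec$regressor == "a"], manual)
})

test_that("fit_regression rejects collinear regressors and frame mismatches", {
  r <- matrix(rnorm(200), nrow = 2)
  r[2, ] <- r[1, ] * 2 + 1e-12
  regs <- structure(list(matrix = r, labels = c("a", "b"), rate_hz = 4),
                    class = "regressor_set")
  y <- matrix(rnorm(100), 1, 100, dimnames = list("r1"))
  expect_error(fit_regression(trace_matrix(y, 4), regs), "collinear")
  regs$matrix <- matrix(rnorm(120), nrow = 2)
  expect_error(fit_regression(trace_matrix(y, 4), regs), "frame counts differ")
})

test_that("censored frames are dropped pairwise in the regression", {
  set.seed(7)
  reg <- abs(rnorm(300))
  regs <- structure(list(matrix = matrix(reg, 1), labels = "a", rate_hz = 4),
                    class = "regressor_set")
  y <- matrix(3 * reg + 1, 2, 300, byrow = TRUE,
              dimnames = list(c("r1", "r2")))
  y[2, 1:40] <- NA       # censored ROI still fits on the remaining frames
  rec <- fit_regression(trace_matrix(y, 4), regs)
  expect_equal(rec$beta, c(3, 3), tolerance = 1e-8)
  expect_equal(rec$r2, c(1, 1), tolerance = 1e-8)
})

test_that("multisensory threshold is WT mean + 2 SD with strict inequalities", {
  ref <- tibble::tibble(roi_id = paste0("w", 1:5), regressor = "s",
                        beta = c(1, 2, 3, 4, 5), r2 = 0.5)
  cutoff <- mean(ref$beta) + 2 * sd(ref$beta)
  rec <- tibble::tibble(
    roi_id = c("a", "b", "c", "d"), regressor = "s",
    beta = c(cutoff + 0.01, cutoff, cutoff + 10, cutoff + 10),
    r2 = c(0.5, 0.5, 0.1, 0.100001))
  out <- threshold_multisensory(rec, ref)
  expect_equal(out$responsive, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(out, "cutoffs")$cutoff, cutoff)
})

test_that("auditory candidate threshold uses strict beta > 0 and r2 > 0.05", {
  rec <- tibble::tibble(roi_id = letters[1:4], regressor = "-12",
                        beta = c(0.5, 0, 0.5, -0.5),
                        r2 = c(0.05, 0.5, 0.0500001, 0.5))
  out <- threshold_auditory(rec)
  expect_equal(out$responsive, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("startle censoring blanks the flanking frames of one larva only", {
  y <- matrix(rnorm(3 * 800), 3, 800,
              dimnames = list(c("a1", "a2", "b1")))
  tr <- trace_matrix(y, rate_hz = 4)
  larva <- c("A", "A", "B")
  cens <- tibble::tibble(larva_id = "A", onset_s = 100)
  out <- exclude_startle_frames(tr, larva, cens, flank_frames = 50)
  f <- floor(100 * 4)
  blanked <- seq.int(f - 50, f + 50 - 1) + 1L   # half-open [f-50, f+50)
  expect_true(all(is.na(unclass(out)[1:2, blanked])))
  expect_true(all(!is.na(unclass(out)[1:2, -blanked])))
  expect_true(all(!is.na(unclass(out)[3, ])))
  # clipping near the recording edge warns via message
  expect_message(
    exclude_startle_frames(tr, larva, tibble::tibble(larva_id = "B", onset_s = 1)),
    "clipped")
  expect_error(
    exclude_startle_frames(tr, larva, tibble::tibble(larva_id = "Z", onset_s = 10)),
    "unknown larva")
})

test_that("detect_events finds planted peaks and enforces separation", {
  rate <- 4
  x <- rnorm(1200, 0, 0.005)
  at <- c(100, 300, 500, 900)       # 1-based frames, well separated
  kern <- as.numeric(gcamp_kernel("fast", rate_hz = rate))
  for (f in at) {
    span <- f:min(1200, f + length(kern) - 1)
    x[span] <- x[span] + 3 * kern[seq_along(span)]
  }
  ev <- detect_events(x, rate)
  expect_equal(ev$n_events, 4)
  expect_true(all(abs(outer(ev$frames + 1L, at, `-`)) |> apply(2, min) <= 2))
  expect_equal(ev$rate_per_min, 4 / (1200 / rate / 60))
  # two peaks 1 s apart merge under a 2-s separation rule
  y <- rnorm(400, 0, 0.01)
  y[100] <- 5; y[104] <- 4
  expect_equal(detect_events(y, rate, min_sep_s = 2)$n_events, 1)
  expect_equal(detect_events(y, rate, min_sep_s = 0.5)$n_events, 2)
})

test_that("correlation_vs_distance pairs within larvae with exact geometry", {
  y <- matrix(rnorm(4 * 200), 4, 200, dimnames = list(paste0("r", 1:4)))
  y[2, ] <- y[1, ] * 2 + 3          # perfectly correlated pair
  rois <- tibble::tibble(roi_id = paste0("r", 1:4),
                         larva_id = c("A", "A", "A", "B"),
                         genotype = "WT", region = "TeO",
                         x = c(0, 3, 0, 0), y = c(0, 4, 0, 0), z = 0)
  p <- correlation_vs_distance(trace_matrix(y, 4), rois)
  expect_equal(nrow(p), 3)          # C(3,2) within A; larva B alone contributes none
  pair12 <- p[p$roi_a == "r1" & p$roi_b == "r2", ]
  expect_equal(pair12$distance_um, 5)
  expect_equal(pair12$correlation, 1)
  binned <- bin_correlation_distance(p)
  expect_equal(sum(binned$n_pairs), 3)
})

test_that("response consistency is 1 for perfectly repeating responses", {
  train <- build_auditory_train()
  rate <- 4
  nf <- n_frames_for(train, rate)
  sound <- train[train$modality == "sound" & train$block != "none", ]
  x <- rnorm(nf, 0, 0.01)
  snippet <- sin(seq(0, 3, length.out = 20))
  for (o in sound$onset_s) {
    f0 <- floor(o * rate)
    x[(f0 + 1):(f0 + 20)] <- snippet
  }
  tr <- trace_matrix(matrix(x, 1, nf, dimnames = list("r1")), rate)
  cons <- response_consistency(tr, train)
  expect_equal(cons$consistency, 1, tolerance = 1e-12)
  # AAFT-shuffled windows lose that consistency
  wins <- event_windows(train, rate, window_s = 5, modalities = "sound")
  shuf <- aaft_shuffle(unclass(tr), wins, seed = 2)
  cons2 <- response_consistency(trace_matrix(shuf, rate), train)
  expect_lt(abs(cons2$consistency), 0.5)
})

test_that("region_summary pools consistently with per-larva summaries", {
  co <- shared_cohort()
  rec <- shared_records()
  pooled <- region_summary(rec, co$rois)
  by_larva <- region_summary(rec, co$rois, by_larva = TRUE)
  expect_setequal(pooled$region, unique(co$rois$region))
  joined <- dplyr::summarise(
    dplyr::group_by(by_larva, .data$region, .data$genotype),
    frac = sum(.data$responsive_fraction * .data$n_rois) / sum(.data$n_rois),
    .groups = "drop")
  m <- dplyr::inner_join(pooled, joined, by = c("region", "genotype"))
  expect_equal(m$responsive_fraction, m$frac, tolerance = 1e-12)
})
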