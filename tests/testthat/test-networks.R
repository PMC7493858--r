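test_that("build_nodes enforces the retention rule and pools member traces", {
  nodes <- shared_nodes()
  expect_s3_class(nodes, "node_set")
  expect_true(all(nodes$nodes$n_members >= 10))
  expect_true(all(nodes$nodes$n_larvae >= 3))
  expect_equal(nrow(nodes$traces), nrow(nodes$nodes))
  # node trace is the mean of its member ROI traces
  co <- shared_cohort()
  id <- nodes$nodes$node_id[1]
  expect_equal(nodes$traces[id, ],
               colMeans(unclass(co$traces)[nodes$members[[id]], , drop = FALSE]),
               tolerance = 1e-12, ignore_attr = TRUE)
  # members are disjoint within a genotype
  for (gt in c("WT", "HOM")) {
    mem <- unlist(nodes$members[nodes$nodes$node_id[nodes$nodes$genotype == gt]])
    expect_false(anyDuplicated(mem) > 0)
  }
})

test_that("matched nodes give identical spatial clusters across genotypes", {
  co <- shared_cohort()
  aud <- auditory_rois(shared_clustering())
  ar <- co$rois[co$rois$roi_id %in% aud$roi_id, ]
  nodes <- suppressMessages(build_nodes(ar, co$traces, variant = "matched", seed = 5))
  by_gt <- split(nodes$nodes, nodes$nodes$genotype)
  key <- function(d) sort(paste(d$region, d$spatial_cluster))
  expect_equal(key(by_gt$WT), key(by_gt$HOM))
  expect_true(all(nodes$nodes$n_members >= 10 & nodes$nodes$n_larvae >= 3))
})

test_that("a group that cannot satisfy the retention rule yields no nodes", {
  rois <- tibble::tibble(roi_id = paste0("r", 1:8),
                         larva_id = rep(c("A", "B"), 4),
                         genotype = "WT", region = "TeO",
                         x = rnorm(8), y = rnorm(8), z = rnorm(8))
  tr <- trace_matrix(matrix(rnorm(8 * 50), 8, 50,
                            dimnames = list(rois$roi_id)), 4)
  # only 2 larvae: min_larvae = 3 can never hold
  expect_message(expect_error(build_nodes(rois, tr), "no region produced"),
                 "retention rule")
})

test_that("amplitude windows are half-open, 0-based, and disjoint", {
  train <- build_auditory_train()
  wins <- amplitude_windows(train, 4, window_s = 5)
  expect_equal(length(wins), 12)
  expect_equal(as.numeric(names(wins)), seq(-33, 0, 3))
  expect_true(all(vapply(wins, length, 0L) == 3 * 20))
  expect_false(anyDuplicated(unlist(wins)) > 0)
  sound <- train[train$modality == "sound" & train$block != "none", ]
  on0 <- floor(min(sound$onset_s[sound$amplitude_db == -33]) * 4)
  expect_true(on0 %in% wins[["-33"]])
  expect_false((on0 - 1L) %in% wins[["-33"]])
  # censored frames are removed; oversized windows overlap and error
  wins2 <- amplitude_windows(train, 4, censor_frames = wins[["-33"]][1:5])
  expect_equal(length(wins2[["-33"]]), 55)
  expect_error(amplitude_windows(train, 4, window_s = 20), "overlap")
})

test_that("graph_at_amplitude binarizes strictly above tau", {
  set.seed(2)
  base <- rnorm(60)
  tr <- rbind(a = base + rnorm(60, 0, 0.01),   # cor(a, b) ~ 1
              b = base + rnorm(60, 0, 0.01),
              c = rnorm(60))
  ns <- list(traces = tr,
             nodes = tibble::tibble(node_id = c("a", "b", "c"),
                                    region = c("TeO", "TS", "TS"),
                                    genotype = "WT"))
  g <- graph_at_amplitude(ns, frames = 0:59, tau = 0.85, amplitude_db = -6)
  expect_true(g$adj["a", "b"] && g$adj["b", "a"])
  expect_false(any(g$adj["c", ]))
  expect_false(any(diag(g$adj)))
  expect_equal(g$amplitude_db, -6)
  # strict threshold: identical series correlate at exactly 1 > tau = 1 is FALSE
  ns$traces <- rbind(a = base, b = base, c = rnorm(60))
  g1 <- graph_at_amplitude(ns, 0:59, tau = 1)
  expect_false(any(g1$adj))
  expect_error(graph_at_amplitude(ns, 0:5), "frames")
  ns$traces[3, ] <- 2
  expect_message(graph_at_amplitude(ns, 0:59), "constant")
})

test_that("network density matches the 2E/(N(N-1)) definition", {
  A <- matrix(FALSE, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- TRUE
  expect_equal(network_density(A), 2 * 2 / (4 * 3))
  expect_equal(network_density(matrix(FALSE, 3, 3)), 0)
  full <- !diag(3)
  expect_equal(network_density(full), 1)
  expect_error(network_density(matrix(FALSE, 1, 1)), "fewer than 2")
})

test_that("participation coefficient matches its formula on a hand graph", {
  # node 1 in region X with edges to one X node and one Y node:
  # P = 1 - (1/2)^2 - (1/2)^2 = 0.5
  A <- matrix(FALSE, 4, 4)
  A[1, 2] <- A[2, 1] <- TRUE  # X-X
  A[1, 3] <- A[3, 1] <- TRUE  # X-Y
  g <- structure(list(adj = A, nodes = tibble::tibble(
    node_id = paste0("n", 1:4), region = c("X", "X", "Y", "Y"))),
    class = "corr_graph")
  p <- participation_coef(g)
  expect_equal(p$participation, c(0.5, 0, 0, 0))
  expect_equal(p$degree, c(2, 1, 1, 0))
  # all edges within one region: P = 0 everywhere; bound 1 - 1/M respected
  expect_true(all(p$participation <= 1 - 1 / 2 + 1e-12))
  rp <- region_participation(g)
  expect_equal(rp$mean_participation[rp$region == "X"], 0.25)
})

test_that("inter-region edges count each unordered cross-region pair once", {
  A <- matrix(FALSE, 4, 4)
  A[1, 3] <- A[3, 1] <- TRUE
  A[2, 3] <- A[3, 2] <- TRUE
  A[1, 2] <- A[2, 1] <- TRUE  # within-region edge, not counted
  g <- structure(list(adj = A, nodes = tibble::tibble(
    node_id = paste0("n", 1:4), region = c("TeO", "TeO", "TS", "Th"))),
    class = "corr_graph")
  e <- inter_region_edges(g)
  expect_equal(sum(e$n_edges), 2)
  expect_equal(e$n_edges[e$region_a == "TS" & e$region_b == "TeO"], 2)
  g$adj[] <- FALSE
  expect_equal(nrow(inter_region_edges(g)), 0)
})

test_that("edge_onset_amplitude scans quiet-to-loud and signs the shift", {
  mk <- function(db, cross) {
    A <- matrix(FALSE, 2, 2)
    if (cross) A[1, 2] <- A[2, 1] <- TRUE
    structure(list(adj = A, amplitude_db = db,
                   nodes = tibble::tibble(node_id = c("a", "b"),
                                          region = c("TeO", "TS"))),
              class = "corr_graph")
  }
  graphs <- list(
    WT = lapply(seq(-33, 0, 3), function(a) mk(a, a >= -12)),
    HOM = lapply(seq(-33, 0, 3), function(a) mk(a, a >= -18)))
  res <- edge_onset_amplitude(graphs)
  expect_equal(res$onsets$onset_db[res$onsets$genotype == "WT"], -12)
  expect_equal(res$onsets$onset_db[res$onsets$genotype == "HOM"], -18)
  expect_equal(res$shift_db, 6)  # positive: HOM engages at quieter sounds
  # no qualifying amplitude yields NA
  res2 <- edge_onset_amplitude(list(WT = lapply(seq(-33, 0, 3), mk, cross = FALSE),
                                    HOM = graphs$HOM))
  expect_true(is.na(res2$onsets$onset_db[res2$onsets$genotype == "WT"]))
  expect_true(is.na(res2$shift_db))
})

test_that("phase randomization preserves the amplitude spectrum exactly", {
  set.seed(11)
  x <- rnorm(128)
  y <- larvanet:::phase_randomize(x)
  expect_equal(Mod(fft(y)), Mod(fft(x)), tolerance = 1e-9)
  expect_equal(mean(y), mean(x), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(x, y)))
})

test_that("AAFT surrogates keep the exact value distribution", {
  set.seed(12)
  x <- rexp(100)  # strongly non-Gaussian
  s <- aaft_surrogate(x)
  expect_identical(sort(s), sort(x))
  expect_false(identical(s, x))
})

test_that("aaft_shuffle acts only inside windows and is seeded", {
  set.seed(13)
  tr <- matrix(rnorm(2 * 200), 2, 200)
  wins <- list(10:29, 50:69)
  out <- aaft_shuffle(tr, wins, seed = 3)
  inside <- c(10:29, 50:69) + 1L
  expect_identical(out[, -inside], tr[, -inside])
  for (w in wins) {
    for (i in 1:2) expect_equal(sort(out[i, w + 1L]), sort(tr[i, w + 1L]))
  }
  expect_identical(out, aaft_shuffle(tr, wins, seed = 3))
  expect_false(identical(out, aaft_shuffle(tr, wins, seed = 4)))
  expect_error(aaft_shuffle(tr, list(1:5)))  # window shorter than 8 frames
  tr[1, 11:30] <- 5
  expect_message(aaft_shuffle(tr, wins, seed = 3), "constant")
})
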