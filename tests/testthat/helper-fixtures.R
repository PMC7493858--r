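# Shared fixtures, built in code. The desk-scale cohort used across tests is
# memoized so expensive stages run once per suite.

.fixture_env <- new.env(parent = emptyenv())

# a reduced two-genotype cohort: 4 regions spanning the sensitivity range
small_specs <- function() {
  s <- default_cluster_specs()
  s[s$region %in% c("ON", "TS", "Th", "TeO"), ]
}

small_cfg <- function(shift_db = 6, seed = 11, ...) {
  synth_config(n_larvae_per_genotype = 3, rois_per_region = 24,
               genotypes = c("WT", "HOM"), cluster_specs = small_specs(),
               genotype_shift_db = shift_db, seed = seed, ...)
}

shared_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_cfg())
  }
  .fixture_env$cohort
}

shared_regs <- function() {
  co <- shared_cohort()
  if (is.null(.fixture_env$regs)) {
    .fixture_env$regs <- make_regressors(co$train, "by_amplitude",
                                         rate_hz = 4, n_frames = ncol(co$traces))
  }
  .fixture_env$regs
}

shared_records <- function() {
  if (is.null(.fixture_env$records)) {
    .fixture_env$records <- threshold_auditory(
      fit_regression(shared_cohort()$traces, shared_regs()))
  }
  .fixture_env$records
}

shared_clustering <- function() {
  if (is.null(.fixture_env$clustering)) {
    .fixture_env$clustering <- suppressMessages(
      cluster_cohort(shared_cohort(), shared_records(), shared_regs(), seed = 5))
  }
  .fixture_env$clustering
}

# graphs across all 12 amplitudes per genotype for the shared cohort
shared_graphs <- function() {
  if (is.null(.fixture_env$graphs)) {
    co <- shared_cohort()
    aud <- auditory_rois(shared_clustering())
    ar <- co$rois[co$rois$roi_id %in% aud$roi_id, ]
    nodes <- build_nodes(ar, co$traces, seed = 5)
    wins <- amplitude_windows(co$train, 4)
    graphs <- lapply(unique(nodes$nodes$genotype), function(gt) {
      ns <- subset_nodes(nodes, gt)
      lapply(names(wins), function(a) {
        graph_at_amplitude(ns, wins[[a]], amplitude_db = as.numeric(a))
      })
    })
    names(graphs) <- unique(nodes$nodes$genotype)
    .fixture_env$graphs <- graphs
    .fixture_env$nodes <- nodes
  }
  .fixture_env$graphs
}

shared_nodes <- function() {
  shared_graphs()
  .fixture_env$nodes
}

# run the detect -> cluster -> network chain on a fresh cohort and return the
# edge-onset shift estimate (used by recovery and exchangeability tests)
onset_shift_for <- function(shift_db, seed, min_edges = 1) {
  co <- generate_cohort(small_cfg(shift_db = shift_db, seed = seed))
  regs <- make_regressors(co$train, "by_amplitude", rate_hz = 4,
                          n_frames = ncol(co$traces))
  rec <- threshold_auditory(fit_regression(co$traces, regs))
  cl <- suppressMessages(cluster_cohort(co, rec, regs, seed = seed))
  aud <- auditory_rois(cl)
  ar <- co$rois[co$rois$roi_id %in% aud$roi_id, ]
  nodes <- suppressMessages(build_nodes(ar, co$traces, seed = seed))
  wins <- amplitude_windows(co$train, 4)
  graphs <- lapply(unique(nodes$nodes$genotype), function(gt) {
    ns <- subset_nodes(nodes, gt)
    lapply(names(wins), function(a) {
      suppressMessages(
        graph_at_amplitude(ns, wins[[a]], amplitude_db = as.numeric(a)))
    })
  })
  names(graphs) <- unique(nodes$nodes$genotype)
  list(result = edge_onset_amplitude(graphs, min_edges = min_edges),
       cohort = co, records = rec, clustering = cl, graphs = graphs)
}

# memoized sweep of full-chain runs on null (shift 0) cohorts; the recovery
# and specificity tests share these
null_chain_runs <- function(seeds) {
  if (is.null(.fixture_env$null_runs)) .fixture_env$null_runs <- list()
  for (s in as.character(seeds)) {
    if (is.null(.fixture_env$null_runs[[s]])) {
      .fixture_env$null_runs[[s]] <- onset_shift_for(0, as.integer(s))
    }
  }
  .fixture_env$null_runs[as.character(seeds)]
}

# minimal sound-only stimulus train for unit tests
new_stim_train_for_test <- function(onset, duration, amplitude_db = 0,
                                    repetition = seq_along(onset),
                                    total_s = max(onset + duration) + 60) {
  larvanet:::new_stim_train(tibble::tibble(
    modality = "sound", onset_s = onset, duration_s = duration,
    amplitude_db = amplitude_db, block = "none",
    repetition = as.integer(repetition)), total_s = total_s)
}

# a noiseless monotone-tuned population covering all amplitudes, as traces
noiseless_population <- function(n_rois = 30, rate_hz = 4, slope_db = 2,
                                 train = build_auditory_train(), seed = 3) {
  set.seed(seed)
  nf <- n_frames_for(train, rate_hz)
  kern <- as.numeric(gcamp_kernel("fast", rate_hz = rate_hz))
  sound <- train[train$modality == "sound" &
                   train$block %in% c("ascending", "quasirandom", "descending"), ]
  onset_frames <- floor(sound$onset_s * rate_hz)
  thetas <- seq(-33, 0, length.out = n_rois)
  tr <- t(vapply(thetas, function(th) {
    peaks <- 2 * plogis((sound$amplitude_db - th) / slope_db)
    impulse <- numeric(nf)
    impulse[onset_frames + 1L] <- peaks
    sig <- stats::convolve(c(impulse, numeric(length(kern))), rev(kern),
                           type = "open")[seq_len(nf)]
    sig + rnorm(nf, 0, 1e-6)  # break constancy for z-scoring
  }, numeric(nf)))
  rownames(tr) <- sprintf("roi%02d", seq_len(n_rois))
  zscore_traces(trace_matrix(tr, rate_hz = rate_hz))
}
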