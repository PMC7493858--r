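#' Validate an ROI table
#'
#' Checks the closed 10-label region vocabulary, the genotype labels, finite
#' coordinates and unique ROI ids.
#'
#' @param rois Tibble with `roi_id`, `larva_id`, `genotype`, `region`, `x`,
#'   `y`, `z`.
#' @return The validated tibble (invisibly usable in pipes).
#' @export
validate_rois <- function(rois) {
  rois <- tibble::as_tibble(rois)
  needed <- c("roi_id", "larva_id", "genotype", "region", "x", "y", "z")
  missing <- setdiff(needed, names(rois))
  if (length(missing)) {
    stop("ROI table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_region <- setdiff(unique(rois$region), BRAIN_REGIONS)
  if (length(bad_region)) {
    stop("unknown brain region label(s): ", paste(bad_region, collapse = ", "),
         call. = FALSE)
  }
  bad_gt <- setdiff(unique(rois$genotype), GENOTYPES)
  if (length(bad_gt)) {
    stop("unknown genotype label(s): ", paste(bad_gt, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rois$roi_id)) stop("duplicate roi_id", call. = FALSE)
  if (!all(is.finite(rois$x) & is.finite(rois$y) & is.finite(rois$z))) {
    stop("non-finite ROI coordinates", call. = FALSE)
  }
  rois
}

#' Write a cohort to delimited text files
#'
#' Writes `rois.csv`, `traces.csv` (first column `roi_id`, then one column
#' per frame), `train.csv`, `meta.csv` (`rate_hz`, `total_s`) and, when
#' ground truth is present, `truth.csv` into `dir`.
#'
#' @param cohort A `larvanet_cohort` (or a list with `rois`, `traces`,
#'   `train`).
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(rois = file.path(dir, "rois.csv"),
             traces = file.path(dir, "traces.csv"),
             train = file.path(dir, "train.csv"),
             meta = file.path(dir, "meta.csv"))
  readr::write_csv(cohort$rois, paths["rois"])
  tr <- tibble::as_tibble(as.data.frame(unclass(cohort$traces)),
                          .name_repair = ~ paste0("f", seq_along(.x) - 1L))
  tr <- dplyr::bind_cols(tibble::tibble(roi_id = rownames(cohort$traces)), tr)
  readr::write_csv(tr, paths["traces"])
  readr::write_csv(tibble::as_tibble(cohort$train), paths["train"])
  readr::write_csv(tibble::tibble(rate_hz = trace_rate(cohort$traces),
                                  total_s = train_total_s(cohort$train)),
                   paths["meta"])
  if (!is.null(cohort$truth)) {
    paths["truth"] <- file.path(dir, "truth.csv")
    readr::write_csv(cohort$truth, paths["truth"])
  }
  paths
}

#' Read and validate a cohort from delimited text files
#'
#' Reads the ROI table, trace matrix and stimulus train, checks that the ROI
#' ids of the table and the trace matrix agree as sets, aligns the trace rows
#' to the table order, validates label vocabularies, and rejects constant
#' traces by ROI id.
#'
#' @param roi_table_path,trace_path,train_path File paths.
#' @param rate_hz Volume rate; if `NULL`, read from `meta.csv` next to
#'   `trace_path`.
#' @return A `larvanet_cohort` list (`rois`, `traces`, `train`).
#' @export
read_cohort <- function(roi_table_path, trace_path, train_path, rate_hz = NULL) {
  rois <- validate_rois(readr::read_csv(roi_table_path, show_col_types = FALSE))
  tr <- readr::read_csv(trace_path, show_col_types = FALSE)
  if (is.null(rate_hz)) {
    meta_path <- file.path(dirname(trace_path), "meta.csv")
    if (!file.exists(meta_path)) {
      stop("rate_hz not given and no meta.csv beside the trace file", call. = FALSE)
    }
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    rate_hz <- meta$rate_hz[1]
  }
  ids <- tr$roi_id
  if (!setequal(ids, rois$roi_id)) {
    stop("ROI ids of the table and the trace matrix do not agree as sets",
         call. = FALSE)
  }
  vals <- as.matrix(tr[, -1])
  rownames(vals) <- ids
  vals <- vals[rois$roi_id, , drop = FALSE]
  sds <- apply(vals, 1, sd, na.rm = TRUE)
  if (any(sds == 0, na.rm = TRUE)) {
    stop("degenerate (constant) trace for ROI: ",
         paste(head(rois$roi_id[which(sds == 0)], 5), collapse = ", "),
         call. = FALSE)
  }
  ev <- readr::read_csv(train_path, show_col_types = FALSE)
  train <- new_stim_train(ev, total_s = ncol(vals) / rate_hz)
  structure(list(rois = rois,
                 traces = trace_matrix(vals, rate_hz = rate_hz),
                 train = train),
            class = "larvanet_cohort")
}

#' Pipeline configuration
#'
#' Collects every tunable threshold of the pipeline with its default:
#' correlation threshold for graph edges (`corr_threshold` 0.85), Rentian box
#' count (`n_boxes` 5000), decoding subsets (`n_decode_subsets` 10),
#' multisensory and auditory r-squared minima (`ms_r2_min` 0.1, `aud_r2_min`
#' 0.05), startle flank (`flank_frames` 50), clusters per region
#' (`k_clusters` 5), member pruning (`member_corr_min` 0.2), the shared
#' response window (`window_s` 5 s), node retention (`node_min_rois` 10,
#' `node_min_larvae` 3), the inter-region edge-onset criterion (`min_edges`
#' 1) and the RNG seed recorded in every output.
#'
#' @param corr_threshold,n_boxes,n_decode_subsets,ms_r2_min,aud_r2_min
#'   See description.
#' @param flank_frames,k_clusters,member_corr_min,window_s See description.
#' @param node_min_rois,node_min_larvae,min_edges See description.
#' @param max_pairs_per_larva Cap on ROIs per larva in the baseline
#'   correlation-distance stage.
#' @param rng_seed Integer seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(corr_threshold = 0.85, n_boxes = 5000,
                            n_decode_subsets = 10, ms_r2_min = 0.1,
                            aud_r2_min = 0.05, flank_frames = 50,
                            k_clusters = 5, member_corr_min = 0.2,
                            window_s = 5, node_min_rois = 10,
                            node_min_larvae = 3, min_edges = 1,
                            max_pairs_per_larva = 200, rng_seed = 1L) {
  stopifnot(corr_threshold >= 0, corr_threshold <= 1,
            ms_r2_min >= 0, ms_r2_min <= 1, aud_r2_min >= 0, aud_r2_min <= 1,
            member_corr_min >= -1, member_corr_min <= 1,
            n_boxes > 0, k_clusters >= 1, flank_frames >= 0)
  structure(list(corr_threshold = corr_threshold, n_boxes = n_boxes,
                 n_decode_subsets = n_decode_subsets, ms_r2_min = ms_r2_min,
                 aud_r2_min = aud_r2_min, flank_frames = flank_frames,
                 k_clusters = k_clusters, member_corr_min = member_corr_min,
                 window_s = window_s, node_min_rois = node_min_rois,
                 node_min_larvae = node_min_larvae, min_edges = min_edges,
                 max_pairs_per_larva = max_pairs_per_larva,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

PIPELINE_STAGES <- c("detect", "baseline", "cluster", "network", "rent",
                     "decode", "motion", "report")
STAGE_DEPS <- list(detect = character(), baseline = character(),
                   cluster = "detect", network = "cluster", rent = "network",
                   decode = "cluster", motion = character(), report = character())

#' Run the full analysis pipeline on a cohort
#'
#' Chains the stages: `detect` (per-amplitude regression and auditory
#' thresholding), `baseline` (event rates and correlation versus distance),
#' `cluster` (functional clustering and the auditory-responsive set),
#' `network` (nodes, per-amplitude graphs, densities with AAFT surrogate
#' nulls, participation, inter-region edges, edge-onset shift), `rent`
#' (Rentian scaling per genotype and amplitude), `decode` (per-region
#' amplitude decoding), `motion` (displacement summary) and `report`
#' (parameter record). Every stage writes a delimited table into `out_dir`
#' and logs its parameters; outputs are deterministic given the cohort and
#' `config$rng_seed`. On failure all files written by this run are removed.
#'
#' @param cohort A `larvanet_cohort` (e.g. from [generate_cohort()] or
#'   [read_cohort()]).
#' @param config A [pipeline_config()].
#' @param out_dir Report directory.
#' @param stages Which stages to run (default all, in order). A stage whose
#'   prerequisite is not included raises an ordered-dependency error.
#' @param motion_trace Optional displacement tibble for the `motion` stage
#'   (generated synthetically when absent and the cohort carries a config).
#' @param censor Optional startle censor table (`larva_id`, `onset_s`)
#'   applied before analysis.
#' @return Invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir,
                         stages = PIPELINE_STAGES, motion_trace = NULL,
                         censor = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  for (s in stages) {
    miss <- setdiff(STAGE_DEPS[[s]], stages)
    if (length(miss)) {
      stop("stage '", s, "' requires stage(s) ", paste(miss, collapse = ", "),
           " to run first", call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  logf <- file.path(out_dir, "pipeline_log.txt")
  log_line <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  emit <- function(tbl, name) {
    p <- file.path(out_dir, name)
    readr::write_csv(tbl, p)
    written <<- c(written, p)
    log_line("wrote ", name, " (", nrow(tbl), " rows)")
  }
  cat("", file = logf)
  written <- c(written, logf)
  seed <- config$rng_seed
  state <- list()

  run_all <- function() {
    rate <- trace_rate(cohort$traces)
    traces <- cohort$traces
    if (!is.null(censor) && nrow(censor)) {
      larva_of <- cohort$rois$larva_id[match(rownames(traces), cohort$rois$roi_id)]
      traces <- exclude_startle_frames(traces, larva_of, censor,
                                       flank_frames = config$flank_frames)
      log_line("censored ", nrow(censor), " startle event(s), flank ",
               config$flank_frames, " frames")
    }
    kern <- gcamp_kernel(if (rate >= 3) "fast" else "slow", rate_hz = rate)
    regs <- make_regressors(cohort$train, "by_amplitude", kernel = kern,
                            rate_hz = rate, n_frames = ncol(traces))

    if ("detect" %in% stages) {
      log_line("stage detect: aud_r2_min = ", config$aud_r2_min)
      rec <- threshold_auditory(fit_regression(traces, regs),
                                r2_min = config$aud_r2_min)
      state$records <<- rec
      emit(rec, "responses.csv")
      emit(region_summary(rec, cohort$rois), "region_summary.csv")
      emit(region_summary(rec, cohort$rois, by_larva = TRUE),
           "region_summary_by_larva.csv")
    }
    if ("baseline" %in% stages) {
      log_line("stage baseline")
      emit(event_rates(traces), "event_rates.csv")
      pairs <- correlation_vs_distance(traces, cohort$rois,
                                       max_rois_per_larva = config$max_pairs_per_larva)
      emit(bin_correlation_distance(pairs), "correlation_distance.csv")
      emit(response_consistency(traces, cohort$train), "consistency.csv")
    }
    if ("cluster" %in% stages) {
      log_line("stage cluster: k = ", config$k_clusters,
               ", member_corr_min = ", config$member_corr_min)
      cl <- cluster_cohort(cohort, state$records, regs, k = config$k_clusters,
                           aud_r2_min = config$aud_r2_min,
                           member_corr_min = config$member_corr_min,
                           seed = child_seed(seed, "cluster"))
      state$clustering <<- cl
      emit(cl$assignments, "clusters.csv")
      tun <- purrr::imap(cl$models, function(m, key) {
        t <- amplitude_tuning(m, state$records)
        t$group <- key
        t
      })
      emit(dplyr::bind_rows(tun), "tuning.csv")
    }
    if ("network" %in% stages) {
      log_line("stage network: tau = ", config$corr_threshold,
               ", window_s = ", config$window_s)
      aud <- auditory_rois(state$clustering)
      aud_rois <- cohort$rois[cohort$rois$roi_id %in% aud$roi_id, ]
      nodes <- build_nodes(aud_rois, traces, variant = "per_genotype",
                           seed = child_seed(seed, "nodes"),
                           min_rois = config$node_min_rois,
                           min_larvae = config$node_min_larvae)
      state$nodes <<- nodes
      emit(nodes$nodes, "nodes.csv")
      wins <- amplitude_windows(cohort$train, rate, window_s = config$window_s)
      ev_wins <- event_windows(cohort$train, rate, window_s = config$window_s,
                               modalities = "sound")
      genotypes <- unique(nodes$nodes$genotype)
      metrics <- list(); part <- list(); edges <- list()
      graphs <- list()
      for (gt in genotypes) {
        ns <- subset_nodes(nodes, gt)
        if (nrow(ns$nodes) < 2) next
        null_tr <- suppressMessages(
          aaft_shuffle(ns$traces, ev_wins, seed = child_seed(seed, paste0("aaft", gt))))
        null_ns <- ns
        null_ns$traces <- null_tr
        graphs[[gt]] <- lapply(names(wins), function(a) {
          graph_at_amplitude(ns, wins[[a]], tau = config$corr_threshold,
                             amplitude_db = as.numeric(a))
        })
        for (gi in seq_along(graphs[[gt]])) {
          g <- graphs[[gt]][[gi]]
          gnull <- graph_at_amplitude(null_ns, wins[[gi]],
                                      tau = config$corr_threshold,
                                      amplitude_db = g$amplitude_db)
          metrics[[paste(gt, gi)]] <- tibble::tibble(
            genotype = gt, amplitude_db = g$amplitude_db,
            density = network_density(g), null_density = network_density(gnull),
            n_inter_region_edges = sum(inter_region_edges(g)$n_edges))
          p <- region_participation(g)
          p$genotype <- gt; p$amplitude_db <- g$amplitude_db
          part[[paste(gt, gi)]] <- p
          e <- inter_region_edges(g)
          if (nrow(e)) {
            e$genotype <- gt; e$amplitude_db <- g$amplitude_db
            edges[[paste(gt, gi)]] <- e
          }
        }
      }
      state$graphs <<- graphs
      emit(dplyr::bind_rows(metrics), "network_metrics.csv")
      emit(dplyr::bind_rows(part), "participation.csv")
      emit(dplyr::bind_rows(edges), "inter_region_edges.csv")
      onset <- edge_onset_amplitude(graphs, min_edges = config$min_edges)
      state$edge_onset <<- onset
      emit(dplyr::mutate(onset$onsets, shift_db = onset$shift_db,
                         min_edges = onset$min_edges), "edge_onset.csv")
    }
    if ("rent" %in% stages) {
      log_line("stage rent: n_boxes = ", config$n_boxes)
      rent <- list()
      for (gt in names(state$graphs)) {
        for (g in state$graphs[[gt]]) {
          fit <- tryCatch(
            rent_scaling(g, n_boxes = config$n_boxes,
                         seed = child_seed(seed, paste("rent", gt, g$amplitude_db))),
            error = function(e) NULL)
          if (is.null(fit)) next
          rent[[paste(gt, g$amplitude_db)]] <- tibble::tibble(
            genotype = gt, amplitude_db = g$amplitude_db,
            exponent = fit$exponent, exponent_sd = fit$exponent_sd,
            n_valid = fit$n_valid, seed = seed)
        }
      }
      state$rent <<- dplyr::bind_rows(rent)
      emit(state$rent, "rent.csv")
    }
    if ("decode" %in% stages) {
      log_line("stage decode: n_subsets = ", config$n_decode_subsets)
      aud <- auditory_rois(state$clustering)
      aud_rois <- cohort$rois[cohort$rois$roi_id %in% aud$roi_id, ]
      dec <- suppressMessages(
        decode_cohort(cohort, aud_rois, window_s = config$window_s,
                      min_rois = config$node_min_rois,
                      n_subsets = config$n_decode_subsets,
                      seed = child_seed(seed, "decode")))
      state$decode <<- dec
      emit(dec, "decode.csv")
      if (all(c("WT", "HOM") %in% dec$genotype)) {
        cmp <- compare_decoding(dec)
        emit(cmp[, c("region", "mean_r2_ref", "mean_r2_alt", "difference")],
             "decode_summary.csv")
      }
    }
    if ("motion" %in% stages) {
      log_line("stage motion")
      mt <- motion_trace
      if (is.null(mt) && !is.null(cohort$config)) {
        mt <- generate_motion_trace(cohort$config, cohort$train)
      }
      if (!is.null(mt)) {
        ms <- motion_summary(mt, cohort$train, rate)
        out <- ms$per_amplitude
        out$total_area_pxs <- ms$total_area_pxs
        emit(out, "motion_summary.csv")
        state$motion <<- ms
      } else {
        log_line("no motion trace available; stage skipped")
      }
    }
    if ("report" %in% stages) {
      cfg_tbl <- tibble::tibble(parameter = names(unclass(config)),
                                value = vapply(unclass(config), format, ""))
      emit(cfg_tbl, "config.csv")
    }
  }

  ok <- FALSE
  tryCatch({
    run_all()
    ok <- TRUE
  }, finally = {
    if (!ok) unlink(written)
  })
  invisible(state)
}
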