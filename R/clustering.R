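#' City-block k-means on time series
#'
#' Lloyd-style k-means under the L1 (city-block) metric: assignment to the
#' nearest centroid in L1 distance and component-wise median centroids, which
#' minimize within-cluster L1 cost. Runs `n_restarts` seeded restarts and
#' keeps the solution with the lowest total cost. Empty clusters are reseeded
#' at the point farthest from its centroid.
#'
#' @param x Numeric matrix (observations x variables).
#' @param k Number of clusters.
#' @param n_restarts Random restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param seed Integer seed.
#' @return List with `centroids` (k x variables), `cluster` (assignments),
#'   `cost` (total within-cluster L1 distance).
#' @export
kmedians <- function(x, k, n_restarts = 10, max_iter = 100, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= k, k >= 1)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cent <- x[sample.int(n, k), , drop = FALSE]
    asg_old <- integer(n)
    d <- NULL
    for (it in seq_len(max_iter)) {
      d <- l1_dist_to(x, cent)
      asg <- max.col(-d, ties.method = "first")
      if (identical(asg, asg_old)) break
      asg_old <- asg
      for (j in seq_len(k)) {
        rows <- which(asg == j)
        if (length(rows)) {
          cent[j, ] <- col_medians(x[rows, , drop = FALSE])
        } else {
          cent[j, ] <- x[which.max(d[cbind(seq_len(n), asg)]), ]
        }
      }
    }
    cost <- sum(d[cbind(seq_len(n), asg)])
    if (is.null(best) || cost < best$cost) {
      best <- list(centroids = cent, cluster = asg, cost = cost)
    }
  }
  best
}

l1_dist_to <- function(x, cent) {
  xt <- t(x)
  vapply(seq_len(nrow(cent)),
         function(j) colSums(abs(xt - cent[j, ])),
         numeric(nrow(x)))
}

# column medians via a single radix sort within columns
col_medians <- function(m) {
  k <- nrow(m)
  if (k == 1L) return(m[1, ])
  s <- matrix(m[order(col(m), m)], nrow = k)
  if (k %% 2L) s[(k + 1L) %/% 2L, ] else (s[k %/% 2L, ] + s[k %/% 2L + 1L, ]) / 2
}

#' Functional clustering of candidate ROIs in one region
#'
#' Applies city-block k-means to the (pooled across larvae) z-scored time
#' series of one region's candidate ROIs of one genotype. Censored frames are
#' imputed at the z-score mean (0) for the distance computation only.
#'
#' @param traces A z-scored [trace_matrix] restricted to the candidates.
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param n_restarts Random restarts.
#' @return A `cluster_model`: list with `centroids`, `assignments` tibble
#'   (`roi_id`, `cluster`, `retained`), `cost`, `k`.
#' @export
cluster_region <- function(traces, k = 5, seed = 1L, n_restarts = 10) {
  if (nrow(traces) < k) {
    stop("fewer candidate ROIs (", nrow(traces), ") than clusters (", k, ")",
         call. = FALSE)
  }
  x <- unclass(traces)
  x[is.na(x)] <- 0
  km <- kmedians(x, k, n_restarts = n_restarts, seed = seed)
  structure(list(
    centroids = km$centroids,
    assignments = tibble::tibble(roi_id = rownames(traces),
                                 cluster = km$cluster,
                                 retained = TRUE),
    cost = km$cost,
    k = k,
    rate_hz = trace_rate(traces)
  ), class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> k = ", x$k, ", ", nrow(x$assignments), " ROIs, L1 cost ",
      format(x$cost, digits = 5), "\n", sep = "")
  invisible(x)
}

# squared correlation of each centroid against each regressor
centroid_r2 <- function(model, regs) {
  cor(t(model$centroids), t(regs$matrix))^2
}

#' Flag auditory clusters
#'
#' A cluster is auditory when its centroid's best univariate r-squared
#' against any auditory regressor strictly exceeds `aud_r2_min`; all other
#' clusters are excluded from downstream auditory analyses.
#'
#' @param model A [cluster_region()] model.
#' @param regs Auditory regressor set (e.g. the twelve per-amplitude
#'   regressors).
#' @param aud_r2_min Minimum centroid r-squared (default 0.05).
#' @return The model with `auditory` (logical per cluster) and
#'   `centroid_best_r2` fields.
#' @export
flag_auditory <- function(model, regs, aud_r2_min = 0.05) {
  r2 <- centroid_r2(model, regs)
  best <- apply(r2, 1, max)
  model$centroid_best_r2 <- best
  model$auditory <- best > aud_r2_min
  model
}

#' Prune weakly-correlated cluster members
#'
#' k-means forces every ROI into a cluster; members whose Pearson correlation
#' with their cluster centroid does not strictly exceed `member_corr_min` are
#' dropped as noise. Clusters losing all members are dropped with a message.
#'
#' @param model A `cluster_model`.
#' @param traces The [trace_matrix] the model was fitted on.
#' @param member_corr_min Minimum member-to-centroid correlation (default 0.2).
#' @return The model with updated `retained` flags.
#' @export
prune_members <- function(model, traces, member_corr_min = 0.2) {
  x <- unclass(traces)[model$assignments$roi_id, , drop = FALSE]
  x[is.na(x)] <- 0
  r <- row_cor(x, model$centroids[model$assignments$cluster, , drop = FALSE])
  model$assignments$retained <- !is.na(r) & r > member_corr_min
  empty <- setdiff(seq_len(model$k),
                   unique(model$assignments$cluster[model$assignments$retained]))
  if (length(empty)) {
    message("cluster(s) ", paste(empty, collapse = ", "),
            " lost all members during pruning")
  }
  model$member_cor <- r
  model
}

#' Larva representation of each cluster
#'
#' Fraction of larvae contributing at least one retained member to each
#' cluster. Reported clusters are expected to be represented by at least 80%
#' of the larvae, guarding against single-animal artifacts.
#'
#' @param model A pruned `cluster_model`.
#' @param rois ROI tibble (maps `roi_id` to `larva_id`).
#' @param n_larvae Total larvae in the pooled group; defaults to the number
#'   of distinct larvae among the model's ROIs.
#' @return Tibble with `cluster` and `representation`.
#' @export
larva_representation <- function(model, rois, n_larvae = NULL) {
  a <- dplyr::inner_join(model$assignments, rois[, c("roi_id", "larva_id")],
                         by = "roi_id")
  n_larvae <- n_larvae %||% length(unique(a$larva_id))
  rep_tbl <- dplyr::summarise(
    dplyr::group_by(a[a$retained, ], .data$cluster),
    representation = length(unique(.data$larva_id)) / n_larvae,
    .groups = "drop"
  )
  dplyr::left_join(tibble::tibble(cluster = seq_len(model$k)), rep_tbl,
                   by = "cluster") |>
    dplyr::mutate(representation = dplyr::coalesce(.data$representation, 0))
}

#' Per-cluster amplitude tuning curves
#'
#' Mean per-amplitude regression coefficient over the retained members of
#' each cluster. Amplitudes with no usable coefficient yield `NA`, never 0.
#'
#' @param model A pruned `cluster_model`.
#' @param records Per-amplitude regression records (from [fit_regression()]
#'   with `by_amplitude` regressors).
#' @return Tibble with `cluster`, `amplitude_db`, `mean_beta`, `n_members`.
#' @export
amplitude_tuning <- function(model, records) {
  a <- model$assignments[model$assignments$retained, ]
  d <- dplyr::inner_join(records, a, by = "roi_id")
  d$amplitude_db <- as.numeric(d$regressor)
  out <- dplyr::summarise(
    dplyr::group_by(d, .data$cluster, .data$amplitude_db),
    mean_beta = if (all(is.na(.data$beta))) NA_real_ else mean(.data$beta, na.rm = TRUE),
    n_members = sum(!is.na(.data$beta)),
    .groups = "drop"
  )
  dplyr::arrange(out, .data$cluster, .data$amplitude_db)
}

#' Match clusters across two models by centroid correlation
#'
#' Greedy one-to-one matching of cluster centroids between two fits (e.g. WT
#' versus mutant refits of one region), highest correlation first. Pairs
#' below `min_cor` are left unmatched, the explicit analogue of reporting a
#' genotype-exclusive cluster when response traces differ strikingly.
#'
#' @param model_a,model_b Two `cluster_model`s on the same frame grid.
#' @param min_cor Minimum centroid correlation to accept a match.
#' @return Tibble with `cluster_a`, `cluster_b`, `correlation`, `matched`.
#' @export
match_clusters <- function(model_a, model_b, min_cor = 0.5) {
  cm <- cor(t(model_a$centroids), t(model_b$centroids))
  out <- tibble::tibble(cluster_a = integer(), cluster_b = integer(),
                        correlation = numeric())
  work <- cm
  repeat {
    if (all(is.na(work))) break
    ij <- which(work == max(work, na.rm = TRUE), arr.ind = TRUE)[1, ]
    out <- dplyr::bind_rows(out, tibble::tibble(
      cluster_a = as.integer(ij[[1]]), cluster_b = as.integer(ij[[2]]),
      correlation = work[ij[[1]], ij[[2]]]))
    work[ij[1], ] <- NA
    work[, ij[2]] <- NA
  }
  dplyr::mutate(out, matched = .data$correlation >= min_cor)
}

#' Cluster an entire cohort and derive the auditory-responsive set
#'
#' For each region and genotype: takes the candidate ROIs (at least one
#' responsive record under the auditory threshold), fits city-block k-means,
#' flags auditory clusters by centroid r-squared, prunes weak members, and
#' computes larva representation. Regions with fewer candidates than `k` are
#' skipped with a message. The final auditory-responsive set is the retained
#' members of auditory-flagged clusters.
#'
#' @param cohort A `larvanet_cohort`.
#' @param records Thresholded auditory regression records.
#' @param regs The per-amplitude regressor set.
#' @param k Clusters per region and genotype (default 5).
#' @param aud_r2_min,member_corr_min Thresholds, see [flag_auditory()] and
#'   [prune_members()].
#' @param seed Integer seed.
#' @return List with `assignments` (tibble: `roi_id`, `region`, `genotype`,
#'   `cluster`, `auditory`, `retained`, `representation`) and `models`
#'   (named list of `cluster_model`s).
#' @export
cluster_cohort <- function(cohort, records, regs, k = 5,
                           aud_r2_min = 0.05, member_corr_min = 0.2, seed = 1L) {
  cand_ids <- unique(records$roi_id[records$responsive])
  cand <- cohort$rois[cohort$rois$roi_id %in% cand_ids, ]
  models <- list()
  rows <- list()
  groups <- split(cand, paste(cand$region, cand$genotype, sep = "."))
  for (key in sort(names(groups))) {
    g <- groups[[key]]
    if (nrow(g) < k) {
      message("skipping ", key, ": only ", nrow(g), " candidates for k = ", k)
      next
    }
    tr <- cohort$traces[g$roi_id, ]
    m <- cluster_region(tr, k = k, seed = child_seed(seed, key))
    m <- flag_auditory(m, regs, aud_r2_min = aud_r2_min)
    m <- suppressMessages(prune_members(m, tr, member_corr_min = member_corr_min))
    rep_tbl <- larva_representation(m, g)
    models[[key]] <- m
    a <- dplyr::left_join(m$assignments, rep_tbl, by = "cluster")
    a$region <- g$region[1]
    a$genotype <- g$genotype[1]
    a$auditory <- m$auditory[a$cluster]
    rows[[key]] <- a
  }
  assignments <- dplyr::bind_rows(rows)
  if (!nrow(assignments)) {
    assignments <- tibble::tibble(roi_id = character(), cluster = integer(),
                                  retained = logical(),
                                  representation = numeric(),
                                  region = character(), genotype = character(),
                                  auditory = logical())
  }
  list(assignments = assignments, models = models)
}

#' The final auditory-responsive ROI set
#'
#' Retained members of auditory-flagged clusters: the intersection of the
#' auditory candidate threshold, the auditory cluster flag, and member
#' pruning.
#'
#' @param clustering Output of [cluster_cohort()].
#' @param min_representation Optionally also require the cluster's larva
#'   representation to reach this fraction (use 0.8 for reported clusters;
#'   default 0 keeps all).
#' @return Tibble of the selected assignment rows.
#' @export
auditory_rois <- function(clustering, min_representation = 0) {
  dplyr::filter(clustering$assignments,
                .data$auditory, .data$retained,
                .data$representation >= min_representation)
}
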