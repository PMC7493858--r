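#' Region-constrained network nodes from auditory ROIs
#'
#' Within each brain region (and genotype, for the `per_genotype` variant),
#' ROIs are grouped into spatial nodes by k-means on their registered 3D
#' coordinates. `k` starts at `floor(20 + n/1000)` and is decreased until
#' every resulting cluster retains at least `min_rois` ROIs from at least
#' `min_larvae` different larvae (an ascending search for the largest
#' satisfying `k` is available behind `search = "ascending"`). The `matched`
#' variant clusters both genotypes' ROIs together and requires the retention
#' rule per genotype within every cluster, yielding identical node sets
#' across genotypes. Each node carries the mean z-scored trace of its member
#' ROIs and the centroid of their coordinates. Regions that cannot satisfy
#' the rule contribute no nodes (with a message).
#'
#' @param rois ROI tibble of the auditory-responsive set.
#' @param traces Z-scored [trace_matrix] covering those ROIs.
#' @param variant `"per_genotype"` or `"matched"`.
#' @param seed Integer seed (k-means initialization).
#' @param min_rois,min_larvae Node retention rule.
#' @param search `"descending"` (from the starting k) or `"ascending"`.
#' @return A `node_set`: list with `nodes` tibble (`node_id`, `region`,
#'   `genotype`, `n_members`, `n_larvae`, `x`, `y`, `z`), `traces` (node x
#'   frame matrix), `members` (named list of member ROI ids).
#' @export
build_nodes <- function(rois, traces, variant = c("per_genotype", "matched"),
                        seed = 1L, min_rois = 10, min_larvae = 3,
                        search = c("descending", "ascending")) {
  variant <- match.arg(variant)
  search <- match.arg(search)
  node_rows <- list()
  node_traces <- list()
  members <- list()

  retention_ok <- function(g, cl) {
    for (j in unique(cl)) {
      sub <- g[cl == j, ]
      if (variant == "matched") {
        for (gt in unique(g$genotype)) {
          s2 <- sub[sub$genotype == gt, ]
          if (nrow(s2) < min_rois || length(unique(s2$larva_id)) < min_larvae) {
            return(FALSE)
          }
        }
      } else {
        if (nrow(sub) < min_rois || length(unique(sub$larva_id)) < min_larvae) {
          return(FALSE)
        }
      }
    }
    TRUE
  }

  groups <- if (variant == "matched") split(rois, rois$region) else
    split(rois, paste(rois$genotype, rois$region, sep = "."))
  for (key in sort(names(groups))) {
    g <- groups[[key]]
    coords <- as.matrix(g[, c("x", "y", "z")])
    k0 <- floor(20 + nrow(g) / 1000)
    n_distinct_pts <- nrow(unique(coords))
    ks <- if (search == "descending") seq(min(k0, n_distinct_pts), 1L) else
      seq_len(min(k0, n_distinct_pts))
    chosen <- NULL
    for (k in ks) {
      set.seed(child_seed(seed, paste(key, k)))
      cl <- tryCatch(kmeans(coords, centers = k, nstart = 10, iter.max = 50)$cluster,
                     error = function(e) NULL)
      if (is.null(cl)) next
      if (retention_ok(g, cl)) {
        chosen <- cl
        if (search == "descending") break
      } else if (search == "ascending" && !is.null(chosen)) {
        break
      }
    }
    if (is.null(chosen)) {
      message("region group ", key, " has no k satisfying the node retention rule")
      next
    }
    for (j in sort(unique(chosen))) {
      sub <- g[chosen == j, ]
      gts <- if (variant == "matched") unique(sub$genotype) else sub$genotype[1]
      for (gt in gts) {
        s2 <- sub[sub$genotype == gt, ]
        id <- paste0(sub$region[1], "_", gt, "_", j)
        node_rows[[id]] <- tibble::tibble(
          node_id = id, region = sub$region[1], genotype = gt,
          spatial_cluster = j,
          n_members = nrow(s2), n_larvae = length(unique(s2$larva_id)),
          x = mean(s2$x), y = mean(s2$y), z = mean(s2$z)
        )
        node_traces[[id]] <- colMeans(unclass(traces)[s2$roi_id, , drop = FALSE],
                                      na.rm = TRUE)
        members[[id]] <- s2$roi_id
      }
    }
  }
  if (!length(node_rows)) stop("no region produced any node", call. = FALSE)
  nodes <- dplyr::bind_rows(node_rows)
  tr <- do.call(rbind, node_traces)
  structure(list(nodes = nodes, traces = tr, members = members,
                 rate_hz = trace_rate(traces), variant = variant),
            class = "node_set")
}

#' @export
print.node_set <- function(x, ...) {
  cat("<node_set> ", nrow(x$nodes), " nodes (", x$variant, ") across ",
      length(unique(x$nodes$region)), " regions\n", sep = "")
  invisible(x)
}

#' Per-amplitude response frame windows
#'
#' For each discrete sound amplitude, the concatenated frames
#' `[onset, onset + window_s)` over its three repetitions, with any listed
#' censored frames removed. Windows of distinct amplitudes must be disjoint.
#'
#' @param train The auditory [stim_train].
#' @param rate_hz Volumes per second.
#' @param window_s Response window after onset (s, default 5).
#' @param censor_frames Optional integer vector of frames (0-based) removed
#'   from every window.
#' @return Named list (amplitude in dB) of frame index vectors (0-based).
#' @export
amplitude_windows <- function(train, rate_hz, window_s = 5, censor_frames = NULL) {
  sound <- dplyr::filter(train, .data$modality == "sound",
                         .data$block %in% c("ascending", "quasirandom", "descending"))
  w <- round(window_s * rate_hz)
  amps <- sort(unique(sound$amplitude_db))
  out <- lapply(amps, function(a) {
    on <- sound$onset_s[sound$amplitude_db == a]
    frames <- unlist(lapply(floor(on * rate_hz), function(f0) seq.int(f0, f0 + w - 1L)))
    setdiff(frames, censor_frames)
  })
  names(out) <- format(amps)
  all_frames <- unlist(out)
  if (anyDuplicated(all_frames)) {
    stop("amplitude response windows overlap; reduce window_s", call. = FALSE)
  }
  out
}

#' Thresholded correlation graph over one amplitude window
#'
#' Pearson correlation of node mean traces restricted to the window's frames,
#' binarized by a strict threshold: an edge exists when correlation exceeds
#' `tau`. Nodes constant within the window are left isolated.
#'
#' @param nodes A [build_nodes()] node set (or one genotype's subset, see
#'   [subset_nodes()]).
#' @param frames Frame indices (0-based) of the window; at least 10.
#' @param tau Correlation threshold (default 0.85).
#' @param amplitude_db Amplitude label attached to the graph.
#' @return A `corr_graph`: list with `cor` (correlation matrix), `adj`
#'   (binary adjacency, zero diagonal), `nodes`, `amplitude_db`, `tau`.
#' @export
graph_at_amplitude <- function(nodes, frames, tau = 0.85, amplitude_db = NA_real_) {
  stopifnot(length(frames) >= 10)
  tr <- nodes$traces[, frames + 1L, drop = FALSE]
  sds <- apply(tr, 1, sd, na.rm = TRUE)
  if (any(sds == 0 | !is.finite(sds))) {
    message(sum(sds == 0 | !is.finite(sds)),
            " node(s) constant within the window; left isolated")
  }
  C <- suppressWarnings(cor(t(tr), use = "pairwise.complete.obs"))
  A <- (C > tau)
  A[is.na(A)] <- FALSE
  diag(A) <- FALSE
  structure(list(cor = C, adj = A, nodes = nodes$nodes,
                 amplitude_db = amplitude_db, tau = tau),
            class = "corr_graph")
}

#' Restrict a node set to one genotype
#' @param nodes A `node_set`.
#' @param genotype Genotype label.
#' @return A `node_set` containing only that genotype's nodes.
#' @export
subset_nodes <- function(nodes, genotype) {
  keep <- nodes$nodes$genotype == genotype
  structure(list(nodes = nodes$nodes[keep, ],
                 traces = nodes$traces[nodes$nodes$node_id[keep], , drop = FALSE],
                 members = nodes$members[nodes$nodes$node_id[keep]],
                 rate_hz = nodes$rate_hz, variant = nodes$variant),
            class = "node_set")
}

#' Density of an undirected simple graph
#'
#' `D = 2E / (N (N - 1))`.
#'
#' @param graph A `corr_graph` (or a logical/0-1 adjacency matrix).
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(graph) {
  A <- if (inherits(graph, "corr_graph")) graph$adj else graph
  n <- nrow(A)
  if (n < 2) stop("density undefined for fewer than 2 nodes", call. = FALSE)
  sum(A) / (n * (n - 1))
}

#' Participation coefficient of each node across brain regions
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2`, where `k_im` counts node i's edges into
#' region m and `k_i` is its degree; isolated nodes score 0. Bounded by
#' `1 - 1/M` for M regions.
#'
#' @param graph A `corr_graph` whose nodes carry a `region` label.
#' @return Tibble with `node_id`, `region`, `degree`, `participation`.
#' @export
participation_coef <- function(graph) {
  A <- graph$adj * 1
  regions <- graph$nodes$region
  M <- model_matrix_regions(regions)
  K <- A %*% M
  k <- rowSums(A)
  P <- 1 - rowSums((K / pmax(k, 1))^2)
  P[k == 0] <- 0
  tibble::tibble(node_id = graph$nodes$node_id, region = regions,
                 degree = k, participation = P)
}

model_matrix_regions <- function(regions) {
  lv <- sort(unique(regions))
  M <- matrix(0, length(regions), length(lv), dimnames = list(NULL, lv))
  M[cbind(seq_along(regions), match(regions, lv))] <- 1
  M
}

#' Mean participation coefficient per region
#' @param graph A `corr_graph`.
#' @return Tibble with `region` and `mean_participation`.
#' @export
region_participation <- function(graph) {
  dplyr::summarise(dplyr::group_by(participation_coef(graph), .data$region),
                   mean_participation = mean(.data$participation),
                   n_nodes = dplyr::n(), .groups = "drop")
}

#' Inter-region edge counts
#'
#' Edges whose endpoints lie in different brain regions, counted per region
#' pair (the table behind a circle plot).
#'
#' @param graph A `corr_graph`.
#' @return Tibble with `region_a`, `region_b` (alphabetical), `n_edges`.
#' @export
inter_region_edges <- function(graph) {
  A <- graph$adj
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  if (!nrow(idx)) {
    return(tibble::tibble(region_a = character(), region_b = character(),
                          n_edges = integer()))
  }
  ra <- graph$nodes$region[idx[, 1]]
  rb <- graph$nodes$region[idx[, 2]]
  keep <- ra != rb
  if (!any(keep)) {
    return(tibble::tibble(region_a = character(), region_b = character(),
                          n_edges = integer()))
  }
  d <- tibble::tibble(region_a = pmin(ra[keep], rb[keep]),
                      region_b = pmax(ra[keep], rb[keep]))
  dplyr::count(d, .data$region_a, .data$region_b, name = "n_edges")
}

#' Earliest amplitude at which inter-region edges form, per genotype
#'
#' For each genotype, scans its per-amplitude graphs from quietest to loudest
#' and reports the first amplitude with at least `min_edges` inter-region
#' edges. The genotype shift estimate is the dB difference between the
#' reference and the alternative genotype's onset amplitudes: positive values
#' mean the alternative genotype's network engages at quieter sounds.
#'
#' @param graphs_by_genotype Named list: genotype -> list of `corr_graph`s
#'   across amplitudes.
#' @param min_edges Edge-count criterion (default 1).
#' @param ref_genotype,alt_genotype Genotypes compared for the shift.
#' @return List with `onsets` tibble (`genotype`, `onset_db`) and `shift_db`.
#' @export
edge_onset_amplitude <- function(graphs_by_genotype, min_edges = 1,
                                 ref_genotype = "WT", alt_genotype = "HOM") {
  onsets <- purrr::imap(graphs_by_genotype, function(graphs, gt) {
    amps <- vapply(graphs, `[[`, 0, "amplitude_db")
    counts <- vapply(graphs, function(g) sum(inter_region_edges(g)$n_edges), 0)
    o <- order(amps)
    hit <- which(counts[o] >= min_edges)
    tibble::tibble(genotype = gt,
                   onset_db = if (length(hit)) amps[o][hit[1]] else NA_real_)
  })
  onsets <- dplyr::bind_rows(onsets)
  shift <- NA_real_
  if (all(c(ref_genotype, alt_genotype) %in% onsets$genotype)) {
    shift <- onsets$onset_db[onsets$genotype == ref_genotype] -
      onsets$onset_db[onsets$genotype == alt_genotype]
  }
  list(onsets = onsets, shift_db = shift, min_edges = min_edges)
}

#' Per-event stimulus windows
#'
#' One frame window `[onset, onset + window_s)` per stimulus event (0-based
#' frames), the unit within which AAFT shuffling operates.
#'
#' @param train A [stim_train].
#' @param rate_hz Volumes per second.
#' @param window_s Window length after onset (s).
#' @param modalities Which modalities to include (default all).
#' @return List of frame index vectors (0-based).
#' @export
event_windows <- function(train, rate_hz, window_s = 5,
                          modalities = unique(train$modality)) {
  ev <- dplyr::filter(train, .data$modality %in% modalities)
  w <- round(window_s * rate_hz)
  lapply(floor(ev$onset_s * rate_hz), function(f0) seq.int(f0, f0 + w - 1L))
}

# phase-randomize a real series, preserving its amplitude spectrum
phase_randomize <- function(g) {
  n <- length(g)
  F <- fft(g)
  half <- floor((n - 1) / 2)
  phases <- numeric(n)
  if (half >= 1) {
    ph <- runif(half, 0, 2 * pi)
    phases[2:(half + 1)] <- ph
    phases[n:(n - half + 1)] <- -ph
  }
  Re(fft(complex(modulus = Mod(F), argument = Arg(F) + phases),
         inverse = TRUE)) / n
}

#' Amplitude-adjusted Fourier transform surrogate of one series
#'
#' Gaussianizes the series by rank, phase-randomizes the Gaussian copy
#' (preserving its amplitude spectrum), and maps the original's sorted values
#' back by the ranks of the randomized copy. The surrogate has exactly the
#' original value distribution and approximately its power spectrum, while
#' destroying stimulus-locked timing. Uses the current RNG state.
#'
#' @param x Numeric vector.
#' @return Surrogate vector of the same length.
#' @export
aaft_surrogate <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  g <- sort(rnorm(n))[r]
  gs <- phase_randomize(g)
  sort(x)[rank(gs, ties.method = "first")]
}

#' AAFT shuffle of node traces within stimulus windows
#'
#' Replaces each trace segment inside each stimulus window with an
#' independent AAFT surrogate, leaving data outside the windows unchanged.
#' Shuffling within (not across) windows keeps responses inside the windows
#' used to study each stimulus while erasing their repeatable structure.
#' Constant windows are returned unchanged with a message.
#'
#' @param traces Numeric matrix (series x frames), e.g. node traces.
#' @param windows List of frame index vectors (0-based), each of length >= 8.
#' @param seed Integer seed.
#' @return Matrix of the same shape.
#' @export
aaft_shuffle <- function(traces, windows, seed = 1L) {
  stopifnot(all(vapply(windows, length, 0L) >= 8))
  set.seed(child_seed(seed, "aaft"))
  out <- traces
  n_const <- 0L
  for (i in seq_len(nrow(traces))) {
    for (w in windows) {
      x <- traces[i, w + 1L]
      if (anyNA(x) || sd(x) == 0) {
        n_const <- n_const + 1L
        next
      }
      out[i, w + 1L] <- aaft_surrogate(x)
    }
  }
  if (n_const > 0) message(n_const, " constant or censored window(s) left unshuffled")
  out
}
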