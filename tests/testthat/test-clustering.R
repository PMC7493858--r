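test_that("kmedians recovers well-separated groups with median centroids", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
             matrix(rnorm(40, 10, 0.1), 20, 2),
             matrix(rnorm(30, c(0, 10), 0.1), 15, 2, byrow = TRUE))
  km <- kmedians(x, 3, seed = 9)
  # the three planted groups are never split
  grp <- rep(1:3, c(20, 20, 15))
  expect_equal(length(unique(paste(grp, km$cluster))), 3)
  # centroids are component-wise medians of their members
  for (j in 1:3) {
    rows <- km$cluster == j
    expect_equal(km$centroids[j, ],
                 apply(x[rows, , drop = FALSE], 2, median), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # reported cost is the total within-cluster L1 distance
  cost <- sum(abs(x - km$centroids[km$cluster, ]))
  expect_equal(km$cost, cost, tolerance = 1e-9)
  # deterministic in the seed
  expect_identical(km, kmedians(x, 3, seed = 9))
})

test_that("the distance kernel is city-block, not Euclidean", {
  # p = (0, 3): L1 distance ties at 3 to both centroids, while the Euclidean
  # distances would differ (3 vs sqrt(2.5^2 + 0.5^2) ~ 2.55)
  d <- larvanet:::l1_dist_to(rbind(c(0, 3)), rbind(c(0, 0), c(2.5, 2.5)))
  expect_equal(as.numeric(d), c(3, 3))
  set.seed(4)
  x <- matrix(rnorm(12), 4, 3)
  cent <- matrix(rnorm(6), 2, 3)
  brute <- outer(seq_len(4), seq_len(2),
                 Vectorize(function(i, j) sum(abs(x[i, ] - cent[j, ]))))
  expect_equal(larvanet:::l1_dist_to(x, cent), brute, ignore_attr = TRUE)
})

test_that("column medians match the reference implementation", {
  set.seed(3)
  for (k in c(1, 2, 5, 8)) {
    m <- matrix(rnorm(k * 17), k, 17)
    expect_equal(larvanet:::col_medians(m), apply(m, 2, median),
                 ignore_attr = TRUE)
  }
})

test_that("cluster_region requires at least k candidates and imputes NAs", {
  m <- matrix(rnorm(3 * 50), 3, 50, dimnames = list(paste0("r", 1:3)))
  expect_error(cluster_region(trace_matrix(m, 4), k = 5), "fewer candidate")
  m2 <- matrix(rnorm(6 * 50), 6, 50, dimnames = list(paste0("r", 1:6)))
  m2[1, 1:5] <- NA
  mod <- cluster_region(trace_matrix(m2, 4), k = 2, seed = 1)
  expect_s3_class(mod, "cluster_model")
  expect_equal(sort(unique(mod$assignments$cluster)), 1:2)
  expect_equal(mod$assignments$roi_id, paste0("r", 1:6))
})

test_that("flag_auditory flags clusters whose centroid tracks a regressor", {
  regs <- shared_regs()
  nf <- ncol(regs$matrix)
  centroids <- rbind(regs$matrix[12, ] + rnorm(nf, 0, 0.02),  # tracks 0 dB
                     rnorm(nf))                               # noise
  model <- structure(list(centroids = centroids, k = 2), class = "cluster_model")
  out <- flag_auditory(model, regs)
  expect_equal(out$auditory, c(TRUE, FALSE))
  expect_gt(out$centroid_best_r2[1], 0.5)
})

test_that("prune_members drops weakly correlated members and flags empty clusters", {
  nf <- 100
  cent <- rbind(sin(seq_len(nf) / 5), cos(seq_len(nf) / 3))
  x <- rbind(cent[1, ] * 2 + 1,          # corr 1 with its centroid
             -cent[1, ],                  # corr -1: pruned
             cent[2, ] + rnorm(nf, 0, 0.05))
  rownames(x) <- paste0("r", 1:3)
  model <- structure(list(centroids = cent, k = 2,
                          assignments = tibble::tibble(
                            roi_id = rownames(x), cluster = c(1L, 1L, 2L),
                            retained = TRUE)), class = "cluster_model")
  out <- prune_members(model, trace_matrix(x, 4))
  expect_equal(out$assignments$retained, c(TRUE, FALSE, TRUE))
  model2 <- model
  model2$assignments$cluster <- c(2L, 1L, 2L)  # cluster 1 keeps only the r2 = -1 member
  expect_message(prune_members(model2, trace_matrix(x, 4)), "lost all members")
})

test_that("larva representation counts distinct larvae of retained members", {
  model <- structure(list(k = 2, assignments = tibble::tibble(
    roi_id = paste0("r", 1:5), cluster = c(1L, 1L, 1L, 2L, 2L),
    retained = c(TRUE, TRUE, TRUE, TRUE, FALSE))), class = "cluster_model")
  rois <- tibble::tibble(roi_id = paste0("r", 1:5),
                         larva_id = c("A", "A", "B", "C", "D"))
  rep_tbl <- larva_representation(model, rois, n_larvae = 4)
  expect_equal(rep_tbl$representation, c(2 / 4, 1 / 4))
  # clusters losing every member report 0, not NA
  model$assignments$retained[4] <- FALSE
  expect_equal(larva_representation(model, rois, n_larvae = 4)$representation[2], 0)
})

test_that("amplitude tuning averages retained members and keeps NA as NA", {
  records <- tibble::tibble(
    roi_id = rep(c("a", "b"), each = 2),
    regressor = rep(c("-12", "0"), 2),
    beta = c(1, 3, 2, NA), r2 = 0.5)
  model <- structure(list(k = 1, assignments = tibble::tibble(
    roi_id = c("a", "b"), cluster = 1L, retained = TRUE)),
    class = "cluster_model")
  tun <- amplitude_tuning(model, records)
  expect_equal(tun$mean_beta[tun$amplitude_db == -12], 1.5)
  expect_equal(tun$mean_beta[tun$amplitude_db == 0], 3)  # NA ignored, not zeroed
  records$beta[c(2, 4)] <- NA
  tun2 <- amplitude_tuning(model, records)
  expect_true(is.na(tun2$mean_beta[tun2$amplitude_db == 0]))
  expect_equal(tun2$n_members[tun2$amplitude_db == 0], 0)
})

test_that("match_clusters pairs permuted centroids one-to-one", {
  set.seed(8)
  cent <- matrix(rnorm(4 * 60), 4, 60)
  perm <- c(3, 1, 4, 2)
  a <- structure(list(centroids = cent, k = 4), class = "cluster_model")
  b <- structure(list(centroids = cent[perm, ] + rnorm(240, 0, 0.01), k = 4),
                 class = "cluster_model")
  m <- match_clusters(a, b)
  expect_equal(nrow(m), 4)
  expect_true(all(m$matched))
  expect_equal(m$cluster_b[order(m$cluster_a)], order(perm))
  expect_true(all(m$correlation > 0.99))
  # dissimilar centroids stay unmatched under min_cor
  c_mod <- structure(list(centroids = matrix(rnorm(240), 4, 60), k = 4),
                     class = "cluster_model")
  m2 <- match_clusters(a, c_mod, min_cor = 0.9)
  expect_false(any(m2$matched))
})

test_that("cluster_cohort assembles per region.genotype and flags auditory sets", {
  cl <- shared_clustering()
  co <- shared_cohort()
  a <- cl$assignments
  expect_true(all(c("roi_id", "region", "genotype", "cluster", "auditory",
                    "retained", "representation") %in% names(a)))
  expect_true(all(a$roi_id %in% shared_records()$roi_id[shared_records()$responsive]))
  aud <- auditory_rois(cl)
  expect_true(all(aud$auditory & aud$retained))
  # the auditory set is dominated by ground-truth tuned ROIs
  truth <- co$truth
  frac_true <- mean(truth$cluster[match(aud$roi_id, truth$roi_id)] > 0)
  expect_gt(frac_true, 0.9)
  # representation filter prunes
  expect_lte(nrow(auditory_rois(cl, min_representation = 0.9)), nrow(aud))
  # groups smaller than k are skipped with a message
  few <- co$rois[1:3, ]
  rec3 <- shared_records()[shared_records()$roi_id %in% few$roi_id, ]
  rec3$responsive <- TRUE
  tiny <- list(rois = few, traces = co$traces[few$roi_id, ], train = co$train)
  expect_message(cluster_cohort(tiny, rec3, shared_regs(), k = 5),
                 "skipping")
})
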