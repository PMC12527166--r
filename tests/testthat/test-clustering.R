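# standardization, PCA cross-validation, GMM/BIC, assignment, SUSM, usage

test_that("the z-scorer uses training statistics only", {
  tr <- cbind(a = c(0, 2), b = c(1, 1))
  expect_warning(zs <- zscore_fit_apply(tr, cbind(a = 2, b = 7)), "zero-variance")
  expect_equal(unname(zs$x[1, "a"]), (2 - 1) / sqrt(2))
  expect_equal(unname(zs$x[1, "b"]), 6)  # unscaled passthrough
  set.seed(1)
  X <- matrix(rnorm(200), 50, 4)
  self <- zscore_fit_apply(X)
  expect_equal(colMeans(self$x), rep(0, 4), tolerance = 1e-12)
  expect_equal(apply(self$x, 2, sd), rep(1, 4), tolerance = 1e-12)
  expect_error(zscore_fit_apply(X, X[, 1:2]), class = "imuseg_schema_error")
})

test_that("element-wise PCA cross-validation recovers a planted rank", {
  set.seed(0)
  n <- 120; p <- 30; r <- 3
  X <- matrix(rnorm(n * r), n, r) %*% matrix(rnorm(r * p, sd = 2), r, p) +
    matrix(rnorm(n * p, sd = 0.01), n, p)
  sel <- select_n_pcs_cv(X, grid = c(1, 2, 3, 5, 8), folds = 4, seed = 0)
  expect_equal(as.integer(sel), 3L)
  err <- attr(sel, "cv_error")
  # U-shape around the planted rank: error drops to 3 then rises
  expect_true(all(diff(err[c("1", "2", "3")]) < 0))
  expect_gt(err[["8"]], err[["3"]])
  # pure noise selects at or near the grid minimum
  Xn <- matrix(rnorm(n * p), n, p)
  seln <- select_n_pcs_cv(Xn, grid = c(1, 2, 5, 10), folds = 4, seed = 0)
  expect_lte(as.integer(seln), 2L)
})

test_that("free-parameter counts match the covariance structures", {
  expect_equal(gmm_param_count(2, 3, "full"), (2 - 1) + 2 * 3 + 2 * (3 * 4 / 2))
  expect_equal(gmm_param_count(4, 5, "tied"), 3 + 20 + 15)
  expect_equal(gmm_param_count(4, 5, "diagonal"), 3 + 20 + 20)
  expect_equal(gmm_param_count(4, 5, "spherical"), 3 + 20 + 4)
})

test_that("BIC selects the planted component count on separated mixtures", {
  set.seed(0)
  d <- 5
  centers <- rbind(rep(0, d), c(rep(8, 2), rep(0, d - 2)), c(rep(-8, 2), rep(0, d - 2)))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(1000 * d), ncol = d), 2, centers[k, ], "+")))
  lab <- rep(1:3, each = 1000)
  model <- fit_gmm_grid(X, K_range = 1:8)
  expect_equal(model$K, 3L)
  asg <- assign_segments(model, X)
  expect_gte(adjusted_rand(asg$labels, lab), 0.99)
  # single-Gaussian data -> K = 1
  X1 <- matrix(rnorm(600 * 3), ncol = 3)
  expect_equal(fit_gmm_grid(X1, K_range = 1:6)$K, 1L)
})

test_that("posteriors are proper and consistent with training assignments", {
  set.seed(2)
  X <- rbind(matrix(rnorm(400, 0), ncol = 2), matrix(rnorm(400, 10), ncol = 2))
  model <- fit_gmm_grid(X, K_range = 2, cov_types = "spherical")
  asg <- assign_segments(model, X)
  expect_equal(rowSums(asg$posteriors), rep(1, 400), tolerance = 1e-9)
  # point at a component mean: posterior ~ 1
  at_mean <- assign_segments(model, rbind(model$means[1, ]))
  expect_gt(max(at_mean$posteriors), 0.99)
  # top-q helper returns the highest-posterior members, ordered
  ts <- top_segments(asg, 1, q = 5)
  expect_length(ts, 5)
  expect_true(all(diff(asg$posteriors[ts, 1]) <= 0))
  expect_error(assign_segments(model, X[, 1, drop = FALSE]),
               class = "imuseg_schema_error")
})

test_that("sparse clusters are the highest-covariance-trace components", {
  model <- structure(list(
    weights = rep(0.2, 5), means = matrix(0, 5, 2),
    covariances = array(vapply(c(1, 2, 9, 3, 8) / 2,
                               function(s) diag(s, 2), matrix(0, 2, 2)),
                        c(2, 2, 5)),
    cov_type = "spherical", K = 5L, d = 2L), class = "cluster_model")
  expect_equal(sort(detect_sparse_clusters(model, 3)), c(3L, 4L, 5L))
  expect_equal(detect_sparse_clusters(model, 3)[1], 3L)  # largest trace first
  expect_length(detect_sparse_clusters(model, 0), 0L)
  expect_error(detect_sparse_clusters(model, 6), class = "imuseg_value_error")
})

test_that("SUSM sits in the expected band and degrades with distance", {
  set.seed(0)
  d <- 4
  X <- rbind(matrix(rnorm(1500 * d), ncol = d),
             sweep(matrix(rnorm(1500 * d), ncol = d), 2, rep(6, d), "+"))
  model <- fit_gmm_grid(X, K_range = 2, cov_types = "full")
  # Monte-Carlo band of the expected log-density under the fitted mixture
  sim <- function(n) {
    ks <- sample.int(model$K, n, replace = TRUE, prob = model$weights)
    t(vapply(ks, function(k)
      model$means[k, ] + chol(model$covariances[, , k]) %*% rnorm(d),
      numeric(d)))
  }
  Xtest <- sim(5000)
  scores <- gmm_logdensity(model, Xtest)
  insusm <- mean(scores)
  band <- quantile(replicate(200, mean(gmm_logdensity(model, sim(200)))),
                   c(0.025, 0.975))
  expect_gte(insusm, band[[1]] - 0.1)
  expect_lte(insusm, band[[2]] + 0.1)
  # +10 SD translation strictly lowers the score
  shifted <- sweep(Xtest, 2, rep(10, d), "+")
  expect_lt(mean(gmm_logdensity(model, shifted)), insusm)
  # monotone degradation along a shift sweep
  sweep_scores <- vapply(c(0, 2, 4, 8), function(s)
    mean(gmm_logdensity(model, sweep(Xtest, 2, rep(s, d), "+"))), numeric(1))
  expect_true(all(diff(sweep_scores) < 0))
})

test_that("leave-one-out SUSM is not optimistic on average", {
  set.seed(1)
  d <- 3
  mk_tab <- function() matrix(rnorm(900 * d), ncol = d)
  deltas <- vapply(1:5, function(s) {
    set.seed(s)
    X <- mk_tab()
    groups <- rep(c("m1", "m2", "m3"), each = 300)
    colnames(X) <- paste0("f", 1:d)
    model <- fit_cluster_model(as_segment_table(X), groups = groups,
                               n_pc = d - 1, K_range = 2,
                               cov_types = "full")
    res <- susm(model, as_segment_table(X), groups, loo_groups = "m1")
    insample <- susm(model, as_segment_table(X), groups)
    res$susm[res$group == "m1"] - insample$susm[insample$group == "m1"]
  }, numeric(1))
  expect_lte(mean(deltas), 0.05)
  # scoring an absent group errors
  X <- mk_tab(); colnames(X) <- paste0("f", 1:d)
  model <- fit_cluster_model(as_segment_table(X), n_pc = 2, K_range = 2,
                             cov_types = "full")
  expect_error(susm(model, as_segment_table(X), rep("g", 900),
                    loo_groups = "g2"), class = "imuseg_value_error")
})

test_that("cluster usage percentages are coherent", {
  asg <- structure(list(labels = c(rep(1L, 6), rep(2L, 3), NA), K = 2L),
                   class = "cluster_assignment")
  u <- cluster_usage(asg, groups = rep("g", 10))
  expect_equal(sum(u$pct_segments), 100)
  expect_equal(u$pct_segments[u$cluster == "1"], 6 / 9 * 100)
  u2 <- cluster_usage(asg, groups = rep("g", 10), include_outliers = TRUE)
  expect_equal(sum(u2$pct_segments), 100)
  expect_equal(u2$pct_segments[u2$cluster == "OUTLIER"], 10)
  # overuse report
  usage <- rbind(
    data.frame(group = "sham", cluster = c("1", "2"), pct_segments = c(50, 50)),
    data.frame(group = "pd", cluster = c("1", "2"), pct_segments = c(80, 20)))
  over <- overused_clusters(usage, "sham", margin = 5)
  expect_equal(over$cluster, "1")
})
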