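# clustering: standardization, cross-validated PCA, BIC-selected Gaussian
# mixtures, hard assignment, sparse clusters, cross-likelihood (SUSM).
#
# EM fitting is delegated to mclust; the covariance structures map as
# full = VVV, tied = EEE, diagonal = VVI, spherical = VII, with identical
# free-parameter counts.  BIC here is 2 lnL - p ln(m) (larger is better;
# equivalent to minimizing the textbook criterion).  mclust's model-based
# hierarchical initialization is deterministic, so the `n_init`/`seed`
# arguments exist for interface stability but do not introduce randomness.
# Posteriors, assignment and all likelihood scoring are computed from the
# stored mixture parameters by this package.

.cov_to_mclust <- c(full = "VVV", tied = "EEE", diagonal = "VVI",
                    spherical = "VII")

#' Free-parameter count of a Gaussian mixture
#'
#' Weights contribute `K - 1`, means `K d`, covariances `K d(d+1)/2`
#' (full), `d(d+1)/2` (tied), `K d` (diagonal) or `K` (spherical).
#'
#' @param K number of components.
#' @param d dimensionality.
#' @param cov_type one of `"full"`, `"tied"`, `"diagonal"`, `"spherical"`.
#' @return integer parameter count.
#' @export
gmm_param_count <- function(K, d, cov_type) {
  covp <- switch(match.arg(cov_type, names(.cov_to_mclust)),
                 full = K * d * (d + 1) / 2,
                 tied = d * (d + 1) / 2,
                 diagonal = K * d,
                 spherical = K)
  as.integer((K - 1) + K * d + covp)
}

#' Fit-and-apply z-scoring
#'
#' Standardizes `apply_to` using the column means and SDs of `train` only
#' (so a reference group's scaler can be applied to other groups without
#' leakage).  Zero-SD columns pass through unscaled, with a warning.
#'
#' @param train matrix whose statistics define the scaler (>= 2 rows).
#' @param apply_to matrix to standardize (defaults to `train`).
#' @return list with `x` (standardized `apply_to`) and `scaler`
#'   (`center`, `scale`).
#' @export
zscore_fit_apply <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  if (nrow(train) < 2L) stop_value("need >= 2 training rows to estimate a scaler")
  if (ncol(train) != ncol(apply_to))
    stop_schema("column mismatch: train has %d, apply_to has %d",
                ncol(train), ncol(apply_to))
  center <- colMeans(train)
  scale_ <- apply(train, 2, sd)
  if (any(scale_ == 0)) {
    warning(sprintf("%d zero-variance column(s) left unscaled", sum(scale_ == 0)))
    scale_[scale_ == 0] <- 1
  }
  list(x = sweep(sweep(apply_to, 2, center), 2, scale_, "/"),
       scaler = list(center = center, scale = scale_))
}

#' Select the PCA dimensionality by element-wise cross-validation
#'
#' Wold-style CV: matrix entries are randomly partitioned into folds; for
#' each fold the held-out entries are masked and imputed iteratively
#' (column-mean start, then repeated rank-q SVD reconstruction), and the
#' squared reconstruction error on the masked entries is scored.  The
#' returned dimension minimizes the mean CV error over folds.
#'
#' @param X standardized matrix.
#' @param grid candidate dimensions (within `[1, min(dim(X)) - 1]`).
#' @param folds number of entry folds (default 5).
#' @param seed RNG seed for the fold assignment.
#' @param max_rows rows are subsampled (seeded) beyond this cap to bound
#'   the SVD cost (default 2000).
#' @param max_iter,tol imputation loop controls.
#' @return selected dimension, with attribute `cv_error` (named vector of
#'   mean errors per candidate).
#' @export
select_n_pcs_cv <- function(X, grid, folds = 5L, seed = 1L, max_rows = 2000L,
                            max_iter = 20L, tol = 1e-4) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop_value("X must be finite")
  rng <- local({
    set.seed(seed)
    if (nrow(X) > max_rows) X <<- X[sample.int(nrow(X), max_rows), , drop = FALSE]
    sample.int(folds, length(X), replace = TRUE)
  })
  grid <- sort(unique(as.integer(grid)))
  if (min(grid) < 1L || max(grid) > min(dim(X)) - 1L)
    stop_config("grid must lie within [1, %d]", min(dim(X)) - 1L)
  fold_of <- matrix(rng, nrow(X), ncol(X))
  err <- matrix(NA_real_, length(grid), folds,
                dimnames = list(as.character(grid), NULL))
  for (f in seq_len(folds)) {
    mask <- fold_of == f
    for (gi in seq_along(grid)) {
      q <- grid[gi]
      Xi <- X
      mu <- colMeans(X)  # column-mean start for held-out entries
      Xi[mask] <- matrix(mu, nrow(X), ncol(X), byrow = TRUE)[mask]
      prev <- Inf
      for (it in seq_len(max_iter)) {
        sv <- svd(Xi, nu = q, nv = q)
        Xhat <- sv$u %*% (sv$d[seq_len(q)] * t(sv$v))
        e <- mean((Xhat[mask] - X[mask])^2)
        Xi[mask] <- Xhat[mask]
        if (is.finite(prev) && abs(prev - e) < tol * max(prev, 1e-12)) break
        prev <- e
      }
      err[gi, f] <- prev
    }
  }
  mean_err <- rowMeans(err)
  sel <- grid[which.min(mean_err)]
  structure(sel, cv_error = mean_err)
}

#' Fit a Gaussian-mixture grid and select by BIC
#'
#' Fits mixtures over every (component count, covariance type) cell and
#' returns the model maximizing `BIC = 2 lnL - p ln(m)`.
#'
#' @param Z m x d projected data matrix.
#' @param K_range candidate component counts (default 5-100, the
#'   animal-data operating range).
#' @param cov_types subset of `c("full", "diagonal", "tied", "spherical")`.
#' @param n_init,seed kept for interface stability; the backend
#'   initialization is deterministic.
#' @return an object of class `cluster_model` with mixture parameters
#'   (`weights`, `means` K x d, `covariances` d x d x K, `cov_type`, `K`)
#'   and `fit_info` (BIC, log-likelihood, parameter count).
#' @export
fit_gmm_grid <- function(Z, K_range = 5:100,
                         cov_types = c("full", "diagonal", "tied", "spherical"),
                         n_init = 10L, seed = NULL) {
  Z <- as.matrix(Z)
  cov_types <- match.arg(cov_types, names(.cov_to_mclust), several.ok = TRUE)
  if (nrow(Z) <= max(K_range))
    stop_value("need more observations (%d) than mixture components (%d)",
               nrow(Z), max(K_range))
  fit <- mclust::Mclust(Z, G = K_range,
                        modelNames = unname(.cov_to_mclust[cov_types]),
                        verbose = FALSE)
  if (is.null(fit)) stop_value("no mixture in the grid could be fitted")
  # single-component fits come back with the X* model family
  single <- c(X = "spherical", XII = "spherical", XXI = "diagonal",
              XXX = "full")
  cov_type <- if (fit$modelName %in% names(single)) single[[fit$modelName]]
  else names(.cov_to_mclust)[match(fit$modelName, .cov_to_mclust)]
  K <- fit$G
  d <- ncol(Z)
  sig <- fit$parameters$variance$sigma
  if (length(dim(sig)) == 2L) sig <- array(sig, c(d, d, K))  # tied expands
  p <- gmm_param_count(K, d, cov_type)
  model <- structure(list(
    weights = as.numeric(fit$parameters$pro),
    means = t(rbind(fit$parameters$mean)),
    covariances = sig,
    cov_type = cov_type, K = K, d = d,
    scaler = NULL, pca = NULL, train = NULL, train_groups = NULL,
    fit_info = list(bic = 2 * fit$loglik - p * log(nrow(Z)),
                    loglik = fit$loglik, n_params = p,
                    n_init = n_init, seed = seed)
  ), class = "cluster_model")
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> K = %d (%s covariance), d = %d; BIC = %.1f\n",
              x$K, x$cov_type, x$d, x$fit_info$bic))
  if (!is.null(x$pca))
    cat(sprintf("  scaler + PCA front end: %d features -> %d PCs\n",
                length(x$scaler$center), ncol(x$pca$rotation)))
  invisible(x)
}

# log N(x; mu, Sigma) per row, via Cholesky
.log_dmvnorm <- function(X, mu, Sigma) {
  d <- ncol(X)
  ch <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-6, d))  # covariance floor against degeneracy
  })
  xc <- sweep(X, 2, mu)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# m x K matrix of log(pi_k) + log N(x; mu_k, Sigma_k)
.component_loglik <- function(model, Z) {
  Z <- rbind(Z)
  sapply(seq_len(model$K), function(k)
    log(model$weights[k]) +
      .log_dmvnorm(Z, model$means[k, ], model$covariances[, , k]))
}

#' Mixture log-density of projected observations
#'
#' @param model a [fit_gmm_grid()] / [fit_cluster_model()] result.
#' @param Z observations in the model's projected space (rows).
#' @return numeric vector of log-densities.
#' @export
gmm_logdensity <- function(model, Z) {
  ll <- rbind(.component_loglik(model, Z))
  mx <- apply(ll, 1, max)
  mx + log(rowSums(exp(ll - mx)))
}

#' Posterior responsibilities and hard assignment
#'
#' Applies the model's scaler and PCA to a feature table (when the model
#' carries them), computes posterior component probabilities by Bayes rule,
#' and hard-assigns each non-excluded segment to its most probable
#' component.  Excluded segments (outliers, wet-dog shakes and their
#' neighbors) receive the label `NA` ("OUTLIER") and no posterior.
#'
#' @param model a [fit_cluster_model()] (or [fit_gmm_grid()]) result.
#' @param table a [extract_features()] result, or a plain matrix already in
#'   the model's projected space.
#' @return an object of class `cluster_assignment`: list with `labels`
#'   (integer cluster id or `NA` for excluded segments), `posteriors`
#'   (m x K; `NA` rows for excluded segments) and `loglik` (per-segment
#'   mixture log-density).
#' @export
assign_segments <- function(model, table) {
  proj <- project_features(model, table)
  Z <- proj$Z
  ll <- rbind(.component_loglik(model, Z))
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  labels <- max.col(post, ties.method = "first")
  logd <- mx + log(rowSums(exp(ll - mx)))
  m_all <- proj$m_all
  out_labels <- rep(NA_integer_, m_all)
  out_post <- matrix(NA_real_, m_all, model$K)
  out_ll <- rep(NA_real_, m_all)
  out_labels[proj$rows] <- labels
  out_post[proj$rows, ] <- post
  out_ll[proj$rows] <- logd
  structure(list(labels = out_labels, posteriors = out_post, loglik = out_ll,
                 K = model$K),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d segments, %d clusters, %d excluded\n",
              length(x$labels), x$K, sum(is.na(x$labels))))
  invisible(x)
}

# shared projection: feature table (or matrix) -> model space
project_features <- function(model, table) {
  if (inherits(table, "segment_table")) {
    keep <- !table$flags$excluded
    X <- table$features[keep, , drop = FALSE]
    rows <- which(keep); m_all <- nrow(table$features)
  } else {
    X <- as.matrix(table)
    rows <- seq_len(nrow(X)); m_all <- nrow(X)
  }
  if (!is.null(model$scaler)) {
    X <- sweep(sweep(X, 2, model$scaler$center), 2, model$scaler$scale, "/")
    X <- X %*% model$pca$rotation
  }
  if (ncol(X) != model$d)
    stop_schema("projected dimensionality (%d) does not match the model (%d)",
                ncol(X), model$d)
  list(Z = X, rows = rows, m_all = m_all)
}

#' Most representative segments of a cluster
#'
#' The `q` segments with the highest posterior probability for the cluster
#' (used e.g. to pick segments for video inspection).
#'
#' @param assign a [assign_segments()] result.
#' @param cluster cluster id.
#' @param q how many segments (default 100).
#' @return integer vector of segment indices, ordered by decreasing
#'   posterior.
#' @export
top_segments <- function(assign, cluster, q = 100L) {
  stopifnot(cluster >= 1L, cluster <= assign$K)
  idx <- which(assign$labels == cluster)
  idx[order(assign$posteriors[idx, cluster], decreasing = TRUE)][seq_len(min(q, length(idx)))]
}

#' Detect sparse clusters
#'
#' Ranks mixture components by the trace of their covariance matrix and
#' returns the `top_n` most dispersed: such components absorb rare,
#' vigorous movements and are weakly informative.
#'
#' @param model a fitted cluster model.
#' @param top_n how many components to flag (default 3).
#' @return integer component ids, by decreasing covariance trace.
#' @export
detect_sparse_clusters <- function(model, top_n = 3L) {
  if (top_n > model$K) stop_value("top_n (%d) exceeds K (%d)", top_n, model$K)
  if (top_n == 0L) return(integer())
  tr <- vapply(seq_len(model$K), function(k)
    sum(diag(model$covariances[, , k])), numeric(1))
  order(tr, decreasing = TRUE)[seq_len(top_n)]
}

#' Fit the full clustering front end on a reference set
#'
#' Standardizes the non-excluded feature rows of `table` (optionally only a
#' reference subset of groups, e.g. healthy animals), projects them on
#' `n_pc` principal components (selected by [select_n_pcs_cv()] when
#' `n_pc = "cv"`), and fits the BIC-selected Gaussian mixture.  The returned
#' model carries the scaler and PCA so it can be applied unchanged to other
#' groups, plus its training features for leave-one-out refits in [susm()].
#'
#' @param table a [extract_features()] result (after [flag_outliers()]).
#' @param groups optional per-segment group labels.
#' @param fit_on optional subset of group labels to fit on (default: all).
#' @param n_pc integer, or `"cv"` for cross-validated selection.
#' @param pc_grid candidate dimensions for `"cv"`.
#' @param K_range,cov_types,n_init,seed passed to [fit_gmm_grid()].
#' @param cv_seed seed for the PCA cross-validation.
#' @return a `cluster_model` with scaler/PCA front end attached.
#' @export
fit_cluster_model <- function(table, groups = NULL, fit_on = NULL,
                              n_pc = "cv", pc_grid = c(2, 5, 10, 20, 30),
                              K_range = 5:100,
                              cov_types = c("full", "diagonal", "tied", "spherical"),
                              n_init = 10L, seed = NULL, cv_seed = 1L) {
  stopifnot(inherits(table, "segment_table"))
  keep <- !table$flags$excluded
  if (!is.null(groups) && length(groups) != nrow(table$features))
    stop_schema("groups length mismatch")
  sel <- keep
  if (!is.null(fit_on)) {
    if (is.null(groups)) stop_config("fit_on requires groups")
    sel <- keep & groups %in% fit_on
  }
  X <- table$features[sel, , drop = FALSE]
  zs <- zscore_fit_apply(X)
  p <- prcomp(zs$x, center = FALSE, scale. = FALSE)
  if (identical(n_pc, "cv")) {
    pc_grid <- pc_grid[pc_grid <= min(dim(zs$x)) - 1L]
    n_pc <- as.integer(select_n_pcs_cv(zs$x, pc_grid, seed = cv_seed))
  }
  rot <- p$rotation[, seq_len(n_pc), drop = FALSE]
  Z <- zs$x %*% rot
  model <- fit_gmm_grid(Z, K_range = K_range, cov_types = cov_types,
                        n_init = n_init, seed = seed)
  model$scaler <- zs$scaler
  model$pca <- list(rotation = rot, n_pc = n_pc)
  model$train <- X
  model$train_groups <- if (!is.null(groups)) groups[sel] else NULL
  model$hyper <- list(K_range = K_range, cov_types = cov_types,
                      n_init = n_init)
  model
}

# refit with frozen hyperparameters (same K, covariance type, n_pc) on a
# subset of the stored training rows
refit_cluster_model <- function(model, rows) {
  X <- model$train[rows, , drop = FALSE]
  zs <- zscore_fit_apply(X)
  p <- prcomp(zs$x, center = FALSE, scale. = FALSE)
  rot <- p$rotation[, seq_len(model$pca$n_pc), drop = FALSE]
  Z <- zs$x %*% rot
  sub <- fit_gmm_grid(Z, K_range = model$K, cov_types = model$cov_type,
                      n_init = model$fit_info$n_init)
  sub$scaler <- zs$scaler
  sub$pca <- list(rotation = rot, n_pc = model$pca$n_pc)
  sub
}

#' Score under a reference ("sham") model
#'
#' The mean mixture log-likelihood of a group's segments under a reference
#' Gaussian mixture fitted on healthy animals: low values flag recordings
#' poorly explained by the healthy behavioral repertoire.  For groups listed
#' in `loo_groups` (typically the reference animals themselves), the
#' reference is refitted with identical hyperparameters on the training set
#' excluding that group before scoring, preventing in-sample optimism.
#'
#' @param reference a [fit_cluster_model()] result.
#' @param table a [extract_features()] result (scored through the
#'   reference's scaler + PCA), or a plain projected matrix.
#' @param groups per-segment group labels.
#' @param loo_groups subset of groups to score leave-one-out.
#' @return data.frame with one row per group: `group`, `susm` (mean
#'   log-likelihood), `n` and `loo`.
#' @export
susm <- function(reference, table, groups, loo_groups = character()) {
  m_all <- if (inherits(table, "segment_table")) nrow(table$features) else nrow(table)
  if (length(groups) != m_all) stop_schema("groups length mismatch")
  absent <- setdiff(loo_groups, groups)
  if (length(absent))
    stop_value("group(s) absent from the data: %s", paste(absent, collapse = ", "))
  asg <- assign_segments(reference, table)
  res <- lapply(unique(groups), function(g) {
    rows <- which(groups == g & !is.na(asg$loglik))
    if (!length(rows)) stop_value("group '%s' has no scoreable segments", g)
    loo <- g %in% loo_groups
    if (loo) {
      if (is.null(reference$train_groups))
        stop_config("leave-one-out scoring requires a model fitted with groups")
      train_rows <- which(reference$train_groups != g)
      if (!length(train_rows)) stop_value("leave-one-out leaves no training data for '%s'", g)
      sub <- refit_cluster_model(reference, train_rows)
      X <- if (inherits(table, "segment_table"))
        table$features[rows, , drop = FALSE] else table[rows, , drop = FALSE]
      Xp <- sweep(sweep(X, 2, sub$scaler$center), 2, sub$scaler$scale, "/") %*%
        sub$pca$rotation
      val <- mean(gmm_logdensity(sub, Xp))
    } else {
      val <- mean(asg$loglik[rows])
    }
    data.frame(group = g, susm = val, n = length(rows), loo = loo)
  })
  do.call(rbind, res)
}

#' Per-group cluster usage
#'
#' Fraction of segments (and of recording duration) each group spends in
#' each cluster.  Excluded segments are dropped by default
#' (`include_outliers = FALSE`); with `include_outliers = TRUE` they are
#' tallied as the extra category `"OUTLIER"`.  Percentages sum to 100 per
#' group under either convention.
#'
#' @param assign a [assign_segments()] result.
#' @param groups per-segment group labels.
#' @param durations optional per-segment durations (for the duration-based
#'   usage).
#' @param include_outliers tally excluded segments as their own category?
#' @return data.frame with `group`, `cluster`, `pct_segments` and
#'   optionally `pct_duration`.
#' @export
cluster_usage <- function(assign, groups, durations = NULL,
                          include_outliers = FALSE) {
  lab <- assign$labels
  if (length(groups) != length(lab)) stop_schema("groups length mismatch")
  lab_chr <- ifelse(is.na(lab), "OUTLIER", as.character(lab))
  keep <- if (include_outliers) rep(TRUE, length(lab)) else !is.na(lab)
  lev <- c(as.character(seq_len(assign$K)), if (include_outliers) "OUTLIER")
  res <- lapply(unique(groups), function(g) {
    i <- which(groups == g & keep)
    tab <- table(factor(lab_chr[i], levels = lev))
    out <- data.frame(group = g, cluster = names(tab),
                      pct_segments = 100 * as.numeric(tab) / max(1L, length(i)))
    if (!is.null(durations)) {
      dsum <- tapply(durations[i], factor(lab_chr[i], levels = lev), sum,
                     default = 0)
      out$pct_duration <- 100 * as.numeric(dsum) / max(sum(durations[i]), 1e-12)
    }
    out
  })
  do.call(rbind, res)
}

#' Clusters overused relative to a reference group
#'
#' @param usage a [cluster_usage()] result.
#' @param reference_group group to compare against.
#' @param margin percentage-point threshold (default 5).
#' @return data.frame of (group, cluster) pairs whose segment usage exceeds
#'   the reference by more than `margin` points.
#' @export
overused_clusters <- function(usage, reference_group, margin = 5) {
  ref <- usage[usage$group == reference_group, c("cluster", "pct_segments")]
  names(ref)[2] <- "ref_pct"
  x <- merge(usage[usage$group != reference_group, ], ref, by = "cluster")
  x <- x[x$pct_segments - x$ref_pct > margin, ]
  x[order(x$group, -x$pct_segments), c("group", "cluster", "pct_segments", "ref_pct")]
}
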