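# pipeline: end-to-end orchestration with per-stage artifacts and resume.

#' Pipeline configuration
#'
#' Bundles every stage parameter.  Defaults are the reference operating
#' point for rat-style recordings: CPD penalty 14 (the mouse configuration
#' uses 9) on z-scored `aG` + `omega`, outlier threshold 35 on robustly
#' rescaled features, wet-dog-shake thresholds 2 g / 1000 deg/s, immobility
#' threshold 20 deg/s after 100 ms Gaussian smoothing, mixture grid
#' K = 5..100 over all four covariance types with 10 initializations, and
#' attitude-filter variances `var_acc = 0.002`, `var_gyr = 0.75`.
#'
#' @param ... named overrides of the defaults listed above (see the
#'   source for the complete set).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    # preprocess
    var_acc = 0.002, var_gyr = 0.75,
    # segmentation
    penalty = 14, target_median_s = NULL, penalty_bracket = c(0.5, 200),
    channels = c("aG", "omega"), min_size_s = 0.03, window_s = NULL,
    # features / outliers
    cwt_freqs = seq(1, 20, by = 0.5), cwt_omega0 = 6,
    rescale_threshold = 35, wds_acc = 2, wds_gyr = 1000,
    immobility_sigma_s = 0.1, immobility_thresh = 20,
    # clustering
    n_pc = "cv", pc_grid = c(2, 5, 10, 20, 30), K_range = 5:100,
    cov_types = c("full", "diagonal", "tied", "spherical"), n_init = 10L,
    fit_on = NULL,
    # sequence model
    hmm_S_range = 2:20, hmm_n_fits = 10L,
    # seeds
    seed = 7L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop_config("unknown config field(s): %s", paste(bad, collapse = ", "))
  structure(modifyList(defaults, over), class = "pipeline_config")
}

config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        null = "null")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full pipeline
#'
#' Executes preprocess -> segment -> featurize/flag -> cluster -> HMM ->
#' metrics on one recording, writing one artifact file per stage into
#' `out_dir` (JSON/CSV).  Stages whose artifact already exists are loaded
#' instead of recomputed, so deleting a single artifact resumes the run
#' from that stage.  Every run is stamped (config hash + seed) in
#' `report.json`; a repeated clean run with the same config reproduces the
#' assignment file byte for byte.
#'
#' @param rec an [imu_recording()] (or path to a CSV readable by
#'   [read_recording()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param groups optional per-segment grouping is not known before
#'   segmentation, so groups are given as a function
#'   `(bounds, rate_hz) -> labels` or left `NULL` (single group).
#' @return invisible list with all in-memory stage results (`kin`, `seg`,
#'   `table`, `model`, `assign`, `hmm`, `metrics`, `paths`).
#' @export
run_pipeline <- function(rec, config = pipeline_config(), out_dir,
                         groups = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(rec)) rec <- read_recording(rec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  paths <- list(seg = pth("segments.json"), features = pth("features.csv"),
                flags = pth("flags.csv"), model = pth("model.json"),
                assign = pth("assignment.csv"), hmm = pth("hmm.json"),
                ethogram = pth("ethogram.csv"), metrics = pth("metrics.csv"),
                report = pth("report.json"))

  # preprocess (cheap; recomputed every run, not persisted)
  kin <- estimate_attitude(rec, var_acc = config$var_acc,
                           var_gyr = config$var_gyr)

  # segmentation
  if (file.exists(paths$seg)) {
    sj <- jsonlite::read_json(paths$seg, simplifyVector = TRUE)
    seg <- segmentation(sj$boundaries, rec$rate_hz)
    penalty <- sj$penalty
  } else {
    x <- cpd_input(kin, config$channels)
    penalty <- config$penalty
    if (!is.null(config$target_median_s)) {
      cal_series <- if (!is.null(config$window_s))
        x[seq_len(min(nrow(x), as.integer(config$window_s * rec$rate_hz))), ,
          drop = FALSE] else x
      penalty <- as.numeric(calibrate_penalty(
        cal_series, config$target_median_s, rec$rate_hz,
        bracket = config$penalty_bracket,
        params = cpd_params(bandwidth = "median",
                            min_size_s = config$min_size_s,
                            channels = config$channels)))
    }
    par <- cpd_params(penalty = penalty, min_size_s = config$min_size_s,
                      channels = config$channels)
    seg <- if (!is.null(config$window_s))
      parallel_cpd(x, config$window_s, par, rec$rate_hz)
    else kernel_cpd(x, par, rec$rate_hz)
    jsonlite::write_json(list(boundaries = seg$boundaries, penalty = penalty,
                              gamma = attr(seg, "gamma")),
                         paths$seg, auto_unbox = TRUE, digits = NA)
  }

  # features + flags
  spec <- feature_spec(freqs = config$cwt_freqs, omega0 = config$cwt_omega0)
  if (file.exists(paths$features) && file.exists(paths$flags)) {
    feats <- as.matrix(read.csv(paths$features, check.names = FALSE))
    flags <- read.csv(paths$flags)
    flags$outlier <- as.logical(flags$outlier)
    flags$wet_dog_shake <- as.logical(flags$wet_dog_shake)
    flags$wds_neighbor <- as.logical(flags$wds_neighbor)
    flags$excluded <- as.logical(flags$excluded)
    table <- structure(list(features = feats, names = colnames(feats),
                            bounds = segment_bounds(seg), flags = flags,
                            rate_hz = rec$rate_hz, spec = spec),
                       class = "segment_table")
  } else {
    table <- extract_features(kin, seg, spec)
    table <- flag_outliers(table, config$rescale_threshold, config$wds_acc,
                           config$wds_gyr)
    write.csv(as.data.frame(table$features), paths$features, row.names = FALSE)
    write.csv(table$flags, paths$flags, row.names = FALSE)
  }

  grp <- if (is.function(groups)) groups(table$bounds, rec$rate_hz) else groups

  # clustering
  if (file.exists(paths$model) && file.exists(paths$assign)) {
    model <- model_from_json(paths$model)
    adf <- read.csv(paths$assign)
    assign <- structure(list(
      labels = ifelse(adf$cluster == "OUTLIER", NA_integer_,
                      suppressWarnings(as.integer(adf$cluster))),
      posteriors = NULL, loglik = adf$loglik, K = model$K
    ), class = "cluster_assignment")
    assign$posteriors <- matrix(NA_real_, nrow(adf), model$K)
  } else {
    model <- fit_cluster_model(table, groups = grp, fit_on = config$fit_on,
                               n_pc = config$n_pc, pc_grid = config$pc_grid,
                               K_range = config$K_range,
                               cov_types = config$cov_types,
                               n_init = config$n_init, seed = config$seed,
                               cv_seed = config$seed)
    assign <- assign_segments(model, table)
    model_to_json(model, paths$model)
    adf <- data.frame(
      segment_id = seq_along(assign$labels),
      cluster = ifelse(is.na(assign$labels), "OUTLIER", assign$labels),
      posterior_max = apply(assign$posteriors, 1, function(r)
        if (all(is.na(r))) NA_real_ else max(r)),
      loglik = assign$loglik)
    write.csv(adf, paths$assign, row.names = FALSE)
  }

  # sequence model: outliers become one extra symbol (M = K + 1)
  symbols <- ifelse(is.na(assign$labels), model$K + 1L, assign$labels)
  if (file.exists(paths$hmm)) {
    hj <- jsonlite::read_json(paths$hmm, simplifyVector = TRUE)
    hmm <- hmm_model(hj$initial, hj$transition, hj$emission)
    hmm$fit_info <- hj$fit_info
  } else {
    hmm <- fit_hmm_grid(symbols, S_range = config$hmm_S_range,
                        M = model$K + 1L, n_fits = config$hmm_n_fits,
                        seed = config$seed)
    jsonlite::write_json(list(initial = hmm$initial,
                              transition = hmm$transition,
                              emission = hmm$emission,
                              fit_info = hmm$fit_info[c("loglik", "bic")]),
                         paths$hmm, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    post <- state_posteriors(hmm, symbols)
    eth <- data.frame(segment_id = seq_along(symbols),
                      cluster = ifelse(is.na(assign$labels), "OUTLIER",
                                       assign$labels),
                      state = max.col(post, ties.method = "first"),
                      posterior_max = apply(post, 1, max))
    write.csv(eth, paths$ethogram, row.names = FALSE)
  }

  # metrics
  if (!file.exists(paths$metrics)) {
    sn <- sniffing_score(table)
    met <- data.frame(segment_id = seq_len(nrow(table$features)),
                      duration_s = table$bounds$length / rec$rate_hz,
                      roll = table$features[, "tilt_roll"],
                      pitch = table$features[, "tilt_pitch"],
                      net_speed = table$features[, "head_net_speed"],
                      sniff_phi = sn$phi,
                      immobile_fraction = table$flags$immobile_fraction)
    write.csv(met, paths$metrics, row.names = FALSE)
  }

  report <- list(config = unclass(config), config_hash = config_hash(config),
                 seed = config$seed, n_samples = n_samples(rec),
                 n_segments = n_segments(seg),
                 median_duration_s = median(table$bounds$length) / rec$rate_hz,
                 n_excluded = sum(table$flags$excluded),
                 K = model$K, cov_type = model$cov_type,
                 n_pc = model$pca$n_pc, hmm_states = hmm$S)
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA)

  invisible(list(kin = kin, seg = seg, table = table, model = model,
                 assign = assign, hmm = hmm, paths = paths,
                 report = report))
}

model_to_json <- function(model, path) {
  jsonlite::write_json(list(
    weights = model$weights, means = model$means,
    covariances = lapply(seq_len(model$K), function(k) model$covariances[, , k]),
    cov_type = model$cov_type, K = model$K, d = model$d,
    scaler = model$scaler,
    pca = list(rotation = model$pca$rotation, n_pc = model$pca$n_pc),
    fit_info = model$fit_info[c("bic", "loglik", "n_params")]
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
}

model_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cov <- array(NA_real_, c(j$d, j$d, j$K))
  for (k in seq_len(j$K)) cov[, , k] <- j$covariances[[k]]
  structure(list(weights = j$weights, means = matrix(j$means, j$K, j$d),
                 covariances = cov, cov_type = j$cov_type, K = j$K, d = j$d,
                 scaler = list(center = j$scaler$center, scale = j$scaler$scale),
                 pca = list(rotation = matrix(j$pca$rotation,
                                              ncol = j$pca$n_pc),
                            n_pc = j$pca$n_pc),
                 train = NULL, train_groups = NULL, fit_info = j$fit_info),
            class = "cluster_model")
}
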