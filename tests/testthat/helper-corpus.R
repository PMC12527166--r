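# Lazily computed, cached artifacts of the standard synthetic corpus
# (30 min at 300 Hz, seed 0), shared by the corpus-level tests.

.corpus_cache <- new.env(parent = emptyenv())

corpus_base <- function() {
  if (is.null(.corpus_cache$base)) {
    g <- generate_imu(default_corpus(seed = 0))
    kin <- estimate_attitude(g$recording)
    x <- cpd_input(kin)
    .corpus_cache$base <- list(g = g, kin = kin, x = x)
  }
  .corpus_cache$base
}

# calibrated-penalty segmentation (350 ms target median, calibrated on the
# first five minutes) and its flagged feature table
corpus_calibrated <- function() {
  if (is.null(.corpus_cache$cal)) {
    b <- corpus_base()
    lam <- calibrate_penalty(b$x[1:90000, ], 0.35, 300, bracket = c(0.5, 200))
    seg <- kernel_cpd(b$x, cpd_params(penalty = as.numeric(lam)), 300)
    tab <- flag_outliers(extract_features(b$kin, seg))
    .corpus_cache$cal <- list(lam = as.numeric(lam), seg = seg, tab = tab,
                              tl = truth_labels_for(b$g$truth, seg))
  }
  .corpus_cache$cal
}

boundary_recall <- function(seg, truth, tol_samples = 15L) {
  planted <- truth$boundaries[-c(1, length(truth$boundaries))]
  found <- seg$boundaries
  mean(vapply(planted, function(b) any(abs(found - b) <= tol_samples),
              logical(1)))
}
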