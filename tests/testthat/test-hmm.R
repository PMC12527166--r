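# categorical HMM: forward-backward, Baum-Welch, model selection, splitting

planted_hmm <- function() {
  hmm_model(
    initial = c(1, 0, 0),
    transition = rbind(c(0.90, 0.05, 0.05),
                       c(0.05, 0.90, 0.05),
                       c(0.05, 0.05, 0.90)),
    emission = rbind(c(0.96, 0.02, 0.02, 0, 0, 0),
                     c(0, 0, 0.02, 0.96, 0.02, 0),
                     c(0.02, 0, 0, 0, 0.02, 0.96)))
}

test_that("stochastic-matrix invariants are enforced and preserved", {
  expect_error(hmm_model(c(0.5, 0.4), diag(2), rbind(c(1, 0), c(0, 1))),
               class = "imuseg_value_error")
  m <- planted_hmm()
  sim <- simulate_hmm(m, 500, seed = 1)
  fit <- fit_hmm(sim$symbols, S = 3, M = 6, n_fits = 3, seed = 2)
  expect_equal(rowSums(fit$transition), rep(1, 3), tolerance = 1e-9)
  expect_equal(rowSums(fit$emission), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(fit$initial), 1, tolerance = 1e-9)
})

test_that("forward-backward matches brute-force path enumeration", {
  m <- planted_hmm()
  set.seed(4)
  for (i in 1:5) {
    T_ <- sample(3:10, 1)
    sym <- simulate_hmm(m, T_, seed = i)$symbols
    brute <- hmm_brute(m, sym)
    fb <- imuseg:::.hmm_forward_backward(m, sym)
    expect_equal(fb$loglik, brute$loglik, tolerance = 1e-9)
    expect_equal(fb$gamma, brute$gamma, tolerance = 1e-9)
  }
  post <- state_posteriors(m, simulate_hmm(m, 50, seed = 9)$symbols)
  expect_equal(rowSums(post), rep(1, 50), tolerance = 1e-9)
})

test_that("deterministic chains give one-hot posteriors and exact transitions", {
  m <- hmm_model(c(1, 0), rbind(c(0, 1), c(1, 0)), diag(2))
  sym <- rep(c(1L, 2L), 10)
  post <- state_posteriors(m, sym)
  expect_equal(post, matrix(rep(c(1, 0, 0, 1), 10), ncol = 2, byrow = TRUE),
               tolerance = 1e-12)
  tr <- transition_summary(sym)
  expect_equal(tr, rbind(c(0, 1), c(1, 0)))
  expect_equal(transition_summary(rep(1L, 5), n_states = 1), rbind(1))
  expect_error(state_posteriors(m, c(1L, 3L)), class = "imuseg_value_error")
})

test_that("Baum-Welch log-likelihood is non-decreasing and BIC finds S", {
  m <- planted_hmm()
  sim <- simulate_hmm(m, 4000, seed = 0)
  fit <- fit_hmm_grid(sim$symbols, S_range = 2:5, M = 6, n_fits = 4, seed = 0)
  expect_equal(fit$S, 3L)
  expect_true(all(diff(fit$fit_info$ll_path) > -1e-6))
  dec <- viterbi(fit, sim$symbols)
  expect_gte(adjusted_rand(dec, sim$states), 0.9)
  # label-permutation invariance of the BIC
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  fit2 <- fit_hmm(perm[sim$symbols], S = 3, M = 6, n_fits = 4, seed = 0)
  fit1 <- fit_hmm(sim$symbols, S = 3, M = 6, n_fits = 4, seed = 0)
  expect_equal(fit1$fit_info$bic, fit2$fit_info$bic, tolerance = 1e-3)
})

test_that("single-symbol sequences fit trivially with a warning", {
  expect_warning(fit <- fit_hmm(rep(1L, 50), S = 1, M = 2, n_fits = 1),
                 "degenerate")
  expect_equal(fit$S, 1L)
})

test_that("dual-context clusters are split by dominant hidden state", {
  # symbol 3 is emitted by both states but in different neighborhoods
  m <- hmm_model(
    initial = c(0.5, 0.5),
    transition = rbind(c(0.95, 0.05), c(0.05, 0.95)),
    emission = rbind(c(0.5, 0, 0.5), c(0, 0.5, 0.5)))
  sim <- simulate_hmm(m, 3000, seed = 2)
  post <- state_posteriors(m, sim$symbols)
  sp <- split_cluster_by_state(3L, post, sim$symbols)
  expect_length(sp$parts, 2L)
  expect_equal(sum(sp$p_state), 1, tolerance = 1e-9)
  truth <- sim$states[sim$symbols == 3L]
  expect_gte(mean(sp$dominant_state == truth), 0.9)
  # single-state emitters give a single part
  sp1 <- split_cluster_by_state(1L, post, sim$symbols)
  expect_length(sp1$parts, 1L)
  expect_error(split_cluster_by_state(9L, post, sim$symbols),
               class = "imuseg_value_error")
})

test_that("transition summaries can exclude self-transitions", {
  s <- c(1L, 1L, 2L, 2L, 1L)
  tr <- transition_summary(s, include_self = FALSE)
  expect_equal(tr, rbind(c(0, 1), c(1, 0)))
  trs <- transition_summary(s, include_self = TRUE)
  expect_equal(rowSums(trs), c(1, 1))
})
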