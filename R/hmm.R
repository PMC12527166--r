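# sequence_model: post-hoc categorical hidden Markov model over the
# cluster-symbol sequence (one symbol per segment; outliers are one extra
# symbol).  Baum-Welch with per-step scaling, BIC model selection over the
# state count.

#' Construct a categorical HMM
#'
#' @param initial length-S initial state distribution.
#' @param transition S x S row-stochastic transition matrix.
#' @param emission S x M row-stochastic emission matrix over M symbols.
#' @return an object of class `hmm_model`.
#' @export
hmm_model <- function(initial, transition, emission) {
  initial <- as.numeric(initial)
  transition <- as.matrix(transition); emission <- as.matrix(emission)
  S <- length(initial)
  if (!all(dim(transition) == c(S, S)) || nrow(emission) != S)
    stop_schema("inconsistent HMM dimensions")
  chk <- function(v) all(abs(v - 1) < 1e-9) && all(unlist(v) >= 0)
  if (abs(sum(initial) - 1) > 1e-9 ||
      any(abs(rowSums(transition) - 1) > 1e-9) ||
      any(abs(rowSums(emission) - 1) > 1e-9))
    stop_value("initial/transition/emission must be (row-)stochastic")
  structure(list(initial = initial, transition = transition,
                 emission = emission, S = S, M = ncol(emission),
                 fit_info = NULL),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat(sprintf("<hmm_model> %d states over %d symbols", x$S, x$M))
  if (!is.null(x$fit_info))
    cat(sprintf("; lnL = %.1f, BIC = %.1f", x$fit_info$loglik, x$fit_info$bic))
  cat("\n")
  invisible(x)
}

# scaled forward-backward; returns alpha, beta, scaling, loglik, gamma, xi
.hmm_forward_backward <- function(model, symbols) {
  S <- model$S; T_ <- length(symbols)
  A <- model$transition; B <- model$emission; p0 <- model$initial
  if (any(symbols < 1L | symbols > model$M))
    stop_value("symbol outside the model alphabet (1..%d)", model$M)
  alpha <- matrix(0, T_, S); beta <- matrix(0, T_, S); cvec <- numeric(T_)
  a <- p0 * B[, symbols[1]]
  cvec[1] <- sum(a)
  if (cvec[1] <= 0) stop_value("impossible symbol at t=1 under the model")
  alpha[1, ] <- a / cvec[1]
  for (t in seq_len(T_)[-1]) {
    a <- (alpha[t - 1, ] %*% A) * B[, symbols[t]]
    cvec[t] <- sum(a)
    if (cvec[t] <= 0) stop_value("impossible symbol at t=%d under the model", t)
    alpha[t, ] <- a / cvec[t]
  }
  beta[T_, ] <- 1
  for (t in rev(seq_len(T_ - 1L))) {
    b <- A %*% (B[, symbols[t + 1]] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(alpha = alpha, beta = beta, scale = cvec, loglik = sum(log(cvec)),
       gamma = gamma)
}

# one Baum-Welch run from a given initialization
.baum_welch <- function(symbols, S, M, init, max_iter = 500L, tol = 1e-4) {
  model <- init
  T_ <- length(symbols)
  ll_path <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    fb <- .hmm_forward_backward(model, symbols)
    ll_path <- c(ll_path, fb$loglik)
    # E-step transition counts, vectorized over time:
    # xi_sum[i,j] = A[i,j] * sum_t alpha[t,i] * B[j,y_{t+1}] beta[t+1,j]/c_{t+1}
    A <- model$transition; B <- model$emission
    xi_sum <- matrix(0, S, S)
    if (T_ > 1L) {
      W <- t(B)[symbols[-1], , drop = FALSE] * fb$beta[-1, , drop = FALSE] /
        fb$scale[-1]
      xi_sum <- A * (t(fb$alpha[-T_, , drop = FALSE]) %*% W)
    }
    # M-step
    p0 <- fb$gamma[1, ]
    Anew <- if (T_ > 1L) xi_sum / pmax(rowSums(xi_sum), 1e-300) else A
    Bnew <- matrix(0, S, M)
    rs <- rowsum(fb$gamma, symbols)
    Bnew[, as.integer(rownames(rs))] <- t(rs)
    Bnew <- Bnew / pmax(rowSums(Bnew), 1e-300)
    model <- hmm_model(p0 / sum(p0), Anew, Bnew)
    if (is.finite(prev) && fb$loglik - prev < tol * abs(prev)) break
    prev <- fb$loglik
  }
  fb <- .hmm_forward_backward(model, symbols)
  model$fit_info <- list(loglik = fb$loglik, ll_path = c(ll_path, fb$loglik),
                         iterations = length(ll_path))
  model
}

# seeded random initialization: emissions from perturbed empirical symbol
# frequencies, transitions near-uniform with a sticky diagonal
.hmm_init <- function(symbols, S, M, sticky = 0.6) {
  freq <- tabulate(symbols, M) / length(symbols)
  B <- matrix(rep(freq, each = S), S, M) *
    matrix(exp(stats::rnorm(S * M, sd = 0.5)), S, M)
  B <- B + 1e-6
  B <- B / rowSums(B)
  A <- matrix((1 - sticky) / max(1, S - 1), S, S)
  diag(A) <- if (S > 1) sticky else 1
  A <- A * matrix(exp(stats::rnorm(S * S, sd = 0.05)), S, S)
  A <- A / rowSums(A)
  hmm_model(rep(1 / S, S), A, B)
}

#' Fit a categorical HMM with multiple restarts
#'
#' @param symbols integer symbol sequence (1..M).
#' @param S number of hidden states.
#' @param M alphabet size (default `max(symbols)`).
#' @param n_fits independent seeded initializations (default 10).
#' @param seed RNG seed.
#' @param max_iter,tol Baum-Welch controls (relative log-likelihood change).
#' @return the best [hmm_model()] by log-likelihood, with `fit_info`
#'   including the BIC `2 lnL - p ln T`,
#'   `p = (S-1) + S(S-1) + S(M-1)`.
#' @export
fit_hmm <- function(symbols, S, M = max(symbols), n_fits = 10L, seed = 1L,
                    max_iter = 500L, tol = 1e-4) {
  symbols <- as.integer(symbols)
  if (length(unique(symbols)) == 1L)
    warning("degenerate single-symbol sequence; the fit is trivial")
  best <- NULL
  set.seed(seed)
  for (i in seq_len(n_fits)) {
    init <- .hmm_init(symbols, S, M)
    fit <- .baum_welch(symbols, S, M, init, max_iter, tol)
    if (is.null(best) || fit$fit_info$loglik > best$fit_info$loglik) best <- fit
  }
  p <- (S - 1) + S * (S - 1) + S * (M - 1)
  best$fit_info$n_params <- p
  best$fit_info$bic <- 2 * best$fit_info$loglik - p * log(length(symbols))
  best$fit_info$seed <- seed
  best$fit_info$n_fits <- n_fits
  best
}

#' Select the HMM state count by BIC
#'
#' Fits [fit_hmm()] for every candidate state count and returns the model
#' maximizing `BIC = 2 lnL - p ln T`.
#'
#' @param symbols integer symbol sequence (1..M).
#' @param S_range candidate state counts.
#' @param M alphabet size.
#' @param n_fits,seed,max_iter,tol passed to [fit_hmm()].
#' @return best [hmm_model()]; attribute `bic_path` holds the BIC per
#'   candidate.
#' @export
fit_hmm_grid <- function(symbols, S_range = 2:12, M = max(symbols),
                         n_fits = 10L, seed = 1L, max_iter = 500L,
                         tol = 1e-4) {
  fits <- lapply(seq_along(S_range), function(i)
    fit_hmm(symbols, S_range[i], M, n_fits, seed + i - 1L, max_iter, tol))
  bics <- vapply(fits, function(f) f$fit_info$bic, numeric(1))
  best <- fits[[which.max(bics)]]
  attr(best, "bic_path") <- setNames(bics, S_range)
  best
}

#' Smoothed state posteriors
#'
#' Forward-backward posterior probability of each hidden state at each
#' position (rows sum to 1).
#'
#' @param model a fitted [hmm_model()].
#' @param symbols integer symbol sequence over the model's alphabet.
#' @return T x S posterior matrix.
#' @export
state_posteriors <- function(model, symbols) {
  .hmm_forward_backward(model, as.integer(symbols))$gamma
}

#' Most likely state path (Viterbi)
#'
#' @param model a fitted [hmm_model()].
#' @param symbols integer symbol sequence.
#' @return integer state sequence of the same length.
#' @export
viterbi <- function(model, symbols) {
  symbols <- as.integer(symbols)
  S <- model$S; T_ <- length(symbols)
  lA <- log(model$transition); lB <- log(model$emission)
  delta <- log(model$initial) + lB[, symbols[1]]
  psi <- matrix(0L, T_, S)
  for (t in seq_len(T_)[-1]) {
    cand <- delta + lA  # S x S: previous state x next state
    psi[t, ] <- max.col(t(cand), ties.method = "first")
    delta <- cand[cbind(psi[t, ], seq_len(S))] + lB[, symbols[t]]
  }
  path <- integer(T_)
  path[T_] <- which.max(delta)
  for (t in rev(seq_len(T_ - 1L))) path[t] <- psi[t + 1L, path[t + 1L]]
  path
}

#' Split a cluster by dominant hidden state
#'
#' Within one cluster, tags every segment with its most probable hidden
#' state (from smoothed posteriors) and aggregates `P(state | cluster)`:
#' clusters emitted by two states in distinct sequence contexts are thereby
#' split into context-resolved sub-clusters.
#'
#' @param cluster_id the cluster (symbol) to split.
#' @param posteriors T x S matrix from [state_posteriors()].
#' @param symbols the symbol sequence the posteriors were computed on.
#' @return list with `parts` (list mapping state id to positions),
#'   `dominant_state` (per-position argmax state) and `p_state`
#'   (`P(state | cluster)`, sums to 1).
#' @export
split_cluster_by_state <- function(cluster_id, posteriors, symbols) {
  pos <- which(symbols == cluster_id)
  if (!length(pos)) stop_value("cluster %s has no segments", cluster_id)
  dom <- max.col(posteriors[pos, , drop = FALSE], ties.method = "first")
  p_state <- colSums(posteriors[pos, , drop = FALSE])
  p_state <- p_state / sum(p_state)
  list(parts = split(pos, dom), dominant_state = dom, p_state = p_state)
}

#' Empirical transition matrix of a decoded sequence
#'
#' Row-stochastic transition frequencies between consecutive elements of a
#' state (or cluster) sequence.  With `include_self = FALSE`,
#' self-transitions are removed before normalization.
#'
#' @param states integer sequence.
#' @param n_states alphabet size (default `max(states)`).
#' @param include_self keep self-transitions (default `TRUE`)?
#' @return n x n row-stochastic matrix (rows with no transitions are 0).
#' @export
transition_summary <- function(states, n_states = max(states),
                               include_self = TRUE) {
  states <- as.integer(states)
  T_ <- length(states)
  counts <- matrix(0, n_states, n_states)
  if (T_ > 1L) {
    from <- states[-T_]; to <- states[-1]
    if (!include_self) { keep <- from != to; from <- from[keep]; to <- to[keep] }
    for (i in seq_along(from)) counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  counts / pmax(rs, 1e-300)
}

#' Simulate a symbol sequence from a categorical HMM
#'
#' @param model an [hmm_model()].
#' @param T_len sequence length.
#' @param seed RNG seed.
#' @return list with `symbols` and `states` (both length `T_len`).
#' @export
simulate_hmm <- function(model, T_len, seed = 1L) {
  set.seed(seed)
  states <- integer(T_len); symbols <- integer(T_len)
  s <- sample.int(model$S, 1L, prob = model$initial)
  for (t in seq_len(T_len)) {
    if (t > 1L) s <- sample.int(model$S, 1L, prob = model$transition[s, ])
    states[t] <- s
    symbols[t] <- sample.int(model$M, 1L, prob = model$emission[s, ])
  }
  list(symbols = symbols, states = states)
}
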