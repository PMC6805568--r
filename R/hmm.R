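# Maximum-likelihood Gaussian hidden Markov model (Baum-Welch + Viterbi),
# used to segment sqrt-transformed NSD series into encamped/transit states.
# Written in-package: the analysis needs only the decoded state path, so a
# small ML implementation with restarts is preferred over a Bayesian fit.

#' Fit a Gaussian hidden Markov model by EM (Baum-Welch)
#'
#' Scaled forward-backward EM with multiple random restarts; the best
#' log-likelihood is kept. Emission standard deviations are floored at a small
#' fraction of the data range to avoid variance collapse.
#'
#' @param x Numeric observation vector (one regular series).
#' @param n_states Number of latent states (default 3).
#' @param n_restarts Random EM initializations (default 10).
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood improves
#'   by less than `tol` or after `max_iter` iterations.
#' @param seed Integer seed controlling the restarts (mandatory for
#'   reproducibility).
#' @return An object of class `gaussian_hmm`: list with `mean`, `sd` (per
#'   state), `trans` (row-stochastic matrix), `init`, `loglik`, `loglik_trace`,
#'   `n_iter`, `converged`, `degenerate`, `posterior` (T x K forward-backward
#'   state probabilities) and `states` (Viterbi path).
#' @export
fit_gaussian_hmm <- function(x, n_states = 3, n_restarts = 10,
                             max_iter = 200, tol = 1e-6, seed) {
  stopifnot(is.numeric(x), length(x) >= n_states)
  if (missing(seed)) abort("fit_gaussian_hmm(): a seed is required")
  x <- as.numeric(x)
  n <- length(x)
  rng <- diff(range(x))
  if (rng < 1e-10) {
    # constant series: no state structure to estimate
    fit <- list(
      mean = rep(x[1], n_states), sd = rep(1e-8, n_states),
      trans = diag(n_states), init = c(1, rep(0, n_states - 1)),
      loglik = NA_real_, loglik_trace = numeric(0), n_iter = 0L,
      converged = TRUE, degenerate = TRUE,
      posterior = matrix(rep(c(1, rep(0, n_states - 1)), each = n), n, n_states),
      states = rep(1L, n), n_states = n_states
    )
    class(fit) <- "gaussian_hmm"
    warn("fit_gaussian_hmm(): constant series; degenerate single-state fallback")
    return(fit)
  }
  sd_floor <- 1e-4 * rng
  best <- NULL
  old_seed <- .save_rng()
  on.exit(.restore_rng(old_seed), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (r in seq_len(n_restarts)) {
    init_means <- quantile(x, probs = seq(0.1, 0.9, length.out = n_states)) +
      rnorm(n_states, 0, 0.1 * rng * (r > 1))
    fit <- .em_gaussian_hmm(x, sort(init_means), n_states, max_iter, tol, sd_floor)
    if (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik)) best <- fit
  }
  best <- .relabel_hmm(best)
  best$degenerate <- FALSE
  best$n_states <- n_states
  dec <- .viterbi(x, best)
  best$states <- dec
  class(best) <- "gaussian_hmm"
  best
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_rng <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}

.em_gaussian_hmm <- function(x, means, K, max_iter, tol, sd_floor) {
  n <- length(x)
  mu <- as.numeric(means)
  sigma <- rep(max(sd(x) / K, sd_floor), K)
  trans <- matrix(0.1 / (K - 1), K, K)
  diag(trans) <- 0.9
  init <- rep(1 / K, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(K), function(k) dnorm(x, mu[k], sigma[k]), numeric(n))
    dens <- pmax(dens, 1e-300)
    fb <- .forward_backward(dens, trans, init)
    ll <- fb$loglik
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_old - 1e-8) {
      # EM guarantees monotone likelihood; a drop signals a numerical issue
      warn(sprintf("EM log-likelihood decreased at iteration %d (%.3g)", it, ll - ll_old))
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- fb$gamma
    xi_sum <- fb$xi_sum
    init <- g[1, ] / sum(g[1, ])
    trans <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    wsum <- colSums(g)
    mu <- colSums(g * x) / wsum
    sigma <- sqrt(colSums(g * (outer(x, mu, "-"))^2) / wsum)
    sigma <- pmax(sigma, sd_floor)
  }
  list(
    mean = mu, sd = sigma, trans = trans, init = init,
    loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
    n_iter = length(ll_trace), converged = converged
  )
}

# scaled forward-backward; dens is T x K emission density matrix
.forward_backward <- function(dens, trans, init) {
  n <- nrow(dens)
  K <- ncol(dens)
  alpha <- matrix(0, n, K)
  beta <- matrix(0, n, K)
  cvec <- numeric(n)
  a <- init * dens[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:n) {
    a <- (alpha[t - 1, ] %*% trans) * dens[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta[n, ] <- 1
  for (t in (n - 1):1) {
    b <- trans %*% (dens[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  xi_sum <- matrix(0, K, K)
  for (t in seq_len(n - 1)) {
    xi <- (alpha[t, ] %o% (dens[t + 1, ] * beta[t + 1, ])) * trans / cvec[t + 1]
    xi_sum <- xi_sum + xi
  }
  list(loglik = sum(log(cvec)), gamma = gamma, xi_sum = xi_sum)
}

# relabel so that: state 3 = largest emission SD (transiting), remaining two
# encamped states ordered by mean (1 = smaller = summer residency near colony)
.relabel_hmm <- function(fit) {
  K <- length(fit$mean)
  if (K == 3) {
    transit <- which.max(fit$sd)
    encamped <- setdiff(1:3, transit)
    encamped <- encamped[order(fit$mean[encamped])]
    perm <- c(encamped, transit) # perm[new] = old
  } else {
    perm <- order(fit$mean)
  }
  fit$mean <- fit$mean[perm]
  fit$sd <- fit$sd[perm]
  fit$init <- fit$init[perm]
  fit$trans <- fit$trans[perm, perm, drop = FALSE]
  fit
}

.viterbi <- function(x, fit) {
  K <- length(fit$mean)
  n <- length(x)
  logd <- vapply(seq_len(K), function(k) dnorm(x, fit$mean[k], fit$sd[k], log = TRUE), numeric(n))
  logt <- log(pmax(fit$trans, 1e-300))
  delta <- matrix(-Inf, n, K)
  psi <- matrix(0L, n, K)
  delta[1, ] <- log(pmax(fit$init, 1e-300)) + logd[1, ]
  for (t in 2:n) {
    for (k in seq_len(K)) {
      v <- delta[t - 1, ] + logt[, k]
      psi[t, k] <- which.max(v)
      delta[t, k] <- v[psi[t, k]] + logd[t, k]
    }
  }
  states <- integer(n)
  states[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) states[t] <- psi[t + 1, states[t + 1]]
  states
}

#' Decode the most likely state path for new data under a fitted HMM
#'
#' @param fit A `gaussian_hmm` object.
#' @param x Numeric observation vector (same transform/scale as the training
#'   series).
#' @return Integer vector of Viterbi states.
#' @export
decode_states <- function(fit, x) {
  stopifnot(inherits(fit, "gaussian_hmm"))
  if (length(x) == 1) {
    return(which.max(log(pmax(fit$init, 1e-300)) + dnorm(x, fit$mean, fit$sd, log = TRUE)))
  }
  .viterbi(as.numeric(x), fit)
}

#' Forward-backward posterior state probabilities
#'
#' @inheritParams decode_states
#' @return A `length(x)` x `n_states` matrix; rows sum to 1.
#' @export
state_posterior <- function(fit, x) {
  stopifnot(inherits(fit, "gaussian_hmm"))
  n <- length(x)
  K <- length(fit$mean)
  dens <- vapply(seq_len(K), function(k) dnorm(x, fit$mean[k], fit$sd[k]), numeric(n))
  dens <- pmax(matrix(dens, n, K), 1e-300)
  .forward_backward(dens, fit$trans, fit$init)$gamma
}

#' @exportS3Method base::print
print.gaussian_hmm <- function(x, ...) {
  cat(sprintf(
    "Gaussian HMM: %d states, logLik %.2f, %d EM iterations%s\n",
    length(x$mean), x$loglik, x$n_iter,
    if (isTRUE(x$degenerate)) " (degenerate fallback)" else ""
  ))
  print(tibble::tibble(state = seq_along(x$mean), mean = x$mean, sd = x$sd))
  invisible(x)
}

#' @rdname fit_gaussian_hmm
#' @param x A `gaussian_hmm` object.
#' @param ... Unused.
#' @export
tidy.gaussian_hmm <- function(x, ...) {
  tibble::tibble(state = seq_along(x$mean), mean = x$mean, sd = x$sd,
                 stationary = .stationary_dist(x$trans))
}

#' @rdname fit_gaussian_hmm
#' @export
glance.gaussian_hmm <- function(x, ...) {
  K <- length(x$mean)
  npar <- 2 * K + K * (K - 1) + (K - 1)
  tibble::tibble(
    logLik = x$loglik, n_iter = x$n_iter, converged = x$converged,
    degenerate = x$degenerate, AIC = -2 * x$loglik + 2 * npar
  )
}

.stationary_dist <- function(trans) {
  e <- eigen(t(trans))
  v <- abs(Re(e$vectors[, which.min(abs(e$values - 1))]))
  v / sum(v)
}
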