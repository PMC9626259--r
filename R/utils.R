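#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ridge-stabilised logistic regression
#'
#' Fits \eqn{logit P(y=1) = a + b x} by maximising the Bernoulli
#' log-likelihood minus a small quadratic penalty
#' \eqn{\lambda (a^2 + b^2)/2}. The penalty keeps the fit defined under
#' complete separation, which is the expected regime when the two
#' progesterone classes are separated by a concentration gap; for
#' well-mixed data the fit agrees with [stats::glm()] to numerical
#' precision.
#'
#' @param x numeric covariate.
#' @param y 0/1 response.
#' @param lambda ridge penalty; default `1e-4` is small enough that the
#'   fitted curve saturates well beyond the 0.1%/99.9% call thresholds
#'   outside the class gap, yet keeps coefficients finite.
#' @param weights optional case weights.
#' @return list with `coef` (intercept, slope) and `converged`.
#' @keywords internal
fit_logistic_ridge <- function(x, y, lambda = 1e-4, weights = NULL) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  w <- weights %||% rep(1, length(x))
  X <- cbind(1, x)
  negll <- function(beta) {
    eta <- drop(X %*% beta)
    # -loglik, numerically stable: log(1+exp(eta)) - y*eta
    -sum(w * (y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))) +
      lambda * sum(beta^2) / 2
  }
  grad <- function(beta) {
    p <- stats::plogis(drop(X %*% beta))
    -drop(crossprod(X, w * (y - p))) + lambda * beta
  }
  fit <- stats::optim(c(0, 0), negll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  list(coef = c(intercept = fit$par[1], slope = fit$par[2]),
       converged = fit$convergence == 0)
}

#' Adaptive random-walk Metropolis sampler
#'
#' Gaussian random-walk Metropolis with a global step-size adapted
#' during warm-up toward an acceptance rate of ~0.30, run as several
#' independent chains. Used for the low-dimensional posteriors in this
#' package (2-parameter logistic curves, 3-parameter photogrammetric
#' error model); convergence is summarised by split-chain R-hat.
#'
#' @param log_post function of the parameter vector returning the
#'   unnormalised log posterior density (`-Inf` allowed).
#' @param init numeric initial value (shared start, jittered per chain).
#' @param prop_sd proposal standard deviations per coordinate.
#' @param n_draws retained draws per chain (post warm-up).
#' @param warmup warm-up iterations per chain (discarded).
#' @param chains number of chains.
#' @return list with `draws` (matrix, chains stacked), `accept_rate`,
#'   `rhat` (per coordinate), `chains`, `n_draws`.
#' @keywords internal
mh_sample <- function(log_post, init, prop_sd, n_draws = 1000,
                      warmup = 500, chains = 4) {
  d <- length(init)
  all_draws <- vector("list", chains)
  acc_tot <- 0
  for (ch in seq_len(chains)) {
    theta <- init + stats::rnorm(d, 0, prop_sd / 4)
    lp <- log_post(theta)
    if (!is.finite(lp)) { theta <- init; lp <- log_post(theta) }
    scale <- 1
    Ct <- diag(prop_sd, d)           # proposal Cholesky factor
    draws <- matrix(NA_real_, n_draws, d)
    hist <- matrix(NA_real_, warmup, d)
    n_acc <- 0; n_try <- 0
    total <- warmup + n_draws
    for (it in seq_len(total)) {
      prop <- theta + scale * drop(Ct %*% stats::rnorm(d))
      lp_prop <- log_post(prop)
      n_try <- n_try + 1
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; n_acc <- n_acc + 1
      }
      if (it <= warmup) {
        hist[it, ] <- theta
        if (it %% 50 == 0) {
          scale <- scale * exp(n_acc / n_try - 0.30)
          n_acc <- 0; n_try <- 0
          # adapt the proposal shape to the warm-up sample covariance
          if (it >= max(200, warmup / 2) && it %% 200 == 0) {
            S <- stats::cov(hist[seq_len(it), , drop = FALSE])
            S <- S + diag(1e-10 + 1e-6 * diag(S), d)
            ch_try <- try(chol(S), silent = TRUE)
            if (!inherits(ch_try, "try-error")) {
              Ct <- t(ch_try) * (2.4 / sqrt(d))
              scale <- 1
            }
          }
        }
      }
      if (it > warmup) draws[it - warmup, ] <- theta
    }
    all_draws[[ch]] <- draws
    acc_tot <- acc_tot + n_acc / max(n_try, 1)
  }
  out <- do.call(rbind, all_draws)
  list(draws = out,
       accept_rate = acc_tot / chains,
       rhat = vapply(seq_len(d), function(j) {
         split_rhat(lapply(all_draws, function(m) m[, j]))
       }, numeric(1)),
       chains = chains, n_draws = n_draws)
}

# split-chain potential scale reduction factor
#' @keywords internal
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# derive a stage seed from a master seed (counter-based, < 2^31)
#' @keywords internal
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 7919 + counter * 104729) %% 2147483647)
}
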