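#' Maximum-likelihood sex-at-length and maturity-at-length curves
#'
#' Fits two logistic curves to catch records by individual-level
#' Bernoulli likelihood: `P(female | L)` over all records and
#' `P(mature | L)` over female records, reporting also the product
#' curve `q(L) = p_F(L) * p_M(L)` — the probability that an animal of
#' length L is a mature female. A binned-proportion fit is available
#' for comparison with display binnings.
#'
#' @param catch data.frame: `length` (m), `sex` (`"M"`/`"F"`), `mature`
#'   (logical, females; NA allowed for males).
#' @param binned if `TRUE`, fit binomial GLMs to proportions in
#'   `bin_width`-m length bins instead of individual records.
#' @param bin_width bin width in metres for the binned mode.
#' @return list of class `maturity_ml`: `sex_at_length` and
#'   `maturity_at_length` (each `c(alpha=, beta=)`), `L50` (m),
#'   `product` (function of length), `separation` (logical).
#' @export
fit_curves_ml <- function(catch, binned = FALSE, bin_width = 0.5) {
  check_catch(catch)
  if (any(catch$length < 3 | catch$length > 12)) {
    warning("catch lengths outside the 3-12 m plausibility band")
  }
  fit_one <- function(x, y) {
    if (binned) {
      bins <- floor(x / bin_width) * bin_width + bin_width / 2
      agg <- stats::aggregate(cbind(k = y, n = 1) ~ bins,
                              data.frame(bins = bins, y = y), sum)
      fit <- stats::glm(cbind(k, n - k) ~ bins, family = stats::binomial(),
                        data = agg)
    } else {
      fit <- suppressWarnings(
        stats::glm(y ~ x, family = stats::binomial()))
    }
    sep <- !fit$converged || max(abs(stats::coef(fit))) > 50
    if (sep) {
      warning("possible separation in logistic fit; using ridge-penalised estimate")
      co <- fit_logistic_ridge(x, y, lambda = 1e-3)$coef
      list(coef = c(alpha = unname(co[["intercept"]]),
                    beta = unname(co[["slope"]])), separation = TRUE)
    } else {
      co <- stats::coef(fit)
      list(coef = c(alpha = unname(co[1]), beta = unname(co[2])),
           separation = FALSE)
    }
  }
  sexfit <- fit_one(catch$length, as.integer(catch$sex == "F"))
  fem <- catch[catch$sex == "F" & !is.na(catch$mature), ]
  matfit <- fit_one(fem$length, as.integer(fem$mature))
  sx <- sexfit$coef; mt <- matfit$coef
  structure(list(sex_at_length = sx, maturity_at_length = mt,
                 L50 = -mt[["alpha"]] / mt[["beta"]],
                 product = function(L) {
                   stats::plogis(sx[["alpha"]] + sx[["beta"]] * L) *
                     stats::plogis(mt[["alpha"]] + mt[["beta"]] * L)
                 },
                 separation = sexfit$separation || matfit$separation),
            class = "maturity_ml")
}

#' @keywords internal
check_catch <- function(catch) {
  stopifnot(all(c("length", "sex", "mature") %in% names(catch)))
  if (!any(catch$sex == "F") || !any(catch$sex == "M")) {
    stop("catch must contain both sexes")
  }
  fem <- catch$mature[catch$sex == "F"]
  if (length(unique(stats::na.omit(fem))) < 2) {
    stop("catch must contain both mature and immature females")
  }
  invisible(TRUE)
}

#' MCMC posterior for the sex-at-length and maturity-at-length curves
#'
#' Samples the posterior of the four logistic parameters
#' (alpha_F, beta_F, alpha_M, beta_M) under independent Bernoulli
#' likelihoods and weak Normal(0, 10^2) priors, via adaptive
#' random-walk Metropolis initialised at the ML fit. The female length
#' at 50% maturity `L50 = -alpha_M / beta_M` is derived per draw.
#' `prior_only = TRUE` drops the likelihood (debug mode: the posterior
#' should reproduce the prior).
#'
#' @param catch catch data.frame as in [fit_curves_ml()].
#' @param draws retained draws per chain.
#' @param warmup warm-up iterations per chain.
#' @param chains chains.
#' @param seed RNG seed.
#' @param prior_only drop the likelihood term.
#' @return object of class `maturity_posterior`: `draws` (matrix with
#'   columns `alpha_F`, `beta_F`, `alpha_M`, `beta_M`, `L50`),
#'   `diagnostics`, `ml` (the ML fit, NULL in prior-only mode).
#' @export
fit_curves_mcmc <- function(catch, draws = 1000, warmup = 500,
                            chains = 4, seed = 1L, prior_only = FALSE) {
  check_catch(catch)
  set.seed(seed)
  # proposals are whitened with the ML covariance so the correlated
  # (intercept, slope) posterior mixes well under a diagonal random walk
  run_curve <- function(x, y, init) {
    if (prior_only) {
      Ct <- diag(2) * 10
    } else {
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      V <- stats::vcov(fit)
      if (!all(is.finite(V))) V <- diag(c(1, 0.1))
      Ct <- t(chol(V))
    }
    log_post_phi <- function(phi) {
      th <- init + drop(Ct %*% phi)
      lp <- sum(stats::dnorm(th, 0, 10, log = TRUE))
      if (!prior_only) {
        eta <- th[1] + th[2] * x
        lp <- lp + sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
      }
      lp
    }
    fit <- mh_sample(log_post_phi, c(0, 0), prop_sd = c(1.7, 1.7),
                     n_draws = draws, warmup = warmup, chains = chains)
    fit$draws <- t(init + Ct %*% t(fit$draws))
    fit
  }
  ml <- if (prior_only) NULL else fit_curves_ml(catch)
  fem <- catch[catch$sex == "F" & !is.na(catch$mature), ]
  init_s <- if (prior_only) c(0, 0) else unname(ml$sex_at_length)
  init_m <- if (prior_only) c(0, 1) else unname(ml$maturity_at_length)
  fs <- run_curve(catch$length, as.integer(catch$sex == "F"), init_s)
  fm <- run_curve(fem$length, as.integer(fem$mature), init_m)
  dm <- cbind(alpha_F = fs$draws[, 1], beta_F = fs$draws[, 2],
              alpha_M = fm$draws[, 1], beta_M = fm$draws[, 2])
  L50 <- -dm[, "alpha_M"] / dm[, "beta_M"]
  bad <- !is.finite(L50)
  if (any(bad)) { dm <- dm[!bad, , drop = FALSE]; L50 <- L50[!bad] }
  structure(list(draws = cbind(dm, L50 = L50),
                 diagnostics = list(
                   rhat = c(alpha_F = fs$rhat[1], beta_F = fs$rhat[2],
                            alpha_M = fm$rhat[1], beta_M = fm$rhat[2]),
                   accept_rate = c(sex = fs$accept_rate,
                                   maturity = fm$accept_rate)),
                 ml = ml),
            class = "maturity_posterior")
}

#' @export
print.maturity_posterior <- function(x, ...) {
  q <- stats::quantile(x$draws[, "L50"], c(0.025, 0.5, 0.975))
  cat("Sex-at-length / maturity-at-length posterior\n")
  cat(sprintf("  draws: %d; max split R-hat %.3f\n",
              nrow(x$draws), max(x$diagnostics$rhat)))
  cat(sprintf("  L50: %.2f m (95%% CrI %.2f-%.2f)\n", q[2], q[1], q[3]))
  invisible(x)
}

#' @keywords internal
posterior_curves <- function(posterior, lengths) {
  d <- posterior$draws
  pF <- stats::plogis(outer(d[, "alpha_F"], rep(1, length(lengths))) +
                        outer(d[, "beta_F"], lengths))
  pM <- stats::plogis(outer(d[, "alpha_M"], rep(1, length(lengths))) +
                        outer(d[, "beta_M"], lengths))
  list(pF = pF, pM = pM)
}

#' Posterior proportion of mature females in a length sample
#'
#' For each posterior draw, the expected proportion of the sampled
#' females that are mature given only the length sample:
#' `P_mat = sum_i p_F(L_i) p_M(L_i) / sum_i p_F(L_i)` — the
#' female-weighted mean of the maturity curve over the observed
#' lengths.
#'
#' @param lengths whale lengths in metres (e.g. photogrammetric
#'   posterior means).
#' @param posterior a `maturity_posterior`.
#' @return list of class `prop_mature`: `draws` (per-draw fractions),
#'   `median`, `ci` (2.5/97.5 percentiles).
#' @export
proportion_mature_females <- function(lengths, posterior) {
  if (length(lengths) < 1) stop("lengths must be non-empty")
  cur <- posterior_curves(posterior, lengths)
  denom <- rowSums(cur$pF)
  if (any(denom == 0)) stop("degenerate draw: sum of female probabilities is zero")
  draws <- rowSums(cur$pF * cur$pM) / denom
  structure(list(draws = draws, median = stats::median(draws),
                 ci = unname(stats::quantile(draws, c(0.025, 0.975)))),
            class = "prop_mature")
}

#' Posterior adjusted sex ratio from a length sample
#'
#' Per draw, the expected female fraction is the mean of
#' `p_F(L_i)` over the length sample and the adjusted ratio is
#' `(1 - f) / f` males per female.
#'
#' @inheritParams proportion_mature_females
#' @return list: `draws` (M:F per draw), `median`, `ci`,
#'   `female_fraction` (median).
#' @export
adjusted_sex_ratio <- function(lengths, posterior) {
  if (length(lengths) < 1) stop("lengths must be non-empty")
  cur <- posterior_curves(posterior, lengths)
  f <- rowMeans(cur$pF)
  if (any(f == 0)) stop("degenerate draw: female fraction is zero")
  ratio <- (1 - f) / f
  list(draws = ratio, median = stats::median(ratio),
       ci = unname(stats::quantile(ratio, c(0.025, 0.975))),
       female_fraction = stats::median(f))
}

#' Maturity-corrected pregnancy-rate distribution
#'
#' Converts the pregnancy rate over all assayed females into a rate
#' over mature females by dividing, per posterior draw, the estimated
#' pregnant count by the expected number of mature females
#' `P_mat * n`. The pregnant count is either a fixed classified count
#' or a [pregnancy_rate()] estimate whose bootstrap replicates are
#' paired with the maturity draws by independent resampling. Values
#' above 1 are retained — the distribution legitimately has a tail
#' above 100% when the proportion mature is uncertain.
#'
#' @param n_females_assayed number of assayed females.
#' @param pregnant a pregnant count (scalar) or a `rate_estimate`.
#' @param prop_mature a `prop_mature` object (or per-draw fractions).
#' @return list of class `demography_estimate`: `draws`, `median`,
#'   `ci`, `n_excluded` (draws with zero mature proportion, dropped).
#' @export
corrected_pregnancy_rate <- function(n_females_assayed, pregnant,
                                     prop_mature) {
  if (n_females_assayed <= 0) stop("n_females_assayed must be positive")
  pm <- if (inherits(prop_mature, "prop_mature")) prop_mature$draws else
    prop_mature
  n_draws <- length(pm)
  preg_count <- if (inherits(pregnant, "rate_estimate")) {
    sample(pregnant$per_replicate_rates, n_draws, replace = TRUE) *
      pregnant$n
  } else rep(pregnant, n_draws)
  bad <- pm == 0
  rate <- preg_count[!bad] / (pm[!bad] * n_females_assayed)
  structure(list(draws = rate, median = stats::median(rate),
                 ci = unname(stats::quantile(rate, c(0.025, 0.975))),
                 n_excluded = sum(bad)),
            class = "demography_estimate")
}

#' @export
print.demography_estimate <- function(x, ...) {
  cat(sprintf("Corrected pregnancy rate: median %.1f%% (95%% CrI %.1f-%.1f%%)\n",
              100 * x$median, 100 * x$ci[1], 100 * x$ci[2]))
  if (any(x$draws > 1)) {
    cat(sprintf("  %.1f%% of draws exceed 100%% (uncertain proportion mature)\n",
                100 * mean(x$draws > 1)))
  }
  invisible(x)
}
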