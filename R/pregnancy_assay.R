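#' Adjust progesterone concentration for extraction efficiency
#'
#' Scales each raw concentration to 100% recovery (`raw / efficiency`)
#' and flags samples below the minimum acceptable efficiency, which in
#' the lab protocol triggers re-extraction rather than analysis.
#'
#' @param raw raw concentration(s), ng/g.
#' @param efficiency recovery fraction(s); must lie in (0, 1.5].
#' @param min_efficiency acceptance threshold (default 0.60).
#' @return data.frame: `adjusted` (ng/g), `valid` (logical).
#' @export
#' @examples
#' adjust_for_efficiency(0.80, 0.80)  # adjusted 1.0, valid TRUE
adjust_for_efficiency <- function(raw, efficiency, min_efficiency = 0.60) {
  if (any(efficiency <= 0)) stop("efficiency must be positive")
  if (any(efficiency > 1.5)) stop("efficiency above 150% is implausible")
  data.frame(adjusted = raw / efficiency,
             valid = efficiency >= min_efficiency)
}

#' Intra- and inter-assay coefficients of variation
#'
#' Intra-assay CV: for each replicate group run within one plate,
#' `100 * sd / mean`, averaged over groups. Inter-assay CV: for each
#' sample run on two or more plates, the CV of its per-plate means,
#' averaged over samples.
#'
#' @param replicates data.frame with columns `value`, `plate`, `sample`.
#' @return `c(intra_cv=, inter_cv=)` in percent (`inter_cv` NA when no
#'   sample spans plates).
#' @export
assay_cv <- function(replicates) {
  stopifnot(all(c("value", "plate", "sample") %in% names(replicates)))
  cv <- function(x) {
    m <- mean(x)
    if (m == 0) stop("replicate group mean is zero; CV undefined")
    100 * stats::sd(x) / m
  }
  within <- split(replicates$value,
                  interaction(replicates$sample, replicates$plate, drop = TRUE))
  sizes <- lengths(within)
  if (all(sizes < 2)) stop("need at least one group with >= 2 replicates")
  intra <- mean(vapply(within[sizes >= 2], cv, numeric(1)))
  plate_means <- stats::aggregate(value ~ sample + plate, replicates, mean)
  by_sample <- split(plate_means$value, plate_means$sample)
  multi <- by_sample[lengths(by_sample) >= 2]
  inter <- if (length(multi)) mean(vapply(multi, cv, numeric(1))) else NA_real_
  c(intra_cv = intra, inter_cv = inter)
}

#' Assay parallelism check against the standard curve
#'
#' Regresses response on log2(dilution) separately for the serially
#' diluted sample pool and the assay standards, reports the ratio of
#' slopes (1 = perfect parallelism) and the r-squared of the joint
#' common-slope fit. Parallelism indicates the assay measures the same
#' antigen in the tissue extract as in the standards.
#'
#' @param dilution_series data.frame `dilution`, `response` for the
#'   pooled sample.
#' @param standard_curve same shape, for the standards.
#' @param tolerance acceptable |slope_ratio - 1| (default 0.1).
#' @return list: `slope_ratio`, `r_squared`, `parallel` (logical).
#' @export
parallelism_check <- function(dilution_series, standard_curve,
                              tolerance = 0.1) {
  if (nrow(dilution_series) < 3 || nrow(standard_curve) < 3) {
    stop("need at least 3 dilution points per series")
  }
  slope <- function(d) {
    stats::coef(stats::lm(response ~ log2(dilution), data = d))[[2]]
  }
  s_sample <- slope(dilution_series)
  s_std <- slope(standard_curve)
  if (s_std == 0) stop("standard-curve slope is zero")
  joint <- rbind(cbind(dilution_series, series = "sample"),
                 cbind(standard_curve, series = "standard"))
  fit <- stats::lm(response ~ log2(dilution) + series, data = joint)
  list(slope_ratio = s_sample / s_std,
       r_squared = summary(fit)$r.squared,
       parallel = abs(s_sample / s_std - 1) <= tolerance)
}

#' Build a labelled reference set for the pregnancy model
#'
#' Two modes mirror the two assignment models: `external_reference`
#' passes through a supplied labelled set (e.g. a reference species of
#' known pregnancy status); `self_bounded` labels the cohort's own
#' samples using the concentration bounds observed in a congener of
#' known status — at or below `np_max` not-pregnant, at or above
#' `p_min` pregnant — leaving in-gap samples unlabelled for prediction.
#'
#' @param concentrations efficiency-adjusted progesterone, ng/g.
#' @param mode `"self_bounded"` or `"external_reference"`.
#' @param external labelled data.frame `log10_conc`, `pregnant` (0/1)
#'   for the external mode.
#' @param bounds `c(np_max=, p_min=)` ng/g; defaults 3.43 and 22.84.
#' @return object of class `reference_set`: `labelled` (log10_conc,
#'   pregnant), `unlabelled` (log10_conc), `provenance`, `bounds`.
#' @export
build_reference <- function(concentrations = NULL,
                            mode = c("self_bounded", "external_reference"),
                            external = NULL,
                            bounds = c(np_max = 3.43, p_min = 22.84)) {
  mode <- match.arg(mode)
  if (mode == "external_reference") {
    if (is.null(external)) stop("external mode requires a labelled set")
    labelled <- external[c("log10_conc", "pregnant")]
    unlab <- if (is.null(concentrations)) numeric(0) else
      log10(concentrations)
  } else {
    if (is.null(concentrations)) stop("self_bounded mode requires cohort concentrations")
    stopifnot(all(concentrations > 0))
    lab_np <- concentrations <= bounds[["np_max"]]
    lab_p <- concentrations >= bounds[["p_min"]]
    if (sum(lab_np) < 2 || sum(lab_p) < 2) {
      stop("self_bounded mode needs >= 2 samples in each bound region")
    }
    labelled <- data.frame(
      log10_conc = log10(concentrations[lab_np | lab_p]),
      pregnant = as.integer(lab_p[lab_np | lab_p]))
    unlab <- log10(concentrations[!lab_np & !lab_p])
  }
  if (length(unique(labelled$pregnant)) < 2) {
    stop("reference set must contain both pregnancy classes")
  }
  structure(list(labelled = labelled, unlabelled = unlab,
                 provenance = mode, bounds = bounds),
            class = "reference_set")
}

#' Fit the logistic pregnancy-probability model with bootstrap envelope
#'
#' Logistic regression of pregnancy status on log10 progesterone
#' concentration, plus `B` nonparametric bootstrap refits of the
#' reference records whose coefficient sets define pointwise confidence
#' envelopes. Fits are ridge-stabilised so that completely separated
#' resamples — the normal situation given the concentration gap between
#' classes — still yield finite coefficients; replicates that draw a
#' single class are redrawn.
#'
#' @param reference a [build_reference()] object.
#' @param B bootstrap replicates (default 10000).
#' @param seed RNG seed.
#' @param lambda ridge penalty passed to the fitter.
#' @return object of class `pregnancy_model`: `coef`, `boot_coef`
#'   (B x 2 matrix), `B`, `envelope_mass`, `reference`.
#' @export
fit_pregnancy_model <- function(reference, B = 10000, seed = 1L,
                                lambda = 1e-4) {
  stopifnot(inherits(reference, "reference_set"), B >= 1)
  x <- reference$labelled$log10_conc
  y <- reference$labelled$pregnant
  if (length(unique(y)) < 2) stop("reference set has a single class")
  set.seed(seed)
  point <- fit_logistic_ridge(x, y, lambda)
  if (point$coef[["slope"]] <= 0) {
    warning("fitted slope is not positive; probability should increase with progesterone")
  }
  n <- length(x)
  boot <- matrix(NA_real_, B, 2,
                 dimnames = list(NULL, c("intercept", "slope")))
  for (b in seq_len(B)) {
    for (try in 1:100) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    boot[b, ] <- fit_logistic_ridge(x[idx], y[idx], lambda)$coef
  }
  structure(list(coef = point$coef, boot_coef = boot, B = B,
                 envelope_mass = 0.95, lambda = lambda,
                 reference = reference),
            class = "pregnancy_model")
}

#' @export
print.pregnancy_model <- function(x, ...) {
  cat("Pregnancy probability model (logit p = a + b log10 conc)\n")
  cat(sprintf("  intercept %.3f, slope %.3f; %d bootstrap replicates\n",
              x$coef[["intercept"]], x$coef[["slope"]], x$B))
  cat("  reference:", x$reference$provenance, "with",
      nrow(x$reference$labelled), "labelled records\n")
  invisible(x)
}

#' Predict pregnancy probability with its confidence envelope
#'
#' @param object a `pregnancy_model`.
#' @param conc concentrations, ng/g (> 0).
#' @param ... unused.
#' @return data.frame: `conc`, `prob` (point fit), `ci_low`, `ci_high`
#'   (2.5/97.5 percentiles of the bootstrap replicate probabilities).
#' @export
predict.pregnancy_model <- function(object, conc, ...) {
  stopifnot(all(conc > 0))
  lx <- log10(conc)
  p <- stats::plogis(object$coef[["intercept"]] + object$coef[["slope"]] * lx)
  a <- (1 - object$envelope_mass) / 2
  probs <- stats::plogis(outer(object$boot_coef[, "slope"], lx) +
                           object$boot_coef[, "intercept"])
  qs <- apply(probs, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  data.frame(conc = conc, prob = p, ci_low = qs[1, ], ci_high = qs[2, ])
}

#' Classify females as pregnant / not-pregnant / undetermined
#'
#' Applies the assignment-confidence rule to the point probability:
#' above the upper threshold (default 99.9%) pregnant, below the lower
#' (0.1%) not-pregnant, otherwise undetermined. The bootstrap envelope
#' is always reported alongside; `rule = "ci"` instead requires the
#' whole envelope to clear the threshold.
#'
#' @param model a `pregnancy_model`.
#' @param conc concentrations, ng/g.
#' @param thresholds `c(lower, upper)` call probabilities.
#' @param rule `"point"` (default) or `"ci"`.
#' @return data.frame: `conc`, `prob`, `ci_low`, `ci_high`, `call`.
#' @export
classify_pregnancy <- function(model, conc,
                               thresholds = c(0.001, 0.999),
                               rule = c("point", "ci")) {
  rule <- match.arg(rule)
  pr <- predict(model, conc)
  lo_stat <- if (rule == "point") pr$prob else pr$ci_high
  hi_stat <- if (rule == "point") pr$prob else pr$ci_low
  pr$call <- ifelse(hi_stat > thresholds[2], "pregnant",
                    ifelse(lo_stat < thresholds[1], "not_pregnant",
                           "undetermined"))
  pr
}

#' Probability-sum pregnancy-rate estimator
#'
#' For each bootstrap replicate b the rate is the sum of that
#' replicate's predicted pregnancy probabilities over all samples
#' divided by the sample size; the estimate is the mean over replicates
#' with a 2.5-97.5 percentile interval. Undetermined animals thereby
#' contribute their partial probability instead of being dropped.
#'
#' @param model a `pregnancy_model`.
#' @param conc concentrations of all assayed females, ng/g.
#' @return object of class `rate_estimate`: `mean_rate`, `ci_low`,
#'   `ci_high` (fractions), `per_replicate_rates`, `n`.
#' @export
pregnancy_rate <- function(model, conc) {
  if (length(conc) < 1) stop("need at least one concentration")
  stopifnot(all(conc > 0))
  lx <- log10(conc)
  probs <- stats::plogis(outer(model$boot_coef[, "slope"], lx) +
                           model$boot_coef[, "intercept"])
  rates <- rowMeans(probs)
  structure(list(mean_rate = mean(rates),
                 ci_low = unname(stats::quantile(rates, 0.025)),
                 ci_high = unname(stats::quantile(rates, 0.975)),
                 per_replicate_rates = rates,
                 n = length(conc)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Pregnancy rate %.2f%% (95%% CI %.2f-%.2f%%), n = %d, B = %d\n",
              100 * x$mean_rate, 100 * x$ci_low, 100 * x$ci_high,
              x$n, length(x$per_replicate_rates)))
  invisible(x)
}

#' Consistency of pregnancy calls across replicate samples
#'
#' Flags, per individual sampled more than once, whether every sample
#' received the same pregnancy designation; single-sample individuals
#' are vacuously consistent.
#'
#' @param calls data.frame with `individual_id` and `call`.
#' @return data.frame: `individual_id`, `n_samples`, `calls`,
#'   `consistent`.
#' @export
replicate_consistency <- function(calls) {
  stopifnot(all(c("individual_id", "call") %in% names(calls)))
  out <- do.call(rbind, lapply(split(calls, calls$individual_id),
    function(d) data.frame(individual_id = d$individual_id[1],
                           n_samples = nrow(d),
                           calls = paste(unique(d$call), collapse = ";"),
                           consistent = length(unique(d$call)) == 1,
                           stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
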