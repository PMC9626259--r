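#' Filter image measurements by quality scores
#'
#' Applies the measurability rules: any attribute scored 3 removes the
#' image; a score of 2 in two or more of body roll, arch and pitch
#' removes it; and at most `max_images` images are retained per
#' individual, preferring the best (lowest) total quality score with
#' ties broken by input order.
#'
#' @param measurements data.frame with `individual_id` and quality
#'   columns `q_focus`, `q_straightness`, `q_roll`, `q_arch`,
#'   `q_pitch`, `q_length_measurability`, `q_width_measurability`
#'   (values 1-3).
#' @param max_images per-individual cap (default 5).
#' @return list: `kept` (data.frame), `rejected` (data.frame with a
#'   `reason` column).
#' @export
quality_filter <- function(measurements, max_images = 5) {
  qcols <- grep("^q_", names(measurements), value = TRUE)
  if (length(qcols) == 0) stop("no quality-score columns (q_*) found")
  Q <- as.matrix(measurements[qcols])
  if (!all(Q %in% 1:3)) stop("quality scores must be 1, 2 or 3")
  any3 <- rowSums(Q == 3) > 0
  rap <- intersect(c("q_roll", "q_arch", "q_pitch"), qcols)
  paired2 <- rowSums(Q[, rap, drop = FALSE] == 2) >= 2
  reason <- ifelse(any3, "score 3",
                   ifelse(paired2, "two scores of 2 among roll/arch/pitch", NA))
  keep <- is.na(reason)
  kept <- measurements[keep, , drop = FALSE]
  # cap per individual: best total score first, stable order
  if (nrow(kept) > 0) {
    total <- rowSums(as.matrix(kept[qcols]))
    ord <- order(kept$individual_id, total)
    kept <- kept[ord, , drop = FALSE]
    within_rank <- stats::ave(seq_len(nrow(kept)), kept$individual_id,
                              FUN = seq_along)
    over <- within_rank > max_images
    if (any(over)) {
      rej_cap <- kept[over, , drop = FALSE]
      rej_cap$reason <- "exceeds per-individual image cap"
      kept <- kept[!over, , drop = FALSE]
    } else rej_cap <- NULL
  } else rej_cap <- NULL
  rejected <- measurements[!keep, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!keep]
  else rejected$reason <- character(0)
  if (!is.null(rej_cap)) rejected <- rbind(rejected, rej_cap)
  list(kept = kept, rejected = rejected)
}

#' Deterministic pinhole length estimate
#'
#' Converts a pixel measurement to metres with the recorded altitude
#' and camera geometry: `L = pixels * GSD`, where the ground sample
#' distance is `altitude * sensor_width / (focal_length * image_width)`
#' (focal and sensor in mm, altitude in m). This is the uncalibrated
#' baseline the error model corrects.
#'
#' @param pixel_length px.
#' @param observed_altitude m.
#' @param focal_length_mm,sensor_width_mm,image_width_px camera fields.
#' @return length in metres.
#' @export
#' @examples
#' naive_length(1787.2, 40, 35, 23.5, 6000)  # ~8.00 m
naive_length <- function(pixel_length, observed_altitude, focal_length_mm,
                         sensor_width_mm, image_width_px) {
  if (any(c(focal_length_mm, sensor_width_mm, image_width_px) <= 0)) {
    stop("camera parameters must be positive")
  }
  pixel_length * observed_altitude * sensor_width_mm /
    (focal_length_mm * image_width_px)
}

#' @keywords internal
naive_length_df <- function(d) {
  naive_length(d$pixel_length, d$observed_altitude, d$focal_length_mm,
               d$sensor_width_mm, d$image_width_px)
}

#' Calibrate the photogrammetric measurement-error model
#'
#' Hierarchical error model fitted to images of known-sized training
#' objects: the recorded altitude is the true altitude times a
#' multiplicative bias plus additive Gaussian noise
#' (`a_obs = a_true * bias + N(0, sd)`), and the pixel measurement
#' carries a multiplicative residual with coefficient of variation
#' `cv`. The observable per image is the ratio of the naive pinhole
#' length to the known length, modelled as
#' `r_i ~ N(bias, sqrt(sd^2 / a_i^2 + cv^2 bias^2))` (first-order
#' propagation). Posterior draws are obtained by adaptive random-walk
#' Metropolis with weak priors (`bias ~ N(1, 0.25^2)`, half-normal
#' scales on `sd` and `cv`); split-chain R-hat and acceptance rates are
#' reported, and a narrow training altitude range triggers an
#' identifiability warning.
#'
#' @param training data.frame: `known_length`, `pixel_length`,
#'   `observed_altitude`, `focal_length_mm`, `sensor_width_mm`,
#'   `image_width_px`, optional `aircraft_id`.
#' @param draws posterior draws retained per chain.
#' @param warmup warm-up iterations per chain.
#' @param chains MCMC chains.
#' @param seed RNG seed.
#' @return object of class `error_model`: `draws` (matrix with columns
#'   `bias`, `sd`, `cv`), `diagnostics`, `aircraft_id`,
#'   `altitude_range`.
#' @export
fit_error_model <- function(training, draws = 2000, warmup = 1000,
                            chains = 4, seed = 1L) {
  if (nrow(training) < 10) stop("need at least 10 training images")
  set.seed(seed)
  r <- naive_length_df(training) / training$known_length
  a <- training$observed_altitude
  if (diff(range(a)) < 1) {
    warning("training altitudes span < 1 m; altitude bias and noise are weakly identifiable")
  }
  log_post <- function(theta) {
    bias <- theta[1]; sd_a <- exp(theta[2]); cv <- exp(theta[3])
    if (bias <= 0) return(-Inf)
    s <- sqrt(sd_a^2 / a^2 + cv^2 * bias^2)
    sum(stats::dnorm(r, bias, pmax(s, 1e-8), log = TRUE)) +
      stats::dnorm(bias, 1, 0.25, log = TRUE) +
      stats::dnorm(sd_a, 0, 5, log = TRUE) + theta[2] +   # half-normal + jacobian
      stats::dnorm(cv, 0, 0.25, log = TRUE) + theta[3]
  }
  init <- c(mean(r), log(stats::sd(r) * mean(a) + 1e-4), log(0.02))
  fit <- mh_sample(log_post, init, prop_sd = c(0.01, 0.3, 0.3),
                   n_draws = draws, warmup = warmup, chains = chains)
  out <- cbind(bias = fit$draws[, 1], sd = exp(fit$draws[, 2]),
               cv = exp(fit$draws[, 3]))
  structure(list(draws = out,
                 diagnostics = list(rhat = fit$rhat,
                                    accept_rate = fit$accept_rate),
                 aircraft_id = training$aircraft_id[1] %||% "unknown",
                 altitude_range = range(a)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  q <- apply(x$draws, 2, stats::quantile, c(0.025, 0.5, 0.975))
  cat("Photogrammetric error model (", x$aircraft_id, ")\n", sep = "")
  cat(sprintf("  altitude bias: %.4f (%.4f-%.4f)\n",
              q[2, "bias"], q[1, "bias"], q[3, "bias"]))
  cat(sprintf("  altitude noise sd (m): %.3f (%.3f-%.3f)\n",
              q[2, "sd"], q[1, "sd"], q[3, "sd"]))
  cat(sprintf("  residual CV: %.4f (%.4f-%.4f)\n",
              q[2, "cv"], q[1, "cv"], q[3, "cv"]))
  cat(sprintf("  max split R-hat %.3f\n", max(x$diagnostics$rhat)))
  invisible(x)
}

#' Posterior predictive total length for one individual
#'
#' Combines all retained images of an individual under the calibrated
#' error model. For each posterior draw of (bias, sd, cv) the
#' likelihood of the candidate true length L is evaluated on a grid
#' over the prior range (each image's naive length is
#' `N(L * bias, L * sqrt(sd^2/a^2 + cv^2 bias^2))`) and one L is
#' sampled per draw, giving posterior predictive samples that carry
#' both calibration and measurement uncertainty.
#'
#' @param measurements quality-passing images of one individual (same
#'   columns as [fit_error_model()] training minus `known_length`).
#' @param model an `error_model`.
#' @param prior length prior range in metres (uniform; default 3-12 m).
#' @param draws number of posterior predictive samples (>= 2000).
#' @param grid_step grid resolution in metres.
#' @param seed optional seed (NULL leaves the RNG stream alone).
#' @return object of class `length_posterior`: `individual_id`,
#'   `samples`, `mean`, `hpd95`, `hpd65`, `n_images`.
#' @export
estimate_length <- function(measurements, model, prior = c(3, 12),
                            draws = 4000, grid_step = 0.01, seed = NULL) {
  if (nrow(measurements) == 0) stop("no quality-passing images for this individual")
  if (!is.null(seed)) set.seed(seed)
  Ln <- naive_length_df(measurements)
  a <- measurements$observed_altitude
  grid <- seq(prior[1], prior[2], by = grid_step)
  nd <- draws
  th <- model$draws[sample.int(nrow(model$draws), nd, replace = nd > nrow(model$draws)), , drop = FALSE]
  # per image j and draw d: Ln_j ~ N(L * bias_d, L * s_jd) with
  # s_jd^2 = sd_d^2 / a_j^2 + cv_d^2 bias_d^2. On the grid the joint
  # log-likelihood collapses to weighted sufficient statistics of the
  # naive lengths, so the grid x draws matrix is built from rank-one
  # products whatever the image count. Terms constant within a draw
  # (column) are dropped: they cancel in the per-draw categorical draw.
  W <- 1 / (2 * (outer(1 / a^2, th[, "sd"]^2) +
                   rep(th[, "cv"]^2 * th[, "bias"]^2, each = length(a))))
  B <- colSums(Ln * W)                                  # sum_j w_jd Ln_j
  C <- colSums(Ln^2 * W)
  n_img <- length(Ln)
  logp <- -n_img * log(grid) - outer(1 / grid^2, C) +
    2 * outer(1 / grid, th[, "bias"] * B)
  # one categorical draw of L per posterior draw (Gumbel-max trick)
  g <- -log(-log(matrix(stats::runif(length(logp)), nrow(logp))))
  idx <- max.col(t(logp + g))
  samples <- grid[idx] + stats::runif(nd, -grid_step / 2, grid_step / 2)
  structure(list(individual_id = measurements$individual_id[1] %||% NA,
                 samples = samples, mean = mean(samples),
                 hpd95 = hpd_interval(samples, 0.95),
                 hpd65 = hpd_interval(samples, 0.65),
                 n_images = length(Ln)),
            class = "length_posterior")
}

#' @export
print.length_posterior <- function(x, ...) {
  cat(sprintf("Length posterior for %s: mean %.2f m, 95%% HPD %.2f-%.2f m, 65%% HPD %.2f-%.2f m (%d image%s)\n",
              x$individual_id, x$mean, x$hpd95[1], x$hpd95[2],
              x$hpd65[1], x$hpd65[2], x$n_images,
              if (x$n_images == 1) "" else "s"))
  invisible(x)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing at least
#' `ceiling(mass * n)` of the sorted samples, found by scanning every
#' window of that size.
#'
#' @param samples numeric sample vector (>= 2 values).
#' @param mass interval mass in (0, 1).
#' @return `c(lo, hi)`.
#' @export
#' @examples
#' hpd_interval(1:100, 0.95)  # a width-94 window
hpd_interval <- function(samples, mass = 0.95) {
  if (length(samples) < 2) stop("need at least 2 samples")
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)")
  s <- sort(samples)
  n <- length(s)
  k <- min(n, max(2, ceiling(mass * n)))
  widths <- s[k:n] - s[1:(n - k + 1)]
  i <- which.min(widths)
  c(s[i], s[i + k - 1])
}

#' Cohort summary of length posteriors
#'
#' Summarises per-individual posterior means (the reported total
#' lengths) and 95% HPD widths (the measurement uncertainty) across a
#' cohort.
#'
#' @param posteriors list of `length_posterior` objects.
#' @return list: `lengths` (data.frame per individual), `mean`, `sd`,
#'   `min`, `max` of posterior means, and `hpd_width` (mean/sd/min/max
#'   of 95% HPD widths).
#' @export
length_summary <- function(posteriors) {
  if (length(posteriors) < 1) stop("need at least one individual")
  tab <- do.call(rbind, lapply(posteriors, function(p) {
    data.frame(individual_id = p$individual_id, mean_m = p$mean,
               hpd95_lo = p$hpd95[1], hpd95_hi = p$hpd95[2],
               hpd65_lo = p$hpd65[1], hpd65_hi = p$hpd65[2],
               n_images = p$n_images, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  w <- tab$hpd95_hi - tab$hpd95_lo
  list(lengths = tab,
       mean = mean(tab$mean_m), sd = stats::sd(tab$mean_m),
       min = min(tab$mean_m), max = max(tab$mean_m),
       hpd_width = c(mean = mean(w), sd = stats::sd(w),
                     min = min(w), max = max(w)))
}
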