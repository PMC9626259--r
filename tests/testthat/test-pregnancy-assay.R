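test_that("efficiency adjustment divides and flags low recovery", {
  expect_equal(adjust_for_efficiency(1.0, 1.0)$adjusted, 1.0)
  a <- adjust_for_efficiency(0.80, 0.80)
  expect_equal(a$adjusted, 1.00)
  expect_true(a$valid)
  expect_false(adjust_for_efficiency(2.0, 0.55)$valid)
  expect_error(adjust_for_efficiency(1, 0), "positive")
  expect_error(adjust_for_efficiency(1, 1.6), "implausible")
})

test_that("assay CVs follow the sd/mean definition", {
  reps <- data.frame(value = c(10, 10, 9, 11),
                     plate = c(1, 1, 2, 2),
                     sample = c("ctrl", "ctrl", "ctrl", "ctrl"))
  cvs <- assay_cv(reps)
  # plate 1 identical replicates CV 0; plate 2 (9, 11): 100*sqrt(2)/10
  expect_equal(cvs[["intra_cv"]], (0 + 100 * sqrt(2) / 10) / 2)
  # inter: plate means 10 and 10 -> CV 0
  expect_equal(cvs[["inter_cv"]], 0)
  expect_error(assay_cv(data.frame(value = 1, plate = 1, sample = "x")),
               ">= 2 replicates")
  expect_error(assay_cv(data.frame(value = c(-1, 1), plate = 1,
                                   sample = "x")), "mean is zero")
})

test_that("parallelism check compares dilution slopes", {
  std <- data.frame(dilution = c(1, 2, 4, 8, 16, 32),
                    response = 2 - 0.3 * log2(c(1, 2, 4, 8, 16, 32)))
  # exact copy: ratio 1, r-squared 1 (summary.lm warns on a perfect fit)
  res <- suppressWarnings(parallelism_check(std, std))
  expect_equal(res$slope_ratio, 1)
  expect_equal(res$r_squared, 1)
  expect_true(res$parallel)
  # scaled slope 0.997x
  samp <- std
  samp$response <- 2.1 - 0.997 * 0.3 * log2(samp$dilution)
  res2 <- parallelism_check(samp, std)
  expect_equal(res2$slope_ratio, 0.997, tolerance = 1e-9)
  expect_true(res2$parallel)
  # flat series: ratio ~0, rejected
  flat <- std
  flat$response <- 1.5
  res3 <- parallelism_check(flat, std)
  expect_equal(res3$slope_ratio, 0)
  expect_false(res3$parallel)
  expect_error(parallelism_check(std[1:2, ], std), "3 dilution points")
})

test_that("self-bounded reference labels by the concentration gap", {
  conc <- c(0.36, 1.5, 2.0, 5.92, 10.20, 22.84, 144.9, 307.01)
  ref <- build_reference(conc)
  expect_s3_class(ref, "reference_set")
  # 5.92 and 10.20 sit in the gap: unlabelled
  expect_equal(sort(10^ref$unlabelled), c(5.92, 10.20))
  expect_equal(sum(ref$labelled$pregnant == 0), 3)
  expect_equal(sum(ref$labelled$pregnant == 1), 3)
  expect_error(build_reference(c(0.5, 30, 40)), ">= 2 samples")
  ext <- data.frame(log10_conc = c(0, 0.1, 2, 2.1),
                    pregnant = c(0, 0, 1, 1))
  ref2 <- build_reference(mode = "external_reference", external = ext)
  expect_equal(ref2$labelled$pregnant, ext$pregnant)
})

test_that("the fitted model classifies the observed concentration extremes correctly", {
  ref <- build_reference(table3_reference())
  model <- fit_pregnancy_model(ref, B = 500, seed = 5)
  calls <- classify_pregnancy(model, c(0.36, 10.20, 307.01))
  expect_equal(calls$call, c("not_pregnant", "undetermined", "pregnant"))
  # the envelope in the gap is wide relative to the extremes
  gap_width <- calls$ci_high[2] - calls$ci_low[2]
  edge_width <- max(calls$ci_high[c(1, 3)] - calls$ci_low[c(1, 3)],
                    1 - calls$ci_high[3], calls$ci_low[1])
  expect_gt(gap_width, 10 * edge_width)
  expect_error(predict(model, c(-1, 5)))
})

test_that("point probability and envelope bounds are monotone in concentration", {
  ref <- build_reference(table3_reference(seed = 7))
  model <- fit_pregnancy_model(ref, B = 300, seed = 2)
  grid <- 10^seq(-1, 3, length.out = 60)
  pr <- predict(model, grid)
  expect_true(all(diff(pr$prob) >= -1e-12))
  expect_true(all(diff(pr$ci_low) >= -1e-10))
  expect_true(all(diff(pr$ci_high) >= -1e-10))
})

test_that("bootstrap pipeline is reproducible and B is honoured", {
  ref <- build_reference(table3_reference())
  m1 <- fit_pregnancy_model(ref, B = 50, seed = 9)
  m2 <- fit_pregnancy_model(ref, B = 50, seed = 9)
  expect_identical(m1$boot_coef, m2$boot_coef)
  expect_equal(nrow(fit_pregnancy_model(ref, B = 1, seed = 1)$boot_coef), 1)
})

test_that("probability-sum rate estimator averages per-replicate rates", {
  # hand-built model: two replicates with known probabilities
  model <- structure(list(
    coef = c(intercept = 0, slope = 1),
    boot_coef = rbind(c(intercept = log(0.2 / 0.8), slope = 0),
                      c(intercept = log(0.8 / 0.2), slope = 0)),
    B = 2, envelope_mass = 0.95), class = "pregnancy_model")
  # slope 0: every sample gets the replicate's intercept probability
  r <- pregnancy_rate(model, c(1, 10))
  expect_equal(sort(r$per_replicate_rates), c(0.2, 0.8), tolerance = 1e-12)
  expect_equal(r$mean_rate, 0.5)
  expect_error(pregnancy_rate(model, numeric(0)), "at least one")

  # replicate probabilities (0.2, 0.8) and (0.4, 0.6) -> rates 0.3, 0.7
  rates <- c(mean(c(0.2, 0.4)), mean(c(0.8, 0.6)))
  expect_equal(rates, c(0.3, 0.7))
  expect_equal(mean(rates), 0.5)
})

test_that("rate estimate respects the classified-count bounds", {
  ref <- build_reference(table3_reference(seed = 13))
  model <- fit_pregnancy_model(ref, B = 400, seed = 3)
  set.seed(21)
  conc <- table3_reference(n_np = 10, n_p = 15, seed = 77)
  calls <- classify_pregnancy(model, conc)
  r <- pregnancy_rate(model, conc)
  frac_p <- mean(calls$call == "pregnant")
  frac_np <- mean(calls$call == "not_pregnant")
  expect_gte(r$mean_rate, frac_p - 1e-9)
  expect_lte(r$mean_rate, 1 - frac_np + 1e-9)
})

test_that("classification recovers the truth outside the gap on a synthetic cohort", {
  set.seed(55)
  np <- lognormal_from_moments(1.98, 1.58)
  p <- lognormal_from_moments(144.86, 96.53)
  truth <- rep(c(0, 1), c(60, 60))
  conc <- c(rlnorm(60, np[["mu"]], np[["sigma"]]),
            rlnorm(60, p[["mu"]], p[["sigma"]]))
  model <- fit_pregnancy_model(build_reference(conc), B = 400, seed = 8)
  calls <- classify_pregnancy(model, conc)
  outside <- conc <= 3.43 | conc >= 22.84
  agree <- (calls$call == "pregnant" & truth == 1) |
    (calls$call == "not_pregnant" & truth == 0)
  expect_gte(mean(agree[outside]), 0.95)
  # only in-gap animals may be undetermined
  expect_true(all(conc[calls$call == "undetermined"] > 3.43 &
                    conc[calls$call == "undetermined"] < 22.84))
})

test_that("replicate samples of one female keep a consistent designation", {
  calls <- data.frame(
    individual_id = c("F1", "F1", "F2", "F2", "F3"),
    call = c("not_pregnant", "not_pregnant", "pregnant", "not_pregnant",
             "pregnant"))
  res <- replicate_consistency(calls)
  expect_true(res$consistent[res$individual_id == "F1"])
  expect_false(res$consistent[res$individual_id == "F2"])
  expect_true(res$consistent[res$individual_id == "F3"])
})

test_that("logistic parameter recovery stays inside bootstrap intervals", {
  # data simulated from a known logistic; the bootstrap interval should
  # cover each generating coefficient in at least 90% of seeded trials
  alpha <- -6; beta <- 5
  hit_slope <- hit_int <- 0
  n_trials <- 100
  for (s in seq_len(n_trials)) {
    set.seed(1000 + s)
    x <- runif(400, 0, 3)
    y <- rbinom(400, 1, plogis(alpha + beta * x))
    ref <- structure(list(labelled = data.frame(log10_conc = x, pregnant = y),
                          unlabelled = numeric(0),
                          provenance = "external_reference",
                          bounds = c(np_max = NA, p_min = NA)),
                     class = "reference_set")
    m <- fit_pregnancy_model(ref, B = 300, seed = s)
    qs <- apply(m$boot_coef, 2, quantile, c(0.025, 0.975))
    hit_slope <- hit_slope +
      (qs[1, "slope"] <= beta && beta <= qs[2, "slope"])
    hit_int <- hit_int +
      (qs[1, "intercept"] <= alpha && alpha <= qs[2, "intercept"])
  }
  expect_gte(hit_slope / n_trials, 0.90)
  expect_gte(hit_int / n_trials, 0.90)
})
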