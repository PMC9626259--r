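#' Validate pipeline input tables
#'
#' Schema and plausibility checks for the five input tables: required
#' columns, physical plausibility (positive altitudes and camera
#' fields, efficiency acceptance rule, quality-score domain), and
#' cross-file id consistency. Issues are returned as data, never
#' raised.
#'
#' @param inputs named list of data.frames (any of `genotypes`,
#'   `hormones`, `images`, `training`, `catch`).
#' @return data.frame of issues: `table`, `severity`
#'   (`"error"`/`"warning"`), `message`; zero rows when clean.
#' @export
validate_inputs <- function(inputs) {
  issues <- list()
  add <- function(tab, sev, msg) {
    issues[[length(issues) + 1]] <<- data.frame(
      table = tab, severity = sev, message = msg, stringsAsFactors = FALSE)
  }
  need <- function(tab, cols) {
    missing <- setdiff(cols, names(inputs[[tab]]))
    if (length(missing)) {
      add(tab, "error", paste("missing columns:",
                              paste(missing, collapse = ", ")))
      FALSE
    } else TRUE
  }
  if (!is.null(inputs$genotypes)) {
    if (need("genotypes", c("sample_id", "date", "sex_marker"))) {
      if (length(locus_names(inputs$genotypes)) == 0) {
        add("genotypes", "error", "no locus columns (locus<i>_a/_b)")
      }
      if (anyDuplicated(inputs$genotypes$sample_id)) {
        add("genotypes", "error", "duplicate sample_id")
      }
    }
  }
  if (!is.null(inputs$hormones)) {
    if (need("hormones", c("sample_id", "raw_progesterone",
                           "extraction_efficiency"))) {
      h <- inputs$hormones
      if (any(h$extraction_efficiency < 0.60, na.rm = TRUE)) {
        add("hormones", "warning",
            "extraction efficiency below the 60% acceptance rule; flagged samples should be re-extracted")
      }
      if (any(h$raw_progesterone <= 0, na.rm = TRUE)) {
        add("hormones", "error", "non-positive progesterone concentration")
      }
      if (!is.null(inputs$genotypes) &&
          !all(h$sample_id %in% inputs$genotypes$sample_id)) {
        add("hormones", "warning",
            "hormone sample_ids not present in the genotype table")
      }
    }
  }
  for (tab in c("images", "training")) {
    if (is.null(inputs[[tab]])) next
    cols <- c("pixel_length", "observed_altitude", "focal_length_mm",
              "sensor_width_mm", "image_width_px")
    if (tab == "training") cols <- c(cols, "known_length")
    if (need(tab, cols)) {
      d <- inputs[[tab]]
      if (any(d$observed_altitude <= 0, na.rm = TRUE)) {
        add(tab, "error", "non-positive altitude")
      }
      if (any(d$focal_length_mm <= 0 | d$sensor_width_mm <= 0 |
                d$image_width_px <= 0, na.rm = TRUE)) {
        add(tab, "error", "non-positive camera parameter")
      }
      if (tab == "images") {
        qcols <- grep("^q_", names(d), value = TRUE)
        if (length(qcols) &&
            !all(as.matrix(d[qcols]) %in% 1:3)) {
          add(tab, "error", "quality scores outside {1, 2, 3}")
        }
      }
    }
  }
  if (!is.null(inputs$catch)) {
    if (need("catch", c("length", "sex", "mature"))) {
      if (any(inputs$catch$length < 3 | inputs$catch$length > 12,
              na.rm = TRUE)) {
        add("catch", "warning", "lengths outside 3-12 m plausibility band")
      }
    }
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(table = character(0), severity = character(0),
               message = character(0))
}

#' Run the full demography pipeline
#'
#' Executes identity resolution, pregnancy assignment, photogrammetric
#' length estimation and the maturity correction in order, wiring each
#' stage's output into the next, and returns a consolidated report.
#' Inputs are either supplied tables or simulated via
#' [simulate_cohort()]. Stage seeds are derived deterministically from
#' the master seed, so a fixed config yields an identical report.
#' Missing tables degrade gracefully: without `catch` the demography
#' section is marked unavailable, without `images`/`training` the
#' length section is.
#'
#' @param inputs named list of input data.frames (`genotypes`,
#'   `hormones`, `images`, `training`, `catch`), or `NULL` to simulate.
#' @param simulate a [cohort_config()] used when `inputs` is `NULL`.
#' @param seed master seed.
#' @param B pregnancy bootstrap replicates.
#' @param mcmc_draws,mcmc_chains maturity/error-model MCMC shape
#'   (draws per chain after warm-up; warm-up is `mcmc_draws / 2`).
#' @param min_match_loci,min_typed_loci genotype matching thresholds.
#' @param reference_mode pregnancy reference construction mode.
#' @param outdir optional directory for stage CSV/JSON outputs.
#' @return list of class `demog_report` with sections `sex_ratio`,
#'   `pregnancy`, `lengths`, `demography`, `provenance`.
#' @export
run_pipeline <- function(inputs = NULL, simulate = cohort_config(),
                         seed = 1L, B = 2000, mcmc_draws = 1000,
                         mcmc_chains = 4, min_match_loci = 7,
                         min_typed_loci = 7,
                         reference_mode = "self_bounded",
                         outdir = NULL) {
  if (is.null(inputs)) {
    simulate$seed <- derive_seed(seed, 1L)
    inputs <- simulate_cohort(simulate)
  }
  issues <- validate_inputs(inputs)
  if (any(issues$severity == "error")) {
    stop("input validation failed:\n",
         paste(issues$message[issues$severity == "error"], collapse = "\n"))
  }

  # stage 1: identity and sex ratio
  if (is.null(inputs$genotypes)) stop("stage identity: genotype table missing")
  identity <- match_genotypes(inputs$genotypes, min_match_loci,
                              min_typed_loci)
  locus_tab <- locus_statistics(inputs$genotypes)
  sex_tab <- sex_ratio_report(identity)

  # stage 2: pregnancy
  pregnancy <- NULL
  if (!is.null(inputs$hormones)) {
    h <- inputs$hormones
    adj <- adjust_for_efficiency(h$raw_progesterone, h$extraction_efficiency)
    h$adjusted <- adj$adjusted
    h <- h[adj$valid, ]
    # within-year de-duplication, most recent sample retained
    ind <- identity$samples$individual_id[match(h$sample_id,
                                                identity$samples$sample_id)]
    h$individual_id <- ifelse(is.na(ind), h$individual_id, ind)
    h$year <- as.integer(format(as.Date(h$date), "%Y"))
    h <- h[order(h$individual_id, h$year, h$date), ]
    h_dedup <- h[!duplicated(h[c("individual_id", "year")], fromLast = TRUE), ]
    ref <- build_reference(h_dedup$adjusted, mode = reference_mode)
    model <- fit_pregnancy_model(ref, B = B, seed = derive_seed(seed, 2L))
    calls <- classify_pregnancy(model, h_dedup$adjusted)
    calls$individual_id <- h_dedup$individual_id
    rate <- pregnancy_rate(model, h_dedup$adjusted)
    all_calls <- classify_pregnancy(model, h$adjusted)
    all_calls$individual_id <- h$individual_id
    pregnancy <- list(model = model, calls = calls, rate = rate,
                      consistency = replicate_consistency(all_calls),
                      n_pregnant = sum(calls$call == "pregnant"),
                      n_not_pregnant = sum(calls$call == "not_pregnant"),
                      n_undetermined = sum(calls$call == "undetermined"))
  }

  # stage 3: photogrammetric lengths
  lengths_out <- NULL
  if (!is.null(inputs$images) && !is.null(inputs$training)) {
    filt <- quality_filter(inputs$images)
    err <- fit_error_model(inputs$training, draws = mcmc_draws,
                           warmup = ceiling(mcmc_draws / 2),
                           chains = mcmc_chains,
                           seed = derive_seed(seed, 3L))
    set.seed(derive_seed(seed, 4L))
    posteriors <- lapply(split(filt$kept, filt$kept$individual_id),
                         estimate_length, model = err)
    lengths_out <- c(length_summary(posteriors),
                     list(error_model = err, n_rejected = nrow(filt$rejected)))
  }

  # stage 4: maturity-corrected demography
  demography <- NULL
  if (!is.null(inputs$catch) && !is.null(lengths_out) &&
      !is.null(pregnancy)) {
    post <- fit_curves_mcmc(inputs$catch, draws = mcmc_draws,
                            warmup = ceiling(mcmc_draws / 2),
                            chains = mcmc_chains,
                            seed = derive_seed(seed, 5L))
    Lmeans <- lengths_out$lengths$mean_m
    pmat <- proportion_mature_females(Lmeans, post)
    ratio <- adjusted_sex_ratio(Lmeans, post)
    set.seed(derive_seed(seed, 6L))
    n_fem <- nrow(pregnancy$calls)
    corrected <- corrected_pregnancy_rate(n_fem, pregnancy$n_pregnant, pmat)
    corrected_probsum <- corrected_pregnancy_rate(n_fem, pregnancy$rate, pmat)
    demography <- list(posterior = post, prop_mature = pmat,
                       adjusted_sex_ratio = ratio,
                       corrected_rate = corrected,
                       corrected_rate_probsum = corrected_probsum,
                       L50_median = stats::median(post$draws[, "L50"]),
                       L50_ci = unname(stats::quantile(post$draws[, "L50"],
                                                       c(0.025, 0.975))))
  }

  report <- structure(list(
    sex_ratio = sex_tab,
    locus_stats = locus_tab,
    identity = identity,
    pregnancy = pregnancy,
    lengths = lengths_out,
    demography = demography,
    provenance = list(seed = seed, B = B, mcmc_draws = mcmc_draws,
                      min_match_loci = min_match_loci,
                      tables = names(inputs),
                      package_version = as.character(
                        utils::packageVersion("minkedemog")))),
    class = "demog_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.demog_report <- function(x, ...) {
  cat("== minke demography report ==\n\n-- sex ratio --\n")
  tot <- x$sex_ratio[x$sex_ratio$stratum == "total", ]
  cat(sprintf("  %d M : %d F (ratio %.2f M:F), parity p = %.3f\n",
              tot$n_males, tot$n_females, tot$ratio_MF, tot$binomial_p))
  if (!is.null(x$pregnancy)) {
    cat("\n-- pregnancy --\n")
    cat(sprintf("  %d pregnant, %d not pregnant, %d undetermined\n",
                x$pregnancy$n_pregnant, x$pregnancy$n_not_pregnant,
                x$pregnancy$n_undetermined))
    cat("  "); print(x$pregnancy$rate)
  }
  if (!is.null(x$lengths)) {
    cat("\n-- lengths --\n")
    cat(sprintf("  n = %d; mean %.2f m, sd %.2f, min %.2f, max %.2f\n",
                nrow(x$lengths$lengths), x$lengths$mean, x$lengths$sd,
                x$lengths$min, x$lengths$max))
    cat(sprintf("  95%% HPD width: mean %.2f m\n",
                x$lengths$hpd_width[["mean"]]))
  }
  if (!is.null(x$demography)) {
    cat("\n-- maturity-corrected demography --\n")
    cat(sprintf("  L50: %.2f m (95%% CrI %.2f-%.2f)\n",
                x$demography$L50_median, x$demography$L50_ci[1],
                x$demography$L50_ci[2]))
    cat(sprintf("  proportion mature: %.1f%% (95%% CrI %.1f-%.1f%%)\n",
                100 * x$demography$prop_mature$median,
                100 * x$demography$prop_mature$ci[1],
                100 * x$demography$prop_mature$ci[2]))
    cat(sprintf("  adjusted sex ratio: %.2f M:F\n",
                x$demography$adjusted_sex_ratio$median))
    cat("  "); print(x$demography$corrected_rate)
  } else {
    cat("\n-- maturity-corrected demography: unavailable (missing catch, length or pregnancy inputs) --\n")
  }
  invisible(x)
}

#' @keywords internal
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$sex_ratio, file.path(outdir, "sex_tally.csv"),
                   row.names = FALSE)
  utils::write.csv(report$identity$individuals,
                   file.path(outdir, "individuals.csv"), row.names = FALSE)
  utils::write.csv(report$locus_stats,
                   file.path(outdir, "locus_stats.csv"), row.names = FALSE)
  if (!is.null(report$pregnancy)) {
    utils::write.csv(report$pregnancy$calls, file.path(outdir, "calls.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(mean = report$pregnancy$rate$mean_rate,
                              ci = c(report$pregnancy$rate$ci_low,
                                     report$pregnancy$rate$ci_high),
                              B = report$pregnancy$model$B,
                              n = report$pregnancy$rate$n),
                         file.path(outdir, "rate.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(report$lengths)) {
    utils::write.csv(report$lengths$lengths,
                     file.path(outdir, "lengths.csv"), row.names = FALSE)
  }
  if (!is.null(report$demography)) {
    d <- report$demography
    jsonlite::write_json(list(
      L50 = list(median = d$L50_median, ci = d$L50_ci),
      prop_mature = list(median = d$prop_mature$median,
                         ci = d$prop_mature$ci),
      adjusted_sex_ratio = list(median = d$adjusted_sex_ratio$median,
                                ci = d$adjusted_sex_ratio$ci),
      corrected_pregnancy_rate = list(median = d$corrected_rate$median,
                                      ci = d$corrected_rate$ci)),
      file.path(outdir, "demography.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(outdir)
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file with optional `paths:` (the five input CSVs) and
#' parameter fields (`seed`, `B`, `mcmc_draws`, `min_match_loci`, ...),
#' returning an argument list for [run_pipeline()].
#'
#' @param path YAML file.
#' @return named list of `run_pipeline()` arguments.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[setdiff(names(cfg), "paths")]
  if (!is.null(cfg$paths)) {
    args$inputs <- lapply(cfg$paths, function(p) {
      if (!file.exists(p)) stop("input file does not exist: ", p)
      utils::read.csv(p, stringsAsFactors = FALSE)
    })
  }
  args
}
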