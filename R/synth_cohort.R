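#' Configuration for a synthetic minke whale cohort
#'
#' Bundles every parameter of the synthetic population: cohort size and
#' sex composition, sex-specific length distributions, the
#' maturity-at-length and sex-at-length logistic curves, the pregnancy
#' probability of mature females, the two blubber-progesterone
#' lognormals (not-pregnant vs pregnant), the microsatellite panel, and
#' biopsy resampling behaviour.
#'
#' Defaults emulate the Western Antarctic Peninsula study conditions:
#' 69 genotyped individuals with a 40:29 female bias; female lengths
#' N(8.3, 0.9) m and male N(7.8, 0.9) m (pooled mean ~8.04 m); female
#' length at 50% maturity 8.20 m; 92% of mature females pregnant;
#' progesterone lognormals moment-matched to class means/s.d. of
#' 1.98 +/- 1.58 and 144.86 +/- 96.53 ng/g; a 10-locus panel with the
#' published per-locus allele counts; and a ~13% within-year resampling
#' rate (9 of 69). The default sex-at-length curve is the Bayes-coherent
#' logistic implied by the sex-specific normals and the female fraction,
#' so the catch generator and the population generator describe the
#' same population.
#'
#' @param n_individuals cohort size.
#' @param prop_female probability an individual is female.
#' @param length_mean_by_sex,length_sd_by_sex named numeric `c(F=, M=)`,
#'   metres.
#' @param maturity_logistic `c(alpha=, beta=)` for
#'   `P(mature | L) = plogis(alpha + beta * L)`; `beta` must be > 0.
#' @param sex_at_length_logistic `c(alpha=, beta=)` for
#'   `P(female | L)`; `NULL` derives the Bayes-coherent curve from the
#'   length normals and `prop_female`.
#' @param preg_prob_mature pregnancy probability of a mature female.
#' @param progesterone_lognormal_np,progesterone_lognormal_p
#'   `c(mu=, sigma=)` on the natural-log scale, ng/g; the pregnant
#'   median must exceed the not-pregnant median.
#' @param n_loci,alleles_per_locus microsatellite panel shape.
#' @param allele_freqs list of per-locus frequency simplexes; `NULL`
#'   gives uniform frequencies.
#' @param resample_rate fraction of individuals biopsied twice within a
#'   year.
#' @param missingness per-locus probability a genotype is untyped.
#' @param triple_sample if `TRUE` one resampled female is sampled three
#'   times (the study recorded one such animal).
#' @param seed integer RNG seed.
#' @return object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_individuals = 50, seed = 1)
#' pop <- gen_population(cfg)
#' table(pop$sex)
cohort_config <- function(n_individuals = 69,
                          prop_female = 40 / 69,
                          length_mean_by_sex = c(F = 8.3, M = 7.8),
                          length_sd_by_sex = c(F = 0.9, M = 0.9),
                          maturity_logistic = c(alpha = -3.0 * 8.20, beta = 3.0),
                          sex_at_length_logistic = NULL,
                          preg_prob_mature = 0.92,
                          progesterone_lognormal_np = lognormal_from_moments(1.98, 1.58),
                          progesterone_lognormal_p = lognormal_from_moments(144.86, 96.53),
                          n_loci = 10,
                          alleles_per_locus = c(13, 16, 16, 8, 16, 14, 31, 15, 28, 10),
                          allele_freqs = NULL,
                          resample_rate = 9 / 69,
                          missingness = 0,
                          triple_sample = FALSE,
                          seed = 1L) {
  if (length(alleles_per_locus) == 1) {
    alleles_per_locus <- rep(alleles_per_locus, n_loci)
  }
  if (prop_female < 0 || prop_female > 1) stop("fractions must lie in [0, 1]")
  if (is.null(sex_at_length_logistic)) {
    # Bayes rule for equal-variance normals gives a linear logit in L
    s2 <- length_sd_by_sex[["F"]] * length_sd_by_sex[["M"]]
    muF <- length_mean_by_sex[["F"]]; muM <- length_mean_by_sex[["M"]]
    beta_F <- (muF - muM) / s2
    alpha_F <- log(prop_female / (1 - prop_female)) - (muF^2 - muM^2) / (2 * s2)
    sex_at_length_logistic <- c(alpha = unname(alpha_F), beta = unname(beta_F))
  }
  if (is.null(allele_freqs)) {
    allele_freqs <- lapply(alleles_per_locus, function(k) rep(1 / k, k))
  }
  cfg <- structure(list(
    n_individuals = n_individuals, prop_female = prop_female,
    length_mean_by_sex = length_mean_by_sex,
    length_sd_by_sex = length_sd_by_sex,
    maturity_logistic = maturity_logistic,
    sex_at_length_logistic = sex_at_length_logistic,
    preg_prob_mature = preg_prob_mature,
    progesterone_lognormal_np = progesterone_lognormal_np,
    progesterone_lognormal_p = progesterone_lognormal_p,
    n_loci = n_loci, alleles_per_locus = alleles_per_locus,
    allele_freqs = allele_freqs,
    resample_rate = resample_rate, missingness = missingness,
    triple_sample = triple_sample, seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Moment-matched lognormal parameters
#'
#' Converts a target arithmetic mean and standard deviation into the
#' `(mu, sigma)` of a lognormal with those moments.
#'
#' @param mean,sd target arithmetic moments (same units as the data).
#' @return `c(mu=, sigma=)` on the natural-log scale.
#' @export
lognormal_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' @keywords internal
validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (!is.numeric(cfg$n_individuals) || cfg$n_individuals < 1) {
    stop("n_individuals must be a positive count")
  }
  fracs <- c(cfg$prop_female, cfg$preg_prob_mature, cfg$resample_rate,
             cfg$missingness)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$maturity_logistic[["beta"]] <= 0) {
    stop("maturity slope must be positive (maturity increases with length)")
  }
  for (p in cfg$allele_freqs) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("allele frequencies at each locus must form a simplex")
    }
  }
  if (length(cfg$allele_freqs) != cfg$n_loci) {
    stop("allele_freqs must have one simplex per locus")
  }
  med_np <- cfg$progesterone_lognormal_np[["mu"]]
  med_p <- cfg$progesterone_lognormal_p[["mu"]]
  if (med_p <= med_np) {
    stop("pregnant progesterone median must exceed the not-pregnant median")
  }
  invisible(cfg)
}

#' Generate a synthetic population of true individuals
#'
#' Draws sex, total length, maturity, pregnancy, blubber progesterone
#' and a multilocus genotype per individual under the configured
#' conditional structure: maturity follows the maturity-at-length
#' logistic (females), pregnancy is Bernoulli for mature females only,
#' and progesterone comes from the pregnant or not-pregnant lognormal
#' accordingly. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return data.frame with one row per individual: `id`, `sex`,
#'   `total_length`, `mature`, `pregnant`, `progesterone`, and genotype
#'   columns `locus<i>_a` / `locus<i>_b` (allele sizes in bp).
#' @export
gen_population <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_individuals
  sex <- ifelse(stats::runif(n) < config$prop_female, "F", "M")
  len <- ifelse(sex == "F",
                stats::rnorm(n, config$length_mean_by_sex[["F"]],
                             config$length_sd_by_sex[["F"]]),
                stats::rnorm(n, config$length_mean_by_sex[["M"]],
                             config$length_sd_by_sex[["M"]]))
  aM <- config$maturity_logistic[["alpha"]]
  bM <- config$maturity_logistic[["beta"]]
  mature <- ifelse(sex == "F",
                   stats::runif(n) < stats::plogis(aM + bM * len), NA)
  pregnant <- ifelse(sex == "F" & mature %in% TRUE,
                     stats::runif(n) < config$preg_prob_mature, FALSE)
  pregnant[sex == "M"] <- FALSE
  prog <- rep(NA_real_, n)
  fem <- sex == "F"
  np <- config$progesterone_lognormal_np
  pp <- config$progesterone_lognormal_p
  prog[fem] <- ifelse(pregnant[fem],
                      stats::rlnorm(sum(fem), pp[["mu"]], pp[["sigma"]]),
                      stats::rlnorm(sum(fem), np[["mu"]], np[["sigma"]]))
  geno <- matrix(NA_integer_, n, 2 * config$n_loci)
  for (l in seq_len(config$n_loci)) {
    sizes <- locus_allele_sizes(l, config$alleles_per_locus[l])
    a1 <- sample(sizes, n, replace = TRUE, prob = config$allele_freqs[[l]])
    a2 <- sample(sizes, n, replace = TRUE, prob = config$allele_freqs[[l]])
    geno[, 2 * l - 1] <- pmin(a1, a2)
    geno[, 2 * l] <- pmax(a1, a2)
  }
  colnames(geno) <- as.vector(rbind(paste0("locus", seq_len(config$n_loci), "_a"),
                                    paste0("locus", seq_len(config$n_loci), "_b")))
  out <- data.frame(id = sprintf("AMW%03d", seq_len(n)), sex = sex,
                    total_length = len, mature = mature, pregnant = pregnant,
                    progesterone = prog, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(geno))
}

# allele ladders: distinct integer sizes per locus (2 bp spacing)
#' @keywords internal
locus_allele_sizes <- function(locus, k) {
  as.integer(80 + 40 * locus + 2 * seq_len(k))
}

#' Generate a biopsy genotype table from a population
#'
#' One row per biopsy sample. A `resample_rate` fraction of individuals
#' (rounded) is biopsied twice within the same year with identical
#' genotypes; `missingness` drops whole-locus genotypes at random to
#' exercise the minimum-typed-loci exclusion rule downstream.
#'
#' @param pop a population from [gen_population()].
#' @param config the [cohort_config()] used to generate `pop`.
#' @param years candidate sampling years.
#' @return data.frame: `sample_id`, `individual_id_truth`, `date`,
#'   `sex_marker`, and locus allele columns (NA = untyped).
#' @export
gen_genotype_table <- function(pop, config,
                               years = c(2013, 2014, 2016:2020)) {
  stopifnot(nrow(pop) > 0)
  if (config$resample_rate < 0 || config$resample_rate > 1) {
    stop("resample_rate must lie in [0, 1]")
  }
  set.seed(derive_seed(config$seed, 2L))
  n <- nrow(pop)
  year <- sample(years, n, replace = TRUE)
  day <- sample(1:180, n, replace = TRUE) # Jan-Jul window
  n_dup <- round(config$resample_rate * n)
  dup_idx <- if (n_dup > 0) sample(seq_len(n), n_dup) else integer(0)
  rows <- c(seq_len(n), dup_idx)
  if (config$triple_sample && n_dup > 0) rows <- c(rows, dup_idx[1])
  dup_flag <- c(rep(FALSE, n), rep(TRUE, length(rows) - n))
  tab <- pop[rows, c("id", grep("^locus", names(pop), value = TRUE))]
  tab <- data.frame(
    sample_id = sprintf("S%04d", seq_along(rows)),
    individual_id_truth = pop$id[rows],
    date = as.Date(sprintf("%d-01-01", year[rows])) +
      day[rows] + ifelse(dup_flag, sample(0:20, length(rows), replace = TRUE), 0),
    sex_marker = pop$sex[rows],
    tab[, -1, drop = FALSE],
    row.names = NULL, stringsAsFactors = FALSE)
  if (config$missingness > 0) {
    for (l in seq_len(config$n_loci)) {
      drop <- stats::runif(nrow(tab)) < config$missingness
      tab[drop, paste0("locus", l, c("_a", "_b"))] <- NA
    }
  }
  tab
}

#' Generate a UAS photogrammetry survey over a population
#'
#' Projects each individual's true length into image pixels through the
#' pinhole relation `pixels = L * focal * image_width /
#' (sensor_width * altitude)` (focal and sensor in mm), perturbs the
#' recorded altitude with a multiplicative bias and additive Gaussian
#' noise, applies a multiplicative measurement residual, and draws the
#' seven per-image quality scores. Training objects of known size are
#' generated under the same error process at altitudes spanning the
#' survey range.
#'
#' @param pop population from [gen_population()].
#' @param aircraft list: `focal_length_mm`, `sensor_width_mm`,
#'   `image_width_px`, `aircraft_id`. Defaults describe a 35 mm lens on
#'   an APS-C (23.5 mm) 6000 px sensor.
#' @param altitude_range metres; default `c(15, 83)`, the survey range.
#' @param noise list: `alt_bias` (multiplicative), `alt_sd` (m),
#'   `resid_cv` (fraction).
#' @param quality_score_rates `c(p2=, p3=)` per-attribute probabilities
#'   of scores 2 and 3 (independent across the seven attributes).
#' @param images_per_individual images taken per individual.
#' @param n_training training-object images; `training_length` their
#'   known size (m), default the 2.95 m boat rail.
#' @param seed RNG seed.
#' @return list of data.frames `images` and `training`.
#' @export
gen_uas_survey <- function(pop,
                           aircraft = list(focal_length_mm = 35,
                                           sensor_width_mm = 23.5,
                                           image_width_px = 6000,
                                           aircraft_id = "hexacopter-1"),
                           altitude_range = c(15, 83),
                           noise = list(alt_bias = 1.02, alt_sd = 1.0,
                                        resid_cv = 0.02),
                           quality_score_rates = c(p2 = 0.15, p3 = 0.05),
                           images_per_individual = 3,
                           n_training = 110, training_length = 2.95,
                           seed = 1L) {
  stopifnot(all(altitude_range > 0),
            aircraft$focal_length_mm > 0, aircraft$sensor_width_mm > 0,
            aircraft$image_width_px > 0)
  set.seed(seed)
  q_attrs <- c("focus", "straightness", "roll", "arch", "pitch",
               "length_measurability", "width_measurability")
  draw_scores <- function(n) {
    p2 <- quality_score_rates[["p2"]]; p3 <- quality_score_rates[["p3"]]
    matrix(sample(1:3, n * length(q_attrs), replace = TRUE,
                  prob = c(1 - p2 - p3, p2, p3)),
           n, length(q_attrs), dimnames = list(NULL, paste0("q_", q_attrs)))
  }
  project <- function(true_len, n_img) {
    alt_true <- stats::runif(n_img, altitude_range[1], altitude_range[2])
    alt_obs <- alt_true * noise$alt_bias + stats::rnorm(n_img, 0, noise$alt_sd)
    px <- true_len * aircraft$focal_length_mm * aircraft$image_width_px /
      (aircraft$sensor_width_mm * alt_true) *
      (1 + stats::rnorm(n_img, 0, noise$resid_cv))
    data.frame(pixel_length = px, observed_altitude = alt_obs)
  }
  img <- do.call(rbind, lapply(seq_len(nrow(pop)), function(i) {
    pr <- project(pop$total_length[i], images_per_individual)
    cbind(data.frame(individual_id = pop$id[i]), pr)
  }))
  img$focal_length_mm <- aircraft$focal_length_mm
  img$sensor_width_mm <- aircraft$sensor_width_mm
  img$image_width_px <- aircraft$image_width_px
  img$aircraft_id <- aircraft$aircraft_id
  img <- cbind(img, as.data.frame(draw_scores(nrow(img))))
  tr <- project(training_length, n_training)
  training <- data.frame(known_length = training_length,
                         pixel_length = tr$pixel_length,
                         observed_altitude = tr$observed_altitude,
                         focal_length_mm = aircraft$focal_length_mm,
                         sensor_width_mm = aircraft$sensor_width_mm,
                         image_width_px = aircraft$image_width_px,
                         aircraft_id = aircraft$aircraft_id)
  list(images = img, training = training)
}

#' Generate a commercial-catch style table
#'
#' Lengths are drawn from a normal distribution; sex follows the
#' sex-at-length logistic `P(female | L)` and maturity (females only)
#' the maturity-at-length logistic. Deterministic given `seed`.
#'
#' @param n records.
#' @param sex_at_length_logistic,maturity_logistic `c(alpha=, beta=)`.
#' @param length_distribution `c(mean=, sd=)` metres.
#' @param seed RNG seed.
#' @return data.frame: `length`, `sex`, `mature` (NA for males).
#' @export
gen_catch_table <- function(n,
                            sex_at_length_logistic = c(alpha = -4.648, beta = 0.617),
                            maturity_logistic = c(alpha = -3.0 * 8.20, beta = 3.0),
                            length_distribution = c(mean = 8.0, sd = 1.1),
                            seed = 1L) {
  stopifnot(n > 0)
  set.seed(seed)
  L <- stats::rnorm(n, length_distribution[["mean"]], length_distribution[["sd"]])
  pF <- stats::plogis(sex_at_length_logistic[["alpha"]] +
                        sex_at_length_logistic[["beta"]] * L)
  sex <- ifelse(stats::runif(n) < pF, "F", "M")
  pM <- stats::plogis(maturity_logistic[["alpha"]] +
                        maturity_logistic[["beta"]] * L)
  mature <- ifelse(sex == "F", stats::runif(n) < pM, NA)
  data.frame(length = L, sex = sex, mature = mature,
             stringsAsFactors = FALSE)
}

#' Generate a hormone assay table for the sampled females
#'
#' Pairs each female's true progesterone concentration with a synthetic
#' extraction efficiency, reporting the raw (pre-adjustment)
#' concentration so the efficiency-adjustment step has work to do.
#'
#' @param pop population from [gen_population()].
#' @param genotypes genotype table from [gen_genotype_table()]; hormone
#'   rows are generated per biopsy sample of a female.
#' @param efficiency_mean,efficiency_sd beta-like spread of extraction
#'   efficiencies (defaults emulate 82.8% +/- 14.5 observed QC).
#' @param seed RNG seed.
#' @return data.frame: `sample_id`, `individual_id`, `date`,
#'   `raw_progesterone`, `extraction_efficiency`, `plate`.
#' @export
gen_hormone_table <- function(pop, genotypes, efficiency_mean = 0.828,
                              efficiency_sd = 0.10, seed = 1L) {
  set.seed(seed)
  fem <- genotypes[genotypes$sex_marker == "F", ]
  conc <- pop$progesterone[match(fem$individual_id_truth, pop$id)]
  eff <- pmin(1.2, pmax(0.3, stats::rnorm(nrow(fem), efficiency_mean,
                                          efficiency_sd)))
  data.frame(sample_id = fem$sample_id,
             individual_id = fem$individual_id_truth,
             date = fem$date,
             raw_progesterone = conc * eff,
             extraction_efficiency = eff,
             plate = sample(1:4, nrow(fem), replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort bundle and optionally write the CSVs
#'
#' Runs every generator under one master seed and returns (or writes)
#' the five input tables the pipeline consumes plus the ground truth.
#'
#' @param config a [cohort_config()].
#' @param outdir optional directory; when given, writes
#'   `genotypes.csv`, `hormones.csv`, `images.csv`, `training.csv`,
#'   `catch.csv` and `ground_truth.csv`.
#' @param n_catch catch-table size.
#' @return invisible list of the six data.frames.
#' @export
simulate_cohort <- function(config = cohort_config(), outdir = NULL,
                            n_catch = 2000) {
  pop <- gen_population(config)
  geno <- gen_genotype_table(pop, config)
  uas <- gen_uas_survey(pop, seed = derive_seed(config$seed, 3L))
  horm <- gen_hormone_table(pop, geno, seed = derive_seed(config$seed, 4L))
  catch <- gen_catch_table(
    n_catch,
    sex_at_length_logistic = config$sex_at_length_logistic,
    maturity_logistic = config$maturity_logistic,
    length_distribution = c(
      mean = sum(c(config$prop_female, 1 - config$prop_female) *
                   config$length_mean_by_sex[c("F", "M")]),
      sd = mean(config$length_sd_by_sex)),
    seed = derive_seed(config$seed, 5L))
  bundle <- list(ground_truth = pop, genotypes = geno, hormones = horm,
                 images = uas$images, training = uas$training,
                 catch = catch)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(bundle)) {
      utils::write.csv(bundle[[nm]], file.path(outdir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
  }
  invisible(bundle)
}
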