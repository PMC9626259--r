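#' Per-locus summary statistics for a microsatellite panel
#'
#' For every locus computes the number of distinct alleles K, observed
#' heterozygosity H_O (fraction of typed individuals carrying two
#' different alleles), expected heterozygosity H_E with the
#' small-sample unbiased correction `(2n/(2n-1)) (1 - sum p_i^2)`
#' (the convention of the usual genotyping software; the uncorrected
#' value is reported alongside), and the probability of identity
#' `P_ID = sum p_i^4 + sum_{i<j} (2 p_i p_j)^2` — the chance two random
#' individuals share a genotype at the locus under Hardy-Weinberg
#' proportions.
#'
#' @param profiles genotype table with locus columns `locus<i>_a` /
#'   `locus<i>_b` (NA = untyped); one row per sample.
#' @return data.frame with one row per locus: `locus`, `n_typed`, `K`,
#'   `H_O`, `H_E`, `H_E_uncorrected`, `P_ID`.
#' @export
#' @examples
#' g <- data.frame(locus1_a = c(100, 100, 102), locus1_b = c(102, 100, 102))
#' locus_statistics(g)
locus_statistics <- function(profiles) {
  loci <- locus_names(profiles)
  if (length(loci) == 0) stop("no locus columns found")
  out <- lapply(loci, function(l) {
    a <- profiles[[paste0(l, "_a")]]
    b <- profiles[[paste0(l, "_b")]]
    typed <- !is.na(a) & !is.na(b)
    if (!any(typed)) stop("locus ", l, " has zero typed individuals")
    a <- a[typed]; b <- b[typed]
    n <- length(a)
    p <- table(c(a, b)) / (2 * n)
    K <- length(p)
    H_O <- mean(a != b)
    sum_p2 <- sum(p^2)
    H_E_unc <- 1 - sum_p2
    H_E <- (2 * n / (2 * n - 1)) * H_E_unc
    p <- as.numeric(p)
    pid <- sum(p^4)
    if (K > 1) {
      cp <- utils::combn(p, 2)
      pid <- pid + sum((2 * cp[1, ] * cp[2, ])^2)
    }
    data.frame(locus = l, n_typed = n, K = K, H_O = H_O, H_E = H_E,
               H_E_uncorrected = H_E_unc, P_ID = pid,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @keywords internal
locus_names <- function(profiles) {
  unique(sub("_a$", "", grep("^locus[0-9]+_a$", names(profiles),
                             value = TRUE)))
}

#' Multi-locus probability of identity over locus subsets
#'
#' Under locus independence the panel P_ID is the product of per-locus
#' values. For a given subset size this enumerates all subsets and
#' returns the range and mean of the products — e.g. the range of P_ID
#' attainable by any seven-locus match in a ten-locus panel.
#'
#' @param stats output of [locus_statistics()] (or any data.frame with
#'   a `P_ID` column).
#' @param subset_size loci per subset.
#' @return list: `min`, `max`, `mean`, `n_subsets`.
#' @export
combined_pid <- function(stats, subset_size) {
  p <- stats$P_ID
  if (subset_size < 1) stop("subset_size must be at least 1")
  if (subset_size > length(p)) {
    stop("subset_size exceeds the number of loci")
  }
  prods <- utils::combn(p, subset_size, prod)
  list(min = min(prods), max = max(prods), mean = mean(prods),
       n_subsets = length(prods))
}

#' Resolve individuals from multilocus genotypes
#'
#' Samples typed at fewer than `min_typed_loci` loci are excluded.
#' Remaining samples match when they agree exactly (zero mismatches)
#' at every mutually typed locus and at least `min_match_loci` loci are
#' compared; the transitive closure of matches defines individuals.
#' Near-matches (exactly one mismatching locus among >= `min_match_loci`
#' compared) are reported for QC but never merged, and sex-marker
#' conflicts within a cluster are flagged rather than silently merged.
#'
#' @param profiles genotype table (`sample_id`, `date`, `sex_marker`,
#'   locus columns).
#' @param min_match_loci minimum mutually typed loci for a match
#'   (default 7, the recapture rule).
#' @param min_typed_loci minimum typed loci for a sample to enter the
#'   analysis (default 7, the exclusion rule).
#' @return list of class `identity_result`: `individuals` (data.frame
#'   `individual_id`, `sex`, `n_samples`, `sample_ids`, `sex_conflict`),
#'   `samples` (per-sample assignment incl. year), `excluded`
#'   (sample_ids typed at too few loci), `near_matches` (QC pairs).
#' @export
match_genotypes <- function(profiles, min_match_loci = 7,
                            min_typed_loci = 7) {
  loci <- locus_names(profiles)
  n_loci <- length(loci)
  n <- nrow(profiles)
  A <- as.matrix(profiles[paste0(loci, "_a")])
  B <- as.matrix(profiles[paste0(loci, "_b")])
  typed <- !is.na(A) & !is.na(B)
  n_typed <- rowSums(typed)
  excluded <- profiles$sample_id[n_typed < min_typed_loci]
  keep <- which(n_typed >= min_typed_loci)

  parent <- seq_along(keep)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  near <- list()
  if (length(keep) > 1) {
    for (ii in seq_len(length(keep) - 1)) {
      for (jj in (ii + 1):length(keep)) {
        i <- keep[ii]; j <- keep[jj]
        both <- typed[i, ] & typed[j, ]
        n_comp <- sum(both)
        if (n_comp < min_match_loci) next
        mm <- sum(A[i, both] != A[j, both] | B[i, both] != B[j, both])
        if (mm == 0) {
          ri <- find(ii); rj <- find(jj)
          if (ri != rj) parent[rj] <- ri
        } else if (mm == 1) {
          near[[length(near) + 1]] <- data.frame(
            sample_1 = profiles$sample_id[i],
            sample_2 = profiles$sample_id[j],
            n_compared = n_comp, stringsAsFactors = FALSE)
        }
      }
    }
  }
  roots <- vapply(seq_along(keep), find, integer(1))
  cl <- match(roots, unique(roots))
  sample_df <- data.frame(
    sample_id = profiles$sample_id[keep],
    individual_id = sprintf("IND%03d", cl),
    sex_marker = profiles$sex_marker[keep],
    date = profiles$date[keep],
    stringsAsFactors = FALSE)
  sample_df$year <- as.integer(format(as.Date(sample_df$date), "%Y"))
  individuals <- do.call(rbind, lapply(split(sample_df, sample_df$individual_id),
    function(d) {
      sexes <- unique(d$sex_marker[!is.na(d$sex_marker) &
                                     d$sex_marker != "unknown"])
      data.frame(individual_id = d$individual_id[1],
                 sex = if (length(sexes) == 1) sexes else NA_character_,
                 n_samples = nrow(d),
                 sample_ids = paste(d$sample_id, collapse = ";"),
                 sex_conflict = length(sexes) > 1,
                 stringsAsFactors = FALSE)
    }))
  rownames(individuals) <- NULL
  if (any(individuals$sex_conflict)) {
    warning("sex-marker conflict within ",
            sum(individuals$sex_conflict), " cluster(s); flagged")
  }
  structure(list(individuals = individuals, samples = sample_df,
                 excluded = excluded,
                 near_matches = if (length(near)) do.call(rbind, near) else
                   data.frame(sample_1 = character(0),
                              sample_2 = character(0),
                              n_compared = integer(0))),
            class = "identity_result")
}

#' @export
print.identity_result <- function(x, ...) {
  cat("Genotype identity resolution\n")
  cat("  samples analysed:", nrow(x$samples), "\n")
  cat("  samples excluded (<min typed loci):", length(x$excluded), "\n")
  cat("  individuals:", nrow(x$individuals), "\n")
  cat("  within-dataset recaptures:",
      sum(x$individuals$n_samples > 1), "\n")
  invisible(x)
}

#' Central two-tailed exact binomial test
#'
#' p-value `min(1, 2 min(P(X <= k), P(X >= k)))` under
#' `Binomial(n, p0)`: the central (double-the-smaller-tail) two-sided
#' definition, which at `p0 = 0.5` coincides with the
#' minimum-likelihood definition used by [stats::binom.test()].
#'
#' @param k successes, `n` trials, `p0` null probability.
#' @param n trials.
#' @param p0 null success probability (0.5 = parity).
#' @return the p-value.
#' @export
#' @examples
#' exact_binomial_test(1, 7)   # 0.125
exact_binomial_test <- function(k, n, p0 = 0.5) {
  if (n < 1) stop("n must be at least 1")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  lower <- stats::pbinom(k, n, p0)
  upper <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Clopper-Pearson exact binomial confidence limits
#'
#' Exact limits from Beta quantiles:
#' lower `qbeta(alpha/2, k, n-k+1)` (0 when k = 0), upper
#' `qbeta(1-alpha/2, k+1, n-k)` (1 when k = n).
#'
#' @param k successes.
#' @param n trials.
#' @param conf confidence level in (0, 1).
#' @return `c(lower=, upper=)` fractions.
#' @export
#' @examples
#' round(100 * binomial_confidence_limits(5, 16), 2)  # 11.02 58.66
binomial_confidence_limits <- function(k, n, conf = 0.95) {
  if (conf <= 0 || conf >= 1) stop("conf must lie in (0, 1)")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  a <- 1 - conf
  c(lower = if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1),
    upper = if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k))
}

#' Sex-ratio tallies with exact tests and confidence limits
#'
#' Tallies resolved individuals per stratum (sampling year) and in
#' total, after removing within-year replicates (the most recent sample
#' of an individual in a year is retained, and an individual counts
#' once per year it was sampled). Reports the M:F ratio, the central
#' two-tailed exact binomial test against parity, and Clopper-Pearson
#' limits for each sex fraction.
#'
#' @param identity an `identity_result` from [match_genotypes()], or a
#'   data.frame with columns `individual_id`, `sex_marker`/`sex`,
#'   `year`.
#' @param conf confidence level for the limits.
#' @return data.frame, one row per stratum plus `total`: `stratum`,
#'   `n_males`, `n_females`, `male_pct`, `male_cl_lower`,
#'   `male_cl_upper`, `female_pct`, `female_cl_lower`,
#'   `female_cl_upper`, `ratio_MF`, `binomial_p`.
#' @export
sex_ratio_report <- function(identity, conf = 0.95) {
  samples <- if (inherits(identity, "identity_result")) {
    s <- identity$samples
    s$sex <- identity$individuals$sex[match(s$individual_id,
                                            identity$individuals$individual_id)]
    s
  } else {
    s <- identity
    if (is.null(s$sex)) s$sex <- s$sex_marker
    s
  }
  # within-year de-duplication: most recent sample per individual-year
  samples <- samples[order(samples$individual_id, samples$year,
                           samples$date %||% seq_len(nrow(samples))), ]
  dedup <- samples[!duplicated(samples[c("individual_id", "year")],
                               fromLast = TRUE), ]
  tally_one <- function(d, label) {
    m <- sum(d$sex == "M", na.rm = TRUE)
    f <- sum(d$sex == "F", na.rm = TRUE)
    n <- m + f
    if (n == 0) {
      return(data.frame(stratum = label, n_males = 0L, n_females = 0L,
                        male_pct = NA_real_, male_cl_lower = NA_real_,
                        male_cl_upper = NA_real_, female_pct = NA_real_,
                        female_cl_lower = NA_real_,
                        female_cl_upper = NA_real_, ratio_MF = NA_real_,
                        binomial_p = NA_real_, stringsAsFactors = FALSE))
    }
    clm <- binomial_confidence_limits(m, n, conf)
    clf <- binomial_confidence_limits(f, n, conf)
    data.frame(stratum = label, n_males = m, n_females = f,
               male_pct = 100 * m / n,
               male_cl_lower = 100 * clm[["lower"]],
               male_cl_upper = 100 * clm[["upper"]],
               female_pct = 100 * f / n,
               female_cl_lower = 100 * clf[["lower"]],
               female_cl_upper = 100 * clf[["upper"]],
               ratio_MF = if (f > 0) m / f else NA_real_,
               binomial_p = exact_binomial_test(m, n),
               stringsAsFactors = FALSE)
  }
  strata <- sort(unique(dedup$year))
  per_year <- do.call(rbind, lapply(strata, function(y) {
    tally_one(dedup[dedup$year == y, ], as.character(y))
  }))
  # total: unique individuals across the whole dataset
  tot <- dedup[!duplicated(dedup$individual_id), ]
  rbind(per_year, tally_one(tot, "total"))
}
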