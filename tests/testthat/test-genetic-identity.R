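test_that("locus statistics match hand-derived values", {
  # monomorphic locus: K = 1, H_E = 0, P_ID = 1
  g <- data.frame(locus1_a = rep(100L, 5), locus1_b = rep(100L, 5))
  s <- locus_statistics(g)
  expect_equal(s$K, 1)
  expect_equal(s$H_E, 0)
  expect_equal(s$P_ID, 1)

  # two alleles at 0.5/0.5: P_ID = 2 * 0.5^4 + (2 * 0.25)^2 = 0.375
  g2 <- data.frame(locus1_a = c(100L, 100L, 102L, 100L),
                   locus1_b = c(100L, 102L, 102L, 102L))
  s2 <- locus_statistics(g2)
  expect_equal(s2$K, 2)
  expect_equal(s2$P_ID, 0.375)
  expect_equal(s2$H_O, 0.5)
  # unbiased H_E = (2n/(2n-1)) * (1 - sum p^2) with n = 4
  expect_equal(s2$H_E, (8 / 7) * 0.5)

  # three alleles at 1/3 each: P_ID = 15/81
  g3 <- data.frame(locus1_a = c(100L, 102L, 104L),
                   locus1_b = c(100L, 102L, 104L))
  expect_equal(locus_statistics(g3)$P_ID, 15 / 81)

  expect_error(locus_statistics(
    data.frame(locus1_a = NA_integer_, locus1_b = NA_integer_)),
    "zero typed")
})

test_that("P_ID formula equals the genotype-collision oracle for loci with up to 6 alleles", {
  set.seed(31)
  for (k in 2:6) {
    freqs <- as.numeric(rmultinom(1, 500, rep(1, k))) / 500
    freqs <- freqs[freqs > 0]
    # build a sample whose empirical allele frequencies equal freqs
    alleles <- rep(seq_along(freqs) * 2L + 100L, round(freqs * 500))
    stopifnot(length(alleles) %% 2 == 0)
    g <- data.frame(locus1_a = alleles[seq(1, length(alleles), 2)],
                    locus1_b = alleles[seq(2, length(alleles), 2)])
    s <- locus_statistics(g)
    p_emp <- as.numeric(table(c(g$locus1_a, g$locus1_b))) / length(alleles)
    expect_equal(s$P_ID, pid_bruteforce(p_emp), tolerance = 1e-12)
  }
})

test_that("combined P_ID enumerates subset products", {
  pid <- c(0.043, 0.014, 0.021, 0.082, 0.022, 0.023, 0.004, 0.016,
           0.005, 0.026)
  stats <- data.frame(P_ID = pid)
  res <- combined_pid(stats, 7)
  expect_equal(res$n_subsets, choose(10, 7))
  expect_equal(res$min, prod(sort(pid)[1:7]))
  expect_equal(res$max, prod(sort(pid, decreasing = TRUE)[1:7]))
  # uniform loci: every subset product identical
  res2 <- combined_pid(data.frame(P_ID = rep(0.1, 10)), 7)
  expect_equal(res2$min, 1e-7, tolerance = 1e-12)
  expect_equal(res2$max, 1e-7, tolerance = 1e-12)
  # subset of all loci: a single product
  res3 <- combined_pid(stats, 10)
  expect_equal(res3$n_subsets, 1)
  expect_equal(res3$min, prod(pid))
  expect_error(combined_pid(stats, 0), "at least 1")
  expect_error(combined_pid(stats, 11), "exceeds")
})

test_that("genotype matching applies the seven-locus rules", {
  ten <- paste(rep("10/12", 10), collapse = " ")
  other <- paste(rep("14/14", 10), collapse = " ")
  # identical at 10 loci -> one cluster of 2
  p <- make_profiles(list(S1 = ten, S2 = ten, S3 = other))
  res <- match_genotypes(p)
  expect_equal(nrow(res$individuals), 2)
  expect_equal(max(res$individuals$n_samples), 2)

  # identical at only 6 mutually typed loci -> not merged
  six <- paste(c(rep("10/12", 6), rep("-", 4)), collapse = " ")
  ten_b <- paste(c(rep("10/12", 6), rep("14/16", 4)), collapse = " ")
  p2 <- make_profiles(list(S1 = six, S2 = ten_b))
  res2 <- match_genotypes(p2, min_typed_loci = 6)
  expect_equal(nrow(res2$individuals), 2)

  # typed at 6 loci with the default floor -> excluded
  res3 <- match_genotypes(p2)
  expect_identical(res3$excluded, "S1")

  # one mismatching locus among ten -> near-match report, no merge
  ten_c <- paste(c(rep("10/12", 9), "14/16"), collapse = " ")
  res4 <- match_genotypes(make_profiles(list(S1 = ten, S2 = ten_c)))
  expect_equal(nrow(res4$individuals), 2)
  expect_equal(nrow(res4$near_matches), 1)
})

test_that("matching is permutation-invariant, transitive and idempotent", {
  cfg <- cohort_config(n_individuals = 40, resample_rate = 0.2, seed = 17)
  tab <- gen_genotype_table(gen_population(cfg), cfg)
  res <- match_genotypes(tab)
  perm <- tab[sample(nrow(tab)), ]
  res_p <- match_genotypes(perm)
  part <- function(r) {
    m <- split(r$samples$sample_id, r$samples$individual_id)
    unname(lapply(m, sort)[order(vapply(lapply(m, sort), `[`, "", 1))])
  }
  expect_identical(part(res), part(res_p))
  expect_equal(nrow(res$individuals), 40)

  # transitivity: A-B match at loci 1-7, B-C at 4-10, A-C only at 4-7
  a <- paste(c(rep("10/12", 7), rep("-", 3)), collapse = " ")
  b <- paste(rep("10/12", 10), collapse = " ")
  cc <- paste(c(rep("-", 3), rep("10/12", 7)), collapse = " ")
  res_t <- match_genotypes(make_profiles(list(A = a, B = b, C = cc)))
  expect_equal(nrow(res_t$individuals), 1)
})

test_that("sex conflicts within a cluster are flagged, not merged silently", {
  ten <- paste(rep("10/12", 10), collapse = " ")
  p <- make_profiles(list(S1 = ten, S2 = ten), sex = c("M", "F"))
  expect_warning(res <- match_genotypes(p), "sex-marker conflict")
  expect_true(res$individuals$sex_conflict[1])
})

test_that("the central exact binomial test reproduces known values and symmetry", {
  expect_equal(exact_binomial_test(1, 7), 0.125)
  expect_equal(exact_binomial_test(5, 16), 0.2101, tolerance = 1e-4)
  expect_equal(exact_binomial_test(8, 16), 1)
  # symmetry k <-> n - k at p0 = 0.5, and agreement with binom.test
  for (n in c(5, 12, 30)) {
    for (k in 0:n) {
      p <- exact_binomial_test(k, n)
      expect_equal(p, exact_binomial_test(n - k, n))
      expect_equal(p, stats::binom.test(k, n)$p.value, tolerance = 1e-12)
    }
  }
  expect_error(exact_binomial_test(3, 0), "at least 1")
  expect_error(exact_binomial_test(5, 4))
})

test_that("Clopper-Pearson limits are exact and achieve nominal coverage", {
  expect_equal(unname(binomial_confidence_limits(5, 16)),
               c(0.1102, 0.5866), tolerance = 1e-4)
  expect_equal(binomial_confidence_limits(0, 9)[["lower"]], 0)
  expect_equal(binomial_confidence_limits(9, 9)[["upper"]], 1)
  expect_error(binomial_confidence_limits(3, 10, conf = 1), "conf")

  set.seed(99)
  for (case in list(c(20, 0.3), c(50, 0.5), c(15, 0.9))) {
    n <- case[1]; p <- case[2]
    k <- rbinom(2000, n, p)
    cls <- vapply(k, function(ki) binomial_confidence_limits(ki, n),
                  numeric(2))
    cover <- mean(cls[1, ] <= p & p <= cls[2, ])
    expect_gte(cover, 0.95 - 2 * sqrt(0.05 * 0.95 / 2000) - 0.005)
  }
})

test_that("sex ratio report tallies strata with de-duplication", {
  # two samples of one male in one year must count once, most recent kept
  df <- data.frame(
    individual_id = c("I1", "I1", "I2", "I3"),
    sex = c("M", "M", "F", "F"),
    year = c(2019L, 2019L, 2019L, 2020L),
    date = as.Date(c("2019-02-01", "2019-03-01", "2019-02-10", "2020-02-01")))
  rep <- sex_ratio_report(df)
  y19 <- rep[rep$stratum == "2019", ]
  expect_equal(y19$n_males, 1)
  expect_equal(y19$n_females, 1)
  tot <- rep[rep$stratum == "total", ]
  expect_equal(tot$n_males, 1)
  expect_equal(tot$n_females, 2)
  expect_equal(tot$ratio_MF, 0.5)

  # empty stratum handling: all-male year has no ratio
  df2 <- data.frame(individual_id = c("I1", "I2"), sex = c("M", "M"),
                    year = 2018L, date = as.Date("2018-02-01"))
  rep2 <- sex_ratio_report(df2)
  expect_true(is.na(rep2$ratio_MF[rep2$stratum == "2018"]))
})
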