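# Independent brute-force oracles used to pin down the analytic
# implementations. These deliberately share no code with the package.

# probability two Hardy-Weinberg genotypes drawn from `freqs` coincide:
# enumerate every unordered genotype and sum squared probabilities
pid_bruteforce <- function(freqs) {
  k <- length(freqs)
  total <- 0
  for (i in seq_len(k)) {
    for (j in i:k) {
      pg <- if (i == j) freqs[i]^2 else 2 * freqs[i] * freqs[j]
      total <- total + pg^2
    }
  }
  total
}

# shortest interval holding >= ceiling(mass * n) samples: scan every
# (start, end) pair
hpd_bruteforce <- function(samples, mass) {
  s <- sort(samples)
  n <- length(s)
  k <- min(n, max(2, ceiling(mass * n)))
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (j - i + 1 >= k && s[j] - s[i] < best[2] - best[1]) {
        best <- c(s[i], s[j])
      }
    }
  }
  best
}

# build a genotype table from compact allele strings:
# list(S1 = "11/12 13/13 ...", ...); "-" marks an untyped locus
make_profiles <- function(samples, dates = NULL, sex = NULL) {
  n_loci <- length(strsplit(samples[[1]], " ")[[1]])
  rows <- lapply(names(samples), function(id) {
    parts <- strsplit(samples[[id]], " ")[[1]]
    al <- lapply(parts, function(p) {
      if (p == "-") c(NA_integer_, NA_integer_) else
        as.integer(strsplit(p, "/")[[1]])
    })
    vals <- unlist(al)
    names(vals) <- as.vector(rbind(paste0("locus", seq_len(n_loci), "_a"),
                                   paste0("locus", seq_len(n_loci), "_b")))
    vals
  })
  g <- as.data.frame(do.call(rbind, rows))
  data.frame(sample_id = names(samples),
             date = dates %||% rep("2019-02-01", length(samples)),
             sex_marker = sex %||% rep("F", length(samples)),
             g, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# reference set drawn from the two class lognormals matched to the
# observed class moments (NP 1.98 +/- 1.58, P 144.86 +/- 96.53 ng/g)
table3_reference <- function(n_np = 13, n_p = 20, seed = 42) {
  set.seed(seed)
  np <- lognormal_from_moments(1.98, 1.58)
  p <- lognormal_from_moments(144.86, 96.53)
  conc <- c(rlnorm(n_np, np[["mu"]], np[["sigma"]]),
            rlnorm(n_p, p[["mu"]], p[["sigma"]]))
  conc
}
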