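# minkedemog

Non-lethal demography of Antarctic minke whales (*Balaenoptera
bonaerensis*) from biopsy and drone data.

Antarctic minke whales are an abundant, ice-dependent krill predator,
and the sea-ice habitat they rely on — especially along the Western
Antarctic Peninsula — is changing fast. Because abundance is hard to
estimate for a cryptic, ice-associated whale, demographic rates (sex
ratio, maturity structure, pregnancy rate) are the most sensitive
indicators of how such a population is doing. This package implements
a complete inference chain that derives those rates without killing or
capturing an animal, for analysts working with biopsy genotypes,
blubber hormone assays, aerial photogrammetry and historical catch
records.

## What it computes

1. **Individuals and sex ratios** from multilocus microsatellite
   genotypes: samples matching exactly at ≥ 7 mutually typed loci are
   recaptures of one individual; per-locus statistics are the allele
   count *K*, observed and expected heterozygosity *H*<sub>O</sub>,
   *H*<sub>E</sub>, and the probability of identity
   *P*<sub>ID</sub> = Σ p<sub>i</sub><sup>4</sup> + ΣΣ<sub>i&lt;j</sub> (2p<sub>i</sub>p<sub>j</sub>)².
   Sex ratios are tested against parity with central two-tailed exact
   binomial tests and Clopper–Pearson confidence limits.
2. **Pregnancy** from blubber progesterone: logistic regression of
   pregnancy status on log₁₀ concentration (external-reference or
   self-bounded reference modes), 95% confidence envelopes from
   10 000 bootstrap refits, calls at the 0.1% / 99.9% assignment
   thresholds, and the probability-sum pregnancy-rate estimator
   (per bootstrap replicate, Σᵢ pᵢ / n).
3. **Total lengths** from UAS (drone) images: pinhole projection
   corrected by a Bayesian measurement-error model (altimeter bias,
   altitude noise, measurement CV) calibrated on known-sized training
   objects; per-individual posterior predictive lengths with 95% and
   65% highest-posterior-density intervals.
4. **Maturity correction**: sex-at-length and maturity-at-length
   logistic curves fitted to commercial catch records (ML + MCMC)
   give, per posterior draw, the proportion of sampled females that
   are mature, P<sub>mat</sub> = Σ p_F(Lᵢ)p_M(Lᵢ) / Σ p_F(Lᵢ), the
   length at 50% maturity L₅₀ = −α_M/β_M, an adjusted sex ratio, and
   the corrected pregnancy rate k / (P<sub>mat</sub> · n) — reported
   unclamped, so genuine uncertainty shows up as a tail above 100%.
5. A **seeded synthetic-cohort generator** that emulates all five
   input streams (genotypes, hormones, images, training objects,
   catch), so the whole chain can be exercised and validated without
   field data.

See `vignettes/minke-demography-methods.Rmd` for the models,
assumptions, defaults and numerical choices.

## Worked example

```r
library(minkedemog)
report <- run_pipeline(simulate = cohort_config(seed = 42), seed = 7,
                       B = 2000, mcmc_draws = 1000, mcmc_chains = 2)
print(report)
```

```
== minke demography report ==

-- sex ratio --
  27 M : 42 F (ratio 0.64 M:F), parity p = 0.091

-- pregnancy --
  19 pregnant, 22 not pregnant, 1 undetermined
  Pregnancy rate 45.29% (95% CI 45.26-45.36%), n = 42, B = 2000

-- lengths --
  n = 65; mean 8.17 m, sd 1.01, min 5.90, max 10.89
  95% HPD width: mean 0.86 m

-- maturity-corrected demography --
  L50: 8.18 m (95% CrI 8.13-8.23)
  proportion mature: 55.6% (95% CrI 52.9-58.4%)
  adjusted sex ratio: 0.68 M:F
  Corrected pregnancy rate: median 81.4% (95% CrI 77.5-85.5%)
```

Reading the report: 69 simulated whales were genotyped and resolved to
individuals; the 0.64 M:F ratio is not distinguishable from parity
(p = 0.091). Of the 42 assayed females, 19 had progesterone
concentrations assigning pregnancy with > 99.9% probability; the
45.29% rate is the probability sum over *all* females, mature or not.
Photogrammetry recovered 65 individuals' lengths with ~0.9 m of
measurement uncertainty each. The catch-calibrated curves put the
length at 50% female maturity at 8.18 m (the generator's truth is
8.20 m) and 55.6% of the sampled females mature, which converts the
all-female pregnancy signal into an 81.4% pregnancy rate among mature
females — the biologically meaningful quantity. Each section of the
report is also written as CSV/JSON stage outputs when `outdir` is
given.

Individual stages are exported directly (`match_genotypes()`,
`fit_pregnancy_model()`, `classify_pregnancy()`, `pregnancy_rate()`,
`quality_filter()`, `fit_error_model()`, `estimate_length()`,
`fit_curves_mcmc()`, `proportion_mature_females()`,
`corrected_pregnancy_rate()`, ...), and `simulate_cohort()` /
`read_run_config()` support file-based workflows.

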