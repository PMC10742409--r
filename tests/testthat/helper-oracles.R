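# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: rank statistics by brute-force pair counting,
# Spearman by the classical closed form / Pearson-on-midranks, chi-squared
# by hand arithmetic.

# Mann-Whitney U for orientation "x over y": pairs with x > y, ties half.
oracle_U <- function(x, y) {
  cmp <- outer(x, y, ">") + 0.5 * outer(x, y, "==")
  sum(cmp)
}

# Spearman rho, untied data: 1 - 6 * sum(d^2) / (n (n^2 - 1)).
oracle_spearman_untied <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Spearman rho with ties: Pearson correlation of mid-ranks.
oracle_spearman_midranks <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Pearson chi-squared for a 2x2 table, closed form.
oracle_chisq_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# Shares recovered by a profile as a plain named vector.
profile_shares <- function(p) {
  c(uCuC = p$uCuC_pct, partial = p$partial_pct, mCmC = p$mCmC_pct)
}

# Convenience: run the full per-cohort pipeline; returns the cohort, the
# deconvolved profiles, and the two merged on sample_id.
run_pipeline <- function(config, seed, noise_cv = config$noise_cv,
                         sampling = "multinomial") {
  cohort <- generate_cohort(config, seed = seed)
  bands <- simulate_cohort_bands(cohort, noise_cv = noise_cv, seed = seed,
                                 sampling = sampling)
  profiles <- deconvolve_bands(bands)
  list(cohort = cohort, profiles = profiles,
       merged = merge(cohort, profiles, by = "sample_id", sort = FALSE))
}
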