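test_that("forward simulation matches hand arithmetic in both stoichiometries", {
  counts <- c(uCuC = 100, partial = 100, mCmC = 100)

  # pool-calibrated staining: normalized abundances recover molar counts
  ab <- normalize_bands(simulate_bands(counts))
  expect_equal(ab$A, 100); expect_equal(ab$B, 100)
  expect_equal(ab$D, 200); expect_equal(ab$C, 100)
  expect_false(ab$qc_flag)

  # no cuts: all signal in the full-length band
  b <- simulate_bands(c(uCuC = 100, partial = 0, mCmC = 0))
  expect_equal(unname(b[["I117"]]), 100 * 117)
  expect_true(all(b[c("I75", "I74", "I43", "I42")] == 0))

  # physical staining: each mCmC molecule puts true lengths in BOTH bands
  b2 <- simulate_bands(c(uCuC = 0, partial = 0, mCmC = 100),
                       stoichiometry = "physical")
  expect_equal(unname(b2[["I43"]]), 100 * 43)
  expect_equal(unname(b2[["I42"]]), 100 * 42)
  expect_true(all(b2[c("I117", "I75", "I74")] == 0))

  expect_error(simulate_bands(counts, noise_cv = -0.1), "noise_cv")
  expect_error(simulate_bands(c(uCuC = 0, partial = 0, mCmC = 0)), "positive")
})

test_that("band normalization applies the printed divisors and QC clamp", {
  ab <- normalize_bands(band_intensities(117, 37.25, 37.25, 43.5, 43.5))
  expect_equal(ab$A, 1); expect_equal(ab$B, 1)
  expect_equal(ab$D, 2); expect_equal(ab$C, 1)

  ab2 <- normalize_bands(band_intensities(I117 = 117))
  expect_equal(ab2$A, 1)
  expect_equal(ab2$B, 0); expect_equal(ab2$D, 0); expect_equal(ab2$C, 0)
  expect_false(ab2$qc_flag)

  # D < B: hypermethylated abundance clamped, flagged, never dropped
  ab3 <- normalize_bands(band_intensities(0, 74.5, 74.5, 21.75, 21.75))
  expect_equal(ab3$B, 2); expect_equal(ab3$D, 1)
  expect_equal(ab3$C, 0)
  expect_true(ab3$qc_flag)

  expect_error(normalize_bands(band_intensities(0, 0, 0, 0, 0)), "zero")
})

test_that("deconvolution formulas match hand arithmetic", {
  ab <- normalize_bands(band_intensities(117, 37.25, 37.25, 43.5, 43.5))
  p <- compute_profile(ab)  # A = B = C = 1
  expect_equal(p$mC_pct, 200 / 3)
  expect_equal(p$mCmC_pct, 100 / 3)
  expect_equal(p$partial_pct, 100 / 3)
  expect_equal(p$uCuC_pct, 100 / 3)
  # equals the second printed form 100 * 2D / (2A + 2D)
  expect_equal(p$mC_pct, 100 * 2 * ab$D / (2 * ab$A + 2 * ab$D))

  p0 <- compute_profile(normalize_bands(band_intensities(I117 = 117)))
  expect_equal(p0$mC_pct, 0); expect_equal(p0$uCuC_pct, 100)

  p1 <- compute_profile(normalize_bands(band_intensities(I43 = 43.5, I42 = 43.5)))
  expect_equal(p1$mC_pct, 100); expect_equal(p1$mCmC_pct, 100)
})

test_that("profile identities hold over random abundances", {
  set.seed(42)
  for (i in 1:500) {
    x <- stats::runif(5, 0, 100)
    names(x) <- c("I117", "I75", "I74", "I43", "I42")
    p <- compute_profile(normalize_bands(x))
    expect_equal(p$mCmC_pct + p$partial_pct + p$uCuC_pct, 100,
                 tolerance = 1e-9)
    expect_equal(p$mC_pct, p$mCmC_pct + p$partial_pct, tolerance = 1e-9)
    expect_true(all(c(p$mC_pct, p$mCmC_pct, p$partial_pct, p$uCuC_pct) >= 0))
    expect_true(all(c(p$mC_pct, p$mCmC_pct, p$partial_pct, p$uCuC_pct) <= 100))
  }
})

test_that("the two printed forms of mC agree whenever C = D - B", {
  set.seed(7)
  for (i in 1:1000) {
    A <- stats::runif(1, 0, 10); B <- stats::runif(1, 0, 10)
    D <- B + stats::runif(1, 0, 10)  # guarantees D >= B
    C <- D - B
    form1 <- 100 * (2 * C + 2 * B) / (2 * A + 2 * B + 2 * C)
    form2 <- 100 * (2 * D) / (2 * A + 2 * D)
    expect_equal(form1, form2, tolerance = 1e-12)
  }
})

test_that("matched forward/inverse pairings are exact at zero noise", {
  set.seed(3)
  for (i in 1:50) {
    pr <- stats::runif(3); pr <- pr / sum(pr)
    p_std <- roundtrip(pr, n_molecules = 1000)
    expect_equal(unname(profile_shares(p_std)), 100 * pr,
                 tolerance = 1e-9)
    p_phys <- roundtrip(pr, n_molecules = 1000, stoichiometry = "physical")
    expect_equal(unname(profile_shares(p_phys)), 100 * pr,
                 tolerance = 1e-9)
  }
})

test_that("physical staining read with the study rule doubles the mCmC abundance", {
  # pure hypermethylated input: both small fragments of every molecule are
  # counted, so C = D - B comes out exactly twice the molecule count when
  # the normalization uses the model's pair-mean divisors
  b <- simulate_bands(c(uCuC = 0, partial = 0, mCmC = 100),
                      stoichiometry = "physical")
  ab <- normalize_bands(b, band_divisors("pair_mean"))
  expect_equal(ab$C, 200, tolerance = 1e-12)

  # and the recovered mCmC share is inflated accordingly on a mixture
  pr <- c(0.4, 0.3, 0.3)
  inflated <- roundtrip(pr, stoichiometry = "physical",
                        deconvolution = "standard",
                        divisors = band_divisors("pair_mean"))
  truth <- 100 * pr
  expect_gt(inflated$mCmC_pct, truth[3])
  # recovered C doubles while A and B are unchanged: share = 2C/(A+B+2C)
  expected <- 100 * 2 * pr[3] / (pr[1] + pr[2] + 2 * pr[3])
  expect_equal(inflated$mCmC_pct, expected, tolerance = 1e-9)
})

test_that("noisy multinomial round trips are unbiased within Monte Carlo error", {
  pr <- c(0.33, 0.42, 0.25)
  reps <- 200
  rec <- t(vapply(seq_len(reps), function(k) {
    profile_shares(roundtrip(pr, n_molecules = 10000, noise_cv = 0.05,
                             seed = 1000 + k, sampling = "multinomial"))
  }, numeric(3)))
  m <- colMeans(rec)
  se <- apply(rec, 2, stats::sd) / sqrt(reps)
  expect_true(all(abs(m - 100 * pr) < 3 * se))
})

test_that("band noise is reproducible under a fixed seed", {
  counts <- c(uCuC = 50, partial = 30, mCmC = 20)
  b1 <- simulate_bands(counts, noise_cv = 0.05, seed = 99)
  b2 <- simulate_bands(counts, noise_cv = 0.05, seed = 99)
  b3 <- simulate_bands(counts, noise_cv = 0.05, seed = 100)
  expect_identical(unclass(b1), unclass(b2))
  expect_false(all(b1 == b3))
})

test_that("table-level deconvolution reports per-row errors without aborting", {
  df <- data.frame(sample_id = c("ok", "bad"),
                   I117 = c(117, 0), I75 = c(37.25, 0), I74 = c(37.25, 0),
                   I43 = c(43.5, 0), I42 = c(43.5, 0))
  out <- deconvolve_bands(df)
  expect_equal(nrow(out), 2)
  expect_equal(out$partial_pct[1], 100 / 3)
  expect_true(is.na(out$partial_pct[2]))
  expect_match(out$error[2], "zero")
  expect_error(deconvolve_bands(df[, -2]), "I117")
})
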