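test_that("median and quartiles use linear interpolation", {
  expect_equal(median_iqr(c(1, 2, 3, 4, 5)),
               c(median = 3, q25 = 2, q75 = 4))
  expect_equal(median_iqr(c(1, 1, 1)), c(median = 1, q25 = 1, q75 = 1))
  expect_equal(median_iqr(c(1, 2, 3, 4)),
               c(median = 2.5, q25 = 1.75, q75 = 3.25))
  expect_error(median_iqr(numeric(0)), "no non-missing")
})

test_that("Mann-Whitney U equals brute-force pair counting", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$U_x, oracle_U(c(1, 2), c(3, 4)))

  set.seed(101)
  for (i in 1:200) {
    n1 <- sample(2:8, 1); n2 <- sample(2:12, 1)
    # mix of continuous and heavily tied data
    if (i %% 2 == 0) {
      x <- stats::rnorm(n1); y <- stats::rnorm(n2)
    } else {
      x <- sample(1:4, n1, replace = TRUE)
      y <- sample(1:4, n2, replace = TRUE)
    }
    r <- mann_whitney_u(x, y)
    Ux <- oracle_U(x, y)
    Uy <- oracle_U(y, x)
    expect_equal(r$U_x, Ux)
    expect_equal(Ux + Uy, n1 * n2)       # orientation identity
    expect_equal(r$U, min(Ux, Uy))       # SPSS-style min orientation
    expect_true(r$p >= 0 && r$p <= 1)
  }
})

test_that("identical samples give p = 1 and exact/approx p-values agree", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1, tolerance = 1e-9)
  set.seed(55)
  for (i in 1:25) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    p_ex <- mann_whitney_u(x, y, mode = "exact")$p
    p_ap <- mann_whitney_u(x, y, mode = "normal_approx")$p
    expect_lt(abs(p_ex - p_ap), 0.02)
  }
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("Spearman matches the closed form and the midrank oracle", {
  expect_equal(spearman_cor(c(1, 2, 3), c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 2, 1))$rho, -1)

  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)  # untied a.s.
    expect_equal(spearman_cor(x, y)$rho, oracle_spearman_untied(x, y),
                 tolerance = 1e-12)
  }
  # ties: Pearson on mid-ranks
  x <- c(1, 1, 2, 3); y <- c(2, 1, 4, 3)
  expect_equal(spearman_cor(x, y)$rho, oracle_spearman_midranks(x, y),
               tolerance = 1e-12)
  # p-value is the two-sided t approximation on n - 2 df
  set.seed(78)
  x <- stats::rnorm(20); y <- stats::rnorm(20)
  r <- spearman_cor(x, y)
  tstat <- r$rho * sqrt((20 - 2) / (1 - r$rho^2))
  expect_equal(r$p, 2 * stats::pt(-abs(tstat), 18), tolerance = 1e-9)

  expect_error(spearman_cor(1:3, 1:4), "equal length")
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "constant")
})

test_that("2x2 chi-squared matches closed-form Pearson arithmetic", {
  r <- chi_squared_2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r$statistic, 0); expect_equal(r$p, 1)
  expect_equal(chi_squared_2x2(matrix(c(20, 0, 0, 20), 2))$statistic, 40)
  tab <- matrix(c(20, 17, 16, 12), 2)   # rows: groups, cols: sexes
  expect_equal(chi_squared_2x2(tab)$statistic, oracle_chisq_2x2(tab),
               tolerance = 1e-12)
  expect_error(chi_squared_2x2(matrix(c(0, 0, 5, 5), 2)), "margins")
  expect_error(chi_squared_2x2(matrix(1:6, 2)), "2x2")
})

test_that("group comparison table has the study's structure", {
  cfg <- cohort_config()
  ch <- generate_cohort(cfg, seed = 21)
  bands <- simulate_cohort_bands(ch, noise_cv = cfg$noise_cv, seed = 21)
  profiles <- deconvolve_bands(bands)
  t1 <- build_table1(ch, profiles)
  expect_s3_class(t1, "cobra_table")
  expect_equal(nrow(t1), 11)
  expect_equal(t1$test[t1$variable == "Males/Females (%)"], "chi-squared")
  expect_equal(sum(t1$test == "mann-whitney"), 10)
  expect_true(all(t1$p >= 0 & t1$p <= 1))
})

test_that("identical arms produce null p-values throughout table 1", {
  cfg <- cohort_config(n_t1d = 20, n_control = 20)
  ch <- generate_cohort(cfg, seed = 31)
  # clone the T1D arm into the control arm so both groups carry the same data
  t1d <- ch[ch$group == "T1D", ]
  clone <- t1d
  clone$group <- "control"
  clone$sample_id <- sub("T1D", "CTL", clone$sample_id)
  ch2 <- rbind(t1d, clone)
  bands <- simulate_cohort_bands(ch2, noise_cv = 0, seed = 31,
                                 sampling = "exact")
  prof <- deconvolve_bands(bands)
  t1 <- build_table1(ch2, prof)
  expect_true(all(t1$p > 0.95))
})

test_that("pattern-covariate association table recovers the study's directions", {
  cfg <- cohort_config(n_t1d = 300, n_control = 50)
  r <- run_pipeline(cfg, seed = 41)
  t2 <- build_table2(r$cohort, r$profiles)
  pick <- function(v, p) t2$estimate[t2$variable == v & t2$pattern == p]
  expect_gt(pick("HbA1c", "uCmC + mCuC (%)"), 0)
  expect_gt(pick("Age at diagnosis", "mCmC (%)"), 0)
  expect_lt(pick("Age at diagnosis", "uCmC + mCuC (%)"), 0)
  # emergent within-arm coupling of total and hypermethylated levels
  expect_gt(pick("mC (%)", "mCmC (%)"), 0)
  # 5 covariates x 4 patterns + 2 MW splits x 4 + 2 pattern-vs-pattern rows
  expect_equal(nrow(t2), 30)
})

test_that("age-at-diagnosis split respects the cutoff and detects the effect", {
  cfg <- cohort_config(n_t1d = 300, n_control = 50)
  r <- run_pipeline(cfg, seed = 51)
  t3 <- build_table3(r$cohort, r$profiles, cutoff = 15)
  expect_equal(nrow(t3), 4)
  expect_equal(t3$n_young[1] + t3$n_older[1], 300)
  # a positive age-at-diagnosis effect on mCmC raises the older-onset median
  young_med <- as.numeric(sub(" .*", "", t3$young[t3$variable == "mCmC (%)"]))
  older_med <- as.numeric(sub(" .*", "", t3$older[t3$variable == "mCmC (%)"]))
  expect_gt(older_med, young_med)
  expect_error(build_table3(r$cohort, r$profiles, cutoff = 0), "empty")
})

test_that("case-control partial-pattern difference is detected in most runs", {
  cfg <- cohort_config()
  hits <- 0L
  for (k in 1:15) {
    d <- run_pipeline(cfg, seed = 600 + k)$merged
    p <- mann_whitney_u(d$partial_pct[d$group == "T1D"],
                        d$partial_pct[d$group == "control"])$p
    hits <- hits + (p < 0.05)
  }
  expect_gt(hits, 7)  # power check at the study's own sample sizes
})
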