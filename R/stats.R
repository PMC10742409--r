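# Nonparametric statistical layer mirroring the study's reporting:
# median/IQR summaries, Mann-Whitney U (SPSS-style min-U orientation),
# Spearman rank correlation with the t approximation, Pearson chi-squared
# for the sex split, and the three report tables. No multiple-testing
# adjustment is applied (single-threshold reporting at p < 0.05), by
# design.

#' Median and interquartile range
#'
#' Quartiles use linear interpolation (R's default type 7).
#'
#' @param values Nonempty numeric vector (NAs dropped).
#' @return Named numeric vector `c(median = , q25 = , q75 = )`.
#' @examples
#' median_iqr(c(1, 2, 3, 4))  # 2.5, 1.75, 3.25
#' @export
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("median_iqr: no non-missing values", call. = FALSE)
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), names = FALSE, type = 7)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison. The reported `U` is the smaller of the
#' two orientation statistics (`U + U' = n1 * n2`), the convention used by
#' SPSS-style reports. `mode = "exact"` enumerates the exact null
#' distribution (no ties; delegated to [stats::wilcox.test()]), falling
#' back to the approximation under ties; `"normal_approx"` uses the
#' tie-corrected normal approximation with continuity correction; `"auto"`
#' picks exact for `min(n) <= 8` untied data.
#'
#' @param x,y Nonempty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return List: `U` (min-orientation statistic), `U_x` (pairs where `x`
#'   exceeds `y`, ties half), `p` (two-sided), `n` (c(n_x, n_y)).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))$U  # 0
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("mann_whitney_u: both groups must be nonempty", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U_x <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U <- min(U_x, n1 * n2 - U_x)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  exact = TRUE,
                  normal_approx = FALSE,
                  auto = min(n1, n2) <= 8 && !has_ties)
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  list(U = U, U_x = U_x, p = min(1, p), n = c(n_x = n1, n_y = n2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties); two-sided
#' p-value from the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 (pairwise-complete).
#' @return List: `rho`, `p`, `n`.
#' @examples
#' spearman_cor(1:5, c(2, 1, 4, 3, 5))
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_cor: x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_cor: need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("spearman_cor: rho undefined for constant input", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' No continuity correction by default, matching the comparison of
#' moderate-sized proportions in the study tables; set `correct = TRUE`
#' for Yates' correction.
#'
#' @param tab 2x2 matrix of nonnegative counts with positive margins.
#' @param correct Apply Yates' continuity correction?
#' @return List: `statistic` (1 df), `p`.
#' @examples
#' chi_squared_2x2(matrix(c(10, 10, 10, 10), 2))
#' @export
chi_squared_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("chi_squared_2x2: table must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi_squared_2x2: counts must be nonnegative with positive margins",
         call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

fmt_med_iqr <- function(v, digits = 1) {
  m <- median_iqr(v)
  sprintf(paste0("%.", digits, "f (%.", digits, "f-%.", digits, "f)"),
          m["median"], m["q25"], m["q75"])
}

attach_profiles <- function(cohort, profiles) {
  stopifnot(is.data.frame(cohort), is.data.frame(profiles))
  need <- c("sample_id", "mC_pct", "mCmC_pct", "partial_pct", "uCuC_pct")
  miss <- setdiff(need, names(profiles))
  if (length(miss))
    stop("profiles table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  orphans <- setdiff(cohort$sample_id, profiles$sample_id)
  if (length(orphans))
    stop("no deconvolved profile for sample(s): ",
         paste(orphans, collapse = ", "), call. = FALSE)
  merge(cohort, profiles[need], by = "sample_id", sort = FALSE)
}

#' Case-control characteristics and methylation pattern table
#'
#' Per-variable group comparison of the T1D and control arms: median (IQR)
#' per arm with a Mann-Whitney test, except sex which is summarized as
#' male/female percentages and tested with Pearson chi-squared.
#'
#' @param cohort An `alu_cohort` data frame.
#' @param profiles Deconvolved profile table (from [deconvolve_bands()])
#'   joinable to the cohort on `sample_id`.
#' @return Data frame of class `cobra_table`: `variable`, `t1d`, `control`
#'   (formatted summaries), `statistic`, `test`, `p`, `significant`.
#' @export
build_table1 <- function(cohort, profiles) {
  d <- attach_profiles(cohort, profiles)
  g1 <- d[d$group == "T1D", ]
  g0 <- d[d$group == "control", ]
  if (!nrow(g1) || !nrow(g0))
    stop("build_table1: cohort must contain both arms", call. = FALSE)

  num_vars <- c("Age (years)" = "age",
                "Systolic blood pressure (mmHg)" = "sbp",
                "Diastolic blood pressure (mmHg)" = "dbp",
                "BMI (kg/m2)" = "bmi",
                "Fasting glucose (mg/dl)" = "fasting_glucose",
                "HbA1c (%)" = "hba1c",
                "mC (%)" = "mC_pct",
                "mCmC (%)" = "mCmC_pct",
                "uCmC + mCuC (%)" = "partial_pct",
                "uCuC (%)" = "uCuC_pct")

  sex_tab <- rbind(table(factor(g1$sex, c("male", "female"))),
                   table(factor(g0$sex, c("male", "female"))))
  chi <- chi_squared_2x2(sex_tab)
  rows <- list(data.frame(
    variable = "Males/Females (%)",
    t1d = sprintf("%.1f/%.1f", 100 * mean(g1$sex == "male"),
                  100 * mean(g1$sex == "female")),
    control = sprintf("%.1f/%.1f", 100 * mean(g0$sex == "male"),
                      100 * mean(g0$sex == "female")),
    statistic = chi$statistic, test = "chi-squared", p = chi$p,
    stringsAsFactors = FALSE))

  for (i in seq_along(num_vars)) {
    v <- num_vars[i]
    mw <- mann_whitney_u(g1[[v]], g0[[v]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = names(num_vars)[i],
      t1d = fmt_med_iqr(g1[[v]]), control = fmt_med_iqr(g0[[v]]),
      statistic = mw$U, test = "mann-whitney", p = mw$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  # present in study order: age, sex, pressures, BMI, glucose, HbA1c, patterns
  out <- out[c(2, 1, 3:11), ]
  rownames(out) <- NULL
  out$significant <- out$p < 0.05
  class(out) <- c("cobra_table", "data.frame")
  attr(out, "title") <- "Characteristics and Alu methylation patterns by group"
  out
}

#' Pattern-covariate association table (T1D arm)
#'
#' Within the patient arm: Spearman correlations of each continuous
#' characteristic (age, age at diagnosis, disease duration, fasting
#' glucose, HbA1c) with each of the four pattern quantities; Mann-Whitney
#' comparisons across sex and complications status; and the within-arm
#' pattern-vs-pattern correlations (mC vs mCmC, mC vs partial).
#'
#' @inheritParams build_table1
#' @return Data frame of class `cobra_table`: `variable`, `pattern`,
#'   `test`, `estimate` (rho or U), `p`, `n`, `significant`.
#' @export
build_table2 <- function(cohort, profiles) {
  d <- attach_profiles(cohort, profiles)
  g1 <- d[d$group == "T1D", ]
  if (!nrow(g1)) stop("build_table2: no T1D subjects", call. = FALSE)

  patterns <- c("mC (%)" = "mC_pct", "mCmC (%)" = "mCmC_pct",
                "uCmC + mCuC (%)" = "partial_pct", "uCuC (%)" = "uCuC_pct")
  covs <- c("Age" = "age", "Age at diagnosis" = "age_at_diagnosis",
            "Duration of disease" = "duration",
            "Fasting glucose" = "fasting_glucose", "HbA1c" = "hba1c")

  rows <- list()
  for (i in seq_along(covs)) {
    for (j in seq_along(patterns)) {
      sp <- spearman_cor(g1[[covs[i]]], g1[[patterns[j]]])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = names(covs)[i], pattern = names(patterns)[j],
        test = "spearman", estimate = sp$rho, p = sp$p, n = sp$n,
        stringsAsFactors = FALSE)
    }
  }
  for (split_var in c("sex", "complications")) {
    f <- if (split_var == "sex") g1$sex == "male" else g1$complications
    lab <- if (split_var == "sex") "Sex (male vs female)" else
      "Chronic complications (yes vs no)"
    for (j in seq_along(patterns)) {
      mw <- mann_whitney_u(g1[[patterns[j]]][f], g1[[patterns[j]]][!f])
      rows[[length(rows) + 1L]] <- data.frame(
        variable = lab, pattern = names(patterns)[j],
        test = "mann-whitney", estimate = mw$U, p = mw$p, n = sum(!is.na(f)),
        stringsAsFactors = FALSE)
    }
  }
  for (pat in c("mCmC (%)", "uCmC + mCuC (%)")) {
    sp <- spearman_cor(g1$mC_pct, g1[[patterns[pat]]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "mC (%)", pattern = pat, test = "spearman",
      estimate = sp$rho, p = sp$p, n = sp$n, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  class(out) <- c("cobra_table", "data.frame")
  attr(out, "title") <-
    "Associations of Alu methylation patterns with patient characteristics (T1D arm)"
  out
}

#' Pattern comparison by age at diagnosis
#'
#' Splits the T1D arm at `age_at_diagnosis < cutoff` versus `>= cutoff`
#' (the cutoff itself falls in the older-onset group) and compares each
#' pattern quantity across strata with the Mann-Whitney test.
#'
#' @inheritParams build_table1
#' @param cutoff Age-at-diagnosis cutoff in years.
#' @return Data frame of class `cobra_table`: `variable`, `young`, `older`
#'   (formatted median (IQR)), `n_young`, `n_older`, `statistic`, `p`,
#'   `significant`.
#' @export
build_table3 <- function(cohort, profiles, cutoff = 15) {
  d <- attach_profiles(cohort, profiles)
  g1 <- d[d$group == "T1D", ]
  if (!nrow(g1)) stop("build_table3: no T1D subjects", call. = FALSE)
  young <- g1$age_at_diagnosis < cutoff
  if (!any(young) || all(young))
    stop("build_table3: empty age-at-diagnosis stratum at cutoff ", cutoff,
         call. = FALSE)
  patterns <- c("mC (%)" = "mC_pct", "mCmC (%)" = "mCmC_pct",
                "uCmC + mCuC (%)" = "partial_pct", "uCuC (%)" = "uCuC_pct")
  rows <- lapply(seq_along(patterns), function(j) {
    v <- patterns[j]
    mw <- mann_whitney_u(g1[[v]][young], g1[[v]][!young])
    data.frame(variable = names(patterns)[j],
               young = fmt_med_iqr(g1[[v]][young], digits = 2),
               older = fmt_med_iqr(g1[[v]][!young], digits = 2),
               n_young = sum(young), n_older = sum(!young),
               statistic = mw$U, p = mw$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p < 0.05
  class(out) <- c("cobra_table", "data.frame")
  attr(out, "title") <- sprintf(
    "Methylation patterns by age at T1D diagnosis (< %s vs >= %s years)",
    cutoff, cutoff)
  out
}

#' @export
print.cobra_table <- function(x, digits = 3, ...) {
  title <- attr(x, "title")
  if (!is.null(title)) cat(title, "\n\n")
  y <- as.data.frame(x)
  for (col in c("statistic", "estimate"))
    if (col %in% names(y)) y[[col]] <- signif(y[[col]], digits)
  if ("p" %in% names(y))
    y$p <- ifelse(y$p < 0.001, "<0.001", formatC(y$p, digits = 3, format = "f"))
  print(y, row.names = FALSE, right = FALSE)
  invisible(x)
}
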