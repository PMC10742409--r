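# Densitometry layer: forward model from pattern-class molecule counts to
# the five gel band intensities, and the deconvolution back to pattern
# percentages.
#
# Physics behind the normalization: SYBR-type stain signal is proportional
# to DNA mass, i.e. fragment length x molarity. Dividing each band's
# intensity by its fragment length therefore recovers molar abundance,
# which is exactly what the study's divide-by-length step does (117 for the
# full-length band, 74.5 for the pooled 74/75 pair, 43.5 for the pooled
# 42/43 pair).

BAND_NAMES <- c("I117", "I75", "I74", "I43", "I42")

#' Band intensity vector constructor
#'
#' @param I117,I75,I74,I43,I42 Nonnegative intensities (arbitrary
#'   densitometry units) of the five gel bands.
#' @return Named numeric vector of class `band_intensities`.
#' @export
band_intensities <- function(I117 = 0, I75 = 0, I74 = 0, I43 = 0, I42 = 0) {
  x <- c(I117 = I117, I75 = I75, I74 = I74, I43 = I43, I42 = I42)
  validate_bands(x)
  structure(x, class = c("band_intensities", "numeric"))
}

validate_bands <- function(x) {
  if (!is.numeric(x) || length(x) != 5L || !all(BAND_NAMES %in% names(x)))
    stop("band intensities must be a numeric vector with elements ",
         paste(BAND_NAMES, collapse = ", "), call. = FALSE)
  if (any(!is.finite(x)) || any(x < 0))
    stop("band intensities must be finite and nonnegative", call. = FALSE)
  if (all(x == 0))
    stop("all five band intensities are zero: sample is not scorable",
         call. = FALSE)
  invisible(x)
}

#' Normalization divisors for the three band pools
#'
#' The deconvolution divides each band pool by a representative fragment
#' length. `"conventional"` uses the assay's standard divisors 117 / 74.5 / 43.5.
#' Note the printed small-pool divisor (43.5) is not the mean of the 43/42
#' fragment pair (42.5), while the mid-pool divisor 74.5 is the 74/75 pair
#' mean; `"pair_mean"` instead derives all three divisors from the amplicon
#' model's actual fragment pairs (117 / 74.5 / 42.5 with the defaults),
#' giving a normalization that is exactly consistent with physical
#' per-fragment staining.
#'
#' @param mode `"conventional"` or `"pair_mean"`.
#' @param model An [alu_amplicon()] model (used by `"pair_mean"`).
#' @return Named numeric vector `c(full = , mid = , small = )`.
#' @export
band_divisors <- function(mode = c("conventional", "pair_mean"),
                          model = alu_amplicon()) {
  mode <- match.arg(mode)
  if (mode == "conventional") {
    c(full = 117, mid = 74.5, small = 43.5)
  } else {
    full <- model$length
    mid <- (model$cut_site2 + (model$length - model$cut_site1)) / 2
    small <- (model$cut_site1 + (model$length - model$cut_site2)) / 2
    c(full = full, mid = mid, small = small)
  }
}

#' Forward-simulate gel band intensities from pattern counts
#'
#' Each molecule is digested according to its pattern and deposits
#' mass-proportional stain signal into the bands of its measured fragments.
#' Two stoichiometry conventions are provided:
#'
#' * `"physical"`: each fragment deposits its true length (so a
#'   double-cut `mCmC` molecule contributes to *both* the 43 and 42 bp
#'   bands). Under the study's `C = D - B` rule this double counting
#'   inflates the recovered hypermethylated abundance about two-fold; the
#'   matching inverse is `deconvolution = "physical_corrected"` on
#'   `"pair_mean"`-normalized abundances.
#' * `"calibrated"`: each molecule contributes exactly one
#'   pool-calibrated deposit per cut outcome — 117 for the uncut band, one
#'   deposit of 74.5 into the mid pool and (for partials) one of 43.5 into
#'   the small pool, and for `mCmC` a single 43.5 deposit alternated
#'   between the 43/42 bands. With the study's divisors this makes the
#'   normalized abundances satisfy `A = n_uCuC`, `B = n_partial`,
#'   `D = B + C` exactly, so the printed formulas invert the forward model
#'   with zero error.
#'
#' Partially methylated molecules split 50/50 between the two single-cut
#' fragment-pair assignments (site 1 -> 43+74, site 2 -> 75+42); the split
#' is applied to signal mass, not sampled. The internal 32 bp double-cut
#' fragment is below the scoring range and deposits nothing.
#'
#' @param counts Named numeric vector `c(uCuC = , partial = , mCmC = )` of
#'   molecule counts (nonnegative, not all zero; need not be integer).
#' @param model An [alu_amplicon()] model.
#' @param stoichiometry `"calibrated"` (default) or `"physical"`.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   band noise (0 disables noise).
#' @param seed Optional integer seed making the noise reproducible.
#' @return A [band_intensities()] vector.
#' @examples
#' simulate_bands(c(uCuC = 100, partial = 0, mCmC = 0))
#' @export
simulate_bands <- function(counts, model = alu_amplicon(),
                           stoichiometry = c("calibrated", "physical"),
                           noise_cv = 0, seed = NULL) {
  stoichiometry <- match.arg(stoichiometry)
  stopifnot(inherits(model, "alu_amplicon"))
  if (!is.numeric(counts) || length(counts) != 3L ||
      !all(c("uCuC", "partial", "mCmC") %in% names(counts)))
    stop("counts must be a numeric vector with elements uCuC, partial, mCmC",
         call. = FALSE)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("pattern counts must be nonnegative with a positive total",
         call. = FALSE)
  if (!is.numeric(noise_cv) || length(noise_cv) != 1L || noise_cv < 0)
    stop("noise_cv must be a single nonnegative number", call. = FALSE)

  n_u <- counts[["uCuC"]]; n_p <- counts[["partial"]]; n_m <- counts[["mCmC"]]
  len <- model$length
  f1_small <- model$cut_site1                  # 43 with defaults
  f1_mid   <- len - model$cut_site1            # 74
  f2_mid   <- model$cut_site2                  # 75
  f2_small <- len - model$cut_site2            # 42

  x <- c(I117 = 0, I75 = 0, I74 = 0, I43 = 0, I42 = 0)
  if (stoichiometry == "physical") {
    x["I117"] <- n_u * len
    x["I74"] <- (n_p / 2) * f1_mid
    x["I75"] <- (n_p / 2) * f2_mid
    x["I43"] <- (n_p / 2) * f1_small + n_m * f1_small
    x["I42"] <- (n_p / 2) * f2_small + n_m * f2_small
  } else {
    div <- band_divisors("conventional")
    x["I117"] <- n_u * div[["full"]]
    x["I74"] <- (n_p / 2) * div[["mid"]]
    x["I75"] <- (n_p / 2) * div[["mid"]]
    # one small-pool deposit per partial molecule (site 1 -> 43 band,
    # site 2 -> 42 band) and one per mCmC molecule, alternated 50/50
    x["I43"] <- (n_p / 2) * div[["small"]] + (n_m / 2) * div[["small"]]
    x["I42"] <- (n_p / 2) * div[["small"]] + (n_m / 2) * div[["small"]]
  }

  if (noise_cv > 0) {
    if (!is.null(seed)) {
      old <- globalenv()$.Random.seed
      on.exit(restore_rng(old), add = TRUE)
      set.seed(as.integer(seed))
    }
    sdlog <- sqrt(log(1 + noise_cv^2))
    x <- x * stats::rlnorm(5L, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  structure(x, class = c("band_intensities", "numeric"))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Length-normalize band intensities to molar abundances
#'
#' Divides each band pool by its fragment-length divisor: `A` from the full
#' 117 bp band, `B` from the pooled 74/75 bands, `D` from the pooled 42/43
#' bands, and derives the hypermethylated abundance `C = D - B`. If noise
#' drives `D` below `B`, `C` is clamped to 0 and a QC flag is set — the
#' sample is reported, never silently dropped.
#'
#' @param bands A [band_intensities()] vector (or named numeric with the
#'   same elements).
#' @param divisors Divisor set from [band_divisors()].
#' @return List of class `alu_abundances`: `A`, `B`, `C`, `D`, `qc_flag`.
#' @examples
#' normalize_bands(band_intensities(117, 37.25, 37.25, 43.5, 43.5))
#' @export
normalize_bands <- function(bands, divisors = band_divisors("conventional")) {
  validate_bands(bands)
  stopifnot(is.numeric(divisors),
            all(c("full", "mid", "small") %in% names(divisors)))
  A <- bands[["I117"]] / divisors[["full"]]
  B <- (bands[["I75"]] + bands[["I74"]]) / divisors[["mid"]]
  D <- (bands[["I43"]] + bands[["I42"]]) / divisors[["small"]]
  C <- D - B
  qc <- C < 0
  if (qc) C <- 0
  structure(list(A = A, B = B, C = C, D = D, qc_flag = qc),
            class = "alu_abundances")
}

#' @export
print.alu_abundances <- function(x, ...) {
  cat(sprintf("normalized band abundances: A = %.4g, B = %.4g, C = %.4g, D = %.4g%s\n",
              x$A, x$B, x$C, x$D,
              if (x$qc_flag) "  [QC: D < B, C clamped to 0]" else ""))
  invisible(x)
}

#' Deconvolve normalized abundances into pattern percentages
#'
#' Applies the study's densitometric formulas:
#' \deqn{\%mCmC = 100\,C/(A+B+C),\quad \%uCuC = 100\,A/(A+B+C),}
#' \deqn{\%(uCmC{+}mCuC) = 100\,B/(A+B+C),}
#' \deqn{\%mC = 100\,(2C+2B)/(2A+2B+2C) = 100\,(2D)/(2A+2D)\ \textrm{when}\ C = D-B.}
#' `mC` is computed as `mCmC + partial`, which equals both printed forms
#' whenever `C = D - B` and keeps the profile identities exact even when
#' `C` was clamped.
#'
#' `deconvolution = "physical_corrected"` first replaces `C` with
#' `(D - B)/2`, undoing the two-measured-fragments-per-`mCmC`-molecule
#' double counting of the physical forward model (pair it with
#' `"pair_mean"` divisors for an exact inverse).
#'
#' @param abund An `alu_abundances` object from [normalize_bands()].
#' @param deconvolution `"standard"` (default) or `"physical_corrected"`.
#' @return List of class `alu_profile`: `mC_pct`, `mCmC_pct`,
#'   `partial_pct`, `uCuC_pct`, `qc_flag`.
#' @examples
#' ab <- normalize_bands(band_intensities(117, 37.25, 37.25, 43.5, 43.5))
#' compute_profile(ab)
#' @export
compute_profile <- function(abund,
                            deconvolution = c("standard", "physical_corrected")) {
  deconvolution <- match.arg(deconvolution)
  stopifnot(inherits(abund, "alu_abundances"))
  A <- abund$A; B <- abund$B; C <- abund$C
  qc <- abund$qc_flag
  if (deconvolution == "physical_corrected") {
    C <- (abund$D - abund$B) / 2
    if (C < 0) { C <- 0; qc <- TRUE }
  }
  tot <- A + B + C
  if (tot <= 0)
    stop("A + B + C must be positive to deconvolve a profile", call. = FALSE)
  mCmC <- 100 * C / tot
  uCuC <- 100 * A / tot
  partial <- 100 * B / tot
  structure(list(mC_pct = mCmC + partial, mCmC_pct = mCmC,
                 partial_pct = partial, uCuC_pct = uCuC, qc_flag = qc),
            class = "alu_profile")
}

#' @export
print.alu_profile <- function(x, ...) {
  cat(sprintf("Alu methylation profile: mC %.1f%%, mCmC %.1f%%, partial (uCmC+mCuC) %.1f%%, uCuC %.1f%%%s\n",
              x$mC_pct, x$mCmC_pct, x$partial_pct, x$uCuC_pct,
              if (x$qc_flag) "  [QC flag]" else ""))
  invisible(x)
}

#' Forward-and-back round trip on one sample
#'
#' Composes [simulate_bands()], [normalize_bands()] and [compute_profile()].
#' With `sampling = "exact"`, zero noise and matched stoichiometry /
#' deconvolution pairing this is the identity on pattern shares (up to
#' floating point); with `sampling = "multinomial"` molecule counts are
#' drawn multinomially first.
#'
#' The stoichiometry determines the matching inverse: `"calibrated"`
#' pairs with `"conventional"` divisors and `"standard"` deconvolution,
#' `"physical"` with
#' `"pair_mean"` divisors and `"physical_corrected"`; pass `divisors` /
#' `deconvolution` explicitly to study mismatched pairings (e.g. the ~2x
#' `C` inflation of physical staining read with the study's rule).
#'
#' @param proportions Numeric length-3 vector of pattern proportions
#'   (`uCuC`, `partial`, `mCmC`), normalized to sum to 1.
#' @param n_molecules Number of molecules in the sample.
#' @param noise_cv Band noise CV, as in [simulate_bands()].
#' @param seed Optional integer seed (noise and multinomial sampling).
#' @param model An [alu_amplicon()] model.
#' @param stoichiometry Forward mode, as in [simulate_bands()].
#' @param deconvolution Inverse mode; default matches `stoichiometry`.
#' @param divisors Normalization divisors; default matches `stoichiometry`.
#' @param sampling `"exact"` (deterministic expected counts) or
#'   `"multinomial"`.
#' @return An `alu_profile`.
#' @examples
#' roundtrip(c(1, 1, 1) / 3, n_molecules = 300)
#' @export
roundtrip <- function(proportions, n_molecules = 10000, noise_cv = 0,
                      seed = NULL, model = alu_amplicon(),
                      stoichiometry = c("calibrated", "physical"),
                      deconvolution = NULL, divisors = NULL,
                      sampling = c("exact", "multinomial")) {
  stoichiometry <- match.arg(stoichiometry)
  sampling <- match.arg(sampling)
  stopifnot(is.numeric(proportions), length(proportions) == 3L,
            all(proportions >= 0), sum(proportions) > 0, n_molecules > 0)
  proportions <- proportions / sum(proportions)
  if (is.null(deconvolution))
    deconvolution <- switch(stoichiometry, calibrated = "standard",
                            physical = "physical_corrected")
  if (is.null(divisors))
    divisors <- switch(stoichiometry,
                       calibrated = band_divisors("conventional"),
                       physical = band_divisors("pair_mean", model))
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  counts <- if (sampling == "exact") {
    n_molecules * proportions
  } else {
    as.numeric(stats::rmultinom(1L, size = n_molecules, prob = proportions))
  }
  names(counts) <- c("uCuC", "partial", "mCmC")
  bands <- simulate_bands(counts, model = model, stoichiometry = stoichiometry,
                          noise_cv = noise_cv, seed = NULL)
  compute_profile(normalize_bands(bands, divisors = divisors),
                  deconvolution = deconvolution)
}

#' Deconvolve a table of band intensities
#'
#' Row-wise [normalize_bands()] + [compute_profile()] over a band-intensity
#' table (columns `sample_id`, `I117`, `I75`, `I74`, `I43`, `I42`). Rows
#' that cannot be scored (e.g. all-zero bands) are reported with `NA`
#' percentages and an error message rather than aborting the run.
#'
#' @param bands_df Data frame of band intensities, one row per sample.
#' @param deconvolution,divisors As in [compute_profile()] /
#'   [normalize_bands()].
#' @return Data frame: `sample_id`, `mC_pct`, `mCmC_pct`, `partial_pct`,
#'   `uCuC_pct`, `qc_flag`, `error` (NA when the row deconvolved cleanly).
#' @export
deconvolve_bands <- function(bands_df, deconvolution = "standard",
                             divisors = band_divisors("conventional")) {
  need <- c("sample_id", BAND_NAMES)
  missing_cols <- setdiff(need, names(bands_df))
  if (length(missing_cols))
    stop("band table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(bands_df) == 0L) stop("band table has no rows", call. = FALSE)
  out <- lapply(seq_len(nrow(bands_df)), function(i) {
    row <- bands_df[i, ]
    x <- as.numeric(row[BAND_NAMES]); names(x) <- BAND_NAMES
    prof <- tryCatch({
      p <- compute_profile(normalize_bands(x, divisors = divisors),
                           deconvolution = deconvolution)
      data.frame(sample_id = row$sample_id, mC_pct = p$mC_pct,
                 mCmC_pct = p$mCmC_pct, partial_pct = p$partial_pct,
                 uCuC_pct = p$uCuC_pct, qc_flag = p$qc_flag,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(sample_id = row$sample_id, mC_pct = NA_real_,
                 mCmC_pct = NA_real_, partial_pct = NA_real_,
                 uCuC_pct = NA_real_, qc_flag = NA,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    prof
  })
  do.call(rbind, out)
}
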