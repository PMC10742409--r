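# Run configuration, CSV interchange and pipeline drivers tying the
# stages together: simulate -> deconvolve -> analyze, plus a round-trip
# validation run. CSV (RFC 4180, header row) is the sole tabular
# interchange; configuration is YAML (JSON is valid YAML and accepted).

RUN_CONFIG_KEYS <- c("amplicon", "stoichiometry", "deconvolution",
                     "divisors", "noise_cv", "n_molecules", "sampling",
                     "cohort", "cutoff", "seed", "out_dir", "log_level")
AMPLICON_KEYS <- c("length", "cut_site1", "cut_site2", "measurable_min")
COHORT_KEYS <- c("n_t1d", "n_control", "n_molecules", "noise_cv", "t1d",
                 "control", "covariates", "p_complications")

#' Default run configuration
#'
#' Assembles the full pipeline configuration: amplicon model geometry,
#' forward stoichiometry and matching deconvolution/divisor modes, noise
#' and molecule-count settings, the cohort generator configuration, the
#' age-at-diagnosis cutoff, seed and output directory.
#'
#' @param seed Integer run seed.
#' @param out_dir Output directory for pipeline products.
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = ".") {
  structure(list(
    amplicon = list(length = 117L, cut_site1 = 43L, cut_site2 = 75L,
                    measurable_min = 40L),
    stoichiometry = "calibrated",
    deconvolution = "standard",
    divisors = "conventional",
    noise_cv = 0.05,
    n_molecules = 10000L,
    sampling = "multinomial",
    cohort = unclass(cohort_config()),
    cutoff = 15,
    seed = as.integer(seed),
    out_dir = out_dir,
    log_level = "info"
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads YAML (or JSON) and overlays it on [default_run_config()]; unknown
#' keys are rejected with a message naming them, so typos never pass
#' silently.
#'
#' @param path Path to a YAML/JSON configuration file.
#' @return Validated list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_run_config_keys(user)
  cfg <- unclass(default_run_config())
  cfg <- merge_config(cfg, user)
  validate_run_config(cfg)
}

validate_run_config_keys <- function(user) {
  unknown <- setdiff(names(user), RUN_CONFIG_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(RUN_CONFIG_KEYS, collapse = ", "),
         call. = FALSE)
  if (!is.null(user$amplicon)) {
    bad <- setdiff(names(user$amplicon), AMPLICON_KEYS)
    if (length(bad))
      stop("unknown amplicon key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  if (!is.null(user$cohort)) {
    bad <- setdiff(names(user$cohort), COHORT_KEYS)
    if (length(bad))
      stop("unknown cohort key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
  }
  invisible(user)
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      base[[k]] <- merge_config(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_run_config <- function(cfg) {
  cfg$amplicon <- lapply(cfg$amplicon, as.integer)
  do.call(alu_amplicon, cfg$amplicon)  # validates geometry
  cfg$stoichiometry <- match.arg(cfg$stoichiometry,
                                 c("calibrated", "physical"))
  cfg$deconvolution <- match.arg(cfg$deconvolution,
                                 c("standard", "physical_corrected"))
  cfg$divisors <- match.arg(cfg$divisors, c("conventional", "pair_mean"))
  cfg$sampling <- match.arg(cfg$sampling, c("multinomial", "exact"))
  if (!is.numeric(cfg$noise_cv) || cfg$noise_cv < 0)
    stop("noise_cv must be nonnegative", call. = FALSE)
  if (cfg$n_molecules <= 0) stop("n_molecules must be positive", call. = FALSE)
  # composition/scale vectors may arrive from YAML as plain lists
  for (arm in c("t1d", "control")) {
    for (f in c("composition", "logit_scale"))
      cfg$cohort[[arm]][[f]] <- unlist(cfg$cohort[[arm]][[f]])
  }
  cfg$cohort$n_molecules <- cfg$n_molecules
  cfg$cohort$noise_cv <- cfg$noise_cv
  validate_cohort_config(cfg$cohort)
  class(cfg$cohort) <- "cohort_config"
  if (!is.numeric(cfg$cutoff)) stop("cutoff must be numeric", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' Write a run configuration to YAML
#'
#' @param config A `run_config` (or the default).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config = default_run_config(), path) {
  yaml::write_yaml(unclass_deep(config), path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

## ---- CSV interchange ----------------------------------------------------

read_checked_csv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L) stop(what, " file ", path, " has no rows", call. = FALSE)
  df
}

#' Band-intensity table I/O
#'
#' Columns: `sample_id`, `I117`, `I75`, `I74`, `I43`, `I42`.
#'
#' @param path CSV path.
#' @param bands_df Data frame to write.
#' @return `read_bands_csv` returns the validated data frame.
#' @export
read_bands_csv <- function(path) {
  read_checked_csv(path, c("sample_id", BAND_NAMES), "band-intensity")
}

#' @rdname read_bands_csv
#' @export
write_bands_csv <- function(bands_df, path) {
  utils::write.csv(bands_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Profile table I/O
#'
#' Columns: `sample_id`, `mC_pct`, `mCmC_pct`, `partial_pct`, `uCuC_pct`,
#' `qc_flag` (and optionally `error`).
#'
#' @param path CSV path.
#' @param profiles_df Data frame to write.
#' @return `read_profiles_csv` returns the validated data frame.
#' @export
read_profiles_csv <- function(path) {
  read_checked_csv(path, c("sample_id", "mC_pct", "mCmC_pct", "partial_pct",
                           "uCuC_pct", "qc_flag"), "profile")
}

#' @rdname read_profiles_csv
#' @export
write_profiles_csv <- function(profiles_df, path) {
  utils::write.csv(profiles_df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cohort table I/O
#'
#' One row per subject with the columns produced by [generate_cohort()].
#'
#' @param path CSV path.
#' @param cohort Cohort data frame to write.
#' @return `read_cohort_csv` returns the validated cohort (class
#'   `alu_cohort`).
#' @export
read_cohort_csv <- function(path) {
  df <- read_checked_csv(path, c("sample_id", "group", "age", "sex", "bmi",
                                 "sbp", "dbp", "fasting_glucose", "hba1c",
                                 "age_at_diagnosis", "duration",
                                 "complications", "p_uCuC", "p_partial",
                                 "p_mCmC", "n_molecules"), "cohort")
  df$complications <- as.logical(df$complications)
  class(df) <- c("alu_cohort", "data.frame")
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

## ---- pipeline drivers ---------------------------------------------------

pipeline_log <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[cobraAlu %s | seed %d | config %s] ",
                  as.character(utils::packageVersion("cobraAlu")),
                  cfg$seed, config_hash(unclass_deep(cfg))),
          sprintf(...))
}

#' Simulate a cohort and its band intensities
#'
#' Stage 1 of the pipeline: draws the synthetic cohort and forward-models
#' each subject's gel bands. If `config$out_dir` exists, writes
#' `cohort.csv` and `bands.csv` there.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [load_run_config()]).
#' @param write Write CSV outputs to `config$out_dir`?
#' @return List with `cohort` and `bands` data frames (invisibly returns
#'   paths as attributes when written).
#' @export
cobra_simulate <- function(config = default_run_config(), write = FALSE) {
  config <- validate_run_config(unclass_deep(config))
  model <- do.call(alu_amplicon, config$amplicon)
  cohort <- generate_cohort(config$cohort, seed = config$seed)
  bands <- simulate_cohort_bands(cohort, model = model,
                                 stoichiometry = config$stoichiometry,
                                 noise_cv = config$noise_cv,
                                 seed = config$seed,
                                 sampling = config$sampling)
  pipeline_log(config, "simulated %d T1D + %d control subjects",
               sum(cohort$group == "T1D"), sum(cohort$group == "control"))
  out <- list(cohort = cohort, bands = bands)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    write_bands_csv(bands, file.path(config$out_dir, "bands.csv"))
  }
  out
}

#' Deconvolve band intensities into pattern profiles
#'
#' Stage 2: row-wise normalization and deconvolution of a band table.
#'
#' @param bands Band-intensity data frame (or CSV path).
#' @param config A `run_config` supplying deconvolution/divisor modes.
#' @return Profile data frame (see [deconvolve_bands()]).
#' @export
cobra_deconvolve <- function(bands, config = default_run_config()) {
  config <- validate_run_config(unclass_deep(config))
  if (is.character(bands)) bands <- read_bands_csv(bands)
  model <- do.call(alu_amplicon, config$amplicon)
  prof <- deconvolve_bands(bands, deconvolution = config$deconvolution,
                           divisors = band_divisors(config$divisors, model))
  n_bad <- sum(!is.na(prof$error))
  pipeline_log(config, "deconvolved %d samples (%d failed rows, %d QC flags)",
               nrow(prof), n_bad, sum(prof$qc_flag, na.rm = TRUE))
  prof
}

#' Run the case-control statistical analysis
#'
#' Stage 3: joins cohort and profiles on `sample_id` and builds the three
#' report tables (group comparison; pattern-covariate associations;
#' age-at-diagnosis split).
#'
#' @param cohort Cohort data frame (or CSV path).
#' @param profiles Profile data frame (or CSV path).
#' @param config A `run_config` (supplies the age-at-diagnosis `cutoff`).
#' @return List of class `cobra_report` with elements `table1`, `table2`,
#'   `table3`.
#' @export
cobra_analyze <- function(cohort, profiles, config = default_run_config()) {
  config <- validate_run_config(unclass_deep(config))
  if (is.character(cohort)) cohort <- read_cohort_csv(cohort)
  if (is.character(profiles)) profiles <- read_profiles_csv(profiles)
  if (!is.null(profiles$error) && any(!is.na(profiles$error))) {
    bad <- profiles$sample_id[!is.na(profiles$error)]
    pipeline_log(config, "dropping %d unscorable sample(s): %s",
                 length(bad), paste(bad, collapse = ", "))
    profiles <- profiles[is.na(profiles$error), , drop = FALSE]
  }
  rep <- list(table1 = build_table1(cohort, profiles),
              table2 = build_table2(cohort, profiles),
              table3 = build_table3(cohort, profiles, cutoff = config$cutoff))
  sig <- rep$table1$variable[rep$table1$significant]
  pipeline_log(config, "group comparison: %d/%d rows significant at 0.05%s",
               length(sig), nrow(rep$table1),
               if (length(sig)) paste0(" (", paste(sig, collapse = "; "), ")")
               else "")
  class(rep) <- "cobra_report"
  rep
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cobra_report <- function(x, ...) {
  for (tab in x) { print(tab); cat("\n") }
  invisible(x)
}

#' End-to-end round-trip validation run
#'
#' Runs simulate -> deconvolve -> analyze under one configuration and
#' summarizes how well the pipeline recovers each subject's latent pattern
#' composition, plus per-arm medians against the calibration targets.
#'
#' @param config A `run_config`.
#' @return List of class `cobra_roundtrip`: `max_abs_error` (percentage
#'   points, recovered vs latent shares), `per_pattern_mae`, `arm_medians`
#'   (per-arm median of each recovered pattern percentage), `report`
#'   (the analysis tables) and `profiles`.
#' @export
cobra_roundtrip <- function(config = default_run_config()) {
  config <- validate_run_config(unclass_deep(config))
  sim <- cobra_simulate(config)
  prof <- cobra_deconvolve(sim$bands, config)
  d <- merge(sim$cohort, prof, by = "sample_id", sort = FALSE)
  err <- cbind(uCuC = d$uCuC_pct - 100 * d$p_uCuC,
               partial = d$partial_pct - 100 * d$p_partial,
               mCmC = d$mCmC_pct - 100 * d$p_mCmC)
  arm_medians <- do.call(rbind, lapply(split(d, d$group), function(g) {
    data.frame(group = g$group[1],
               mC = stats::median(g$mC_pct),
               mCmC = stats::median(g$mCmC_pct),
               partial = stats::median(g$partial_pct),
               uCuC = stats::median(g$uCuC_pct))
  }))
  rownames(arm_medians) <- NULL
  report <- cobra_analyze(sim$cohort, prof, config)
  structure(list(max_abs_error = max(abs(err)),
                 per_pattern_mae = colMeans(abs(err)),
                 arm_medians = arm_medians,
                 report = report, profiles = prof, cohort = sim$cohort),
            class = "cobra_roundtrip")
}

#' @export
print.cobra_roundtrip <- function(x, ...) {
  cat("COBRA-Alu round-trip validation\n")
  cat(sprintf("  max |recovered - latent| share error: %.3g percentage points\n",
              x$max_abs_error))
  cat(sprintf("  mean absolute error: uCuC %.3g, partial %.3g, mCmC %.3g\n",
              x$per_pattern_mae["uCuC"], x$per_pattern_mae["partial"],
              x$per_pattern_mae["mCmC"]))
  cat("  per-arm medians of recovered percentages:\n")
  print(x$arm_medians, row.names = FALSE)
  invisible(x)
}
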