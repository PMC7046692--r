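#' Policy objects and pipeline configuration
#'
#' The pipeline's tunables are grouped into small policy objects mirroring the
#' stages they control. `pipeline_config()` bundles them, validates every key,
#' and rejects unknown ones, so a typo in a config file fails loudly before any
#' stage runs.
#'
#' @name perigrow-config
NULL

#' Censored-value substitution policy
#'
#' Values reported below the analytical detection limit are left-censored.
#' They are replaced by `substitution_fraction` times the detection limit,
#' but only when the censored share of a site-analyte series does not exceed
#' `max_censored_fraction`; above that the whole series is excluded, since
#' substitution would dominate the median.
#'
#' @param substitution_fraction Fraction of the detection limit substituted
#'   for a censored value. Default 0.5 (half the detection limit).
#' @param max_censored_fraction Maximum tolerated censored share per
#'   site-analyte series; a strictly greater share excludes the series.
#'   Default 0.10.
#' @return An object of class `censoring_policy`.
#' @export
censoring_policy <- function(substitution_fraction = 0.5,
                             max_censored_fraction = 0.10) {
  stopifnot(is.numeric(substitution_fraction), length(substitution_fraction) == 1,
            substitution_fraction > 0, substitution_fraction < 1,
            is.numeric(max_censored_fraction), length(max_censored_fraction) == 1,
            max_censored_fraction > 0, max_censored_fraction < 1)
  structure(list(substitution_fraction = substitution_fraction,
                 max_censored_fraction = max_censored_fraction),
            class = "censoring_policy")
}

#' Analytical-method acceptance policy
#'
#' Total N and P are comparable across laboratories only when obtained by
#' digestion of unfiltered samples (strong acid or acidified persulfate).
#' Dissolved reactive P must come from samples filtered below
#' `drp_max_pore_um` micrometres. Nitrate-N methods in `accepted_no3_methods`
#' are treated as comparable; everything else is rejected, never corrected.
#'
#' @param accepted_tn_tp_methods Method codes accepted for TN and TP.
#' @param drp_max_pore_um Strict upper bound on filter pore size (micrometres)
#'   for DRP samples. Default 0.7; the conventional 0.45 um filtrate passes.
#' @param accepted_drp_methods Method codes accepted for DRP.
#' @param accepted_no3_methods Method codes accepted for NO3-N.
#' @return An object of class `method_policy`.
#' @export
method_policy <- function(accepted_tn_tp_methods = c("acid_digestion",
                                                     "persulfate_digestion"),
                          drp_max_pore_um = 0.7,
                          accepted_drp_methods = c("molybdenum_blue",
                                                   "ion_chromatography"),
                          accepted_no3_methods = c("ion_chromatography",
                                                   "cadmium_reduction",
                                                   "azo_dye_colorimetry",
                                                   "optical_sensor")) {
  stopifnot(length(accepted_tn_tp_methods) > 0,
            length(accepted_drp_methods) > 0,
            length(accepted_no3_methods) > 0,
            is.numeric(drp_max_pore_um), drp_max_pore_um > 0)
  structure(list(accepted_tn_tp_methods = as.character(accepted_tn_tp_methods),
                 drp_max_pore_um = drp_max_pore_um,
                 accepted_drp_methods = as.character(accepted_drp_methods),
                 accepted_no3_methods = as.character(accepted_no3_methods)),
            class = "method_policy")
}

#' Growing-season policy
#'
#' Periphyton growth peaks in the warm half of the year, so extratropical
#' records are restricted to May-October (Northern Hemisphere) or
#' November-April (Southern Hemisphere). Within the tropics
#' (|latitude| <= `tropics_abs_lat`) all months are retained.
#'
#' @param nh_months Growing-season months (integers 1-12) for latitudes north
#'   of the Tropic of Cancer.
#' @param sh_months Growing-season months for latitudes south of the Tropic of
#'   Capricorn.
#' @param tropics_abs_lat Absolute latitude of the tropics boundary, decimal
#'   degrees. Default 23.43695.
#' @return An object of class `season_policy`.
#' @export
season_policy <- function(nh_months = 5:10,
                          sh_months = c(11, 12, 1:4),
                          tropics_abs_lat = 23.43695) {
  nh <- sort(as.integer(nh_months)); sh <- sort(as.integer(sh_months))
  if (!setequal(union(nh, sh), 1:12) || length(intersect(nh, sh)) > 0)
    stop("nh_months and sh_months must be complementary halves of the year")
  stopifnot(tropics_abs_lat > 0, tropics_abs_lat < 90)
  structure(list(nh_months = nh, sh_months = sh,
                 tropics_abs_lat = tropics_abs_lat),
            class = "season_policy")
}

#' Site-eligibility policy
#'
#' A site-analyte series supports a stable median only with enough samples
#' taken regularly enough: at least `min_samples` points and a median
#' inter-sample gap of at most `max_interval_days` (about bimonthly), within
#' the most recent `window_years` of data inside `date_range`.
#'
#' @param min_samples Minimum samples per site-analyte series. Default 37.
#' @param max_interval_days Maximum median gap between consecutive samples,
#'   days. Default 61 (two months).
#' @param window_years Length of the trailing analysis window, years. Default 7.
#' @param date_range Two calendar years bounding usable data. Default
#'   `c(1990, 2016)`.
#' @return An object of class `eligibility_policy`.
#' @export
eligibility_policy <- function(min_samples = 37L,
                               max_interval_days = 61L,
                               window_years = 7L,
                               date_range = c(1990L, 2016L)) {
  stopifnot(min_samples >= 1, max_interval_days >= 1, window_years >= 1,
            length(date_range) == 2, date_range[1] <= date_range[2])
  structure(list(min_samples = as.integer(min_samples),
                 max_interval_days = as.integer(max_interval_days),
                 window_years = as.integer(window_years),
                 date_range = as.integer(date_range)),
            class = "eligibility_policy")
}

#' Catchment classification rule
#'
#' Encodes the four-way periphyton-growth/limitation rule set: the Redfield
#' mass ratio boundary separating N- from P-limitation and the TN and TP
#' concentrations above which growth is undesirable.
#'
#' @param ratio_boundary TN:TP mass ratio at and above which growth is
#'   P-limited. Default 7.
#' @param tn_threshold TN concentration (mg/L) above which growth is
#'   undesirable in N-limited catchments. Default 0.800.
#' @param tp_threshold TP concentration (mg/L) above which growth is
#'   undesirable in P-limited catchments. Default 0.046.
#' @param equality_undesirable Whether a median exactly at a concentration
#'   threshold classifies as undesirable. The rule set defines only the strict
#'   inequalities; the default `FALSE` takes the conservative reading
#'   (acceptable).
#' @return An object of class `classification_rule`.
#' @export
classification_rule <- function(ratio_boundary = 7,
                                tn_threshold = 0.800,
                                tp_threshold = 0.046,
                                equality_undesirable = FALSE) {
  stopifnot(ratio_boundary > 0, tn_threshold > 0, tp_threshold > 0,
            is.logical(equality_undesirable))
  structure(list(ratio_boundary = ratio_boundary,
                 tn_threshold = tn_threshold,
                 tp_threshold = tp_threshold,
                 equality_undesirable = isTRUE(equality_undesirable)),
            class = "classification_rule")
}

#' Pipeline configuration
#'
#' Bundles every stage tunable into one validated object. Defaults reproduce
#' the canonical analysis settings. Arguments may be supplied directly or read
#' from a YAML key-value file via `read_pipeline_config()`; unknown keys are
#' rejected.
#'
#' @param alpha Lyne-Hollick filter parameter. Default 0.925.
#' @param passes Number of filter passes (odd). Default 3.
#' @param min_baseflow Minimum day-of-sampling baseflow fraction for a sample
#'   to be retained. Default 0.75.
#' @param max_gauge_km Maximum downstream distance (km) for a site-gauge link.
#'   Default 50.
#' @param unit_anomaly_factor Multiple of the site-analyte median at or above
#'   which a value is flagged as a likely unit error. Default 100.
#' @param censoring A [censoring_policy()].
#' @param methods A [method_policy()].
#' @param season A [season_policy()].
#' @param eligibility An [eligibility_policy()].
#' @param rule A [classification_rule()].
#' @param cp_rule Subset-selection rule: `"min_cp"` (minimise Mallows Cp) or
#'   `"cp_le_p"` (smallest subset with Cp <= p).
#' @param max_exhaustive Largest predictor-group pool searched exhaustively;
#'   larger pools are pre-screened by forward steps first. Default 20.
#' @param exclude_regions Continent/region names dropped from the world row of
#'   aggregate tables. Default Antarctica and Greenland.
#' @param seed Integer seed propagated to all stochastic components.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.925,
                            passes = 3L,
                            min_baseflow = 0.75,
                            max_gauge_km = 50,
                            unit_anomaly_factor = 100,
                            censoring = censoring_policy(),
                            methods = method_policy(),
                            season = season_policy(),
                            eligibility = eligibility_policy(),
                            rule = classification_rule(),
                            cp_rule = c("min_cp", "cp_le_p"),
                            max_exhaustive = 20L,
                            exclude_regions = c("Antarctica", "Greenland"),
                            seed = 1L) {
  cp_rule <- match.arg(cp_rule)
  stopifnot(alpha > 0, alpha < 1, passes >= 1, passes %% 2 == 1,
            min_baseflow >= 0, min_baseflow <= 1, max_gauge_km >= 0,
            unit_anomaly_factor > 1,
            inherits(censoring, "censoring_policy"),
            inherits(methods, "method_policy"),
            inherits(season, "season_policy"),
            inherits(eligibility, "eligibility_policy"),
            inherits(rule, "classification_rule"),
            max_exhaustive >= 1)
  structure(list(alpha = alpha, passes = as.integer(passes),
                 min_baseflow = min_baseflow, max_gauge_km = max_gauge_km,
                 unit_anomaly_factor = unit_anomaly_factor,
                 censoring = censoring, methods = methods, season = season,
                 eligibility = eligibility, rule = rule, cp_rule = cp_rule,
                 max_exhaustive = as.integer(max_exhaustive),
                 exclude_regions = as.character(exclude_regions),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML key-value file
#'
#' Flat keys map onto [pipeline_config()] arguments; nested policy fields use
#' dotted keys, e.g. `eligibility.min_samples: 40`. Unknown keys raise an
#' error.
#'
#' @param path Path to a YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  top <- names(formals(pipeline_config))
  policies <- list(censoring = censoring_policy, methods = method_policy,
                   season = season_policy, eligibility = eligibility_policy,
                   rule = classification_rule)
  args <- list(); pol_args <- lapply(policies, function(x) list())
  for (key in names(raw)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2 && parts[1] %in% names(policies)) {
      valid <- names(formals(policies[[parts[1]]]))
      if (!parts[2] %in% valid)
        stop(sprintf("unknown config key '%s'", key))
      pol_args[[parts[1]]][[parts[2]]] <- raw[[key]]
    } else if (key %in% setdiff(top, names(policies))) {
      args[[key]] <- raw[[key]]
    } else {
      stop(sprintf("unknown config key '%s'", key))
    }
  }
  for (p in names(policies))
    if (length(pol_args[[p]]) > 0)
      args[[p]] <- do.call(policies[[p]], pol_args[[p]])
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  baseflow filter: alpha = %.3f, %d passes, min fraction %.2f\n",
              x$alpha, x$passes, x$min_baseflow))
  cat(sprintf("  site-gauge link: <= %g km downstream\n", x$max_gauge_km))
  cat(sprintf("  censoring: %g x DL substitution, exclude > %.0f%% censored\n",
              x$censoring$substitution_fraction,
              100 * x$censoring$max_censored_fraction))
  cat(sprintf("  eligibility: >= %d samples, median gap <= %d d, %d-y window, %d-%d\n",
              x$eligibility$min_samples, x$eligibility$max_interval_days,
              x$eligibility$window_years, x$eligibility$date_range[1],
              x$eligibility$date_range[2]))
  cat(sprintf("  classification: N:P boundary %g, TN > %.3f, TP > %.3f mg/L\n",
              x$rule$ratio_boundary, x$rule$tn_threshold, x$rule$tp_threshold))
  cat(sprintf("  subset selection: %s (exhaustive pool <= %d)\n",
              x$cp_rule, x$max_exhaustive))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
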