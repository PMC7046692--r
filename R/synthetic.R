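#' Synthetic worlds with known ground truth
#'
#' Every pipeline input can be generated at toy scale with its truth
#' recorded: sparse log-linear catchment medians, log-normal site samples
#' with left-censoring at the detection limit, hydrographs with slow baseflow
#' recession plus fast-decaying storm pulses, and a literature-style
#' threshold survey. All generators are pure functions of their parameters
#' and a seed.
#'
#' @name synthetic-data
NULL

CONTINENTS <- c("Africa", "Asia", "Europe", "North America", "Oceania",
                "South America")

#' Generate a daily discharge series
#'
#' Flow is a slowly recessing baseflow component (recharged a little by each
#' storm) plus Poisson-arriving storm pulses that decay with a two-day
#' half-life — fast enough that the 75% baseflow criterion excludes a
#' nontrivial share of days when storms are frequent.
#'
#' @param n_days Length of record.
#' @param base_level Long-run baseflow, m3/s.
#' @param recession_rate Daily relaxation rate of baseflow toward
#'   `base_level`. Default 0.05.
#' @param storm_rate Per-day probability of a storm pulse. Default 0.04
#'   (a storm roughly every three to four weeks, giving a baseflow index
#'   near 0.6 while still excluding a nontrivial share of sampling days).
#' @param storm_size Mean pulse peak as a multiple of `base_level`. Default 6.
#' @param recharge_frac Fraction of a pulse routed into baseflow. Default 0.1.
#' @param start_date First day of record.
#' @param gauge_id Gauge label.
#' @param seed Integer seed.
#' @return A list with `discharge` (a `discharge` data frame) and `bfi_true`
#'   (the generated baseflow share of total flow).
#' @export
gen_discharge <- function(n_days = 730, base_level = 5, recession_rate = 0.05,
                          storm_rate = 0.04, storm_size = 6,
                          recharge_frac = 0.1,
                          start_date = as.Date("2010-01-01"),
                          gauge_id = "G001", seed = 1L) {
  stopifnot(n_days >= 2, base_level > 0, recession_rate > 0,
            storm_rate >= 0, storm_rate <= 1, storm_size > 0)
  set.seed(seed)
  decay <- 2^(-1 / 2)                      # two-day half-life
  b <- numeric(n_days); q <- numeric(n_days)
  b[1] <- base_level
  pulse_mean <- storm_size * base_level
  for (t in seq_len(n_days)) {
    if (t > 1) {
      b[t] <- base_level + (b[t - 1] - base_level) * exp(-recession_rate)
      q[t] <- q[t - 1] * decay
    }
    if (stats::runif(1) < storm_rate) {
      pulse <- stats::rexp(1, rate = 1 / pulse_mean)
      q[t] <- q[t] + (1 - recharge_frac) * pulse
      b[t] <- b[t] + recharge_frac * pulse
    }
  }
  flow <- b + q
  list(discharge = data.frame(gauge_id = gauge_id,
                              date = start_date + seq_len(n_days) - 1,
                              flow_m3s = flow, stringsAsFactors = FALSE),
       bfi_true = sum(b) / sum(flow))
}

#' Generate a catchment predictor table with sparse linear truth
#'
#' Continuous predictors are standard normal catchment means; one categorical
#' "biome" has five levels. The true systematic log median for each analyte
#' is `intercept + X beta_true` with `n_active` nonzero coefficients of
#' magnitude `beta_scale` (the biome carries no effect, so selection should
#' leave it out). Observed catchment medians add a log-normal residual of
#' standard deviation `sigma`, the catchment-level scatter the regression is
#' expected to absorb. Intercepts default to the logs of the TN and TP growth
#' thresholds, centring each analyte on its classification boundary.
#'
#' @param n_catchments Number of catchments.
#' @param n_predictors Number of continuous candidate predictors. Default 10.
#' @param n_active Number with nonzero true effect. Default 2.
#' @param beta_scale Magnitude of active coefficients (log space). Default 1.
#' @param sigma Residual standard deviation, log space. Default 0.3.
#' @param analytes Analytes to generate. Default TN and TP.
#' @param intercepts Named log-space intercepts per analyte.
#' @param seed Integer seed.
#' @return A list with `catchments` (a `catchments` data frame with predictor
#'   columns `pred01`... and `biome`), `truth` (class `synthetic_truth`:
#'   `beta`, `active`, `intercepts`, `sigma`, `lp` and `eps` matrices,
#'   `seed`), and `medians_obs` (catchment_id, analyte, median_mgL =
#'   `exp(lp + eps)`).
#' @export
gen_catchment_table <- function(n_catchments = 60, n_predictors = 10,
                                n_active = 2, beta_scale = 1, sigma = 0.3,
                                analytes = c("TN", "TP"),
                                intercepts = c(TN = log(0.800),
                                               TP = log(0.046)),
                                seed = 1L) {
  stopifnot(n_active <= n_predictors, sigma >= 0,
            all(analytes %in% names(intercepts)))
  set.seed(seed)
  ids <- sprintf("C%04d", seq_len(n_catchments))
  pn <- sprintf("pred%02d", seq_len(n_predictors))
  X <- matrix(stats::rnorm(n_catchments * n_predictors), n_catchments,
              dimnames = list(ids, pn))
  biome <- sample(paste0("biome_", LETTERS[1:5]), n_catchments, replace = TRUE)
  area <- 10^stats::runif(n_catchments, 3, 5)
  pop <- round(area * 20 * exp(0.5 * X[, 1] + stats::rnorm(n_catchments, 0, 0.5)))
  sh <- matrix(stats::runif(n_catchments * 3), n_catchments)
  sh <- sh / rowSums(sh)
  beta <- matrix(0, n_predictors, length(analytes),
                 dimnames = list(pn, analytes))
  active <- stats::setNames(vector("list", length(analytes)), analytes)
  lp <- eps <- matrix(NA_real_, n_catchments, length(analytes),
                      dimnames = list(ids, analytes))
  for (a in analytes) {
    if (n_active > 0) {
      act <- sort(sample(n_predictors, n_active))
      beta[act, a] <- beta_scale * sample(c(-1, 1), n_active, replace = TRUE)
      active[[a]] <- pn[act]
    } else active[[a]] <- character(0)
    lp[, a] <- intercepts[[a]] + drop(X %*% beta[, a])
    eps[, a] <- stats::rnorm(n_catchments, 0, sigma)
  }
  catchments <- data.frame(catchment_id = ids,
                           continent = sample(CONTINENTS, n_catchments,
                                              replace = TRUE),
                           area_km2 = area, population = pop,
                           agriculture_km2 = sh[, 1] * area,
                           forest_km2 = sh[, 2] * area,
                           other_km2 = sh[, 3] * area,
                           stringsAsFactors = FALSE)
  catchments <- cbind(catchments, as.data.frame(X), biome = biome,
                      stringsAsFactors = FALSE)
  medians_obs <- do.call(rbind, lapply(analytes, function(a)
    data.frame(catchment_id = ids, analyte = a,
               median_mgL = exp(lp[, a] + eps[, a]), stringsAsFactors = FALSE)))
  truth <- structure(list(beta = beta, active = active,
                          intercepts = intercepts[analytes], sigma = sigma,
                          lp = lp, eps = eps, seed = seed),
                     class = "synthetic_truth")
  list(catchments = catchments, truth = truth, medians_obs = medians_obs)
}

#' True systematic medians implied by a synthetic truth
#'
#' @param truth A `synthetic_truth` object.
#' @return Data frame with catchment_id, analyte, median_mgL = `exp(lp)`.
#' @export
truth_medians <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  do.call(rbind, lapply(colnames(truth$lp), function(a)
    data.frame(catchment_id = rownames(truth$lp), analyte = a,
               median_mgL = exp(truth$lp[, a]), stringsAsFactors = FALSE)))
}

#' Generate monitoring sites and censored sample records
#'
#' Sites are spread across both hemispheres and the tropics and assigned
#' round-robin to catchments. Each site samples every `interval_days` for
#' `n_years`, and each concentration is log-normal around its catchment's
#' realised median (`exp(lp + eps)` from the truth) with within-site scatter
#' `sigma_site`. The detection limit per site-analyte sits at the
#' `censor_target` quantile of that distribution, so the realised censored
#' fraction concentrates around the target; censored rows carry the
#' detection limit in `value`, by convention.
#'
#' @param truth A `synthetic_truth` from [gen_catchment_table()].
#' @param n_sites Number of sites. Default one per catchment.
#' @param lat_range Latitude range, degrees. Default `c(-60, 60)`.
#' @param interval_days Sampling interval. Default 14.
#' @param n_years Length of the sampling record. Default 5.
#' @param end_date Last sampling date. Default `"2016-12-01"`.
#' @param censor_target Target censored fraction in `[0, 0.3]`. Default 0.05.
#' @param sigma_site Within-site log-space scatter. Default 0.4.
#' @param seed Integer seed.
#' @return A list with `sites` and `samples` data frames.
#' @export
gen_sites_and_samples <- function(truth, n_sites = nrow(truth$lp),
                                  lat_range = c(-60, 60), interval_days = 14,
                                  n_years = 5,
                                  end_date = as.Date("2016-12-01"),
                                  censor_target = 0.05, sigma_site = 0.4,
                                  seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            censor_target >= 0, censor_target <= 0.3)
  set.seed(seed)
  cids <- rownames(truth$lp)
  analytes <- colnames(truth$lp)
  sites <- data.frame(
    site_id = sprintf("S%04d", seq_len(n_sites)),
    latitude = stats::runif(n_sites, lat_range[1], lat_range[2]),
    catchment_id = cids[(seq_len(n_sites) - 1) %% length(cids) + 1],
    stringsAsFactors = FALSE)
  n_per <- floor(n_years * 365.25 / interval_days)
  dates <- rev(seq(end_date, by = -interval_days, length.out = n_per))
  rows <- vector("list", n_sites * length(analytes))
  k <- 0
  for (i in seq_len(n_sites)) {
    ci <- match(sites$catchment_id[i], cids)
    for (a in analytes) {
      mu <- truth$lp[ci, a] + truth$eps[ci, a]   # realised site-level median
      val <- exp(mu + stats::rnorm(n_per, 0, sigma_site))
      dl <- if (censor_target > 0)
        exp(mu + stats::qnorm(censor_target) * sigma_site)
      else exp(mu - 6 * sigma_site)
      cens <- val < dl
      val[cens] <- dl
      k <- k + 1
      rows[[k]] <- data.frame(
        site_id = sites$site_id[i], date = dates, analyte = a,
        value = val, detection_limit = dl, censored = cens,
        method_code = if (a %in% c("TN", "TP")) "persulfate_digestion"
        else if (a == "DRP") "molybdenum_blue" else "cadmium_reduction",
        filter_pore_um = if (a == "DRP") 0.45 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  list(sites = sites, samples = samples)
}

#' Generate a literature-style threshold survey
#'
#' Thresholds per analyte are log-normal around the analyte mean (the
#' log-scale meanlog is shifted by `-sdlog^2/2`, so the arithmetic mean of
#' the generated thresholds targets `analyte_means`), with biome labels
#' carrying no systematic effect — matching a survey whose biome means do
#' not differ.
#'
#' @param n_studies Studies per analyte. Default 27.
#' @param analyte_means Named mean thresholds, mg/L.
#' @param sdlog Log-space spread of thresholds. Default 0.5.
#' @param biomes Biome labels to assign.
#' @param seed Integer seed.
#' @return A `thresholds` data frame.
#' @export
gen_threshold_survey <- function(n_studies = 27,
                                 analyte_means = c(TN = 0.800, TP = 0.046),
                                 sdlog = 0.5,
                                 biomes = c("temperate_forest", "grassland",
                                            "xeric", "tropical"),
                                 seed = 1L) {
  stopifnot(all(analyte_means > 0), sdlog >= 0, n_studies >= 2)
  set.seed(seed)
  rows <- lapply(names(analyte_means), function(a) {
    thr <- exp(log(analyte_means[[a]]) - sdlog^2 / 2 +
                 stats::rnorm(n_studies, 0, sdlog))
    data.frame(study_id = sprintf("%s_study_%02d", a, seq_len(n_studies)),
               analyte = a, threshold_mgL = thr,
               biome = sample(biomes, n_studies, replace = TRUE),
               region = sample(c("US", "Europe", "China", "Australasia",
                                 "South America", "Africa"),
                               n_studies, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic world
#'
#' Bundles catchments-with-truth, sites and censored samples, one gauge per
#' site (linked at a uniform 0-40 km downstream distance) with its own
#' discharge record covering the sampling window, and a threshold survey.
#' Sub-seeds for each component are derived deterministically from `seed`.
#'
#' @param n_catchments,n_sites World size. Defaults 60 and 60.
#' @param n_predictors,n_active,beta_scale,sigma Passed to
#'   [gen_catchment_table()].
#' @param interval_days,n_years,censor_target,sigma_site Passed to
#'   [gen_sites_and_samples()].
#' @param storm_rate Passed to [gen_discharge()].
#' @param seed Integer seed.
#' @return A list with `catchments`, `truth`, `medians_obs`, `sites`,
#'   `samples`, `links`, `discharge` (all gauges, one data frame),
#'   `thresholds`, and `bfi_true` (named per gauge).
#' @export
gen_world <- function(n_catchments = 60, n_sites = n_catchments,
                      n_predictors = 10, n_active = 2, beta_scale = 1,
                      sigma = 0.3, interval_days = 14, n_years = 5,
                      censor_target = 0.05, sigma_site = 0.4,
                      storm_rate = 0.04, seed = 1L) {
  seed <- as.integer(seed)
  ct <- gen_catchment_table(n_catchments, n_predictors, n_active, beta_scale,
                            sigma, seed = seed)
  ss <- gen_sites_and_samples(ct$truth, n_sites,
                              interval_days = interval_days, n_years = n_years,
                              censor_target = censor_target,
                              sigma_site = sigma_site, seed = seed + 1L)
  end_date <- max(ss$samples$date)
  start_date <- min(ss$samples$date) - 60
  n_days <- as.integer(end_date - start_date) + 1L
  links <- data.frame(site_id = ss$sites$site_id,
                      gauge_id = sprintf("G%04d", seq_len(n_sites)),
                      distance_km = stats::runif(n_sites, 0, 40),
                      stringsAsFactors = FALSE)
  disc <- vector("list", n_sites); bfi <- numeric(n_sites)
  for (i in seq_len(n_sites)) {
    g <- gen_discharge(n_days = n_days, storm_rate = storm_rate,
                       start_date = start_date,
                       gauge_id = links$gauge_id[i],
                       seed = (seed + 100L + i) %% .Machine$integer.max)
    disc[[i]] <- g$discharge; bfi[i] <- g$bfi_true
  }
  thr <- gen_threshold_survey(seed = seed + 2L)
  list(catchments = ct$catchments, truth = ct$truth,
       medians_obs = ct$medians_obs, sites = ss$sites, samples = ss$samples,
       links = links, discharge = do.call(rbind, disc), thresholds = thr,
       bfi_true = stats::setNames(bfi, links$gauge_id))
}
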