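#' Growing-season site and catchment medians
#'
#' After harmonisation and baseflow filtering, each site-analyte series is
#' restricted to the most recent seven years of record inside 1990-2016 and
#' to the growing-season months for its hemisphere (all months within the
#' tropics). Series that remain long and regular enough then yield a median
#' concentration per site, pooled to a median of site medians per catchment.
#'
#' @name medians
NULL

#' Restrict each site-analyte series to its trailing analysis window
#'
#' Retains samples within the most recent `window_years`-year span ending at
#' the series' last sample date, after clipping to the policy's calendar
#' range (default 1990-2016).
#'
#' @param samples A `samples` data frame.
#' @param policy An [eligibility_policy()].
#' @return The filtered data frame.
#' @export
filter_window <- function(samples, policy = eligibility_policy()) {
  lo <- as.Date(sprintf("%d-01-01", policy$date_range[1]))
  hi <- as.Date(sprintf("%d-12-31", policy$date_range[2]))
  samples <- samples[samples$date >= lo & samples$date <= hi, , drop = FALSE]
  keep <- rep(TRUE, nrow(samples))
  for (idx in split(seq_len(nrow(samples)), .site_analyte(samples))) {
    last <- max(samples$date[idx])
    start <- seq(last, by = sprintf("-%d years", policy$window_years),
                 length.out = 2)[2]
    keep[idx] <- samples$date[idx] > start
  }
  samples[keep, , drop = FALSE]
}

#' Retain growing-season samples outside the tropics
#'
#' Northern extratropical sites keep May-October, southern ones keep
#' November-April; within `|latitude| <= tropics_abs_lat` every month is
#' retained, since tropical periphyton growth is not seasonal in the same way.
#'
#' @param samples A `samples` data frame.
#' @param sites A `sites` data frame supplying latitude per site.
#' @param policy A [season_policy()].
#' @return The filtered data frame.
#' @export
filter_season <- function(samples, sites, policy = season_policy()) {
  lat <- sites$latitude[match(samples$site_id, sites$site_id)]
  if (anyNA(lat)) stop("sample site missing from the sites table")
  month <- as.integer(format(samples$date, "%m"))
  keep <- abs(lat) <= policy$tropics_abs_lat |
    (lat > policy$tropics_abs_lat & month %in% policy$nh_months) |
    (lat < -policy$tropics_abs_lat & month %in% policy$sh_months)
  samples[keep, , drop = FALSE]
}

#' Check whether a site-analyte series supports a stable median
#'
#' Eligible iff the series has at least `min_samples` points and its median
#' gap between consecutive sampling dates is at most `max_interval_days`
#' (about bimonthly). Both reasons are reported when both fail.
#'
#' @param dates Sample dates of one site-analyte series (post-filtering).
#' @param policy An [eligibility_policy()].
#' @return A list with `eligible` (logical) and `reasons` (character vector,
#'   empty when eligible).
#' @export
check_eligibility <- function(dates, policy = eligibility_policy()) {
  dates <- sort(as.Date(dates))
  reasons <- character(0)
  if (length(dates) < policy$min_samples)
    reasons <- c(reasons, "too_few_samples")
  if (length(dates) >= 2) {
    gap <- stats::median(diff(as.integer(dates)))
    if (gap > policy$max_interval_days)
      reasons <- c(reasons, "too_infrequent")
  }
  list(eligible = length(reasons) == 0, reasons = reasons)
}

#' Compute per-site growing-season medians
#'
#' Applies [check_eligibility()] per site-analyte series and returns the
#' standard middle-value median (mean of the two central order statistics for
#' even n) for eligible series, with provenance: sample count, window, and
#' the ineligible series with reasons.
#'
#' @param samples Fully filtered `samples` data frame.
#' @param sites A `sites` data frame (for catchment ids).
#' @param policy An [eligibility_policy()].
#' @return A list with `medians` (site_id, catchment_id, analyte, median_mgL,
#'   n_samples, window_start, window_end), `ineligible` (site_id, analyte,
#'   reasons), and `report`.
#' @export
site_medians <- function(samples, sites, policy = eligibility_policy()) {
  rows <- list(); inel <- list()
  for (idx in split(seq_len(nrow(samples)), .site_analyte(samples))) {
    sid <- samples$site_id[idx[1]]; an <- samples$analyte[idx[1]]
    el <- check_eligibility(samples$date[idx], policy)
    if (!el$eligible) {
      inel[[length(inel) + 1]] <- data.frame(
        site_id = sid, analyte = an,
        reasons = paste(el$reasons, collapse = ";"), stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      site_id = sid,
      catchment_id = sites$catchment_id[match(sid, sites$site_id)],
      analyte = an,
      median_mgL = stats::median(samples$value[idx]),
      n_samples = length(idx),
      window_start = min(samples$date[idx]),
      window_end = max(samples$date[idx]),
      stringsAsFactors = FALSE)
  }
  empty <- data.frame(site_id = character(0), analyte = character(0),
                      reasons = character(0), stringsAsFactors = FALSE)
  medians <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  list(medians = medians,
       ineligible = if (length(inel) > 0) do.call(rbind, inel) else empty,
       report = list(n_series = length(rows) + length(inel),
                     n_eligible = length(rows)))
}

#' Pool site medians to catchment medians
#'
#' Catchments are the modelling unit; where several eligible sites fall in
#' one catchment their medians are pooled by a further median, analyte by
#' analyte. Catchments with no eligible site are absent from the output.
#'
#' @param site_meds The `medians` element of [site_medians()].
#' @return Data frame with catchment_id, analyte, median_mgL, n_sites.
#' @export
catchment_medians <- function(site_meds) {
  if (is.null(site_meds) || nrow(site_meds) == 0)
    return(data.frame(catchment_id = character(0), analyte = character(0),
                      median_mgL = numeric(0), n_sites = integer(0),
                      stringsAsFactors = FALSE))
  key <- interaction(site_meds$catchment_id, site_meds$analyte,
                     drop = TRUE, sep = "\r")
  rows <- lapply(split(seq_len(nrow(site_meds)), key), function(idx)
    data.frame(catchment_id = site_meds$catchment_id[idx[1]],
               analyte = site_meds$analyte[idx[1]],
               median_mgL = stats::median(site_meds$median_mgL[idx]),
               n_sites = length(idx), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$catchment_id, out$analyte), , drop = FALSE]
}
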