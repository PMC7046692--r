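#' Harmonisation of raw nutrient samples
#'
#' Three screening steps make heterogeneous monitoring records comparable:
#' flagging likely unit errors, substituting half the detection limit for
#' left-censored values (excluding series where censoring exceeds 10%), and
#' accepting only comparable analytical methods. Nothing is silently
#' corrected: every removal carries a reason and is returned alongside the
#' retained rows.
#'
#' @name harmonize
NULL

.site_analyte <- function(samples)
  interaction(samples$site_id, samples$analyte, drop = TRUE, sep = "\r")

#' Flag values that look like unit mix-ups
#'
#' A value at least `factor` times its site-analyte median is almost always a
#' record entered in the wrong unit (e.g. ug/L typed as mg/L). Flagged rows
#' are excluded from downstream stages, never rescaled: an automated pipeline
#' must not invent corrections. Series with a single sample have no reference
#' median and are never flagged.
#'
#' @param samples A `samples` data frame (see [read_table()]).
#' @param factor Multiple of the site-analyte median at or above which a value
#'   is flagged. Default 100.
#' @return A list with `samples` (retained rows), `flagged` (excluded rows
#'   with a `reason` column), and `report` (counts).
#' @export
screen_anomalies <- function(samples, factor = 100) {
  stopifnot(nrow(samples) >= 1, factor > 1)
  flag <- logical(nrow(samples))
  for (idx in split(seq_len(nrow(samples)), .site_analyte(samples))) {
    if (length(idx) < 2) next
    med <- stats::median(samples$value[idx])
    if (is.na(med) || med <= 0) next
    flag[idx] <- samples$value[idx] >= factor * med
  }
  flagged <- samples[flag, , drop = FALSE]
  if (nrow(flagged) > 0) flagged$reason <- "suspect_units"
  list(samples = samples[!flag, , drop = FALSE],
       flagged = flagged,
       report = list(n_in = nrow(samples), n_flagged = sum(flag)))
}

#' Substitute censored values or exclude heavily censored series
#'
#' Each value below the detection limit is replaced by
#' `policy$substitution_fraction` (default half) of its detection limit.
#' When more than `policy$max_censored_fraction` (default 10%) of a
#' site-analyte series is censored, the whole series is excluded instead:
#' a median built mostly from substituted values is an artefact of the
#' detection limit, not the river. Exactly 10% censored is retained (the
#' rule is strictly greater than).
#'
#' @param samples A `samples` data frame.
#' @param policy A [censoring_policy()].
#' @return A list with `samples` (retained rows, censored values substituted),
#'   `excluded_series` (data frame of site_id/analyte/censored_fraction/reason),
#'   and `report`.
#' @export
impute_censored <- function(samples, policy = censoring_policy()) {
  stopifnot(inherits(policy, "censoring_policy"))
  if (nrow(samples) > 0 &&
      any(samples$censored & (is.na(samples$detection_limit) |
                              samples$detection_limit <= 0)))
    stop("censored sample without a valid detection limit")
  keep <- rep(TRUE, nrow(samples))
  excl <- list()
  out <- samples
  for (idx in split(seq_len(nrow(samples)), .site_analyte(samples))) {
    frac <- mean(samples$censored[idx])
    if (frac > policy$max_censored_fraction) {
      keep[idx] <- FALSE
      excl[[length(excl) + 1]] <- data.frame(
        site_id = samples$site_id[idx[1]],
        analyte = samples$analyte[idx[1]],
        censored_fraction = frac,
        reason = "censored_fraction_exceeded",
        stringsAsFactors = FALSE)
    } else {
      cens <- idx[samples$censored[idx]]
      out$value[cens] <-
        policy$substitution_fraction * samples$detection_limit[cens]
    }
  }
  excluded <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(site_id = character(0), analyte = character(0),
               censored_fraction = numeric(0), reason = character(0),
               stringsAsFactors = FALSE)
  list(samples = out[keep, , drop = FALSE],
       excluded_series = excluded,
       report = list(n_in = nrow(samples), n_substituted =
                       sum(samples$censored[keep]),
                     n_series_excluded = nrow(excluded)))
}

#' Screen out samples measured with non-comparable methods
#'
#' TN and TP are retained only for accepted digestion codes; DRP only when
#' filtered strictly below the pore-size bound and measured with an accepted
#' method; NO3-N only for accepted method codes. Unknown codes are rejected
#' with reason `unknown_method`, not raised as errors, so a single mislabelled
#' record cannot abort a run.
#'
#' @param samples A `samples` data frame.
#' @param policy A [method_policy()].
#' @return A list with `samples` (accepted), `rejected` (rows plus `reason`),
#'   and `report` (rejection counts per method code).
#' @export
screen_methods <- function(samples, policy = method_policy()) {
  stopifnot(inherits(policy, "method_policy"))
  n <- nrow(samples)
  reason <- rep(NA_character_, n)
  pore <- if ("filter_pore_um" %in% names(samples))
    samples$filter_pore_um else rep(NA_real_, n)
  known <- c(policy$accepted_tn_tp_methods, policy$accepted_drp_methods,
             policy$accepted_no3_methods)
  for (i in seq_len(n)) {
    a <- samples$analyte[i]; m <- samples$method_code[i]
    if (is.na(m) || !m %in% known) { reason[i] <- "unknown_method"; next }
    if (a %in% c("TN", "TP")) {
      if (!m %in% policy$accepted_tn_tp_methods) reason[i] <- "method_not_accepted"
    } else if (a == "DRP") {
      if (!m %in% policy$accepted_drp_methods) reason[i] <- "method_not_accepted"
      else if (is.na(pore[i]) || pore[i] >= policy$drp_max_pore_um)
        reason[i] <- "filter_pore_too_large"
    } else if (a == "NO3N") {
      if (!m %in% policy$accepted_no3_methods) reason[i] <- "method_not_accepted"
    }
  }
  ok <- is.na(reason)
  rejected <- samples[!ok, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[!ok]
  counts <- if (any(!ok))
    as.list(table(samples$method_code[!ok], useNA = "ifany")) else list()
  list(samples = samples[ok, , drop = FALSE], rejected = rejected,
       report = list(n_in = n, n_rejected = sum(!ok),
                     rejected_by_code = counts))
}

#' Run the full harmonisation sequence
#'
#' Applies anomaly screening, method screening and censored-value handling in
#' order, accumulating per-step accounting. The censored-value step can be
#' deferred (`impute = FALSE`) so the 10% rule is evaluated on the series that
#' actually enters the analysis window, after baseflow and season filtering.
#'
#' @param samples A `samples` data frame.
#' @param config A [pipeline_config()].
#' @param impute Run the censored-value step here (default `TRUE`).
#' @return A list with `samples` and `log` (one accounting entry per step).
#' @export
harmonize_samples <- function(samples, config = pipeline_config(),
                              impute = TRUE) {
  log <- list()
  st <- screen_anomalies(samples, factor = config$unit_anomaly_factor)
  log$anomalies <- st$report
  st2 <- screen_methods(st$samples, config$methods)
  log$methods <- st2$report
  out <- st2$samples
  if (impute) {
    st3 <- impute_censored(out, config$censoring)
    log$censoring <- st3$report
    out <- st3$samples
  }
  list(samples = out, log = log)
}
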