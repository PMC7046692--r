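#' Baseflow separation and baseflow-conditioned sample filtering
#'
#' Nutrient medians are meant to characterise baseflow, when periphyton can
#' accumulate: storm flows scour biofilm and carry particulate loads that are
#' not comparable with low-flow chemistry. Daily discharge is split into
#' baseflow and quickflow with the Lyne-Hollick recursive digital filter, and
#' samples are retained only when taken on days whose baseflow fraction
#' reaches a minimum (default 75%).
#'
#' @name hydrograph
NULL

# one filter pass over a single gap-free segment; x is the input series of
# this pass (flow on pass 1, previous baseflow after)
.lh_pass <- function(x, alpha) {
  n <- length(x)
  qf <- numeric(n)            # quickflow; qf[1] = 0 (padding absorbs start-up)
  k <- (1 + alpha) / 2
  for (t in 2:n) {
    v <- alpha * qf[t - 1] + k * (x[t] - x[t - 1])
    qf[t] <- min(max(v, 0), x[t])
  }
  x - qf
}

.lh_segment <- function(q, alpha, passes, reflect) {
  n <- length(q)
  pad <- min(reflect, n - 1)
  # reflect the series at both ends so the recursion is warmed up before it
  # reaches real data
  x <- c(rev(q[seq(2, pad + 1)]), q, rev(q[seq(n - pad, n - 1)]))
  forward <- TRUE
  for (p in seq_len(passes)) {
    x <- if (forward) .lh_pass(x, alpha) else rev(.lh_pass(rev(x), alpha))
    forward <- !forward
  }
  x[seq(pad + 1, pad + n)]
}

#' Separate daily discharge into baseflow and quickflow
#'
#' Applies the Lyne-Hollick single-parameter recursive filter: per pass, the
#' quickflow at day t is `alpha * qf[t-1] + (1+alpha)/2 * (Q[t] - Q[t-1])`,
#' clamped to `[0, Q[t]]`; baseflow is what remains. Passes alternate
#' forward/backward (default 3: forward-backward-forward), and each segment
#' is warmed up by reflecting up to 30 days of record at both ends. Missing
#' flow days split the record into segments filtered independently; segments
#' shorter than `min_segment` days are left unfiltered (baseflow `NA`).
#'
#' @param discharge A `discharge` data frame for a single gauge (columns
#'   `gauge_id`, `date`, `flow_m3s`; consecutive calendar days, gaps as `NA`).
#' @param alpha Filter parameter in (0, 1). Default 0.925.
#' @param passes Odd number of passes. Default 3.
#' @param reflect Warm-up reflection length, days. Default 30.
#' @param min_segment Minimum gap-free segment length filtered. Default 10.
#' @return An object of class `baseflow_result`: a data frame with `date`,
#'   `flow`, `baseflow`, `quickflow` and attributes `gauge_id`, `alpha`,
#'   `passes`, `bfi` (baseflow index, total baseflow / total flow over
#'   filtered days).
#' @export
baseflow_separate <- function(discharge, alpha = 0.925, passes = 3L,
                              reflect = 30L, min_segment = 10L) {
  stopifnot(alpha > 0, alpha < 1, passes >= 1, passes %% 2 == 1)
  gid <- unique(discharge$gauge_id)
  if (length(gid) != 1) stop("baseflow_separate expects a single gauge")
  o <- order(discharge$date)
  dates <- discharge$date[o]; q <- discharge$flow_m3s[o]
  if (length(dates) < 2) stop("need at least 2 days of record")
  dd <- diff(as.integer(dates))
  if (any(dd != 1))
    stop("discharge record must be on a daily step (mark gaps as NA flow)")
  if (all(is.na(q))) stop("all flow values are missing")
  if (any(q < 0, na.rm = TRUE)) stop("flow must be >= 0")

  bf <- rep(NA_real_, length(q))
  r <- rle(!is.na(q))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (s in which(r$values)) {
    idx <- seq(starts[s], ends[s])
    if (length(idx) < max(2, min_segment)) next
    bf[idx] <- .lh_segment(q[idx], alpha, passes, reflect)
  }
  ok <- !is.na(bf)
  bfi <- if (any(ok) && sum(q[ok]) > 0) sum(bf[ok]) / sum(q[ok]) else
    if (any(ok)) 1 else NA_real_
  structure(data.frame(date = dates, flow = q, baseflow = bf,
                       quickflow = q - bf),
            gauge_id = gid, alpha = alpha, passes = as.integer(passes),
            bfi = bfi, class = c("baseflow_result", "data.frame"))
}

#' @export
print.baseflow_result <- function(x, ...) {
  cat(sprintf("Baseflow separation for gauge %s: %d days, alpha = %.3f, %d passes, BFI = %.3f\n",
              attr(x, "gauge_id"), nrow(x), attr(x, "alpha"),
              attr(x, "passes"), attr(x, "bfi")))
  invisible(x)
}

#' Baseflow fraction on given days
#'
#' @param result A [baseflow_separate()] result.
#' @param dates Dates to query (must fall within the record span).
#' @return Baseflow / flow per day, in `[0, 1]`. A zero-flow day returns 1
#'   (no quickflow is possible); a day whose flow is missing or that sits in
#'   an unfiltered short segment returns `NA`.
#' @export
baseflow_fraction <- function(result, dates) {
  stopifnot(inherits(result, "baseflow_result"))
  i <- match(as.integer(as.Date(dates)), as.integer(result$date))
  if (anyNA(i)) stop("date outside the discharge record span")
  frac <- ifelse(result$flow[i] == 0, 1, result$baseflow[i] / result$flow[i])
  as.numeric(frac)
}

#' Link monitoring sites to discharge gauges
#'
#' A site is paired with the nearest linked gauge no more than `max_km`
#' downstream (inclusive). Sites without such a gauge are returned unlinked
#' with a reason; downstream stages exclude them, because without discharge
#' the baseflow criterion cannot be evaluated.
#'
#' @param sites A `sites` data frame.
#' @param links A `site_gauge_links` data frame (site_id, gauge_id,
#'   distance_km downstream).
#' @param max_km Maximum downstream distance, km. Default 50.
#' @return A list with `sites` (with `gauge_id`/`gauge_distance_km` filled),
#'   `unlinked` (site ids plus reason), and `report`.
#' @export
link_sites_to_gauges <- function(sites, links, max_km = 50) {
  if (any(links$distance_km < 0, na.rm = TRUE))
    stop("negative gauge distance")
  out <- sites
  out$gauge_id <- NA_character_
  out$gauge_distance_km <- NA_real_
  for (i in seq_len(nrow(out))) {
    cand <- links[links$site_id == out$site_id[i] &
                    links$distance_km <= max_km, , drop = FALSE]
    if (nrow(cand) > 0) {
      j <- which.min(cand$distance_km)
      out$gauge_id[i] <- cand$gauge_id[j]
      out$gauge_distance_km[i] <- cand$distance_km[j]
    }
  }
  miss <- out$site_id[is.na(out$gauge_id)]
  unlinked <- data.frame(site_id = miss,
                         reason = rep("no_gauge_within_range", length(miss)),
                         stringsAsFactors = FALSE)
  list(sites = out, unlinked = unlinked,
       report = list(n_sites = nrow(out), n_linked = sum(!is.na(out$gauge_id))))
}

#' Retain samples taken at baseflow
#'
#' Keeps samples whose day-of-sampling baseflow fraction is at least
#' `min_fraction` (inclusive) at the gauge linked to the sample's site.
#'
#' @param samples A `samples` data frame.
#' @param sites Linked sites, as returned by [link_sites_to_gauges()].
#' @param baseflow Named list of [baseflow_separate()] results, one per gauge.
#' @param min_fraction Minimum baseflow fraction. Default 0.75.
#' @return A list with `samples` (retained), `dropped` (rows plus `reason`:
#'   `no_gauge_link`, `no_flow_record`, or `stormflow`), and `report`.
#' @export
filter_baseflow_samples <- function(samples, sites, baseflow,
                                    min_fraction = 0.75) {
  si <- match(samples$site_id, sites$site_id)
  if (anyNA(si)) stop("sample site missing from the sites table")
  gauge <- sites$gauge_id[si]
  reason <- rep(NA_character_, nrow(samples))
  reason[is.na(gauge) | !gauge %in% names(baseflow)] <- "no_gauge_link"
  for (g in intersect(unique(gauge), names(baseflow))) {
    idx <- which(!is.na(gauge) & gauge == g)
    res <- baseflow[[g]]
    j <- match(as.integer(samples$date[idx]), as.integer(res$date))
    frac <- ifelse(res$flow[j] == 0, 1, res$baseflow[j] / res$flow[j])
    r <- rep(NA_character_, length(idx))
    r[is.na(j) | is.na(frac)] <- "no_flow_record"
    r[!is.na(frac) & frac < min_fraction] <- "stormflow"
    reason[idx] <- r
  }
  ok <- is.na(reason)
  dropped <- samples[!ok, , drop = FALSE]
  if (nrow(dropped) > 0) dropped$reason <- reason[!ok]
  list(samples = samples[ok, , drop = FALSE], dropped = dropped,
       report = list(n_in = nrow(samples), n_retained = sum(ok),
                     dropped_by_reason = if (any(!ok))
                       as.list(table(reason[!ok])) else list()))
}
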