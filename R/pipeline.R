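#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains every stage — harmonisation, gauge linking and
#' baseflow filtering, date-window and growing-season filters, censored-value
#' handling, site and catchment medians, per-analyte regression, prediction,
#' classification, and aggregation — on a bundle of input tables, keeping a
#' provenance log of record counts in and out of every filter.
#'
#' @name pipeline
NULL

#' Read all pipeline inputs from a directory of CSV files
#'
#' Expects `samples.csv`, `sites.csv`, `discharge.csv`,
#' `site_gauge_links.csv`, `catchments.csv` and optionally `thresholds.csv`,
#' each validated against its schema.
#'
#' @param dir Directory path.
#' @return A named list of tables suitable for [run_pipeline()].
#' @export
read_pipeline_inputs <- function(dir) {
  need <- c(samples = "samples", sites = "sites", discharge = "discharge",
            links = "site_gauge_links", catchments = "catchments")
  out <- lapply(names(need), function(nm) {
    p <- file.path(dir, paste0(need[[nm]], ".csv"))
    read_table(p, need[[nm]])
  })
  names(out) <- names(need)
  tp <- file.path(dir, "thresholds.csv")
  if (file.exists(tp)) out$thresholds <- read_table(tp, "thresholds")
  out
}

#' Write a generated world to a directory of CSV files
#'
#' @param world A [gen_world()] bundle.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_inputs <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(world$samples, file.path(dir, "samples.csv"), "samples")
  write_table(world$sites, file.path(dir, "sites.csv"), "sites")
  write_table(world$discharge, file.path(dir, "discharge.csv"), "discharge")
  write_table(world$links, file.path(dir, "site_gauge_links.csv"),
              "site_gauge_links")
  write_table(world$catchments, file.path(dir, "catchments.csv"), "catchments")
  write_table(world$thresholds, file.path(dir, "thresholds.csv"), "thresholds")
  invisible(dir)
}

# predictor columns = everything beyond the fixed catchment attributes
.predictor_columns <- function(catchments)
  setdiff(names(catchments),
          c("catchment_id", "continent", "area_km2", "population",
            "agriculture_km2", "forest_km2", "other_km2"))

#' Run the full analysis pipeline
#'
#' @param inputs Named list of tables (`samples`, `sites`, `discharge`,
#'   `links`, `catchments`, optionally `thresholds`), e.g. from [gen_world()]
#'   or [read_pipeline_inputs()].
#' @param config A [pipeline_config()].
#' @param analytes Analytes to model and classify; classification needs both
#'   TN and TP. Default `c("TN", "TP")`.
#' @return An object of class `perigrow_pipeline`: a list with
#'   `site_medians`, `catchment_medians`, `models` (one [nutrient_lm()] per
#'   analyte), `predictions` (per catchment and analyte, mg/L),
#'   `classification`, `aggregate`, `headline`, `landuse`,
#'   `threshold_summary` (when a survey is supplied), and `log` (per-stage
#'   record accounting).
#' @export
run_pipeline <- function(inputs, config = pipeline_config(),
                         analytes = c("TN", "TP")) {
  stopifnot(inherits(config, "pipeline_config"))
  for (nm in c("samples", "sites", "discharge", "links", "catchments"))
    if (is.null(inputs[[nm]]))
      stop(sprintf("pipeline stage 'inputs': missing table '%s'", nm))
  log <- list()
  tick <- function(stage, n_in, n_out, detail = NULL)
    log[[stage]] <<- c(list(n_in = n_in, n_out = n_out), detail)

  samples <- inputs$samples[inputs$samples$analyte %in% analytes, ,
                            drop = FALSE]
  tick("analyte_subset", nrow(inputs$samples), nrow(samples))

  h <- harmonize_samples(samples, config, impute = FALSE)
  tick("harmonize", nrow(samples), nrow(h$samples), h$log)

  lk <- link_sites_to_gauges(inputs$sites, inputs$links, config$max_gauge_km)
  gauges <- unique(stats::na.omit(lk$sites$gauge_id))
  bf <- lapply(gauges, function(g)
    baseflow_separate(inputs$discharge[inputs$discharge$gauge_id == g, ,
                                       drop = FALSE],
                      alpha = config$alpha, passes = config$passes))
  names(bf) <- gauges
  fb <- filter_baseflow_samples(h$samples, lk$sites, bf, config$min_baseflow)
  tick("baseflow_filter", nrow(h$samples), nrow(fb$samples),
       list(unlinked_sites = nrow(lk$unlinked),
            dropped_by_reason = fb$report$dropped_by_reason))

  fw <- filter_window(fb$samples, config$eligibility)
  tick("date_window", nrow(fb$samples), nrow(fw))
  fs <- filter_season(fw, lk$sites, config$season)
  tick("season", nrow(fw), nrow(fs))

  ic <- impute_censored(fs, config$censoring)
  tick("censoring", nrow(fs), nrow(ic$samples),
       list(series_excluded = nrow(ic$excluded_series)))

  sm <- site_medians(ic$samples, lk$sites, config$eligibility)
  tick("eligibility", nrow(ic$samples),
       if (is.null(sm$medians)) 0L else nrow(sm$medians),
       list(ineligible_series = nrow(sm$ineligible)))
  cm <- catchment_medians(sm$medians)

  catchments <- inputs$catchments
  preds <- .predictor_columns(catchments)
  if (length(preds) == 0) stop("catchment table has no predictor columns")
  models <- list(); predictions <- list()
  for (a in analytes) {
    obs <- cm[cm$analyte == a, , drop = FALSE]
    d <- merge(obs, catchments, by = "catchment_id")
    d <- d[stats::complete.cases(d[, preds, drop = FALSE]), , drop = FALSE]
    if (nrow(d) < length(preds) + 3)
      stop(sprintf("too few catchments with observed %s medians to fit (%d)",
                   a, nrow(d)))
    fit <- suppressWarnings(nutrient_lm(
      stats::reformulate(preds, response = "median_mgL"), d, analyte = a,
      rule = config$cp_rule, max_exhaustive = config$max_exhaustive))
    models[[a]] <- fit
    pr <- predict(fit, catchments, type = "response")
    predictions[[a]] <- data.frame(catchment_id = catchments$catchment_id,
                                   analyte = a, predicted_mgL = as.numeric(pr),
                                   stringsAsFactors = FALSE)
  }
  predictions <- do.call(rbind, predictions)
  rownames(predictions) <- NULL

  classification <- NULL; agg <- NULL; head_pct <- NULL; lu <- NULL
  if (all(c("TN", "TP") %in% analytes)) {
    tn <- predictions[predictions$analyte == "TN", ]
    tp <- predictions[predictions$analyte == "TP", ]
    ok <- !is.na(tn$predicted_mgL) & !is.na(tp$predicted_mgL)
    classification <- classify_catchment(tn$predicted_mgL[ok],
                                         tp$predicted_mgL[ok], config$rule,
                                         tn$catchment_id[ok])
    tick("classification", nrow(catchments), nrow(classification))
    agg <- aggregate_types(classification, catchments, config$exclude_regions)
    head_pct <- headline_percentages(agg)
    lu <- landuse_breakdown(classification, catchments, config$exclude_regions)
  }

  thr_sum <- NULL
  if (!is.null(inputs$thresholds))
    thr_sum <- lapply(intersect(analytes, unique(inputs$thresholds$analyte)),
                      function(a) summarize_thresholds(inputs$thresholds, a))

  structure(list(config = config, site_medians = sm$medians,
                 catchment_medians = cm, models = models,
                 predictions = predictions, classification = classification,
                 aggregate = agg, headline = head_pct, landuse = lu,
                 threshold_summary = thr_sum, log = log),
            class = "perigrow_pipeline")
}

#' @export
print.perigrow_pipeline <- function(x, ...) {
  cat("perigrow pipeline run\n")
  cat("  record accounting:\n")
  for (nm in names(x$log))
    cat(sprintf("    %-16s %6d -> %6d\n", nm, x$log[[nm]]$n_in,
                x$log[[nm]]$n_out))
  for (a in names(x$models)) {
    m <- x$models[[a]]
    cat(sprintf("  %s model: n = %d, R2 = %.3f, S = %.4f, terms: %s\n",
                a, m$n, m$r2, m$S,
                if (length(m$selected) > 0)
                  paste(m$selected, collapse = ", ") else "(intercept)"))
  }
  if (!is.null(x$headline))
    cat(sprintf("  undesirable growth: %.1f%% of classified area (P-share %.1f%%, N-share %.1f%%)\n",
                x$headline$pct_undesirable, x$headline$pct_P_of_undesirable,
                x$headline$pct_N_of_undesirable))
  invisible(x)
}
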