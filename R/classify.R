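#' Literature thresholds and the four-way catchment classification
#'
#' Literature-reported nutrient thresholds for undesirable periphyton growth
#' are summarised per analyte (mean, standard error, range) and compared
#' across biomes with a one-way ANOVA. Catchments are then classified by
#' crossing the limiting nutrient (Redfield mass ratio, boundary 7) with
#' whether the limiting nutrient's median exceeds its threshold:
#' type 1 = N-limited/acceptable, 2 = N-limited/undesirable,
#' 3 = P-limited/acceptable, 4 = P-limited/undesirable.
#'
#' @name thresholds-classify
NULL

#' Summarise literature thresholds for one analyte
#'
#' @param studies A `thresholds` data frame.
#' @param analyte Analyte to summarise.
#' @return A list with `analyte`, `mean`, `se` (sd / sqrt(n)), `min`, `max`,
#'   `n_studies`. At least two studies are required, else the standard error
#'   is undefined.
#' @export
summarize_thresholds <- function(studies, analyte) {
  x <- studies$threshold_mgL[studies$analyte == analyte]
  if (length(x) < 2)
    stop(sprintf("need >= 2 studies for analyte %s to compute a standard error",
                 analyte))
  list(analyte = analyte, mean = mean(x),
       se = stats::sd(x) / sqrt(length(x)),
       min = min(x), max = max(x), n_studies = length(x))
}

#' One-way ANOVA of thresholds across biomes
#'
#' Tests whether reported thresholds differ systematically between biomes;
#' when they do not, a single global mean threshold per analyte is defensible.
#'
#' @param studies A `thresholds` data frame (one analyte).
#' @param analyte Optional analyte to subset on first.
#' @return A list with `F`, `p`, `df` (between, within), and `group_means`.
#' @export
anova_thresholds_by_biome <- function(studies, analyte = NULL) {
  if (!is.null(analyte)) studies <- studies[studies$analyte == analyte, ]
  tab <- table(studies$biome)
  if (length(tab) < 2 || sum(tab >= 2) < 2)
    stop("need >= 2 biome groups with >= 2 studies each")
  fit <- stats::lm(threshold_mgL ~ biome, data = studies)
  av <- stats::anova(fit)
  gm <- tapply(studies$threshold_mgL, studies$biome, mean)
  list(F = av$`F value`[1], p = av$`Pr(>F)`[1],
       df = c(between = av$Df[1], within = av$Df[2]),
       group_means = gm)
}

#' Classify catchments by nutrient limitation and growth risk
#'
#' For each catchment, the TN:TP mass ratio decides the limiting nutrient
#' (ratio below the boundary: N-limited; at or above: P-limited), and the
#' limiting nutrient's median decides growth: undesirable when it exceeds the
#' threshold. Equality with a concentration threshold follows
#' `rule$equality_undesirable` (default acceptable: the rule set defines only
#' the strict inequalities).
#'
#' @param tn_median,tp_median Positive TN and TP medians, mg/L (vectorised).
#' @param rule A [classification_rule()].
#' @param catchment_id Optional ids carried into the result.
#' @return A data frame with `catchment_id`, `tn_median`, `tp_median`,
#'   `np_ratio`, `limitation` (`"N"`/`"P"`), `growth`
#'   (`"acceptable"`/`"undesirable"`), and `type_code` (1-4).
#' @export
classify_catchment <- function(tn_median, tp_median,
                               rule = classification_rule(),
                               catchment_id = NULL) {
  stopifnot(inherits(rule, "classification_rule"),
            length(tn_median) == length(tp_median))
  if (any(is.na(tn_median) | is.na(tp_median) |
            tn_median <= 0 | tp_median <= 0))
    stop("tn_median and tp_median must be positive")
  ratio <- tn_median / tp_median
  # compare with a relative tolerance so medians sitting exactly on the
  # boundary (e.g. 0.70/0.10) are not misrouted by floating-point rounding
  p_limited <- ratio >= rule$ratio_boundary * (1 - 1e-9)
  exceeds <- function(x, thr)
    if (rule$equality_undesirable) x >= thr else x > thr
  undesirable <- ifelse(p_limited,
                        exceeds(tp_median, rule$tp_threshold),
                        exceeds(tn_median, rule$tn_threshold))
  type_code <- 1L + 2L * p_limited + undesirable
  data.frame(
    catchment_id = if (is.null(catchment_id))
      as.character(seq_along(tn_median)) else as.character(catchment_id),
    tn_median = tn_median, tp_median = tp_median, np_ratio = ratio,
    limitation = ifelse(p_limited, "P", "N"),
    growth = ifelse(undesirable, "undesirable", "acceptable"),
    type_code = as.integer(type_code),
    stringsAsFactors = FALSE)
}

#' Classify under regional thresholds and compare with the global rule
#'
#' Each catchment is classified twice: once with its region's thresholds and
#' once with the global fallback rule. Regions listed without thresholds
#' (both `NA`) follow `missing_region`; a region with only one of the two
#' thresholds is an error, because the classifier needs both.
#'
#' @param predictions Data frame with `catchment_id`, `tn_median`,
#'   `tp_median`, `region`, and optionally `area_km2` (default 1 per
#'   catchment, so counts act as areas).
#' @param regional Data frame with `region`, `tn_threshold`, `tp_threshold`
#'   (mg/L; both `NA` marks a region without thresholds).
#' @param fallback A [classification_rule()] providing the global thresholds
#'   and the ratio boundary (shared by both rule sets).
#' @param missing_region `"fallback"` (classify with the global rule) or
#'   `"exclude"`.
#' @return A list with `results` (per catchment: both type codes and
#'   `differs`), `by_region` (area per type under both rule sets and percent
#'   difference), and `total` (the same, summed).
#' @export
classify_with_regional_thresholds <- function(predictions, regional,
                                              fallback = classification_rule(),
                                              missing_region = c("fallback",
                                                                 "exclude")) {
  missing_region <- match.arg(missing_region)
  partial <- !is.na(regional$tn_threshold) + !is.na(regional$tp_threshold) == 1
  if (any(partial))
    stop(sprintf("region %s has only one of the two thresholds",
                 regional$region[which(partial)[1]]))
  if (anyDuplicated(regional$region))
    stop("duplicate region in the regional threshold table")
  area <- if ("area_km2" %in% names(predictions)) predictions$area_km2 else
    rep(1, nrow(predictions))

  glob <- classify_catchment(predictions$tn_median, predictions$tp_median,
                             fallback, predictions$catchment_id)
  ri <- match(predictions$region, regional$region)
  tn_thr <- regional$tn_threshold[ri]; tp_thr <- regional$tp_threshold[ri]
  has_reg <- !is.na(tn_thr)
  reg_type <- rep(NA_integer_, nrow(predictions))
  for (i in which(has_reg)) {
    r <- classification_rule(ratio_boundary = fallback$ratio_boundary,
                             tn_threshold = tn_thr[i],
                             tp_threshold = tp_thr[i],
                             equality_undesirable = fallback$equality_undesirable)
    reg_type[i] <- classify_catchment(predictions$tn_median[i],
                                      predictions$tp_median[i], r)$type_code
  }
  if (missing_region == "fallback") {
    reg_type[!has_reg] <- glob$type_code[!has_reg]
    used <- rep(TRUE, nrow(predictions))
  } else {
    used <- has_reg
  }
  results <- data.frame(catchment_id = predictions$catchment_id,
                        region = predictions$region,
                        area_km2 = area,
                        type_global = glob$type_code,
                        type_regional = reg_type,
                        stringsAsFactors = FALSE)[used, , drop = FALSE]
  results$differs <- results$type_global != results$type_regional

  tally <- function(df, key) {
    out <- list()
    for (k in sort(unique(key))) {
      sub <- df[key == k, , drop = FALSE]
      for (tc in 1:4) {
        ar <- sum(sub$area_km2[sub$type_regional == tc])
        ag <- sum(sub$area_km2[sub$type_global == tc])
        tot <- sum(sub$area_km2)
        out[[length(out) + 1]] <- data.frame(
          group = k, type_code = tc, area_regional = ar, area_global = ag,
          pct_regional = 100 * ar / tot, pct_global = 100 * ag / tot,
          pct_difference = 100 * (ar - ag) / tot, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }
  list(results = results,
       by_region = tally(results, results$region),
       total = tally(results, rep("total", nrow(results))))
}
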