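#' Continental and world roll-ups of classified catchments
#'
#' Sums catchment area, population and land use per (continent, catchment
#' type) and for the world, with percentages computed from unrounded sums;
#' rounding belongs to report rendering only, because rounded continental
#' rows generally do not add up to their world row.
#'
#' @name aggregate-report
NULL

#' Aggregate classified catchments by continent and for the world
#'
#' @param results A [classify_catchment()] result (needs `catchment_id`,
#'   `type_code`).
#' @param catchments A `catchments` data frame supplying continent, area,
#'   population and land use per catchment.
#' @param exclude_regions Continent names excluded from the world row (they
#'   keep their own rows). Default Antarctica and Greenland.
#' @return A data frame of class `aggregate_table`: one row per (grouping,
#'   type_code) with `area_km2`, `area_percent` (of the grouping's classified
#'   area), `population`, `agriculture_km2`, `forest_km2`, `other_km2`.
#'   Groupings are the continents present plus `"World"`.
#' @export
aggregate_types <- function(results, catchments,
                            exclude_regions = c("Antarctica", "Greenland")) {
  ci <- match(results$catchment_id, catchments$catchment_id)
  if (anyNA(ci)) stop("classified catchment missing from the catchment table")
  cont <- catchments$continent[ci]
  if (any(is.na(cont) | cont == ""))
    stop("catchment without a continent assignment")
  df <- data.frame(continent = cont,
                   type_code = results$type_code,
                   area_km2 = catchments$area_km2[ci],
                   population = catchments$population[ci],
                   agriculture_km2 = catchments$agriculture_km2[ci],
                   forest_km2 = catchments$forest_km2[ci],
                   other_km2 = catchments$other_km2[ci],
                   stringsAsFactors = FALSE)
  one_group <- function(sub, label) {
    tot <- sum(sub$area_km2)
    rows <- lapply(1:4, function(tc) {
      s <- sub[sub$type_code == tc, , drop = FALSE]
      data.frame(grouping = label, type_code = tc,
                 area_km2 = sum(s$area_km2),
                 area_percent = if (tot > 0) 100 * sum(s$area_km2) / tot else 0,
                 population = sum(s$population),
                 agriculture_km2 = sum(s$agriculture_km2),
                 forest_km2 = sum(s$forest_km2),
                 other_km2 = sum(s$other_km2),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  pieces <- lapply(sort(unique(df$continent)), function(cn)
    one_group(df[df$continent == cn, , drop = FALSE], cn))
  world <- one_group(df[!df$continent %in% exclude_regions, , drop = FALSE],
                     "World")
  out <- rbind(do.call(rbind, pieces), world)
  rownames(out) <- NULL
  structure(out, class = c("aggregate_table", "data.frame"),
            exclude_regions = exclude_regions)
}

#' @export
print.aggregate_table <- function(x, digits = 1, ...) {
  cat("Area (km2), population and land use by grouping and catchment type\n")
  y <- as.data.frame(x)
  y$area_percent <- round(y$area_percent, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}

#' Headline shares of the classified area
#'
#' @param table An [aggregate_types()] result.
#' @param grouping Which grouping row set to summarise. Default `"World"`.
#' @return A list with `pct_undesirable` (share of classified area in types 2
#'   and 4), `pct_P_of_undesirable` and `pct_N_of_undesirable` (shares of the
#'   undesirable area attributed to P- and N-enrichment), and
#'   `population_by_type`.
#' @export
headline_percentages <- function(table, grouping = "World") {
  sub <- table[table$grouping == grouping, , drop = FALSE]
  if (nrow(sub) == 0) stop(sprintf("no '%s' rows in the table", grouping))
  area <- sub$area_km2[match(1:4, sub$type_code)]
  total <- sum(area)
  if (total <= 0) stop("zero total classified area")
  und <- area[2] + area[4]
  list(pct_undesirable = 100 * und / total,
       pct_P_of_undesirable = if (und > 0) 100 * area[4] / und else NA_real_,
       pct_N_of_undesirable = if (und > 0) 100 * area[2] / und else NA_real_,
       population_by_type = stats::setNames(
         sub$population[match(1:4, sub$type_code)], paste0("type", 1:4)))
}

#' Land-use composition per grouping and catchment type
#'
#' @param results A [classify_catchment()] result.
#' @param catchments A `catchments` data frame.
#' @param exclude_regions Continents excluded from the world rows.
#' @return Data frame with one row per (grouping, type_code, land_use) giving
#'   `area_km2` and `percent` within the (grouping, type) cell.
#' @export
landuse_breakdown <- function(results, catchments,
                              exclude_regions = c("Antarctica", "Greenland")) {
  ci <- match(results$catchment_id, catchments$catchment_id)
  if (anyNA(ci)) stop("classified catchment missing from the catchment table")
  lu <- catchments$agriculture_km2[ci] + catchments$forest_km2[ci] +
    catchments$other_km2[ci]
  over <- which(lu > catchments$area_km2[ci] * (1 + 1e-6))
  if (length(over) > 0)
    stop(sprintf("land-use areas exceed catchment area for %s",
                 catchments$catchment_id[ci][over[1]]))
  agg <- aggregate_types(results, catchments, exclude_regions)
  rows <- list()
  for (i in seq_len(nrow(agg))) {
    cell <- agg[i, ]
    tot <- cell$agriculture_km2 + cell$forest_km2 + cell$other_km2
    for (use in c("agriculture", "forest", "other")) {
      a <- cell[[paste0(use, "_km2")]]
      rows[[length(rows) + 1]] <- data.frame(
        grouping = cell$grouping, type_code = cell$type_code, land_use = use,
        area_km2 = a, percent = if (tot > 0) 100 * a / tot else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
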