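test_that("aggregation conserves area and population under any grouping", {
  fx <- table1_fixture()
  agg <- aggregate_types(fx$results, fx$catchments)
  world <- agg[agg$grouping == "World", ]
  expect_equal(sum(world$area_km2), sum(fx$catchments$area_km2))
  conts <- agg[agg$grouping != "World", ]
  expect_equal(sum(conts$area_km2), sum(world$area_km2))
  expect_equal(sum(conts$population), sum(world$population))
  # per-grouping percentages sum to 100 on unrounded areas
  for (g in unique(agg$grouping))
    expect_equal(sum(agg$area_percent[agg$grouping == g]), 100,
                 tolerance = 1e-9)
})

test_that("single and two-catchment edge cases give exact percentages", {
  cat1 <- data.frame(catchment_id = c("A", "B"), continent = "Europe",
                     area_km2 = c(10, 10), population = c(5, 7),
                     agriculture_km2 = 5, forest_km2 = 3, other_km2 = 2,
                     stringsAsFactors = FALSE)
  res1 <- data.frame(catchment_id = "A", type_code = 1L,
                     stringsAsFactors = FALSE)
  a1 <- aggregate_types(res1, cat1)
  expect_equal(a1$area_percent[a1$grouping == "Europe" & a1$type_code == 1],
               100)
  res2 <- data.frame(catchment_id = c("A", "B"), type_code = c(1L, 4L),
                     stringsAsFactors = FALSE)
  a2 <- aggregate_types(res2, cat1)
  expect_equal(a2$area_percent[a2$grouping == "World"], c(50, 0, 0, 50))
})

test_that("excluded regions keep their rows but leave the world total", {
  cats <- data.frame(catchment_id = c("A", "B"),
                     continent = c("Europe", "Antarctica"),
                     area_km2 = c(10, 90), population = c(1, 0),
                     agriculture_km2 = 0, forest_km2 = 0,
                     other_km2 = c(10, 90), stringsAsFactors = FALSE)
  res <- data.frame(catchment_id = c("A", "B"), type_code = c(2L, 1L),
                    stringsAsFactors = FALSE)
  agg <- aggregate_types(res, cats)
  expect_equal(sum(agg$area_km2[agg$grouping == "World"]), 10)
  expect_true("Antarctica" %in% agg$grouping)

  noc <- cats; noc$continent[2] <- ""
  expect_error(aggregate_types(res, noc), "continent")
})

test_that("continental type-2 areas sum exactly to the world row", {
  fx <- table1_fixture()
  agg <- aggregate_types(fx$results, fx$catchments)
  world_t2 <- agg$area_km2[agg$grouping == "World" & agg$type_code == 2]
  expect_equal(world_t2, sum(fx$areas[, 2]))
  expect_equal(world_t2, 11.1)
})

test_that("headline percentages follow their arithmetic", {
  fx <- table1_fixture()
  agg <- aggregate_types(fx$results, fx$catchments)
  h <- headline_percentages(agg)
  areas <- colSums(fx$areas)
  expect_equal(h$pct_undesirable, 100 * (areas[2] + areas[4]) / sum(areas),
               ignore_attr = TRUE)
  expect_equal(h$pct_P_of_undesirable,
               100 * areas[4] / (areas[2] + areas[4]), ignore_attr = TRUE)

  all1 <- data.frame(catchment_id = fx$results$catchment_id, type_code = 1L,
                     stringsAsFactors = FALSE)
  h1 <- headline_percentages(aggregate_types(all1, fx$catchments))
  expect_equal(h1$pct_undesirable, 0)

  eq24 <- data.frame(catchment_id = c("A", "B"), type_code = c(2L, 4L),
                     stringsAsFactors = FALSE)
  cats <- data.frame(catchment_id = c("A", "B"), continent = "Asia",
                     area_km2 = 5, population = 0, agriculture_km2 = 0,
                     forest_km2 = 0, other_km2 = 5, stringsAsFactors = FALSE)
  h2 <- headline_percentages(aggregate_types(eq24, cats))
  expect_equal(h2$pct_P_of_undesirable, 50)
  expect_equal(h2$pct_undesirable, 100)
})

test_that("land-use breakdown conserves areas and yields cell percentages", {
  fx <- table1_fixture()
  lu <- landuse_breakdown(fx$results, fx$catchments)
  world_lu <- lu[lu$grouping == "World", ]
  expect_equal(sum(world_lu$area_km2), sum(fx$catchments$area_km2))
  cell <- lu[lu$grouping == "Africa" & lu$type_code == 1, ]
  expect_equal(cell$percent, c(50, 25, 25), ignore_attr = TRUE)

  allag <- fx$catchments
  allag$agriculture_km2 <- allag$area_km2
  allag$forest_km2 <- 0; allag$other_km2 <- 0
  lu2 <- landuse_breakdown(fx$results, allag)
  ag <- lu2[lu2$land_use == "agriculture" & lu2$area_km2 > 0, ]
  expect_true(all(ag$percent == 100))
})

test_that("aggregation is idempotent on already aggregated input", {
  fx <- table1_fixture()
  agg <- aggregate_types(fx$results, fx$catchments)
  # re-aggregate the per-continent cells as one catchment per cell
  cells <- agg[agg$grouping != "World" & agg$area_km2 > 0, ]
  cats2 <- data.frame(catchment_id = sprintf("R%02d", seq_len(nrow(cells))),
                      continent = cells$grouping, area_km2 = cells$area_km2,
                      population = cells$population,
                      agriculture_km2 = cells$agriculture_km2,
                      forest_km2 = cells$forest_km2,
                      other_km2 = cells$other_km2, stringsAsFactors = FALSE)
  res2 <- data.frame(catchment_id = cats2$catchment_id,
                     type_code = cells$type_code, stringsAsFactors = FALSE)
  agg2 <- aggregate_types(res2, cats2)
  expect_equal(agg2$area_km2, agg$area_km2)
  expect_equal(agg2$population, agg$population)
})
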