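test_that("threshold surveys summarise to mean, SE and range", {
  st <- data.frame(study_id = c("a", "b", "c"), analyte = "TN",
                   threshold_mgL = c(0.2, 0.8, 1.4),
                   biome = "temperate", region = "US",
                   stringsAsFactors = FALSE)
  s <- summarize_thresholds(st, "TN")
  expect_equal(s$mean, 0.8)
  expect_equal(s$min, 0.2)
  expect_equal(s$max, 1.4)
  expect_equal(s$se, sd(c(0.2, 0.8, 1.4)) / sqrt(3))

  rep2 <- st; rep2$threshold_mgL <- 0.5
  expect_equal(summarize_thresholds(rep2, "TN")$se, 0)
  expect_error(summarize_thresholds(st[1, ], "TN"), ">= 2")
})

test_that("biome ANOVA matches base-R decompositions", {
  st <- data.frame(study_id = letters[1:8], analyte = "TN",
                   threshold_mgL = c(1, 2, 1, 2, 1, 2, 1, 2),
                   biome = rep(c("g1", "g2"), each = 4),
                   region = "US", stringsAsFactors = FALSE)
  a <- anova_thresholds_by_biome(st)
  expect_equal(a$F, 0)
  expect_equal(a$p, 1)

  # two-group ANOVA equals the squared pooled t statistic
  set.seed(6)
  st2 <- st
  st2$threshold_mgL <- rnorm(8, rep(c(0.5, 0.9), each = 4), 0.2)
  a2 <- anova_thresholds_by_biome(st2)
  tt <- t.test(threshold_mgL ~ biome, st2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-9)

  expect_error(anova_thresholds_by_biome(st[1:5, ]), "groups")
})

test_that("the four rules reproduce their worked examples", {
  expect_equal(classify_catchment(1.40, 0.100)$type_code, 4L)
  expect_equal(classify_catchment(1.40, 0.300)$type_code, 2L)
  expect_equal(classify_catchment(0.50, 0.020)$type_code, 3L)
  expect_equal(classify_catchment(0.50, 0.300)$type_code, 1L)
  # ratio exactly 7 goes down the P-limited branch
  r7 <- classify_catchment(0.70, 0.100)
  expect_equal(r7$limitation, "P")
  expect_equal(r7$type_code, 4L)
  # equality with a concentration threshold is acceptable by default
  expect_equal(classify_catchment(0.800, 0.2)$type_code, 1L)
  expect_equal(classify_catchment(0.7, 0.046)$type_code, 3L)
  strict <- classification_rule(equality_undesirable = TRUE)
  expect_equal(classify_catchment(0.800, 0.2, strict)$type_code, 2L)
  expect_error(classify_catchment(0, 0.1), "positive")
})

test_that("the rules partition the positive quadrant exactly once", {
  tn <- exp(seq(log(0.01), log(20), length.out = 40))
  tp <- exp(seq(log(0.001), log(2), length.out = 40))
  grid <- expand.grid(tn = tn, tp = tp)
  res <- classify_catchment(grid$tn, grid$tp)
  expect_true(all(res$type_code %in% 1:4))
  expect_equal(res$limitation, ifelse(grid$tn / grid$tp >= 7, "P", "N"))
  # reconstruct the type from limitation x growth and compare
  manual <- ifelse(res$limitation == "N",
                   ifelse(grid$tn > 0.800, 2L, 1L),
                   ifelse(grid$tp > 0.046, 4L, 3L))
  expect_equal(res$type_code, manual)
})

test_that("classification is scale-consistent and monotone in thresholds", {
  set.seed(14)
  tn <- exp(rnorm(100, 0, 1)); tp <- exp(rnorm(100, -3, 1))
  base <- classify_catchment(tn, tp)
  ug <- classify_catchment(tn * 1000, tp * 1000,
                           classification_rule(tn_threshold = 800,
                                               tp_threshold = 46))
  expect_equal(ug$type_code, base$type_code)

  looser <- classify_catchment(tn, tp, classification_rule(tn_threshold = 2))
  # raising the TN threshold can only move catchments 2 -> 1, never 1 -> 2
  expect_true(all(!(base$type_code == 1 & looser$type_code == 2)))
})

test_that("regional thresholds classify against the global fallback", {
  preds <- data.frame(catchment_id = c("A", "B", "C"),
                      tn_median = c(0.2, 0.9, 0.9),
                      tp_median = c(0.02, 0.03, 0.2),
                      region = c("I", "I", "II"),
                      area_km2 = c(10, 10, 20), stringsAsFactors = FALSE)
  reg_same <- data.frame(region = c("I", "II"),
                         tn_threshold = c(0.800, 0.800),
                         tp_threshold = c(0.046, 0.046),
                         stringsAsFactors = FALSE)
  outs <- classify_with_regional_thresholds(preds, reg_same)
  expect_true(all(!outs$results$differs))
  expect_true(all(outs$total$pct_difference == 0))

  # catchment low in both nutrients classifies type 3 under both rule sets
  regI <- data.frame(region = "I", tn_threshold = 0.310,
                     tp_threshold = 0.047, stringsAsFactors = FALSE)
  one <- data.frame(catchment_id = "X", tn_median = 0.2, tp_median = 0.02,
                    region = "I", stringsAsFactors = FALSE)
  o1 <- classify_with_regional_thresholds(one, regI)
  expect_equal(o1$results$type_regional, 3L)
  expect_equal(o1$results$type_global, 3L)

  # a stricter regional TP threshold flips type 3 to 4 and is counted
  strictP <- data.frame(region = "I", tn_threshold = 0.800,
                        tp_threshold = 0.010, stringsAsFactors = FALSE)
  flip <- data.frame(catchment_id = "Y", tn_median = 0.3, tp_median = 0.03,
                     region = "I", stringsAsFactors = FALSE)
  o2 <- classify_with_regional_thresholds(flip, strictP)
  expect_equal(o2$results$type_global, 3L)
  expect_equal(o2$results$type_regional, 4L)
  expect_true(o2$results$differs)

  partial <- data.frame(region = "I", tn_threshold = 0.8,
                        tp_threshold = NA_real_, stringsAsFactors = FALSE)
  expect_error(classify_with_regional_thresholds(one, partial), "only one")

  # a region without thresholds follows the missing_region setting
  none <- data.frame(region = "Z", tn_threshold = NA_real_,
                     tp_threshold = NA_real_, stringsAsFactors = FALSE)
  one$region <- "Z"
  expect_equal(nrow(classify_with_regional_thresholds(
    one, none, missing_region = "exclude")$results), 0)
  fb <- classify_with_regional_thresholds(one, none,
                                          missing_region = "fallback")
  expect_equal(fb$results$type_regional, fb$results$type_global)
})
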