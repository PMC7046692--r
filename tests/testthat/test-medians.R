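test_that("the trailing seven-year window is applied per site-analyte", {
  dates <- seq(as.Date("2005-03-01"), as.Date("2016-09-01"), by = "month")
  s <- make_samples(values = rep(0.05, length(dates)), dates = dates)
  out <- filter_window(s)
  expect_equal(min(out$date), as.Date("2009-10-01"))
  expect_equal(max(out$date), as.Date("2016-09-01"))
  expect_true(max(out$date) - min(out$date) <= 7 * 366)

  short <- make_samples(values = rep(0.05, 40),
                        dates = seq(as.Date("1992-01-01"), by = "month",
                                    length.out = 40))
  expect_equal(nrow(filter_window(short)), 40)

  old <- make_samples(values = 0.05, dates = as.Date("1989-06-01"))
  expect_equal(nrow(filter_window(old)), 0)
})

test_that("growing-season filtering depends on hemisphere and the tropics", {
  sites <- data.frame(site_id = c("N", "S", "T"),
                      latitude = c(45, -40, -10),
                      catchment_id = "C1", stringsAsFactors = FALSE)
  dates <- c(as.Date("2015-07-15"), as.Date("2015-01-15"))
  s <- rbind(make_samples("N", values = c(1, 1), dates = dates),
             make_samples("S", values = c(1, 1), dates = dates),
             make_samples("T", values = c(1, 1), dates = dates))
  out <- filter_season(s, sites)
  kept <- paste(out$site_id, format(out$date, "%m"))
  expect_setequal(kept, c("N 07", "S 01", "T 07", "T 01"))
})

test_that("eligibility needs 37 points sampled at least bimonthly", {
  monthly <- seq(as.Date("2010-01-01"), by = "month", length.out = 37)
  expect_true(check_eligibility(monthly)$eligible)

  e36 <- check_eligibility(monthly[1:36])
  expect_false(e36$eligible)
  expect_equal(e36$reasons, "too_few_samples")

  quarterly <- seq(as.Date("2000-01-01"), by = "quarter", length.out = 60)
  eq <- check_eligibility(quarterly)
  expect_false(eq$eligible)
  expect_equal(eq$reasons, "too_infrequent")
})

test_that("site medians use the middle-value convention and resist outliers", {
  sites <- data.frame(site_id = "S1", latitude = 40, catchment_id = "C1",
                      stringsAsFactors = FALSE)
  dates <- seq(as.Date("2010-01-01"), by = "2 weeks", length.out = 40)
  s <- make_samples(values = c(1, 2, 100, rep(2, 37)), dates = dates)
  sm <- site_medians(s, sites)
  expect_equal(sm$medians$median_mgL, 2)
  expect_equal(sm$medians$n_samples, 40)

  # order-statistic oracle on log-normal draws
  set.seed(3)
  v <- exp(rnorm(37, log(0.05), 0.5))
  s2 <- make_samples(values = v, dates = dates[1:37])
  oracle <- sort(v)[19]               # odd n: middle order statistic
  expect_equal(site_medians(s2, sites)$medians$median_mgL, oracle)
  expect_equal(stats::median(c(1, 2, 3, 4)), 2.5)  # even-n convention used

  # permutation invariance
  s3 <- s2[sample(37), ]
  expect_equal(site_medians(s3, sites)$medians$median_mgL, oracle)
})

test_that("ineligible series are reported with reasons, not dropped silently", {
  sites <- data.frame(site_id = c("A", "B"), latitude = 40,
                      catchment_id = "C1", stringsAsFactors = FALSE)
  dates <- seq(as.Date("2010-01-01"), by = "2 weeks", length.out = 36)
  s <- rbind(make_samples("A", values = rep(0.05, 36), dates = dates),
             make_samples("B", values = rep(0.05, 40),
                          dates = seq(as.Date("2010-01-01"), by = "2 weeks",
                                      length.out = 40)))
  sm <- site_medians(s, sites)
  expect_equal(sm$medians$site_id, "B")
  expect_equal(sm$ineligible$site_id, "A")
  expect_match(sm$ineligible$reasons, "too_few_samples")
})

test_that("catchment medians pool site medians and ignore order", {
  sm <- data.frame(site_id = c("A", "B", "C", "D"),
                   catchment_id = c("C1", "C1", "C1", "C2"),
                   analyte = "TN",
                   median_mgL = c(0.02, 0.04, 0.06, 0.5),
                   stringsAsFactors = FALSE)
  cm <- catchment_medians(sm)
  expect_equal(cm$median_mgL[cm$catchment_id == "C1"], 0.04)
  expect_equal(cm$median_mgL[cm$catchment_id == "C2"], 0.5)
  expect_equal(cm$n_sites, c(3L, 1L))
  cm2 <- catchment_medians(sm[sample(4), ])
  expect_equal(cm2, cm)
})

test_that("window, season and baseflow filters commute", {
  w <- gen_world(n_catchments = 10, n_sites = 10, seed = 8)
  lk <- link_sites_to_gauges(w$sites, w$links)
  bf <- lapply(split(w$discharge, w$discharge$gauge_id), baseflow_separate)
  f_base <- function(s) filter_baseflow_samples(s, lk$sites, bf)$samples
  f_win <- function(s) filter_window(s)
  f_sea <- function(s) filter_season(s, lk$sites)
  key <- function(s) sort(paste(s$site_id, s$analyte, s$date))
  a <- f_sea(f_win(f_base(w$samples)))
  b <- f_base(f_sea(f_win(w$samples)))
  c_ <- f_win(f_base(f_sea(w$samples)))
  expect_equal(key(b), key(a))
  expect_equal(key(c_), key(a))
})
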