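test_that("Mallows Cp matches its closed form and the full-model identity", {
  expect_equal(mallows_cp(30, 3, 2, 20), 1)        # 15 - 20 + 6
  # full model: sse = sigma2 * (n - p)  =>  Cp = p
  expect_equal(mallows_cp(2.5 * (50 - 6), 6, 2.5, 50), 6)
  expect_error(mallows_cp(10, 2, 0, 20), "sigma2_full")
})

test_that("the smearing factor follows its closed forms and Jensen bound", {
  expect_equal(smearing_factor(rep(0, 10)), 1)
  expect_equal(smearing_factor(c(log(2), -log(2))), 1.25)
  set.seed(19)
  for (i in 1:200) {
    e <- rnorm(sample(2:40, 1), 0, runif(1, 0.01, 2))
    e <- e - mean(e)
    expect_gte(smearing_factor(e), 1)
  }
})

test_that("log_transform_check normalises skewed medians and flags failures", {
  set.seed(2)
  m <- exp(rnorm(80, log(0.5), 0.8))
  chk <- log_transform_check(m)
  expect_equal(chk$response, log(m))
  expect_gt(chk$shapiro_log$p, chk$shapiro_raw$p)
  expect_null(chk$warning)

  expect_warning(log_transform_check(rep(1, 10)), "degenerate")
  mm <- m; names(mm) <- sprintf("C%03d", seq_along(mm)); mm[3] <- 0
  expect_error(log_transform_check(mm), "C003")
})

test_that("best subsets agrees with the exhaustive brute-force oracle", {
  set.seed(42)
  for (i in 1:12) {
    n <- sample(25:60, 1); k <- sample(3:7, 1)
    x <- matrix(rnorm(n * k), n, dimnames = list(NULL, paste0("v", 1:k)))
    beta <- rbinom(k, 1, 0.4) * runif(k, 0.5, 1.5)
    y <- drop(x %*% beta) + rnorm(n, 0, 0.5)
    got <- best_subsets(x, y)
    want <- subset_oracle(x, y)
    expect_setequal(got$chosen_labels, want$labels)
    expect_equal(min(got$table$cp), want$cp, tolerance = 1e-9)
    # full-subset Cp equals its parameter count
    full <- got$table[got$table$p == k + 1, ]
    expect_equal(full$cp, full$p, tolerance = 1e-6)
  }
})

test_that("strong predictors are kept, pure noise collapses to the intercept", {
  set.seed(1)
  n <- 200
  x <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("v", 1:5)))
  y <- 1.0 * x[, 2] - 1.0 * x[, 4] + rnorm(n, 0, 0.3)
  got <- best_subsets(x, y)
  expect_true(all(c("v2", "v4") %in% got$chosen_labels))

  # all-noise designs: the intercept-only subset is the modal choice (Cp is
  # minimised at p = 1 in expectation, though any one seed may admit noise)
  picks <- sapply(1:40, function(s) {
    set.seed(s + 500)
    xn <- matrix(rnorm(60 * 4), 60, dimnames = list(NULL, paste0("v", 1:4)))
    paste(sort(best_subsets(xn, rnorm(60))$chosen_labels), collapse = "+")
  })
  tab <- sort(table(picks), decreasing = TRUE)
  expect_equal(names(tab)[1], "")
})

test_that("nutrient_lm fits by least squares with correct smearing", {
  set.seed(9)
  d <- data.frame(x1 = rnorm(10), x2 = rnorm(10), x3 = rnorm(10))
  d$med <- exp(0.3 + 1.1 * d$x1 - 0.7 * d$x2 + rnorm(10, 0, 0.2))
  fit <- suppressWarnings(nutrient_lm(med ~ x1 + x2, d, analyte = "TN",
                                      max_exhaustive = 2))
  X <- cbind(1, as.matrix(d[, fit$selected, drop = FALSE]))
  oracle <- ols_oracle(X, log(d$med))
  expect_equal(unname(coef(fit)), unname(oracle), tolerance = 1e-9)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-8)
  expect_equal(fit$S, mean(exp(residuals(fit))))

  # perfect linear data: no residuals, S = 1, R2 = 1
  d2 <- data.frame(x1 = 1:12 / 3)
  d2$med <- exp(0.5 + 2 * d2$x1)
  fit2 <- suppressWarnings(nutrient_lm(med ~ x1, d2))
  expect_equal(fit2$S, 1, tolerance = 1e-10)
  expect_equal(fit2$r2, 1, tolerance = 1e-10)
  expect_equal(max(abs(residuals(fit2))), 0, tolerance = 1e-10)
})

test_that("predictions back-transform with a uniform smearing correction", {
  set.seed(4)
  d <- data.frame(x = rnorm(40))
  d$med <- exp(0.2 + 0.9 * d$x + rnorm(40, 0, 0.3))
  fit <- suppressWarnings(nutrient_lm(med ~ x, d))
  nd <- data.frame(x = c(0.5, -0.5, NA))
  lp <- predict(fit, nd, type = "link")
  pr <- predict(fit, nd, type = "response")
  expect_equal(pr[1:2], exp(lp[1:2]) * fit$S)
  expect_true(is.na(pr[3]))
  expect_equal(attr(pr, "skipped"), 3L)

  # x.beta + intercept = 0  =>  prediction is exactly S
  x0 <- -fit$coefficients["(Intercept)"] / fit$coefficients["x"]
  expect_equal(as.numeric(predict(fit, data.frame(x = x0))), fit$S)

  # training-set predictions average above the geometric mean of the fit
  prt <- predict(fit, d, type = "response")
  expect_gte(mean(prt), exp(mean(log(prt / fit$S))))
})

test_that("categorical predictors enter and leave as indicator blocks", {
  set.seed(12)
  n <- 150
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n),
                  biome = sample(c("wet", "dry", "cold"), n, replace = TRUE))
  eff <- c(wet = 0, dry = 1.0, cold = -0.5)
  d$med <- exp(0.1 + 1.2 * d$x1 + eff[d$biome] + rnorm(n, 0, 0.3))
  fit <- suppressWarnings(nutrient_lm(med ~ x1 + x2 + biome, d))
  expect_true(all(c("x1", "biome") %in% fit$selected))
  # all biome indicator columns are present together
  expect_equal(sum(grepl("^biome", names(coef(fit)))), 2)
  pr <- predict(fit, d[1:5, ])
  expect_true(all(pr > 0))
})

test_that("hold-out validation recovers consistency and bias closed forms", {
  set.seed(21)
  d <- data.frame(x = rnorm(60))
  d$med <- exp(0.4 + 1.1 * d$x + rnorm(60, 0, 0.3))
  fit <- suppressWarnings(nutrient_lm(med ~ x, d))
  v <- validate_holdout(fit, d)
  expect_equal(v$r2, fit$r2, tolerance = 1e-9)

  # doubling every prediction means +100% bias
  obs <- predict(fit, d, type = "response") * 2
  d2 <- d; d2$med <- as.numeric(obs)
  v2 <- validate_holdout(fit, d2)
  expect_equal(v2$bias_percent, -50, tolerance = 1e-9)
  d3 <- d; d3$med <- as.numeric(predict(fit, d, type = "response")) / 2
  expect_equal(validate_holdout(fit, d3)$bias_percent, 100, tolerance = 1e-9)

  expect_error(validate_holdout(fit, d[1:2, ]), "at least 3")
})

test_that("hold-out bias stays small under the data-generating model", {
  set.seed(77)
  bias <- replicate(30, {
    g <- gen_catchment_table(250, 5, 2, 1, 0.3, seed = sample.int(1e6, 1))
    d <- merge(g$medians_obs[g$medians_obs$analyte == "TN", ], g$catchments,
               by = "catchment_id")
    tr <- d[1:200, ]; ho <- d[201:250, ]
    f <- suppressWarnings(nutrient_lm(
      median_mgL ~ pred01 + pred02 + pred03 + pred04 + pred05, tr))
    validate_holdout(f, ho)$bias_percent
  })
  expect_lt(abs(mean(bias)), 5)
})

test_that("simulate and plot methods work on a fitted model", {
  set.seed(30)
  d <- data.frame(x = rnorm(30))
  d$med <- exp(0.2 + 0.8 * d$x + rnorm(30, 0, 0.2))
  fit <- suppressWarnings(nutrient_lm(med ~ x, d))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(fit$n, 3))
  expect_true(all(sims > 0))
  tf <- withr::local_tempfile(fileext = ".pdf")
  grDevices::pdf(tf); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tf))
  expect_output(print(summary(fit)), "Mallows Cp")
})
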