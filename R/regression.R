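#' Log-space best-subsets regression with smearing retransformation
#'
#' Catchment median concentrations are right-skewed; their natural logarithms
#' are close to normal, so the model is ordinary least squares on
#' `ln(median)`. Predictor subsets are chosen with the Mallows Cp statistic
#' (categorical predictors enter and leave as whole indicator blocks), and
#' predictions are back-transformed with the Duan smearing factor
#' `S = mean(exp(residuals))`, which corrects the downward bias of
#' `exp(fitted)` under homoscedastic residuals.
#'
#' @name regression
NULL

#' Mallows Cp
#'
#' `Cp = SSE_p / sigma2_full - n + 2 p`, where `sigma2_full` is the residual
#' variance of the model with every candidate predictor. A subset that leaves
#' no systematic signal behind has `Cp` close to its parameter count `p`; in
#' particular the full model satisfies `Cp = p` identically.
#'
#' @param sse_p Residual sum of squares of the candidate subset.
#' @param p Parameter count of the subset, including the intercept.
#' @param sigma2_full Residual variance of the full model.
#' @param n Number of observations.
#' @return The Cp value.
#' @export
mallows_cp <- function(sse_p, p, sigma2_full, n) {
  if (!is.numeric(sigma2_full) || sigma2_full <= 0)
    stop("sigma2_full must be > 0")
  sse_p / sigma2_full - n + 2 * p
}

#' Duan smearing factor
#'
#' `S = (1/n) * sum(exp(residuals))`. By Jensen's inequality `S >= 1`, with
#' equality only for an exact fit; it multiplies every back-transformed
#' prediction under the homoscedasticity assumption.
#'
#' @param residuals Log-space residuals.
#' @return The smearing factor.
#' @export
smearing_factor <- function(residuals) {
  stopifnot(length(residuals) >= 1, !anyNA(residuals))
  mean(exp(residuals))
}

#' Log-transform a response and report normality
#'
#' @param medians Positive concentrations (mg/L). Names, if present, identify
#'   catchments in error messages.
#' @return A list with `response` (natural logs), `shapiro_raw` and
#'   `shapiro_log` (each `list(W, p)`, `NA` when the test is undefined), and
#'   `warning` (`NULL` or a message, also emitted as a condition). The
#'   pipeline proceeds regardless of the test outcome.
#' @export
log_transform_check <- function(medians) {
  bad <- which(is.na(medians) | medians <= 0)
  if (length(bad) > 0) {
    who <- if (!is.null(names(medians))) names(medians)[bad[1]] else
      sprintf("#%d", bad[1])
    stop(sprintf("non-positive median for catchment %s", who))
  }
  lx <- log(medians)
  sw <- function(x) {
    if (length(x) < 3 || length(x) > 5000 || stats::sd(x) == 0)
      return(list(W = NA_real_, p = NA_real_))
    t <- stats::shapiro.test(x)
    list(W = unname(t$statistic), p = t$p.value)
  }
  raw <- sw(medians); trans <- sw(lx)
  warn <- NULL
  if (is.na(trans$p)) {
    warn <- "normality of the log response is undefined (degenerate sample)"
  } else if (trans$p < 0.05) {
    warn <- sprintf("log response still departs from normality (Shapiro-Wilk p = %.3g)",
                    trans$p)
  }
  if (!is.null(warn)) warning(warn, call. = FALSE)
  list(response = lx, shapiro_raw = raw, shapiro_log = trans, warning = warn)
}

# exhaustive / pre-screened subset search over predictor groups using
# crossproducts, so per-subset cost is independent of n
.subset_search <- function(y, X, assign, labels, n, rule = "min_cp",
                           max_exhaustive = 20L) {
  stopifnot(ncol(X) >= 1, assign[1] == 0)    # intercept first
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X))]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(dep, collapse = ", ")))
  }
  p_full <- ncol(X)
  if (n <= p_full + 1) stop("need n > p_full + 1 observations")
  XtX <- crossprod(X); Xty <- crossprod(X, y); yty <- sum(y^2)
  sse_of <- function(cols) {
    b <- solve(XtX[cols, cols, drop = FALSE], Xty[cols, , drop = FALSE])
    max(yty - sum(b * Xty[cols, ]), 0)
  }
  g <- length(labels)
  sse_full <- sse_of(seq_len(p_full))
  sigma2_full <- sse_full / (n - p_full)
  # an exactly-fitting full model leaves Cp undefined; fall back to the
  # smallest subset that also fits exactly
  perfect <- sigma2_full <= 1e-12 * max(yty / n, .Machine$double.xmin)

  pool <- seq_len(g)
  if (g > max_exhaustive) {
    # forward pre-screen: greedily add the group with the largest SSE drop
    chosen <- integer(0); cur <- 1L   # intercept column
    for (step in seq_len(max_exhaustive)) {
      rem <- setdiff(seq_len(g), chosen)
      drops <- vapply(rem, function(j)
        sse_of(c(cur, which(assign == j))), numeric(1))
      best <- rem[which.min(drops)]
      chosen <- c(chosen, best)
      cur <- c(cur, which(assign == best))
    }
    pool <- sort(chosen)
  }

  k <- length(pool)
  n_sub <- 2^k
  subs <- vector("list", n_sub)
  sse <- pcount <- numeric(n_sub)
  for (m in seq_len(n_sub) - 1L) {
    in_g <- pool[bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L]
    cols <- c(1L, which(assign %in% in_g))
    subs[[m + 1L]] <- in_g
    sse[m + 1L] <- sse_of(cols)
    pcount[m + 1L] <- length(cols)
  }
  key <- vapply(subs, function(s) paste(sort(labels[s]), collapse = "+"),
                character(1))
  if (perfect) {
    cp <- rep(NA_real_, n_sub)
    fits <- sse <= 1e-9 * max(yty, 1)
    pick <- which(fits)[order(pcount[fits], key[fits])[1]]
    return(list(table = data.frame(subset = key, p = pcount, sse = sse,
                                   cp = cp, stringsAsFactors = FALSE),
                chosen = subs[[pick]], chosen_labels = labels[subs[[pick]]],
                sigma2_full = sigma2_full, p_full = p_full,
                pool = labels[pool]))
  }
  cp <- mallows_cp(sse, pcount, sigma2_full, n)
  pick <- switch(rule,
    min_cp = order(cp, pcount, key)[1],
    cp_le_p = {
      ok <- which(cp <= pcount + 1e-8)
      if (length(ok) == 0) order(cp, pcount, key)[1]
      else ok[order(pcount[ok], cp[ok], key[ok])[1]]
    },
    stop(sprintf("unknown selection rule '%s'", rule)))
  list(table = data.frame(subset = key, p = pcount, sse = sse, cp = cp,
                          stringsAsFactors = FALSE),
       chosen = subs[[pick]], chosen_labels = labels[subs[[pick]]],
       sigma2_full = sigma2_full, p_full = p_full, pool = labels[pool])
}

#' Best-subsets search by Mallows Cp on a numeric design
#'
#' Convenience interface for a numeric predictor matrix where each column is
#' its own candidate; [nutrient_lm()] runs the same search on a formula with
#' categorical blocks. All `2^k` subsets are scored when `k <=
#' max_exhaustive`; larger pools are first capped by forward selection. The
#' chosen subset minimises Cp (ties: fewer parameters, then lexicographic
#' predictor names).
#'
#' @param x Numeric predictor matrix with column names (no intercept column).
#' @param y Numeric response.
#' @param rule `"min_cp"` or `"cp_le_p"`.
#' @param max_exhaustive Largest pool searched exhaustively. Default 20.
#' @return A list with `table` (subset, p, sse, cp per candidate),
#'   `chosen_labels`, and `sigma2_full`.
#' @export
best_subsets <- function(x, y, rule = c("min_cp", "cp_le_p"),
                         max_exhaustive = 20L) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  X <- cbind(`(Intercept)` = 1, x)
  res <- .subset_search(as.numeric(y), X, assign = c(0L, seq_len(ncol(x))),
                        labels = colnames(x), n = length(y), rule = rule,
                        max_exhaustive = max_exhaustive)
  res[c("table", "chosen_labels", "sigma2_full")]
}

#' Fit a nutrient-concentration regression
#'
#' Fits `ln(response) ~ selected predictors` by ordinary least squares, with
#' the subset selected from the formula's terms by Mallows Cp. Factor terms
#' are treated as indicator blocks that enter or leave together (reference
#' level: the most frequent category). The returned object carries the
#' smearing factor `S` and supports `print`, `summary`, `coef`, `fitted`,
#' `residuals`, `predict`, `simulate` and `plot`.
#'
#' @param formula Model formula; the response is a positive concentration
#'   (mg/L) and is log-transformed internally unless `log_response = FALSE`
#'   (in which case it is taken as already in log space).
#' @param data Data frame of catchment medians and predictors.
#' @param analyte Optional analyte label (`"TN"`, `"TP"`, ...) carried in the
#'   object for reporting.
#' @param rule Subset-selection rule, `"min_cp"` (default) or `"cp_le_p"`.
#' @param max_exhaustive Largest term pool searched exhaustively. Default 20.
#' @param log_response Log-transform the response (default `TRUE`).
#' @return An object of class `nutrient_lm`.
#' @examples
#' d <- data.frame(med = exp(0.5 + 1.2 * rnorm(50) + rnorm(50, sd = 0.3)))
#' d$x1 <- (log(d$med) - 0.5) / 1.2   # informative predictor
#' d$x2 <- rnorm(50)                  # noise
#' fit <- nutrient_lm(med ~ x1 + x2, d, analyte = "TN")
#' predict(fit, d[1:3, ])
#' @export
nutrient_lm <- function(formula, data, analyte = NULL,
                        rule = c("min_cp", "cp_le_p"), max_exhaustive = 20L,
                        log_response = TRUE) {
  rule <- match.arg(rule)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y_raw <- stats::model.response(mf)
  if (log_response) {
    nm <- rownames(mf)
    names(y_raw) <- nm
    chk <- suppressWarnings(log_transform_check(y_raw))
    y <- chk$response
  } else {
    y <- as.numeric(y_raw)
    chk <- NULL
  }
  # put the most frequent level first so it becomes the reference
  for (v in names(mf)[-1])
    if (is.character(mf[[v]]) || is.factor(mf[[v]])) {
      f <- as.factor(mf[[v]])
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      mf[[v]] <- stats::relevel(f, ref = ref)
    }
  tt <- stats::terms(mf)
  labels <- attr(tt, "term.labels")
  X <- stats::model.matrix(tt, mf)
  srch <- .subset_search(as.numeric(y), X, assign = attr(X, "assign"),
                         labels = labels, n = nrow(X), rule = rule,
                         max_exhaustive = max_exhaustive)
  sel <- srch$chosen_labels
  sub_form <- stats::reformulate(if (length(sel) > 0) sel else "1",
                                 response = NULL)
  terms_sel <- stats::terms(sub_form)
  sel_vars <- all.vars(sub_form)
  Xs <- X[, attr(X, "assign") %in% c(0L, match(sel, labels)), drop = FALSE]
  fit <- stats::lm.fit(Xs, as.numeric(y))
  res <- fit$residuals
  sse <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  p <- length(fit$coefficients)
  sigma2_hat <- sse / max(nrow(Xs) - p, 1)
  # per-coefficient t-tests, reported but never used for selection
  se <- sqrt(diag(solve(crossprod(Xs))) * sigma2_hat)
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(abs(tval), df = nrow(Xs) - p, lower.tail = FALSE)
  structure(list(
    call = cl, formula = formula, analyte = analyte,
    selected = sel, subset_formula = sub_form,
    coefficients = fit$coefficients,
    coef_table = data.frame(estimate = fit$coefficients, se = se,
                            t = tval, p_value = pval),
    residuals = res, fitted_log = as.numeric(y) - res,
    sigma2_hat = sigma2_hat,
    r2 = if (tss > 0) 1 - sse / tss else NA_real_,
    S = smearing_factor(res),
    n = nrow(Xs), p = p,
    search = srch$table, sigma2_full = srch$sigma2_full,
    shapiro = chk[c("shapiro_raw", "shapiro_log")],
    normality_warning = chk$warning,
    rule = rule, log_response = log_response,
    terms = tt, terms_sel = terms_sel,
    xlevels = Filter(Negate(is.null),
                     stats::.getXlevels(tt, mf)[sel_vars]),
    contrasts = {
      ctr <- attr(X, "contrasts")
      ctr[names(ctr) %in% sel_vars]
    }),
    class = "nutrient_lm")
}

#' @export
coef.nutrient_lm <- function(object, ...) object$coefficients

#' @export
residuals.nutrient_lm <- function(object, ...) object$residuals

#' Fitted medians on the concentration scale
#'
#' @param object A [nutrient_lm()] fit.
#' @param ... Unused.
#' @return `exp(fitted log) * S` when the response was log-transformed,
#'   otherwise the plain linear fit.
#' @export
fitted.nutrient_lm <- function(object, ...) {
  if (object$log_response) exp(object$fitted_log) * object$S
  else object$fitted_log
}

#' Predict catchment median concentrations
#'
#' @param object A [nutrient_lm()] fit.
#' @param newdata Data frame with the selected predictors. Rows with a
#'   missing predictor yield `NA` and are listed in the `skipped` attribute:
#'   a catchment without a full predictor set cannot be scored.
#' @param type `"response"` (back-transformed, smearing-corrected, mg/L) or
#'   `"link"` (log-space linear predictor).
#' @param ... Unused.
#' @return Numeric predictions; attribute `skipped` holds the row indices
#'   dropped for missing predictors.
#' @export
predict.nutrient_lm <- function(object, newdata,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  tt <- object$terms_sel
  need <- all.vars(tt)
  for (v in need)
    if (is.null(newdata[[v]]))
      stop(sprintf("predictor '%s' missing from newdata", v))
  miss <- rep(FALSE, nrow(newdata))
  for (v in need)
    miss <- miss | is.na(newdata[[v]])
  ok <- which(!miss)
  lp <- rep(NA_real_, nrow(newdata))
  if (length(ok) > 0) {
    mf <- stats::model.frame(tt, newdata[ok, , drop = FALSE],
                             na.action = stats::na.pass,
                             xlev = object$xlevels)
    X <- stats::model.matrix(tt, mf, contrasts.arg =
                               if (length(object$contrasts) > 0)
                                 object$contrasts else NULL)
    lp[ok] <- drop(X[, names(object$coefficients), drop = FALSE] %*%
                     object$coefficients)
  }
  out <- if (type == "link" || !object$log_response) lp else exp(lp) * object$S
  attr(out, "skipped") <- which(miss)
  out
}

#' Simulate new responses from a fitted model
#'
#' Draws log-normal responses around the fitted log medians with the
#' estimated residual standard deviation — the model's own account of
#' sampling variability.
#'
#' @param object A [nutrient_lm()] fit.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, as for [stats::simulate()].
#' @export
simulate.nutrient_lm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  sims <- replicate(nsim, {
    e <- stats::rnorm(n, 0, sqrt(object$sigma2_hat))
    if (object$log_response) exp(object$fitted_log + e)
    else object$fitted_log + e
  })
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
print.nutrient_lm <- function(x, ...) {
  cat(sprintf("Nutrient concentration model%s (log-space OLS, %s selection)\n",
              if (!is.null(x$analyte)) paste0(" for ", x$analyte) else "",
              x$rule))
  cat(sprintf("  n = %d, p = %d, R2 = %.3f, smearing S = %.4f\n",
              x$n, x$p, x$r2, x$S))
  cat("  selected terms:",
      if (length(x$selected) > 0) paste(x$selected, collapse = ", ")
      else "(intercept only)", "\n")
  invisible(x)
}

#' @export
summary.nutrient_lm <- function(object, ...) {
  structure(list(fit = object), class = "summary.nutrient_lm")
}

#' @export
print.summary.nutrient_lm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nCoefficients (log space):\n")
  ct <- f$coef_table
  ct$sig <- ifelse(ct$p_value < 0.05, "*", "")
  print(format(ct, digits = 4))
  cat(sprintf("\nResidual sd (log space): %.4f on %d df\n",
              sqrt(f$sigma2_hat), f$n - f$p))
  if (!is.null(f$shapiro$shapiro_log$p) && !is.na(f$shapiro$shapiro_log$p))
    cat(sprintf("Shapiro-Wilk on log response: W = %.4f, p = %.3g\n",
                f$shapiro$shapiro_log$W, f$shapiro$shapiro_log$p))
  best <- utils::head(f$search[order(f$search$cp), ], 5)
  cat("\nTop subsets by Mallows Cp:\n")
  print(format(best, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Observed-versus-fitted plot
#'
#' @param x A [nutrient_lm()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.nutrient_lm <- function(x, ...) {
  obs <- if (x$log_response) exp(x$fitted_log + x$residuals) else
    x$fitted_log + x$residuals
  fit <- fitted(x)
  graphics::plot(fit, obs, log = if (x$log_response) "xy" else "",
                 xlab = "fitted median (mg/L)", ylab = "observed median (mg/L)",
                 main = sprintf("%s: observed vs fitted",
                                if (is.null(x$analyte)) "model" else x$analyte),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Validate a fitted model on held-out catchments
#'
#' @param object A [nutrient_lm()] fit.
#' @param newdata Hold-out data frame containing the response and predictors;
#'   it must be disjoint from the training set for the validation to mean
#'   anything.
#' @return A list with `r2` (squared correlation of log observed vs log
#'   predicted), `slope` (log observed on log predicted), `bias_percent`
#'   (`100 * (mean predicted - mean observed) / mean observed`, concentration
#'   scale), and `n`.
#' @export
validate_holdout <- function(object, newdata) {
  stopifnot(inherits(object, "nutrient_lm"))
  obs <- stats::model.response(
    stats::model.frame(object$formula, newdata, na.action = stats::na.pass))
  pred <- predict(object, newdata, type = "response")
  ok <- !is.na(obs) & !is.na(pred)
  if (sum(ok) < 3) stop("hold-out set must contain at least 3 usable rows")
  obs <- as.numeric(obs[ok]); pred <- as.numeric(pred[ok])
  lo <- log(obs); lp <- log(pred)
  list(r2 = stats::cor(lo, lp)^2,
       slope = unname(stats::coef(stats::lm(lo ~ lp))[2]),
       bias_percent = 100 * (mean(pred) - mean(obs)) / mean(obs),
       n = sum(ok))
}
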