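# Independent oracles and fixture builders used across the suite.

# Direct hand-iterated Lyne-Hollick recursion, written independently of the
# package implementation: works on an explicitly mirrored series, tracks the
# quickflow state step by step in whichever direction the pass runs.
lh_oracle <- function(q, alpha = 0.925, passes = 3, reflect = 30) {
  n <- length(q)
  pad <- min(reflect, n - 1)
  left <- q[(pad + 1):2]
  right <- q[(n - 1):(n - pad)]
  x <- c(left, q, right)
  m <- length(x)
  for (pass in seq_len(passes)) {
    idx <- if (pass %% 2 == 1) 1:m else m:1
    qf_prev <- 0
    bf <- numeric(m)
    bf[idx[1]] <- x[idx[1]]          # qf starts at zero
    for (k in 2:m) {
      i <- idx[k]; ip <- idx[k - 1]
      qf <- alpha * qf_prev + 0.5 * (1 + alpha) * (x[i] - x[ip])
      if (qf < 0) qf <- 0
      if (qf > x[i]) qf <- x[i]
      bf[i] <- x[i] - qf
      qf_prev <- qf
    }
    x <- bf
  }
  x[(pad + 1):(pad + n)]
}

# Ordinary least squares through the normal equations (independent of lm).
ols_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Exhaustive best-subsets oracle: fits every subset with .lm.fit and applies
# the same Cp criterion with ties broken by parameter count then subset name.
subset_oracle <- function(x, y) {
  x <- as.matrix(x)
  k <- ncol(x)
  n <- length(y)
  full <- .lm.fit(cbind(1, x), y)
  sigma2_full <- sum(full$residuals^2) / (n - (k + 1))
  best <- NULL
  for (m in 0:(2^k - 1)) {
    in_s <- which(bitwAnd(m, 2^(seq_len(k) - 1)) != 0)
    X <- cbind(1, x[, in_s, drop = FALSE])
    sse <- sum(.lm.fit(X, y)$residuals^2)
    p <- ncol(X)
    cp <- sse / sigma2_full - n + 2 * p
    key <- paste(sort(colnames(x)[in_s]), collapse = "+")
    cand <- list(cp = cp, p = p, key = key, labels = colnames(x)[in_s])
    if (is.null(best) || cp < best$cp ||
        (cp == best$cp && (p < best$p || (p == best$p && key < best$key))))
      best <- cand
  }
  best
}

# Quick builder for sample tables.
make_samples <- function(site_id = "S1", analyte = "TN", values,
                         dates = NULL, censored = FALSE, dl = 0.01,
                         method_code = "persulfate_digestion",
                         pore = NA_real_) {
  n <- length(values)
  if (is.null(dates))
    dates <- as.Date("2010-01-15") + seq_len(n) * 30
  data.frame(site_id = rep(site_id, length.out = n),
             date = rep(as.Date(dates), length.out = n),
             analyte = rep(analyte, length.out = n),
             value = values,
             detection_limit = rep(dl, length.out = n),
             censored = rep(censored, length.out = n),
             method_code = rep(method_code, length.out = n),
             filter_pore_um = rep(pore, length.out = n),
             stringsAsFactors = FALSE)
}

# Continental areas of the published world summary (millions km2), used as an
# aggregation fixture with one catchment per (continent, type) cell.
table1_fixture <- function() {
  areas <- rbind(
    Africa          = c(22.7, 6.1, 0.0, 1.1),
    Asia            = c(19.4, 4.2, 8.1, 12.5),
    Europe          = c(2.2, 0.0, 0.6, 6.6),
    `North America` = c(11.7, 0.0, 4.2, 6.1),
    Oceania         = c(3.8, 0.8, 0.3, 2.6),
    `South America` = c(15.6, 0.0, 0.7, 1.5))
  rows <- list(); res <- list(); k <- 0
  for (cn in rownames(areas)) for (tc in 1:4) {
    a <- areas[cn, tc]
    if (a == 0) next
    k <- k + 1
    id <- sprintf("F%02d", k)
    rows[[k]] <- data.frame(catchment_id = id, continent = cn,
                            area_km2 = a, population = 0,
                            agriculture_km2 = a / 2, forest_km2 = a / 4,
                            other_km2 = a / 4, stringsAsFactors = FALSE)
    res[[k]] <- data.frame(catchment_id = id, type_code = tc,
                           stringsAsFactors = FALSE)
  }
  list(catchments = do.call(rbind, rows), results = do.call(rbind, res),
       areas = areas)
}
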