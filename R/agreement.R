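# Agreement and repeatability statistics: Bland-Altman, Pearson/regression,
# the exact paired Wilcoxon signed-rank test, and comparison-table assembly.
#
# Convention: differences are always (test method - reference), e.g.
# 4D - 2D or scan2 - scan1; every table output states this in its metadata.

#' Bland-Altman agreement between two paired methods
#'
#' Differences `d = a - b`; bias is `mean(d)`, SD is the sample standard
#' deviation (n-1 denominator), and the limits of agreement are
#' `bias -/+ 1.96 * SD`.
#'
#' @param a test-method values.
#' @param b reference-method values (same length, pairwise complete).
#' @return A list: `n`, `bias`, `sd`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b) {
  check_paired(a, b, min_n = 2L)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(n = length(d), bias = bias, sd = s,
       loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s)
}

#' Pearson correlation and least-squares regression of paired methods
#'
#' Regresses the test method on the reference (`a = slope * b + intercept`)
#' and reports the Pearson correlation coefficient.
#'
#' @param a test-method values (the y variable).
#' @param b reference-method values (the x variable; must have nonzero
#'   variance).
#' @return A list: `n`, `r`, `slope`, `intercept`.
#' @export
pearson_regression <- function(a, b) {
  check_paired(a, b, min_n = 3L)
  if (stats::var(b) == 0) {
    stop("degenerate-input error: reference values have zero variance",
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, b), a)
  r <- if (stats::var(a) == 0) 0 else stats::cor(a, b)
  list(n = length(a), r = r,
       slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]))
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided paired signed-rank test. Zero differences are dropped before
#' ranking; ties in |d| receive midranks. The statistic is
#' `W = min(W+, W-)`. For `n <= 20` the p value is exact over all `2^n`
#' equally likely sign assignments (computed via the rank-sum distribution;
#' identical to full enumeration, ties included); above that, a normal
#' approximation with tie-corrected variance is used. The two-sided p is
#' twice the smaller tail, capped at 1.
#'
#' @param a first sample (or the differences themselves if `b` is NULL).
#' @param b optional second sample, paired with `a`.
#' @return A list: `statistic` (W), `w_plus`, `w_minus`, `p_value`,
#'   `n_used` (pairs after dropping zeros), `method` ("exact" or "normal").
#' @export
wilcoxon_signed_rank <- function(a, b = NULL) {
  d <- if (is.null(b)) a else {
    check_paired(a, b, min_n = 1L)
    a - b
  }
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all differences are zero; p = 1")
    return(list(statistic = 0, w_plus = 0, w_minus = 0, p_value = 1,
                n_used = 0L, method = "degenerate"))
  }
  rk <- rank(abs(d))
  w_plus <- sum(rk[d > 0])
  w_minus <- sum(rk[d < 0])
  W <- min(w_plus, w_minus)
  if (n <= 20L) {
    dist <- signed_rank_distribution(rk)
    p_le <- sum(dist$prob[dist$w <= w_plus + 1e-9])
    p_ge <- sum(dist$prob[dist$w >= w_plus - 1e-9])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = W, w_plus = w_plus, w_minus = w_minus, p_value = p,
       n_used = n, method = method)
}

# Exact null distribution of W+ for given ranks (midranks allowed).
# Doubled ranks are integers, so the distribution is built by dynamic
# programming over an integer sum grid - equivalent to enumerating all 2^n
# sign assignments.
signed_rank_distribution <- function(rk) {
  r2 <- round(2 * rk)
  total <- sum(r2)
  f <- numeric(total + 1L)  # counts over doubled-sum grid 0..total
  f[1] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1):(total + 1)] <- g[(r + 1):(total + 1)] + f[1:(total + 1 - r)]
    f <- g
  }
  w <- (0:total) / 2
  keep <- f > 0
  list(w = w[keep], prob = f[keep] / 2^length(rk))
}

#' Full agreement summary between two paired methods
#'
#' Combines [bland_altman()], [pearson_regression()] and
#' [wilcoxon_signed_rank()] into one record; components whose preconditions
#' are not met (too few pairs, zero reference variance) are returned as NA
#' rather than raising.
#'
#' @inheritParams bland_altman
#' @return A one-row tibble: `n`, `bias`, `sd`, `loa_low`, `loa_high`, `r`,
#'   `slope`, `intercept`, `p_wilcoxon`.
#' @export
agree_methods <- function(a, b) {
  ba <- bland_altman(a, b)
  pr <- if (length(a) >= 3L && stats::var(b) > 0) {
    pearson_regression(a, b)
  } else {
    list(r = NA_real_, slope = NA_real_, intercept = NA_real_)
  }
  wx <- if (all(a == b)) {
    list(p_value = 1)
  } else {
    wilcoxon_signed_rank(a, b)
  }
  tibble::tibble(n = ba$n, bias = ba$bias, sd = ba$sd,
                 loa_low = ba$loa_low, loa_high = ba$loa_high,
                 r = pr$r, slope = pr$slope, intercept = pr$intercept,
                 p_wilcoxon = wx$p_value)
}

#' Assemble a method/scanner/day comparison table
#'
#' The repeatability/reproducibility machinery of a validation study: given
#' a long measurement table (one row per subject, occasion, scanner, method
#' and metric) and a set of planned comparisons, pairs the measurements on
#' all identifying columns except the compared factor and computes one
#' agreement row per comparison and metric. Differences are
#' (test - reference). Incomplete pairs are dropped and counted.
#'
#' @param measurements data frame with a `value` column, a `metric` column,
#'   and identifying columns (e.g. `subject`, `occasion`, `scanner`,
#'   `method`).
#' @param design data frame of planned comparisons with columns `label`
#'   (comparison name), `factor` (the column being compared), `test` and
#'   `ref` (its two levels).
#' @return A tibble with one row per comparison and metric: `label`,
#'   `metric`, `n`, `n_dropped`, and the [agree_methods()] statistics.
#' @export
build_comparison_table <- function(measurements, design) {
  measurements <- tibble::as_tibble(measurements)
  if (!all(c("value", "metric") %in% names(measurements))) {
    stop("measurements need 'value' and 'metric' columns", call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(design))) {
    fac <- design$factor[i]
    if (!fac %in% names(measurements)) {
      stop("unknown factor column: ", fac, call. = FALSE)
    }
    t_df <- measurements[measurements[[fac]] == design$test[i], ]
    r_df <- measurements[measurements[[fac]] == design$ref[i], ]
    by_cols <- setdiff(names(measurements), c(fac, "value"))
    merged <- dplyr::inner_join(t_df, r_df, by = by_cols,
                                suffix = c("_test", "_ref"))
    for (m in sort(unique(measurements$metric))) {
      mm <- merged[merged$metric == m, ]
      n_m <- sum(t_df$metric == m) + sum(r_df$metric == m) - 2 * nrow(mm)
      if (nrow(mm) < 2L) next
      row <- agree_methods(mm$value_test, mm$value_ref)
      out[[length(out) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(label = design$label[i], metric = m,
                       n_dropped = n_m), row)
    }
  }
  if (length(out) == 0L) {
    stop("insufficient-data error: no comparison has >= 2 complete pairs",
         call. = FALSE)
  }
  res <- dplyr::bind_rows(out)
  res[, c("label", "metric", "n", "n_dropped", "bias", "sd", "loa_low",
          "loa_high", "r", "slope", "intercept", "p_wilcoxon")]
}

check_paired <- function(a, b, min_n) {
  if (length(a) != length(b)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) {
    stop("paired samples must be complete (no NA)", call. = FALSE)
  }
  if (length(a) < min_n) {
    stop("insufficient-data error: need at least ", min_n, " pairs",
         call. = FALSE)
  }
  invisible(TRUE)
}
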