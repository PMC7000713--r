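# run code under a temporary RNG state so generators never disturb the
# caller's random stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fit a power law on log-log axes
#'
#' Fits `log(y) = intercept + exponent * log(x)` by ordinary least squares
#' (default) or standardized major axis (SMA; slope =
#' `sign(cor) * sd(log y) / sd(log x)`, appropriate when both axes carry
#' error).  Confidence intervals on the exponent are analytic (t-based for
#' OLS, the standard SMA interval for SMA) or percentile bootstrap over
#' case resampling.
#'
#' @param x,y Strictly positive numeric vectors of equal length (>= 3).
#' @param method `"ols"` or `"sma"`.
#' @param ci_method `"analytic"` or `"bootstrap"`.
#' @param n_bootstrap Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; required for `ci_method = "bootstrap"` so fits
#'   are reproducible.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `power_law_fit` with fields `exponent`,
#'   `intercept`, `ci_low`, `ci_high`, `n`, `method`, `ci_method`, `seed`,
#'   `r_squared`.
#' @examples
#' fit <- fit_power_law(1:20, (1:20)^2)
#' fit$exponent  # 2
#' @export
fit_power_law <- function(x, y, method = c("ols", "sma"),
                          ci_method = c("analytic", "bootstrap"),
                          n_bootstrap = 2000, seed = NULL,
                          conf_level = 0.95) {
  method <- match.arg(method)
  ci_method <- match.arg(ci_method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 points")
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stop("all x and y values must be finite and strictly positive")
  lx <- log(x); ly <- log(y)
  if (stats::sd(lx) == 0) stop("zero variance in x: degenerate input")
  n <- length(x)

  est <- .pl_slope(lx, ly, method)
  if (ci_method == "analytic") {
    ci <- .pl_analytic_ci(lx, ly, est, method, conf_level)
  } else {
    if (is.null(seed))
      stop("'seed' is required for bootstrap confidence intervals")
    slopes <- with_seed(seed, vapply(seq_len(n_bootstrap), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      lxi <- lx[idx]
      if (stats::sd(lxi) == 0) return(NA_real_)  # degenerate resample
      .pl_slope(lxi, ly[idx], method)["slope"]
    }, numeric(1)))
    a <- (1 - conf_level) / 2
    ci <- unname(stats::quantile(slopes, c(a, 1 - a), na.rm = TRUE))
  }
  r <- stats::cor(lx, ly)
  structure(list(exponent = unname(est["slope"]),
                 intercept = unname(est["intercept"]),
                 ci_low = min(ci[1], unname(est["slope"])),
                 ci_high = max(ci[2], unname(est["slope"])),
                 n = n, method = method, ci_method = ci_method,
                 seed = seed, r_squared = r^2),
            class = "power_law_fit")
}

.pl_slope <- function(lx, ly, method) {
  if (method == "ols") {
    slope <- stats::cov(lx, ly) / stats::var(lx)
  } else {
    r <- stats::cor(lx, ly)
    s <- if (is.na(r) || r == 0) 1 else sign(r)
    slope <- s * stats::sd(ly) / stats::sd(lx)
  }
  c(slope = slope, intercept = mean(ly) - slope * mean(lx))
}

.pl_analytic_ci <- function(lx, ly, est, method, conf_level) {
  n <- length(lx)
  b <- est["slope"]
  r2 <- stats::cor(lx, ly)^2
  if (method == "ols") {
    resid <- ly - est["intercept"] - b * lx
    se <- sqrt(sum(resid^2) / (n - 2)) / (stats::sd(lx) * sqrt(n - 1))
    tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
    unname(c(b - tq * se, b + tq * se))
  } else {
    # standard SMA interval: b * (sqrt(B + 1) +/- sqrt(B)),
    # B = F_{1, n-2} (1 - r^2) / (n - 2)
    Fq <- stats::qf(conf_level, 1, n - 2)
    B <- Fq * (1 - r2) / (n - 2)
    lims <- b * (sqrt(B + 1) + c(-1, 1) * sqrt(B))
    unname(sort(lims))
  }
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit (%s, %s CI): exponent = %.4f [%.4f, %.4f], intercept = %.4f, n = %d\n",
    toupper(x$method), x$ci_method, x$exponent, x$ci_low, x$ci_high,
    x$intercept, x$n))
  invisible(x)
}

#' Does a fit's confidence interval cover a predicted exponent?
#'
#' @param fit A [fit_power_law()] result.
#' @param predicted_exponent The theoretically predicted scaling exponent.
#' @return `TRUE` iff `ci_low <= predicted_exponent <= ci_high`.
#' @export
prediction_covered <- function(fit, predicted_exponent) {
  stopifnot(inherits(fit, "power_law_fit"), is.numeric(predicted_exponent))
  fit$ci_low <= predicted_exponent & predicted_exponent <= fit$ci_high
}
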