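#' Ordinary least squares with slope F-test
#'
#' Closed-form simple linear regression used throughout the pipeline. The
#' slope test is the F statistic on (1, n - 2) degrees of freedom, equal to
#' the squared slope t statistic; this is the test used to ask whether a
#' reactivity- or metabolic-downscaling regression line differs from flat.
#'
#' Exact fits (zero residual variance) are legitimate on constructed data;
#' they are reported with `exact_fit = TRUE`, `se_slope = 0`, and an
#' infinite F rather than an error, except that a constant response gives
#' slope 0 and F = 0.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); `x` must not be
#'   constant.
#' @return An object of class `ols_fit`: a list with `n`, `slope`,
#'   `intercept`, `se_slope`, `se_intercept`, `r2`, `f_slope`, `p_slope`,
#'   `rss`, `exact_fit`.
#' @examples
#' fit <- ols_fit(1:10, 2 * (1:10) + 1)
#' fit$slope; fit$r2
#' @export
ols_fit <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("ols_fit needs at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  if (sxx == 0) stop("x is constant; slope is not identifiable")
  sxy <- sum((x - xb) * (y - yb))
  syy <- sum((y - yb)^2)
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  rss <- syy - slope * sxy
  rss <- max(rss, 0)        # guard tiny negative round-off
  sigma2 <- rss / (n - 2L)
  se_slope <- sqrt(sigma2 / sxx)
  se_intercept <- sqrt(sigma2 * (1 / n + xb^2 / sxx))
  r2 <- if (syy > 0) 1 - rss / syy else 1
  exact_fit <- syy > 0 && rss <= .Machine$double.eps * syy * n
  if (slope == 0 && syy == 0) {
    f <- 0; p <- 1
  } else if (exact_fit || sigma2 == 0) {
    f <- if (slope == 0) 0 else Inf
    p <- if (slope == 0) 1 else 0
  } else {
    f <- (slope / se_slope)^2
    p <- stats::pf(f, 1, n - 2L, lower.tail = FALSE)
  }
  structure(
    list(n = n, slope = slope, intercept = intercept,
         se_slope = se_slope, se_intercept = se_intercept,
         r2 = r2, f_slope = f, p_slope = p, rss = rss,
         exact_fit = exact_fit),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("<ols_fit> n = %d: y = %.4g + %.4g x; R2 = %.3f; F(1,%d) = %.3g, p = %.3g%s\n",
              x$n, x$intercept, x$slope, x$r2, x$n - 2L, x$f_slope, x$p_slope,
              if (x$exact_fit) " [exact fit]" else ""))
  invisible(x)
}

#' Confidence interval for an OLS slope
#'
#' @param fit An [ols_fit()] result.
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`. For exact fits the interval is
#'   degenerate at the slope.
#' @export
slope_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "ols_fit"))
  if (fit$se_slope == 0) return(c(fit$slope, fit$slope))
  tq <- stats::qt(1 - (1 - level) / 2, fit$n - 2L)
  fit$slope + c(-1, 1) * tq * fit$se_slope
}

#' ANCOVA comparing regression lines across groups
#'
#' Sequential analysis of covariance on g groups of (x, y) data, mirroring
#' how genotype contrasts are reported for reactivity and metabolic
#' regressions: first an equal-slopes F-test (separate-slopes model vs
#' common-slope model, df (g - 1, n - 2g)); then, under a common slope, an
#' equal-intercepts F-test (common-slope model vs single-line model,
#' df (g - 1, n - g - 1)). Both tests are residual-sum-of-squares
#' comparisons computed in closed form. Exact-fit degeneracies (zero
#' residual variance in the richer model) yield an infinite F flagged via
#' `exact_fit` rather than a division by zero.
#'
#' @param groups A named or unnamed list with one element per group, each a
#'   list or data.frame holding numeric `x` and `y` (each satisfying the
#'   [ols_fit()] preconditions).
#' @return An object of class `ancova_result`: list with `g`, `n`,
#'   `f_slopes`, `df_slopes`, `p_slopes`, `f_intercepts`, `df_intercepts`,
#'   `p_intercepts`, `common_slope`, `rss` (the three model RSS values) and
#'   `exact_fit`.
#' @examples
#' g1 <- list(x = 1:10, y = 1:10 + rnorm(10))
#' g2 <- list(x = 1:10, y = 2 + 1:10 + rnorm(10))
#' ancova(list(a = g1, b = g2))
#' @export
ancova <- function(groups) {
  if (length(groups) < 2L) stop("ancova needs at least 2 groups")
  stats_g <- lapply(groups, function(g) {
    x <- g$x; y <- g$y
    if (length(x) < 3L) stop("each group needs at least 3 observations")
    if (anyNA(x) || anyNA(y)) stop("groups must not contain NA")
    xb <- mean(x); yb <- mean(y)
    sxx <- sum((x - xb)^2)
    if (sxx == 0) stop("a group has constant x; its slope is not identifiable")
    list(n = length(x), xb = xb, yb = yb, sxx = sxx,
         sxy = sum((x - xb) * (y - yb)), syy = sum((y - yb)^2),
         x = x, y = y)
  })
  g <- length(stats_g)
  n <- sum(vapply(stats_g, `[[`, numeric(1), "n"))
  # separate slopes & intercepts: RSS is the sum of per-group OLS RSS
  rss_sep <- sum(vapply(stats_g, function(s) {
    max(s$syy - s$sxy^2 / s$sxx, 0)
  }, numeric(1)))
  # common slope, separate intercepts (pooled within-group slope)
  sxx_w <- sum(vapply(stats_g, `[[`, numeric(1), "sxx"))
  sxy_w <- sum(vapply(stats_g, `[[`, numeric(1), "sxy"))
  syy_w <- sum(vapply(stats_g, `[[`, numeric(1), "syy"))
  common_slope <- sxy_w / sxx_w
  rss_common <- max(syy_w - sxy_w^2 / sxx_w, 0)
  # single line over the pooled data
  x_all <- unlist(lapply(stats_g, `[[`, "x"))
  y_all <- unlist(lapply(stats_g, `[[`, "y"))
  xb <- mean(x_all); yb <- mean(y_all)
  sxx_t <- sum((x_all - xb)^2)
  sxy_t <- sum((x_all - xb) * (y_all - yb))
  syy_t <- sum((y_all - yb)^2)
  rss_single <- max(syy_t - sxy_t^2 / sxx_t, 0)

  f_test <- function(rss_full, rss_red, df1, df2, scale) {
    num <- max(rss_red - rss_full, 0) / df1
    exact <- rss_full <= .Machine$double.eps * max(scale, 1) * n
    if (exact) {
      if (num <= .Machine$double.eps * max(scale, 1) * n) {
        list(f = 0, p = 1, exact = TRUE)
      } else {
        list(f = Inf, p = 0, exact = TRUE)
      }
    } else {
      f <- num / (rss_full / df2)
      list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
           exact = FALSE)
    }
  }
  ts <- f_test(rss_sep, rss_common, g - 1L, n - 2L * g, syy_t)
  ti <- f_test(rss_common, rss_single, g - 1L, n - g - 1L, syy_t)
  structure(
    list(g = g, n = n,
         f_slopes = ts$f, df_slopes = c(g - 1L, n - 2L * g), p_slopes = ts$p,
         f_intercepts = ti$f, df_intercepts = c(g - 1L, n - g - 1L),
         p_intercepts = ti$p,
         common_slope = common_slope,
         rss = c(separate = rss_sep, common_slope = rss_common,
                 single_line = rss_single),
         exact_fit = ts$exact || ti$exact),
    class = "ancova_result"
  )
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("<ancova> %d groups, n = %d\n", x$g, x$n))
  cat(sprintf("  equal slopes:     F(%d,%d) = %.4g, p = %.4g\n",
              x$df_slopes[1], x$df_slopes[2], x$f_slopes, x$p_slopes))
  cat(sprintf("  equal intercepts: F(%d,%d) = %.4g, p = %.4g (common slope %.4g)\n",
              x$df_intercepts[1], x$df_intercepts[2], x$f_intercepts,
              x$p_intercepts, x$common_slope))
  invisible(x)
}
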