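# Locally weighted polynomial regression with tricube weights and
# pointwise confidence bands from the linear-smoother variance formula.

tricube <- function(u) ifelse(u < 1, (1 - u^3)^3, 0)

# hat ("equivalent kernel") row at x0: fitted(x0) = l %*% y
local_fit_vector <- function(x, x0, q, degree) {
  d <- abs(x - x0)
  n <- length(x)
  # the farthest included neighbour has weight exactly 0; widen the window
  # if ties leave fewer than degree + 1 points with positive weight
  repeat {
    d_q <- sort(d)[q]
    w <- if (d_q == 0) as.numeric(d == 0) else tricube(d / d_q)
    if (sum(w > 0) >= degree + 1 || q >= n) break
    q <- q + 1
  }
  if (sum(w > 0) < degree + 1) {
    w <- as.numeric(rank(d, ties.method = "first") <= degree + 1)
  }
  keep <- which(w > 0)
  xk <- x[keep] - x0
  X <- outer(xk, 0:degree, `^`)
  W <- w[keep]
  XtW <- t(X * W)
  A <- XtW %*% X
  # first row of (X'WX)^-1 X'W picks the intercept = fit at x0
  l <- rep(0, length(x))
  l[keep] <- solve(A, XtW)[1, ]
  l
}

#' Fit a locally weighted regression curve with a 95% confidence band
#'
#' At each evaluation point the `floor(span * n)` nearest data points are
#' fit by weighted least squares with tricube weights (distances scaled by
#' the distance to the farthest included neighbour) and a local polynomial
#' of the given degree; the fitted value is the local intercept. Because
#' the smoother is linear in the responses, the fitted value at `x0` is
#' `l(x0)' y` and its standard error is `sigma * ||l(x0)||`, with `sigma^2`
#' estimated from the residuals using the equivalent residual degrees of
#' freedom `n - 2 tr(L) + tr(L'L)`. The band is the pointwise Gaussian
#' interval `fitted +/- 1.96 se`.
#'
#' @param x,y Numeric vectors (at least `degree + 2` points).
#' @param span Fraction of points in each local window, in (0, 1].
#' @param degree Local polynomial degree (1 or 2).
#' @param eval_x Evaluation points; default the sorted data `x` values.
#' @return A `loess_band`: list with `span`, `degree`, the training data,
#'   per-point `fitted` and `residuals`, `sigma`, `enp` (trace of the
#'   smoother matrix), `df_residual`, and a `grid` tibble
#'   (`x`, `fitted`, `se`, `ci_lo`, `ci_hi`).
#' @export
fit_loess <- function(x, y, span = 0.75, degree = 2, eval_x = NULL) {
  stopifnot(length(x) == length(y), span > 0, span <= 1,
            degree %in% c(1, 2))
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  n <- length(x)
  if (n < degree + 2) {
    stop("need at least degree + 2 points", call. = FALSE)
  }
  q <- floor(span * n)
  if (q < degree + 1) {
    stop("span * n = ", span * n, " < degree + 1; increase the span",
         call. = FALSE)
  }
  if (is.null(eval_x)) eval_x <- x

  L <- t(vapply(x, local_fit_vector, numeric(n), x = x, q = q,
                degree = degree))
  fitted_data <- as.numeric(L %*% y)
  resid <- y - fitted_data
  nu1 <- sum(diag(L))
  nu2 <- sum(L * L)
  df_resid <- n - 2 * nu1 + nu2
  sigma2 <- if (df_resid > 0) sum(resid^2) / df_resid else 0
  sigma <- sqrt(max(sigma2, 0))

  Le <- t(vapply(eval_x, local_fit_vector, numeric(n), x = x, q = q,
                 degree = degree))
  fitted_eval <- as.numeric(Le %*% y)
  se <- sigma * sqrt(rowSums(Le * Le))
  grid <- tibble::tibble(
    x = eval_x, fitted = fitted_eval, se = se,
    ci_lo = fitted_eval - 1.96 * se, ci_hi = fitted_eval + 1.96 * se
  )
  structure(
    list(span = span, degree = degree, x = x, y = y, fitted = fitted_data,
         residuals = resid, sigma = sigma, enp = nu1,
         df_residual = df_resid, grid = grid),
    class = "loess_band"
  )
}

#' @export
print.loess_band <- function(x, ...) {
  cat(sprintf(
    "Local regression: %d points, span %.2f, degree %d\n", length(x$x),
    x$span, x$degree))
  cat(sprintf("  equivalent parameters %.2f, residual sd %.4g\n",
              x$enp, x$sigma))
  invisible(x)
}
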