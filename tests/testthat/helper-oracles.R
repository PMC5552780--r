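# Independent brute-force oracles kept deliberately separate from the
# package's implementation paths.

# local regression oracle: explicit weighted normal equations at one point
oracle_local_fit <- function(x, y, x0, span, degree) {
  n <- length(x)
  q <- floor(span * n)
  d <- abs(x - x0)
  d_q <- sort(d)[q]
  w <- pmax(0, 1 - (d / d_q)^3)^3
  X <- outer(x - x0, 0:degree, `^`)
  A <- t(X) %*% diag(w) %*% X
  beta <- solve(A, t(X) %*% diag(w) %*% y)
  beta[1]
}

# two-stage decadal mean oracle: explicit loops
oracle_two_stage_mean <- function(series_id, mid_year, value) {
  decades <- sort(unique(10 * floor(mid_year / 10)))
  sapply(decades, function(d) {
    in_d <- 10 * floor(mid_year / 10) == d
    per_series <- sapply(unique(series_id[in_d]), function(s) {
      mean(value[in_d & series_id == s])
    })
    mean(per_series)
  })
}

# OLS slope oracle via stats::lm
oracle_lm_slope <- function(x, y) unname(stats::coef(stats::lm(y ~ x))[2])

# per-cell declining-forest-area oracle: explicit loop over cells
oracle_area_summary <- function(slope, grid) {
  declining_area <- 0
  total_area <- 0
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      a <- grid$forest_fraction[i, j] * grid$cell_area_ha
      total_area <- total_area + a
      if (!is.na(slope[i, j]) && slope[i, j] < 0) {
        declining_area <- declining_area + a
      }
    }
  }
  list(pct = 100 * declining_area / total_area, mha = declining_area / 1e6)
}
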