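# Post-1970 trend estimation and attribution: per-core slopes, site
# aggregation, the climate-covariate multiple regression with Bonferroni
# outlier screening, growth-residual regressions, the tree-level mixed
# model, and model-based decline predictions.

#' Fit per-core d15N slopes since a start year
#'
#' Simple linear regression of d15N (or anomaly; the slope is identical
#' because centering only shifts the intercept) on sample span midpoint,
#' per core, over `[from_year, end of record]`. Records of unequal length
#' are accepted; no truncation to a common final year.
#'
#' @param samples Sample tibble (needs `core_id`, `mid_year`, and `d15n` or
#'   `anomaly`).
#' @param from_year Window start, default 1970.
#' @param min_points Minimum samples in the window (default 3); cores below
#'   it are skipped with a message and listed in the `skipped` attribute.
#' @return A tibble of trend estimates: `core_id`, metadata columns carried
#'   from the input (`site_id`, `tree_id`, `taxon_group` when present),
#'   `slope` (permil y-1), `intercept` (permil at `from_year`), `n_points`.
#' @export
fit_core_slopes <- function(samples, from_year = 1970, min_points = 3) {
  value_col <- if ("d15n" %in% names(samples)) "d15n" else "anomaly"
  meta_cols <- intersect(c("site_id", "tree_id", "taxon_group"),
                         names(samples))
  win <- samples[samples$mid_year >= from_year, ]
  est <- win |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("core_id", meta_cols)))) |>
    dplyr::summarise(
      slope = if (dplyr::n() >= 3)
        ols_slope(.data$mid_year, .data[[value_col]]) else NA_real_,
      intercept = if (dplyr::n() >= 3)
        mean(.data[[value_col]]) - slope *
          (mean(.data$mid_year) - from_year) else NA_real_,
      n_points = dplyr::n(), .groups = "drop"
    )
  skipped <- est$core_id[est$n_points < min_points]
  if (length(skipped) > 0) {
    message(length(skipped), " core(s) with < ", min_points,
            " samples since ", from_year, " skipped: ",
            paste(skipped, collapse = ", "))
  }
  out <- est[est$n_points >= min_points, ]
  attr(out, "skipped") <- skipped
  attr(out, "from_year") <- from_year
  out
}

#' Aggregate core slopes to site means
#'
#' @param core_slopes Output of [fit_core_slopes()] (needs `site_id`).
#' @return A tibble `site_id`, `mean_slope`, `n_cores`; the observed
#'   cross-site slope range is stored in the `slope_range` attribute.
#' @export
aggregate_site_slopes <- function(core_slopes) {
  out <- core_slopes |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(mean_slope = mean(.data$slope),
                     n_cores = dplyr::n(), .groups = "drop")
  attr(out, "slope_range") <- range(out$mean_slope)
  out
}

term_names <- function(log_base) {
  c("intercept",
    if (log_base == 10) "log10_map" else sprintf("log%g_map", log_base),
    "mat", "ndep")
}

#' Regress site mean slopes on climate and N-deposition covariates
#'
#' Ordinary least squares of site mean d15N slope on log-transformed MAP
#' (base 10 by default), MAT and total N deposition, with intercept.
#' Two-sided p-values use the t distribution on `n - 4` degrees of freedom.
#'
#' @param site_slopes Output of [aggregate_site_slopes()].
#' @param sites Site covariate tibble.
#' @param log_base Base of the MAP log transform (default 10).
#' @return A `site_trend_fit`: list with `terms` (tibble of term, estimate,
#'   se, p_value), `residuals` (named by site), `n_sites`, `log_base`,
#'   the merged `data`, and the underlying `lm` object.
#' @export
fit_site_regression <- function(site_slopes, sites, log_base = 10) {
  df <- dplyr::inner_join(site_slopes, sites, by = "site_id")
  if (nrow(df) < 5) {
    stop("need at least 5 sites with slopes and complete covariates",
         call. = FALSE)
  }
  df$log_map <- log(df$map_mm, base = log_base)
  constant <- c("log_map", "mat_c", "ndep")[
    vapply(df[c("log_map", "mat_c", "ndep")],
           function(v) diff(range(v)) == 0, logical(1))]
  if (length(constant) > 0) {
    labels <- sub("log_map", term_names(log_base)[2],
                  sub("mat_c", "mat", constant))
    stop("covariate(s) constant across sites (non-identifiable): ",
         paste(labels, collapse = ", "), call. = FALSE)
  }
  model <- stats::lm(mean_slope ~ log_map + mat_c + ndep, data = df)
  if (model$rank < 4) {
    stop("rank-deficient design: collinear covariates", call. = FALSE)
  }
  coefs <- summary(model)$coefficients
  terms <- tibble::tibble(
    term = term_names(log_base),
    estimate = unname(coefs[, 1]), se = unname(coefs[, 2]),
    p_value = unname(coefs[, 4])
  )
  res <- stats::residuals(model)
  names(res) <- df$site_id
  structure(
    list(terms = terms, residuals = res, n_sites = nrow(df),
         log_base = log_base, data = df, model = model),
    class = "site_trend_fit"
  )
}

#' @export
print.site_trend_fit <- function(x, ...) {
  cat(sprintf("Site trend regression (%d sites, log base %g for MAP)\n",
              x$n_sites, x$log_base))
  print(as.data.frame(x$terms), digits = 4)
  invisible(x)
}

#' Bonferroni outlier test on the site regression
#'
#' Externally studentized residual for each site, two-sided t tail on
#' `n - p - 1` degrees of freedom, multiplied by the number of sites
#' (Bonferroni) and capped at 1; sites with adjusted p < `alpha` are
#' flagged.
#'
#' @param fit A `site_trend_fit`.
#' @param alpha Flagging threshold on the adjusted p (default 0.05).
#' @return A tibble `site_id`, `studentized`, `p_adj`, `flagged`, sorted by
#'   `p_adj`.
#' @export
bonferroni_outlier_test <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "site_trend_fit"))
  n <- fit$n_sites
  if (n < 6) stop("need at least 6 sites for the outlier test",
                  call. = FALSE)
  t_i <- stats::rstudent(fit$model)
  df <- n - 4 - 1
  p_adj <- pmin(1, 2 * stats::pt(-abs(t_i), df) * n)
  out <- tibble::tibble(site_id = fit$data$site_id,
                        studentized = unname(t_i),
                        p_adj = unname(p_adj),
                        flagged = unname(p_adj < alpha))
  dplyr::arrange(out, .data$p_adj)
}

#' Regress site-trend residuals on growth metrics
#'
#' Two simple regressions of the climate-model residuals against mean BAI
#' since 1970 and against the BAI slope since 1970, used to check whether
#' wood production explains trend variation the climate model does not.
#'
#' @param fit A `site_trend_fit`.
#' @param bai_site Output of [bai_site_stats()].
#' @return A tibble with one row per predictor (`mean_bai`, `bai_slope`):
#'   estimate, se, p_value, n.
#' @export
residual_bai_regression <- function(fit, bai_site) {
  stopifnot(inherits(fit, "site_trend_fit"))
  res <- tibble::tibble(site_id = names(fit$residuals),
                        residual = as.numeric(fit$residuals))
  shared <- dplyr::inner_join(res, bai_site, by = "site_id")
  if (nrow(shared) < nrow(res)) {
    warning("site sets differ; using the ", nrow(shared), " shared sites")
  }
  if (nrow(shared) < 5) {
    stop("need at least 5 shared sites (have ", nrow(shared), ")",
         call. = FALSE)
  }
  one <- function(predictor) {
    m <- stats::lm(shared$residual ~ shared[[predictor]])
    s <- summary(m)$coefficients
    tibble::tibble(predictor = predictor, estimate = s[2, 1], se = s[2, 2],
                   p_value = s[2, 4], n = nrow(shared))
  }
  dplyr::bind_rows(one("mean_bai"), one("bai_slope"))
}

#' Tree-level mixed model for d15N slopes
#'
#' Restricted-maximum-likelihood fit of tree slope on log-MAP, MAT, N
#' deposition and taxonomic group (gymnosperm vs angiosperm) with a site
#' random intercept. Fixed-effect p-values are Wald normal approximations.
#' A boundary fit (site variance 0) is a valid result and is flagged.
#'
#' @param tree_slopes Output of [fit_core_slopes()] with `site_id` and
#'   `taxon_group` columns (one core per tree).
#' @param sites Site covariate tibble.
#' @param log_base Base of the MAP log transform (default 10).
#' @return A `tree_mixed_fit`: list with `fixed` (tibble of term, estimate,
#'   se, p_value), `site_variance`, `residual_variance`, `n_trees`,
#'   `n_sites`, `boundary`, and the `lmerMod` object.
#' @export
fit_tree_mixed_model <- function(tree_slopes, sites, log_base = 10) {
  df <- dplyr::inner_join(tree_slopes, sites, by = "site_id")
  df$log_map <- log(df$map_mm, base = log_base)
  has_taxon <- "taxon_group" %in% names(df) &&
    dplyr::n_distinct(df$taxon_group) >= 2
  if (!has_taxon) {
    warning("fewer than two taxonomic groups present; taxon term dropped")
    form <- slope ~ log_map + mat_c + ndep + (1 | site_id)
  } else {
    df$taxon_group <- factor(df$taxon_group,
                             levels = c("angiosperm", "gymnosperm"))
    form <- slope ~ log_map + mat_c + ndep + taxon_group + (1 | site_id)
  }
  model <- lme4::lmer(form, data = df, REML = TRUE)
  s <- summary(model)$coefficients
  fixed_names <- c(term_names(log_base),
                   if (has_taxon) "taxon_gymnosperm")
  fixed <- tibble::tibble(
    term = fixed_names, estimate = unname(s[, 1]), se = unname(s[, 2]),
    p_value = unname(2 * stats::pnorm(-abs(s[, 1] / s[, 2])))
  )
  vc <- as.data.frame(lme4::VarCorr(model))
  site_var <- vc$vcov[vc$grp == "site_id"]
  resid_var <- vc$vcov[vc$grp == "Residual"]
  structure(
    list(fixed = fixed, site_variance = site_var,
         residual_variance = resid_var, n_trees = nrow(df),
         n_sites = dplyr::n_distinct(df$site_id),
         boundary = lme4::isSingular(model), model = model),
    class = "tree_mixed_fit"
  )
}

#' @export
print.tree_mixed_fit <- function(x, ...) {
  cat(sprintf("Tree-level mixed model (%d trees, %d sites)\n",
              x$n_trees, x$n_sites))
  print(as.data.frame(x$fixed), digits = 4)
  cat(sprintf("  site variance %.3g, residual variance %.3g%s\n",
              x$site_variance, x$residual_variance,
              if (x$boundary) " [boundary fit]" else ""))
  invisible(x)
}

fit_coefficients <- function(object, log_base = 10) {
  if (inherits(object, "site_trend_fit")) {
    stats::setNames(object$terms$estimate,
                    c("intercept", "log_map", "mat", "ndep"))
  } else if (is.numeric(object) && !is.null(names(object))) {
    known <- c("intercept", "log_map", "log10_map", "mat", "ndep")
    if (!all(names(object) %in% known)) {
      stop("unknown coefficient name(s): ",
           paste(setdiff(names(object), known), collapse = ", "),
           call. = FALSE)
    }
    get0 <- function(nm) if (nm %in% names(object)) object[[nm]] else 0
    c(intercept = get0("intercept"),
      log_map = get0("log_map") + get0("log10_map"),
      mat = get0("mat"), ndep = get0("ndep"))
  } else {
    stop("object must be a site_trend_fit or a named coefficient vector",
         call. = FALSE)
  }
}

#' Predict cumulative d15N change from the fitted trend model
#'
#' The model's predicted slope at the given covariates multiplied by the
#' horizon; negative values are declines. Covariates outside the fitted
#' range trigger an extrapolation warning.
#'
#' @param object A `site_trend_fit`, or a named numeric vector of
#'   coefficients (`intercept`, `log10_map`/`log_map`, `mat`, `ndep`;
#'   missing names are treated as 0).
#' @param map_mm,mat_c,ndep Covariate values.
#' @param horizon_y Horizon in years.
#' @param log_base Base of the MAP log transform when `object` is a plain
#'   coefficient vector (taken from the fit otherwise).
#' @return Predicted change in permil over the horizon.
#' @export
predict_decline <- function(object, map_mm, mat_c = 0, ndep = 0,
                            horizon_y = 40, log_base = 10) {
  if (inherits(object, "site_trend_fit")) {
    log_base <- object$log_base
    rng <- list(map = range(object$data$map_mm),
                mat = range(object$data$mat_c),
                ndep = range(object$data$ndep))
    if (any(map_mm < rng$map[1] | map_mm > rng$map[2]) ||
        any(mat_c < rng$mat[1] | mat_c > rng$mat[2]) ||
        any(ndep < rng$ndep[1] | ndep > rng$ndep[2])) {
      warning("covariates outside the fitted range; prediction is an ",
              "extrapolation")
    }
  }
  b <- fit_coefficients(object, log_base)
  slope <- b[["intercept"]] + b[["log_map"]] * log(map_mm, base = log_base) +
    b[["mat"]] * mat_c + b[["ndep"]] * ndep
  slope * horizon_y
}
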