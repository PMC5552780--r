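test_that("core slopes match simple linear regression", {
  s <- tibble::tibble(site_id = "S1", core_id = "A",
                      mid_year = c(1970, 1990, 2010),
                      d15n = c(0.0, -0.2, -0.4))
  est <- fit_core_slopes(s)
  expect_equal(est$slope, -0.010, tolerance = 1e-12)

  # centering invariance: anomalies give the same slope as raw values
  anom <- s
  anom$anomaly <- s$d15n - mean(s$d15n)
  anom$d15n <- NULL
  expect_equal(fit_core_slopes(anom)$slope, est$slope, tolerance = 1e-12)

  # agreement with the lm oracle on noisy data
  set.seed(61)
  noisy <- tibble::tibble(site_id = "S1", core_id = "B",
                          mid_year = seq(1970.5, 2009.5, 1.6),
                          d15n = rnorm(25))
  expect_equal(fit_core_slopes(noisy)$slope,
               oracle_lm_slope(noisy$mid_year, noisy$d15n),
               tolerance = 1e-10)

  # short cores are skipped with a message and recorded
  short <- tibble::tibble(site_id = "S1", core_id = "C",
                          mid_year = c(1980, 1990), d15n = c(1, 2))
  expect_message(out <- fit_core_slopes(dplyr::bind_rows(s, short)),
                 "skipped")
  expect_equal(attr(out, "skipped"), "C")
  expect_equal(nrow(out), 1)
})

test_that("slope estimation is unbiased under the generator", {
  cfg <- generator_config(n_sites = 40, trees_per_site = 5, seed = 62,
                          coeff_log10map = 0, coeff_mat = 0, coeff_ndep = 0,
                          intercept = -0.01, site_slope_noise_sd = 0)
  ds <- generate_dataset(cfg)
  est <- fit_core_slopes(ds$samples)
  mc_se <- sd(est$slope) / sqrt(nrow(est))
  expect_lt(abs(mean(est$slope) - (-0.01)), 2 * mc_se + 1e-6)
})

test_that("site aggregation is an unweighted mean of core slopes", {
  est <- tibble::tibble(site_id = c("s1", "s1", "s2"),
                        core_id = c("a", "b", "c"),
                        slope = c(0.01, -0.03, 0.005),
                        intercept = 0, n_points = 10)
  agg <- aggregate_site_slopes(est)
  expect_equal(agg$mean_slope[agg$site_id == "s1"], -0.01)
  expect_equal(agg$mean_slope[agg$site_id == "s2"], 0.005)
  expect_equal(attr(agg, "slope_range"), c(-0.01, 0.005))
})

test_that("noise-free data identify the regression coefficients exactly", {
  cfg <- small_config(seed = 63, within_core_noise_sd = 0,
                      site_slope_noise_sd = 0)
  ds <- generate_dataset(cfg)
  fit <- suppressWarnings(fit_site_regression(
    aggregate_site_slopes(fit_core_slopes(ds$samples)), ds$sites))
  expect_equal(fit$terms$estimate,
               unname(ds$truth$coefficients), tolerance = 1e-7)
  expect_lt(max(fit$terms$se), 1e-7)
  # residuals sum to zero (intercept included)
  expect_lt(abs(sum(fit$residuals)), 1e-10)
})

test_that("regression inference is invariant to site order and level", {
  ds <- generate_dataset(small_config(seed = 64))
  ss <- aggregate_site_slopes(fit_core_slopes(ds$samples))
  f1 <- fit_site_regression(ss, ds$sites)
  perm <- ss[sample(nrow(ss)), ]
  f2 <- fit_site_regression(perm, ds$sites)
  expect_equal(f1$terms$estimate, f2$terms$estimate, tolerance = 1e-12)

  shifted <- ss
  shifted$mean_slope <- ss$mean_slope + 0.5
  f3 <- fit_site_regression(shifted, ds$sites)
  expect_equal(f3$terms$estimate[-1], f1$terms$estimate[-1],
               tolerance = 1e-10)
  expect_equal(f3$terms$estimate[1], f1$terms$estimate[1] + 0.5,
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected naming the culprit", {
  ds <- generate_dataset(small_config(seed = 65))
  ss <- aggregate_site_slopes(fit_core_slopes(ds$samples))
  flat <- ds$sites
  flat$ndep <- 7
  expect_error(fit_site_regression(ss, flat), "ndep")
  expect_error(fit_site_regression(ss[1:3, ], ds$sites), "5 sites")
})

test_that("the Bonferroni outlier test flags planted outliers only", {
  ds <- generate_dataset(generator_config(seed = 66))
  ss <- aggregate_site_slopes(fit_core_slopes(ds$samples))
  fit <- fit_site_regression(ss, ds$sites)
  out <- bonferroni_outlier_test(fit)
  expect_true(all(out$p_adj >= 0 & out$p_adj <= 1))

  # cross-check the adjusted p-values against an established implementation
  ref <- car::outlierTest(fit$model, cutoff = Inf, n.max = 3)
  sid <- fit$data$site_id[as.integer(names(ref$rstudent))]
  top <- out[match(sid, out$site_id), ]
  expect_equal(top$studentized, unname(ref$rstudent), tolerance = 1e-10)
  expect_equal(pmin(top$p_adj, 1), pmin(unname(ref$bonf.p), 1),
               tolerance = 1e-10)

  # displace one site by ten residual sds: it must be flagged
  sigma <- stats::sigma(fit$model)
  planted <- ss
  planted$mean_slope[5] <- planted$mean_slope[5] + 10 * sigma
  fit2 <- fit_site_regression(planted, ds$sites)
  out2 <- bonferroni_outlier_test(fit2)
  expect_true(out2$flagged[out2$site_id == planted$site_id[5]])

  expect_error(bonferroni_outlier_test(
    fit_site_regression(ss[1:5, ], ds$sites)), "6 sites")
})

test_that("residual-growth regressions detect planted coupling", {
  ds <- generate_dataset(generator_config(seed = 67))
  fit <- fit_site_regression(
    aggregate_site_slopes(fit_core_slopes(ds$samples)), ds$sites)
  # residuals exactly proportional to mean BAI: p ~ 0, sign preserved
  fake_bai <- tibble::tibble(
    site_id = names(fit$residuals),
    mean_bai = 1000 + as.numeric(fit$residuals) * 5e4,
    bai_slope = rnorm(length(fit$residuals)))
  res <- suppressWarnings(residual_bai_regression(fit, fake_bai))
  row <- res[res$predictor == "mean_bai", ]
  expect_lt(row$p_value, 1e-6)
  expect_gt(row$estimate, 0)

  # a single shared site is insufficient
  expect_error(suppressWarnings(residual_bai_regression(fit, fake_bai[1, ])),
               "at least 5")
})

test_that("the mixed model degenerates to OLS when site variance is zero", {
  # Tree slopes exactly linear in the site covariates plus within-site
  # deviations that sum to zero per site and are balanced across taxa:
  # the between-site residual is exactly zero, so REML must land on the
  # boundary (site variance 0) and the fixed effects equal OLS -- which
  # here recovers the generating coefficients exactly.
  cfg <- generator_config(n_sites = 12, seed = 68)
  sites <- generate_sites(cfg)
  b <- c(0.19, -0.069, 0.0028, -0.0014)
  dev <- c(-0.003, 0.003, -0.003, 0.003)
  taxa <- c("gymnosperm", "gymnosperm", "angiosperm", "angiosperm")
  slopes <- dplyr::bind_rows(lapply(seq_len(12), function(s) {
    base <- b[1] + b[2] * log10(sites$map_mm[s]) + b[3] * sites$mat_c[s] +
      b[4] * sites$ndep[s]
    tibble::tibble(site_id = sites$site_id[s],
                   core_id = sprintf("%s_t%d", sites$site_id[s], 1:4),
                   tree_id = core_id, taxon_group = taxa,
                   slope = base + dev, intercept = 0, n_points = 10)
  }))
  mm <- suppressWarnings(suppressMessages(
    fit_tree_mixed_model(slopes, sites)))
  expect_true(mm$boundary)
  expect_lt(mm$site_variance, 1e-12)
  expect_lt(max(abs(mm$fixed$estimate[1:4] - b)), 1e-8)
  expect_lt(abs(mm$fixed$estimate[5]), 1e-8)  # no taxon contrast planted
})

test_that("a planted taxon contrast is recovered within its uncertainty", {
  cfg <- generator_config(n_sites = 30, trees_per_site = 5, seed = 69,
                          taxon_effect = 0.02, within_core_noise_sd = 0.2,
                          site_slope_noise_sd = 0.005)
  ds <- generate_dataset(cfg)
  mm <- suppressWarnings(suppressMessages(
    fit_tree_mixed_model(fit_core_slopes(ds$samples), ds$sites)))
  row <- mm$fixed[mm$fixed$term == "taxon_gymnosperm", ]
  expect_lt(abs(row$estimate - 0.02), 2 * row$se)
  expect_lt(row$p_value, 0.05)
})

test_that("a single taxonomic group drops the taxon term with a warning", {
  ds <- generate_dataset(small_config(seed = 70))
  slopes <- fit_core_slopes(ds$samples)
  slopes$taxon_group <- "gymnosperm"
  expect_warning(mm <- fit_tree_mixed_model(slopes, ds$sites), "taxon")
  expect_false("taxon_gymnosperm" %in% mm$fixed$term)
})

test_that("model-based decline predictions follow the linear form", {
  b <- c(intercept = 0, log10_map = -0.069, mat = 0, ndep = 0)
  d_1000 <- predict_decline(b, map_mm = 1000, horizon_y = 40)
  d_1500 <- predict_decline(b, map_mm = 1500, horizon_y = 40)
  expect_equal(d_1500 - d_1000, -0.069 * log10(1.5) * 40, tolerance = 1e-12)
  expect_equal(predict_decline(b, map_mm = 1234, horizon_y = 0), 0)

  # the MAT gradient over 19 degrees C at the reported coefficient
  bm <- c(mat = 0.0028)
  contrast <- predict_decline(bm, map_mm = 1, mat_c = 19, horizon_y = 40) -
    predict_decline(bm, map_mm = 1, mat_c = 0, horizon_y = 40)
  expect_equal(contrast, 2.128, tolerance = 1e-12)

  # base-10 log is what reproduces the observed wet-dry contrast;
  # natural log overshoots by a factor ln(10)
  printed_contrast <- 0.95 - 0.48
  expect_lt(abs(abs(d_1500 - d_1000) - printed_contrast), 0.05)
  nat <- abs(-0.069 * log(1.5) * 40)
  expect_gt(abs(nat - printed_contrast), 0.5)

  # extrapolation outside the fitted covariate range warns
  ds <- generate_dataset(small_config(seed = 71))
  fit <- fit_site_regression(
    aggregate_site_slopes(fit_core_slopes(ds$samples)), ds$sites)
  expect_warning(predict_decline(fit, map_mm = 10000, mat_c = 10, ndep = 5),
                 "extrapolation")
})
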