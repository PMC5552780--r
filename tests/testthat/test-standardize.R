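test_that("standardization mean-centers over the reference window", {
  s <- tibble::tibble(core_id = "A", mid_year = c(1975, 1985),
                      d15n = c(3.1, 2.9))
  out <- standardize_cores(s, c(1970, 2015))
  expect_equal(out$anomaly, c(0.1, -0.1))

  # constant series map to all-zero anomalies
  s2 <- tibble::tibble(core_id = "B", mid_year = seq(1900, 2000, 10),
                       d15n = rep(4.2, 11))
  expect_equal(standardize_cores(s2)$anomaly, rep(0, 11))
})

test_that("window means vanish and offsets cancel over random series", {
  set.seed(71)
  n_series <- 1000
  n_each <- 12
  s <- tibble::tibble(
    core_id = rep(sprintf("c%04d", 1:n_series), each = n_each),
    mid_year = rep(seq(1905, 2015, 10), n_series),
    d15n = rnorm(n_series * n_each, mean = rep(runif(n_series, -5, 5),
                                               each = n_each))
  )
  out <- standardize_cores(s, c(1970, 2015))
  window_means <- tapply(
    out$anomaly[out$mid_year >= 1970], out$core_id[out$mid_year >= 1970],
    mean)
  expect_lt(max(abs(window_means)), 1e-10)

  # invariance: adding any constant per core leaves anomalies unchanged
  shifted <- s
  shifted$d15n <- s$d15n + rep(runif(n_series, -100, 100), each = n_each)
  expect_equal(standardize_cores(shifted, c(1970, 2015))$anomaly,
               out$anomaly, tolerance = 1e-9)

  # pairwise differences are preserved exactly
  a <- out[out$core_id == "c0001", ]
  raw <- s[s$core_id == "c0001", ]
  expect_equal(diff(a$anomaly), diff(raw$d15n), tolerance = 1e-12)
})

test_that("cores without reference-window samples are a named error", {
  s <- tibble::tibble(core_id = c("ok", "ok", "dead", "dead"),
                      mid_year = c(1980, 1990, 1900, 1910),
                      d15n = c(1, 2, 3, 4))
  expect_error(standardize_cores(s, c(1970, 2015)), "dead")
})

test_that("decadal averaging is a two-stage, equally weighted mean", {
  # single series: plain mean and mean sample year
  one <- tibble::tibble(core_id = "A", mid_year = c(1852, 1857),
                        anomaly = c(0.2, 0.4))
  cp <- decadal_average(one)
  expect_equal(cp$decade_start, 1850)
  expect_equal(cp$mean_anomaly, 0.3)
  expect_equal(cp$mean_sample_year, 1854.5)
  expect_equal(cp$n_series, 1)

  # two balanced series cancel
  two <- tibble::tibble(core_id = c("A", "B"), mid_year = c(1903, 1907),
                        anomaly = c(0.1, -0.1))
  expect_equal(decadal_average(two)$mean_anomaly, 0)

  # unbalanced series: series-first averaging, not sample-weighted
  set.seed(5)
  a_vals <- rnorm(5)
  b_val <- rnorm(1)
  unb <- tibble::tibble(core_id = c(rep("A", 5), "B"),
                        mid_year = c(1901:1905, 1906),
                        anomaly = c(a_vals, b_val))
  got <- decadal_average(unb)
  expect_equal(got$mean_anomaly, (mean(a_vals) + b_val) / 2)
  expect_equal(got$mean_anomaly,
               oracle_two_stage_mean(unb$core_id, unb$mid_year,
                                     unb$anomaly))
  # invariants on the composite points
  expect_true(all(got$decade_start <= got$mean_sample_year &
                    got$mean_sample_year < got$decade_start + 10))
})

test_that("cross-site compositing is unweighted and permutation-invariant", {
  sc <- tibble::tibble(
    site_id = c("s1", "s2"), decade_start = 1920,
    mean_anomaly = c(0.5, -0.5), mean_sample_year = c(1924, 1926),
    n_series = c(3, 5))
  out <- composite_across_sites(sc)
  expect_equal(out$mean_anomaly, 0)
  expect_equal(out$mean_sample_year, 1925)
  expect_equal(out$n_series, 2)

  # single site passes through
  expect_equal(composite_across_sites(sc[1, ])$mean_anomaly, 0.5)

  # permutation invariance across both levels
  ds <- generate_dataset(small_config(seed = 31))
  anom <- standardize_cores(ds$samples)
  comp1 <- composite_across_sites(site_composites(anom))
  perm <- anom[sample(nrow(anom)), ]
  comp2 <- composite_across_sites(site_composites(perm))
  expect_equal(comp1, comp2, tolerance = 1e-12)
})

test_that("the composite recovers a common linear trend", {
  cfg <- generator_config(n_sites = 30, trees_per_site = 3, seed = 41,
                          coeff_log10map = 0, coeff_mat = 0, coeff_ndep = 0,
                          intercept = -0.012, site_slope_noise_sd = 0,
                          within_core_noise_sd = 0.3)
  ds <- generate_dataset(cfg)
  comp <- composite_across_sites(site_composites(standardize_cores(
    ds$samples)))
  slope <- oracle_lm_slope(comp$mean_sample_year, comp$mean_anomaly)
  expect_lt(abs(slope - (-0.012)), 0.002)
})

test_that("cumulative change reads endpoints off composites and bands", {
  comp <- tibble::tibble(decade_start = seq(1850, 2010, 10),
                         mean_anomaly = seq(1.41, 0, length.out = 17),
                         mean_sample_year = seq(1855, 2015, 10),
                         n_series = 5)
  cc <- cumulative_change(comp, 1850, 2010)
  expect_equal(cc$change, -1.41)
  expect_equal(cc$rate, -1.41 / 160)

  flat <- comp
  flat$mean_anomaly <- 0.7
  cc0 <- cumulative_change(flat, 1850, 2010)
  expect_equal(cc0$change, 0)
  expect_equal(cc0$rate, 0)

  # nearest decade with warning; too far is an error
  expect_warning(cumulative_change(comp, 1845, 2010), "nearest")
  expect_error(cumulative_change(comp, 1820, 2010), "more than")

  # loess band endpoints by interpolation
  band <- fit_loess(comp$mean_sample_year, comp$mean_anomaly, span = 1,
                    degree = 1)
  ccl <- cumulative_change(band, 1855, 2015)
  expect_equal(ccl$source, "loess")
  expect_equal(ccl$change, -1.41, tolerance = 1e-6)
})
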