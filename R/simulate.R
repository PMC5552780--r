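# Synthetic multi-site increment-core generator with known ground truth.
#
# Sites get climate/deposition covariates drawn uniformly over configured
# ranges; each site's true post-1970 d15N slope is a linear function of
# log10(MAP), MAT and Ndep plus site-level noise; each tree's latent d15N is
# linear in time around that slope with a tree-specific baseline and
# within-core measurement noise. Ring widths are generated independently of
# d15N by default so growth covariates are null with respect to isotope
# trends.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate a 49-site continental increment-core collection:
#' record lengths ~ Normal(123, 60) years truncated to \[40, 300\], final
#' years between 2005 and 2015, contiguous wood segments averaging 1.6 years
#' each (which guarantees at least two d15N values per complete decade), and
#' site covariates spanning >2400 mm MAP, 19 degrees C MAT and
#' 14.5 kg ha-1 y-1 N deposition. True site slopes follow
#' `intercept + coeff_log10map*log10(MAP) + coeff_mat*MAT + coeff_ndep*Ndep`
#' plus Normal site noise; the default intercept (0.191) makes the
#' ensemble-mean slope -0.0088 permil y-1, i.e. a 1.41 permil decline over
#' the 160 years from 1850 to 2010.
#'
#' @param n_sites Number of sites (>= 2).
#' @param trees_per_site Trees (one core each) per site (>= 3).
#' @param seed Integer RNG seed; identical config + seed gives identical
#'   output.
#' @param record_length_mean_y,record_length_sd_y Target mean and parent-normal
#'   sd of core record length in years; lengths are drawn from a normal
#'   truncated to \[40, 300\] by resampling, with the parent location offset
#'   so the realized ensemble mean equals `record_length_mean_y`.
#' @param sample_span_mean_y Mean wood-segment span in years (in \[1, 5\]);
#'   spans are a mixture of the two nearest integers.
#' @param min_samples_per_decade Required d15N samples per complete decade.
#' @param coeff_log10map,coeff_mat,coeff_ndep,intercept Coefficients of the
#'   true site-slope model (permil y-1 per unit covariate).
#' @param site_slope_noise_sd SD of site-level slope noise (permil y-1).
#' @param within_core_noise_sd SD of per-sample d15N noise (permil).
#' @param tree_baseline_sd SD of tree-level d15N baselines (permil); the
#'   baseline is removed by anomaly standardization.
#' @param map_range,mat_range,ndep_range Uniform covariate ranges
#'   (mm; degrees C; kg ha-1 y-1).
#' @param last_year_range Range of core final years.
#' @param trend_onset_year Optional change-point: before this calendar year
#'   the latent series is flat; `NULL` (default) means the linear trend runs
#'   over the whole record.
#' @param taxon_effect Additive true slope offset (permil y-1) for
#'   gymnosperms; default 0 (no taxonomic difference).
#' @param bai_coupling Coupling of site-level growth to site slope noise;
#'   default 0 (ring widths independent of d15N trends).
#' @param ring_width_mean_mm Median annual ring width (mm).
#' @param grid_cell_area_ha Cell area used by [generate_climate_grid()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_sites = 49,
                             trees_per_site = 5,
                             seed = 1L,
                             record_length_mean_y = 123,
                             record_length_sd_y = 60,
                             sample_span_mean_y = 1.6,
                             min_samples_per_decade = 2,
                             coeff_log10map = -0.069,
                             coeff_mat = 0.0028,
                             coeff_ndep = -0.0014,
                             intercept = 0.191,
                             site_slope_noise_sd = 0.02,
                             within_core_noise_sd = 0.5,
                             tree_baseline_sd = 1.0,
                             map_range = c(400, 2800),
                             mat_range = c(1, 20),
                             ndep_range = c(1, 15.5),
                             last_year_range = c(2005, 2015),
                             trend_onset_year = NULL,
                             taxon_effect = 0,
                             bai_coupling = 0,
                             ring_width_mean_mm = 1.2,
                             grid_cell_area_ha = 100) {
  config <- list(
    n_sites = n_sites, trees_per_site = trees_per_site, seed = as.integer(seed),
    record_length_mean_y = record_length_mean_y,
    record_length_sd_y = record_length_sd_y,
    sample_span_mean_y = sample_span_mean_y,
    min_samples_per_decade = min_samples_per_decade,
    coeff_log10map = coeff_log10map, coeff_mat = coeff_mat,
    coeff_ndep = coeff_ndep, intercept = intercept,
    site_slope_noise_sd = site_slope_noise_sd,
    within_core_noise_sd = within_core_noise_sd,
    tree_baseline_sd = tree_baseline_sd,
    map_range = map_range, mat_range = mat_range, ndep_range = ndep_range,
    last_year_range = last_year_range,
    trend_onset_year = trend_onset_year,
    taxon_effect = taxon_effect, bai_coupling = bai_coupling,
    ring_width_mean_mm = ring_width_mean_mm,
    grid_cell_area_ha = grid_cell_area_ha
  )
  validate_generator_config(config)
  structure(config, class = "generator_config")
}

validate_generator_config <- function(config) {
  stopifnot(config$n_sites >= 2, config$trees_per_site >= 3)
  for (nm in c("record_length_sd_y", "site_slope_noise_sd",
               "within_core_noise_sd", "tree_baseline_sd")) {
    if (config[[nm]] < 0) stop(nm, " must be >= 0", call. = FALSE)
  }
  for (nm in c("map_range", "mat_range", "ndep_range")) {
    r <- config[[nm]]
    if (length(r) != 2 || r[1] > r[2]) {
      stop(nm, " must be an increasing (or degenerate) range", call. = FALSE)
    }
  }
  if (config$map_range[1] <= 0) {
    stop("map_range lower bound must be > 0 (MAP is log-transformed)",
         call. = FALSE)
  }
  if (config$sample_span_mean_y < 1 || config$sample_span_mean_y > 5) {
    stop("sample_span_mean_y must be in [1, 5]", call. = FALSE)
  }
  max_span <- ceiling(config$sample_span_mean_y)
  if (config$min_samples_per_decade > floor(10 / max_span)) {
    stop("min_samples_per_decade unattainable with sample spans this long",
         call. = FALSE)
  }
  invisible(config)
}

# Each generator stage uses its own offset from the config seed so the
# stages are reproducible both standalone and when composed by
# generate_dataset(); the caller's RNG state is untouched.
with_stage_seed <- function(config, offset, code) {
  withr::with_seed(config$seed + offset, code)
}

#' Generate site covariate records
#'
#' @param config A [generator_config()].
#' @return A tibble of site records with uniformly drawn covariates.
#' @export
generate_sites <- function(config) {
  validate_generator_config(config)
  with_stage_seed(config, 1L, {
    n <- config$n_sites
    tibble::tibble(
      site_id = sprintf("S%03d", seq_len(n)),
      latitude = stats::runif(n, 26, 49),
      longitude = stats::runif(n, -124, -68),
      map_mm = stats::runif(n, config$map_range[1], config$map_range[2]),
      mat_c = stats::runif(n, config$mat_range[1], config$mat_range[2]),
      ndep = stats::runif(n, config$ndep_range[1], config$ndep_range[2])
    )
  })
}

#' Generate true site-level d15N slopes
#'
#' @param sites Site tibble from [generate_sites()].
#' @param config A [generator_config()].
#' @param site_growth_factor Optional numeric vector (one per site) of
#'   standardized site growth levels; with `bai_coupling != 0` it leaks into
#'   the slope noise so residual-vs-growth regressions have signal.
#' @return A tibble with `site_id`, `true_slope` (permil y-1) and the linear
#'   predictor `mean_structure`.
#' @export
generate_true_slopes <- function(sites, config, site_growth_factor = NULL) {
  validate_generator_config(config)
  if (is.null(site_growth_factor)) site_growth_factor <- rep(0, nrow(sites))
  stopifnot(length(site_growth_factor) == nrow(sites))
  with_stage_seed(config, 2L, {
    mu <- config$intercept +
      config$coeff_log10map * log10(sites$map_mm) +
      config$coeff_mat * sites$mat_c +
      config$coeff_ndep * sites$ndep
    eps <- stats::rnorm(nrow(sites), 0, config$site_slope_noise_sd) +
      config$bai_coupling * site_growth_factor
    tibble::tibble(site_id = sites$site_id, true_slope = mu + eps,
                   mean_structure = mu)
  })
}

# Parent-normal location whose [lo, hi]-truncated mean equals `target`.
# Closed-form truncated-normal mean, inverted with uniroot.
truncated_normal_location <- function(target, sd, lo, hi) {
  if (sd == 0) return(target)
  truncated_mean <- function(mu) {
    a <- (lo - mu) / sd
    b <- (hi - mu) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  stats::uniroot(function(mu) truncated_mean(mu) - target,
                 lower = target - 3 * sd, upper = target + sd,
                 tol = 1e-8)$root
}

# span sizes: mixture of the two integers bracketing the target mean
draw_spans <- function(total_years, mean_span) {
  lo <- floor(mean_span)
  hi <- lo + 1
  p_hi <- mean_span - lo
  n_max <- ceiling(total_years / lo)
  spans <- sample(c(lo, hi), n_max, replace = TRUE, prob = c(1 - p_hi, p_hi))
  cs <- cumsum(spans)
  k <- which(cs >= total_years)[1]
  spans <- spans[seq_len(k)]
  spans[k] <- spans[k] - (cs[k] - total_years)
  spans[spans > 0]
}

#' Generate per-core d15N sample and ring-width series
#'
#' One core per tree. Latent d15N at a segment's span midpoint `t` is
#' `baseline_tree + slope * (g(t) - 1970)` where `g` is the identity, or
#' clamps at the configured trend onset year for change-point experiments,
#' plus Normal within-core noise. Ring widths are lognormal around a
#' tree-level mean width.
#'
#' @param sites Site tibble.
#' @param true_slopes Tibble from [generate_true_slopes()].
#' @param config A [generator_config()].
#' @param site_growth_factor Optional standardized per-site growth level
#'   (see [generate_true_slopes()]).
#' @return A list with tibbles `samples` (the d15N long table) and
#'   `ring_widths`, plus `trees` (per-tree truth: taxon, true slope).
#' @export
generate_core_series <- function(sites, true_slopes, config,
                                 site_growth_factor = NULL) {
  validate_generator_config(config)
  if (is.null(site_growth_factor)) site_growth_factor <- rep(0, nrow(sites))
  gymno_species <- c("Pinus strobus", "Tsuga canadensis", "Picea rubens",
                     "Pseudotsuga menziesii")
  angio_species <- c("Quercus alba", "Acer saccharum", "Fagus grandifolia",
                     "Liriodendron tulipifera")
  slope_of <- true_slopes$true_slope[match(sites$site_id,
                                           true_slopes$site_id)]
  onset <- if (is.null(config$trend_onset_year)) -Inf else
    config$trend_onset_year

  # Location of the parent normal such that, after truncation to [40, 300],
  # the mean record length equals the configured value (truncation discards
  # mostly short records, so the parent must sit below the target).
  parent_mu <- truncated_normal_location(config$record_length_mean_y,
                                         config$record_length_sd_y, 40, 300)

  with_stage_seed(config, 3L, {
    n_trees <- config$n_sites * config$trees_per_site
    acc_starts <- vector("list", n_trees)
    acc_ends <- vector("list", n_trees)
    acc_d15n <- vector("list", n_trees)
    acc_widths <- vector("list", n_trees)
    acc_years <- vector("list", n_trees)
    tree_site <- tree_core <- tree_taxon <- tree_species <-
      character(n_trees)
    tree_first <- tree_last <- tree_len <- tree_slope_v <- numeric(n_trees)
    idx <- 0L
    for (s in seq_len(config$n_sites)) {
      site_dominant_gymno <- stats::runif(1) < 0.5
      for (k in seq_len(config$trees_per_site)) {
        idx <- idx + 1L
        # record length truncated to [40, 300] by resampling
        repeat {
          len <- round(stats::rnorm(1, parent_mu,
                                    config$record_length_sd_y))
          if (len >= 40 && len <= 300) break
        }
        last_year <- sample(seq(config$last_year_range[1],
                                config$last_year_range[2]), 1)
        first_year <- last_year - len + 1
        gymno <- stats::runif(1) < (if (site_dominant_gymno) 0.85 else 0.15)
        tree_slope <- slope_of[s] + if (gymno) config$taxon_effect else 0

        spans <- draw_spans(len, config$sample_span_mean_y)
        ends <- first_year + cumsum(spans) - 1
        starts <- ends - spans + 1
        mid <- (starts + ends) / 2
        baseline <- stats::rnorm(1, 0, config$tree_baseline_sd)
        t_eff <- pmax(mid, onset)
        acc_starts[[idx]] <- starts
        acc_ends[[idx]] <- ends
        acc_d15n[[idx]] <- baseline + tree_slope * (t_eff - 1970) +
          stats::rnorm(length(mid), 0, config$within_core_noise_sd)
        mean_width <- config$ring_width_mean_mm *
          exp(stats::rnorm(1, 0, 0.35) + 0.3 * site_growth_factor[s])
        acc_widths[[idx]] <- mean_width * stats::rlnorm(len, -0.3^2 / 2, 0.3)
        acc_years[[idx]] <- first_year:last_year

        tree_site[idx] <- sites$site_id[s]
        tree_core[idx] <- sprintf("S%03d_T%02d", s, k)
        tree_taxon[idx] <- if (gymno) "gymnosperm" else "angiosperm"
        tree_species[idx] <- if (gymno) sample(gymno_species, 1) else
          sample(angio_species, 1)
        tree_first[idx] <- first_year
        tree_last[idx] <- last_year
        tree_len[idx] <- len
        tree_slope_v[idx] <- tree_slope
      }
    }
    n_samp <- lengths(acc_starts)
    starts <- unlist(acc_starts)
    ends <- unlist(acc_ends)
    samples <- tibble::tibble(
      site_id = rep(tree_site, n_samp),
      core_id = rep(tree_core, n_samp),
      tree_id = rep(tree_core, n_samp),
      species = rep(tree_species, n_samp),
      taxon_group = rep(tree_taxon, n_samp),
      year_start = starts, year_end = ends,
      mid_year = (starts + ends) / 2,
      d15n = unlist(acc_d15n)
    )
    ring_widths <- tibble::tibble(
      core_id = rep(tree_core, tree_len),
      year = unlist(acc_years),
      width_mm = unlist(acc_widths)
    )
    trees <- tibble::tibble(
      site_id = tree_site, core_id = tree_core, tree_id = tree_core,
      taxon_group = tree_taxon, first_year = tree_first,
      last_year = tree_last, record_length = tree_len,
      true_slope = tree_slope_v
    )
    list(samples = samples, ring_widths = ring_widths, trees = trees)
  })
}

#' Generate a complete synthetic dataset with ground truth
#'
#' @param config A [generator_config()].
#' @return A list with `sites`, `samples`, `ring_widths`, `trees` and
#'   `truth` (the generating coefficients and true site slopes).
#' @export
generate_dataset <- function(config = generator_config()) {
  validate_generator_config(config)
  sites <- generate_sites(config)
  growth <- with_stage_seed(config, 5L, stats::rnorm(nrow(sites)))
  slopes <- generate_true_slopes(sites, config, site_growth_factor = growth)
  series <- generate_core_series(sites, slopes, config,
                                 site_growth_factor = growth)
  truth <- list(
    coefficients = c(intercept = config$intercept,
                     log10_map = config$coeff_log10map,
                     mat = config$coeff_mat,
                     ndep = config$coeff_ndep),
    site_slopes = slopes,
    site_growth_factor = growth
  )
  list(sites = sites, samples = series$samples,
       ring_widths = series$ring_widths, trees = series$trees, truth = truth)
}

#' Generate a gridded climate surface for trend projection
#'
#' MAP and MAT vary smoothly (opposed diagonal gradients with seeded smooth
#' perturbations) across the configured ranges; forest fraction is a smooth
#' field clipped to \[0, 1\]; cell area is constant.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param config A [generator_config()].
#' @return A `climate_grid`: list of matrices `map_mm`, `mat_c`,
#'   `forest_fraction` and scalar `cell_area_ha`.
#' @export
generate_climate_grid <- function(n_rows, n_cols,
                                  config = generator_config()) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  validate_generator_config(config)
  with_stage_seed(config, 4L, {
    r <- matrix(seq(0, 1, length.out = n_rows), n_rows, n_cols)
    c_ <- matrix(seq(0, 1, length.out = n_cols), n_rows, n_cols, byrow = TRUE)
    ripple <- function(amp) {
      ph <- stats::runif(2, 0, 2 * pi)
      amp * (sin(2 * pi * r + ph[1]) + cos(2 * pi * c_ + ph[2])) / 2
    }
    unit <- function(base, amp) {
      u <- base + ripple(amp)
      if (diff(range(u)) == 0) u * 0 else
        (u - min(u)) / (max(u) - min(u))
    }
    u_map <- unit((r + c_) / 2, 0.15)
    u_mat <- unit((1 - r + c_) / 2, 0.15)
    map_mm <- config$map_range[1] + u_map * diff(config$map_range)
    mat_c <- config$mat_range[1] + u_mat * diff(config$mat_range)
    forest <- 0.6 + ripple(0.6)
    forest[forest < 0] <- 0
    forest[forest > 1] <- 1
    structure(
      list(n_rows = n_rows, n_cols = n_cols, map_mm = map_mm, mat_c = mat_c,
           forest_fraction = forest, cell_area_ha = config$grid_cell_area_ha),
      class = "climate_grid"
    )
  })
}
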