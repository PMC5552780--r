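# Anomaly standardization and two-stage decadal compositing.

#' Standardize cores to a common modern baseline
#'
#' For each core, the mean d15N over samples whose span midpoint falls in
#' the reference window is subtracted from every sample, so all cores share
#' a 0 permil mean over the window and values become anomalies from the
#' modern baseline. Pairwise differences within a core are untouched, and
#' the result is invariant to adding any constant to a core's raw values.
#'
#' @param samples Sample tibble (needs `core_id`, `mid_year`, `d15n`).
#' @param reference_window Closed year interval, default `c(1970, 2015)`.
#' @return The input tibble with an `anomaly` column and the window stored
#'   in the `reference_window` attribute.
#' @export
standardize_cores <- function(samples, reference_window = c(1970, 2015)) {
  stopifnot(length(reference_window) == 2,
            reference_window[1] <= reference_window[2])
  work <- samples
  work$.in_window <- samples$mid_year >= reference_window[1] &
    samples$mid_year <= reference_window[2]
  ref_means <- work |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(
      n_ref = sum(.data$.in_window),
      ref_mean = mean(.data$d15n[.data$.in_window]),
      .groups = "drop"
    )
  missing <- ref_means$core_id[ref_means$n_ref == 0]
  if (length(missing) > 0) {
    stop("core(s) with no samples in the reference window [",
         reference_window[1], ", ", reference_window[2], "]: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- samples
  out$anomaly <- samples$d15n -
    ref_means$ref_mean[match(samples$core_id, ref_means$core_id)]
  attr(out, "reference_window") <- reference_window
  out
}

decade_of <- function(mid_year) 10 * floor(mid_year / 10)

#' Average anomaly series at the decadal scale
#'
#' Two-stage mean within each calendar decade `[10k, 10k+9]`: first each
#' series' own decadal mean, then the unweighted mean across series, so a
#' series contributes one value per decade regardless of how many samples
#' it has there. A sample belongs to the decade containing its span
#' midpoint. `mean_sample_year` is the mean midpoint of all contributing
#' samples; decades with no data are omitted.
#'
#' @param anomalies Tibble with `mid_year`, a value column and a series
#'   identifier column.
#' @param series Name of the series identifier column (default `"core_id"`).
#' @param value Name of the value column (default `"anomaly"`).
#' @return A tibble of composite points: `decade_start`, `mean_anomaly`,
#'   `mean_sample_year`, `n_series`.
#' @export
decadal_average <- function(anomalies, series = "core_id",
                            value = "anomaly") {
  stopifnot(nrow(anomalies) > 0)
  df <- tibble::tibble(
    series = anomalies[[series]],
    decade_start = decade_of(anomalies$mid_year),
    mid_year = anomalies$mid_year,
    value = anomalies[[value]]
  )
  per_series <- df |>
    dplyr::group_by(.data$series, .data$decade_start) |>
    dplyr::summarise(series_mean = mean(.data$value),
                     sum_mid = sum(.data$mid_year),
                     n_samples = dplyr::n(), .groups = "drop")
  per_series |>
    dplyr::group_by(.data$decade_start) |>
    dplyr::summarise(
      mean_anomaly = mean(.data$series_mean),
      mean_sample_year = sum(.data$sum_mid) / sum(.data$n_samples),
      n_series = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$decade_start)
}

#' Per-site decadal composites
#'
#' Applies [decadal_average()] within each site (cores as series).
#'
#' @param anomalies Output of [standardize_cores()] (needs `site_id`).
#' @return A tibble of composite points with a leading `site_id` column.
#' @export
site_composites <- function(anomalies) {
  # same two-stage mean as decadal_average(), grouped by site in one pass
  per_core <- anomalies |>
    dplyr::mutate(decade_start = decade_of(.data$mid_year)) |>
    dplyr::group_by(.data$site_id, .data$core_id, .data$decade_start) |>
    dplyr::summarise(core_mean = mean(.data$anomaly),
                     sum_mid = sum(.data$mid_year),
                     n_samples = dplyr::n(), .groups = "drop")
  per_core |>
    dplyr::group_by(.data$site_id, .data$decade_start) |>
    dplyr::summarise(
      mean_anomaly = mean(.data$core_mean),
      mean_sample_year = sum(.data$sum_mid) / sum(.data$n_samples),
      n_series = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$site_id, .data$decade_start)
}

#' Composite site decadal means across all sites
#'
#' Unweighted mean of the sites' decadal values per decade;
#' `mean_sample_year` is the mean of the sites' mean sample years and
#' `n_series` counts contributing sites.
#'
#' @param site_comp Output of [site_composites()].
#' @return A tibble of cross-site composite points.
#' @export
composite_across_sites <- function(site_comp) {
  stopifnot(nrow(site_comp) > 0)
  site_comp |>
    dplyr::group_by(.data$decade_start) |>
    dplyr::summarise(
      mean_anomaly = mean(.data$mean_anomaly),
      mean_sample_year = mean(.data$mean_sample_year),
      n_series = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$decade_start)
}

#' Cumulative change and annual rate between two years
#'
#' Evaluates a composite chronology (at its decadal points) or a fitted
#' loess band (by linear interpolation of the fitted curve) at two years and
#' returns the difference and the per-year rate over the nominal interval.
#' For a composite, a year maps to its calendar decade; if that decade is
#' absent the nearest available decade within 10 years is used with a
#' warning, and anything further away is an error.
#'
#' @param x A composite tibble (from [composite_across_sites()] or
#'   [decadal_average()]) or a `loess_band` from [fit_loess()].
#' @param from_year,to_year Calendar years, `from_year < to_year`.
#' @return A list with `change` (permil), `rate` (permil y-1), the endpoint
#'   values, and `source` ("composite" or "loess").
#' @export
cumulative_change <- function(x, from_year, to_year) {
  stopifnot(from_year < to_year)
  if (inherits(x, "loess_band")) {
    rng <- range(x$grid$x)
    if (from_year < rng[1] - 10 || to_year > rng[2] + 10) {
      stop("endpoint outside the fitted range by more than one decade",
           call. = FALSE)
    }
    clamp <- function(y) min(max(y, rng[1]), rng[2])
    if (from_year < rng[1] || to_year > rng[2]) {
      warning("endpoint outside fitted range; nearest fitted point used")
    }
    v <- stats::approx(x$grid$x, x$grid$fitted,
                       xout = c(clamp(from_year), clamp(to_year)))$y
    src <- "loess"
  } else {
    value_at <- function(year) {
      d <- decade_of(year)
      if (!d %in% x$decade_start) {
        nearest <- x$decade_start[which.min(abs(x$decade_start - d))]
        if (abs(nearest - d) > 10) {
          stop("year ", year, " outside the composite range by more than ",
               "one decade", call. = FALSE)
        }
        warning("decade ", d, " absent; using nearest decade ", nearest)
        d <- nearest
      }
      x$mean_anomaly[x$decade_start == d]
    }
    v <- c(value_at(from_year), value_at(to_year))
    src <- "composite"
  }
  change <- v[2] - v[1]
  list(change = change, rate = change / (to_year - from_year),
       from_value = v[1], to_value = v[2], source = src)
}

#' Plot a composite chronology with its loess band
#'
#' @param composite Cross-site composite tibble.
#' @param band Optional `loess_band` from [fit_loess()].
#' @return A ggplot object.
#' @export
plot_composite <- function(composite, band = NULL) {
  p <- ggplot2::ggplot(composite,
                       ggplot2::aes(x = .data$mean_sample_year,
                                    y = .data$mean_anomaly))
  if (!is.null(band)) {
    p <- p +
      ggplot2::geom_ribbon(
        data = band$grid,
        ggplot2::aes(x = .data$x, ymin = .data$ci_lo, ymax = .data$ci_hi),
        inherit.aes = FALSE, fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_line(
        data = band$grid, ggplot2::aes(x = .data$x, y = .data$fitted),
        inherit.aes = FALSE, colour = "steelblue")
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = "Year (mean sample year per decade)",
                  y = "Wood d15N anomaly (permil)")
}
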