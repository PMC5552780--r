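# Basal area increment from cumulative ring widths.

#' Compute basal area increment from ring widths
#'
#' From the pith outwards, the radius after year `t` is the cumulative sum
#' of ring widths and the year's increment of cross-sectional area is
#' `BAI_t = pi * r_t^2 - pi * r_{t-1}^2` with `r_0 = 0`. The sum of BAI
#' over all years telescopes to `pi * r_final^2` exactly.
#'
#' @param ring_widths Tibble with `core_id`, `year`, `width_mm`; years must
#'   be consecutive within each core (locally absent rings entered as 0).
#' @return A tibble `core_id`, `year`, `bai_mm2`.
#' @export
compute_bai <- function(ring_widths) {
  stopifnot(all(c("core_id", "year", "width_mm") %in% names(ring_widths)))
  if (any(ring_widths$width_mm < 0)) {
    bad <- unique(ring_widths$core_id[ring_widths$width_mm < 0])
    stop("negative ring width(s) in core(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rw <- dplyr::arrange(ring_widths, .data$core_id, .data$year)
  gaps <- rw |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(gap = any(diff(.data$year) != 1), .groups = "drop")
  bad <- gaps$core_id[gaps$gap]
  if (length(bad) > 0) {
    stop("non-consecutive years in core(s): ", paste(bad, collapse = ", "),
         "; enter locally absent rings as width 0", call. = FALSE)
  }
  rw |>
    dplyr::group_by(.data$core_id) |>
    dplyr::mutate(
      bai_mm2 = {
        r <- cumsum(.data$width_mm)
        pi * r^2 - pi * c(0, r[-length(r)])^2
      }
    ) |>
    dplyr::ungroup() |>
    dplyr::select("core_id", "year", "bai_mm2")
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * (y - mean(y))) / sum(xc^2)
}

#' Summarize growth since a start year
#'
#' Per core: the arithmetic mean of BAI over `[from_year, last year]` and
#' the OLS slope of BAI against year over the same window.
#'
#' @param bai Output of [compute_bai()].
#' @param from_year Window start, default 1970 (matching the d15N trend
#'   window).
#' @return A tibble `core_id`, `mean_since` (mm2 y-1), `slope_since`
#'   (mm2 y-2), `n_years`. The slope is `NA` for windows of fewer than
#'   3 years.
#' @export
bai_summary <- function(bai, from_year = 1970) {
  win <- bai[bai$year >= from_year, ]
  if (nrow(win) == 0) {
    stop("no BAI values at or after ", from_year, call. = FALSE)
  }
  win |>
    dplyr::group_by(.data$core_id) |>
    dplyr::summarise(
      mean_since = mean(.data$bai_mm2),
      slope_since = if (dplyr::n() >= 3)
        ols_slope(.data$year, .data$bai_mm2) else NA_real_,
      n_years = dplyr::n(), .groups = "drop"
    )
}

#' Aggregate per-core growth summaries to sites
#'
#' @param core_stats Output of [bai_summary()].
#' @param membership Tibble mapping `core_id` to `site_id`.
#' @return A tibble `site_id`, `mean_bai`, `bai_slope`, `n_cores`
#'   (unweighted means of the core statistics).
#' @export
bai_site_stats <- function(core_stats, membership) {
  merged <- dplyr::inner_join(core_stats,
                              dplyr::distinct(membership[c("core_id",
                                                           "site_id")]),
                              by = "core_id")
  merged |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(
      mean_bai = mean(.data$mean_since),
      bai_slope = mean(.data$slope_since, na.rm = TRUE),
      n_cores = dplyr::n(), .groups = "drop"
    )
}
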