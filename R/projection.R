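# Projection of the fitted site-level trend model onto gridded climate
# surfaces and forest-area accounting.

#' Project the fitted trend model onto a climate grid
#'
#' Per-cell predicted d15N slope
#' `b0 + b1 * log(MAP) + b2 * MAT + b3 * ndep_value`, with N deposition
#' held constant across the grid (the cross-site mean from the fit by
#' default). Cells with zero forest fraction are masked to `NA`.
#'
#' @param grid A `climate_grid` from [generate_climate_grid()] (or any list
#'   with matrices `map_mm`, `mat_c`, `forest_fraction` and scalar
#'   `cell_area_ha`).
#' @param fit A `site_trend_fit`, or a named coefficient vector as accepted
#'   by [predict_decline()].
#' @param ndep_value Constant N deposition (kg ha-1 y-1); defaults to the
#'   mean over the sites used in the fit.
#' @return A `trend_field`: list with the `slope` matrix (permil y-1,
#'   `NA` off-forest), the `grid`, and `ndep_used`.
#' @export
project_trend <- function(grid, fit, ndep_value = NULL) {
  if (is.null(ndep_value)) {
    if (!inherits(fit, "site_trend_fit")) {
      stop("ndep_value is required when fit is a plain coefficient vector",
           call. = FALSE)
    }
    ndep_value <- mean(fit$data$ndep)
  }
  log_base <- if (inherits(fit, "site_trend_fit")) fit$log_base else 10
  b <- fit_coefficients(fit, log_base)
  forested <- grid$forest_fraction > 0
  if (any(forested & grid$map_mm <= 0)) {
    bad <- which(forested & grid$map_mm <= 0, arr.ind = TRUE)
    stop("non-positive MAP on forested cell(s), first at row ",
         bad[1, 1], ", col ", bad[1, 2], call. = FALSE)
  }
  slope <- b[["intercept"]] +
    b[["log_map"]] * log(grid$map_mm, base = log_base) +
    b[["mat"]] * grid$mat_c + b[["ndep"]] * ndep_value
  slope[!forested] <- NA_real_
  structure(list(slope = slope, grid = grid, ndep_used = ndep_value),
            class = "trend_field")
}

#' Summarize declining forest area under a projected trend field
#'
#' Forest area per cell is `forest_fraction * cell_area_ha`; a cell is
#' "declining" when its predicted slope is strictly negative (zero-slope
#' cells count as not declining). Areas are reported in Mha (1e6 ha).
#'
#' @param field A `trend_field` from [project_trend()], or a slope matrix
#'   (in which case `grid` must be supplied).
#' @param grid The `climate_grid`, when `field` is a plain matrix.
#' @return A `projection_summary`: list with `pct_declining`,
#'   `area_declining_mha`, `total_forest_mha`, `ndep_used`.
#' @export
summarize_area <- function(field, grid = NULL) {
  if (inherits(field, "trend_field")) {
    grid <- field$grid
    slope <- field$slope
    ndep_used <- field$ndep_used
  } else {
    stopifnot(!is.null(grid))
    slope <- field
    ndep_used <- NA_real_
  }
  area <- grid$forest_fraction * grid$cell_area_ha
  total <- sum(area)
  if (total <= 0) stop("total forest area is zero", call. = FALSE)
  declining <- !is.na(slope) & slope < 0
  area_declining <- sum(area[declining])
  structure(
    list(pct_declining = 100 * area_declining / total,
         area_declining_mha = area_declining / 1e6,
         total_forest_mha = total / 1e6,
         ndep_used = ndep_used),
    class = "projection_summary"
  )
}

#' @export
print.projection_summary <- function(x, ...) {
  cat(sprintf(
    "Forest-area projection: %.1f%% of %.3g Mha forested area declining (%.3g Mha)\n",
    x$pct_declining, x$total_forest_mha, x$area_declining_mha))
  if (!is.na(x$ndep_used)) {
    cat(sprintf("  N deposition held at %.2f kg ha-1 y-1\n", x$ndep_used))
  }
  invisible(x)
}

#' Write and read a climate grid as a headered ASCII raster
#'
#' Plain-text format: a header with `n_rows`, `n_cols`, `cell_area_ha`,
#' then the `map_mm`, `mat_c` and `forest_fraction` fields as
#' whitespace-delimited blocks in row-major order.
#'
#' @param grid A `climate_grid`.
#' @param path Output path.
#' @return `write_climate_grid()`: the path, invisibly;
#'   `read_climate_grid()`: a `climate_grid`.
#' @export
write_climate_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("n_rows %d", grid$n_rows), con)
  writeLines(sprintf("n_cols %d", grid$n_cols), con)
  writeLines(sprintf("cell_area_ha %.17g", grid$cell_area_ha), con)
  for (fieldname in c("map_mm", "mat_c", "forest_fraction")) {
    writeLines(paste("field", fieldname), con)
    utils::write.table(grid[[fieldname]], con, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_climate_grid
#' @export
read_climate_grid <- function(path) {
  lines <- readLines(path)
  get_scalar <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)[1]
    as.numeric(strsplit(ln, " ")[[1]][2])
  }
  n_rows <- as.integer(get_scalar("n_rows"))
  n_cols <- as.integer(get_scalar("n_cols"))
  area <- get_scalar("cell_area_ha")
  fields <- list()
  starts <- grep("^field ", lines)
  for (i in seq_along(starts)) {
    nm <- sub("^field ", "", lines[starts[i]])
    block <- lines[(starts[i] + 1):(starts[i] + n_rows)]
    fields[[nm]] <- matrix(scan(text = block, quiet = TRUE), n_rows, n_cols,
                           byrow = TRUE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, map_mm = fields$map_mm,
         mat_c = fields$mat_c, forest_fraction = fields$forest_fraction,
         cell_area_ha = area),
    class = "climate_grid"
  )
}
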