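# Orchestration: resolved run configuration, simulate-to-disk, and the
# end-to-end analysis that writes every intermediate table.

#' Build a resolved run configuration
#'
#' Every field has a documented default; [run_simulate()] and
#' [run_analyze()] write the resolved configuration verbatim (as YAML) into
#' their output directory together with a manifest of file checksums.
#'
#' @param reference_window Standardization window (default `c(1970, 2015)`).
#' @param trend_start_year Start of the slope window, 1960 or 1970
#'   (default 1970).
#' @param loess_span,loess_degree Smoother settings (default 0.75 / 2).
#' @param log_base Base of the MAP log transform (default 10).
#' @param projection_ndep Constant N deposition for projection; `NULL`
#'   means the cross-site mean.
#' @param project Whether [run_analyze()] also projects onto a synthetic
#'   climate grid (default TRUE).
#' @param grid_dim Grid dimensions for the projection step.
#' @param make_plots Whether [run_analyze()] writes a composite figure.
#' @param seed RNG seed, forwarded to the generator.
#' @param generator A [generator_config()] (its seed is overridden by
#'   `seed`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(reference_window = c(1970, 2015),
                       trend_start_year = 1970,
                       loess_span = 0.75, loess_degree = 2,
                       log_base = 10, projection_ndep = NULL,
                       project = TRUE, grid_dim = c(40, 60),
                       make_plots = FALSE, seed = 1L,
                       generator = generator_config()) {
  stopifnot(trend_start_year %in% c(1960, 1970))
  generator$seed <- as.integer(seed)
  structure(
    list(reference_window = reference_window,
         trend_start_year = trend_start_year,
         loess_span = loess_span, loess_degree = loess_degree,
         log_base = log_base, projection_ndep = projection_ndep,
         project = project, grid_dim = grid_dim, make_plots = make_plots,
         seed = as.integer(seed), generator = generator),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Keys absent from the file keep their [run_config()] defaults; keys under
#' `generator:` override [generator_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen_over <- raw$generator
  raw$generator <- NULL
  gen <- do.call(generator_config,
                 utils::modifyList(list(), gen_over %||% list()))
  cfg <- do.call(run_config, c(raw, list(generator = gen)))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_resolved_config <- function(config, out_dir) {
  plain <- lapply(unclass(config), function(v)
    if (inherits(v, "generator_config")) unclass(v) else v)
  yaml::write_yaml(plain, file.path(out_dir, "config.yaml"))
}

write_manifest <- function(out_dir) {
  files <- setdiff(list.files(out_dir), "manifest.csv")
  sums <- tools::md5sum(file.path(out_dir, files))
  utils::write.csv(data.frame(file = files, md5 = unname(sums)),
                   file.path(out_dir, "manifest.csv"), row.names = FALSE)
}

#' Simulate a dataset to disk
#'
#' Writes `cores.csv`, `ring_widths.csv`, `sites.csv`, a ground-truth file
#' (`truth_coefficients.csv`, `truth_site_slopes.csv`), the resolved
#' configuration and a checksum manifest. Identical config + seed gives
#' byte-identical files.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The generated dataset list, invisibly.
#' @export
run_simulate <- function(config = run_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_dataset(config$generator)
  message("simulate: seed ", config$seed, ", ", nrow(ds$sites), " sites, ",
          nrow(ds$trees), " cores, ", nrow(ds$samples), " d15N samples")
  write_core_table(ds$samples, file.path(out_dir, "cores.csv"))
  write_ring_width_table(ds$ring_widths,
                         file.path(out_dir, "ring_widths.csv"))
  write_site_table(ds$sites, file.path(out_dir, "sites.csv"))
  write_csv_exact(
    tibble::tibble(term = names(ds$truth$coefficients),
                   value = unname(ds$truth$coefficients)),
    file.path(out_dir, "truth_coefficients.csv"))
  write_csv_exact(ds$truth$site_slopes,
                  file.path(out_dir, "truth_site_slopes.csv"))
  write_resolved_config(config, out_dir)
  write_manifest(out_dir)
  invisible(ds)
}

#' Run the full analysis pipeline on a dataset directory
#'
#' Reads the three input tables, applies inclusion criteria, standardizes
#' cores, builds site and cross-site decadal composites, fits the loess
#' band, estimates per-core and site slopes, fits the climate-covariate
#' regression with the Bonferroni outlier screen, computes BAI summaries
#' and the residual-growth regressions, fits the tree-level mixed model,
#' and (optionally) projects the fitted model onto a synthetic climate
#' grid. Every intermediate table is written as CSV.
#'
#' @param config A [run_config()].
#' @param in_dir Directory holding `cores.csv`, `ring_widths.csv`,
#'   `sites.csv` (as written by [run_simulate()]).
#' @param out_dir Output directory (created if needed).
#' @return A list with all intermediate and final results, invisibly.
#' @export
run_analyze <- function(config = run_config(), in_dir, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(in_dir, c("cores.csv", "ring_widths.csv", "sites.csv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  samples <- stage("read", read_core_table(paths[1]))
  ring_widths <- stage("read", read_ring_width_table(paths[2]))
  sites <- stage("read", read_site_table(paths[3]))

  qc <- stage("qc", apply_inclusion_criteria(samples, sites))
  write_qc_report(qc$qc, file.path(out_dir, "qc_report.csv"))

  anom <- stage("standardize",
                standardize_cores(qc$samples, config$reference_window))
  site_comp <- stage("composite", site_composites(anom))
  composite <- stage("composite", composite_across_sites(site_comp))
  utils::write.csv(composite, file.path(out_dir, "composite.csv"),
                   row.names = FALSE)

  band <- stage("loess", fit_loess(composite$mean_sample_year,
                                   composite$mean_anomaly,
                                   span = config$loess_span,
                                   degree = config$loess_degree))
  utils::write.csv(band$grid, file.path(out_dir, "loess_grid.csv"),
                   row.names = FALSE)
  if (isTRUE(config$make_plots)) {
    p <- plot_composite(composite, band)
    ggplot2::ggsave(file.path(out_dir, "composite.pdf"), p,
                    width = 7, height = 5)
  }

  core_slopes <- stage("trends",
                       fit_core_slopes(anom, config$trend_start_year))
  utils::write.csv(core_slopes, file.path(out_dir, "core_slopes.csv"),
                   row.names = FALSE)
  site_slopes <- stage("trends", aggregate_site_slopes(core_slopes))
  utils::write.csv(site_slopes, file.path(out_dir, "site_slopes.csv"),
                   row.names = FALSE)
  regression <- stage("trends",
                      fit_site_regression(site_slopes, qc$sites,
                                          config$log_base))
  utils::write.csv(regression$terms,
                   file.path(out_dir, "site_regression.csv"),
                   row.names = FALSE)
  outliers <- stage("trends", bonferroni_outlier_test(regression))
  utils::write.csv(outliers, file.path(out_dir, "outlier_test.csv"),
                   row.names = FALSE)

  bai <- stage("bai", compute_bai(ring_widths))
  bai_cores <- stage("bai", bai_summary(bai, config$trend_start_year))
  utils::write.csv(bai_cores, file.path(out_dir, "bai_core_summary.csv"),
                   row.names = FALSE)
  bai_sites <- stage("bai", bai_site_stats(bai_cores, qc$samples))
  utils::write.csv(bai_sites, file.path(out_dir, "bai_site_summary.csv"),
                   row.names = FALSE)
  resid_bai <- stage("bai", residual_bai_regression(regression, bai_sites))
  utils::write.csv(resid_bai,
                   file.path(out_dir, "residual_bai_regression.csv"),
                   row.names = FALSE)

  mixed <- stage("mixed", fit_tree_mixed_model(core_slopes, qc$sites,
                                               config$log_base))
  utils::write.csv(mixed$fixed, file.path(out_dir, "mixed_model.csv"),
                   row.names = FALSE)

  projection <- NULL
  if (isTRUE(config$project)) {
    grid <- stage("project",
                  generate_climate_grid(config$grid_dim[1],
                                        config$grid_dim[2],
                                        config$generator))
    field <- stage("project",
                   project_trend(grid, regression, config$projection_ndep))
    projection <- stage("project", summarize_area(field))
    utils::write.csv(
      data.frame(pct_declining = projection$pct_declining,
                 area_declining_mha = projection$area_declining_mha,
                 total_forest_mha = projection$total_forest_mha,
                 ndep_used = projection$ndep_used),
      file.path(out_dir, "projection_summary.csv"), row.names = FALSE)
  }

  write_resolved_config(config, out_dir)
  write_manifest(out_dir)
  invisible(list(qc = qc, anomalies = anom, site_composites = site_comp,
                 composite = composite, loess = band,
                 core_slopes = core_slopes, site_slopes = site_slopes,
                 regression = regression, outliers = outliers,
                 bai_cores = bai_cores, bai_sites = bai_sites,
                 residual_bai = resid_bai, mixed = mixed,
                 projection = projection))
}
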