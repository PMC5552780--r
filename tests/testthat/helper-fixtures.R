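# Small in-code fixtures shared across tests.

small_config <- function(seed = 1, ...) {
  generator_config(n_sites = 8, trees_per_site = 3, seed = seed, ...)
}

# a tiny hand-built sample table: 2 cores, 3 samples each
tiny_samples <- function() {
  tibble::tibble(
    site_id = rep("S1", 6),
    core_id = rep(c("A", "B"), each = 3),
    tree_id = rep(c("A", "B"), each = 3),
    species = "Quercus alba",
    taxon_group = "angiosperm",
    year_start = rep(c(1960, 1980, 2000), 2),
    year_end = rep(c(1961, 1981, 2001), 2),
    mid_year = rep(c(1960.5, 1980.5, 2000.5), 2),
    d15n = c(1.0, 0.5, 0.0, 2.0, 1.5, 1.0)
  )
}

# long-record core covering [first, last] with annual samples and an exact
# linear d15N trend
linear_core <- function(core_id = "C1", site_id = "S1", first = 1900,
                        last = 2010, slope = -0.01, intercept = 3,
                        taxon = "gymnosperm") {
  years <- first:last
  tibble::tibble(
    site_id = site_id, core_id = core_id, tree_id = core_id,
    species = "Tsuga canadensis", taxon_group = taxon,
    year_start = years, year_end = years, mid_year = as.numeric(years),
    d15n = intercept + slope * (years - 1970)
  )
}

write_tiny_csvs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_core_table(tiny_samples(), file.path(dir, "cores.csv"))
  sites <- tibble::tibble(site_id = "S1", latitude = 40, longitude = -90,
                          map_mm = 1000, mat_c = 10, ndep = 5)
  write_site_table(sites, file.path(dir, "sites.csv"))
  invisible(dir)
}
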