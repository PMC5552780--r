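# Tabular I/O for wood d15N samples, ring widths and site covariates.
# All tables are comma-delimited with a header row, UTF-8, "." decimal.

CORE_COLUMNS <- c("site_id", "core_id", "tree_id", "species", "taxon_group",
                  "year_start", "year_end", "d15n")
RING_COLUMNS <- c("core_id", "year", "width_mm")
SITE_COLUMNS <- c("site_id", "latitude", "longitude", "map_mm", "mat_c", "ndep")

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("file '", path, "' is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# data row i sits on file line i + 1 (header)
file_lines <- function(rows) rows + 1L

#' Read a long-format table of wood d15N samples
#'
#' Each row is one wood segment from one increment core: a closed span of
#' calendar years `[year_start, year_end]` and its measured d15N (permil vs
#' AIR). Samples are returned sorted by core and by span midpoint
#' (`mid_year = (year_start + year_end) / 2`), which is the time coordinate
#' used throughout the package.
#'
#' @param path Path to a CSV file with columns `site_id`, `core_id`,
#'   `tree_id`, `species`, `taxon_group`, `year_start`, `year_end`, `d15n`.
#' @return A tibble of samples with an added `mid_year` column.
#' @details Rows with missing or non-numeric year or isotope values are hard
#'   errors reported with their file line numbers, as are spans with
#'   `year_end < year_start` and overlapping spans within a core.
#' @export
read_core_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, CORE_COLUMNS, path)
  for (col in c("year_start", "year_end", "d15n")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  bad <- which(is.na(df$year_start) | is.na(df$year_end) | is.na(df$d15n))
  if (length(bad) > 0) {
    stop("file '", path, "': malformed numeric fields on line(s) ",
         paste(file_lines(bad), collapse = ", "), call. = FALSE)
  }
  rev_span <- which(df$year_end < df$year_start)
  if (length(rev_span) > 0) {
    stop("file '", path, "': year_end < year_start for core(s) ",
         paste(unique(df$core_id[rev_span]), collapse = ", "),
         " on line(s) ", paste(file_lines(rev_span), collapse = ", "),
         call. = FALSE)
  }
  df$mid_year <- (df$year_start + df$year_end) / 2
  samples <- tibble::as_tibble(df[c(CORE_COLUMNS[1:7], "mid_year",
                                    CORE_COLUMNS[8])])
  samples <- dplyr::arrange(samples, .data$site_id, .data$core_id,
                            .data$mid_year)
  check_no_overlap(samples)
  samples
}

check_no_overlap <- function(samples) {
  overlap <- samples |>
    dplyr::group_by(.data$core_id) |>
    dplyr::arrange(.data$year_start, .by_group = TRUE) |>
    dplyr::summarise(
      overlap = any(.data$year_start[-1] <= .data$year_end[-dplyr::n()]),
      .groups = "drop"
    )
  bad <- overlap$core_id[which(overlap$overlap)]
  if (length(bad) > 0) {
    stop("overlapping year spans within core(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(samples)
}

#' Read a long-format ring-width table
#'
#' @param path Path to a CSV file with columns `core_id`, `year`, `width_mm`.
#'   Years within a core must be consecutive; locally absent rings are
#'   entered as width 0, not omitted.
#' @return A tibble sorted by core and year.
#' @export
read_ring_width_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, RING_COLUMNS, path)
  df$year <- suppressWarnings(as.numeric(df$year))
  df$width_mm <- suppressWarnings(as.numeric(df$width_mm))
  bad <- which(is.na(df$year) | is.na(df$width_mm))
  if (length(bad) > 0) {
    stop("file '", path, "': malformed numeric fields on line(s) ",
         paste(file_lines(bad), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df[RING_COLUMNS]) |>
    dplyr::arrange(.data$core_id, .data$year)
}

#' Read the site covariate table
#'
#' @param path Path to a CSV file with columns `site_id`, `latitude`,
#'   `longitude`, `map_mm` (mean total annual precipitation, mm),
#'   `mat_c` (mean annual temperature, degrees C) and `ndep`
#'   (total N deposition, kg ha-1 y-1).
#' @return A tibble of site records.
#' @export
read_site_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  check_columns(df, SITE_COLUMNS, path)
  for (col in SITE_COLUMNS[-1]) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  if (any(is.na(df$map_mm)) || any(df$map_mm <= 0)) {
    stop("file '", path, "': map_mm must be present and > 0 for every site ",
         "(required for the log transform)", call. = FALSE)
  }
  tibble::as_tibble(df[SITE_COLUMNS])
}

fmt_full <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else x
}

write_csv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_full), stringsAsFactors = FALSE,
                       check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write sample, ring-width and site tables
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/read round trip reproduces every value exactly.
#'
#' @param samples,ring_widths,sites Tibbles as returned by the corresponding
#'   readers (or the synthetic generator).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_core_table <- function(samples, path) {
  write_csv_exact(samples[intersect(c(CORE_COLUMNS[1:7], CORE_COLUMNS[8]),
                                    names(samples))], path)
}

#' @rdname write_core_table
#' @export
write_ring_width_table <- function(ring_widths, path) {
  write_csv_exact(ring_widths[RING_COLUMNS], path)
}

#' @rdname write_core_table
#' @export
write_site_table <- function(sites, path) {
  write_csv_exact(sites[SITE_COLUMNS], path)
}

#' Apply series-length and replication inclusion criteria
#'
#' Cores whose sampled span covers fewer than `min_span_years` consecutive
#' calendar years are excluded, then sites left with fewer than `min_trees`
#' distinct trees carrying d15N data are excluded together with their cores.
#' Matches the common requirement for published wood-isotope chronologies of
#' at least three trees per site and records of at least 40 years.
#'
#' @param samples Sample tibble from [read_core_table()].
#' @param sites Site tibble from [read_site_table()].
#' @param min_span_years Minimum core span in years (default 40).
#' @param min_trees Minimum distinct trees per site (default 3).
#' @return A list with elements `samples`, `sites` (the filtered tables) and
#'   `qc`, a `qc_report` holding counts and one row per exclusion with the
#'   rule that removed it. Filtering is idempotent.
#' @export
apply_inclusion_criteria <- function(samples, sites,
                                     min_span_years = 40, min_trees = 3) {
  core_info <- samples |>
    dplyr::group_by(.data$site_id, .data$core_id, .data$tree_id) |>
    dplyr::summarise(span = max(.data$year_end) - min(.data$year_start) + 1,
                     .groups = "drop")
  n_cores_in <- nrow(core_info)
  n_sites_in <- nrow(sites)

  short <- core_info$span < min_span_years
  excl <- tibble::tibble(
    level = rep("core", sum(short)),
    id = core_info$core_id[short],
    rule = sprintf("span %g y < %g y minimum", core_info$span[short],
                   min_span_years)
  )
  surviving <- core_info[!short, ]

  trees_per_site <- surviving |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n_trees = dplyr::n_distinct(.data$tree_id),
                     .groups = "drop")
  # sites absent from the sample table count as zero trees
  site_counts <- dplyr::left_join(sites["site_id"], trees_per_site,
                                  by = "site_id")
  site_counts$n_trees[is.na(site_counts$n_trees)] <- 0L
  bad_sites <- site_counts$site_id[site_counts$n_trees < min_trees]

  if (length(bad_sites) > 0) {
    n_bad <- site_counts$n_trees[match(bad_sites, site_counts$site_id)]
    excl <- dplyr::bind_rows(
      excl,
      tibble::tibble(level = "site", id = bad_sites,
                     rule = sprintf("%d trees < %d minimum", n_bad, min_trees))
    )
    cascade <- surviving$core_id[surviving$site_id %in% bad_sites]
    if (length(cascade) > 0) {
      excl <- dplyr::bind_rows(
        excl,
        tibble::tibble(level = "core", id = cascade,
                       rule = "site excluded (below minimum tree count)")
      )
    }
    surviving <- surviving[!surviving$site_id %in% bad_sites, ]
  }

  kept_sites <- sites[!sites$site_id %in% bad_sites, ]
  kept_samples <- samples[samples$core_id %in% surviving$core_id, ]
  if (nrow(kept_samples) == 0 || nrow(kept_sites) == 0) {
    stop("no cores or sites survive the inclusion criteria", call. = FALSE)
  }

  qc <- structure(
    list(n_sites_in = n_sites_in, n_sites_kept = nrow(kept_sites),
         n_cores_in = n_cores_in, n_cores_kept = nrow(surviving),
         exclusions = excl),
    class = "qc_report"
  )
  list(samples = kept_samples, sites = kept_sites, qc = qc)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  sites: %d in, %d kept\n", x$n_sites_in, x$n_sites_kept))
  cat(sprintf("  cores: %d in, %d kept\n", x$n_cores_in, x$n_cores_kept))
  if (nrow(x$exclusions) == 0) {
    cat("  no exclusions\n")
  } else {
    cat(sprintf("  %d exclusion(s):\n", nrow(x$exclusions)))
    for (i in seq_len(nrow(x$exclusions))) {
      cat(sprintf("    [%s] %s: %s\n", x$exclusions$level[i],
                  x$exclusions$id[i], x$exclusions$rule[i]))
    }
  }
  invisible(x)
}

#' Write a QC report to CSV
#'
#' @param qc A `qc_report` from [apply_inclusion_criteria()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  header <- tibble::tibble(
    level = "summary",
    id = sprintf("sites %d/%d, cores %d/%d", qc$n_sites_kept, qc$n_sites_in,
                 qc$n_cores_kept, qc$n_cores_in),
    rule = "kept/in"
  )
  utils::write.csv(rbind(as.data.frame(header), as.data.frame(qc$exclusions)),
                   path, row.names = FALSE)
  invisible(path)
}
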