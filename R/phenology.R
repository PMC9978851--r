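#' Read daily larval-stage proportion tables
#'
#' Ingests the daily phenology export dialect: comma-delimited UTF-8 text with
#' header `plot_id,year,doy,<stage>...`, one row per plot, year and day-of-year
#' (DOY), stage columns holding the percent of the population in each life
#' stage (0-100). This is the format produced by weather-driven insect
#' phenology simulators (one combined column per instar label); the package
#' consumes the format only and does not model development rates itself.
#'
#' Non-feeding stages (egg, L1, pupa, adult, ...) may be present as extra
#' columns; they are validated for range but ignored by all downstream
#' computations.
#'
#' @param path Path to a delimited phenology file.
#' @param config A [species_config()]; all of its feeding instars must be
#'   present as columns.
#' @param sum_tolerance Allowed excess over 100 for a row's total across all
#'   stage columns (default 0.5, accommodating rounded percentages).
#' @return A `phenology_tbl`: a tibble with columns `plot_id`, `year`, `doy`
#'   and one numeric column per stage, validated and ordered by plot, year,
#'   doy. One plot-year forms one table in the sense of [feeding_window()].
#' @export
read_phenology <- function(path, config, sum_tolerance = 0.5) {
  if (!file.exists(path)) abort_format(paste0("Phenology file not found: ", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0) {
    warn("Phenology file has a header but no rows; returning an empty table.")
  }
  as_phenology(tbl, config, sum_tolerance = sum_tolerance)
}

#' Validate a data frame as a phenology table
#'
#' @param tbl A data frame with `plot_id`, `year`, `doy` and stage columns.
#' @inheritParams read_phenology
#' @return The validated tibble (class `phenology_tbl`).
#' @export
as_phenology <- function(tbl, config, sum_tolerance = 0.5) {
  required <- c("plot_id", "year", "doy", config$feeding_instars)
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0)
    abort_format(paste0("Phenology table is missing required column(s): ",
                        paste(missing, collapse = ", ")))
  stage_cols <- setdiff(names(tbl), c("plot_id", "year", "doy"))
  tbl <- as_tibble(tbl)
  tbl$plot_id <- as.character(tbl$plot_id)
  tbl$year <- as.integer(tbl$year)
  tbl$doy <- as.integer(tbl$doy)

  if (nrow(tbl) > 0) {
    for (col in stage_cols) {
      v <- tbl[[col]]
      bad <- which(!is.finite(v) | v < 0 | v > 100)
      if (length(bad) > 0)
        abort_validation(sprintf(
          "Stage column '%s' has percent outside [0, 100] at row %d (value %s).",
          col, bad[1], format(v[bad[1]])))
    }
    dup <- tbl |>
      dplyr::count(.data$plot_id, .data$year, .data$doy) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0)
      abort_validation(sprintf(
        "Duplicated doy %d within plot '%s' year %d.",
        dup$doy[1], dup$plot_id[1], dup$year[1]))
    totals <- rowSums(tbl[stage_cols])
    over <- which(totals > 100 + sum_tolerance)
    if (length(over) > 0)
      abort_validation(sprintf(
        "Row %d: life-stage percents sum to %.4f, exceeding 100 + tolerance.",
        over[1], totals[over[1]]))
    tbl <- dplyr::arrange(tbl, .data$plot_id, .data$year, .data$doy)
  }
  class(tbl) <- c("phenology_tbl", class(tbl))
  attr(tbl, "feeding_instars") <- config$feeding_instars
  tbl
}

#' Write a phenology table in the package's file dialect
#'
#' @param tbl A phenology tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phenology <- function(tbl, path) {
  readr::write_csv(as_tibble(tbl), path, progress = FALSE)
  invisible(path)
}

#' Feeding phenological window
#'
#' The span of days-of-year over which feeding instars are present above a
#' threshold: the smallest and largest doy at which the summed feeding-instar
#' percent is at least `threshold`. The default 0.1 percent excludes numerical
#' dust while retaining essentially all the seasonal signal.
#'
#' @param tbl A phenology tibble (may hold several plot-years).
#' @param config A [species_config()].
#' @param threshold Minimum summed feeding percent (default 0.1).
#' @return A tibble with one row per plot-year: `plot_id`, `year`,
#'   `start_doy`, `end_doy`.
#' @export
feeding_window <- function(tbl, config, threshold = 0.1) {
  if (threshold < 0) abort_parameter("`threshold` must be non-negative.")
  instars <- config$feeding_instars
  missing <- setdiff(instars, names(tbl))
  if (length(missing) > 0)
    abort_format(paste0("Missing feeding instar column(s): ",
                        paste(missing, collapse = ", ")))
  flat <- as_tibble(tbl)
  flat$.feed <- rowSums(flat[instars])
  hit <- dplyr::filter(flat, .data$.feed >= threshold)
  all_groups <- dplyr::distinct(flat, .data$plot_id, .data$year)
  if (nrow(hit) == 0)
    abort_validation(sprintf(
      "No doy reaches the feeding threshold %g for plot '%s' year %d: no feeding season.",
      threshold, all_groups$plot_id[1], all_groups$year[1]))
  out <- hit |>
    dplyr::group_by(.data$plot_id, .data$year) |>
    dplyr::summarise(start_doy = min(.data$doy), end_doy = max(.data$doy),
                     .groups = "drop")
  if (nrow(out) < nrow(all_groups)) {
    miss <- dplyr::anti_join(all_groups, out, by = c("plot_id", "year"))
    abort_validation(sprintf(
      "No doy reaches the feeding threshold %g for plot '%s' year %d: no feeding season.",
      threshold, miss$plot_id[1], miss$year[1]))
  }
  out
}

# Internal: split a multi-plot phenology tibble into per-plot-year pieces.
split_plot_years <- function(tbl) {
  split(as_tibble(tbl), interaction(tbl$plot_id, tbl$year, drop = TRUE))
}
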