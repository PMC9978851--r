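#' Read frass-trap field records
#'
#' Trap-record dialect: comma-delimited text with header
#' `plot_id,trap_id,area_cm2,set_time,collect_time,frass_g,greenfall_g`,
#' ISO-8601 timestamps at minute resolution. Timestamps given as bare dates
#' (no time of day) default to 12:00, an unbiased midpoint under the
#' nearest-minute rule.
#'
#' @param path Path to a delimited trap-record file.
#' @return A validated tibble of trap records with POSIXct times.
#' @export
read_trap_records <- function(path) {
  if (!file.exists(path)) abort_format(paste0("Trap-record file not found: ", path))
  tbl <- readr::read_csv(
    path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      plot_id = readr::col_character(),
      trap_id = readr::col_character(),
      set_time = readr::col_character(),
      collect_time = readr::col_character()
    )
  )
  as_trap_records(tbl)
}

#' Validate a data frame of trap records
#'
#' @param tbl A data frame with columns `plot_id`, `trap_id`, `area_cm2`,
#'   `set_time`, `collect_time`, `frass_g`, `greenfall_g`.
#' @return The validated tibble.
#' @export
as_trap_records <- function(tbl) {
  required <- c("plot_id", "trap_id", "area_cm2", "set_time", "collect_time",
                "frass_g", "greenfall_g")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0)
    abort_format(paste0("Trap records missing required column(s): ",
                        paste(missing, collapse = ", ")))
  tbl <- as_tibble(tbl)
  tbl$set_time <- parse_trap_time(tbl$set_time)
  tbl$collect_time <- parse_trap_time(tbl$collect_time)
  if (any(!is.finite(tbl$area_cm2) | tbl$area_cm2 <= 0))
    abort_validation("Trap surface area (`area_cm2`) must be positive.")
  if (any(tbl$frass_g < 0, na.rm = TRUE) || any(tbl$greenfall_g < 0, na.rm = TRUE))
    abort_validation("Trap masses must be non-negative.")
  if (any(is.na(tbl$frass_g)) || any(is.na(tbl$greenfall_g)))
    abort_validation("Trap masses must not be missing.")
  if (any(tbl$collect_time <= tbl$set_time))
    abort_validation("Each `collect_time` must be strictly after its `set_time`.")
  tbl
}

parse_trap_time <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  date_only <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  x[date_only] <- paste0(x[date_only], "T12:00:00")
  out <- as.POSIXct(x, tz = "UTC", tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                                  "%Y-%m-%dT%H:%M",
                                                  "%Y-%m-%d %H:%M:%OS",
                                                  "%Y-%m-%d %H:%M"))
  if (any(is.na(out) & !is.na(x)))
    abort_format("Unparseable timestamp(s) in trap records; expected ISO-8601.")
  out
}

#' Area- and time-normalized deposition rates per trap
#'
#' Scales oven-dry trap masses to deposition rates in kg/ha/day:
#' `rate = (mass_g / 1000) * (1e8 cm2/ha / area_cm2) / duration_days`, the
#' deployment duration computed to the nearest minute and the rate assumed
#' uniform over the deployment interval.
#'
#' @param records A trap-record tibble (see [read_trap_records()]).
#' @return The input with added columns `duration_days`, `frass_rate` and
#'   `greenfall_rate` (kg/ha/day).
#' @examples
#' recs <- tibble::tibble(
#'   plot_id = "P1", trap_id = "T1", area_cm2 = 2000,
#'   set_time = "2006-06-01T08:00:00", collect_time = "2006-06-02T08:00:00",
#'   frass_g = 1, greenfall_g = 0
#' )
#' trap_rates(as_trap_records(recs))$frass_rate # 50 kg/ha/day
#' @export
trap_rates <- function(records) {
  records <- as_trap_records(records)
  mins <- round(as.numeric(difftime(records$collect_time, records$set_time,
                                    units = "mins")))
  if (any(mins <= 0))
    abort_validation("Trap deployment duration must be positive (nearest minute).")
  duration_days <- mins / 1440
  records |>
    dplyr::mutate(
      duration_days = duration_days,
      frass_rate = (.data$frass_g / 1000) * (1e8 / .data$area_cm2) / duration_days,
      greenfall_rate = (.data$greenfall_g / 1000) * (1e8 / .data$area_cm2) / duration_days
    )
}

#' Plot-level deposition rates per collection interval
#'
#' Averages per-trap deposition rates (unweighted arithmetic mean) across the
#' traps of a plot that were deployed over a common collection interval,
#' yielding one plot-level frass and greenfall rate per interval. Traps are
#' grouped into intervals either by an explicit `interval_id` column or, by
#' default, by chaining records whose deployment spans overlap in time. The
#' plot interval is `[earliest set, latest collect)` of the group, expressed
#' as fractional day-of-year.
#'
#' @param records A trap-record tibble; an optional `interval_id` column fixes
#'   the grouping.
#' @return A tibble with one row per plot interval: `plot_id`, `year`,
#'   `start_doy`, `end_doy` (fractional), `frass_rate`, `greenfall_rate`
#'   (kg/ha/day) and `n_traps`.
#' @export
plot_interval_rates <- function(records) {
  rates <- trap_rates(records)
  rates$.start <- doy_fraction(rates$set_time)
  rates$.end <- doy_fraction(rates$collect_time)
  rates$.year <- timestamp_year(rates$set_time)

  grouped <- rates |>
    dplyr::group_by(.data$plot_id, .data$.year) |>
    dplyr::group_split() |>
    purrr::map(assign_intervals) |>
    purrr::list_rbind()

  grouped |>
    dplyr::group_by(.data$plot_id, .data$.year, .data$.interval) |>
    dplyr::summarise(
      start_doy = min(.data$.start),
      end_doy = max(.data$.end),
      frass_rate = mean(.data$frass_rate),
      greenfall_rate = mean(.data$greenfall_rate),
      n_traps = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::rename(year = ".year") |>
    dplyr::select(!".interval") |>
    dplyr::arrange(.data$plot_id, .data$year, .data$start_doy)
}

# Chain-overlap clustering of trap deployments into collection intervals; an
# explicit interval_id is honoured but its spans must still be connected.
assign_intervals <- function(df) {
  df <- dplyr::arrange(df, .data$.start, .data$.end)
  if ("interval_id" %in% names(df)) {
    df$.interval <- as.character(df$interval_id)
    for (id in unique(df$.interval)) {
      sub <- df[df$.interval == id, ]
      sub <- dplyr::arrange(sub, .data$.start)
      run_end <- cummax_num(sub$.end)
      if (nrow(sub) > 1 && any(sub$.start[-1] >= head(run_end, -1) - 1e-9))
        abort_validation(sprintf(
          "Traps in collection interval '%s' of plot '%s' have non-overlapping deployment spans.",
          id, sub$plot_id[1]))
    }
    return(df)
  }
  idx <- integer(nrow(df))
  current <- 1L
  run_end <- df$.end[1]
  idx[1] <- current
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      if (df$.start[i] >= run_end - 1e-9) {
        current <- current + 1L
        run_end <- df$.end[i]
      } else {
        run_end <- max(run_end, df$.end[i])
      }
      idx[i] <- current
    }
  }
  df$.interval <- idx
  df
}

cummax_num <- function(x) Reduce(max, x, accumulate = TRUE)

#' Ingested biomass from frass
#'
#' Larvae excrete only the indigestible share of what they eat, so observed
#' frass underestimates consumption. Ingested biomass is
#' `IB = frass / (1 - AD)` where AD is the approximate digestibility, the
#' proportion of ingested host biomass retained for growth. Works on totals
#' (kg/ha) or rates (kg/ha/day) alike.
#'
#' @param frass Frass mass or rate (non-negative).
#' @param ad Approximate digestibility, in `[0, 1)`; a [species_config()] may
#'   be given instead.
#' @return Ingested biomass in the same units as `frass`.
#' @examples
#' ingested_biomass(70, 0.30) # 100
#' @export
ingested_biomass <- function(frass, ad) {
  if (inherits(ad, "species_config")) ad <- ad$approximate_digestibility
  if (!is.numeric(ad) || length(ad) != 1 || is.na(ad) || ad < 0 || ad >= 1)
    abort_parameter("`ad` must be a single approximate digestibility in [0, 1).")
  if (any(frass < 0, na.rm = TRUE))
    abort_validation("`frass` must be non-negative.")
  frass / (1 - ad)
}

#' Total foliage biomass loss
#'
#' Consumed foliage (ingested biomass) plus greenfall: foliage severed but not
#' eaten during feeding, caught in the same traps.
#'
#' @inheritParams ingested_biomass
#' @param greenfall Greenfall mass or rate, same units as `frass`.
#' @return Foliage biomass loss in the same units.
#' @examples
#' foliage_loss(70, 10, 0.30) # 110
#' @export
foliage_loss <- function(frass, greenfall, ad) {
  if (any(greenfall < 0, na.rm = TRUE))
    abort_validation("`greenfall` must be non-negative.")
  ingested_biomass(frass, ad) + greenfall
}

# Per-interval response for the selected analysis channel.
channel_rates <- function(rates, channel = c("frass", "foliage_loss"), config = NULL) {
  channel <- match.arg(channel)
  if (channel == "frass") return(rates$frass_rate)
  if (is.null(config))
    abort_parameter("The foliage-loss channel needs a `config` for the AD value.")
  foliage_loss(rates$frass_rate, rates$greenfall_rate,
               config$approximate_digestibility)
}
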