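#' Simulate a daily larval-stage proportion table
#'
#' Generates unimodal, time-ordered stage-proportion curves that telescope to
#' 100 percent on every day, emulating the daily output of weather-driven
#' phenology simulators. Each stage's entry into the population follows a
#' smooth non-decreasing bell-integral (Gaussian CDF) curve `G_i` with a mean
#' entry day and spread; the percent in feeding instar `i` on day `d` is
#' `100 * (G_i(d) - G_{i+1}(d))`. A pre-feeding stage (labelled `L1`) absorbs
#' `100 * (1 - G_first)` and a post-feeding stage (`pupa`) drains the final
#' instar via one extra exit curve, so all stages always sum to exactly 100.
#'
#' @param config A [species_config()].
#' @param entry_means Strictly increasing entry-day means, one per feeding
#'   instar plus a final exit mean (length `n_instars + 1`).
#' @param entry_sds Positive entry-day spreads (days), recycled to the length
#'   of `entry_means`.
#' @param doy_range Integer vector of days to tabulate (e.g. `115:205`).
#' @param plot_id,year Identifiers for the generated plot-year.
#' @return A validated phenology tibble including the non-feeding `L1` and
#'   `pupa` columns.
#' @export
simulate_phenology <- function(config, entry_means, entry_sds, doy_range,
                               plot_id = "P1", year = 2006L) {
  k <- length(config$feeding_instars)
  if (length(entry_means) != k + 1)
    abort_parameter("`entry_means` must have one value per feeding instar plus an exit mean.")
  if (any(diff(entry_means) <= 0))
    abort_parameter("`entry_means` must be strictly increasing.")
  entry_sds <- rep_len(entry_sds, k + 1)
  if (any(entry_sds <= 0))
    abort_parameter("`entry_sds` must be positive.")
  doy <- sort(unique(as.integer(doy_range)))

  G <- vapply(seq_len(k + 1),
              function(i) pnorm(doy, entry_means[i], entry_sds[i]),
              numeric(length(doy)))
  tbl <- tibble(plot_id = plot_id, year = as.integer(year), doy = doy)
  # entry curves can cross by ~1e-16 in the tails; clamp at exact zero
  tbl[["L1"]] <- pmax(100 * (1 - G[, 1]), 0)
  for (i in seq_len(k)) {
    tbl[[config$feeding_instars[i]]] <- pmax(100 * (G[, i] - G[, i + 1]), 0)
  }
  tbl[["pupa"]] <- 100 * G[, k + 1]
  as_phenology(tbl, config)
}

#' Simulate interval-censored frass-trap records
#'
#' Generates trap records whose expected deposition follows the model the
#' estimation method assumes: the true daily frass rate of plot `p` is
#' `r_p(d) = s_p * sum_i w_i p_i(d)` (a plot density scale times the
#' weighted-larvae signal). Each trap's expected interval catch integrates
#' the daily rate over its deployment, scaled to the trap area; observed
#' masses are perturbed by multiplicative mean-one log-normal noise with the
#' requested coefficient of variation (deposition is positive and its spread
#' grows with the mean). Greenfall is generated so that it forms a fixed
#' fraction of total foliage loss, consistent with the digestibility
#' arithmetic. All randomness derives from one master seed via per-plot
#' child streams.
#'
#' @param phenology A phenology tibble (one or more plot-years).
#' @param config A [species_config()].
#' @param true_weights Named weight vector on the unit simplex (the
#'   simulation truth).
#' @param plot_scales Positive scale(s) `s_p` in kg/ha/day per weighted-larvae
#'   percent: a single value or a vector named by `plot_id`.
#' @param schedule Data frame of collection intervals with integer
#'   `start_doy`, `end_doy` (day-aligned, non-overlapping, ordered); applied
#'   to every plot.
#' @param noise_cv Coefficient of variation of the multiplicative trap noise
#'   (default 0.1; 0 gives noiseless records).
#' @param greenfall_fraction Fraction of total foliage loss that is severed
#'   unconsumed foliage, in `[0, 1)` (default 0.2).
#' @param n_traps Traps per plot (default 5).
#' @param trap_area_range Range (cm^2) from which trap areas are drawn
#'   (default `c(1231.63, 2370)`).
#' @param seed Master seed.
#' @param threshold Feeding-window threshold used for the truth totals.
#' @return A list with `records` (trap-record tibble), `truth` (per-plot
#'   scales and true annual frass/foliage totals over the feeding window)
#'   and `daily_rates` (true daily frass rates).
#' @export
simulate_frass <- function(phenology, config, true_weights, plot_scales,
                           schedule, noise_cv = 0.1, greenfall_fraction = 0.2,
                           n_traps = 5, trap_area_range = c(1231.63, 2370),
                           seed = 1, threshold = 0.1) {
  if (any(schedule$end_doy <= schedule$start_doy))
    abort_parameter("Schedule intervals must have positive length.")
  if (is.unsorted(schedule$start_doy) ||
      any(utils::head(schedule$end_doy, -1) > utils::tail(schedule$start_doy, -1) + 1e-9))
    abort_parameter("Schedule intervals must be ordered and non-overlapping.")
  if (greenfall_fraction < 0 || greenfall_fraction >= 1)
    abort_parameter("`greenfall_fraction` must be in [0, 1).")
  if (noise_cv < 0) abort_parameter("`noise_cv` must be non-negative.")

  gf_factor <- greenfall_fraction / (1 - greenfall_fraction) /
    (1 - config$approximate_digestibility)
  sdlog <- sqrt(log(1 + noise_cv^2))
  fw <- feeding_window(phenology, config, threshold)

  pieces <- split_plot_years(phenology)
  records <- list()
  truth <- list()
  daily <- list()
  for (idx in seq_along(pieces)) {
    piece <- pieces[[idx]]
    pid <- piece$plot_id[1]
    yr <- piece$year[1]
    if (min(schedule$start_doy) < min(piece$doy) ||
        max(schedule$end_doy) > max(piece$doy) + 1)
      abort_parameter("Schedule lies outside the phenology table's doy range.")
    s_p <- if (length(plot_scales) == 1 && is.null(names(plot_scales)))
      plot_scales else unname(plot_scales[pid])
    if (is.na(s_p) || s_p <= 0)
      abort_parameter(paste0("No positive scale for plot '", pid, "'."))

    wl <- weighted_larvae(piece, true_weights)
    rate <- setNames(s_p * wl$wl, wl$doy)
    win <- fw[fw$plot_id == pid & fw$year == yr, ]
    win_doys <- as.character(win$start_doy:win$end_doy)
    annual_frass <- sum(rate[win_doys])
    annual_foliage <- annual_frass / (1 - config$approximate_digestibility) +
      annual_frass * gf_factor

    recs <- with_seed(child_seed(seed, idx), {
      areas <- runif(n_traps, trap_area_range[1], trap_area_range[2])
      out <- list()
      for (iv in seq_len(nrow(schedule))) {
        s0 <- schedule$start_doy[iv]
        e0 <- schedule$end_doy[iv]
        dd <- doys_in_interval(s0, e0)
        integral <- sum(rate[as.character(dd)] * day_coverage(dd, s0, e0))
        for (tr in seq_len(n_traps)) {
          expected_g <- integral * areas[tr] / 1e5
          noise_f <- if (noise_cv > 0) rlnorm(1, -sdlog^2 / 2, sdlog) else 1
          noise_g <- if (noise_cv > 0) rlnorm(1, -sdlog^2 / 2, sdlog) else 1
          out[[length(out) + 1]] <- tibble(
            plot_id = pid,
            trap_id = sprintf("%s-T%d", pid, tr),
            area_cm2 = areas[tr],
            set_time = doy_to_timestamp(yr, s0),
            collect_time = doy_to_timestamp(yr, e0),
            frass_g = expected_g * noise_f,
            greenfall_g = expected_g * gf_factor * noise_g
          )
        }
      }
      purrr::list_rbind(out)
    })
    records[[idx]] <- recs
    truth[[idx]] <- tibble(plot_id = pid, year = yr, scale = s_p,
                           annual_frass = annual_frass,
                           annual_foliage = annual_foliage,
                           window_start = win$start_doy,
                           window_end = win$end_doy)
    daily[[idx]] <- tibble(plot_id = pid, year = yr, doy = wl$doy,
                           frass_rate = unname(rate))
  }
  list(records = purrr::list_rbind(records),
       truth = purrr::list_rbind(truth),
       daily_rates = purrr::list_rbind(daily))
}

#' Simulate a complete multi-plot field study
#'
#' One call generating phenology tables and trap records for a study shaped
#' like the reference field designs: 12 calibration plots per species by
#' default, with weekly continuous trap collections for the jack pine budworm
#' scenario and ~24-h collections at weekly visits for the spongy moth
#' scenario, head/tail sampling gaps relative to the feeding window, 4-6
#' traps per plot with areas in the 1231.63-2370 cm^2 range, and
#' multiplicative trap noise with CV 0.10. Plot-to-plot variability enters as
#' a seeded whole-season shift of each plot's phenology and a log-normal
#' spread of plot density scales. True weights default to the
#' [calibrated_weights()] of the species.
#'
#' @param species `"cpinus"` or `"ldispar"`.
#' @param n_plots Number of plots (default 12).
#' @param n_intervals Number of collection intervals per plot (defaults:
#'   7 weekly for `cpinus`, 7 one-day-per-week for `ldispar`).
#' @param schedule_start First collection day-of-year (defaults: 139 for
#'   `cpinus`, 142 for `ldispar`).
#' @param interval_days Length of each collection interval in days (defaults:
#'   7 for `cpinus`, 1 for `ldispar`).
#' @param interval_step Days between interval starts (default 7).
#' @param noise_cv Trap-noise coefficient of variation (default 0.1).
#' @param greenfall_fraction See [simulate_frass()].
#' @param true_weights Optional named weight vector overriding the species
#'   default.
#' @param phenology_jitter_sd SD (days) of the per-plot season shift
#'   (default 2).
#' @param scale_meanlog,scale_sdlog Log-normal parameters of the plot density
#'   scales (defaults `log(0.65)`, 0.3).
#' @param seed Master seed.
#' @return A list: `config`, `true_weights`, `phenology`, `records`, `truth`,
#'   `daily_rates`, `schedule`.
#' @examples
#' study <- simulate_study("cpinus", n_plots = 3, seed = 7)
#' dplyr::count(study$records, plot_id)
#' @export
simulate_study <- function(species = c("cpinus", "ldispar"), n_plots = 12,
                           n_intervals = NULL, schedule_start = NULL,
                           interval_days = NULL, interval_step = 7,
                           noise_cv = 0.1, greenfall_fraction = 0.2,
                           true_weights = NULL, phenology_jitter_sd = 2,
                           scale_meanlog = log(0.65), scale_sdlog = 0.3,
                           seed = 1) {
  species <- match.arg(species)
  if (species == "cpinus") {
    config <- cpinus_config()
    base_means <- c(135, 146, 155, 162, 168, 174, 181)
    base_sds <- 4
    doy_range <- 112:208
    year <- 2006L
    n_intervals <- n_intervals %||% 7
    schedule_start <- schedule_start %||% 139
    interval_days <- interval_days %||% 7
  } else {
    config <- ldispar_config()
    base_means <- c(130, 140, 149, 157, 165, 176)
    base_sds <- c(4, 4, 4, 4, 4, 5)
    doy_range <- 108:200
    year <- 2007L
    n_intervals <- n_intervals %||% 7
    schedule_start <- schedule_start %||% 142
    interval_days <- interval_days %||% 1
  }
  if (is.null(true_weights)) {
    cw <- calibrated_weights()
    cw <- cw[cw$species == config$species_name, ]
    true_weights <- setNames(cw$weight / sum(cw$weight), cw$instar)
  }
  schedule <- tibble(
    start_doy = schedule_start + interval_step * (seq_len(n_intervals) - 1)
  )
  schedule$end_doy <- schedule$start_doy + interval_days

  shifts <- with_seed(child_seed(seed, 1000L),
                      round(rnorm(n_plots, 0, phenology_jitter_sd)))
  scales <- with_seed(child_seed(seed, 2000L),
                      setNames(rlnorm(n_plots, scale_meanlog, scale_sdlog),
                               sprintf("%s%02d", toupper(substr(species, 1, 1)),
                                       seq_len(n_plots))))
  phen <- purrr::map(seq_len(n_plots), function(i) {
    simulate_phenology(config, base_means + shifts[i], base_sds, doy_range,
                       plot_id = names(scales)[i], year = year)
  }) |> purrr::list_rbind()
  phen <- as_phenology(phen, config)

  sim <- simulate_frass(phen, config, true_weights, scales, schedule,
                        noise_cv = noise_cv,
                        greenfall_fraction = greenfall_fraction,
                        seed = child_seed(seed, 3000L))
  c(list(config = config, true_weights = true_weights, phenology = phen,
         schedule = schedule), sim)
}
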