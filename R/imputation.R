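#' Season cumulative density function of weighted larvae
#'
#' The cumulative fraction of total seasonal consumption signal through each
#' day of the feeding window: `F(d) = sum_{d' <= d} WL(d') / sum_window WL`.
#' `F` is a discrete daily step function, matching the daily resolution of
#' the phenology input; it is the basis for imputing deposition over
#' unsampled parts of the season.
#'
#' @param phenology A phenology tibble for a single plot-year.
#' @param weights Instar weights (vector, data frame or [optimize_weights()]
#'   fit).
#' @param config A [species_config()].
#' @param window Optional `c(start_doy, end_doy)`; defaults to the
#'   [feeding_window()] at `threshold`.
#' @param threshold Feeding-window threshold when `window` is `NULL`.
#' @return A `season_cdf` tibble with columns `doy`, `wl`, `mass` (daily
#'   fraction) and `cdf`, carrying `plot_id`/`year` attributes.
#' @export
season_cdf <- function(phenology, weights, config, window = NULL,
                       threshold = 0.1) {
  ids <- dplyr::distinct(as_tibble(phenology), .data$plot_id, .data$year)
  if (nrow(ids) != 1)
    abort_parameter("`season_cdf()` expects a single plot-year; got several.")
  if (is.null(window)) {
    fw <- feeding_window(phenology, config, threshold)
    window <- c(fw$start_doy, fw$end_doy)
  }
  if (window[1] < min(phenology$doy) || window[2] > max(phenology$doy))
    abort_parameter("`window` extends beyond the phenology table's doy range.")
  wl <- weighted_larvae(phenology, weights)
  wl <- wl[wl$doy >= window[1] & wl$doy <= window[2], , drop = FALSE]
  total <- sum(wl$wl)
  if (total <= 0)
    abort_validation("Total weighted larvae over the window is zero: degenerate season.")
  daily <- wl$wl
  out <- tibble(doy = wl$doy, wl = daily, mass = daily / total,
                cdf = cumsum(daily) / total)
  attr(out, "plot_id") <- ids$plot_id
  attr(out, "year") <- ids$year
  attr(out, "window") <- window
  class(out) <- c("season_cdf", class(out))
  out
}

# Coverage fraction of each cdf day by a set of observation intervals.
cdf_coverage <- function(cdf, start, end) {
  cov <- rep(0, nrow(cdf))
  for (j in seq_along(start)) {
    cov <- cov + day_coverage(cdf$doy, start[j], end[j])
  }
  pmin(cov, 1)
}

#' Impute unsampled deposition and estimate the annual total
#'
#' Field sampling rarely spans the whole feeding season. Given plot-level
#' interval rates and the season CDF of weighted larvae, the observed
#' cumulative deposition is divided by the fraction of seasonal CDF mass the
#' sampling covered, yielding the annual total; each unsampled gap is then
#' assigned its share `annual_total * F-mass(gap)`. All gaps are filled from
#' the one global annual total, so observed plus imputed equals the annual
#' total by construction.
#'
#' @param rates Plot-interval rates for the cdf's plot-year (rows for other
#'   plot-years are ignored with a message).
#' @param cdf A [season_cdf()].
#' @param channel `"frass"` or `"foliage_loss"`.
#' @param config Needed for the foliage-loss channel (AD value).
#' @return An `imputation` object: observed, imputed and annual totals
#'   (kg/ha), the sampled mass fraction, and the imputed segments tiling the
#'   unsampled window. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
impute_annual <- function(rates, cdf, channel = c("frass", "foliage_loss"),
                          config = NULL) {
  channel <- match.arg(channel)
  plot_id <- attr(cdf, "plot_id")
  year <- attr(cdf, "year")
  sel <- rates$plot_id == plot_id & rates$year == year
  if (!all(sel)) {
    inform(sprintf("Using the %d of %d intervals belonging to plot '%s' year %d.",
                   sum(sel), length(sel), plot_id, year))
    rates <- rates[sel, ]
  }
  if (nrow(rates) == 0)
    abort_validation("No observation intervals for the cdf's plot-year.")

  window <- attr(cdf, "window")
  w_start <- window[1]
  w_end <- window[2] + 1   # day w_end spans [w_end, w_end + 1)
  clipped_start <- pmax(rates$start_doy, w_start)
  clipped_end <- pmin(rates$end_doy, w_end)
  overlap <- pmax(clipped_end - clipped_start, 0)
  if (any(overlap <= 0))
    warn(sprintf("%d interval(s) fall outside the feeding window and were clipped away.",
                 sum(overlap <= 0)))

  values <- channel_rates(rates, channel, config) * overlap
  observed_total <- sum(values)

  keep <- overlap > 0
  coverage <- cdf_coverage(cdf, clipped_start[keep], clipped_end[keep])
  sampled_mass_fraction <- sum(cdf$mass * coverage)
  if (sampled_mass_fraction <= 0)
    abort_validation("Sampling covers none of the season's CDF mass: imputation impossible.")
  annual_total <- observed_total / sampled_mass_fraction

  deficit <- 1 - coverage
  open <- deficit > 1e-12
  segs <- list()
  i <- 1
  while (i <= length(open)) {
    if (open[i]) {
      j <- i
      while (j < length(open) && open[j + 1]) j <- j + 1
      mass <- sum(cdf$mass[i:j] * deficit[i:j])
      segs[[length(segs) + 1]] <- tibble(
        start_doy = cdf$doy[i], end_doy = cdf$doy[j],
        mass_fraction = mass, imputed = annual_total * mass
      )
      i <- j + 1
    } else i <- i + 1
  }
  segments <- if (length(segs)) purrr::list_rbind(segs) else
    tibble(start_doy = integer(0), end_doy = integer(0),
           mass_fraction = numeric(0), imputed = numeric(0))

  structure(
    list(
      plot_id = plot_id, year = year, channel = channel,
      observed_total = observed_total,
      sampled_mass_fraction = sampled_mass_fraction,
      annual_total = annual_total,
      imputed_total = sum(segments$imputed),
      imputed_segments = segments,
      cdf = cdf,
      intervals = tibble(start_doy = clipped_start[keep],
                         end_doy = clipped_end[keep],
                         observed = values[keep],
                         rate = channel_rates(rates, channel, config)[keep])
    ),
    class = "imputation"
  )
}

#' @export
print.imputation <- function(x, ...) {
  cat("<imputation> plot '", x$plot_id, "' year ", x$year, " (", x$channel,
      ")\n", sep = "")
  cat(sprintf("  observed: %.2f kg/ha over %.1f%% of seasonal mass\n",
              x$observed_total, 100 * x$sampled_mass_fraction))
  cat(sprintf("  annual total: %.2f kg/ha (imputed: %.2f over %d gap(s))\n",
              x$annual_total, x$imputed_total, nrow(x$imputed_segments)))
  invisible(x)
}

#' @describeIn impute_annual Imputed gap segments, one row each.
#' @param x,object An `imputation` object.
#' @param ... Unused.
#' @method tidy imputation
#' @export
tidy.imputation <- function(x, ...) x$imputed_segments

#' @describeIn impute_annual One-row summary of totals.
#' @method glance imputation
#' @export
glance.imputation <- function(x, ...) {
  tibble(plot_id = x$plot_id, year = x$year, channel = x$channel,
         observed_total = x$observed_total,
         sampled_mass_fraction = x$sampled_mass_fraction,
         imputed_total = x$imputed_total, annual_total = x$annual_total)
}

#' @describeIn impute_annual Observed interval rates (bars), the season CDF
#'   scaled to the annual total (line), and shaded unsampled gaps.
#' @method autoplot imputation
#' @export
autoplot.imputation <- function(object, ...) {
  cdf <- object$cdf
  curve <- tibble(doy = cdf$doy, value = cdf$cdf * object$annual_total)
  bars <- object$intervals
  gaps <- object$imputed_segments
  p <- ggplot2::ggplot()
  if (nrow(gaps) > 0) {
    p <- p + ggplot2::geom_rect(
      data = gaps,
      ggplot2::aes(xmin = .data$start_doy, xmax = .data$end_doy + 1,
                   ymin = -Inf, ymax = Inf),
      fill = "grey85"
    )
  }
  p +
    ggplot2::geom_rect(
      data = bars,
      ggplot2::aes(xmin = .data$start_doy, xmax = .data$end_doy,
                   ymin = 0, ymax = .data$rate),
      fill = "steelblue", alpha = 0.7
    ) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$doy, y = .data$value),
                       colour = "red") +
    ggplot2::labs(
      x = "Day of year",
      y = "Rate (kg/ha/day) | cumulative total (kg/ha)",
      title = sprintf("Plot %s %d: observed %s and imputed season",
                      object$plot_id, object$year, object$channel)
    ) +
    ggplot2::theme_minimal()
}

#' Annual defoliation totals for many plot-years
#'
#' Convenience wrapper running [season_cdf()] and [impute_annual()] for every
#' plot-year shared by the phenology and rate tables.
#'
#' @inheritParams optimize_weights
#' @param weights Instar weights (vector, data frame or fit).
#' @param threshold Feeding-window threshold.
#' @return A tibble with one row per plot-year: `species`, `plot_id`, `year`,
#'   `channel`, `observed_total`, `sampled_mass_fraction`, `imputed_total`,
#'   `annual_total`.
#' @export
estimate_annual <- function(rates, phenology, weights, config,
                            channel = c("frass", "foliage_loss"),
                            threshold = 0.1) {
  channel <- match.arg(channel)
  out <- list()
  for (piece in split_plot_years(phenology)) {
    key <- paste(piece$plot_id[1], piece$year[1])
    sel <- paste(rates$plot_id, rates$year) == key
    if (!any(sel)) next
    cdf <- season_cdf(piece, weights, config, threshold = threshold)
    imp <- impute_annual(rates[sel, ], cdf, channel = channel, config = config)
    out[[key]] <- dplyr::bind_cols(tibble(species = config$species_name),
                                   glance(imp))
  }
  if (length(out) == 0)
    abort_validation("No plot-year is shared by the phenology and rate tables.")
  purrr::list_rbind(out)
}

#' Leave-one-interval-out ("K-week") cross-validation of the imputation
#'
#' For every plot and every sampled collection interval: withhold the
#' interval, estimate the annual total from the remaining (training)
#' intervals via the season CDF, and predict the withheld deposition as
#' `annual_total(training) * F-mass(withheld interval)`. Fold errors are
#' predicted minus observed withheld biomass; RMSE and nRMSE pool all
#' plot-intervals. Plots with a single interval are skipped with a warning.
#'
#' @inheritParams estimate_annual
#' @param per_plot If `TRUE`, withhold only one randomly chosen interval per
#'   plot (seeded) instead of iterating over all intervals.
#' @param seed Seed for `per_plot` selection.
#' @return A `cv_report` (method `"kweek"`).
#' @export
kweek_crossval <- function(rates, phenology, weights, config,
                           channel = c("frass", "foliage_loss"),
                           threshold = 0.1, per_plot = FALSE, seed = 20230215) {
  channel <- match.arg(channel)
  folds <- list()
  all_res <- numeric(0)
  all_obs <- numeric(0)
  for (piece in split_plot_years(phenology)) {
    key <- paste(piece$plot_id[1], piece$year[1])
    sel <- which(paste(rates$plot_id, rates$year) == key)
    if (length(sel) == 0) next
    if (length(sel) < 2) {
      warn(sprintf("Plot '%s' year %d has a single interval; skipped in K-week CV.",
                   piece$plot_id[1], piece$year[1]))
      next
    }
    cdf <- season_cdf(piece, weights, config, threshold = threshold)
    held <- seq_along(sel)
    if (per_plot) {
      held <- with_seed(child_seed(seed, match(key, unique(paste(rates$plot_id, rates$year)))),
                        sample(seq_along(sel), 1))
    }
    for (h in held) {
      test_i <- sel[h]
      train <- rates[sel[-h], ]
      imp <- impute_annual(train, cdf, channel = channel, config = config)
      w_start <- attr(cdf, "window")[1]
      w_end <- attr(cdf, "window")[2] + 1
      s <- max(rates$start_doy[test_i], w_start)
      e <- min(rates$end_doy[test_i], w_end)
      mass <- if (e > s) sum(cdf$mass * cdf_coverage(cdf, s, e)) else 0
      predicted <- imp$annual_total * mass
      observed <- channel_rates(rates[test_i, ], channel, config) *
        max(e - s, 0)
      folds[[length(folds) + 1]] <- tibble(
        plot_id = piece$plot_id[1], year = piece$year[1],
        start_doy = rates$start_doy[test_i], end_doy = rates$end_doy[test_i],
        observed = observed, predicted = predicted,
        error = predicted - observed
      )
      all_res <- c(all_res, predicted - observed)
      all_obs <- c(all_obs, observed)
    }
  }
  if (length(folds) == 0)
    abort_validation("No plot has the two or more intervals K-week CV requires.")
  new_cv_report(purrr::list_rbind(folds), all_res, all_obs,
                method = "kweek", channel = channel)
}

#' Summarize annual totals by species and year
#'
#' Means, sample standard deviations and counts of the per-plot annual
#' defoliation totals, grouped by species, year and channel.
#'
#' @param results A tibble from [estimate_annual()] (must carry a `species`
#'   column).
#' @return A tibble with `species`, `year`, `channel`, `n`, `mean_annual`,
#'   `sd_annual`.
#' @export
annual_report <- function(results) {
  if (nrow(results) == 0) abort_validation("`results` is empty.")
  if (!"species" %in% names(results))
    abort_validation("`results` must carry a `species` column for grouping.")
  results |>
    dplyr::group_by(.data$species, .data$year, .data$channel) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_annual = mean(.data$annual_total),
      sd_annual = ifelse(dplyr::n() > 1, sd(.data$annual_total), 0),
      .groups = "drop"
    )
}
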