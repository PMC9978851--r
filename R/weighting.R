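#' Weighted-larvae signal
#'
#' The consumption-weighted percent of the population feeding on each day:
#' `WL(d) = sum_i w_i * p_i(d)`, where `p_i(d)` is the percent of the
#' population in feeding instar `i` on day-of-year `d` and `w_i` is that
#' instar's share of total seasonal consumption. Because the weights lie on
#' the unit simplex and each percent is in `[0, 100]`, `WL` is also in
#' `[0, 100]`.
#'
#' @param tbl A phenology tibble (any number of plot-years).
#' @param weights Named numeric vector of instar weights, a data frame with
#'   columns `instar` and `weight`, or an [optimize_weights()] fit.
#' @param doy Optional integer vector restricting the result to specific
#'   days; a requested day absent from the table is an error.
#' @return A tibble `plot_id`, `year`, `doy`, `wl`.
#' @export
weighted_larvae <- function(tbl, weights, doy = NULL) {
  w <- as_weight_vector(weights)
  missing <- setdiff(names(w), names(tbl))
  if (length(missing) > 0)
    abort_format(paste0("Phenology table lacks instar column(s): ",
                        paste(missing, collapse = ", ")))
  out <- as_tibble(tbl)[c("plot_id", "year", "doy")]
  out$wl <- as.numeric(as.matrix(as_tibble(tbl)[names(w)]) %*% w)
  if (!is.null(doy)) {
    absent <- setdiff(doy, out$doy)
    if (length(absent) > 0)
      abort_validation(paste0("Day(s) absent from phenology table: ",
                              paste(absent, collapse = ", ")))
    out <- out[out$doy %in% doy, ]
  }
  out
}

# Accepts a named vector, an (instar, weight) data frame, or an instar_fit.
as_weight_vector <- function(weights) {
  if (inherits(weights, "instar_fit")) return(weights$weights)
  if (is.data.frame(weights)) {
    if (!all(c("instar", "weight") %in% names(weights)))
      abort_parameter("Weight data frames need columns `instar` and `weight`.")
    weights <- setNames(weights$weight, weights$instar)
  }
  if (!is.numeric(weights) || is.null(names(weights)))
    abort_parameter("`weights` must be a named numeric vector, data frame or fit.")
  weights
}

#' Root-mean-square error and normalized RMSE
#'
#' `rmse` is the square root of the mean squared residual between predictions
#' and observations; `nrmse` divides it by the mean of the observations, a
#' dimensionless error used to compare plots or species with different
#' deposition magnitudes.
#'
#' @param pred,obs Equal-length numeric vectors.
#' @return A single number.
#' @examples
#' rmse(c(3, 4), c(0, 0)) # sqrt(25/2)
#' @export
rmse <- function(pred, obs) {
  if (length(pred) != length(obs) || length(obs) < 1)
    abort_parameter("`pred` and `obs` must be equal-length, non-empty vectors.")
  sqrt(mean((pred - obs)^2))
}

#' @rdname rmse
#' @export
nrmse <- function(pred, obs) {
  m <- mean(obs)
  if (!is.finite(m) || m <= 0)
    abort_numerical("nRMSE is undefined when mean(obs) is not positive.")
  rmse(pred, obs) / m
}

# ---------------------------------------------------------------------------
# Calibration design: per plot-year, the matrix of mean feeding-instar
# percents over each observation interval, and the observed channel rates.

prep_calibration <- function(rates, phenology, config,
                             channel = "frass") {
  instars <- config$feeding_instars
  y_all <- channel_rates(rates, channel, config)
  keys_r <- paste(rates$plot_id, rates$year)
  phen_split <- split_plot_years(phenology)
  items <- list()
  for (piece in phen_split) {
    key <- paste(piece$plot_id[1], piece$year[1])
    sel <- which(keys_r == key)
    if (length(sel) == 0) next
    P <- as.matrix(piece[instars])
    doy_index <- setNames(seq_len(nrow(piece)), piece$doy)
    M <- matrix(NA_real_, length(sel), length(instars),
                dimnames = list(NULL, instars))
    keep <- logical(length(sel))
    for (j in seq_along(sel)) {
      i <- sel[j]
      dd <- doys_in_interval(rates$start_doy[i], rates$end_doy[i])
      dd <- dd[as.character(dd) %in% names(doy_index)]
      if (length(dd) == 0) next
      M[j, ] <- colMeans(P[doy_index[as.character(dd)], , drop = FALSE])
      keep[j] <- TRUE
    }
    if (any(!keep))
      warn(sprintf("Dropped %d interval(s) of plot '%s' with no overlap with its phenology table.",
                   sum(!keep), piece$plot_id[1]))
    if (sum(keep) == 0) next
    items[[key]] <- list(plot_id = piece$plot_id[1], year = piece$year[1],
                         M = M[keep, , drop = FALSE], y = y_all[sel][keep],
                         doys = piece$doy,
                         start = rates$start_doy[sel][keep],
                         end = rates$end_doy[sel][keep])
  }
  if (length(items) == 0)
    abort_validation("No overlap between phenology tables and observation intervals.")
  items
}

# Closed-form least-squares scale through the origin for one plot.
plot_scale_ls <- function(pred0, y) {
  den <- sum(pred0^2)
  if (den <= 0) return(0)
  max(sum(y * pred0) / den, 0)
}

# Pooled residuals at a weight vector. mode "direct" compares s_p * interval
# means of WL with observed rates; mode "bell-smoothed" first smooths each
# plot's daily WL with the bell curve and predicts interval means from the
# smooth, mirroring the iterative distribution-refitting reading of the
# calibration procedure.
calibration_residuals <- function(w, items, mode = "direct") {
  res <- numeric(0)
  scales <- numeric(length(items))
  for (k in seq_along(items)) {
    it <- items[[k]]
    if (mode == "direct") {
      pred0 <- as.numeric(it$M %*% w)
    } else {
      wl <- as.numeric(it$P_daily %*% w)
      bf <- tryCatch(fit_bell(it$doys, wl), error = function(e) NULL)
      smooth <- if (is.null(bf)) wl else bell_curve(it$doys, bf$a, bf$b, bf$c)
      lookup <- setNames(smooth, it$doys)
      pred0 <- vapply(seq_along(it$start), function(j) {
        dd <- doys_in_interval(it$start[j], it$end[j])
        mean(lookup[as.character(dd)], na.rm = TRUE)
      }, numeric(1))
    }
    s <- plot_scale_ls(pred0, it$y)
    scales[k] <- s
    res <- c(res, s * pred0 - it$y)
  }
  list(residuals = res, scales = scales)
}

softmax_weights <- function(par, n, floor = 1e-6) {
  theta <- c(par, 0)
  e <- exp(theta - max(theta))
  floor + (1 - n * floor) * e / sum(e)
}

# Analytic gradient of the pooled RMSE objective (direct mode) with respect
# to the unconstrained softmax parameters: residual r_p = s_p(w) M_p w - y_p
# with the scale profiled out in closed form, chained through the softmax
# Jacobian. At a zero-residual optimum the gradient is zero by convention.
direct_objective_grad <- function(par, items, n, floor) {
  theta <- c(par, 0)
  e <- exp(theta - max(theta))
  sm <- e / sum(e)
  w <- floor + (1 - n * floor) * sm
  g_w <- numeric(n)
  ssr <- 0
  n_obs <- 0
  for (it in items) {
    m <- as.numeric(it$M %*% w)
    mm <- sum(m^2)
    ym <- sum(it$y * m)
    s <- if (mm > 0) ym / mm else 0
    if (s < 0) s <- 0
    r <- s * m - it$y
    ssr <- ssr + sum(r^2)
    n_obs <- n_obs + length(r)
    if (s > 0) {
      ds_dw <- (crossprod(it$M, it$y) - 2 * s * crossprod(it$M, m)) / mm
      g_w <- g_w + s * as.numeric(crossprod(it$M, r)) +
        as.numeric(ds_dw) * sum(m * r)
    }
  }
  f <- sqrt(ssr / n_obs)
  if (f <= 0) return(rep(0, n - 1))
  df_dw <- g_w / (n_obs * f)
  jac <- (1 - n * floor) * (diag(sm) - tcrossprod(sm))
  as.numeric(jac %*% df_dw)[seq_len(n - 1)]
}

#' Optimize per-instar feeding weights against observed deposition
#'
#' Estimates the instar weighting vector `w` (each weight strictly positive,
#' summing to one) that best links simulated daily instar proportions to
#' field-observed deposition rates. For candidate weights, each plot's
#' weighted-larvae signal is averaged over its collection intervals, scaled by
#' a per-plot free positive factor `s_p` (estimated in closed form by least
#' squares through the origin — instar proportions carry no information about
#' absolute population density), and compared to the observed rates; the
#' objective is the pooled RMSE in kg/ha/day. Weights are parameterized by a
#' softmax of unconstrained reals so the simplex constraints hold exactly at
#' every iterate, and a quasi-Newton search is run from `n_starts` starting
#' points (the first is the uniform weighting, the rest are seeded draws);
#' the best objective wins, ties going to the lowest start index.
#'
#' @param rates Plot-interval rate tibble from [plot_interval_rates()].
#' @param phenology Phenology tibble covering the same plot-years.
#' @param config A [species_config()].
#' @param channel `"frass"` (default) or `"foliage_loss"`; the latter applies
#'   the digestibility correction and adds greenfall at the interval level.
#' @param mode `"direct"` (default) scores `s_p *` interval means of the
#'   weighted-larvae signal; `"bell-smoothed"` scores the bell-curve fit of
#'   the daily signal instead (see the methods vignette for the distinction).
#' @param n_starts Number of optimizer starts (default 8).
#' @param seed Seed for the random starts (default 20230215).
#' @param weight_floor Lower bound kept on every weight (default `1e-6`).
#' @param max_iter Iteration cap per start (default 500).
#' @param reltol Relative objective-change convergence tolerance (default
#'   `1e-10`).
#' @return An `instar_fit`: weights, per-plot scales, objective (RMSE,
#'   kg/ha/day), convergence info, and a descriptive bell fit of the weights
#'   against instar index. Supports `tidy()`, `glance()`, `autoplot()`.
#' @export
optimize_weights <- function(rates, phenology, config,
                             channel = c("frass", "foliage_loss"),
                             mode = c("direct", "bell-smoothed"),
                             n_starts = 8, seed = 20230215,
                             weight_floor = 1e-6, max_iter = 500,
                             reltol = 1e-10) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  items <- prep_calibration(rates, phenology, config, channel)
  if (mode == "bell-smoothed") {
    phen_split <- split_plot_years(phenology)
    for (key in names(items)) {
      piece <- phen_split[[match(key, vapply(phen_split, function(p)
        paste(p$plot_id[1], p$year[1]), character(1)))]]
      items[[key]]$P_daily <- as.matrix(piece[config$feeding_instars])
    }
  }
  n <- length(config$feeding_instars)

  objective <- function(par) {
    w <- softmax_weights(par, n, weight_floor)
    r <- calibration_residuals(w, items, mode)$residuals
    sqrt(mean(r^2))
  }
  gradient <- if (mode == "direct") {
    function(par) direct_objective_grad(par, items, n, weight_floor)
  } else NULL

  starts <- list(rep(0, n - 1))
  if (n_starts > 1) {
    extra <- with_seed(seed, lapply(seq_len(n_starts - 1),
                                    function(i) rnorm(n - 1, 0, 1.5)))
    starts <- c(starts, extra)
  }

  best <- NULL
  total_evals <- 0L
  for (i in seq_along(starts)) {
    fit <- if (n == 1) {
      list(par = numeric(0), value = objective(numeric(0)),
           counts = c(`function` = 1L), convergence = 0L)
    } else {
      optim(starts[[i]], objective, gr = gradient, method = "BFGS",
            control = list(maxit = max_iter, reltol = reltol))
    }
    total_evals <- total_evals + unname(fit$counts[1])
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      best$start_index <- i
    }
  }
  if (is.null(best))
    abort_numerical("Weight optimization failed from every start.")

  w <- softmax_weights(best$par, n, weight_floor)
  names(w) <- config$feeding_instars
  final <- calibration_residuals(w, items, mode)
  scales <- tibble(
    plot_id = vapply(items, `[[`, character(1), "plot_id"),
    year = vapply(items, `[[`, integer(1), "year"),
    scale = final$scales
  )
  weight_bell <- tryCatch(fit_bell(seq_len(n), w), error = function(e) NULL)

  structure(
    list(
      weights = w,
      plot_scales = scales,
      objective = best$value,
      n_iterations = total_evals,
      converged = best$convergence == 0,
      mode = mode,
      channel = channel,
      species = config$species_name,
      n_plots = length(items),
      n_intervals = length(final$residuals),
      n_starts = length(starts),
      best_start = best$start_index,
      weight_bell = weight_bell
    ),
    class = "instar_fit"
  )
}

#' @export
print.instar_fit <- function(x, ...) {
  cat("<instar_fit> ", x$species, " - ", x$channel, " channel, mode '",
      x$mode, "'\n", sep = "")
  print(round(x$weights, 4))
  cat(sprintf("  objective RMSE: %.4f kg/ha/day over %d intervals in %d plots\n",
              x$objective, x$n_intervals, x$n_plots))
  cat(sprintf("  converged: %s (best of %d starts)\n", x$converged, x$n_starts))
  invisible(x)
}

#' @describeIn optimize_weights One row per instar: `instar`, `weight`,
#'   `share_pct`.
#' @param x,object An `instar_fit`.
#' @param ... Unused.
#' @method tidy instar_fit
#' @export
tidy.instar_fit <- function(x, ...) {
  tibble(instar = names(x$weights), weight = unname(x$weights),
         share_pct = 100 * unname(x$weights) / sum(x$weights))
}

#' @describeIn optimize_weights One-row model summary.
#' @method glance instar_fit
#' @export
glance.instar_fit <- function(x, ...) {
  tibble(objective = x$objective, mode = x$mode, channel = x$channel,
         n_plots = x$n_plots, n_intervals = x$n_intervals,
         converged = x$converged, n_iterations = x$n_iterations)
}

#' @describeIn optimize_weights Weights by instar with the descriptive bell
#'   curve overlaid (dotted).
#' @method autoplot instar_fit
#' @export
autoplot.instar_fit <- function(object, ...) {
  df <- tidy(object)
  df$index <- seq_len(nrow(df))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$weight)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_continuous(breaks = df$index, labels = df$instar) +
    ggplot2::labs(x = "Instar", y = "Weighting (w)",
                  title = paste(object$species, "instar weighting")) +
    ggplot2::theme_minimal()
  if (!is.null(object$weight_bell)) {
    grid <- tibble(index = seq(1, nrow(df), length.out = 100))
    grid$fit <- predict(object$weight_bell, grid$index)
    p <- p + ggplot2::geom_line(data = grid,
                                ggplot2::aes(x = .data$index, y = .data$fit),
                                linetype = "dotted")
  }
  p
}
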