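#' Leave-one-plot-out cross-validation of the weight optimization
#'
#' For each plot(-year): re-optimize the instar weights on the remaining
#' plots, estimate the held-out plot's density scale by closed-form least
#' squares against its own observed rates, and score the RMSE between
#' predicted and observed interval rates. The pooled RMSE is computed over
#' all held-out residuals; nRMSE divides it by the mean of the held-out
#' observations.
#'
#' @inheritParams optimize_weights
#' @param ... Further arguments passed to [optimize_weights()] (e.g.
#'   `n_starts`, `seed`, `mode`).
#' @return A `cv_report` with per-fold and pooled RMSE/nRMSE; supports
#'   `tidy()` and `glance()`.
#' @export
loocv_weights <- function(rates, phenology, config,
                          channel = c("frass", "foliage_loss"),
                          mode = c("direct", "bell-smoothed"), ...) {
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  items <- prep_calibration(rates, phenology, config, channel)
  if (length(items) < 2)
    abort_validation("Leave-one-plot-out validation needs at least 2 plots.")

  keys_r <- paste(rates$plot_id, rates$year)
  keys_p <- paste(phenology$plot_id, phenology$year)

  folds <- list()
  all_res <- numeric(0)
  all_obs <- numeric(0)
  for (key in names(items)) {
    train_rates <- rates[keys_r != key, ]
    train_phen <- phenology[keys_p != key, ]
    fit <- optimize_weights(train_rates, train_phen, config,
                            channel = channel, mode = mode, ...)
    it <- items[[key]]
    pred0 <- as.numeric(it$M %*% fit$weights[colnames(it$M)])
    s <- plot_scale_ls(pred0, it$y)
    pred <- s * pred0
    folds[[key]] <- tibble(
      unit = key, plot_id = it$plot_id, year = it$year,
      n_obs = length(it$y), scale = s, rmse = rmse(pred, it$y)
    )
    all_res <- c(all_res, pred - it$y)
    all_obs <- c(all_obs, it$y)
  }
  new_cv_report(purrr::list_rbind(folds), all_res, all_obs,
                method = "loocv", channel = channel)
}

new_cv_report <- function(folds, residuals, observed, method, channel) {
  overall <- sqrt(mean(residuals^2))
  structure(
    list(
      folds = folds,
      rmse = overall,
      nrmse = overall / mean(observed),
      n_folds = nrow(folds),
      n_obs = length(observed),
      mean_observed = mean(observed),
      method = method,
      channel = channel
    ),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$method, " (", x$channel, " channel)\n", sep = "")
  cat(sprintf("  folds: %d, held-out observations: %d\n", x$n_folds, x$n_obs))
  cat(sprintf("  RMSE: %.4f kg/ha  nRMSE: %.4f\n", x$rmse, x$nrmse))
  invisible(x)
}

#' Per-fold results of a cross-validation report
#' @param x,object A `cv_report`.
#' @param ... Unused.
#' @method tidy cv_report
#' @export
tidy.cv_report <- function(x, ...) x$folds

#' @rdname tidy.cv_report
#' @method glance cv_report
#' @export
glance.cv_report <- function(x, ...) {
  tibble(method = x$method, channel = x$channel, rmse = x$rmse,
         nrmse = x$nrmse, n_folds = x$n_folds, n_obs = x$n_obs)
}
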