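# Shared fixtures, built in code: a 3-instar toy species, hand-assembled
# phenology tables, and direct constructors for plot-interval rate rows.

toy_config <- function(k = 3, ad = 0.3) {
  species_config("Toyworm", paste0("L", seq(2, k + 1)),
                 approximate_digestibility = ad)
}

# Phenology tibble from an explicit doy-by-instar percent matrix.
make_phen <- function(config, doys, percents, plot_id = "P1", year = 2006L) {
  stopifnot(nrow(percents) == length(doys),
            ncol(percents) == length(config$feeding_instars))
  tbl <- tibble::tibble(plot_id = plot_id, year = as.integer(year),
                        doy = as.integer(doys))
  for (j in seq_along(config$feeding_instars))
    tbl[[config$feeding_instars[j]]] <- percents[, j]
  as_phenology(tbl, config)
}

# Directly assembled plot-interval rates (bypasses trap records).
make_rates <- function(start_doy, end_doy, frass_rate, greenfall_rate = 0,
                       plot_id = "P1", year = 2006L) {
  tibble::tibble(plot_id = plot_id, year = as.integer(year),
                 start_doy = start_doy, end_doy = end_doy,
                 frass_rate = frass_rate, greenfall_rate = greenfall_rate,
                 n_traps = 1L)
}

# Random point on the k-simplex.
random_simplex <- function(k) {
  g <- stats::rgamma(k, 1)
  g / sum(g)
}

# Independent re-implementation of the calibration objective (direct mode),
# used as an oracle: for each plot, interval means of the weighted-larvae
# signal, closed-form scale through the origin, pooled RMSE.
oracle_objective <- function(w, rates, phenology, config) {
  res <- numeric(0)
  for (key in unique(paste(rates$plot_id, rates$year))) {
    r <- rates[paste(rates$plot_id, rates$year) == key, ]
    p <- phenology[paste(phenology$plot_id, phenology$year) == key, ]
    wl <- as.matrix(p[config$feeding_instars]) %*% w
    pred0 <- sapply(seq_len(nrow(r)), function(i) {
      lo <- ceiling(r$start_doy[i]); hi <- ceiling(r$end_doy[i]) - 1
      dd <- if (lo > hi) floor(r$start_doy[i]) else lo:hi
      mean(wl[match(dd, p$doy)])
    })
    s <- sum(r$frass_rate * pred0) / sum(pred0^2)
    if (!is.finite(s) || s < 0) s <- 0
    res <- c(res, s * pred0 - r$frass_rate)
  }
  sqrt(mean(res^2))
}

# Uniform-signal toy: one instar at constant percent over `n` days, so every
# day carries CDF mass 1/n and imputation arithmetic is hand-checkable.
uniform_cdf <- function(n, config = toy_config(1), start = 1L) {
  phen <- make_phen(config, seq(start, start + n - 1), cbind(rep(50, n)))
  season_cdf(phen, c(L2 = 1), config)
}
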