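test_that("season CDF is a normalized prefix sum of weighted larvae", {
  cdf <- uniform_cdf(10)
  expect_equal(cdf$cdf[5], 0.5)
  expect_equal(cdf$cdf[10], 1)
  expect_true(all(diff(cdf$cdf) >= 0))

  # prefix-sum oracle on a bell-shaped season
  config <- toy_config()
  phen <- simulate_phenology(config, c(140, 150, 160, 170), 4, 120:190)
  w <- c(L2 = 0.2, L3 = 0.5, L4 = 0.3)
  cdf2 <- season_cdf(phen, w, config)
  wl <- weighted_larvae(phen, w)
  wl <- wl[wl$doy %in% cdf2$doy, ]
  expect_equal(cdf2$cdf, cumsum(wl$wl) / sum(wl$wl), tolerance = 1e-12)
  expect_equal(cdf2$cdf[nrow(cdf2)], 1, tolerance = 1e-9)
  expect_equal(cdf2$cdf[1], wl$wl[1] / sum(wl$wl), tolerance = 1e-12)

  # degenerate: zero signal over the window
  zero <- make_phen(toy_config(1), 1:5, cbind(rep(0, 5)))
  expect_error(season_cdf(zero, c(L2 = 1), toy_config(1), window = c(1, 5)),
               class = "phenofrass_validation_error")
})

test_that("annual totals follow the sampled-mass-fraction identity", {
  # 10 uniform days; sampling covers 8 of them at 10 kg/ha/day
  cdf <- uniform_cdf(10)
  rates <- make_rates(1, 9, 10)
  imp <- impute_annual(rates, cdf)
  expect_equal(imp$observed_total, 80)
  expect_equal(imp$sampled_mass_fraction, 0.8)
  expect_equal(imp$annual_total, 100)
  expect_equal(imp$imputed_total, 20)

  # full-season sampling: annual equals observed exactly
  full <- impute_annual(make_rates(1, 11, 10), cdf)
  expect_equal(full$annual_total, full$observed_total)
  expect_equal(nrow(full$imputed_segments), 0)

  # head and tail gaps with F-masses 0.10 and 0.15 impute in ratio 2:3
  cdf20 <- uniform_cdf(20)
  imp2 <- impute_annual(make_rates(3, 18, 10), cdf20)
  segs <- tidy(imp2)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$mass_fraction, c(0.10, 0.15), tolerance = 1e-12)
  expect_equal(segs$imputed[1] / segs$imputed[2], 2 / 3, tolerance = 1e-12)
  expect_equal(sum(segs$imputed), imp2$annual_total * 0.25, tolerance = 1e-12)
})

test_that("observed plus imputed equals the annual total for arbitrary sampling", {
  set.seed(33)
  config <- toy_config()
  phen <- simulate_phenology(config, c(140, 150, 160, 170), 4, 120:190)
  cdf <- season_cdf(phen, c(L2 = 0.1, L3 = 0.6, L4 = 0.3), config)
  for (i in 1:25) {
    n_int <- sample(1:4, 1)
    starts <- sort(sample(125:180, n_int))
    ends <- starts + sample(1:6, n_int, replace = TRUE)
    ends <- pmin(ends, c(starts[-1], 200))   # keep intervals disjoint
    keep <- ends > starts
    if (!any(keep)) next
    rates <- make_rates(starts[keep], ends[keep], runif(sum(keep), 0, 20))
    imp <- suppressWarnings(impute_annual(rates, cdf))
    expect_lt(abs(imp$observed_total + imp$imputed_total - imp$annual_total),
              1e-9)
    expect_gte(imp$annual_total, imp$observed_total - 1e-12)
    # segments tile exactly the unsampled mass
    expect_equal(sum(tidy(imp)$mass_fraction), 1 - imp$sampled_mass_fraction,
                 tolerance = 1e-12)
  }
})

test_that("adding an observation interval never shrinks the sampled fraction", {
  cdf <- uniform_cdf(30)
  base <- make_rates(5, 12, 10)
  f_base <- impute_annual(base, cdf)$sampled_mass_fraction
  for (extra_start in c(1, 14, 20, 28)) {
    more <- dplyr::bind_rows(base, make_rates(extra_start, extra_start + 3, 5))
    f_more <- impute_annual(more, cdf)$sampled_mass_fraction
    expect_gte(f_more, f_base - 1e-12)
  }
})

test_that("K-week cross-validation is self-consistent and hand-checkable", {
  # noise-free synthetic plots: every fold error vanishes
  st <- simulate_study("cpinus", n_plots = 3, noise_cv = 0, seed = 13)
  rates <- plot_interval_rates(st$records)
  cv <- kweek_crossval(rates, st$phenology, st$true_weights, st$config)
  expect_lt(max(abs(tidy(cv)$error)), 1e-9)
  expect_equal(cv$nrmse * cv$mean_observed, cv$rmse, tolerance = 1e-12)

  # 3-interval uniform toy: training annual = observed/coverage, prediction =
  # annual * withheld mass; all by hand
  config1 <- toy_config(1)
  phen <- make_phen(config1, 1:10, cbind(rep(50, 10)))
  rates <- make_rates(c(1, 4, 7), c(3, 6, 9), c(10, 20, 30))
  cv1 <- kweek_crossval(rates, phen, c(L2 = 1), config1)
  folds <- tidy(cv1)
  # withhold interval 1: training observed = 2*20 + 2*30 = 100 over mass 0.4
  expect_equal(folds$predicted[1], (100 / 0.4) * 0.2, tolerance = 1e-12)
  expect_equal(folds$observed[1], 20, tolerance = 1e-12)
  # withhold interval 3: training observed = 2*10 + 2*20 = 60 over mass 0.4
  expect_equal(folds$predicted[3], (60 / 0.4) * 0.2, tolerance = 1e-12)

  # a withheld interval with zero F-mass predicts zero
  rates0 <- dplyr::bind_rows(make_rates(c(1, 4), c(3, 6), c(10, 20)),
                             make_rates(11, 12, 0))
  cv0 <- suppressWarnings(kweek_crossval(rates0, phen, c(L2 = 1), config1))
  f0 <- tidy(cv0)
  expect_equal(f0$predicted[f0$start_doy == 11], 0)

  # plots with a single interval are skipped with a warning
  single <- make_rates(1, 3, 10, plot_id = "S1")
  expect_warning(
    expect_error(kweek_crossval(single, make_phen(config1, 1:10,
                                                  cbind(rep(50, 10)),
                                                  plot_id = "S1"),
                                c(L2 = 1), config1),
                 class = "phenofrass_validation_error"),
    regexp = "single interval")
})

test_that("annual report summarizes totals by species and year", {
  results <- tibble::tibble(
    species = "Toyworm", plot_id = c("A", "B"), year = 2000L,
    channel = "frass", observed_total = c(90, 180),
    sampled_mass_fraction = 0.9, imputed_total = c(10, 20),
    annual_total = c(100, 200)
  )
  rep2 <- annual_report(results)
  expect_equal(rep2$mean_annual, 150)
  expect_equal(rep2$sd_annual, 70.7107, tolerance = 1e-4)
  expect_equal(rep2$n, 2L)

  one <- annual_report(results[1, ])
  expect_equal(one$mean_annual, 100)
  expect_equal(one$sd_annual, 0)

  expect_error(annual_report(results[0, ]), class = "phenofrass_validation_error")
  expect_error(annual_report(dplyr::select(results, -"species")),
               class = "phenofrass_validation_error")
})

test_that("imputation recovers true annual totals within statistical tolerance", {
  # 200 seeded replicates at 10% trap noise, sampling covering >= 50% of mass:
  # the median relative error stays within 5%, and the signed median within 1%
  rel_err <- numeric(0)
  for (i in 1:200) {
    st <- simulate_study("cpinus", n_plots = 2, noise_cv = 0.1, seed = 5000 + i)
    rates <- plot_interval_rates(st$records)
    ann <- estimate_annual(rates, st$phenology, st$true_weights, st$config)
    cmp <- dplyr::inner_join(ann, st$truth, by = c("plot_id", "year"))
    stopifnot(all(cmp$sampled_mass_fraction >= 0.5))
    rel_err <- c(rel_err, (cmp$annual_total - cmp$annual_frass) / cmp$annual_frass)
  }
  expect_lte(median(abs(rel_err)), 0.05)
  expect_lte(abs(median(rel_err)), 0.01)
})
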