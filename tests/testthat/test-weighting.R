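test_that("weighted larvae is the weight/percent dot product", {
  config <- toy_config(2)
  phen <- make_phen(config, 150:152,
                    rbind(c(0, 0), c(40, 60), c(100, 0)))
  w <- c(L2 = 0.5, L3 = 0.5)
  wl <- weighted_larvae(phen, w)
  expect_equal(wl$wl, c(0, 50, 50))
  one_hot <- weighted_larvae(phen, c(L2 = 1, L3 = 0), doy = 152)
  expect_equal(one_hot$wl, 100)
  expect_error(weighted_larvae(phen, w, doy = 999),
               class = "phenofrass_validation_error")
})

test_that("rmse and nrmse match hand arithmetic and their definitions", {
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(rmse(c(3, 4), c(0, 0)), 3.535534, tolerance = 1e-6)
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(nrmse(c(60, 40), c(50, 50)), rmse(c(60, 40), c(50, 50)) / 50)
  # RMSE 10 against mean(obs) 50 -> nRMSE 0.2
  expect_equal(nrmse(c(60, 60), c(50, 50)), 0.2)
  expect_error(nrmse(c(1, -1), c(1, -1)), class = "phenofrass_numerical_error")
  expect_error(rmse(1:3, 1:2), class = "phenofrass_parameter_error")
})

test_that("bell fit recovers exact curves and beats a grid-search oracle", {
  x <- seq(146, 174, by = 2)
  exact <- fit_bell(x, bell_curve(x, 2, 160, 8))
  expect_equal(unname(coef(exact)), c(2, 160, 8), tolerance = 1e-6)
  expect_true(exact$converged)

  # noisy series: residual sum of squares no worse than a 50x50x50 grid
  set.seed(12)
  y <- bell_curve(x, 3, 158, 6) + rnorm(length(x), 0, 0.2)
  y <- pmax(y, 0)
  fit <- fit_bell(x, y)
  grid_rss <- Inf
  as <- seq(max(y) / 2, 2 * max(y), length.out = 50)
  for (b in seq(min(x), max(x), length.out = 50)) {
    for (cc in seq(0.5, diff(range(x)), length.out = 50)) {
      g <- exp(-0.5 * ((x - b) / cc)^2)
      rss <- sum(y^2) - 2 * as * sum(y * g) + as^2 * sum(g^2)
      grid_rss <- min(grid_rss, rss)
    }
  }
  expect_lte(fit$rss, grid_rss + 1e-9)

  expect_error(fit_bell(c(1, 2), c(1, 2)), class = "phenofrass_validation_error")
  expect_error(fit_bell(1:5, rep(0, 5)), class = "phenofrass_validation_error")
})

test_that("noise-free synthetic data returns the true weights", {
  st <- simulate_study("cpinus", n_plots = 5, noise_cv = 0, seed = 3)
  rates <- plot_interval_rates(st$records)
  fit <- optimize_weights(rates, st$phenology, st$config)
  expect_lt(max(abs(fit$weights - st$true_weights)), 1e-3)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  expect_true(all(fit$weights >= 1e-6))
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-6)
  # negatively skewed truth: recovered consumption peaks at second-to-last instar
  expect_identical(names(which.max(fit$weights)), "L6")
})

test_that("optimizer matches an exhaustive simplex grid on 3-instar toys", {
  config <- toy_config()
  phen <- simulate_phenology(config, c(145, 155, 165, 175), 5, 130:190)
  set.seed(21)
  for (rep in 1:2) {
    w_true <- random_simplex(3)
    wl <- as.matrix(tibble::as_tibble(phen)[config$feeding_instars]) %*% w_true
    starts <- seq(140, 175, by = 5)
    pred <- sapply(seq_along(starts), function(i)
      mean(wl[match(starts[i]:(starts[i] + 4), phen$doy)]))
    noise <- exp(rnorm(length(pred), 0, 0.15))
    rates <- make_rates(starts, starts + 5, 0.5 * pred * noise)
    fit <- optimize_weights(rates, phen, config, n_starts = 4)
    best_grid <- Inf
    for (w1 in seq(0, 1, by = 0.01)) {
      for (w2 in seq(0, 1 - w1, by = 0.01)) {
        obj <- oracle_objective(c(w1, w2, 1 - w1 - w2), rates, phen, config)
        best_grid <- min(best_grid, obj)
      }
    }
    expect_lte(fit$objective, best_grid + 1e-9)
  }
})

test_that("weights are invariant to plot relabeling and per-plot rate scaling", {
  st <- simulate_study("cpinus", n_plots = 4, noise_cv = 0.1, seed = 17)
  rates <- plot_interval_rates(st$records)
  fit <- optimize_weights(rates, st$phenology, st$config, n_starts = 2)

  # permutation invariance: relabel plots consistently
  relabel <- setNames(paste0("Z", 4:1), sort(unique(rates$plot_id)))
  rates2 <- dplyr::mutate(rates, plot_id = unname(relabel[plot_id]))
  phen2 <- dplyr::mutate(tibble::as_tibble(st$phenology),
                         plot_id = unname(relabel[plot_id]))
  fit2 <- optimize_weights(rates2, phen2, st$config, n_starts = 2)
  expect_equal(fit2$objective, fit$objective, tolerance = 1e-9)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-6)

  # scale identifiability: scaling a plot's observed rates by k scales its
  # s_p by k and leaves the weights unchanged. Exact for a single-plot
  # dataset (the objective scales uniformly) ...
  k <- 3.7
  target <- sort(unique(rates$plot_id))[2]
  r1 <- rates[rates$plot_id == target, ]
  p1 <- tibble::as_tibble(st$phenology)
  p1 <- p1[p1$plot_id == target, ]
  fa <- optimize_weights(r1, p1, st$config, n_starts = 2)
  fb <- optimize_weights(dplyr::mutate(r1, frass_rate = k * frass_rate),
                         p1, st$config, n_starts = 2)
  expect_equal(fb$weights, fa$weights, tolerance = 1e-6)
  expect_equal(fb$plot_scales$scale, k * fa$plot_scales$scale,
               tolerance = 1e-6)

  # ... and in a multi-plot design wherever the model fits the data
  st0 <- simulate_study("cpinus", n_plots = 3, noise_cv = 0, seed = 18)
  r0 <- plot_interval_rates(st0$records)
  f0 <- optimize_weights(r0, st0$phenology, st0$config, n_starts = 2)
  r0k <- dplyr::mutate(r0, frass_rate = frass_rate *
                         ifelse(plot_id == "C02", k, 1))
  f0k <- optimize_weights(r0k, st0$phenology, st0$config, n_starts = 2)
  expect_equal(f0k$weights, f0$weights, tolerance = 1e-6)
  s_old <- f0$plot_scales$scale[f0$plot_scales$plot_id == "C02"]
  s_new <- f0k$plot_scales$scale[f0k$plot_scales$plot_id == "C02"]
  expect_equal(s_new, k * s_old, tolerance = 1e-6)
})

test_that("bell-smoothed mode runs and stays on the simplex", {
  st <- simulate_study("cpinus", n_plots = 2, noise_cv = 0.05, seed = 29)
  rates <- plot_interval_rates(st$records)
  fit <- optimize_weights(rates, st$phenology, st$config,
                          mode = "bell-smoothed", n_starts = 1, max_iter = 60)
  expect_equal(sum(fit$weights), 1, tolerance = 1e-6)
  expect_true(all(fit$weights >= 1e-6))
  expect_identical(fit$mode, "bell-smoothed")
})

test_that("leave-one-plot-out validation scores held-out plots correctly", {
  # noise-free: pooled RMSE is essentially zero
  st <- simulate_study("cpinus", n_plots = 3, noise_cv = 0, seed = 13)
  rates <- plot_interval_rates(st$records)
  cv <- loocv_weights(rates, st$phenology, st$config, n_starts = 2)
  expect_lt(cv$rmse, 1e-6)
  expect_equal(cv$n_folds, 3)

  # single-instar toy: the training fit is forced to w = 1, so every fold is
  # hand-computable from the closed-form scale s = sum(y*m)/sum(m^2)
  config1 <- toy_config(1)
  phen <- dplyr::bind_rows(
    make_phen(config1, 150:153, cbind(c(10, 20, 40, 20)), plot_id = "A"),
    make_phen(config1, 150:153, cbind(c(10, 20, 40, 20)), plot_id = "B")
  )
  phen <- as_phenology(phen, config1)
  rates <- dplyr::bind_rows(
    make_rates(c(150, 152), c(152, 154), c(16, 28), plot_id = "A"),
    make_rates(c(150, 152), c(152, 154), c(31, 62), plot_id = "B")
  )
  cv1 <- loocv_weights(rates, phen, config1, n_starts = 1)
  # fold A: m = (15, 30); s = (16*15 + 28*30)/(15^2 + 30^2) = 1080/1125
  sA <- 1080 / 1125
  rmseA <- sqrt(mean((sA * c(15, 30) - c(16, 28))^2))
  # fold B: s = (31*15 + 62*30)/1125 = 2325/1125
  sB <- 2325 / 1125
  rmseB <- sqrt(mean((sB * c(15, 30) - c(31, 62))^2))
  folds <- tidy(cv1)
  expect_equal(folds$rmse[folds$plot_id == "A"], rmseA, tolerance = 1e-8)
  expect_equal(folds$rmse[folds$plot_id == "B"], rmseB, tolerance = 1e-8)

  # definitional identity: pooled nRMSE * mean(observed) = pooled RMSE
  expect_equal(cv1$nrmse * cv1$mean_observed, cv1$rmse, tolerance = 1e-12)
  expect_error(loocv_weights(rates[rates$plot_id == "A", ],
                             phen[phen$plot_id == "A", ], config1),
               class = "phenofrass_validation_error")
})
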