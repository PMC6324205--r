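# Filtering rules, the constrained fit, and its oracles.

test_that("filters retain exactly the low-F, far-from-interface points", {
  positions <- c(0.04, 0.1, seq(0.12, 0.3, by = 0.02))
  pm <- theoretical_profile_set(tube_geometry(), d_eff = 1e-6,
                                frame_times = c(600, 3600),
                                positions = positions)
  pm$f[] <- 0.10
  pm$f[1, positions == 0.1] <- 0.30    # over the intensity ceiling
  pm$f[2, positions == 0.1] <- 0.20    # under it
  obs <- apply_filters(pm, filter_spec(min_points = 10))
  got <- paste(obs$time_s, obs$x_cm)
  expect_false("600 0.1" %in% got)     # F = 0.30 removed
  expect_true("3600 0.1" %in% got)     # F = 0.20 retained
  expect_false(any(obs$x_cm == 0.04))  # distance rule
  counts <- attr(obs, "counts")
  expect_equal(counts$retained + counts$removed,
               rep(length(positions), 2L))
  expect_equal(counts$retained, c(10L, 11L))
  # uniformly bright matrix: nothing survives
  pm$f[] <- 0.9
  expect_error(apply_filters(pm), "insufficient filtered data")
})

test_that("noise-free observations identify the coefficient to 0.5%", {
  pm <- theoretical_profile_set(tube_geometry(), d_eff = 1e-6,
                                frame_times = seq(240, 7200, by = 240))
  fit <- fit_deff(pm)
  expect_lt(abs(fit$d_eff - 1e-6) / 1e-6, 0.005)
  expect_true(fit$converged)
  expect_false(fit$at_bound)
  expect_equal(unname(coef(fit)["d_eff"]), fit$d_eff)
})

test_that("the optimizer matches the exhaustive grid-search oracle", {
  d_vals <- c(5e-7, 1e-6, 1.5e-6, 8e-7, 2e-6)
  for (seed in 1:5) {
    obs <- make_observations(d_true = d_vals[seed], seed = seed)
    fit <- fit_deff(obs)
    oracle <- fit_deff_grid(obs, bounds = c(1e-9, 1e-4), n_grid = 400)
    step <- log10(oracle$grid[2] / oracle$grid[1])
    expect_lt(abs(log10(fit$d_eff / oracle$d_eff)), step)
  }
})

test_that("the SSR landscape is unimodal with its minimum at the truth", {
  obs <- make_observations(2e-6, seed = 3, sigma = 0)
  g <- fit_deff_grid(obs, n_grid = 200)
  i_min <- which.min(g$ssr_values)
  expect_lt(abs(log10(g$grid[i_min] / 2e-6)), log10(g$grid[2] / g$grid[1]))
  expect_true(all(diff(g$ssr_values[seq_len(i_min)]) <= 1e-12))
  expect_true(all(diff(g$ssr_values[i_min:length(g$ssr_values)]) >= -1e-12))
})

test_that("the fit is invariant to observation order", {
  obs <- make_observations(1e-6, seed = 8)
  fit1 <- fit_deff(obs)
  set.seed(1)
  fit2 <- fit_deff(obs[sample(nrow(obs)), ])
  expect_equal(fit2$d_eff, fit1$d_eff, tolerance = 1e-10)
})

test_that("estimates at a search bound raise a warning", {
  obs <- make_observations(1e-6, seed = 2, sigma = 0)
  expect_warning(fit <- fit_deff(obs, bounds = c(1e-5, 1e-4)), "bound")
  expect_true(fit$at_bound)
})

test_that("the contact-time offset can be co-estimated", {
  true_t0 <- 700
  times_nominal <- 240 + (0:14) * 480
  obs <- expand.grid(x_cm = seq(0.055, 0.25, by = 0.005),
                     time_s = times_nominal)
  obs$f <- erfc_profile(obs$x_cm, obs$time_s - 240 + true_t0, 1e-6)
  obs <- obs[obs$f < 0.25, ]
  attr(obs, "t_offset") <- 240
  fit <- fit_deff(obs, t_offset_mode = "fit")
  expect_equal(unname(coef(fit)["t_offset"]), true_t0, tolerance = 0.1)
  expect_lt(abs(fit$d_eff - 1e-6) / 1e-6, 0.01)
})

test_that("full-pipeline recovery sweep stays within the accuracy bands", {
  bm <- run_recovery_benchmark(d_true = c(4e-7, 1e-6, 2e-6), seeds = 1:10)
  expect_equal(nrow(bm), 30L)
  expect_lt(median(abs(bm$rel_error)), 0.05)
  expect_lt(max(abs(bm$rel_error)), 0.15)
  expect_true(all(bm$converged))
})

test_that("filtering improves accuracy on saturated data", {
  b <- render_stack(tube_geometry(), imaging_config(), d_eff = 1.73e-6,
                    noise = noise_model(0.01, 0, 7),
                    sat = saturation_map(enabled = TRUE))
  pm <- extract_profiles(b)
  filtered <- fit_deff(pm)
  unfiltered <- fit_deff(pm, filter = filter_spec(max_f = 1, min_x = 0))
  err_f <- abs(filtered$d_eff - 1.73e-6) / 1.73e-6
  err_u <- abs(unfiltered$d_eff - 1.73e-6) / 1.73e-6
  expect_lt(err_f, err_u)
})

test_that("fit objects expose the standard modelling methods", {
  obs <- make_observations(1e-6, seed = 4)
  fit <- fit_deff(obs)
  expect_s3_class(fit, "deff_fit")
  expect_output(print(fit), "D_eff")
  expect_output(print(summary(fit)), "RMSE")
  expect_equal(length(residuals(fit)), nrow(obs))
  expect_lt(sd(residuals(fit)), 0.01)
  nd <- data.frame(x_cm = c(0, 0.1), time_s = c(100, 3600))
  pr <- predict(fit, nd)
  expect_equal(pr[1], 1)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(obs), 3L))
  expect_identical(simulate(fit, nsim = 2, seed = 5),
                   simulate(fit, nsim = 2, seed = 5))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("similarity predictions propagate converged references only", {
  obs <- make_observations(1e-6, seed = 6)
  fit <- fit_deff(obs)
  pred <- predict_deff_by_similarity(fit, protein = "BMP-2",
                                     note = "matched MW and pI")
  expect_equal(pred$d_eff, fit$d_eff)
  expect_match(pred$provenance, "similarity")
  expect_error(predict_deff_by_similarity(), "required")
  broken <- fit; broken$converged <- FALSE
  expect_error(predict_deff_by_similarity(broken), "converge")
  # a prediction can be checked against an independent fit
  fit2 <- fit_deff(make_observations(1e-6, seed = 7))
  cmp <- chisq_profile_test(
    erfc_profile(seq(0.06, 0.3, 0.01), 3600, fit2$d_eff),
    erfc_profile(seq(0.06, 0.3, 0.01), 3600, pred$d_eff))
  expect_s3_class(cmp, "profile_comparison")
  expect_gt(cmp$p_value, 0.9)
})
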