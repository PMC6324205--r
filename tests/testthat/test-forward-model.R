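# Analytic erfc profile and the Crank-Nicolson verification solver.

test_that("erfc profile matches the quadrature oracle and its limits", {
  # x = 0 is the reservoir boundary: exactly 1 for any t, D
  for (d in c(1e-7, 1e-6, 2e-6))
    expect_identical(erfc_profile(0, t = 240, d_eff = d), 1)
  # argument = 1: x = 2*sqrt(D*t)
  for (case in list(c(1e-6, 3600), c(4e-7, 240), c(2e-6, 7200))) {
    d <- case[1]; tt <- case[2]
    expect_equal(erfc_profile(2 * sqrt(d * tt), tt, d),
                 erfc_quadrature(1), tolerance = 1e-7)
  }
  expect_equal(erfc_quadrature(1), 0.15730, tolerance = 1e-4)
  # argument = 5: effectively the zero limit
  expect_lt(erfc_profile(5 * 2 * sqrt(1e-6 * 3600), 3600, 1e-6), 2e-12)
  expect_lt(abs(erfc_profile(5 * 2 * sqrt(1e-6 * 3600), 3600, 1e-6) -
                  erfc_quadrature(5)), 1e-13)
})

test_that("erfc profile rejects invalid parameters", {
  expect_error(erfc_profile(0.1, t = 0, d_eff = 1e-6), "positive")
  expect_error(erfc_profile(0.1, t = -5, d_eff = 1e-6), "positive")
  expect_error(erfc_profile(0.1, t = 100, d_eff = 0), "d_eff")
  expect_error(erfc_profile(0.1, t = 100, d_eff = -1e-6), "d_eff")
  expect_error(erfc_profile(-0.1, t = 100, d_eff = 1e-6), "non-negative")
})

test_that("erfc profile is monotone in x and t", {
  x <- seq(0, 0.3, by = 0.01)
  f <- erfc_profile(x, 3600, 1e-6)
  expect_true(all(diff(f) < 0))
  for (xx in c(0.01, 0.1, 0.25)) {
    ft <- vapply(c(240, 1200, 3600, 7200),
                 function(tt) erfc_profile(xx, tt, 1e-6), numeric(1))
    expect_true(all(diff(ft) > 0))
  }
})

test_that("profiles collapse onto one curve under sqrt(D*t) rescaling", {
  z <- seq(0.05, 3, by = 0.05)
  pairs <- list(c(4e-7, 600), c(1e-6, 3600), c(2e-6, 7200), c(8.65e-7, 1800))
  vals <- lapply(pairs, function(p) erfc_profile(z * 2 * sqrt(p[1] * p[2]),
                                                 p[2], p[1]))
  for (i in 2:length(vals))
    expect_equal(vals[[i]], vals[[1]], tolerance = 1e-12)
})

test_that("finite-difference solution agrees with the analytic model", {
  geo <- tube_geometry()
  fld <- solve_diffusion_fd(geo, d_eff = 2e-6,
                            output_times = c(240, 3600, 7200))
  for (i in seq_along(fld$times)) {
    expect_lt(max(abs(fld$values[i, ] -
                        erfc_profile(fld$positions, fld$times[i], 2e-6))),
              1e-3)
  }
  # C(0, t) = 1, values in [0, 1], monotone non-increasing in x
  expect_true(all(fld$values[, 1] == 1))
  expect_true(all(fld$values >= 0 & fld$values <= 1))
  expect_true(all(apply(fld$values, 1, function(v) all(diff(v) <= 1e-12))))
})

test_that("vanishing diffusivity leaves the interior empty", {
  fld <- solve_diffusion_fd(tube_geometry(), d_eff = 1e-15,
                            output_times = c(60, 120),
                            grid = grid_spec(dx = 0.05, dt = 10))
  expect_true(all(fld$values[, 1] == 1))
  expect_lt(max(fld$values[, -1]), 1e-6)
})

test_that("solute mass increases and matches the integrated boundary flux", {
  fld <- solve_diffusion_fd(tube_geometry(), d_eff = 2e-6,
                            output_times = seq(600, 7200, by = 600),
                            grid = grid_spec(dx = 20e-4, dt = 5))
  cons <- fld$conservation
  expect_true(all(diff(cons$mass) > 0))
  expect_true(all(abs(cons$mass - cons$flux_integral) <=
                    1e-3 * cons$mass))
})

test_that("halving dx and dt reduces the error at second order", {
  geo <- tube_geometry()
  err <- function(dx, dt) {
    fld <- solve_diffusion_fd(geo, d_eff = 2e-6, output_times = 3600,
                              grid = grid_spec(dx = dx, dt = dt))
    max(abs(fld$values[1, ] - erfc_profile(fld$positions, 3600, 2e-6)))
  }
  e1 <- err(0.02, 120)
  e2 <- err(0.01, 60)
  ratio <- e1 / e2
  expect_gt(ratio, 4 * 0.8)
  expect_lt(ratio, 4 * 1.2)
})

test_that("larger diffusivity dominates pointwise", {
  geo <- tube_geometry()
  g <- grid_spec(dx = 50e-4, dt = 30)
  base <- solve_diffusion_fd(geo, 4e-7, output_times = c(1200, 7200), grid = g)
  for (ratio in c(2, 10)) {
    fast <- solve_diffusion_fd(geo, 4e-7 * ratio,
                               output_times = c(1200, 7200), grid = g)
    expect_true(all(fast$values - base$values >= -1e-10))
  }
})

test_that("solver validates its grid and output times", {
  geo <- tube_geometry()
  expect_error(solve_diffusion_fd(geo, 1e-2, output_times = 100,
                                  grid = grid_spec(dx = 1e-4, dt = 100)),
               "diffusion number")
  expect_error(solve_diffusion_fd(geo, 1e-6, output_times = 125,
                                  grid = grid_spec(dx = 0.05, dt = 10)),
               "multiple")
  expect_error(grid_spec(dx = -1), "dx")
})

test_that("theoretical profile sets match their backends and lattices", {
  geo <- tube_geometry()
  th <- theoretical_profile_set(geo, d_eff = 1e-6,
                                frame_times = c(240, 3600))
  for (i in 1:2)
    expect_equal(th$f[i, ], erfc_profile(th$positions, th$times[i], 1e-6),
                 tolerance = 1e-14)
  num <- theoretical_profile_set(geo, d_eff = 2e-6,
                                 frame_times = c(240, 3600),
                                 backend = "numeric",
                                 grid = grid_spec(dx = 10e-4, dt = 2))
  ana <- theoretical_profile_set(geo, d_eff = 2e-6,
                                 frame_times = c(240, 3600),
                                 positions = num$positions)
  expect_lt(max(abs(num$f - ana$f)), 1e-3)
  # the two-time-point kymograph presentation (4 and 60 min)
  th2 <- theoretical_profile_set(geo, d_eff = 1e-6,
                                 frame_times = c(240, 3600))
  expect_identical(th2$times, c(240, 3600))
  expect_error(theoretical_profile_set(geo, 1e-6, frame_times = c(3600, 240)),
               "increasing")
  pm_like <- theoretical_profile_set(geo, 1e-6, frame_times = c(240, 480))
  expect_error(theoretical_profile_set(geo, 1e-6, frame_times = c(240, 480),
                                       like = pm_like),
               "not both")
})

test_that("concentration fields round-trip through CSV + JSON", {
  fld <- solve_diffusion_fd(tube_geometry(), 1e-6, output_times = c(600, 1200),
                            grid = grid_spec(dx = 0.05, dt = 60))
  csv <- file.path(tempdir(), "field.csv")
  write_concentration_field(fld, csv)
  back <- read_concentration_field(csv)
  expect_equal(back$values, unname(fld$values), tolerance = 1e-12)
  expect_equal(back$positions, fld$positions)
  expect_equal(back$backend, "numeric")
  unlink(c(csv, sub("csv$", "json", csv)))
})
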