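# ROI extraction, interface detection and reservoir normalization.

test_that("raw extraction averages across the configured width", {
  stack <- array(0L, dim = c(2, 10, 20))
  stack[1, , ] <- 500L
  stack[2, , ] <- 700L
  roi <- roi_spec(c(0, 5), c(19, 5), averaging_width = 3,
                  reservoir_window = c(0, 3))
  raw <- extract_raw_profiles(stack, roi)
  expect_equal(dim(raw), c(2L, 20L))
  expect_true(all(raw[1, ] == 500))
  expect_true(all(raw[2, ] == 700))
  # width 1 equals the single-pixel line read
  stack[1, 6, ] <- seq_len(20)
  roi1 <- roi_spec(c(0, 5), c(19, 5), averaging_width = 1,
                   reservoir_window = c(0, 3))
  expect_equal(as.vector(extract_raw_profiles(stack, roi1)[1, ]),
               as.numeric(seq_len(20)))
  expect_error(extract_raw_profiles(stack,
                                    roi_spec(c(0, 9), c(25, 9), 1, c(0, 3))),
               "outside")
  expect_error(roi_spec(c(0, 1), c(10, 4), 1, c(0, 3)), "horizontal")
})

test_that("noise-free extraction reproduces the generator's column values", {
  b <- mini_bundle(d_eff = 1e-6, sigma = 0, n_frames = 4)
  img <- b$config$imaging
  raw <- extract_raw_profiles(b$stack,
                              roi_spec(c(0, 60), c(699, 60), 40, c(5, 80)))
  res_dn <- img$reservoir_fraction * (2^img$bit_depth - 1)
  bg <- img$background_level
  x <- (seq_len(600) - 0.5) * img$pixel_size * 1e-4
  t3 <- b$truth$t_offset + 2 * img$frame_interval
  expected <- round((bg + (1 - bg) * erfc_profile(x, t3, 1e-6)) * res_dn)
  expect_equal(as.vector(raw[3, -(1:100)]), as.vector(expected))
})

test_that("interface detection: step crossing, model fit, failure modes", {
  p <- c(rep(1, 100), rep(0, 100))
  expect_equal(as.numeric(detect_interface(p, method = "crossing")), 99.5)
  expect_error(detect_interface(rep(1, 50)), "interface not found")
  # on a diffused synthetic first frame the model method stays within 2 px
  for (d in c(4.38e-7, 1.73e-6)) {
    b <- mini_bundle(d_eff = d, seed = 17, sigma = 0.01, n_frames = 2)
    pm <- extract_profiles(b)
    expect_lt(abs(pm$interface_px - b$truth$interface_x_px), 2)
    # the plain 0.5-crossing is biased into the gel by ~ sqrt(D t0)
    raw <- extract_raw_profiles(b$stack,
                                roi_spec(c(0, 60), c(699, 60), 96, c(5, 80)))
    cross <- detect_interface(raw[1, ], method = "crossing",
                              background = pm$background,
                              reservoir = pm$normalization_value)
    expect_gt(as.numeric(cross), b$truth$interface_x_px + 5)
  }
})

test_that("normalization maps reservoir to 1, background to 0, erfc to F", {
  b <- mini_bundle(d_eff = 1e-6, sigma = 0, n_frames = 6)
  pm <- extract_profiles(b)
  img <- b$config$imaging
  raw <- extract_raw_profiles(b$stack,
                              roi_spec(c(0, 60), c(699, 60), 96, c(5, 80)))
  res_dn <- img$reservoir_fraction * (2^img$bit_depth - 1)
  expect_equal(pm$normalization_value / res_dn, 1, tolerance = 1e-3)
  # F at the argument = 1 position/time equals erfc(1)
  for (k in c(2, 6)) {
    x_star <- 2 * sqrt(1e-6 * pm$times[k])
    j <- which.min(abs(pm$positions - x_star))
    expect_lt(abs(pm$f[k, j] - 0.15730), 0.002)
  }
  # far-field gel is at background: F ~ 0
  expect_lt(max(pm$f[1, pm$positions > 0.25]), 1e-3)
  # times carry the contact offset
  expect_equal(pm$times, 240 + (0:5) * img$frame_interval)
})

test_that("position axis spans the field of view within one pixel", {
  b <- mini_bundle(n_frames = 2)
  pm <- extract_profiles(b)
  px_cm <- b$config$imaging$pixel_size * 1e-4
  fov_cm <- b$config$geometry$field_of_view * 0.1
  expect_lt(abs(ncol(pm$f) * px_cm - fov_cm), 2 * px_cm)
  expect_true(all(diff(pm$positions) > 0))
  expect_true(all(pm$f >= 0))
})

test_that("normalization is invariant to global linear intensity rescaling", {
  b <- mini_bundle(d_eff = 1e-6, seed = 9, sigma = 0.01, n_frames = 3)
  roi <- roi_spec(c(0, 60), c(699, 60), 96, c(5, 80))
  raw <- extract_raw_profiles(b$stack, roi)
  gain <- 3.7
  raw2 <- raw * gain
  attr(raw2, "coords") <- attr(raw, "coords")
  pm1 <- normalize_profiles(raw, roi, pixel_size = 5, frame_interval = 240)
  pm2 <- normalize_profiles(raw2, roi, pixel_size = 5, frame_interval = 240)
  expect_equal(pm2$f, pm1$f, tolerance = 1e-10)
  expect_equal(pm2$interface_px, pm1$interface_px, tolerance = 1e-6)
})

test_that("reservoir drift beyond 5% triggers the constancy warning", {
  b <- mini_bundle(sigma = 0, n_frames = 4)
  roi <- roi_spec(c(0, 60), c(699, 60), 96, c(5, 80))
  raw <- extract_raw_profiles(b$stack, roi)
  drifting <- raw * c(1, 0.99, 0.95, 0.90)
  attr(drifting, "coords") <- attr(raw, "coords")
  expect_warning(normalize_profiles(drifting, roi, pixel_size = 5,
                                    frame_interval = 240),
                 "drift")
  expect_silent(pmref <- normalize_profiles(raw, roi, pixel_size = 5,
                                            frame_interval = 240))
})

test_that("an explicit interface override is honoured", {
  b <- mini_bundle(sigma = 0, n_frames = 2)
  pm <- extract_profiles(b, interface = 99.5)
  expect_equal(pm$interface_px, 99.5)
  expect_equal(pm$meta$interface_method, "override")
})

test_that("profile matrices round-trip through wide CSV + JSON", {
  b <- mini_bundle(sigma = 0, n_frames = 3)
  pm <- extract_profiles(b)
  csv <- file.path(tempdir(), "pm.csv")
  write_profile_matrix(pm, csv)
  back <- read_profile_matrix(csv)
  expect_equal(unname(back$f), unname(pm$f), tolerance = 1e-6)
  expect_equal(back$times, pm$times)
  expect_equal(back$positions, pm$positions, tolerance = 1e-6)
  expect_equal(back$t_offset, pm$t_offset)
  unlink(c(csv, sub("csv$", "json", csv)))
})
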