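# Shared fixtures: a reduced-size synthetic experiment (coarser pixels,
# fewer frames) keeps unit tests fast while exercising the full pipeline.
# Acceptance tests use the full default configuration.

mini_geometry <- function() tube_geometry()

mini_imaging <- function(n_frames = 8, pixel_size = 5) {
  imaging_config(pixel_size = pixel_size, n_frames = n_frames,
                 reservoir_pixels = 100)
}

mini_bundle <- function(d_eff = 1e-6, seed = 1, sigma = 0.01,
                        n_frames = 8, sat = saturation_map(),
                        t_offset = 240) {
  render_stack(mini_geometry(), mini_imaging(n_frames), d_eff = d_eff,
               t_offset = t_offset, noise = noise_model(sigma, 0, seed),
               sat = sat)
}

# independent erfc oracle: numerical quadrature of the Gaussian tail
erfc_quadrature <- function(z) {
  2 / sqrt(pi) * stats::integrate(function(u) exp(-u^2), z, Inf,
                                  rel.tol = 1e-12)$value
}

# synthetic filtered observation sets generated directly from the model
# (no imaging), for fitter-only tests
make_observations <- function(d_true, seed, sigma = 0.005,
                              times = seq(240, 7200, by = 480),
                              x = seq(0.055, 0.295, by = 0.005)) {
  set.seed(seed)
  df <- expand.grid(x_cm = x, time_s = times)
  df$f <- pmax(erfc_profile(df$x_cm, df$time_s, d_true) +
                 rnorm(nrow(df), sd = sigma), 0)
  df <- df[df$f < 0.25, , drop = FALSE]
  df
}
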