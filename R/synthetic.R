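# Seeded synthetic fluorescence stacks of capillary-tube experiments.
# The renderer inverts exactly: with noise and saturation off, extracting
# and normalizing a rendered stack recovers the generating erfc profile to
# quantization.

#' Concentration-to-intensity response
#'
#' Applies a [saturation_map()] to normalized concentrations: identity
#' below the linear limit, smooth compression above (see
#' [saturation_map()] for the law).  The map is strictly increasing and
#' continuous with continuous slope at the knee; when the map is disabled
#' it is the identity everywhere.
#'
#' @param c_norm Normalized concentrations in `[0, 1]`.
#' @param sat A [saturation_map()].
#' @return Normalized intensities, same length as `c_norm`.
#' @examples
#' intensity_map(c(0.1, 0.5, 1), saturation_map(enabled = TRUE))
#' @export
intensity_map <- function(c_norm, sat = saturation_map()) {
  stopifnot(inherits(sat, "saturation_map"))
  if (!is.numeric(c_norm) || any(!is.finite(c_norm)) ||
      any(c_norm < 0) || any(c_norm > 1))
    stop_invalid("'c_norm' must lie in [0, 1]")
  if (!sat$enabled) return(c_norm)
  a <- sat$linear_limit
  g <- sat$compression
  out <- c_norm
  hi <- c_norm > a
  if (any(hi)) {
    u <- (c_norm[hi] - a) / (1 - a)
    out[hi] <- a + (1 - a) * (1 - exp(-g * u)) / g
  }
  out
}

#' Render a synthetic capillary-tube image stack
#'
#' Renders a seeded multi-frame grayscale image stack of one
#' hydrogel-filled capillary with the protein reservoir at the left edge.
#' Frame `k` (0-indexed) shows the state at `t = t_offset +
#' k * frame_interval` seconds after protein--hydrogel contact: reservoir
#' columns at constant reservoir intensity, gel columns following
#' [erfc_profile()] mapped through [intensity_map()], everything scaled to
#' the detector's bit depth, Gaussian (and optional Poisson) noise added,
#' and values clipped to the valid range.  The tube renders with uniform
#' intensity across its apparent width; rows above and below it stay at the
#' background level.
#'
#' The returned bundle carries the full ground truth, so a stack is
#' bit-reproducible from its metadata: the same seed gives the identical
#' stack.
#'
#' @param geometry A [tube_geometry()].
#' @param imaging An [imaging_config()].
#' @param d_eff True effective diffusion coefficient, cm^2/s.
#' @param t_offset Seconds between protein--hydrogel contact and the first
#'   frame (>= 0); default 240 s (first frame taken 4 min after contact).
#' @param noise A [noise_model()].
#' @param sat A [saturation_map()].
#' @return An object of class `"stack_bundle"`: list with `stack` (integer
#'   array, frames x rows x columns), `truth` (d_eff, t_offset,
#'   interface_x_px, seed, noise, saturation) and `config` (geometry +
#'   imaging).  `interface_x_px` is in 0-based pixel-index coordinates:
#'   the interface lies half a pixel left of the first gel column.
#' @examples
#' b <- render_stack(tube_geometry(), imaging_config(n_frames = 3),
#'                   d_eff = 1e-6, noise = noise_model(seed = 7))
#' dim(b$stack)
#' @export
render_stack <- function(geometry, imaging, d_eff, t_offset = 240,
                         noise = noise_model(), sat = saturation_map()) {
  stopifnot(inherits(geometry, "tube_geometry"),
            inherits(imaging, "imaging_config"),
            inherits(noise, "noise_model"),
            inherits(sat, "saturation_map"))
  check_scalar(d_eff, "d_eff")
  check_scalar(t_offset, "t_offset", allow_zero = TRUE)

  px_um <- imaging$pixel_size
  n_gel <- as.integer(round(geometry$field_of_view * 1000 / px_um))
  n_res <- imaging$reservoir_pixels
  if (n_res * px_um > geometry$reservoir_length * 1000)
    stop_invalid(paste0("geometry error: rendered reservoir (%d px = %g mm) ",
                        "is longer than the physical reservoir (%g mm)"),
                 n_res, n_res * px_um / 1000, geometry$reservoir_length)
  width <- n_res + n_gel
  tube_px <- as.integer(round(geometry$inner_diameter / px_um))
  if (tube_px < 1L)
    stop_invalid("geometry error: tube diameter below one pixel")
  height <- tube_px + 2L * imaging$margin_px
  tube_rows <- imaging$margin_px + seq_len(tube_px)

  max_dn <- 2^imaging$bit_depth - 1
  res_dn <- imaging$reservoir_fraction * max_dn
  bg <- imaging$background_level
  px_cm <- um_to_cm(px_um)
  x_gel <- (seq_len(n_gel) - 0.5) * px_cm   # gel column centres, cm

  # preserve the caller's RNG state; the stack is seeded from the model
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(noise$seed)

  nf <- imaging$n_frames
  stack <- array(0L, dim = c(nf, height, width))
  for (k in seq_len(nf)) {
    t_k <- t_offset + (k - 1L) * imaging$frame_interval
    conc <- c(rep(1, n_res),
              if (t_k > 0) erfc_profile(x_gel, t_k, d_eff) else numeric(n_gel))
    inten <- intensity_map(conc, sat)
    mu <- matrix(bg, height, width)
    mu[tube_rows, ] <- rep(bg + (1 - bg) * inten, each = length(tube_rows))
    if (noise$poisson_scale > 0) {
      lam <- mu * noise$poisson_scale
      mu <- matrix(rpois(length(lam), lam) / noise$poisson_scale,
                   height, width)
    }
    dn <- mu * res_dn
    if (noise$gaussian_sigma > 0)
      dn <- dn + rnorm(length(dn), sd = noise$gaussian_sigma * res_dn)
    stack[k, , ] <- as.integer(pmin(pmax(round(dn), 0), max_dn))
  }

  structure(list(
    stack = stack,
    truth = list(d_eff = d_eff, t_offset = t_offset,
                 interface_x_px = n_res - 0.5, seed = noise$seed,
                 noise = unclass(noise), saturation = unclass(sat)),
    config = list(geometry = geometry, imaging = imaging)),
    class = "stack_bundle")
}

#' @export
print.stack_bundle <- function(x, ...) {
  d <- dim(x$stack)
  cat("Synthetic capillary stack bundle\n")
  cat(sprintf("  %d frames, %d x %d px, %d-bit\n", d[1], d[2], d[3],
              x$config$imaging$bit_depth))
  cat(sprintf("  true D_eff = %.4g cm^2/s, t_offset = %g s, seed = %d\n",
              x$truth$d_eff, x$truth$t_offset, x$truth$seed))
  invisible(x)
}

#' Write / read a stack bundle
#'
#' A bundle is stored as a multi-page grayscale TIFF (`<path>.tif`) plus a
#' JSON sidecar (`<path>.json`) holding ground truth, configuration and
#' array dimensions.  The round trip is bit-exact.
#'
#' @param bundle A `"stack_bundle"`.
#' @param path Path prefix (without extension).
#' @return `write_bundle()` returns `path` invisibly; `read_bundle()`
#'   returns the reconstructed bundle.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "stack_bundle"))
  d <- dim(bundle$stack)
  max_dn <- 2^bundle$config$imaging$bit_depth - 1
  pages <- lapply(seq_len(d[1]),
                  function(k) bundle$stack[k, , ] / max_dn)
  tiff::writeTIFF(pages, paste0(path, ".tif"),
                  bits.per.sample = bundle$config$imaging$bit_depth,
                  compression = "none", reduce = FALSE)
  meta <- list(truth = bundle$truth,
               config = list(geometry = unclass(bundle$config$geometry),
                             imaging = unclass(bundle$config$imaging)),
               dim = d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  tif <- paste0(path, ".tif")
  json <- paste0(path, ".json")
  if (!file.exists(tif))
    stop_invalid("stack file not found: '%s'", tif)
  if (!file.exists(json))
    stop_invalid("missing JSON sidecar: '%s'", json)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)
  imaging <- do.call(imaging_config, as.list(meta$config$imaging))
  geometry <- do.call(tube_geometry, as.list(meta$config$geometry))
  pages <- tiff::readTIFF(tif, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dim)
  if (length(pages) != d[1] || !all(dim(pages[[1]]) == d[2:3]))
    stop_invalid(paste0("stack shape mismatch: sidecar records %d x %d x %d ",
                        "but TIFF holds %d pages of %d x %d"),
                 d[1], d[2], d[3], length(pages),
                 dim(pages[[1]])[1], dim(pages[[1]])[2])
  stack <- array(0L, dim = d)
  for (k in seq_len(d[1])) stack[k, , ] <- as.integer(pages[[k]])
  truth <- meta$truth
  truth$noise <- as.list(truth$noise)
  truth$saturation <- as.list(truth$saturation)
  structure(list(stack = stack, truth = truth,
                 config = list(geometry = geometry, imaging = imaging)),
            class = "stack_bundle")
}
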