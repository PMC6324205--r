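# From image stack to reservoir-normalized profile matrix.
#
# Pixel coordinates are 0-based: a profile sample from column j of the
# image sits at axial coordinate j - 1 + roi offset.  The interface
# position returned by detect_interface() uses the same coordinates, so a
# sharp step between columns at coordinates 99 and 100 yields 99.5.

#' Region of interest for profile extraction
#'
#' A line through the long axis of the tube, an averaging width
#' perpendicular to it, and the axial pixel range of the reservoir used
#' for normalization.  Only horizontal axis lines (constant row) are
#' supported; rotate the stack first if the tube is not axis-aligned.
#'
#' @param axis_start,axis_end `c(column, row)` pixel coordinates (0-based)
#'   of the line ends; rows must be equal and `axis_end` to the right.
#' @param averaging_width Rows averaged perpendicular to the axis (>= 1).
#' @param reservoir_window `c(lo, hi)` axial coordinate range (0-based,
#'   inclusive) of reservoir pixels used for normalization; must lie on
#'   the reservoir side of the interface.
#' @return An object of class `"roi_spec"`.
#' @examples
#' roi_spec(c(0, 120), c(1399, 120), averaging_width = 180,
#'          reservoir_window = c(5, 180))
#' @export
roi_spec <- function(axis_start, axis_end, averaging_width = 1,
                     reservoir_window) {
  if (length(axis_start) != 2L || length(axis_end) != 2L)
    stop_invalid("axis ends must be c(column, row) pixel coordinates")
  if (axis_start[2] != axis_end[2])
    stop_invalid("axis line must be horizontal (equal rows); rotate the stack otherwise")
  if (axis_end[1] <= axis_start[1])
    stop_invalid("axis_end must lie to the right of axis_start")
  if (averaging_width < 1 || averaging_width != round(averaging_width))
    stop_invalid("'averaging_width' must be an integer >= 1")
  if (length(reservoir_window) != 2L || reservoir_window[1] > reservoir_window[2])
    stop_invalid("'reservoir_window' must be c(lo, hi) with lo <= hi")
  structure(list(axis_start = as.numeric(axis_start),
                 axis_end = as.numeric(axis_end),
                 averaging_width = as.integer(averaging_width),
                 reservoir_window = as.numeric(reservoir_window)),
            class = "roi_spec")
}

#' Extract raw axial intensity profiles
#'
#' For each frame, averages the image over `averaging_width` rows centred
#' on the ROI axis at every axial pixel, producing a frames x positions
#' matrix of raw intensities.  Column coordinates (0-based, image frame)
#' are attached as attribute `"coords"`.
#'
#' @param stack A `"stack_bundle"` or an integer array
#'   (frames x rows x columns).
#' @param roi An [roi_spec()].
#' @return Raw intensity matrix (frames x axial pixels) with attributes
#'   `coords` and `roi`.
#' @export
extract_raw_profiles <- function(stack, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  if (inherits(stack, "stack_bundle")) stack <- stack$stack
  if (!is.array(stack) || length(dim(stack)) != 3L)
    stop_invalid("'stack' must be a frames x rows x columns array")
  d <- dim(stack)
  cols <- seq(roi$axis_start[1], roi$axis_end[1])       # 0-based
  row_c <- roi$axis_start[2]
  half_lo <- floor((roi$averaging_width - 1) / 2)
  rows <- seq(row_c - half_lo, length.out = roi$averaging_width)  # 0-based
  if (min(cols) < 0 || max(cols) > d[3] - 1 ||
      min(rows) < 0 || max(rows) > d[2] - 1)
    stop_invalid("ROI extends outside the image (%d x %d px)", d[2], d[3])
  out <- matrix(NA_real_, d[1], length(cols))
  for (k in seq_len(d[1])) {
    sub <- stack[k, rows + 1L, cols + 1L, drop = FALSE]
    out[k, ] <- colMeans(matrix(sub, length(rows), length(cols)))
  }
  attr(out, "coords") <- cols
  attr(out, "roi") <- roi
  out
}

#' Locate the protein--hydrogel interface
#'
#' Finds the interface position (0-based pixel coordinate, sub-pixel) from
#' the first frame's profile.  Two methods:
#'
#' * `"crossing"`: sub-pixel location where the normalized profile first
#'   crosses 0.5 going down, by linear interpolation between the
#'   bracketing pixels.  Exact for a sharp step, but biased towards the
#'   gel when the first frame is already diffused: the 0.5 level of an
#'   erfc profile sits `0.954 * sqrt(D * t0)` past the true interface.
#' * `"model"` (default): fits the frame-0 profile to a reservoir plateau
#'   followed by an erfc decay, `F(p) = erfc((p - x0)/s)` for `p > x0`
#'   and 1 before, by least squares over a window around the crossing;
#'   `x0` locates the interface without the diffusion bias.
#'
#' @param profile Raw first-frame intensity profile (vector).
#' @param coords 0-based pixel coordinates of the samples.
#' @param method `"model"` or `"crossing"`.
#' @param background Raw background intensity subtracted before
#'   normalization.
#' @param reservoir Raw reservoir intensity defining level 1; default is
#'   the mean of the first 5% of samples.
#' @return Interface position (0-based px, numeric scalar), strictly
#'   inside the profile.  For `"model"`, attribute `s_px` holds the fitted
#'   erfc width in pixels.
#' @examples
#' p <- c(rep(1, 100), rep(0, 100))
#' detect_interface(p, method = "crossing")   # 99.5
#' @export
detect_interface <- function(profile, coords = seq_along(profile) - 1,
                             method = c("model", "crossing"),
                             background = 0, reservoir = NULL) {
  method <- match.arg(method)
  if (length(profile) < 4L || length(profile) != length(coords))
    stop_invalid("'profile' and 'coords' must be equal-length vectors (>= 4)")
  if (is.null(reservoir))
    reservoir <- mean(profile[seq_len(max(2L, floor(length(profile) * 0.05)))])
  if (reservoir - background <= 0)
    stop_invalid("reservoir level must exceed background")
  v <- (profile - background) / (reservoir - background)

  cross_at <- function(level) {
    below <- v < level
    i <- which(!below[-length(v)] & below[-1L])
    if (length(i) == 0L) return(NA_real_)
    i <- i[1L]
    coords[i] + (v[i] - level) / (v[i] - v[i + 1L]) * (coords[i + 1L] - coords[i])
  }
  p50 <- cross_at(0.5)
  if (is.na(p50))
    stop_invalid("interface not found: profile never crosses 0.5")
  if (method == "crossing") {
    if (p50 <= min(coords) || p50 >= max(coords))
      stop_invalid("interface not found: crossing lies at the profile edge")
    return(structure(p50, method = "crossing"))
  }

  # model method: quantile-matched initial values, then least squares
  z50 <- erfcinv_(0.5); z20 <- erfcinv_(0.2)
  p20 <- cross_at(0.2)
  if (is.na(p20)) p20 <- p50 + 2 * (coords[2] - coords[1])
  s0 <- max((p20 - p50) / (z20 - z50), 1e-3)
  x0_0 <- p50 - z50 * s0
  win <- coords >= x0_0 - 3 * s0 & coords <= x0_0 + 6 * s0
  if (sum(win) < 5L) win <- rep(TRUE, length(coords))
  cw <- coords[win]; vw <- v[win]
  objective <- function(par) {
    x0 <- par[1]; s <- exp(par[2])
    u <- (cw - x0) / s
    m <- ifelse(u <= 0, 1, erfc_(u))
    sum((vw - m)^2)
  }
  fit <- optim(c(x0_0, log(s0)), objective, method = "Nelder-Mead",
               control = list(maxit = 500, reltol = 1e-12))
  x0 <- fit$par[1]
  if (x0 <= min(coords) || x0 >= max(coords))
    stop_invalid("interface not found: model fit places it outside the profile")
  structure(x0, method = "model", s_px = exp(fit$par[2]))
}

# internal constructor with invariant checks
new_profile_matrix <- function(f, times, positions, normalization_value,
                               background, interface_px, pixel_size,
                               t_offset, meta = list()) {
  if (!is.matrix(f) || nrow(f) != length(times) || ncol(f) != length(positions))
    stop_invalid("profile matrix dimensions do not match times/positions")
  if (any(f < 0)) stop_invalid("normalized fluorescence must be >= 0")
  if (any(diff(times) <= 0))
    stop_invalid("'times' must be strictly increasing")
  if (any(diff(positions) <= 0))
    stop_invalid("'positions' must be strictly increasing")
  structure(list(f = f, times = times, positions = positions,
                 normalization_value = normalization_value,
                 background = background, interface_px = interface_px,
                 pixel_size = pixel_size, t_offset = t_offset, meta = meta),
            class = "profile_matrix")
}

#' Normalize raw profiles to the reservoir
#'
#' Converts a raw intensity matrix into a reservoir-normalized profile
#' matrix: `F = (raw - background) / (reservoir_mean - background)`, with
#' the reservoir mean taken over the ROI's reservoir window and all
#' frames (the reservoir intensity is assumed constant; a warning is
#' raised if per-frame reservoir means drift by more than 5%).  Axial
#' positions are converted to cm from the detected (or supplied)
#' interface; only gel-side positions (x > 0) are kept.  Times are
#' `t_offset + k * frame_interval` for frame k = 0, 1, ...
#'
#' @param raw Raw matrix from [extract_raw_profiles()] (needs its
#'   `coords` attribute, or supply 0-based coordinates via `coords`).
#' @param roi The [roi_spec()] used (for the reservoir window).
#' @param pixel_size Pixel pitch, um/px.
#' @param frame_interval Seconds between frames.
#' @param t_offset Seconds between contact and frame 0 (default 240).
#' @param background Raw background intensity; default: mean of the
#'   dimmest 1% of frame-0 samples.
#' @param interface Optional interface override, 0-based px; default:
#'   [detect_interface()] on frame 0.
#' @param interface_method Passed to [detect_interface()].
#' @param coords Optional explicit 0-based coordinates.
#' @return An object of class `"profile_matrix"`: list with `f`
#'   (frames x positions, dimensionless), `times` (s since contact),
#'   `positions` (cm from interface), `normalization_value` (raw reservoir
#'   mean), `background`, `interface_px`, `pixel_size`, `t_offset`.
#' @export
normalize_profiles <- function(raw, roi, pixel_size, frame_interval,
                               t_offset = 240, background = NULL,
                               interface = NULL,
                               interface_method = c("model", "crossing"),
                               coords = attr(raw, "coords")) {
  stopifnot(inherits(roi, "roi_spec"))
  interface_method <- match.arg(interface_method)
  if (is.null(coords)) coords <- seq_len(ncol(raw)) - 1
  res_cols <- which(coords >= roi$reservoir_window[1] &
                    coords <= roi$reservoir_window[2])
  if (length(res_cols) == 0L)
    stop_invalid("reservoir window contains no profile samples")
  res_frame <- rowMeans(raw[, res_cols, drop = FALSE])
  res_mean <- mean(res_frame)
  drift <- (max(res_frame) - min(res_frame)) / res_mean
  if (drift > 0.05)
    warning(sprintf(paste0("reservoir intensity drifts by %.1f%% across ",
                           "frames; the constant-reservoir assumption of the ",
                           "normalization may be violated"), 100 * drift),
            call. = FALSE)
  if (is.null(background)) {
    v0 <- raw[1L, ]
    background <- mean(v0[v0 <= quantile(v0, 0.01)])
  }
  denom <- res_mean - background
  if (denom <= 0)
    stop_invalid("reservoir mean does not exceed background; cannot normalize")
  if (is.null(interface)) {
    interface <- detect_interface(raw[1L, ], coords = coords,
                                  method = interface_method,
                                  background = background,
                                  reservoir = mean(raw[1L, res_cols]))
  }
  if (interface <= roi$reservoir_window[2])
    stop_invalid("reservoir window must lie on the reservoir side of the interface")
  f <- pmax((raw - background) / denom, 0)
  gel <- which(coords > interface)
  if (length(gel) < 2L)
    stop_invalid("no gel-side positions beyond the interface")
  positions <- (coords[gel] - as.numeric(interface)) * um_to_cm(pixel_size)
  times <- t_offset + (seq_len(nrow(raw)) - 1L) * frame_interval
  new_profile_matrix(f = f[, gel, drop = FALSE], times = times,
                     positions = positions, normalization_value = res_mean,
                     background = background,
                     interface_px = as.numeric(interface),
                     pixel_size = pixel_size, t_offset = t_offset,
                     meta = list(interface_method =
                                   attr(interface, "method") %||% "override",
                                 reservoir_drift = drift))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full extraction pipeline for a stack bundle
#'
#' Builds a default ROI from the bundle's configuration (axis through the
#' tube centre, averaging over 80% of the tube width, reservoir window
#' inside the rendered reservoir), estimates the background from the
#' dimmest 1% of frame-0 pixels, and runs [extract_raw_profiles()] +
#' [normalize_profiles()].
#'
#' @param bundle A `"stack_bundle"` (or a path prefix readable by
#'   [read_bundle()]).
#' @param roi Optional [roi_spec()] overriding the default.
#' @param t_offset Seconds between contact and frame 0; default: the
#'   bundle's acquisition metadata.
#' @param interface Optional interface override, 0-based px.
#' @param interface_method Passed to [detect_interface()].
#' @return A `"profile_matrix"`.
#' @examples
#' b <- render_stack(tube_geometry(), imaging_config(n_frames = 4),
#'                   d_eff = 1e-6, noise = noise_model(seed = 3))
#' pm <- extract_profiles(b)
#' pm
#' @export
extract_profiles <- function(bundle, roi = NULL, t_offset = NULL,
                             interface = NULL,
                             interface_method = c("model", "crossing")) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  stopifnot(inherits(bundle, "stack_bundle"))
  img <- bundle$config$imaging
  geo <- bundle$config$geometry
  d <- dim(bundle$stack)
  if (is.null(roi)) {
    tube_px <- round(geo$inner_diameter / img$pixel_size)
    row_c <- img$margin_px + floor((tube_px + 1) / 2)   # 0-based centre row
    width <- max(1L, floor(0.8 * tube_px))
    rw_hi <- max(1, img$reservoir_pixels - 20)
    roi <- roi_spec(c(0, row_c), c(d[3] - 1, row_c),
                    averaging_width = width,
                    reservoir_window = c(min(5, rw_hi - 1), rw_hi))
  }
  raw <- extract_raw_profiles(bundle$stack, roi)
  frame0 <- bundle$stack[1L, , ]
  background <- mean(frame0[frame0 <= quantile(frame0, 0.01)])
  normalize_profiles(raw, roi,
                     pixel_size = img$pixel_size,
                     frame_interval = img$frame_interval,
                     t_offset = t_offset %||% bundle$truth$t_offset,
                     background = background, interface = interface,
                     interface_method = match.arg(interface_method))
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("Normalized fluorescence profile matrix\n")
  cat(sprintf("  %d frames x %d positions; x in [%.4f, %.4f] cm; t in [%g, %g] s\n",
              nrow(x$f), ncol(x$f), min(x$positions), max(x$positions),
              min(x$times), max(x$times)))
  if (!is.na(x$interface_px))
    cat(sprintf("  interface at %.2f px (%s); reservoir level %.1f\n",
                x$interface_px, x$meta$interface_method %||% "?",
                x$normalization_value))
  invisible(x)
}

#' @export
as.data.frame.profile_matrix <- function(x, ...) {
  data.frame(frame = rep(seq_len(nrow(x$f)), times = ncol(x$f)),
             time_s = rep(x$times, times = ncol(x$f)),
             x_cm = rep(x$positions, each = nrow(x$f)),
             f = as.vector(x$f))
}

#' @export
plot.profile_matrix <- function(x, frames = NULL, ...) {
  if (is.null(frames))
    frames <- unique(round(seq(1, nrow(x$f), length.out = 4)))
  cols <- hcl.colors(length(frames), "viridis")
  matplot(x$positions, t(x$f[frames, , drop = FALSE]), type = "l", lty = 1,
          col = cols, xlab = "x (cm from interface)",
          ylab = "normalized fluorescence F", ...)
  legend("topright", legend = sprintf("t = %g s", x$times[frames]),
         col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Write / read a profile matrix
#'
#' Wide CSV: first column `time_s`, remaining columns one per axial
#' position with headers `x_<cm>`; plus a JSON metadata sidecar.
#'
#' @param pm A `"profile_matrix"`.
#' @param csv CSV path.
#' @param json JSON metadata path; default replaces the extension.
#' @return `write_profile_matrix()` returns `csv` invisibly;
#'   `read_profile_matrix()` the reconstructed object.
#' @export
write_profile_matrix <- function(pm, csv,
                                 json = sub("\\.csv$", ".json", csv)) {
  stopifnot(inherits(pm, "profile_matrix"))
  wide <- data.frame(time_s = pm$times, pm$f, check.names = FALSE)
  names(wide) <- c("time_s", sprintf("x_%.6g", pm$positions))
  write.csv(wide, csv, row.names = FALSE)
  meta <- list(normalization_value = pm$normalization_value,
               background = pm$background,
               interface_px = pm$interface_px,
               pixel_size = pm$pixel_size,
               t_offset = pm$t_offset)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(csv, json = sub("\\.csv$", ".json", csv)) {
  wide <- read.csv(csv, check.names = FALSE)
  if (names(wide)[1] != "time_s" || !all(grepl("^x_", names(wide)[-1])))
    stop_invalid("'%s' is not a profile-matrix CSV (time_s + x_* columns)", csv)
  meta <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
          else list()
  positions <- as.numeric(sub("^x_", "", names(wide)[-1]))
  new_profile_matrix(f = as.matrix(wide[, -1, drop = FALSE]),
                     times = wide$time_s, positions = positions,
                     normalization_value = meta$normalization_value %||% NA_real_,
                     background = meta$background %||% NA_real_,
                     interface_px = meta$interface_px %||% NA_real_,
                     pixel_size = meta$pixel_size %||% NA_real_,
                     t_offset = meta$t_offset %||% NA_real_)
}
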