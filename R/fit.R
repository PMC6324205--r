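# Filtering rules and constrained nonlinear least-squares estimation of
# the effective diffusion coefficient.

#' Apply the low-intensity / far-from-interface filters
#'
#' Keeps exactly the observations with normalized fluorescence
#' `F < max_f` and distance `x > min_x` from the interface (see
#' [filter_spec()] for why), pooled across all frames.
#'
#' @param pm A `"profile_matrix"`.
#' @param spec A [filter_spec()].
#' @return A data frame of retained observations with columns `frame`,
#'   `time_s`, `x_cm`, `f`, plus attributes `counts` (per-frame retained /
#'   removed), `filter` and `t_offset`.
#' @examples
#' th <- theoretical_profile_set(tube_geometry(), d_eff = 1e-6,
#'                               frame_times = seq(240, 7200, by = 240))
#' obs <- apply_filters(th, filter_spec())
#' nrow(obs)
#' @export
apply_filters <- function(pm, spec = filter_spec()) {
  stopifnot(inherits(pm, "profile_matrix"), inherits(spec, "filter_spec"))
  df <- as.data.frame(pm)
  keep <- df$f < spec$max_f & df$x_cm > spec$min_x
  counts <- data.frame(
    frame = seq_len(nrow(pm$f)),
    time_s = pm$times,
    retained = vapply(seq_len(nrow(pm$f)),
                      function(k) sum(keep[df$frame == k]), integer(1)))
  counts$removed <- ncol(pm$f) - counts$retained
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) < spec$min_points)
    stop_invalid(paste0("insufficient filtered data: %d points survive the ",
                        "F < %g and x > %g cm filters (need >= %d)"),
                 nrow(out), spec$max_f, spec$min_x, spec$min_points)
  attr(out, "counts") <- counts
  attr(out, "filter") <- spec
  attr(out, "t_offset") <- pm$t_offset
  out
}

ssr_deff <- function(obs_x, obs_t, obs_f, d_eff) {
  sum((obs_f - erfc_(obs_x / (2 * sqrt(d_eff * obs_t))))^2)
}

#' Fit the effective diffusion coefficient
#'
#' Fits the semi-infinite diffusion model
#' \eqn{F = \mathrm{erfc}(x / (2\sqrt{D_{eff} t}))} to filtered,
#' reservoir-normalized observations pooled from all frames, by minimizing
#' the sum of squared residuals over `log10(D)` within bounds (bounded
#' scalar minimization with log-spaced multi-starts; ties broken towards
#' the smaller coefficient).  With `t_offset_mode = "fit"` the time
#' between protein--hydrogel contact and the first frame is co-estimated
#' by two-parameter bounded minimization.
#'
#' @param object A `"profile_matrix"` (filtered via `filter`) or a data
#'   frame of observations with columns `x_cm`, `time_s`, `f` (already
#'   filtered).
#' @param filter A [filter_spec()] applied when `object` is a profile
#'   matrix.
#' @param bounds Search bounds on D, cm^2/s (default `c(1e-9, 1e-4)`).
#' @param t_offset_mode `"fixed"` (use the time axis as given) or `"fit"`.
#' @param t_offset_bounds Bounds for the co-estimated offset, s.
#' @param multistart Number of log-spaced sub-intervals searched.
#' @param ... Passed between methods.
#' @return An object of class `"deff_fit"`; see [coef.deff_fit()],
#'   [predict.deff_fit()], `summary()`, `plot()`, `residuals()`,
#'   `simulate()`.
#' @examples
#' th <- theoretical_profile_set(tube_geometry(), d_eff = 1e-6,
#'                               frame_times = seq(240, 7200, by = 240))
#' fit <- fit_deff(th)
#' coef(fit)
#' @export
fit_deff <- function(object, ...) UseMethod("fit_deff")

#' @rdname fit_deff
#' @export
fit_deff.profile_matrix <- function(object, filter = filter_spec(),
                                    bounds = c(1e-9, 1e-4),
                                    t_offset_mode = c("fixed", "fit"),
                                    t_offset_bounds = c(1, 3600),
                                    multistart = 3, ...) {
  obs <- apply_filters(object, filter)
  fit_deff.data.frame(obs, bounds = bounds, t_offset_mode = t_offset_mode,
                      t_offset_bounds = t_offset_bounds,
                      multistart = multistart,
                      t_offset = object$t_offset, ...)
}

#' @rdname fit_deff
#' @param t_offset Known offset (s) already included in `time_s`; needed
#'   only for `t_offset_mode = "fit"` on a plain data frame.
#' @export
fit_deff.data.frame <- function(object, bounds = c(1e-9, 1e-4),
                                t_offset_mode = c("fixed", "fit"),
                                t_offset_bounds = c(1, 3600),
                                multistart = 3,
                                t_offset = attr(object, "t_offset"), ...) {
  t_offset_mode <- match.arg(t_offset_mode)
  if (!all(c("x_cm", "time_s", "f") %in% names(object)))
    stop_invalid("observations need columns x_cm, time_s, f")
  if (nrow(object) == 0L) stop_invalid("no observations to fit")
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2])
    stop_invalid("'bounds' must be c(low, high) with 0 < low < high (cm^2/s)")
  x <- object$x_cm; tt <- object$time_s; f <- object$f
  if (any(tt <= 0)) stop_invalid("observation times must be positive")
  lb <- log10(bounds[1]); ub <- log10(bounds[2])

  if (t_offset_mode == "fixed") {
    obj <- function(l) ssr_deff(x, tt, f, 10^l)
    edges <- seq(lb, ub, length.out = multistart + 1L)
    cand <- lapply(seq_len(multistart), function(i) {
      o <- optimize(obj, lower = edges[i], upper = edges[i + 1L], tol = 1e-9)
      c(l = o$minimum, ssr = o$objective)
    })
    cand <- do.call(rbind, cand)
    # lowest SSR wins; equal SSR resolved towards the smaller coefficient
    ord <- order(cand[, "ssr"], cand[, "l"])
    best <- cand[ord[1L], ]
    width <- (ub - lb) / multistart
    polish <- optimize(obj, lower = max(lb, best["l"] - width),
                       upper = min(ub, best["l"] + width), tol = 1e-10)
    l_hat <- if (polish$objective <= best["ssr"]) polish$minimum else best["l"]
    ssr <- min(polish$objective, best["ssr"])
    t_used <- t_offset
    converged <- TRUE
    candidates <- data.frame(log10_d = cand[, "l"], ssr = cand[, "ssr"])
  } else {
    if (is.null(t_offset) || is.na(t_offset))
      stop_invalid("t_offset_mode = 'fit' needs the nominal t_offset to anchor frame times")
    t_base <- tt - t_offset              # frame clock (0 at first exposure)
    lo_t <- max(t_offset_bounds[1], 1e-6 - min(t_base))
    hi_t <- t_offset_bounds[2]
    obj2 <- function(par) ssr_deff(x, t_base + par[2L], f, 10^par[1L])
    starts <- expand.grid(l = seq(lb + 0.1 * (ub - lb), ub - 0.1 * (ub - lb),
                                  length.out = multistart),
                          t0 = c(t_offset, (lo_t + hi_t) / 2))
    runs <- lapply(seq_len(nrow(starts)), function(i) {
      tryCatch(optim(c(starts$l[i], starts$t0[i]), obj2, method = "L-BFGS-B",
                     lower = c(lb, lo_t), upper = c(ub, hi_t)),
               error = function(e) NULL)
    })
    runs <- Filter(Negate(is.null), runs)
    if (length(runs) == 0L)
      stop_invalid("optimizer failed to converge from any start")
    ssrs <- vapply(runs, function(r) r$value, numeric(1))
    ls <- vapply(runs, function(r) r$par[1L], numeric(1))
    best <- runs[[order(ssrs, ls)[1L]]]
    l_hat <- best$par[1L]; t_used <- best$par[2L]; ssr <- best$value
    converged <- best$convergence == 0L
    candidates <- data.frame(log10_d = ls, ssr = ssrs)
    tt <- t_base + t_used
  }

  d_hat <- 10^l_hat
  at_bound <- (l_hat - lb) < 1e-6 * (ub - lb) || (ub - l_hat) < 1e-6 * (ub - lb)
  if (at_bound)
    warning("D_eff estimate sits at a search bound; widen 'bounds'",
            call. = FALSE)
  resid <- f - erfc_(x / (2 * sqrt(d_hat * tt)))
  per_frame <- tapply(resid^2, object$time_s, function(r) sqrt(mean(r)))
  structure(list(d_eff = d_hat, ssr = ssr, n_points = nrow(object),
                 bounds = bounds, converged = converged,
                 at_bound = at_bound,
                 t_offset = t_used, t_offset_mode = t_offset_mode,
                 per_frame_rmse = per_frame,
                 observations = object,
                 obs_times = tt,
                 filter = attr(object, "filter"),
                 candidates = candidates,
                 call = match.call()),
            class = "deff_fit")
}

#' @export
print.deff_fit <- function(x, ...) {
  cat("Capillary-tube diffusion fit (1D semi-infinite erfc model)\n")
  cat(sprintf("  D_eff = %.4g cm^2/s  (SSR = %.4g over %d filtered points)\n",
              x$d_eff, x$ssr, x$n_points))
  if (x$t_offset_mode == "fit")
    cat(sprintf("  co-estimated t_offset = %.1f s\n", x$t_offset))
  if (x$at_bound) cat("  WARNING: estimate at a search bound\n")
  invisible(x)
}

#' Extract the fitted coefficient
#'
#' @param object A `"deff_fit"`.
#' @param ... Ignored.
#' @return Named vector: `d_eff` (cm^2/s), plus `t_offset` (s) when it was
#'   co-estimated.
#' @export
coef.deff_fit <- function(object, ...) {
  if (object$t_offset_mode == "fit")
    c(d_eff = object$d_eff, t_offset = object$t_offset)
  else c(d_eff = object$d_eff)
}

#' @export
summary.deff_fit <- function(object, ...) {
  structure(list(fit = object,
                 rmse = sqrt(object$ssr / object$n_points),
                 per_frame_rmse = object$per_frame_rmse),
            class = "summary.deff_fit")
}

#' @export
print.summary.deff_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  bounds [%g, %g] cm^2/s; converged: %s; RMSE = %.4g\n",
              f$bounds[1], f$bounds[2], f$converged, x$rmse))
  cat(sprintf("  per-frame RMSE: %.4g (min) .. %.4g (max) over %d frames\n",
              min(x$per_frame_rmse), max(x$per_frame_rmse),
              length(x$per_frame_rmse)))
  invisible(x)
}

#' Model predictions from a fit
#'
#' @param object A `"deff_fit"`.
#' @param newdata Data frame with columns `x_cm` and `time_s`; default:
#'   the fitted observations.
#' @param ... Ignored.
#' @return Predicted normalized fluorescence.
#' @export
predict.deff_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(erfc_(object$observations$x_cm /
                   (2 * sqrt(object$d_eff * object$obs_times))))
  if (!all(c("x_cm", "time_s") %in% names(newdata)))
    stop_invalid("'newdata' needs columns x_cm and time_s")
  erfc_profile(newdata$x_cm, newdata$time_s, object$d_eff)
}

#' @export
fitted.deff_fit <- function(object, ...) predict(object)

#' @export
residuals.deff_fit <- function(object, ...) {
  object$observations$f - predict(object)
}

#' @export
plot.deff_fit <- function(x, frames = 4, ...) {
  obs <- x$observations
  times <- sort(unique(obs$time_s))
  sel <- times[unique(round(seq(1, length(times), length.out = frames)))]
  cols <- hcl.colors(length(sel), "viridis")
  plot(NA, xlim = range(obs$x_cm), ylim = c(0, max(obs$f) * 1.05),
       xlab = "x (cm from interface)", ylab = "normalized fluorescence F",
       main = sprintf("D_eff = %.3g cm^2/s", x$d_eff), ...)
  for (i in seq_along(sel)) {
    sub <- obs[obs$time_s == sel[i], ]
    points(sub$x_cm, sub$f, col = cols[i], pch = 16, cex = 0.4)
    xs <- seq(min(obs$x_cm), max(obs$x_cm), length.out = 200)
    lines(xs, erfc_profile(xs, sel[i], x$d_eff), col = cols[i])
  }
  legend("topright", legend = sprintf("t = %g s", sel), col = cols,
         lty = 1, bty = "n")
  invisible(x)
}

#' @export
simulate.deff_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sigma <- sqrt(object$ssr / max(object$n_points - 1L, 1L))
  out <- matrix(rnorm(length(mu) * nsim, mean = mu, sd = sigma),
                ncol = nsim)
  out[out < 0] <- 0
  as.data.frame(out)
}

#' Brute-force grid-search estimate of D_eff
#'
#' Exhaustive evaluation of the fit objective on a log-spaced grid of
#' diffusion coefficients.  Slow but assumption-free; used to
#' cross-check the bounded scalar optimizer (the two must agree to within
#' one grid step).  Ties resolve to the smaller coefficient.
#'
#' @param observations Data frame with columns `x_cm`, `time_s`, `f`.
#' @param bounds Grid limits, cm^2/s.
#' @param n_grid Number of grid points (log-spaced).
#' @return List with `d_eff`, `ssr`, `grid` (all D values) and
#'   `ssr_values`.
#' @export
fit_deff_grid <- function(observations, bounds = c(1e-9, 1e-4),
                          n_grid = 400) {
  if (!all(c("x_cm", "time_s", "f") %in% names(observations)))
    stop_invalid("observations need columns x_cm, time_s, f")
  grid <- 10^seq(log10(bounds[1]), log10(bounds[2]), length.out = n_grid)
  ssr <- vapply(grid, function(d) ssr_deff(observations$x_cm,
                                           observations$time_s,
                                           observations$f, d), numeric(1))
  i <- which.min(ssr)   # first minimum = smallest D on the ascending grid
  list(d_eff = grid[i], ssr = ssr[i], grid = grid, ssr_values = ssr)
}

#' Predict a protein's coefficient from a size/charge-matched reference
#'
#' Records a fitted reference coefficient as the predicted coefficient of
#' a protein of similar molecular weight and isoelectric point (e.g. a
#' cheap model protease standing in for a costly therapeutic protein).
#' No scaling law is applied; this is a provenance-tagged bookkeeping
#' record meant to be checked later against an independent fit.
#'
#' @param reference A converged `"deff_fit"`.
#' @param protein Name of the protein being predicted.
#' @param note Free-text rationale (e.g. matched MW and pI values).
#' @return An object of class `"deff_prediction"`.
#' @export
predict_deff_by_similarity <- function(reference, protein = NA_character_,
                                       note = NA_character_) {
  if (missing(reference) || is.null(reference))
    stop_invalid("a reference fit is required")
  if (!inherits(reference, "deff_fit"))
    stop_invalid("'reference' must be a deff_fit")
  if (!isTRUE(reference$converged))
    stop_invalid("reference fit did not converge; refusing to propagate it")
  structure(list(d_eff = reference$d_eff, protein = protein, note = note,
                 provenance = sprintf(
                   "similarity transfer from reference fit (D_eff = %.4g cm^2/s, n = %d)",
                   reference$d_eff, reference$n_points)),
            class = "deff_prediction")
}

#' @export
print.deff_prediction <- function(x, ...) {
  cat(sprintf("Predicted D_eff = %.4g cm^2/s for %s\n", x$d_eff,
              ifelse(is.na(x$protein), "(unnamed protein)", x$protein)))
  cat("  ", x$provenance, "\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}
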