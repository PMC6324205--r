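# Analytic and numerical forward models of axial diffusion from an
# infinite reservoir into a hydrogel-filled capillary.

erfc_ <- function(z) 2 * pnorm(z * sqrt(2), lower.tail = FALSE)
erfcinv_ <- function(p) -qnorm(p / 2) / sqrt(2)

#' Semi-infinite diffusion profile (complementary error function)
#'
#' Normalized concentration of solute diffusing from a constant reservoir
#' (C/C0 = 1 at x = 0) into an initially empty semi-infinite medium:
#' \deqn{C(x,t)/C_0 = \mathrm{erfc}\!\left(\frac{x}{2\sqrt{D_{eff}\,t}}\right).}
#' This is the model fitted to normalized fluorescence profiles to obtain
#' the effective diffusion coefficient.
#'
#' @param x Axial distances from the interface, cm (>= 0); vectorized.
#' @param t Time since protein--hydrogel contact, s (> 0); scalar or a
#'   vector recycled against `x`.
#' @param d_eff Effective diffusion coefficient, cm^2/s (> 0).
#' @return Normalized concentrations in (0, 1]; 1 at x = 0.
#' @examples
#' erfc_profile(c(0, 0.05, 0.1), t = 3600, d_eff = 2e-6)
#' @export
erfc_profile <- function(x, t, d_eff) {
  check_scalar(d_eff, "d_eff")
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop_invalid("'t' must be positive and finite (time since contact, s)")
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop_invalid("'x' must be non-negative and finite (cm from interface)")
  erfc_(x / (2 * sqrt(d_eff * t)))
}

#' Finite-difference solution of capillary diffusion
#'
#' Solves the one-dimensional diffusion equation
#' \eqn{\partial C/\partial t = D\,\partial^2 C/\partial x^2} on
#' x in `[0, L]` with a constant-concentration boundary `C(0, t) = 1`
#' (infinite reservoir), zero flux at `x = L` (sealed tube end) and
#' `C(x, 0) = 0`, by the Crank-Nicolson scheme (second order in space and
#' time, unconditionally stable).  Start-up uses two implicit-Euler half
#' steps (Rannacher smoothing) to damp the oscillations Crank-Nicolson
#' otherwise produces from the discontinuous initial condition.
#'
#' The capillary problem has no radial gradient (uniform initial state,
#' impermeable walls, axial driving force only), so the axisymmetric tube
#' reduces exactly to this 1D problem.  The solver is the package's
#' verification oracle for the analytic [erfc_profile()] while the
#' penetration depth stays well below `L`.
#'
#' @param geometry A [tube_geometry()]; supplies the domain length
#'   (hydrogel length) and field of view.
#' @param d_eff Effective diffusion coefficient, cm^2/s.
#' @param output_times Times (s since contact) at which to record the
#'   field; each must be a multiple of `grid$dt` within the horizon.
#' @param grid A [grid_spec()].
#' @param full_domain Return all nodes (`TRUE`) or only those inside the
#'   field of view (default).
#' @return An object of class `"concentration_field"`: list with
#'   `positions` (cm), `times` (s), `values` (times x positions matrix of
#'   C/C0), `backend`, `grid`, `params`, and a `conservation` data frame
#'   with the discrete mass and time-integrated boundary flux at each
#'   output time.
#' @examples
#' fld <- solve_diffusion_fd(tube_geometry(), d_eff = 2e-6,
#'                           output_times = c(240, 3600),
#'                           grid = grid_spec(dx = 50e-4, dt = 10))
#' max(abs(fld$values[2, ] - erfc_profile(fld$positions, 3600, 2e-6)))
#' @export
solve_diffusion_fd <- function(geometry, d_eff, output_times,
                               grid = grid_spec(), full_domain = FALSE) {
  stopifnot(inherits(geometry, "tube_geometry"), inherits(grid, "grid_spec"))
  check_scalar(d_eff, "d_eff")
  if (!is.numeric(output_times) || length(output_times) == 0 ||
      any(output_times <= 0))
    stop_invalid("'output_times' must be positive times in seconds")
  output_times <- sort(unique(output_times))
  dx <- grid$dx; dt <- grid$dt
  L <- if (is.null(grid$domain_length)) mm_to_cm(geometry$hydrogel_length)
       else grid$domain_length
  if (L < mm_to_cm(geometry$field_of_view))
    stop_invalid("grid domain_length (%g cm) is shorter than the field of view",
                 L)
  r <- d_eff * dt / dx^2
  if (r > grid$max_diffusion_number)
    stop_invalid(paste0("grid accuracy constraint violated: diffusion number ",
                        "D*dt/dx^2 = %.3g exceeds max_diffusion_number = %g; ",
                        "reduce dt or increase dx"),
                 r, grid$max_diffusion_number)
  steps_out <- output_times / dt
  if (any(abs(steps_out - round(steps_out)) > 1e-8))
    stop_invalid("every output time must be a multiple of grid dt = %g s", dt)
  steps_out <- as.integer(round(steps_out))
  n_steps <- max(steps_out)

  n <- as.integer(round(L / dx)) + 1L   # nodes 1..n at x = 0, dx, ..., L
  m <- n - 1L                           # unknowns: nodes 2..n
  # Laplacian on unknowns; last row uses the zero-flux ghost (2, -2)
  lower <- rep(1, m - 1L); lower[m - 1L] <- 2
  main <- rep(-2, m)
  upper <- rep(1, m - 1L)
  lap <- Matrix::bandSparse(m, m, k = c(-1L, 0L, 1L),
                            diagonals = list(lower, main, upper))
  I_m <- Matrix::Diagonal(m)
  # Crank-Nicolson operators
  A_cn <- methods::as(I_m - (r / 2) * lap, "CsparseMatrix")
  B_cn <- methods::as(I_m + (r / 2) * lap, "CsparseMatrix")
  fac_cn <- Matrix::lu(A_cn)
  # implicit-Euler half-step operator for Rannacher start-up
  r_h <- r / 2
  A_be <- methods::as(I_m - r_h * lap, "CsparseMatrix")
  fac_be <- Matrix::lu(A_be)

  C <- numeric(m)                       # interior + far node, C0 = 1 fixed
  c0 <- 1
  mass <- dx * sum(C)                   # rectangle rule over unknown nodes
  flux_int <- 0                         # time-integrated net boundary flux
  want <- match(seq_len(n_steps), steps_out, nomatch = 0L)
  out_vals <- matrix(NA_real_, length(steps_out), n)
  cons <- matrix(NA_real_, length(steps_out), 2L,
                 dimnames = list(NULL, c("mass", "flux_integral")))

  for (k in seq_len(n_steps)) {
    if (k == 1L) {
      # two implicit-Euler half steps
      C_mid <- as.numeric(Matrix::solve(fac_be, C + c(r_h * c0, numeric(m - 1L))))
      C_new <- as.numeric(Matrix::solve(fac_be, C_mid + c(r_h * c0, numeric(m - 1L))))
      # discrete balance of BE: flux evaluated at the new level
      flux_int <- flux_int +
        d_eff * (dt / 2) / dx * ((c0 - C_mid[1L]) - (C_mid[m] - C_mid[m - 1L])) +
        d_eff * (dt / 2) / dx * ((c0 - C_new[1L]) - (C_new[m] - C_new[m - 1L]))
    } else {
      rhs <- as.numeric(B_cn %*% C)
      rhs[1L] <- rhs[1L] + r * c0       # r/2 from each operator side
      C_new <- as.numeric(Matrix::solve(fac_cn, rhs))
      flux_int <- flux_int + d_eff * dt / dx *
        (((c0 - C[1L]) + (c0 - C_new[1L])) / 2 -
         ((C[m] - C[m - 1L]) + (C_new[m] - C_new[m - 1L])) / 2)
    }
    C <- C_new
    if (want[k] > 0L) {
      out_vals[want[k], ] <- c(c0, C)
      cons[want[k], ] <- c(dx * sum(C), flux_int)
    }
  }

  positions <- seq(0, L, by = dx)[seq_len(n)]
  if (!full_domain) {
    fov <- mm_to_cm(geometry$field_of_view)
    keep <- positions <= fov + 1e-12
    positions <- positions[keep]
    out_vals <- out_vals[, keep, drop = FALSE]
  }
  structure(list(positions = positions, times = output_times,
                 values = out_vals, backend = "numeric",
                 grid = grid,
                 params = list(d_eff = d_eff, domain_length = L),
                 conservation = data.frame(time_s = output_times,
                                           mass = cons[, "mass"],
                                           flux_integral = cons[, "flux_integral"])),
            class = "concentration_field")
}

#' @export
print.concentration_field <- function(x, ...) {
  cat(sprintf("Concentration field (%s backend)\n", x$backend))
  cat(sprintf("  %d times x %d positions; x in [%g, %g] cm; t in [%g, %g] s\n",
              length(x$times), length(x$positions),
              min(x$positions), max(x$positions), min(x$times), max(x$times)))
  cat(sprintf("  D_eff = %.4g cm^2/s\n", x$params$d_eff))
  invisible(x)
}

#' @export
as.data.frame.concentration_field <- function(x, ...) {
  data.frame(time_s = rep(x$times, each = length(x$positions)),
             x_cm = rep(x$positions, times = length(x$times)),
             value = as.vector(t(x$values)))
}

#' Write / read a concentration field
#'
#' Long-format CSV (`time_s, x_cm, value`) plus a JSON sidecar recording
#' the backend, grid and parameters.
#'
#' @param field A `"concentration_field"`.
#' @param csv Path of the CSV file to write.
#' @param json Path of the JSON metadata file; default replaces the CSV
#'   extension.
#' @return `write_concentration_field()` returns `csv` invisibly;
#'   `read_concentration_field()` returns the reconstructed field.
#' @export
write_concentration_field <- function(field, csv,
                                      json = sub("\\.csv$", ".json", csv)) {
  stopifnot(inherits(field, "concentration_field"))
  write.csv(as.data.frame(field), csv, row.names = FALSE)
  meta <- list(backend = field$backend,
               grid = unclass(field$grid),
               params = field$params)
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(csv)
}

#' @rdname write_concentration_field
#' @export
read_concentration_field <- function(csv,
                                     json = sub("\\.csv$", ".json", csv)) {
  df <- read.csv(csv)
  if (!all(c("time_s", "x_cm", "value") %in% names(df)))
    stop_invalid("'%s' is not a concentration-field CSV", csv)
  meta <- if (file.exists(json)) jsonlite::read_json(json, simplifyVector = TRUE)
          else list(backend = "unknown", grid = NULL, params = NULL)
  times <- sort(unique(df$time_s))
  positions <- sort(unique(df$x_cm))
  values <- matrix(NA_real_, length(times), length(positions))
  values[cbind(match(df$time_s, times), match(df$x_cm, positions))] <- df$value
  structure(list(positions = positions, times = times, values = values,
                 backend = meta$backend, grid = meta$grid,
                 params = meta$params, conservation = NULL),
            class = "concentration_field")
}

#' Model profiles on an experimental lattice
#'
#' Convenience wrapper producing model concentration profiles on the same
#' (time, position) lattice as an experimental profile matrix, from either
#' the analytic erfc solution or the finite-difference solver.  Used e.g.
#' to overlay theory on measured kymographs or to feed
#' [chisq_profile_test()].
#'
#' @param geometry A [tube_geometry()].
#' @param d_eff Effective diffusion coefficient, cm^2/s.
#' @param frame_times Strictly increasing times, s since contact.  Ignored
#'   (and must be `NULL`) when `like` is given.
#' @param positions Axial positions, cm from the interface.  Default: pixel
#'   centres of a default [imaging_config()] across the field of view.
#'   Ignored when `like` is given.
#' @param like Optional `"profile_matrix"` whose lattice is copied.
#' @param backend `"analytic"` (erfc) or `"numeric"` (finite differences).
#' @param grid A [grid_spec()] for the numeric backend.
#' @return A `"profile_matrix"` whose `f` holds model values
#'   (`normalization_value = 1`), with attribute field `backend`.
#' @examples
#' th <- theoretical_profile_set(tube_geometry(), d_eff = 1e-6,
#'                               frame_times = c(240, 3600))
#' @export
theoretical_profile_set <- function(geometry, d_eff, frame_times = NULL,
                                    positions = NULL, like = NULL,
                                    backend = c("analytic", "numeric"),
                                    grid = grid_spec()) {
  stopifnot(inherits(geometry, "tube_geometry"))
  backend <- match.arg(backend)
  if (!is.null(like)) {
    if (!inherits(like, "profile_matrix"))
      stop_invalid("'like' must be a profile_matrix")
    if (!is.null(frame_times) || !is.null(positions))
      stop_invalid("give either 'like' or explicit 'frame_times'/'positions', not both")
    frame_times <- like$times
    positions <- like$positions
  }
  if (is.null(frame_times))
    stop_invalid("'frame_times' is required when 'like' is not given")
  if (any(diff(frame_times) <= 0) || any(frame_times <= 0))
    stop_invalid("'frame_times' must be positive and strictly increasing")
  if (is.null(positions)) {
    img <- imaging_config()
    px_cm <- um_to_cm(img$pixel_size)
    n_px <- round(mm_to_cm(geometry$field_of_view) / px_cm)
    positions <- (seq_len(n_px) - 0.5) * px_cm
  }
  if (any(diff(positions) <= 0) || any(positions < 0))
    stop_invalid("'positions' must be non-negative and strictly increasing")

  if (backend == "analytic") {
    f <- t(vapply(frame_times,
                  function(tt) erfc_profile(positions, tt, d_eff),
                  numeric(length(positions))))
  } else {
    fld <- solve_diffusion_fd(geometry, d_eff, output_times = frame_times,
                              grid = grid, full_domain = TRUE)
    f <- t(vapply(seq_along(frame_times), function(i) {
      approx(fld$positions, fld$values[i, ], xout = positions, rule = 2)$y
    }, numeric(length(positions))))
  }
  new_profile_matrix(f = f, times = frame_times, positions = positions,
                     normalization_value = 1, background = 0,
                     interface_px = NA_real_, pixel_size = NA_real_,
                     t_offset = NA_real_,
                     meta = list(backend = backend, d_eff = d_eff))
}
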