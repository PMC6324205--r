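# Profile-agreement testing and replicate summaries.

#' Chi-square agreement test between two profiles
#'
#' Pearson chi-square comparison of an observed against an expected
#' profile on a shared (x, t) lattice:
#' \eqn{\chi^2 = \sum_i (O_i - E_i)^2 / E_i} over points whose expected
#' value is at least `floor` (tiny expected values would otherwise blow
#' the statistic up on numerically-zero tails), with `dof = n - 1` and an
#' upper-tail p-value.  The comparison is not symmetric: expected values
#' come from the model, observed from data.
#'
#' @param observed,expected Equal-length numeric vectors on a shared
#'   lattice.
#' @param floor Expected-value floor below which points are excluded
#'   (default 1e-3; recorded in the output).
#' @return An object of class `"profile_comparison"`: `chi2`, `dof`,
#'   `p_value`, `n_points`, `floor`.
#' @examples
#' e <- erfc_profile(seq(0.05, 0.3, by = 0.01), 3600, 1e-6)
#' chisq_profile_test(e, e)   # chi2 = 0, p = 1
#' @export
chisq_profile_test <- function(observed, expected, floor = 1e-3) {
  if (length(observed) != length(expected))
    stop_invalid("'observed' and 'expected' must have equal length")
  if (!is.numeric(observed) || !is.numeric(expected))
    stop_invalid("profiles must be numeric")
  keep <- expected >= floor
  if (!any(keep))
    stop_invalid("all expected values fall below the floor (%g); nothing to compare",
                 floor)
  o <- observed[keep]; e <- expected[keep]
  n <- length(o)
  if (n < 2L)
    stop_invalid("need at least 2 points above the floor for dof = n - 1 >= 1")
  chi2 <- sum((o - e)^2 / e)
  dof <- n - 1L
  structure(list(chi2 = chi2, dof = dof,
                 p_value = pchisq(chi2, df = dof, lower.tail = FALSE),
                 n_points = n, floor = floor),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("Profile agreement: chi2 = %.4g on %d dof, p = %.4g (n = %d, floor = %g)\n",
              x$chi2, x$dof, x$p_value, x$n_points, x$floor))
  invisible(x)
}

#' Replicate summary (mean and SEM)
#'
#' Mean and standard error of the mean (sample sd over sqrt(n)) of
#' replicate diffusion-coefficient estimates.  Experiments are summarized
#' over at least three independent replicates; a defined SEM needs n >= 2.
#'
#' @param d_values Numeric vector of replicate estimates, cm^2/s.
#' @return An object of class `"replicate_summary"`: `mean_d`, `sem_d`,
#'   `n`.
#' @examples
#' summarize_replicates(c(1.7e-6, 2.1e-6, 1.9e-6))
#' @export
summarize_replicates <- function(d_values) {
  if (!is.numeric(d_values) || any(!is.finite(d_values)))
    stop_invalid("'d_values' must be finite numbers")
  n <- length(d_values)
  if (n < 2L)
    stop_invalid("need at least 2 replicates for a defined SEM (got %d)", n)
  structure(list(mean_d = mean(d_values),
                 sem_d = sd(d_values) / sqrt(n), n = n),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("D_eff = %.4g +/- %.4g cm^2/s (mean +/- SEM, n = %d)\n",
              x$mean_d, x$sem_d, x$n))
  invisible(x)
}

#' Closed-loop parameter-recovery benchmark
#'
#' For every (true coefficient, seed) cell: render a synthetic stack,
#' extract and normalize profiles, apply the filters, fit, and record the
#' estimate and its relative error.  Deterministic given the seeds.
#'
#' @param d_true True coefficients, cm^2/s.
#' @param seeds Integer RNG seeds; each is combined with each `d_true`.
#' @param gaussian_sigma Additive noise s.d. (fraction of reservoir).
#' @param geometry,imaging,sat,filter,t_offset,bounds Pipeline settings;
#'   see the respective constructors.
#' @param t_offset_mode Passed to [fit_deff()].
#' @return A data frame (class `"recovery_benchmark"`) with one row per
#'   cell: `d_true`, `seed`, `d_hat`, `rel_error`, `n_points`, `ssr`,
#'   `converged`; per-`d_true` medians/maxima of `|rel_error|` in
#'   attribute `"summary"`.
#' @examples
#' \donttest{
#' bm <- run_recovery_benchmark(d_true = 1e-6, seeds = 1:2)
#' attr(bm, "summary")
#' }
#' @export
run_recovery_benchmark <- function(d_true, seeds, gaussian_sigma = 0.01,
                                   geometry = tube_geometry(),
                                   imaging = imaging_config(),
                                   sat = saturation_map(),
                                   filter = filter_spec(),
                                   t_offset = 240,
                                   bounds = c(1e-9, 1e-4),
                                   t_offset_mode = "fixed") {
  if (length(d_true) == 0L || length(seeds) == 0L)
    stop_invalid("'d_true' and 'seeds' must be non-empty")
  cells <- expand.grid(d_true = d_true, seed = as.integer(seeds),
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    d0 <- cells$d_true[i]; sd_i <- cells$seed[i]
    tag <- sprintf("cell (d_true = %.3g, seed = %d)", d0, sd_i)
    stage <- function(name, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("benchmark stage '%s' failed in %s: %s",
                     name, tag, conditionMessage(e)), call. = FALSE))
    }
    bundle <- stage("simulate",
                    render_stack(geometry, imaging, d_eff = d0,
                                 t_offset = t_offset,
                                 noise = noise_model(gaussian_sigma, 0, sd_i),
                                 sat = sat))
    pm <- stage("extract", extract_profiles(bundle))
    fit <- stage("fit", fit_deff(pm, filter = filter, bounds = bounds,
                                 t_offset_mode = t_offset_mode))
    rows[[i]] <- data.frame(d_true = d0, seed = sd_i, d_hat = fit$d_eff,
                            rel_error = (fit$d_eff - d0) / d0,
                            n_points = fit$n_points, ssr = fit$ssr,
                            converged = fit$converged)
  }
  out <- do.call(rbind, rows)
  smry <- do.call(rbind, lapply(split(out, out$d_true), function(s)
    data.frame(d_true = s$d_true[1],
               median_abs_rel_error = stats::median(abs(s$rel_error)),
               max_abs_rel_error = max(abs(s$rel_error)),
               n = nrow(s))))
  rownames(smry) <- NULL
  structure(out, summary = smry,
            class = c("recovery_benchmark", "data.frame"))
}

#' @export
print.recovery_benchmark <- function(x, ...) {
  cat(sprintf("Parameter-recovery benchmark: %d cells\n", nrow(x)))
  print.data.frame(x, digits = 4)
  cat("\nSummary by true coefficient:\n")
  print.data.frame(attr(x, "summary"), digits = 4)
  invisible(x)
}

#' Literature diffusion coefficients (static reference table)
#'
#' Published diffusion coefficients of proteins through aqueous solutions
#' and various hydrogels, shipped as a static reference CSV for context
#' when judging fitted values.
#'
#' @return Data frame with protein, temperature, polymer, measurement
#'   method and coefficient (cm^2/s x 1e6) columns.
#' @export
literature_coefficients <- function() {
  read.csv(system.file("extdata", "literature_diffusion_coefficients.csv",
                       package = "capdiff"), check.names = FALSE)
}
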