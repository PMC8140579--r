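# broom-style tidiers and print methods for fitted objects.

#' @export
tidy.loglogistic_fit <- function(x, ...) {
  tibble(
    term = c("c", "d", "b", "u"),
    estimate = c(x$c, x$d, x$b, x$u),
    fixed = switch(x$constraint_mode,
      anderson_free = c(FALSE, FALSE, FALSE, FALSE),
      flint_c0 = c(TRUE, FALSE, FALSE, FALSE),
      c(TRUE, TRUE, FALSE, FALSE)
    )
  )
}

#' @export
glance.loglogistic_fit <- function(x, ...) {
  tibble(
    constraint_mode = x$constraint_mode,
    pseudo_R2 = x$pseudo_R2,
    LT50 = x$u,
    converged = x$converged,
    n_points = x$n_points
  )
}

#' @export
tidy.gompertz_fit <- function(x, ...) {
  tibble(term = c("b", "k"), estimate = c(x$b, x$k), fixed = c(FALSE, FALSE))
}

#' @export
glance.gompertz_fit <- function(x, ...) {
  tibble(
    pseudo_R2 = x$pseudo_R2,
    LT50 = if (isTRUE(x$converged)) lt_p_gompertz(x, 50) else NA_real_,
    LTmax = if (isTRUE(x$converged)) lt_max_gompertz(x) else NA_real_,
    converged = x$converged,
    n_points = x$n_points
  )
}

#' @export
tidy.deming_fit <- function(x, ...) {
  tibble(term = "slope", estimate = x$slope,
         conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @export
glance.deming_fit <- function(x, ...) {
  tibble(
    slope = x$slope, ci_low = x$ci_low, ci_high = x$ci_high,
    r2_xy = x$r2_xy, r2_yx = x$r2_yx, delta = x$delta,
    n_used = x$n_used, n_outliers = length(x$outlier_ids)
  )
}

#' @export
print.loglogistic_fit <- function(x, ...) {
  cat("Four-parameter log-logistic damage curve (", x$constraint_mode, ")\n", sep = "")
  if (isTRUE(x$converged)) {
    cat(sprintf("  c = %.4g  d = %.4g  b = %.4g  u (LT50) = %.4g degC\n",
                x$c, x$d, x$b, x$u))
    cat(sprintf("  pseudo-R2 = %.4f on %d points\n", x$pseudo_R2, x$n_points))
  } else {
    cat("  did not converge\n")
  }
  invisible(x)
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz damage curve\n")
  if (isTRUE(x$converged)) {
    cat(sprintf("  b = %.4g  k = %.4g  LT50 = %.4g degC  LTmax = %.4g degC\n",
                x$b, x$k, lt_p_gompertz(x, 50), lt_max_gompertz(x)))
    cat(sprintf("  pseudo-R2 = %.4f on %d points\n", x$pseudo_R2, x$n_points))
  } else {
    cat("  did not converge\n")
  }
  invisible(x)
}

#' @export
print.deming_fit <- function(x, ...) {
  cat("Zero-intercept Deming regression\n")
  cat(sprintf("  slope = %.4f  (95%% CI %.4f - %.4f)\n", x$slope, x$ci_low, x$ci_high))
  cat(sprintf("  r2 (y|x) = %.3f  r2 (x|y) = %.3f  n = %d  outliers removed = %d\n",
              x$r2_xy, x$r2_yx, x$n_used, length(x$outlier_ids)))
  invisible(x)
}

#' @export
print.approach_comparison <- function(x, ...) {
  cat("Fitted-value comparison (first approach minus second)\n")
  cat(sprintf("  bias = %.2f  RMSE = %.2f  (%d grid points)\n", x$bias, x$rmse, x$n))
  if (!is.null(x$restrict)) {
    cat(sprintf("  restricted to reference in [%g, %g]: bias = %.2f  RMSE = %.2f (%d points)\n",
                x$restrict[1], x$restrict[2], x$bias_restricted,
                x$rmse_restricted, x$n_restricted))
  }
  cat(sprintf("  fraction within %g-point band of 1:1 line = %.2f\n",
              x$band, x$frac_within_band))
  invisible(x)
}
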