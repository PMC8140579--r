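# Damage-curve fitting.
#
# Four-parameter log-logistic:  y(T) = c + (d - c) / (1 + exp(b (T - u)))
# with b > 0 so damage rises as temperature falls; u is the inflection and
# equals LT50 under the relative-damage convention. Constraint modes fix c
# and/or d to match the standardization approach:
#   anderson_free  - all four free (R series; bounds c >= 0, d <= d_max)
#   flint_c0       - c = 0 (I series)
#   lim_c0_d100    - c = 0, d = 100 (I_adj series)
#   vd_c0_d100     - c = 0, d = 100 (visual damage)
#
# Gompertz (on the percent scale):  y(T) = 100 exp(-b exp(-k T)), b > 0,
# k < 0, an asymmetric alternative for I_adj whose steepest-slope temperature
# LTmax = ln(b)/k is decoupled from LT50.

constraint_modes <- c("anderson_free", "flint_c0", "lim_c0_d100", "vd_c0_d100")

#' Evaluate the four-parameter log-logistic damage curve
#'
#' `y(T) = c + (d - c) / (1 + exp(b (T - u)))`. With `b > 0` the curve rises
#' from `c` (warm) to `d` (cold) with inflection at `u`.
#'
#' @param temperature_C Temperature, degC. Vectorised.
#' @param c,d Lower and upper asymptotes.
#' @param b Slope parameter (positive for freeze damage).
#' @param u Inflection temperature, degC (equals LT50).
#' @return Fitted damage at each temperature.
#' @export
#' @examples
#' loglogistic_eval(-25, c = 0, d = 100, b = 0.3, u = -25) # 50
loglogistic_eval <- function(temperature_C, c, d, b, u) {
  c + (d - c) / (1 + exp(b * (temperature_C - u)))
}

#' Evaluate the Gompertz damage curve
#'
#' `y(T) = 100 exp(-b exp(-k T))` with `b > 0`, `k < 0`: damage tends to 100
#' as temperature falls and to 0 as it warms.
#'
#' @param temperature_C Temperature, degC. Vectorised.
#' @param b,k Gompertz parameters (`b > 0`, `k < 0`).
#' @return Fitted damage (percent).
#' @export
gompertz_eval <- function(temperature_C, b, k) {
  100 * exp(-b * exp(-k * temperature_C))
}

# Deterministic, derivative-free starting values shared by both families.
# Linearise the logistic: with f = (y - c0)/(d0 - c0) clipped away from {0, 1},
# logit(f) = -b (T - u), so an ordinary regression of logit(f) on the
# per-temperature mean temperatures gives b0 (negated slope) and u0 (root).
# A too-shallow b start leaves the four-parameter Jacobian numerically rank
# deficient, so b0 falls back to a mid-steep default rather than ~0.
loglogistic_start <- function(tt, yy) {
  means <- tapply(yy, tt, mean)
  temps <- as.numeric(names(means))
  ord <- order(temps)
  temps <- temps[ord]; means <- as.numeric(means)[ord]
  c0 <- min(means); d0 <- max(means)
  f <- pmin(pmax((means - c0) / max(d0 - c0, 1e-8), 0.02), 0.98)
  lg <- log(f / (1 - f))
  use <- abs(lg) < log(0.98 / 0.02) - 1e-9 # drop clipped plateau points
  b0 <- u0 <- NA_real_
  if (sum(use) >= 2 && sd(temps[use]) > 0) {
    sl <- cov(temps[use], lg[use]) / var(temps[use])
    if (is.finite(sl) && sl < 0) {
      b0 <- -sl
      u0 <- mean(temps[use]) + mean(lg[use]) / b0
    }
  }
  if (!is.finite(b0)) {
    span <- diff(range(temps))
    b0 <- 10 / max(span, 1e-8)
    mid <- (c0 + d0) / 2
    u0 <- approx(means, temps, xout = mid, ties = mean)$y
    if (!is.finite(u0)) u0 <- median(temps)
  }
  list(c0 = max(c0, 0), d0 = d0, b0 = min(max(b0, 0.02), 5), u0 = u0)
}

check_series <- function(tt, yy, n_free, flat_tol) {
  if (length(unique(tt)) < 4) {
    abort("need >= 4 distinct temperatures to fit", class = "cryoleak_degenerate_error")
  }
  if (length(yy) < n_free + 1) {
    abort("too few points for the number of free parameters",
          class = "cryoleak_degenerate_error")
  }
  if (diff(range(yy)) < flat_tol) {
    abort("flat response: series range below tolerance, nothing to fit",
          class = "cryoleak_degenerate_error")
  }
}

fit_diagnostics <- function(yy, fitted) {
  ss_res <- sum((yy - fitted)^2)
  ss_tot <- sum((yy - mean(yy))^2)
  list(ss_res = ss_res, pseudo_R2 = 1 - ss_res / ss_tot)
}

#' Fit a constrained four-parameter log-logistic damage curve
#'
#' Unweighted least squares on replicate-level points (not temperature means)
#' via Levenberg-Marquardt with box bounds. The constraint mode fixes
#' asymptotes to match the standardization approach (see Details in the
#' package vignette). Non-convergence returns a fit flagged
#' `converged = FALSE` rather than an error.
#'
#' @param data A data frame with columns `temperature_C` and `value` (one
#'   replicate-level point per row), e.g. one genotype's rows from
#'   [standardize_leakage()].
#' @param mode Constraint mode: one of `"anderson_free"`, `"flint_c0"`,
#'   `"lim_c0_d100"`, `"vd_c0_d100"`.
#' @param d_max Upper bound on the free upper asymptote (soft headroom above
#'   100 so the optimizer does not stick to the boundary).
#' @param b_max Upper bound on the slope parameter. Quantized responses
#'   (e.g. quartile-scale visual damage) can look like perfect steps, for
#'   which the unconstrained optimum is an unbounded slope; the default caps
#'   the transition width at well under one treatment step (about 1 degC
#'   between 10% and 90% damage) rather than letting the fit diverge.
#' @param flat_tol Minimum response range; flatter series raise a
#'   degenerate-data error.
#' @return An object of class `loglogistic_fit`: parameters `c`, `d`, `b`,
#'   `u`, the constraint mode, `pseudo_R2`, `converged`, `n_points`, and the
#'   data fitted.
#' @export
#' @examples
#' d <- data.frame(temperature_C = rep(c(4, -10, -20, -30, -40, -60, -80), 2))
#' d$value <- loglogistic_eval(d$temperature_C, 0, 100, 0.3, -25)
#' fit <- fit_loglogistic(d, mode = "lim_c0_d100")
#' tidy(fit)
fit_loglogistic <- function(data, mode = constraint_modes, d_max = 110,
                            b_max = 5, flat_tol = 1e-6) {
  mode <- match.arg(mode)
  tt <- data$temperature_C
  yy <- data$value
  n_free <- switch(mode, anderson_free = 4, flint_c0 = 3, lim_c0_d100 = 2, vd_c0_d100 = 2)
  check_series(tt, yy, n_free, flat_tol)
  st <- loglogistic_start(tt, yy)
  df <- data.frame(tt = tt, yy = yy)
  eps <- 1e-6

  spec <- switch(mode,
    anderson_free = list(
      resid = function(p) yy - loglogistic_eval(tt, p[1], p[2], p[3], p[4]),
      start = c(st$c0, min(st$d0, d_max), st$b0, st$u0),
      lower = c(0, -Inf, eps, -Inf),
      upper = c(Inf, d_max, b_max, Inf),
      b_index = 3,
      unpack = function(p) list(c = p[1], d = p[2], b = p[3], u = p[4])
    ),
    flint_c0 = list(
      resid = function(p) yy - loglogistic_eval(tt, 0, p[1], p[2], p[3]),
      start = c(min(st$d0, d_max), st$b0, st$u0),
      lower = c(-Inf, eps, -Inf),
      upper = c(d_max, b_max, Inf),
      b_index = 2,
      unpack = function(p) list(c = 0, d = p[1], b = p[2], u = p[3])
    ),
    list( # lim_c0_d100 and vd_c0_d100
      resid = function(p) yy - loglogistic_eval(tt, 0, 100, p[1], p[2]),
      start = c(st$b0, st$u0),
      lower = c(eps, -Inf),
      upper = c(b_max, Inf),
      b_index = 1,
      unpack = function(p) list(c = 0, d = 100, b = p[1], u = p[2])
    )
  )

  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = spec$start, fn = spec$resid,
                       lower = spec$lower, upper = spec$upper, control = ctrl),
    error = function(e) NULL
  )
  # Step-like responses (e.g. quantized visual-damage scores with identical
  # replicates) have their unconstrained optimum at an unbounded slope: the
  # optimizer then exhausts iterations crawling along a flat valley. Profile
  # the slope at its bound; if that boundary solution is at least as good,
  # take it as the (boundary) least-squares fit.
  if (!is.null(fit) && fit$info %in% c(-1, 5)) {
    bi <- spec$b_index
    subfn <- function(q) {
      p <- numeric(length(spec$start))
      p[-bi] <- q
      p[bi] <- b_max
      spec$resid(p)
    }
    bfit <- tryCatch(
      minpack.lm::nls.lm(par = fit$par[-bi], fn = subfn,
                         lower = spec$lower[-bi], upper = spec$upper[-bi],
                         control = ctrl),
      error = function(e) NULL
    )
    if (!is.null(bfit) && bfit$info %in% 1:4 &&
        bfit$deviance <= fit$deviance * (1 + 1e-8) + 1e-12) {
      p <- numeric(length(spec$start))
      p[-bi] <- bfit$par
      p[bi] <- b_max
      fit$par <- p
      fit$info <- 1
    }
  }
  # info codes 1-4 indicate a satisfied convergence criterion
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    out <- list(c = NA_real_, d = NA_real_, b = NA_real_, u = NA_real_,
                constraint_mode = mode, pseudo_R2 = NA_real_,
                converged = FALSE, n_points = length(yy), data = df)
    class(out) <- "loglogistic_fit"
    warn(sprintf("log-logistic fit (%s) did not converge", mode))
    return(out)
  }

  pars <- spec$unpack(fit$par)
  fitted_y <- loglogistic_eval(tt, pars$c, pars$d, pars$b, pars$u)
  diag <- fit_diagnostics(yy, fitted_y)
  out <- c(pars, list(constraint_mode = mode, pseudo_R2 = diag$pseudo_R2,
                      ss_res = diag$ss_res, converged = TRUE,
                      n_points = length(yy), data = df))
  class(out) <- "loglogistic_fit"
  out
}

#' Fit a Gompertz damage curve
#'
#' Fits `y(T) = 100 exp(-b exp(-k T))` to adjusted-index (percent-scale)
#' points by bounded Levenberg-Marquardt least squares, with `b > 0` and
#' `k < 0` enforced.
#'
#' @inheritParams fit_loglogistic
#' @return An object of class `gompertz_fit` with `b`, `k`, `pseudo_R2`,
#'   `converged`, `n_points`.
#' @export
fit_gompertz <- function(data, flat_tol = 1e-6) {
  tt <- data$temperature_C
  yy <- data$value
  check_series(tt, yy, 2, flat_tol)
  st <- loglogistic_start(tt, yy)
  # At T = u0 the logistic is at half range; matching the Gompertz midpoint
  # 100 exp(-b exp(-k u0)) = 50 with slope-scale k0 gives the start below.
  k0 <- -max(st$b0 / 2, 1e-3)
  b0 <- log(2) * exp(k0 * st$u0)
  b0 <- min(max(b0, 1e-8), 1e8)
  df <- data.frame(tt = tt, yy = yy)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(b0, k0),
      fn = function(p) yy - gompertz_eval(tt, p[1], p[2]),
      lower = c(1e-12, -Inf), upper = c(Inf, -1e-12),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !(fit$info %in% 1:4)) {
    out <- list(b = NA_real_, k = NA_real_, pseudo_R2 = NA_real_,
                converged = FALSE, n_points = length(yy), data = df)
    class(out) <- "gompertz_fit"
    warn("Gompertz fit did not converge")
    return(out)
  }
  p <- fit$par
  fitted_y <- gompertz_eval(tt, p[1], p[2])
  diag <- fit_diagnostics(yy, fitted_y)
  out <- list(b = p[1], k = p[2], pseudo_R2 = diag$pseudo_R2,
              ss_res = diag$ss_res, converged = TRUE,
              n_points = length(yy), data = df)
  class(out) <- "gompertz_fit"
  out
}

#' Critical temperature from a log-logistic fit
#'
#' Solves the fitted curve for the temperature at which damage reaches `p`%
#' of the fitted span `c -> d` (the relative-damage convention):
#' `LT_p = u + ln((100 - p)/p) / b`. `LT_50 = u` exactly. With
#' `absolute = TRUE` the threshold is instead `p` on the response scale
#' itself; `NA` is returned (with a warning) when `p` lies outside `(c, d)`.
#'
#' @param fit A `loglogistic_fit`.
#' @param p Damage threshold(s), percent, in `(0, 100)`.
#' @param absolute Use the absolute-threshold variant.
#' @return Temperature(s), degC.
#' @export
lt_from_loglogistic <- function(fit, p, absolute = FALSE) {
  stopifnot(inherits(fit, "loglogistic_fit"))
  if (any(p <= 0 | p >= 100)) abort("p must be in (0, 100)", class = "cryoleak_domain_error")
  if (!isTRUE(fit$converged)) return(rep(NA_real_, length(p)))
  if (absolute) {
    frac <- (p - fit$c) / (fit$d - fit$c)
    bad <- frac <= 0 | frac >= 1
    if (any(bad)) warn("absolute threshold outside the fitted span; returning NA")
    out <- ifelse(bad, NA_real_, fit$u + log((1 - frac) / frac) / fit$b)
    return(out)
  }
  fit$u + log((100 - p) / p) / fit$b
}

#' Temperature of maximum slope of a Gompertz fit
#'
#' `LTmax = ln(b)/k`, the inflection of the Gompertz curve, i.e. the
#' temperature at which damage accrues fastest. With `k < 0` this lies warmer
#' than LT50, reflecting the curve's asymmetry.
#'
#' @param fit A `gompertz_fit`.
#' @return Temperature, degC.
#' @export
lt_max_gompertz <- function(fit) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (!isTRUE(fit$converged)) return(NA_real_)
  if (fit$b <= 0) abort("Gompertz b must be > 0", class = "cryoleak_domain_error")
  log(fit$b) / fit$k
}

#' Critical temperature from a Gompertz fit
#'
#' Inverts `y(T) = 100 exp(-b exp(-k T))` at damage level `p`:
#' `LT_p = (ln(b) - ln(ln(100/p))) / k`.
#'
#' @param fit A `gompertz_fit`.
#' @param p Damage threshold(s), percent, in `(0, 100)`.
#' @return Temperature(s), degC.
#' @export
lt_p_gompertz <- function(fit, p) {
  stopifnot(inherits(fit, "gompertz_fit"))
  if (any(p <= 0 | p >= 100)) abort("p must be in (0, 100)", class = "cryoleak_domain_error")
  if (!isTRUE(fit$converged)) return(rep(NA_real_, length(p)))
  (log(fit$b) - log(log(100 / p))) / fit$k
}

# Map a standardization kind / data role to the fitting family + constraints.
approach_spec <- function(approach) {
  switch(approach,
    anderson = list(kind = "R", family = "loglogistic", mode = "anderson_free"),
    flint = list(kind = "I", family = "loglogistic", mode = "flint_c0"),
    lim_logistic = list(kind = "I_adj", family = "loglogistic", mode = "lim_c0_d100"),
    lim_gompertz = list(kind = "I_adj", family = "gompertz", mode = NULL),
    vd = list(kind = "VD", family = "loglogistic", mode = "vd_c0_d100"),
    abort(sprintf("unknown approach '%s'", approach), class = "cryoleak_domain_error")
  )
}

#' Fit damage curves for every genotype (or species) in a series table
#'
#' Maps [fit_loglogistic()] / [fit_gompertz()] over a standardized leakage (or
#' visual damage) table. At `level = "species"`, replicate-level points are
#' pooled across genotypes before fitting. Genotypes whose fit fails or does
#' not converge are kept in the table with `converged = FALSE` and a warning,
#' so downstream joins show them as missing rather than wrong.
#'
#' @param series Tibble with `species`, `genotype`, `temperature_C`, `value`
#'   columns (e.g. from [standardize_leakage()], or a visual-damage table with
#'   `damage_pct` renamed to `value`).
#' @param approach One of `"anderson"`, `"flint"`, `"lim_logistic"`,
#'   `"lim_gompertz"`, `"vd"`. Controls the curve family and constraints; the
#'   caller is responsible for supplying the matching index kind.
#' @param level `"genotype"` (default) or `"species"` (pooled points).
#' @return A tibble with one row per unit: `level`, `id`, `species`,
#'   `approach`, a list-column `fit`, and unnested `pseudo_R2`, `converged`.
#' @export
fit_damage_curves <- function(series,
                              approach = c("anderson", "flint", "lim_logistic",
                                           "lim_gompertz", "vd"),
                              level = c("genotype", "species")) {
  approach <- match.arg(approach)
  level <- match.arg(level)
  spec <- approach_spec(approach)
  if (nrow(series) == 0) abort("empty series table", class = "cryoleak_domain_error")
  # R series arrive as fractions; the free-asymptote fit is presented on the
  # percent scale (affine rescaling leaves u and b, hence every LT, unchanged).
  if (approach == "anderson" && max(abs(series$value), na.rm = TRUE) <= 1.5) {
    series <- mutate(series, value = .data$value * 100)
  }
  keys <- if (level == "genotype") c("species", "genotype") else "species"
  groups <- series |>
    group_by(across(all_of(keys))) |>
    tidyr::nest() |>
    ungroup()
  fits <- map(groups$data, function(d) {
    tryCatch(
      if (spec$family == "gompertz") fit_gompertz(d) else fit_loglogistic(d, mode = spec$mode),
      cryoleak_degenerate_error = function(e) {
        warn(conditionMessage(e))
        NULL
      }
    )
  })
  tibble(
    level = level,
    id = if (level == "genotype") groups$genotype else groups$species,
    species = groups$species,
    approach = approach,
    fit = fits,
    pseudo_R2 = map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$pseudo_R2),
    converged = map_dbl(fits, ~ if (is.null(.x)) FALSE else isTRUE(.x$converged)) > 0
  )
}

#' Critical-value table from fitted damage curves
#'
#' Extracts LT thresholds (and, for Gompertz fits, LTmax) from a table of
#' fits, in the long layout written by [write_critical_value_table()].
#'
#' @param fits Tibble from [fit_damage_curves()].
#' @param thresholds Damage thresholds, percent.
#' @param include_ltmax Add the `LTmax` row for Gompertz fits.
#' @return Tidy tibble: `level`, `id`, `species`, `approach`, `metric`
#'   (`"LT20"`, `"LT50"`, ..., `"LTmax"`), `temperature_C`. Non-converged
#'   fits yield `NA` temperatures.
#' @export
critical_value_table <- function(fits, thresholds = c(20, 50, 80),
                                 include_ltmax = TRUE) {
  rows <- pmap(list(fits$fit, fits$level, fits$id, fits$species, fits$approach),
    function(fit, level, id, species, approach) {
      lt <- if (is.null(fit)) {
        rep(NA_real_, length(thresholds))
      } else if (inherits(fit, "gompertz_fit")) {
        lt_p_gompertz(fit, thresholds)
      } else {
        lt_from_loglogistic(fit, thresholds)
      }
      out <- tibble(
        level = level, id = id, species = species, approach = approach,
        metric = paste0("LT", thresholds), temperature_C = lt
      )
      if (include_ltmax && inherits(fit, "gompertz_fit")) {
        out <- bind_rows(out, tibble(
          level = level, id = id, species = species, approach = approach,
          metric = "LTmax",
          temperature_C = if (isTRUE(fit$converged)) lt_max_gompertz(fit) else NA_real_
        ))
      }
      out
    })
  list_rbind(rows)
}
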