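# Control calibration: zero-intercept Deming ("least rectangle") regression of
# liquid-nitrogen against autoclave conductivities, and conversion of leakage
# between the two control standards.
#
# For a line through the origin y = s x with error-variance ratio
# delta = var(e_y)/var(e_x), the errors-in-variables loss is
#   L(s) = sum (y_i - s x_i)^2 / (delta + s^2),
# minimized in closed form by
#   s = [ (Syy - delta Sxx) + sqrt((Syy - delta Sxx)^2 + 4 delta Sxy^2) ] / (2 Sxy)
# with uncentred moments Sxx = sum x^2 etc. With delta = 1 this is orthogonal
# regression and satisfies the reciprocity slope(y~x) * slope(x~y) = 1.

deming_slope_closed_form <- function(x, y, delta = 1) {
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  if (sxy == 0) abort("x and y are orthogonal; slope undefined", class = "cryoleak_domain_error")
  a <- syy - delta * sxx
  (a + sqrt(a^2 + 4 * delta * sxy^2)) / (2 * sxy)
}

#' Zero-intercept Deming regression of paired control conductivities
#'
#' Fits `y = slope * x` through the origin taking measurement error on both
#' axes into account (errors-in-variables, "least rectangle" regression), as
#' used to calibrate liquid-nitrogen against autoclave maximum-damage
#' controls. Outliers (by default: perpendicular residuals from an initial
#' all-data fit exceeding 3 x 1.4826 x MAD, a single pass) are removed once
#' and the fit recomputed. A seeded nonparametric bootstrap gives a 95%
#' confidence interval on the slope. Goodness of fit is reported as ordinary
#' R-squared with residuals taken in each direction (`r2_xy`: y given x;
#' `r2_yx`: x given y).
#'
#' @param pairs Data frame with numeric columns `x` (e.g. autoclave
#'   conductivity, uS/cm) and `y` (e.g. liquid-nitrogen conductivity), one
#'   tube per row.
#' @param delta Error-variance ratio var(y-error)/var(x-error). Default 1:
#'   both axes are read with the same instrument.
#' @param outlier_policy `"mad"` (default) or `"none"`.
#' @param mad_k Outlier cut in robust SDs of perpendicular residual.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed Integer seed for the bootstrap (reproducible by default).
#' @param conf Confidence level.
#' @return An object of class `deming_fit`: `slope`, `ci_low`, `ci_high`,
#'   `r2_xy`, `r2_yx`, `delta`, `outlier_ids` (row indices removed),
#'   `n_used`, and the data.
#' @export
#' @examples
#' p <- data.frame(x = c(100, 200, 300), y = c(58, 116, 174))
#' deming_zero_intercept(p)$slope # 0.58
deming_zero_intercept <- function(pairs, delta = 1,
                                  outlier_policy = c("mad", "none"),
                                  mad_k = 3, n_boot = 10000, seed = 17,
                                  conf = 0.95) {
  outlier_policy <- match.arg(outlier_policy)
  x <- as.numeric(pairs$x); y <- as.numeric(pairs$y)
  if (any(is.na(x)) || any(is.na(y))) {
    abort("unpaired or missing values in x/y", class = "cryoleak_domain_error")
  }
  if (length(x) < 3) abort("need at least 3 pairs", class = "cryoleak_domain_error")
  if (all(x == 0)) abort("all x are zero", class = "cryoleak_domain_error")
  if (delta <= 0) abort("delta must be > 0", class = "cryoleak_domain_error")

  outlier_ids <- integer(0)
  if (outlier_policy == "mad") {
    s0 <- deming_slope_closed_form(x, y, delta)
    perp <- (y - s0 * x) / sqrt(delta + s0^2)
    cut <- mad_k * mad(perp) # mad() already scales by 1.4826
    if (cut > 0) outlier_ids <- which(abs(perp) > cut)
  }
  keep <- setdiff(seq_along(x), outlier_ids)
  xk <- x[keep]; yk <- y[keep]
  if (length(xk) < 3) abort("fewer than 3 pairs remain after outlier removal",
                            class = "cryoleak_domain_error")
  slope <- deming_slope_closed_form(xk, yk, delta)

  r2_dir <- function(obs, fit) 1 - sum((obs - fit)^2) / sum((obs - mean(obs))^2)
  r2_xy <- r2_dir(yk, slope * xk)
  r2_yx <- r2_dir(xk, yk / slope)

  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- length(xk)
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        tryCatch(deming_slope_closed_form(xk[idx], yk[idx], delta),
                 error = function(e) NA_real_)
      }, numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }

  out <- list(
    slope = slope, ci_low = ci[1], ci_high = ci[2],
    r2_xy = r2_xy, r2_yx = r2_yx, delta = delta,
    outlier_ids = outlier_ids, n_used = length(xk),
    data = tibble(x = x, y = y, outlier = seq_along(x) %in% outlier_ids)
  )
  class(out) <- "deming_fit"
  out
}

#' Convert relative leakage from an autoclave to a liquid-nitrogen standard
#'
#' Divides autoclave-referenced relative leakage by the calibration slope
#' (liquid-nitrogen conductivity per unit autoclave conductivity), capping
#' the result at `cap` since converted relative leakage above 100% of the
#' liquid-nitrogen maximum is physically meaningless. Capped records are
#' counted in a warning.
#'
#' @param R_auto Relative leakage under an autoclave control, fraction.
#' @param slope Calibration slope (e.g. `deming_zero_intercept(...)$slope`).
#' @param cap Upper cap on converted leakage; `Inf` disables capping.
#' @return Converted relative leakage, fraction.
#' @export
#' @examples
#' convert_to_ln_standard(0.288, slope = 0.576) # 0.5
convert_to_ln_standard <- function(R_auto, slope, cap = 1) {
  if (!is.finite(slope) || slope <= 0) abort("slope must be > 0", class = "cryoleak_domain_error")
  r <- R_auto / slope
  n_cap <- sum(r > cap)
  if (is.finite(cap) && n_cap > 0) {
    warn(sprintf("%d converted value(s) capped at %g", n_cap, cap))
    r <- pmin(r, cap)
  }
  r
}

#' Mean per-tube ratio between two control treatments
#'
#' For tubes measured under two maximum-damage controls (e.g. liquid nitrogen
#' then autoclave), returns the mean and dispersion of the per-tube ratio
#' `y / x`.
#'
#' @param pairs Data frame with columns `x` and `y`; optionally an `id`
#'   column naming the pairing key (rows with a missing member are reported
#'   as orphans and raise an error).
#' @return One-row tibble: `mean_ratio`, `sd_ratio`, `n`.
#' @export
#' @examples
#' mean_control_ratio(data.frame(x = c(100, 200), y = c(58, 116)))$mean_ratio # 0.58
mean_control_ratio <- function(pairs) {
  x <- as.numeric(pairs$x); y <- as.numeric(pairs$y)
  orphan <- which(is.na(x) | is.na(y))
  if (length(orphan) > 0) {
    ids <- if ("id" %in% names(pairs)) pairs$id[orphan] else orphan
    abort(sprintf("unpaired tubes (one control missing): %s",
                  paste(ids, collapse = ", ")),
          class = "cryoleak_domain_error")
  }
  if (any(x <= 0)) abort("denominator conductivities must be > 0",
                         class = "cryoleak_domain_error")
  ratio <- y / x
  tibble(mean_ratio = mean(ratio), sd_ratio = sd(ratio), n = length(ratio))
}

#' Re-express a dataset under a liquid-nitrogen control and refit
#'
#' Converts an autoclave-referenced dataset to an assumed liquid-nitrogen
#' standard (post-control conductivities multiplied by the calibration slope,
#' so relative leakage divides by it), recomputes the `R` and `I` series, and
#' refits the requested approach before and after conversion. The adjusted
#' index is unaffected by the control standard (the slope cancels in
#' `(R - R_o)/(R_max - R_o)`), which this function exposes by returning both
#' versions.
#'
#' @param records Conductivity tibble standardized against an autoclave
#'   control (`L_K_uS` present).
#' @param slope Calibration slope (liquid-nitrogen / autoclave conductivity).
#' @param approach `"anderson"` (R series) or `"flint"` (I series).
#' @param cap Cap applied to converted relative leakage (see
#'   [convert_to_ln_standard()]); the cap is applied to the `R`/`I` series
#'   only, never inside the adjusted index.
#' @return A list: `fits_before`, `fits_after` (tibbles from
#'   [fit_damage_curves()]), `series_before`, `series_after`, and
#'   `i_adj_before` / `i_adj_after` (value vectors demonstrating invariance).
#' @export
refit_under_converted_control <- function(records, slope,
                                          approach = c("anderson", "flint"),
                                          cap = 1) {
  approach <- match.arg(approach)
  if (!is.finite(slope) || slope <= 0) abort("slope must be > 0", class = "cryoleak_domain_error")
  kind <- approach_spec(approach)$kind
  series_before <- suppressWarnings(standardize_leakage(records, kind = kind))
  converted <- mutate(records, L_K_uS = .data$L_K_uS * slope)
  series_after <- suppressWarnings(standardize_leakage(converted, kind = kind))
  if (is.finite(cap)) {
    upper <- if (kind == "R") cap else 100 * cap
    series_after <- mutate(series_after, value = pmin(.data$value, upper))
  }
  i_adj_before <- suppressWarnings(standardize_leakage(records, kind = "I_adj"))
  i_adj_after <- suppressWarnings(standardize_leakage(converted, kind = "I_adj"))
  list(
    fits_before = suppressWarnings(fit_damage_curves(series_before, approach = approach)),
    fits_after = suppressWarnings(fit_damage_curves(series_after, approach = approach)),
    series_before = series_before,
    series_after = series_after,
    i_adj_before = i_adj_before$value,
    i_adj_after = i_adj_after$value
  )
}
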