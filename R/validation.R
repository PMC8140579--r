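# Cross-method validation: agreement metrics between leakage-derived and
# visual-damage-derived critical temperatures, threshold grids, fitted-curve
# comparisons, and the lowest survival temperature.

#' Mean bias between paired predictions and observations
#'
#' `bias = mean(pred - obs)`. Sign convention: the first argument minus the
#' second, i.e. leakage minus the reference when validating electrolyte
#' leakage. A positive bias in degC means the prediction is warmer.
#'
#' @param pred,obs Paired numeric vectors.
#' @return Mean difference.
#' @export
bias <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  mean(pred - obs)
}

#' Root-mean-square error between paired predictions and observations
#'
#' @inheritParams bias
#' @return RMSE (same units as the inputs).
#' @export
rmse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  sqrt(mean((pred - obs)^2))
}

# Species-level metrics are correlated at species means; everything else at
# genotype level. LTE is the only species-level metric in the standard design.
species_level_metrics <- "LTE"

#' Correlation matrix of critical cold-hardiness values across approaches
#'
#' Aligns critical values by genotype (columns = approach x metric) and
#' returns all pairwise correlations with significance flags. Pairs that
#' involve a species-level metric (LTE) are computed on species means of both
#' members; all other pairs use genotype-level values.
#'
#' @param cv Tidy critical-value table (columns `id`, `species`, `approach`,
#'   `metric`, `temperature_C`), e.g. [critical_value_table()] output from
#'   several approaches bound together, plus any LST/LTE rows.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param alpha Significance level for the `significant` flag.
#' @return A tibble of class `cv_correlations`: `var1`, `var2` (approach and
#'   metric pasted), `rho`, `p_value`, `n`, `significant`. Pairs with fewer
#'   than 3 aligned values have `rho = NA`.
#' @export
critical_value_correlations <- function(cv, method = c("pearson", "spearman"),
                                        alpha = 0.05) {
  method <- match.arg(method)
  cv <- mutate(cv, var = paste(.data$approach, .data$metric, sep = "_"))
  vars <- unique(cv$var)
  sp_means <- cv |>
    group_by(.data$species, .data$var) |>
    summarise(value = mean(.data$temperature_C, na.rm = TRUE), .groups = "drop")
  geno <- cv |>
    group_by(.data$id, .data$species, .data$var) |>
    summarise(value = mean(.data$temperature_C, na.rm = TRUE), .groups = "drop")
  is_species_metric <- function(v) any(vapply(species_level_metrics, grepl, logical(1), x = v))

  pair_cor <- function(v1, v2) {
    if (is_species_metric(v1) || is_species_metric(v2)) {
      w <- tidyr::pivot_wider(filter(sp_means, .data$var %in% c(v1, v2)),
                              id_cols = "species", names_from = "var",
                              values_from = "value")
    } else {
      w <- tidyr::pivot_wider(filter(geno, .data$var %in% c(v1, v2)),
                              id_cols = c("id", "species"), names_from = "var",
                              values_from = "value")
    }
    if (!all(c(v1, v2) %in% names(w))) return(tibble(rho = NA_real_, p_value = NA_real_, n = 0L))
    a <- w[[v1]]; b <- w[[v2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) return(tibble(rho = NA_real_, p_value = NA_real_, n = sum(ok)))
    ct <- suppressWarnings(cor.test(a[ok], b[ok], method = method))
    tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
  }

  combos <- utils::combn(vars, 2, simplify = FALSE)
  out <- list_rbind(map(combos, function(vv) {
    mutate(pair_cor(vv[1], vv[2]), var1 = vv[1], var2 = vv[2], .before = 1)
  }))
  out <- mutate(out, significant = !is.na(.data$p_value) & .data$p_value < alpha)
  class(out) <- c("cv_correlations", class(out))
  out
}

#' Threshold grid of agreement between leakage and visual damage
#'
#' For every pair of damage thresholds `(p, q)` on a 10-90% grid (10% steps),
#' extracts `LT_p` from the electrolyte-leakage fits and `LT_q` from the
#' visual-damage fits of the shared genotypes and computes their
#' across-genotype correlation, bias (`EL - VD`, degC) and RMSE. Boolean
#' agreement masks at the conventional cutoffs (correlation > 0.55,
#' |bias| < 5 degC, RMSE < 7 degC) are included.
#'
#' @param el_fits,vd_fits Fit tables from [fit_damage_curves()] (any curve
#'   family) sharing genotype `id`s.
#' @param thresholds Grid of thresholds, percent.
#' @param cutoffs Named list with `cor`, `bias`, `rmse` mask cutoffs.
#' @return A tibble of class `threshold_grid`: `el_p`, `vd_p`, `correlation`,
#'   `bias`, `rmse`, `n`, and logical `ok_cor`, `ok_bias`, `ok_rmse`.
#' @export
threshold_grid <- function(el_fits, vd_fits, thresholds = seq(10, 90, by = 10),
                           cutoffs = list(cor = 0.55, bias = 5, rmse = 7)) {
  shared <- intersect(el_fits$id, vd_fits$id)
  if (length(shared) == 0) abort("no shared genotypes between the fit sets",
                                 class = "cryoleak_domain_error")
  lt_of <- function(fits, p) {
    map_dbl(shared, function(g) {
      fit <- fits$fit[[match(g, fits$id)]]
      if (is.null(fit)) return(NA_real_)
      if (inherits(fit, "gompertz_fit")) lt_p_gompertz(fit, p) else lt_from_loglogistic(fit, p)
    })
  }
  el_lt <- lapply(thresholds, function(p) lt_of(el_fits, p))
  vd_lt <- lapply(thresholds, function(p) lt_of(vd_fits, p))
  grid <- tidyr::expand_grid(el_p = thresholds, vd_p = thresholds)
  cells <- pmap(grid, function(el_p, vd_p) {
    a <- el_lt[[match(el_p, thresholds)]]
    b <- vd_lt[[match(vd_p, thresholds)]]
    ok <- is.finite(a) & is.finite(b)
    a <- a[ok]; b <- b[ok]
    tibble(
      correlation = if (length(a) >= 3 && sd(a) > 0 && sd(b) > 0) cor(a, b) else NA_real_,
      bias = if (length(a) >= 1) bias(a, b) else NA_real_,
      rmse = if (length(a) >= 1) rmse(a, b) else NA_real_,
      n = length(a)
    )
  })
  out <- dplyr::bind_cols(grid, list_rbind(cells))
  out <- mutate(out,
    ok_cor = !is.na(.data$correlation) & .data$correlation > cutoffs$cor,
    ok_bias = !is.na(.data$bias) & abs(.data$bias) < cutoffs$bias,
    ok_rmse = !is.na(.data$rmse) & .data$rmse < cutoffs$rmse
  )
  class(out) <- c("threshold_grid", class(out))
  out
}

#' Compare fitted damage values between two approaches
#'
#' Evaluates two sets of genotype fits on a shared temperature grid (fitted
#' values, not raw points) and summarises their agreement: overall bias and
#' RMSE in percentage points (first approach minus second), the same
#' restricted to grid points where the reference (second) approach predicts
#' damage inside `restrict`, and the fraction of points within `band`
#' percentage points of the 1:1 line.
#'
#' @param fits_a,fits_b Fit tables from [fit_damage_curves()] sharing
#'   genotype `id`s. `fits_b` is the reference (e.g. the Lim-logistic fits).
#' @param t_grid Temperatures at which to evaluate, degC. Default: 1-degC
#'   steps spanning -80 to 4.
#' @param restrict Two-element range (percent of the reference value) for the
#'   restricted statistics; `NULL` skips them.
#' @param band Half-width of the 1:1 agreement band, percentage points.
#' @param scale100 Rescale fraction-scale fitted values (max <= 1.5) to
#'   percent before comparison.
#' @return A list of class `approach_comparison`: `points` (tibble of paired
#'   fitted values), `bias`, `rmse`, `bias_restricted`, `rmse_restricted`,
#'   `frac_within_band`, `n`, `n_restricted`.
#' @export
compare_fitted_approaches <- function(fits_a, fits_b,
                                      t_grid = seq(-80, 4, by = 1),
                                      restrict = NULL, band = 15,
                                      scale100 = TRUE) {
  shared <- intersect(fits_a$id, fits_b$id)
  if (length(shared) == 0) abort("no shared genotypes", class = "cryoleak_domain_error")
  eval_fit <- function(fit) {
    if (is.null(fit) || !isTRUE(fit$converged)) return(rep(NA_real_, length(t_grid)))
    if (inherits(fit, "gompertz_fit")) {
      gompertz_eval(t_grid, fit$b, fit$k)
    } else {
      loglogistic_eval(t_grid, fit$c, fit$d, fit$b, fit$u)
    }
  }
  pts <- list_rbind(map(shared, function(g) {
    va <- eval_fit(fits_a$fit[[match(g, fits_a$id)]])
    vb <- eval_fit(fits_b$fit[[match(g, fits_b$id)]])
    tibble(id = g, temperature_C = t_grid, value_a = va, value_b = vb)
  }))
  pts <- filter(pts, is.finite(.data$value_a) & is.finite(.data$value_b))
  if (scale100) {
    rescale <- function(v) if (max(abs(v)) <= 1.5) v * 100 else v
    pts <- mutate(pts, value_a = rescale(.data$value_a), value_b = rescale(.data$value_b))
  }
  res <- list(
    points = pts,
    bias = bias(pts$value_a, pts$value_b),
    rmse = rmse(pts$value_a, pts$value_b),
    frac_within_band = mean(abs(pts$value_a - pts$value_b) <= band),
    n = nrow(pts),
    bias_restricted = NA_real_, rmse_restricted = NA_real_, n_restricted = 0L,
    restrict = restrict, band = band
  )
  if (!is.null(restrict)) {
    sub <- filter(pts, .data$value_b >= restrict[1], .data$value_b <= restrict[2])
    if (nrow(sub) == 0) {
      warn("restricted range contains no grid points; restricted stats undefined")
    } else {
      res$bias_restricted <- bias(sub$value_a, sub$value_b)
      res$rmse_restricted <- rmse(sub$value_a, sub$value_b)
      res$n_restricted <- nrow(sub)
    }
  }
  class(res) <- "approach_comparison"
  res
}

#' Lowest survival temperature from visual-damage scores
#'
#' For each species, the coldest tested temperature at which no stem segment
#' experienced more than 50% visual damage. The definition is applied per
#' temperature independently (no monotonicity repair). If it is already
#' violated at the warmest freezing (sub-zero) temperature, the LST is
#' undefined (`NA`) with a warning.
#'
#' @param vd_records Visual-damage tibble (`species`, `temperature_C`,
#'   `damage_pct`), quartile scale.
#' @param max_damage Survival cutoff, percent (default 50).
#' @return A tibble: `species`, `LST_C`.
#' @export
lowest_survival_temperature <- function(vd_records, max_damage = 50) {
  if (nrow(vd_records) == 0) abort("empty visual-damage input", class = "cryoleak_domain_error")
  vd_records |>
    group_by(.data$species) |>
    summarise(LST_C = {
      ok_tbl <- dplyr::pick(dplyr::everything()) |>
        group_by(.data$temperature_C) |>
        summarise(ok = all(.data$damage_pct <= max_damage), .groups = "drop")
      frz <- filter(ok_tbl, .data$temperature_C < 0)
      if (nrow(frz) < 1) {
        warn("fewer than one freezing temperature; LST undefined")
        NA_real_
      } else if (!frz$ok[which.max(frz$temperature_C)]) {
        warn(sprintf("damage above %g%% already at the warmest freezing temperature; LST undefined",
                     max_damage))
        NA_real_
      } else {
        min(ok_tbl$temperature_C[ok_tbl$ok])
      }
    }, .groups = "drop")
}
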