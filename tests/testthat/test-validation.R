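test_that("bias and RMSE follow their definitions and symmetry", {
  expect_equal(bias(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bias(c(4, 5, 6), c(1, 2, 3)), 3)
  expect_equal(bias(-20, -23), 3)
  expect_equal(rmse(c(1, 2), c(1, 2)), 0)
  expect_equal(rmse(c(4, 5, 6), c(1, 2, 3)), 3)
  expect_equal(rmse(c(0, 0), c(0, 4)), sqrt(8), tolerance = 1e-9) # hand arithmetic
  withr::with_seed(2, {
    a <- rnorm(20); b <- rnorm(20)
    expect_equal(bias(a, b), -bias(b, a))
    expect_equal(rmse(a, b), rmse(b, a))
  })
})

make_cv <- function(values, approach, metric = "LT50") {
  tibble::tibble(
    level = "genotype", id = paste0("g", seq_along(values)),
    species = paste0("s", rep(seq_len(ceiling(length(values) / 3)), each = 3))[seq_along(values)],
    approach = approach, metric = metric, temperature_C = values
  )
}

test_that("critical-value correlations: identical approaches correlate at 1, inverted at -1", {
  withr::with_seed(4, {
    v <- sort(rnorm(12, -25, 5))
    cv <- dplyr::bind_rows(
      make_cv(v, "lim_logistic"),
      make_cv(v, "duplicate"),
      make_cv(-v, "antimonotone")
    )
    out <- critical_value_correlations(cv)
    self <- out[out$var1 == "lim_logistic_LT50" & out$var2 == "duplicate_LT50", ]
    expect_equal(self$rho, 1, tolerance = 1e-12)
    anti <- out[out$var1 == "lim_logistic_LT50" & out$var2 == "antimonotone_LT50", ]
    expect_equal(anti$rho, -1, tolerance = 1e-12)
    expect_true(all(out$n == 12))
  })
})

test_that("LTE pairs are correlated at species means, not genotype level", {
  withr::with_seed(9, {
    v <- rnorm(12, -25, 4)
    cv <- dplyr::bind_rows(
      make_cv(v, "lim_logistic"),
      make_cv(v - 10 + rnorm(12, 0, 1), "dta", metric = "LTE")
    )
    out <- critical_value_correlations(cv)
    lte_row <- out[grepl("LTE", out$var2) | grepl("LTE", out$var1), ]
    expect_true(all(lte_row$n == 4)) # 4 species of 3 genotypes
  })
})

test_that("threshold grid: identical fits give a perfect diagonal; a -3 degC shift shows as bias", {
  withr::with_seed(14, {
    fits <- purrr::map(1:8, function(i) {
      u <- runif(1, -32, -15)
      fit_loglogistic(loglogistic_series(b = 0.3, u = u), mode = "lim_c0_d100")
    })
    ftab <- tibble::tibble(
      level = "genotype", id = paste0("g", 1:8), species = "s",
      approach = "lim_logistic", fit = fits,
      pseudo_R2 = purrr::map_dbl(fits, "pseudo_R2"), converged = TRUE
    )
    g_same <- threshold_grid(ftab, ftab)
    diag <- g_same[g_same$el_p == g_same$vd_p, ]
    expect_equal(diag$bias, rep(0, 9), tolerance = 1e-9)
    expect_equal(diag$rmse, rep(0, 9), tolerance = 1e-9)
    expect_equal(diag$correlation, rep(1, 9), tolerance = 1e-9)
    expect_true(all(diag$ok_cor & diag$ok_bias & diag$ok_rmse))

    shifted <- ftab
    shifted$fit <- purrr::map(fits, function(f) { f$u <- f$u - 3; f })
    g_shift <- threshold_grid(ftab, shifted)
    dsh <- g_shift[g_shift$el_p == g_shift$vd_p, ]
    expect_equal(dsh$bias, rep(3, 9), tolerance = 1e-9) # EL minus VD

    one <- threshold_grid(ftab[1, ], shifted[1, ])
    expect_true(all(is.na(one$correlation)))
    expect_true(all(is.finite(one$bias) & is.finite(one$rmse)))
  })
})

test_that("swapping the fit sets negates bias and preserves RMSE and |correlation|", {
  withr::with_seed(15, {
    fits_a <- purrr::map(1:6, ~ fit_loglogistic(
      loglogistic_series(b = runif(1, 0.2, 0.4), u = runif(1, -30, -15)),
      mode = "lim_c0_d100"))
    fits_b <- purrr::map(1:6, ~ fit_loglogistic(
      loglogistic_series(b = runif(1, 0.3, 0.6), u = runif(1, -33, -18)),
      mode = "lim_c0_d100"))
    mk <- function(fits) tibble::tibble(
      level = "genotype", id = paste0("g", seq_along(fits)), species = "s",
      approach = "x", fit = fits, pseudo_R2 = 1, converged = TRUE
    )
    g1 <- threshold_grid(mk(fits_a), mk(fits_b))
    g2 <- threshold_grid(mk(fits_b), mk(fits_a))
    m1 <- g1[g1$el_p == 30 & g1$vd_p == 70, ]
    m2 <- g2[g2$el_p == 70 & g2$vd_p == 30, ]
    expect_equal(m1$bias, -m2$bias, tolerance = 1e-12)
    expect_equal(m1$rmse, m2$rmse, tolerance = 1e-12)
    expect_equal(abs(m1$correlation), abs(m2$correlation), tolerance = 1e-12)
  })
})

test_that("fitted-approach comparison: identity, conversion construction, empty restriction", {
  fit1 <- fit_loglogistic(loglogistic_series(b = 0.3, u = -25), mode = "lim_c0_d100")
  ftab <- tibble::tibble(level = "genotype", id = "g1", species = "s",
                         approach = "a", fit = list(fit1), pseudo_R2 = 1, converged = TRUE)
  same <- compare_fitted_approaches(ftab, ftab)
  expect_equal(same$bias, 0, tolerance = 1e-12)
  expect_equal(same$frac_within_band, 1)

  # B = A / 0.576 capped at 100: A sits below B wherever the cap is not engaged
  fit_b <- fit1
  scaled <- ftab
  scaled$fit <- list({ f <- fit1; f$d <- 100 * 0.576; f })
  cmp <- compare_fitted_approaches(scaled, ftab)
  expect_lt(cmp$bias, 0)
  pre_cap <- cmp$points[cmp$points$value_b < 100, ]
  expect_true(all(pre_cap$value_a <= pre_cap$value_b + 1e-9))

  expect_warning(r <- compare_fitted_approaches(ftab, ftab, restrict = c(150, 200)),
                 "no grid points")
  expect_true(is.na(r$bias_restricted))
})

test_that("lowest survival temperature follows the segment-wise definition", {
  vd <- tibble::tibble(
    species = "s", genotype = "g", replicate = rep(1:3, 2),
    temperature_C = rep(c(-30, -40), each = 3),
    damage_pct = c(25, 50, 50, 50, 75, 25)
  )
  expect_equal(lowest_survival_temperature(vd)$LST_C, -30)

  all_ok <- dplyr::mutate(vd, damage_pct = 25)
  expect_equal(lowest_survival_temperature(all_ok)$LST_C, -40)

  warm_fail <- tibble::tibble(species = "s", genotype = "g", replicate = 1:3,
                              temperature_C = -10, damage_pct = c(75, 0, 0))
  expect_warning(out <- lowest_survival_temperature(warm_fail), "undefined")
  expect_true(is.na(out$LST_C))

  expect_error(lowest_survival_temperature(vd[0, ]), class = "cryoleak_domain_error")
})
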