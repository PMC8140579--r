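test_that("log-logistic evaluation honours inflection symmetry and asymptotes", {
  expect_equal(loglogistic_eval(-25, 0, 100, 0.3, -25), 50)
  expect_equal(loglogistic_eval(10, 10, 60, 0.3, 10), 35)
  expect_equal(loglogistic_eval(-1e6, 0, 100, 0.3, -25), 100)
  expect_equal(loglogistic_eval(1e6, 0, 100, 0.3, -25), 0)
})

test_that("constrained fits recover noise-free truth; nested modes agree on u", {
  d <- loglogistic_series(c = 0, d = 100, b = 0.3, u = -25)
  fit <- fit_loglogistic(d, mode = "lim_c0_d100")
  expect_true(fit$converged)
  expect_equal(fit$u, -25, tolerance = 1e-6)
  expect_equal(fit$b, 0.3, tolerance = 1e-6)
  expect_gt(fit$pseudo_R2, 1 - 1e-10)

  fit_free <- fit_loglogistic(d, mode = "anderson_free")
  expect_equal(fit_free$c, 0, tolerance = 1e-3)
  expect_equal(fit_free$d, 100, tolerance = 1e-2)
  expect_equal(fit_free$u, -25, tolerance = 1e-4)

  flat <- data.frame(temperature_C = std_temps, value = 40)
  expect_error(fit_loglogistic(flat, mode = "lim_c0_d100"),
               class = "cryoleak_degenerate_error")
})

test_that("LT extraction inverts the logistic: LT50 = u, algebraic LT20/LT80", {
  d <- loglogistic_series(b = 0.2, u = -25)
  fit <- fit_loglogistic(d, mode = "lim_c0_d100")
  expect_equal(lt_from_loglogistic(fit, 50), fit$u)
  # frozen from the closed-form inversion, verified by forward evaluation
  expect_equal(lt_from_loglogistic(fit, 20), -25 + log(4) / 0.2, tolerance = 1e-6)
  expect_equal(lt_from_loglogistic(fit, 80), -25 - log(4) / 0.2, tolerance = 1e-6)
  expect_equal(loglogistic_eval(lt_from_loglogistic(fit, 20), 0, 100, fit$b, fit$u),
               20, tolerance = 1e-9)
  expect_error(lt_from_loglogistic(fit, 0), class = "cryoleak_domain_error")
  # ordering: warmer thresholds first
  lts <- lt_from_loglogistic(fit, c(20, 50, 80))
  expect_true(all(diff(lts) < 0))
})

test_that("Gompertz fits recover truth and its critical values invert correctly", {
  d <- gompertz_series(b = 2, k = -0.15)
  fit <- fit_gompertz(d)
  expect_true(fit$converged)
  expect_equal(fit$b, 2, tolerance = 1e-6)
  expect_equal(fit$k, -0.15, tolerance = 1e-6)

  expect_equal(lt_max_gompertz(fit), log(2) / -0.15, tolerance = 1e-6)
  # closed form checked by forward evaluation
  lt50 <- lt_p_gompertz(fit, 50)
  expect_equal(lt50, (log(2) - log(log(2))) / -0.15, tolerance = 1e-6)
  expect_equal(lt50, -7.065, tolerance = 1e-3)
  expect_equal(gompertz_eval(lt50, fit$b, fit$k), 50, tolerance = 1e-9)
  # b = ln 2 puts 50% damage at T = 0 for any k
  fit2 <- fit
  fit2$b <- log(2)
  expect_equal(lt_p_gompertz(fit2, 50), 0, tolerance = 1e-12)
  # asymmetry: steepest slope warmer than half-damage when k < 0
  expect_gt(lt_max_gompertz(fit), lt50)

  expect_error(fit_gompertz(data.frame(temperature_C = std_temps, value = 40)),
               class = "cryoleak_degenerate_error")
})

test_that("LTmax matches a brute-force scan for the steepest-slope temperature", {
  b <- 2; k <- -0.15
  grid <- seq(-40, 10, by = 0.001)
  slopes <- abs(diff(gompertz_eval(grid, b, k)) / diff(grid))
  argmax <- grid[which.max(slopes)]
  expect_equal(log(b) / k, argmax, tolerance = 0.01)
})

test_that("cross-family fit: Gompertz explains logistic truth well at the standard design", {
  d <- loglogistic_series(c = 0, d = 100, b = 0.3, u = -25)
  fit <- fit_gompertz(d)
  expect_true(fit$converged)
  expect_gt(fit$pseudo_R2, 0.95)
})

test_that("free-asymptote fits are invariant to affine rescaling of the response (property)", {
  # nonnegative offsets only: the fit constrains c >= 0 (leakage cannot be
  # negative), so a shift pushing the lower asymptote below zero is out of
  # the model family by design
  withr::with_seed(31, {
    for (i in 1:8) {
      b <- runif(1, 0.15, 0.5); u <- runif(1, -35, -12)
      d <- loglogistic_series(c = 0, d = 100, b = b, u = u)
      a <- runif(1, 0.3, 0.9); m <- runif(1, 0, 20)
      d2 <- transform(d, value = a * value + m)
      f1 <- fit_loglogistic(d, mode = "anderson_free")
      f2 <- fit_loglogistic(d2, mode = "anderson_free")
      expect_equal(f1$u, f2$u, tolerance = 1e-6)
      expect_equal(f1$b, f2$b, tolerance = 1e-6)
    }
  })
})

test_that("solver SSE matches a dense grid search (oracle equivalence)", {
  withr::with_seed(7, {
    d <- loglogistic_series(b = 0.3, u = -25)
    d$value <- d$value + rnorm(nrow(d), 0, 5)
    fit <- fit_loglogistic(d, mode = "lim_c0_d100")
    sse_grid <- grid_search_sse(d$temperature_C, d$value, 0, 100,
                                b_grid = seq(0.05, 1, by = 0.002),
                                u_grid = seq(-40, -10, by = 0.02))
    expect_lte(fit$ss_res, sse_grid * 1.001)
  })
})

test_that("species fits pool replicate points across genotypes", {
  cfg <- sim_config(n_species = 1, n_genotypes = 3, noise_sd = 0,
                    u_jitter_sd = 0, b_range = c(0.3, 0.3), seed = 5)
  sim <- simulate_leakage_experiment(cfg)
  s <- standardize_leakage(sim$records, kind = "I_adj")
  by_geno <- fit_damage_curves(s, approach = "lim_logistic", level = "genotype")
  by_sp <- fit_damage_curves(s, approach = "lim_logistic", level = "species")
  # identical genotypes (no jitter): species fit equals each genotype fit
  expect_equal(by_sp$fit[[1]]$u, by_geno$fit[[1]]$u, tolerance = 1e-4)

  # distinct genotypes: species u falls inside the genotype range
  rows <- purrr::map(c(-20, -25, -30), function(u) {
    d <- loglogistic_series(b = 0.3, u = u, n_rep = 3)
    tibble::tibble(species = "sp", genotype = paste0("g", u),
                   replicate = 1, temperature_C = d$temperature_C, value = d$value)
  }) |> purrr::list_rbind()
  sp <- fit_damage_curves(rows, approach = "lim_logistic", level = "species")
  expect_gt(sp$fit[[1]]$u, -30)
  expect_lt(sp$fit[[1]]$u, -20)

  expect_error(fit_damage_curves(rows[0, ], approach = "lim_logistic"),
               class = "cryoleak_domain_error")
})

test_that("critical-value tables are tidy, ordered, and flag failed fits as missing", {
  cfg <- sim_config(n_species = 2, noise_sd = 0.02, seed = 8)
  sim <- simulate_leakage_experiment(cfg)
  s <- suppressWarnings(standardize_leakage(sim$records, kind = "I_adj"))
  fits <- fit_damage_curves(s, approach = "lim_logistic")
  cv <- critical_value_table(fits, thresholds = c(20, 50, 80))
  expect_setequal(unique(cv$metric), c("LT20", "LT50", "LT80"))
  wide <- tidyr::pivot_wider(cv, names_from = "metric", values_from = "temperature_C")
  expect_true(all(wide$LT20 >= wide$LT50 & wide$LT50 >= wide$LT80))

  gfits <- fit_damage_curves(s, approach = "lim_gompertz")
  gcv <- critical_value_table(gfits)
  expect_true("LTmax" %in% gcv$metric)
  gw <- tidyr::pivot_wider(gcv, names_from = "metric", values_from = "temperature_C")
  expect_true(all(gw$LTmax > gw$LT50)) # Gompertz asymmetry
})
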