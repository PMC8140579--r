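# Synthetic freeze-thaw experiments with known ground truth.
#
# Generative model for one tube at temperature T within a genotype with true
# damage curve D(T) = 1 / (1 + exp(b* (T - u*))):
#   L_T               = P (f0 + (m - f0) D(T)) (1 + eps)
#   L_K (autoclave)   = P (1 + eps)
#   L_K (liquid N)    = P m (1 + eps)
# with multiplicative Gaussian noise eps ~ N(0, sd) (conductivity errors scale
# with magnitude), total electrolyte pool P (uS/cm), handling-leakage fraction
# f0, and maximum freezing-induced leakage fraction m relative to autoclave.
# At sd = 0 the relative leakage plateaus at m below the damage transition and
# the adjusted index plateaus at 100.

#' Configuration for a simulated electrolyte-leakage experiment
#'
#' Defaults emulate the standard maple-panel design: 12 species x 3 genotypes
#' x 3 replicate tubes at temperatures {4, -10, -20, -30, -40, -60, -80} degC,
#' a maximum freezing-induced leakage fraction of 0.58 of the autoclave
#' leakage, and a leakage plateau below about -40 degC. Per-genotype truth:
#' species-level LT50 drawn uniformly on `u_range`, genotype jitter
#' `N(0, u_jitter_sd)`, slope `b` uniform on `b_range`. The visual-damage
#' curve is shifted `vd_offset` degC colder and steepened by `vd_slope_mult`.
#'
#' @param n_species,n_genotypes,n_replicates Design sizes.
#' @param temperatures Treatment temperatures, degC (4 is the unfrozen
#'   control).
#' @param pool_uS Total electrolyte pool P, uS/cm.
#' @param f0 Handling-leakage fraction at zero freeze damage (`0 <= f0 < m`).
#' @param m Maximum freezing-induced leakage fraction relative to autoclave.
#' @param noise_sd Fractional (multiplicative) noise SD.
#' @param u_range,u_jitter_sd,b_range Truth distributions for LT50 and slope.
#' @param vd_offset Visual-damage LT50 shift, degC.
#' @param vd_slope_mult Visual-damage slope multiplier.
#' @param seed Integer seed; every simulator run with the same config is
#'   byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 12, n_genotypes = 3, n_replicates = 3,
                       temperatures = c(4, -10, -20, -30, -40, -60, -80),
                       pool_uS = 400, f0 = 0.1, m = 0.58, noise_sd = 0.03,
                       u_range = c(-30, -12), u_jitter_sd = 1.5,
                       b_range = c(0.25, 0.45),
                       vd_offset = -3, vd_slope_mult = 1.5, seed = 1) {
  if (f0 < 0 || f0 >= m || m > 1) abort("need 0 <= f0 < m <= 1", class = "cryoleak_domain_error")
  if (noise_sd < 0) abort("noise_sd must be >= 0", class = "cryoleak_domain_error")
  structure(
    list(n_species = n_species, n_genotypes = n_genotypes,
         n_replicates = n_replicates, temperatures = temperatures,
         pool_uS = pool_uS, f0 = f0, m = m, noise_sd = noise_sd,
         u_range = u_range, u_jitter_sd = u_jitter_sd, b_range = b_range,
         vd_offset = vd_offset, vd_slope_mult = vd_slope_mult, seed = seed),
    class = "sim_config"
  )
}

# True damage fraction at temperature T.
sim_damage <- function(temperature_C, u, b) {
  1 / (1 + exp(b * (temperature_C - u)))
}

# Draw the per-genotype truth table for a config.
sim_truth <- function(config) {
  n_g <- config$n_species * config$n_genotypes
  species <- rep(sprintf("sp%02d", seq_len(config$n_species)),
                 each = config$n_genotypes)
  genotype <- paste0(species, "_g", rep(seq_len(config$n_genotypes), config$n_species))
  u_species <- rep(runif(config$n_species, config$u_range[1], config$u_range[2]),
                   each = config$n_genotypes)
  tibble(
    species = species, genotype = genotype,
    u_true = u_species + rnorm(n_g, 0, config$u_jitter_sd),
    b_true = runif(n_g, config$b_range[1], config$b_range[2]),
    m = config$m, f0 = config$f0
  )
}

#' Simulate a full electrolyte-leakage experiment
#'
#' Draws per-genotype truth (LT50 `u_true`, slope `b_true`) and generates one
#' conductivity record per tube under the generative model in the package
#' vignette, including autoclave post-control conductivities.
#'
#' @param config A [sim_config()].
#' @param control_type Control generating `L_K_uS`: `"autoclave_120"`
#'   (default) or `"liquid_nitrogen"` (conductivity `m` times smaller).
#' @return A list: `records` (conductivity tibble as from
#'   [read_conductivity_table()]) and `truth` (per-genotype truth table).
#' @export
#' @examples
#' sim <- simulate_leakage_experiment(sim_config(n_species = 2, seed = 42))
#' head(sim$records)
simulate_leakage_experiment <- function(config = sim_config(),
                                        control_type = c("autoclave_120", "liquid_nitrogen")) {
  control_type <- match.arg(control_type)
  withr::with_seed(config$seed, {
    truth <- sim_truth(config)
    grid <- tidyr::expand_grid(
      truth |> select(all_of(c("species", "genotype", "u_true", "b_true"))),
      temperature_C = config$temperatures,
      replicate = seq_len(config$n_replicates)
    )
    nr <- nrow(grid)
    k_scale <- if (control_type == "liquid_nitrogen") config$m else 1
    records <- grid |>
      mutate(
        D = sim_damage(.data$temperature_C, .data$u_true, .data$b_true),
        L_T_uS = config$pool_uS * (config$f0 + (config$m - config$f0) * .data$D) *
          (1 + rnorm(nr, 0, config$noise_sd)),
        L_K_uS = config$pool_uS * k_scale * (1 + rnorm(nr, 0, config$noise_sd)),
        control_type = control_type
      ) |>
      select(all_of(c("species", "genotype", "replicate", "temperature_C",
                      "L_T_uS", "L_K_uS", "control_type")))
    list(records = records, truth = truth)
  })
}

# Round a continuous damage percentage to the quartile scale; exact midpoints
# round toward 50 (the scale's centre).
quartile_round <- function(x) {
  x <- pmin(pmax(x, 0), 100)
  lo <- floor(x / 25) * 25
  hi <- pmin(lo + 25, 100)
  d_lo <- x - lo
  d_hi <- hi - x
  ifelse(d_lo < d_hi, lo,
         ifelse(d_hi < d_lo, hi,
                ifelse(abs(lo - 50) <= abs(hi - 50), lo, hi)))
}

#' Simulate quartile-scale visual-damage scores
#'
#' Visual damage follows a shifted (`vd_offset`) and steepened
#' (`vd_slope_mult`) version of each genotype's true damage curve - browning
#' is accrued faster than electrolyte leakage - with multiplicative noise,
#' then rounding to the quartile scale {0, 25, 50, 75, 100} (exact midpoints
#' round toward 50).
#'
#' @param config A [sim_config()].
#' @param truth Optional truth table from [simulate_leakage_experiment()] so
#'   both assays share genotypes; drawn fresh from `config` when `NULL`.
#' @return A visual-damage tibble (`species`, `genotype`, `replicate`,
#'   `temperature_C`, `damage_pct`).
#' @export
simulate_visual_damage <- function(config = sim_config(), truth = NULL) {
  withr::with_seed(config$seed + 1L, {
    if (is.null(truth)) truth <- withr::with_seed(config$seed, sim_truth(config))
    grid <- tidyr::expand_grid(
      truth |> select(all_of(c("species", "genotype", "u_true", "b_true"))),
      temperature_C = config$temperatures,
      replicate = seq_len(config$n_replicates)
    )
    nr <- nrow(grid)
    grid |>
      mutate(
        vd_cont = 100 * sim_damage(.data$temperature_C,
                                   .data$u_true + config$vd_offset,
                                   .data$b_true * config$vd_slope_mult) *
          (1 + rnorm(nr, 0, config$noise_sd)),
        damage_pct = quartile_round(.data$vd_cont)
      ) |>
      select(all_of(c("species", "genotype", "replicate", "temperature_C", "damage_pct")))
  })
}

#' Simulate paired autoclave / liquid-nitrogen control conductivities
#'
#' Generates `n` tubes with autoclave conductivity drawn uniformly on
#' `x_range` and liquid-nitrogen conductivity `slope * x (1 + eps)`, the
#' validation design for the Deming calibration.
#'
#' @param n Number of paired tubes.
#' @param slope True conductivity ratio (liquid nitrogen / autoclave).
#' @param noise_sd Fractional noise SD on y.
#' @param x_range Range of autoclave conductivities, uS/cm.
#' @param seed Integer seed.
#' @return A tibble with columns `id`, `x`, `y`.
#' @export
simulate_control_pairs <- function(n = 176, slope = 0.576, noise_sd = 0.05,
                                   x_range = c(50, 400), seed = 1) {
  withr::with_seed(seed, {
    x <- runif(n, x_range[1], x_range[2])
    y <- slope * x * (1 + rnorm(n, 0, noise_sd))
    tibble(id = seq_len(n), x = x, y = y)
  })
}

#' Simulate a DTA cooling trace with known exotherms
#'
#' Cools from `start_C` to `end_C` at `rate_C_per_h` (default -4 degC/h to
#' -60 degC), sampling every `sample_every_s` seconds, with Gaussian voltage
#' bumps at the requested exotherm temperatures plus white noise and a slow
#' baseline drift.
#'
#' @param exotherms_C Temperatures of true exotherms, degC (may be empty).
#' @param amplitudes_mV Bump heights; recycled.
#' @param width_C Bump SD on the temperature axis, degC.
#' @param start_C,end_C,rate_C_per_h Cooling ramp.
#' @param sample_every_s Sampling interval, s.
#' @param noise_sd_mV White-noise SD.
#' @param drift_mV Amplitude of a slow sinusoidal baseline drift.
#' @param genotype Label attached to the trace.
#' @param seed Integer seed.
#' @return A `dta_trace` tibble.
#' @export
simulate_dta_trace <- function(exotherms_C = c(-8, -36),
                               amplitudes_mV = c(2, 1.5), width_C = 0.6,
                               start_C = 0, end_C = -60, rate_C_per_h = -4,
                               sample_every_s = 10, noise_sd_mV = 0.05,
                               drift_mV = 0.3, genotype = "sim", seed = 1) {
  withr::with_seed(seed, {
    total_s <- (end_C - start_C) / rate_C_per_h * 3600
    time_s <- seq(0, total_s, by = sample_every_s)
    temperature_C <- start_C + rate_C_per_h * time_s / 3600
    voltage <- drift_mV * sin(2 * pi * time_s / max(total_s, 1)) +
      rnorm(length(time_s), 0, noise_sd_mV)
    if (length(exotherms_C) > 0) {
      amps <- rep_len(amplitudes_mV, length(exotherms_C))
      for (i in seq_along(exotherms_C)) {
        voltage <- voltage +
          amps[i] * exp(-(temperature_C - exotherms_C[i])^2 / (2 * width_C^2))
      }
    }
    new_dta_trace(
      tibble(time_s = time_s, temperature_C = temperature_C, voltage_mV = voltage),
      genotype = genotype
    )
  })
}
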