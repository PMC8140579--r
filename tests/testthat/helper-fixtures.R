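# Fixtures built in code: tiny CSVs and noise-free series.

std_temps <- c(4, -10, -20, -30, -40, -60, -80)

write_fixture_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

conductivity_fixture <- function(with_lk = TRUE) {
  hdr <- if (with_lk) {
    "species,genotype,replicate,temperature_C,L_T_uS,L_K_uS"
  } else {
    "species,genotype,replicate,temperature_C,L_T_uS"
  }
  rows <- c(
    "A. rubrum,g1,1,4,12.5",
    "A. rubrum,g1,1,-20,55.0",
    "A. rubrum,g1,1,−80,70.2" # typographic minus on purpose
  )
  if (with_lk) rows <- paste0(rows, ",110")
  write_fixture_csv(c(hdr, rows))
}

# Replicate-level noise-free log-logistic series at the standard design.
loglogistic_series <- function(c = 0, d = 100, b = 0.3, u = -25,
                               temps = std_temps, n_rep = 3) {
  tt <- rep(temps, each = n_rep)
  data.frame(temperature_C = tt, value = loglogistic_eval(tt, c, d, b, u))
}

gompertz_series <- function(b = 2, k = -0.15, temps = std_temps, n_rep = 3) {
  tt <- rep(temps, each = n_rep)
  data.frame(temperature_C = tt, value = gompertz_eval(tt, b, k))
}

# Independent oracle: dense grid search over (b, u) for SSE with c, d fixed.
grid_search_sse <- function(tt, yy, c, d, b_grid, u_grid) {
  best <- Inf
  for (b in b_grid) for (u in u_grid) {
    sse <- sum((yy - loglogistic_eval(tt, c, d, b, u))^2)
    if (sse < best) best <- sse
  }
  best
}

# Independent oracle: one-dimensional minimizer of the origin-constrained
# errors-in-variables ("least rectangle") loss.
deming_slope_optimize <- function(x, y, delta = 1) {
  loss <- function(s) sum((y - s * x)^2) / (delta + s^2)
  optimize(loss, interval = c(1e-3, 1e3), tol = 1e-12)$minimum
}
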