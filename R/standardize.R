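# Standardization of raw conductivities into the three leakage indices.
#
# R_T    = L_T / L_K                          (relative leakage, fraction)
# I_T    = 100 (R_T - R_o) / (1 - R_o)        (index of injury, %)
# I_adj  = 100 (R_T - R_o) / (R_max - R_o)    (adjusted index, %)
#
# R_o is the unfrozen-control baseline and R_max the maximum relative leakage
# reached within a genotype; both are estimated per genotype with pluggable
# strategies. Values outside the nominal range (R > 1, I < 0) are retained and
# flagged, never silently clamped: clamping before curve fitting would bias
# the fitted asymptotes.

#' Relative electrolyte leakage
#'
#' `R_T = L_T / L_K`: post-freeze conductivity relative to the same tube's
#' conductivity after a maximum-damage control (autoclave or liquid-nitrogen
#' immersion). Values above 1 are possible with noisy controls and are
#' flagged with a warning rather than rejected.
#'
#' @param L_T Post-freeze conductivity, uS/cm (>= 0). Vectorised.
#' @param L_K Post-control conductivity, uS/cm (> 0). Vectorised.
#' @return Relative leakage as a fraction.
#' @export
#' @examples
#' relative_leakage(30, 120) # 0.25
relative_leakage <- function(L_T, L_K) {
  if (any(!is.finite(L_K)) || any(L_K <= 0)) {
    abort("L_K must be finite and > 0", class = "cryoleak_domain_error")
  }
  if (any(L_T < 0)) abort("L_T must be >= 0", class = "cryoleak_domain_error")
  r <- L_T / L_K
  if (any(r > 1)) warn(sprintf("%d relative leakage value(s) exceed 1", sum(r > 1)))
  r
}

#' Index of injury
#'
#' `I_T = 100 (R_T - R_o) / (1 - R_o)`: relative leakage zeroed against the
#' unfrozen-control baseline `R_o`, so that handling damage scores 0%.
#' Negative values (tubes leaking less than the control) are retained and
#' flagged.
#'
#' @param R_T Relative leakage, fraction. Vectorised.
#' @param R_o Baseline relative leakage of the unfrozen control, in `[0, 1)`.
#' @return Index of injury, percent.
#' @export
index_of_injury <- function(R_T, R_o) {
  if (any(!is.finite(R_o)) || any(R_o >= 1) || any(R_o < 0)) {
    abort("R_o must be in [0, 1)", class = "cryoleak_domain_error")
  }
  i <- 100 * (R_T - R_o) / (1 - R_o)
  if (any(i < 0)) warn(sprintf("%d index-of-injury value(s) are negative", sum(i < 0)))
  i
}

#' Adjusted index of injury
#'
#' `I_adj = 100 (R_T - R_o) / (R_max - R_o)`: the index of injury additionally
#' stretched so that the maximum relative leakage observed within the genotype
#' scores 100%. Assumes maximum freezing damage occurred within the
#' temperatures tested (a leakage plateau at the coldest treatments).
#'
#' @param R_T Relative leakage, fraction. Vectorised.
#' @param R_o Baseline relative leakage, in `[0, 1)`.
#' @param R_max Maximum relative leakage, `> R_o`.
#' @param genotype Optional label used in the degenerate-genotype error.
#' @return Adjusted index, percent.
#' @export
adjusted_index <- function(R_T, R_o, R_max, genotype = NULL) {
  if (any(!is.finite(R_max)) || any(R_max <= R_o)) {
    abort(
      sprintf(
        "R_max must exceed R_o%s",
        if (!is.null(genotype)) sprintf(" (genotype %s)", paste(unique(genotype), collapse = ", ")) else ""
      ),
      class = "cryoleak_degenerate_error"
    )
  }
  100 * (R_T - R_o) / (R_max - R_o)
}

# Per-genotype baseline R_o. Strategies:
#   mean_unfrozen_4C     - mean R over unfrozen (4 degC) replicates (default);
#   min_of_4C_or_minus5C - lowest single R at either 4 or -5 degC (the rule
#                          used for designs without replicate tubes).
baseline_r_o <- function(df, strategy, unfrozen_C = 4) {
  if (strategy == "mean_unfrozen_4C") {
    ctl <- df$R[abs(df$temperature_C - unfrozen_C) < 1e-9]
    if (length(ctl) == 0) return(NA_real_)
    mean(ctl)
  } else {
    ctl <- df$R[df$temperature_C %in% c(4, -5) |
                  abs(df$temperature_C - unfrozen_C) < 1e-9]
    if (length(ctl) == 0) return(NA_real_)
    min(ctl)
  }
}

# Per-genotype maximum R_max. Strategies:
#   max_temperature_mean - max over per-temperature replicate means (default,
#                          robust to a single leaky tube);
#   max_replicate        - max over individual tubes (a literal reading of
#                          "maximum measured for any genotype").
maximum_r_max <- function(df, strategy) {
  if (strategy == "max_temperature_mean") {
    means <- df |>
      group_by(.data$temperature_C) |>
      summarise(m = mean(.data$R), .groups = "drop")
    max(means$m)
  } else {
    max(df$R)
  }
}

#' Per-genotype baseline and maximum leakage
#'
#' Computes, for each genotype, the unfrozen-control baseline `R_o`, the
#' maximum relative leakage `R_max`, and the maximum unadjusted injury
#' `I_max = 100 (R_max - R_o)/(1 - R_o)`.
#'
#' @param records Conductivity tibble as from [read_conductivity_table()],
#'   with `L_K_uS` present.
#' @param baseline Baseline strategy: `"mean_unfrozen_4C"` (mean of unfrozen
#'   4 degC replicates) or `"min_of_4C_or_minus5C"` (lowest leakage at either
#'   4 or -5 degC, for designs without replicate tubes).
#' @param maximum Maximum strategy: `"max_temperature_mean"` (maximum of
#'   per-temperature replicate means) or `"max_replicate"` (maximum single
#'   tube).
#' @param unfrozen_C Temperature of the unfrozen control, degC.
#' @return A tibble with one row per genotype: `species`, `genotype`, `R_o`,
#'   `R_max`, `I_max`.
#' @export
genotype_reference_leakage <- function(records,
                                       baseline = c("mean_unfrozen_4C", "min_of_4C_or_minus5C"),
                                       maximum = c("max_temperature_mean", "max_replicate"),
                                       unfrozen_C = 4) {
  baseline <- match.arg(baseline)
  maximum <- match.arg(maximum)
  withCallingHandlers(
    records <- mutate(records, R = relative_leakage(.data$L_T_uS, .data$L_K_uS)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  records |>
    group_by(.data$species, .data$genotype) |>
    summarise(
      R_o = baseline_r_o(dplyr::pick(dplyr::everything()), baseline, unfrozen_C),
      R_max = maximum_r_max(dplyr::pick(dplyr::everything()), maximum),
      .groups = "drop"
    ) |>
    mutate(I_max = 100 * (.data$R_max - .data$R_o) / (1 - .data$R_o))
}

#' Standardize a conductivity dataset into leakage series
#'
#' Converts raw conductivities into one of the three leakage indices, one
#' tidy row per tube, ready for curve fitting. `kind = "R"` needs no
#' unfrozen controls; `"I"` and `"I_adj"` need at least one unfrozen-control
#' record per genotype (genotypes without one are dropped with a warning).
#'
#' @param records Conductivity tibble (long format; `L_K_uS` required).
#' @param kind Index to compute: `"R"`, `"I"` or `"I_adj"`.
#' @inheritParams genotype_reference_leakage
#' @param clamp If `TRUE`, clamp `I_adj` to `[0, 100]` (and `I`/`R` below at
#'   0). Off by default: clamping before fitting biases the lower asymptote.
#' @return A tibble with columns `species`, `genotype`, `replicate`,
#'   `temperature_C`, `kind`, `value`, and logical flags `flag_gt_max`
#'   (`R > 1` or index above 100) and `flag_negative`.
#' @export
#' @examples
#' sim <- simulate_leakage_experiment(sim_config(n_species = 1, noise_sd = 0, seed = 1))
#' standardize_leakage(sim$records, kind = "I_adj")
standardize_leakage <- function(records,
                                kind = c("R", "I", "I_adj"),
                                baseline = c("mean_unfrozen_4C", "min_of_4C_or_minus5C"),
                                maximum = c("max_temperature_mean", "max_replicate"),
                                unfrozen_C = 4,
                                clamp = FALSE) {
  kind <- match.arg(kind)
  baseline <- match.arg(baseline)
  maximum <- match.arg(maximum)
  if (any(is.na(records$L_K_uS))) {
    abort("records lack post-control conductivity (L_K_uS); run the control step first",
          class = "cryoleak_domain_error")
  }
  withCallingHandlers(
    out <- mutate(records, R = relative_leakage(.data$L_T_uS, .data$L_K_uS)),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (kind == "R") {
    out <- mutate(out, kind = "R", value = .data$R)
  } else {
    refs <- genotype_reference_leakage(records, baseline, maximum, unfrozen_C)
    missing_ctl <- refs$genotype[is.na(refs$R_o)]
    if (length(missing_ctl) > 0) {
      warn(sprintf(
        "genotype(s) without unfrozen-control records skipped: %s",
        paste(missing_ctl, collapse = ", ")
      ))
      refs <- filter(refs, !is.na(.data$R_o))
    }
    if (kind == "I_adj") {
      degen <- refs$genotype[refs$R_max <= refs$R_o]
      if (length(degen) > 0) {
        abort(sprintf(
          "R_max does not exceed R_o for genotype(s): %s",
          paste(degen, collapse = ", ")
        ), class = "cryoleak_degenerate_error")
      }
    }
    out <- inner_join(out, refs, by = c("species", "genotype"))
    out <- if (kind == "I") {
      mutate(out, kind = "I", value = 100 * (.data$R - .data$R_o) / (1 - .data$R_o))
    } else {
      mutate(out, kind = "I_adj",
             value = 100 * (.data$R - .data$R_o) / (.data$R_max - .data$R_o))
    }
  }
  upper <- if (kind == "R") 1 else 100
  out <- out |>
    mutate(
      flag_gt_max = .data$value > upper,
      flag_negative = .data$value < 0
    )
  if (clamp) {
    out <- mutate(out, value = pmin(pmax(.data$value, 0), upper))
  }
  select(out, all_of(c("species", "genotype", "replicate", "temperature_C",
                       "kind", "value", "flag_gt_max", "flag_negative")))
}
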