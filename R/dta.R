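# Differential thermal analysis: algorithmic exotherm detection.
#
# Extracellular water freezes at mild sub-zero temperatures and releases heat
# (high-temperature exotherm, HTE; benign). Supercooled intracellular water
# freezes much colder and lethally (low-temperature exotherm, LTE). Peaks are
# called on the baseline-subtracted voltage trace: baseline = running median
# over a configurable temperature window, candidate peaks = local maxima with
# height at least k robust-SDs above the noise floor, classified HTE/LTE by a
# temperature cutoff.

#' Detect exotherm peaks in a DTA voltage trace
#'
#' Subtracts a running-median baseline (window expressed in degC of cooling,
#' converted to samples via the local cooling rate), estimates the noise
#' floor as the MAD of the residual, and calls peaks where the residual forms
#' a local maximum at least `prominence_k` x MAD above baseline. Peaks warmer
#' than `hte_cutoff` are classed `HTE`, colder ones `LTE`. Detection is
#' invariant to additive voltage offsets (removed by the baseline) and to
#' uniform time rescaling (all windows are on the temperature axis).
#'
#' @param trace A `dta_trace` (or data frame with `time_s`, `temperature_C`,
#'   `voltage_mV`).
#' @param baseline_window_C Running-median window, degC of trace (default 5).
#' @param prominence_k Peak height threshold in MADs of the residual noise.
#' @param hte_cutoff Temperature (degC) separating HTE (warmer) from LTE.
#' @param min_separation_C Minimum temperature separation between reported
#'   peaks; of any closer pair the more prominent wins.
#' @return A tibble: `genotype`, `temperature_C`, `prominence_mV`, `width_C`,
#'   `klass` (`"HTE"`/`"LTE"`), sorted by descending prominence.
#' @export
detect_exotherms <- function(trace, baseline_window_C = 5, prominence_k = 6,
                             hte_cutoff = -15, min_separation_C = 2) {
  genotype <- attr(trace, "genotype") %||% NA_character_
  tt <- trace$temperature_C
  vv <- trace$voltage_mV
  span <- max(tt) - min(tt)
  if (span < 10) abort("cooling span below 10 degC; trace too short",
                       class = "cryoleak_domain_error")
  deg_per_sample <- span / (length(tt) - 1)
  k <- max(3, round(baseline_window_C / deg_per_sample))
  if (k %% 2 == 0) k <- k + 1
  if (k >= length(vv)) abort("trace shorter than the baseline window",
                             class = "cryoleak_domain_error")
  baseline <- runmed(vv, k, endrule = "median")
  resid <- as.vector(vv - baseline)
  noise <- mad(resid)
  if (noise == 0) noise <- max(sd(resid), .Machine$double.eps)
  thr <- prominence_k * noise

  pk <- pracma::findpeaks(resid, minpeakheight = thr, minpeakdistance = max(1, floor(k / 2)))
  if (is.null(pk)) {
    return(tibble(genotype = character(0), temperature_C = numeric(0),
                  prominence_mV = numeric(0), width_C = numeric(0),
                  klass = character(0)))
  }
  peaks <- tibble(
    genotype = genotype,
    temperature_C = tt[pk[, 2]],
    prominence_mV = pk[, 1],
    width_C = abs(tt[pk[, 3]] - tt[pk[, 4]]),
    klass = ifelse(tt[pk[, 2]] > hte_cutoff, "HTE", "LTE")
  ) |>
    arrange(dplyr::desc(.data$prominence_mV))

  # collapse peaks closer than min_separation_C, keeping the more prominent
  keep <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    keep[i] <- !any(keep & abs(peaks$temperature_C - peaks$temperature_C[i]) < min_separation_C)
  }
  peaks[keep, ]
}

#' Species-level low-temperature exotherm summary
#'
#' For each genotype, takes the most prominent LTE (all detected LTEs remain
#' in the peak table; pooled multi-segment cells can produce several), then
#' averages over genotypes within species. Genotypes with no detected LTE are
#' excluded with a warning.
#'
#' @param peaks Peak tibble from [detect_exotherms()] (rows from several
#'   traces bound together) with a `species` column joined on.
#' @return A tibble: `species`, `LTE_C` (mean over genotypes), `n_genotypes`.
#' @export
species_lte_summary <- function(peaks) {
  if (!"species" %in% names(peaks)) {
    abort("peaks must carry a species column", class = "cryoleak_domain_error")
  }
  ltes <- peaks |>
    filter(.data$klass == "LTE") |>
    group_by(.data$species, .data$genotype) |>
    slice(which.max(.data$prominence_mV)) |>
    ungroup()
  missing <- setdiff(unique(peaks$genotype), unique(ltes$genotype))
  if (length(missing) > 0) {
    warn(sprintf("genotype(s) with no detected LTE excluded: %s",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(ltes) == 0) {
    warn("no LTEs detected in any genotype; summary undefined")
    return(tibble(species = character(0), LTE_C = numeric(0), n_genotypes = integer(0)))
  }
  ltes |>
    group_by(.data$species) |>
    summarise(LTE_C = mean(.data$temperature_C), n_genotypes = dplyr::n(),
              .groups = "drop")
}
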