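# Reading and writing the delimited formats the rest of the package consumes.
# All tables are long ("tidy"): one tube, one scored segment, or one DTA sample
# per row. Unfrozen controls are ordinary rows (temperature_C = 4, or -5 for
# the oak-style design); downstream code selects them by role, not by flag.

cond_required_cols <- c("species", "genotype", "replicate", "temperature_C", "L_T_uS")
cond_all_cols <- c(cond_required_cols, "L_K_uS", "control_type", "incubation_days")

# Accept the true minus sign as well as ASCII hyphen in numeric fields.
parse_signed <- function(x) {
  suppressWarnings(as.numeric(gsub("−", "-", trimws(as.character(x)))))
}

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s: missing required column%s: %s",
        path, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "cryoleak_schema_error"
    )
  }
  invisible(df)
}

row_errors <- function(bad, what) {
  if (length(bad) == 0) return(invisible(NULL))
  abort(
    sprintf(
      "non-numeric or missing %s on data row%s: %s",
      what, if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")
    ),
    class = "cryoleak_row_error"
  )
}

#' Read a long-format conductivity table
#'
#' Reads a comma-delimited table of freeze-thaw conductivity measurements, one
#' tube per row, with columns `species`, `genotype`, `replicate`,
#' `temperature_C`, `L_T_uS` (post-freeze conductivity, uS/cm), and optionally
#' `L_K_uS` (post-control conductivity), `control_type` and `incubation_days`.
#' `L_K_uS` may be absent entirely (datasets read before the maximum-damage
#' control step) or missing per row.
#'
#' Temperatures are the actual values reached (signed degrees Celsius); both
#' ASCII `-` and the typographic minus are accepted. Rows whose `L_T_uS`
#' cannot be parsed raise a row-indexed error.
#'
#' @param path Path to a CSV file with a header row.
#' @return A tibble with one `ConductivityRecord` per row. `L_K_uS`,
#'   `control_type` and `incubation_days` are `NA` where absent.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "species,genotype,replicate,temperature_C,L_T_uS,L_K_uS",
#'   "A. rubrum,g1,1,4,12.5,110",
#'   "A. rubrum,g1,1,-20,55.0,110"
#' ), f)
#' read_conductivity_table(f)
read_conductivity_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, cond_required_cols, path)
  out <- tibble(
    species = as.character(raw$species),
    genotype = as.character(raw$genotype),
    replicate = as.integer(parse_signed(raw$replicate)),
    temperature_C = parse_signed(raw$temperature_C),
    L_T_uS = parse_signed(raw$L_T_uS),
    L_K_uS = if ("L_K_uS" %in% names(raw)) parse_signed(raw$L_K_uS) else NA_real_,
    control_type = if ("control_type" %in% names(raw)) as.character(raw$control_type) else NA_character_,
    incubation_days = if ("incubation_days" %in% names(raw)) {
      as.integer(parse_signed(raw$incubation_days))
    } else NA_integer_
  )
  row_errors(which(is.na(out$L_T_uS)), "L_T_uS")
  row_errors(which(is.na(out$temperature_C)), "temperature_C")
  bad_ct <- which(!is.na(out$control_type) & !(out$control_type %in% control_types))
  if (length(bad_ct) > 0) {
    abort(sprintf(
      "unknown control_type on data row%s: %s (expected one of %s)",
      if (length(bad_ct) > 1) "s" else "", paste(bad_ct, collapse = ", "),
      paste(control_types, collapse = ", ")
    ), class = "cryoleak_row_error")
  }
  if (any(out$temperature_C < -210 | out$temperature_C > 50)) {
    warn("temperatures outside [-210, 50] degC present; check units")
  }
  if (any(out$L_T_uS < 0)) {
    abort("negative conductivity (L_T_uS) present", class = "cryoleak_row_error")
  }
  out
}

#' Read a visual-damage score table
#'
#' Reads a CSV of quartile-scale visual damage scores (columns `species`,
#' `genotype`, `replicate`, `temperature_C`, `damage_pct`). Scores must fall
#' exactly on the quartile scale 0/25/50/75/100.
#'
#' @param path Path to a CSV file.
#' @return A tibble of visual-damage records.
#' @export
read_visual_damage_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("species", "genotype", "replicate", "temperature_C", "damage_pct"), path)
  out <- tibble(
    species = as.character(raw$species),
    genotype = as.character(raw$genotype),
    replicate = as.integer(parse_signed(raw$replicate)),
    temperature_C = parse_signed(raw$temperature_C),
    damage_pct = parse_signed(raw$damage_pct)
  )
  row_errors(which(is.na(out$damage_pct)), "damage_pct")
  off <- which(!(out$damage_pct %in% vd_levels))
  if (length(off) > 0) {
    abort(sprintf(
      "damage_pct outside the quartile scale {0,25,50,75,100} on row%s: %s",
      if (length(off) > 1) "s" else "", paste(off, collapse = ", ")
    ), class = "cryoleak_row_error")
  }
  out
}

#' Read a differential thermal analysis (DTA) trace
#'
#' Reads a three-column CSV (`time_s`, `temperature_C`, `voltage_mV`) recorded
#' while a pooled-stem cell cools on a thermoelectric module. Time must be
#' strictly increasing; temperature is checked for an overall cooling trend
#' (small reversals up to `temp_tol` degC between consecutive samples are
#' tolerated, as real controllers overshoot).
#'
#' @param path Path to a CSV file.
#' @param genotype Optional genotype label attached to the trace.
#' @param temp_tol Maximum tolerated sample-to-sample temperature rise, degC.
#' @return A tibble of class `dta_trace` with attribute `genotype`.
#' @export
read_dta_trace <- function(path, genotype = NA_character_, temp_tol = 0.5) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  check_columns(raw, c("time_s", "temperature_C", "voltage_mV"), path)
  out <- tibble(
    time_s = parse_signed(raw$time_s),
    temperature_C = parse_signed(raw$temperature_C),
    voltage_mV = parse_signed(raw$voltage_mV)
  )
  row_errors(which(is.na(out$voltage_mV)), "voltage_mV")
  new_dta_trace(out, genotype = genotype, temp_tol = temp_tol)
}

# Validate and class a DTA trace tibble.
new_dta_trace <- function(df, genotype = NA_character_, temp_tol = 0.5) {
  if (any(diff(df$time_s) <= 0)) {
    abort("DTA trace time_s must be strictly increasing", class = "cryoleak_row_error")
  }
  if (any(diff(df$temperature_C) > temp_tol)) {
    abort(sprintf(
      "DTA trace temperature_C rises by more than %g degC between samples; not a cooling ramp",
      temp_tol
    ), class = "cryoleak_row_error")
  }
  structure(df, class = c("dta_trace", class(df)), genotype = genotype)
}

#' Write a critical-value table to CSV
#'
#' Writes a tidy table of critical cold-hardiness temperatures (columns
#' `level`, `id`, `species`, `approach`, `metric`, `temperature_C`) so that
#' reading it back reproduces the values to six decimals.
#'
#' @param table A critical-value tibble, e.g. from [critical_value_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_critical_value_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0) warn("writing an empty critical-value table (header only)")
  out <- mutate(as_tibble(table), across(dplyr::where(is.numeric), ~ round(.x, 6)))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a critical-value table written by [write_critical_value_table()]
#'
#' @param path Path to the CSV.
#' @return A tibble.
#' @export
read_critical_value_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
}
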