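#' Convert Fahrenheit to Celsius
#'
#' @param f temperature in degrees Fahrenheit.
#' @return temperature in degrees Celsius.
#' @export
#' @examples
#' fahrenheit_to_celsius(102.4) # 39.1 to one decimal
fahrenheit_to_celsius <- function(f) (f - 32) * 5 / 9

#' Convert Celsius to Fahrenheit
#'
#' @param c_ temperature in degrees Celsius.
#' @return temperature in degrees Fahrenheit.
#' @export
celsius_to_fahrenheit <- function(c_) c_ * 9 / 5 + 32

# plausibility window for a measured axillary/oral temperature, degrees C
.TEMP_MIN <- 30
.TEMP_MAX <- 45

#' Validate and normalise a measured temperature
#'
#' Converts to Celsius when the unit tag is "F" and checks the measurement
#' against a physiological plausibility window of 30-45 degrees C. Unrecorded
#' readings (no thermometer measurement at the visit) carry no value.
#'
#' @param value numeric temperature(s); ignored (may be `NA`) where
#'   `recorded` is `FALSE`.
#' @param recorded logical; was a thermometer measurement taken?
#' @param unit "C" or "F" (scalar or vector), the unit of `value`.
#' @return numeric vector of Celsius temperatures, `NA` where not recorded.
#' @export
temperature_celsius <- function(value, recorded = TRUE, unit = "C") {
  n <- max(length(value), length(recorded), length(unit))
  value <- rep_len(as.numeric(value), n)
  recorded <- rep_len(as.logical(recorded), n)
  unit <- rep_len(as.character(unit), n)
  if (!all(unit %in% c("C", "F"))) {
    stop_("temperature unit must be 'C' or 'F', got: %s",
          paste(unique(setdiff(unit, c("C", "F"))), collapse = ", "))
  }
  celsius <- ifelse(unit == "F", fahrenheit_to_celsius(value), value)
  celsius[!recorded] <- NA_real_
  bad <- recorded & (is.na(celsius) | celsius < .TEMP_MIN | celsius > .TEMP_MAX)
  if (any(bad)) {
    stop_("implausible recorded temperature(s) outside [%.1f, %.1f] C: %s",
          .TEMP_MIN, .TEMP_MAX,
          paste(utils::head(format(celsius[bad]), 5), collapse = ", "))
  }
  celsius
}

#' Categorise a measured temperature as high fever, fever, or none
#'
#' High fever is a recorded temperature of 39.1 C (102.4 F) or higher; fever
#' (moderate) is 38.1-39.0 C (100.6-102.3 F). The internal cut points sit on
#' the half-grid (39.05, 38.05) so that readings reported to one decimal place
#' fall unambiguously on one side. A visit with no thermometer measurement is
#' categorised `NONE` regardless of any reported fever history, which is a
#' separate symptom.
#'
#' @param celsius numeric Celsius temperature(s), `NA` where not recorded.
#' @param recorded logical; defaults to `!is.na(celsius)`.
#' @return factor with levels `NONE`, `MODERATE`, `HIGH`.
#' @export
#' @examples
#' fever_category(c(39.1, 38.1, 37.0, NA))
fever_category <- function(celsius, recorded = !is.na(celsius)) {
  celsius <- temperature_celsius(celsius, recorded)
  out <- rep("NONE", length(celsius))
  out[recorded & celsius >= 38.05 & celsius < 39.05] <- "MODERATE"
  out[recorded & celsius >= 39.05] <- "HIGH"
  factor(out, levels = c("NONE", "MODERATE", "HIGH"))
}
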