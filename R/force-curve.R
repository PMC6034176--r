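#' A single force-distance curve
#'
#' The atomic measurement of a force map: sampled piezo height and cantilever
#' deflection for one grid point, with per-sample segment labels. The
#' deflection carries an explicit unit tag (`"V"` straight from the
#' photodiode, or `"nm"` if already converted through the deflection
#' sensitivity); every downstream step refuses untagged deflection.
#'
#' @param piezo_height_um Piezo height in um; decreasing during approach.
#' @param deflection Cantilever deflection samples, same length.
#' @param deflection_unit `"V"` or `"nm"`.
#' @param segment Per-sample labels, `"approach"` or `"retract"`.
#' @param sample_rate_hz Data sample rate in Hz.
#' @param grid_index Integer `(row, col)` position in the map, or `NA`.
#' @param timestamp_s Seconds since map start.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(piezo_height_um, deflection,
                        deflection_unit = c("V", "nm"),
                        segment = rep("approach", length(piezo_height_um)),
                        sample_rate_hz = 2000,
                        grid_index = c(NA_integer_, NA_integer_),
                        timestamp_s = 0) {
  deflection_unit <- match.arg(deflection_unit)
  n <- length(piezo_height_um)
  if (length(deflection) != n || length(segment) != n) {
    stop("piezo_height_um, deflection and segment must have equal length",
         call. = FALSE)
  }
  if (!all(segment %in% c("approach", "retract"))) {
    stop("segment labels must be 'approach' or 'retract'", call. = FALSE)
  }
  for (seg in unique(segment)) {
    if (sum(segment == seg) < 50L) {
      stop("segment '", seg, "' has fewer than 50 samples", call. = FALSE)
    }
  }
  app <- piezo_height_um[segment == "approach"]
  if (length(app) && any(diff(app) > 0)) {
    stop("approach samples must be ordered by decreasing piezo height",
         call. = FALSE)
  }
  structure(list(piezo_height_um = as.numeric(piezo_height_um),
                 deflection = as.numeric(deflection),
                 deflection_unit = deflection_unit,
                 segment = segment,
                 sample_rate_hz = sample_rate_hz,
                 grid_index = as.integer(grid_index),
                 timestamp_s = timestamp_s),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  napp <- sum(x$segment == "approach")
  nret <- sum(x$segment == "retract")
  cat(sprintf(
    "<force_curve> %d approach + %d retract samples, deflection in %s\n",
    napp, nret, x$deflection_unit))
  cat(sprintf("  piezo range %.3f - %.3f um, sample rate %g Hz\n",
              min(x$piezo_height_um), max(x$piezo_height_um),
              x$sample_rate_hz))
  invisible(x)
}

#' Probe calibration record
#'
#' Deflection sensitivity (hard-surface slope) and cantilever spring
#' constant (thermal-noise method) that together convert photodiode volts
#' into force: `F[nN] = k[N/m] * sensitivity[nm/V] * deflection[V]`.
#'
#' @param sensitivity_nm_per_v Deflection sensitivity, nm/V; positive.
#' @param spring_constant_n_per_m Cantilever spring constant, N/m; positive.
#' @param temperature_k Calibration temperature in kelvin.
#' @return An object of class `calibration_record`.
#' @export
calibration_record <- function(sensitivity_nm_per_v,
                               spring_constant_n_per_m,
                               temperature_k = 310.15) {
  if (!is.numeric(sensitivity_nm_per_v) || sensitivity_nm_per_v <= 0) {
    stop("sensitivity must be positive (nm/V)", call. = FALSE)
  }
  if (!is.numeric(spring_constant_n_per_m) || spring_constant_n_per_m <= 0) {
    stop("spring constant must be positive (N/m)", call. = FALSE)
  }
  structure(list(sensitivity_nm_per_v = sensitivity_nm_per_v,
                 spring_constant_n_per_m = spring_constant_n_per_m,
                 temperature_k = temperature_k),
            class = "calibration_record")
}

# Deflection of the approach (or whole) curve in nm, converting volts
# through the sensitivity when needed. Errors on a missing unit tag.
.deflection_nm <- function(curve, calib) {
  if (is.null(curve$deflection_unit)) {
    stop("force curve has no deflection unit tag", call. = FALSE)
  }
  switch(curve$deflection_unit,
         nm = curve$deflection,
         V  = curve$deflection * calib$sensitivity_nm_per_v,
         stop("unknown deflection unit '", curve$deflection_unit, "'",
              call. = FALSE))
}
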