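#' Deflection sensitivity from a hard-surface curve
#'
#' On a rigid substrate the cantilever deflects exactly as far as the piezo
#' travels past contact, so the slope of photodiode voltage against piezo
#' height in the contact region gives the optical lever sensitivity. The
#' contact region is taken as the samples whose deflection exceeds the free
#' baseline by half of the total excursion; the sensitivity is the inverse
#' regression slope in nm of travel per volt of deflection.
#'
#' @param hard_surface_curve A [force_curve()] recorded on a rigid
#'   substrate, deflection in volts.
#' @return Deflection sensitivity in nm/V.
#' @export
calibrate_sensitivity <- function(hard_surface_curve) {
  curve <- hard_surface_curve
  stopifnot(inherits(curve, "force_curve"))
  if (curve$deflection_unit != "V") {
    stop("sensitivity calibration needs raw deflection in volts",
         call. = FALSE)
  }
  app <- curve$segment == "approach"
  z <- curve$piezo_height_um[app]
  v <- curve$deflection[app]
  if (length(z) < 20L) stop("too few approach samples", call. = FALSE)
  # free-level and noise from the first (high, out-of-contact) quarter
  nfree <- max(10L, length(v) %/% 4L)
  v0 <- median(v[seq_len(nfree)])
  noise <- sd(v[seq_len(nfree)])
  rng <- max(v) - v0
  if (!is.finite(rng) || rng <= max(5 * noise, 1e-9)) {
    stop("no contact region detected on the hard-surface curve",
         call. = FALSE)
  }
  contact <- v > v0 + 0.5 * rng
  if (sum(contact) < 5L) {
    stop("contact region too short for sensitivity regression",
         call. = FALSE)
  }
  slope <- coef(lm(v[contact] ~ z[contact]))[[2L]]  # V per um
  if (!is.finite(slope) || slope >= 0) {
    stop("hard-surface slope is not negative; not a contact ramp",
         call. = FALSE)
  }
  # z decreases into contact, so slope is negative; invert to nm per V
  -1000 / slope
}

#' Spring constant from thermal fluctuations
#'
#' Equipartition estimate of the cantilever spring constant from a free-air
#' deflection record: `k = kB * T / var(deflection)`, with the trace
#' mean-detrended first.
#'
#' @param deflection_nm Free-air deflection trace in nm.
#' @param temperature_k Absolute temperature in kelvin.
#' @return Spring constant in N/m.
#' @export
#' @examples
#' set.seed(1)
#' tr <- rnorm(1e4, sd = sqrt(1.380649e-23 * 300 / 0.018) * 1e9)
#' spring_constant_thermal(tr, temperature_k = 300)
spring_constant_thermal <- function(deflection_nm, temperature_k = 310.15) {
  if (!is.numeric(deflection_nm) || length(deflection_nm) < 2L) {
    stop("deflection trace must contain at least 2 samples", call. = FALSE)
  }
  if (temperature_k <= 0) stop("temperature must be positive", call. = FALSE)
  d_m <- (deflection_nm - mean(deflection_nm)) * .NM
  v <- mean(d_m^2)
  if (v <= 0) {
    stop("deflection trace has zero variance; cannot calibrate",
         call. = FALSE)
  }
  .KB * temperature_k / v
}
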