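# Per-curve processing: baseline correction, volt-to-force conversion,
# contact-point estimation by exhaustive robust scan, Young's-modulus
# fitting on the approach segment, and the five-rule QC filter cascade.

# Minimum contact-side samples for an identifiable fit. At the mapping
# settings used here (k ~ 18 mN/m, 16.7 nm piezo travel per sample) a rigid
# dish reaches the 1 nN set point after only ~4 contact samples, so the
# minimum must not exceed that or substrate stiffness becomes unassignable.
.MIN_CONTACT_SAMPLES <- 4L

.approach_arrays <- function(curve, calib) {
  app <- curve$segment == "approach"
  list(z = curve$piezo_height_um[app],
       d = .deflection_nm(curve, calib)[app],
       idx = which(app))
}

# Closed-form linear regression of d on z over the prefix 1..m, via
# precomputed cumulative sums; returns c(intercept, slope).
.prefix_line <- function(cs, m) {
  if (m < 2L) return(c(cs$d1[max(m, 1L)], 0))
  sx <- cs$sz[m]; sy <- cs$sd[m]; sxx <- cs$szz[m]; sxy <- cs$szd[m]
  den <- m * sxx - sx^2
  if (abs(den) < 1e-30) return(c(sy / m, 0))
  b1 <- (m * sxy - sx * sy) / den
  c((sy - b1 * sx) / m, b1)
}

.cumsums <- function(z, d) {
  list(sz = cumsum(z), szz = cumsum(z^2), sd = cumsum(d), szd = cumsum(z * d),
       d1 = d)
}

# Force (nN) and indentation (um) for contact-side samples j..n given a
# free-side baseline line; d in nm, z in um, k in N/m (= nN/nm).
.force_indent <- function(z, d, j, line, k) {
  zi <- z[j:length(z)]
  di <- d[j:length(d)] - (line[1] + line[2] * zi)
  force <- k * di
  delta <- (z[j] - zi) - (di - di[1]) / 1000
  delta[delta < 0] <- 0
  list(delta_um = delta, force_nn = force)
}

#' Convert a curve to force and indentation relative to a contact point
#'
#' Applies the calibration (`F = k * sensitivity * deflection`), subtracts a
#' straight-line baseline fitted to the free part of the approach segment,
#' and converts piezo travel past the contact point into true indentation by
#' subtracting the cantilever bending:
#' `delta_i = (z0 - z_i) - (d_i - d0)`. Only contact-side approach samples
#' are returned; indentation is zero at the contact point.
#'
#' @param curve A [force_curve()].
#' @param calib A [calibration_record()].
#' @param z0_index Index of the contact point within the approach segment.
#' @return A data.frame with columns `indentation_um` and `force_nn`.
#' @export
to_force_indentation <- function(curve, calib, z0_index) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(calib, "calibration_record"))
  arr <- .approach_arrays(curve, calib)
  j <- as.integer(z0_index)
  if (j < 1L || j > length(arr$z)) {
    stop("z0_index outside the approach segment", call. = FALSE)
  }
  cs <- .cumsums(arr$z, arr$d)
  line <- .prefix_line(cs, j - 1L)
  fi <- .force_indent(arr$z, arr$d, j, line, calib$spring_constant_n_per_m)
  data.frame(indentation_um = fi$delta_um, force_nn = fi$force_nn)
}

# Least-squares modulus for P_i = E * g_i (exactly linear in E), with the
# geometric factor g in um^2 so that E comes out in kPa.
.ls_modulus <- function(g, p) {
  sg2 <- sum(g^2)
  if (sg2 <= 0) return(NA_real_)
  sum(g * p) / sg2
}

# Robust modulus: Huber M-estimator solved by iteratively reweighted
# least squares (the model is exactly linear in E, so each iteration is
# closed-form). Residual scale from the MAD; tuning constant 1.345 gives
# ~95 percent Gaussian efficiency while bounding the influence of gross
# outlier samples. The exact estimator of the original desktop software is
# unpublished; this M-estimator is the package's documented stand-in,
# isolated here so it can be swapped.
.HUBER_K <- 1.345

.huber_loss <- function(r, s) {
  a <- abs(r) / s
  k <- .HUBER_K
  sum(ifelse(a <= k, 0.5 * a^2, k * a - 0.5 * k^2)) * s^2
}

.robust_modulus <- function(g, p, e_ls) {
  if (!is.finite(e_ls) || e_ls <= 0) return(NA_real_)
  e <- e_ls
  for (it in 1:30) {
    r <- p - e * g
    s <- mad(r, center = 0)
    if (s <= 0) break
    a <- abs(r) / s
    w <- ifelse(a <= .HUBER_K, 1, .HUBER_K / a)
    sgw <- sum(w * g^2)
    if (sgw <= 0) break
    e_new <- sum(w * g * p) / sgw
    if (!is.finite(e_new) || e_new <= 0) break
    done <- abs(e_new - e) <= 1e-10 * e
    e <- e_new
    if (done) break
  }
  e
}

# Huber objective value at the converged estimate, for profiling the
# contact height.
.robust_objective <- function(r) {
  s <- mad(r, center = 0)
  if (s <= 0) sum(r^2) else .huber_loss(r, s)
}

#' Configuration of the QC filter cascade
#'
#' Thresholds of the five per-curve quality filters applied to fitted
#' curves, with each rule independently toggleable:
#' \describe{
#'   \item{substrate_stiff}{modulus above `ym_substrate_threshold_kpa`
#'     (default 10 kPa) marks dish or very thin cell regions;}
#'   \item{over_indented}{fitted indentation beyond `max_indentation_um`
#'     (default 2 um) marks faulty contact-point estimates;}
#'   \item{short_fit}{force at the deepest fitted point below
#'     `min_force_fraction` (default 0.80) of the set point marks fits over
#'     too small a region;}
#'   \item{poor_rms}{model RMS deviation above `max_rms_fraction` (default
#'     0.05) of the set point;}
#'   \item{poor_maxdev}{maximum pointwise model deviation above
#'     `max_dev_fraction` (default 0.07) of the set point.}
#' }
#'
#' @param ym_substrate_threshold_kpa Substrate modulus threshold, kPa.
#' @param max_indentation_um Maximum admissible fitted indentation, um.
#' @param min_force_fraction Minimum deepest-point force as a fraction of
#'   the set point, in (0, 1).
#' @param max_rms_fraction Maximum RMS residual as a fraction of the set
#'   point, in (0, 1).
#' @param max_dev_fraction Maximum pointwise residual as a fraction of the
#'   set point, in (0, 1).
#' @param enabled Named logical vector switching individual rules off.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(ym_substrate_threshold_kpa = 10,
                          max_indentation_um = 2,
                          min_force_fraction = 0.80,
                          max_rms_fraction = 0.05,
                          max_dev_fraction = 0.07,
                          enabled = c(substrate_stiff = TRUE,
                                      over_indented = TRUE,
                                      short_fit = TRUE,
                                      poor_rms = TRUE,
                                      poor_maxdev = TRUE)) {
  stopifnot(ym_substrate_threshold_kpa > 0, max_indentation_um > 0,
            min_force_fraction > 0, min_force_fraction < 1,
            max_rms_fraction > 0, max_rms_fraction < 1,
            max_dev_fraction > 0, max_dev_fraction < 1)
  rules <- c("substrate_stiff", "over_indented", "short_fit",
             "poor_rms", "poor_maxdev")
  en <- rep(TRUE, 5L); names(en) <- rules
  en[names(enabled)] <- enabled
  structure(list(ym_substrate_threshold_kpa = ym_substrate_threshold_kpa,
                 max_indentation_um = max_indentation_um,
                 min_force_fraction = min_force_fraction,
                 max_rms_fraction = max_rms_fraction,
                 max_dev_fraction = max_dev_fraction,
                 enabled = en),
            class = "filter_config")
}

#' Construct an indentation-fit record
#'
#' Container for the result of fitting one force curve: the modulus, contact
#' point, residual diagnostics and QC state. Mostly produced by
#' [fit_young_modulus()]; the constructor is exported so that filter
#' behaviour can be exercised on hand-built fits.
#'
#' @param young_modulus_kpa Fitted Young's modulus, kPa.
#' @param contact_point_height_um Piezo height at contact, um.
#' @param contact_point_index Sample index of the contact point within the
#'   approach segment.
#' @param max_indentation_um Depth difference between the contact point and
#'   the deepest fitted point, um.
#' @param force_at_deepest_nn Measured force at the deepest fitted point, nN.
#' @param rms_residual_nn RMS model residual, nN.
#' @param max_abs_residual_nn Maximum absolute model residual, nN.
#' @param set_point_nn Nominal set point, nN.
#' @param qc_flags Character vector of raised flags.
#' @param accepted Logical; `TRUE` iff no flags are raised.
#' @return An object of class `indentation_fit`.
#' @export
indentation_fit <- function(young_modulus_kpa, contact_point_height_um = NA,
                            contact_point_index = NA_integer_,
                            max_indentation_um = 0, force_at_deepest_nn = NA,
                            rms_residual_nn = 0, max_abs_residual_nn = 0,
                            set_point_nn = 1, qc_flags = character(0),
                            accepted = NA) {
  structure(list(young_modulus_kpa = young_modulus_kpa,
                 contact_point_height_um = contact_point_height_um,
                 contact_point_index = as.integer(contact_point_index),
                 max_indentation_um = max_indentation_um,
                 force_at_deepest_nn = force_at_deepest_nn,
                 rms_residual_nn = rms_residual_nn,
                 max_abs_residual_nn = max_abs_residual_nn,
                 set_point_nn = set_point_nn,
                 qc_flags = qc_flags,
                 accepted = accepted),
            class = "indentation_fit")
}

#' @export
print.indentation_fit <- function(x, ...) {
  cat(sprintf("<indentation_fit> E = %.3f kPa, contact at sample %d (z0 = %.3f um)\n",
              x$young_modulus_kpa, x$contact_point_index,
              x$contact_point_height_um))
  cat(sprintf("  max indentation %.3f um, deepest force %.3f nN, rms %.4f nN\n",
              x$max_indentation_um, x$force_at_deepest_nn, x$rms_residual_nn))
  flags <- if (length(x$qc_flags)) paste(x$qc_flags, collapse = ", ") else "none"
  cat(sprintf("  QC flags: %s; accepted: %s\n", flags, x$accepted))
  invisible(x)
}

#' Apply the QC filter cascade to a fit
#'
#' Recomputes all five flags of the filter cascade from the fit diagnostics
#' and the thresholds in `config`; the operation is pure flagging and
#' therefore idempotent and order-independent. A fit is accepted exactly
#' when no enabled rule fires.
#'
#' @param fit An [indentation_fit()].
#' @param config A [filter_config()].
#' @return The fit with `qc_flags` and `accepted` filled in.
#' @export
apply_qc_filters <- function(fit, config = filter_config()) {
  stopifnot(inherits(fit, "indentation_fit"),
            inherits(config, "filter_config"))
  sp <- fit$set_point_nn
  flags <- character(0)
  en <- config$enabled
  if (en[["substrate_stiff"]] &&
      isTRUE(fit$young_modulus_kpa > config$ym_substrate_threshold_kpa)) {
    flags <- c(flags, "substrate_stiff")
  }
  if (en[["over_indented"]] &&
      isTRUE(fit$max_indentation_um > config$max_indentation_um)) {
    flags <- c(flags, "over_indented")
  }
  if (en[["short_fit"]] &&
      isTRUE(fit$force_at_deepest_nn < config$min_force_fraction * sp)) {
    flags <- c(flags, "short_fit")
  }
  if (en[["poor_rms"]] &&
      isTRUE(fit$rms_residual_nn > config$max_rms_fraction * sp)) {
    flags <- c(flags, "poor_rms")
  }
  if (en[["poor_maxdev"]] &&
      isTRUE(fit$max_abs_residual_nn > config$max_dev_fraction * sp)) {
    flags <- c(flags, "poor_maxdev")
  }
  fit$qc_flags <- flags
  fit$accepted <- length(flags) == 0L
  fit
}

#' Estimate the contact point of an approach curve
#'
#' Exhaustive scan over candidate contact indices within a coarse bracket
#' around the first force excursion above the baseline noise. For every
#' candidate, a straight-line baseline is fitted to the free side and the
#' spherical contact model to the contact side; the candidate is scored by
#' a robust objective (Huber loss of all residuals at the free-side noise
#' scale, so spike outliers count only linearly). The minimiser wins;
#' exact ties go to the smallest index. Deterministic for fixed input.
#'
#' @param curve A [force_curve()].
#' @param calib A [calibration_record()].
#' @param probe A [probe_geometry()].
#' @param poisson_ratio Poisson ratio used in the candidate fits.
#' @param bracket_fraction Half-width of the candidate bracket as a
#'   fraction of the approach length (default 0.10).
#' @return A list with `index` (within the approach segment), `height_um`
#'   (piezo height at contact) and `score`.
#' @export
estimate_contact_point <- function(curve, calib, probe,
                                   poisson_ratio = 0.5,
                                   bracket_fraction = 0.10) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(calib, "calibration_record"),
            inherits(probe, "probe_geometry"))
  arr <- .approach_arrays(curve, calib)
  z <- arr$z; d <- arr$d
  n <- length(z)
  if (n < 50L) stop("approach segment too short", call. = FALSE)
  k <- calib$spring_constant_n_per_m

  # coarse pre-bracket: first sustained excursion above 3x baseline noise
  nhalf <- n %/% 2L
  base_line <- .prefix_line(.cumsums(z, d), nhalf)
  resid_half <- d[seq_len(nhalf)] - (base_line[1] + base_line[2] * z[seq_len(nhalf)])
  noise <- sd(resid_half)
  excur <- d - (base_line[1] + base_line[2] * z)
  thr <- max(3 * noise, 1e-3 * max(excur), 1e-9)
  above <- excur > thr
  # require the excursion to persist to the end of the ramp
  runs <- rev(cumprod(rev(above)))
  idx0 <- which(runs == 1)[1]
  if (is.na(idx0)) {
    stop("no contact region found on the approach segment", call. = FALSE)
  }
  w <- ceiling(bracket_fraction * n)
  jmin <- max(6L, idx0 - w)
  jmax <- min(n - .MIN_CONTACT_SAMPLES + 1L, idx0 + w)
  if (idx0 <= 6L || jmin > jmax) {
    stop("curve appears to be entirely in contact; no free baseline",
         call. = FALSE)
  }

  cs <- .cumsums(z, d)
  R <- probe$radius_um
  fac <- 1 / (1 - poisson_ratio^2)
  # fixed robust residual scale for the scan score: the free-side noise
  # level (floored so noise-free curves stay well-posed)
  s0 <- max(mad(resid_half) * k, 1e-6)
  best_j <- NA_integer_
  best_score <- Inf
  for (j in jmin:jmax) {
    line <- .prefix_line(cs, j - 1L)
    fi <- .force_indent(z, d, j, line, k)
    g <- fac * .sneddon_shape(fi$delta_um, R)
    e <- .ls_modulus(g, fi$force_nn)
    if (!is.finite(e) || e <= 0) next
    rc <- fi$force_nn - e * g
    rf <- (d[seq_len(j - 1L)] - (line[1] + line[2] * z[seq_len(j - 1L)])) * k
    # Huber score at fixed scale: outlier samples count linearly, but a
    # systematic misfit of the few contact samples of a stiff curve still
    # dominates (a median objective goes blind there)
    score <- (.huber_loss(rc, s0) + .huber_loss(rf, s0)) / (length(rc) + length(rf))
    if (score < best_score) {
      best_score <- score
      best_j <- j
    }
  }
  if (is.na(best_j)) {
    stop("contact-point scan failed: no candidate produced a valid fit",
         call. = FALSE)
  }
  list(index = best_j, height_um = z[best_j], score = best_score)
}

#' Fit the Young's modulus of one approach curve
#'
#' Converts the contact side of the approach segment to force and
#' indentation (see [to_force_indentation()]) and estimates the modulus of
#' the spherical contact model. With `robust = TRUE` (the default) the
#' estimator minimises the median absolute residual, which tolerates gross
#' outlier samples; `robust = FALSE` is plain least squares (the model is
#' exactly linear in E). All residual diagnostics consumed by the QC
#' cascade are filled in.
#'
#' @param curve A [force_curve()].
#' @param calib A [calibration_record()].
#' @param probe A [probe_geometry()].
#' @param z0_index Contact-point index within the approach segment, e.g.
#'   from [estimate_contact_point()].
#' @param robust Use the robust median-residual objective (default) or
#'   least squares.
#' @param poisson_ratio Poisson ratio; 0.5 for incompressible cells.
#' @param set_point_nn Nominal set point in nN; defaults to the maximum
#'   measured contact force.
#' @return An [indentation_fit()] (QC flags not yet applied).
#' @export
fit_young_modulus <- function(curve, calib, probe, z0_index,
                              robust = TRUE, poisson_ratio = 0.5,
                              set_point_nn = NULL) {
  stopifnot(inherits(curve, "force_curve"),
            inherits(calib, "calibration_record"),
            inherits(probe, "probe_geometry"))
  arr <- .approach_arrays(curve, calib)
  j <- as.integer(z0_index)
  n <- length(arr$z)
  if (j < 2L || j > n) stop("z0_index outside the approach segment", call. = FALSE)
  if (n - j + 1L < .MIN_CONTACT_SAMPLES) {
    stop("fewer than ", .MIN_CONTACT_SAMPLES,
         " contact samples; modulus not identifiable", call. = FALSE)
  }
  k <- calib$spring_constant_n_per_m
  cs <- .cumsums(arr$z, arr$d)
  line <- .prefix_line(cs, j - 1L)
  d_corr_nm <- arr$d - (line[1] + line[2] * arr$z)
  fac <- 1 / (1 - poisson_ratio^2)
  R <- probe$radius_um

  # The true contact lies between samples; treat its piezo height as a
  # continuous parameter within one sample spacing of the scanned index
  # and profile the fit objective over it (the modulus is closed-form at
  # fixed contact height, so this stays a 1-D search).
  eval_at <- function(z0c) {
    jj <- which(arr$z < z0c)[1]
    if (is.na(jj) || n - jj + 1L < .MIN_CONTACT_SAMPLES) return(NULL)
    idx <- jj:n
    delta <- (z0c - arr$z[idx]) - d_corr_nm[idx] / 1000
    delta[delta < 0] <- 0
    p <- k * d_corr_nm[idx]
    g <- fac * .sneddon_shape(delta, R)
    e_ls <- .ls_modulus(g, p)
    e <- if (robust) .robust_modulus(g, p, e_ls) else e_ls
    if (!is.finite(e) || e <= 0) return(NULL)
    r <- p - e * g
    val <- if (robust) .robust_objective(r) else sum(r^2)
    list(e = e, val = val, index = jj, delta = delta, p = p, r = r)
  }
  z_hi <- arr$z[max(j - 1L, 1L)]
  z_lo <- arr$z[min(j + 1L, n)]
  opt <- optimize(function(z0c) {
    res <- eval_at(z0c)
    if (is.null(res)) 1e300 else res$val
  }, lower = z_lo, upper = z_hi, tol = (z_hi - z_lo) * 1e-6)
  best <- eval_at(opt$minimum)
  if (is.null(best)) best <- eval_at(arr$z[j] + 1e-9)
  if (is.null(best)) {
    stop("modulus fit failed (non-positive estimate)", call. = FALSE)
  }
  deepest <- which.max(best$delta)
  sp <- if (is.null(set_point_nn)) max(best$p) else set_point_nn
  indentation_fit(
    young_modulus_kpa = best$e,
    contact_point_height_um = opt$minimum,
    contact_point_index = best$index,
    max_indentation_um = best$delta[deepest],
    force_at_deepest_nn = best$p[deepest],
    rms_residual_nn = sqrt(mean(best$r^2)),
    max_abs_residual_nn = max(abs(best$r)),
    set_point_nn = sp)
}
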