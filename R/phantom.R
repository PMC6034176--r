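# Synthetic force-map generation: phantom cells with known ground truth,
# simulated through the same spherical contact model the fitter inverts
# (the generator and the fitter share only the contact-mechanics core; the
# fitter never sees the ground-truth fields).

# Evaluate an expression under a given seed without disturbing the
# caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a phantom cell and its acquisition conditions
#'
#' Ground truth for the synthetic force-map generator: a spherical-cap cell
#' on a rigid dish, a compartmental elasticity field (soft nucleus, stiffer
#' periphery, optional perinuclear ring and fiber lines), instrument-like
#' noise, and a multiplicative post-thaw stiffness decay
#' `E(t) = E0 * (f + (1 - f) * exp(-t / tau))`.
#'
#' Acquisition defaults mirror a typical colloidal-probe mapping session:
#' probe radius 3.31 um, spring constant 18 mN/m, sensitivity 15.2 nm/V,
#' set point 1 nN, Z-length 15 um, 33.3 um/s ramp at 2 kHz sampling.
#'
#' @param seed Integer seed; mandatory, drives all simulated noise.
#' @param n_rows,n_cols Grid shape (at most 64 x 64).
#' @param extent_um Physical extent `c(x, y)` in um.
#' @param cell_center_um Cell centre `c(x, y)` in um; default map centre.
#' @param cell_radius_um Footprint (base) radius of the spherical cap, um.
#' @param cell_peak_um Peak height of the cap, um.
#' @param nucleus_fraction Nucleus radius as a fraction of the footprint.
#' @param nucleus_e_kpa,periphery_e_kpa,substrate_e_kpa Compartment moduli.
#' @param ring `NULL`, or `list(radius_fraction, width_fraction, e_kpa)`
#'   for a stiff perinuclear ring.
#' @param fibers `NULL`, or a list of
#'   `list(from_um, to_um, width_um, e_kpa)` stress-fiber segments.
#' @param plane_tilt_deg,plane_azimuth_deg Dish-plane tilt and direction.
#' @param decay `list(final_fraction, tau_min)`; `final_fraction` (and
#'   `tau_min`) may be a scalar or named per compartment
#'   (`nucleus`, `periphery`, `ring`, `fiber`).
#' @param noise_fraction Deflection noise SD as a fraction of the set
#'   point (noise enters on the deflection signal, where it arises
#'   physically).
#' @param baseline_offset_v,baseline_tilt_v_per_um Linear baseline of the
#'   photodiode signal.
#' @param set_point_nn,z_length_um,sample_rate_hz,speed_um_per_s
#'   Ramp parameters.
#' @param probe_radius_um,spring_constant_n_per_m,sensitivity_nm_per_v,temperature_k
#'   Instrument parameters.
#' @param poisson_ratio Poisson ratio of all compartments.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed,
                         n_rows = 64L, n_cols = 64L,
                         extent_um = c(100, 100),
                         cell_center_um = NULL,
                         cell_radius_um = 30,
                         cell_peak_um = 4,
                         nucleus_fraction = 0.55,
                         nucleus_e_kpa = 2,
                         periphery_e_kpa = 4,
                         ring = NULL,
                         fibers = NULL,
                         substrate_e_kpa = 2000,
                         plane_tilt_deg = 0,
                         plane_azimuth_deg = 0,
                         decay = list(final_fraction = 1, tau_min = Inf),
                         noise_fraction = 0.02,
                         baseline_offset_v = 0.01,
                         baseline_tilt_v_per_um = 2e-4,
                         set_point_nn = 1,
                         z_length_um = 15,
                         sample_rate_hz = 2000,
                         speed_um_per_s = 33.3,
                         probe_radius_um = 3.31,
                         spring_constant_n_per_m = 0.018,
                         sensitivity_nm_per_v = 15.2,
                         temperature_k = 310.15,
                         poisson_ratio = 0.5) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed)) {
    stop("a single integer seed is mandatory for a phantom spec",
         call. = FALSE)
  }
  if (is.null(cell_center_um)) cell_center_um <- extent_um / 2
  stopifnot(n_rows >= 1, n_rows <= 64, n_cols >= 1, n_cols <= 64,
            all(extent_um > 0), cell_radius_um > 0, cell_peak_um > 0,
            nucleus_fraction > 0, nucleus_fraction <= 1,
            nucleus_e_kpa > 0, periphery_e_kpa > 0, substrate_e_kpa > 0,
            noise_fraction >= 0, set_point_nn > 0,
            cell_peak_um < z_length_um)
  if (cell_center_um[1] - cell_radius_um < 0 ||
      cell_center_um[1] + cell_radius_um > extent_um[1] ||
      cell_center_um[2] - cell_radius_um < 0 ||
      cell_center_um[2] + cell_radius_um > extent_um[2]) {
    stop("cell footprint exceeds the scan extent", call. = FALSE)
  }
  structure(list(seed = as.integer(seed),
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 extent_um = extent_um, cell_center_um = cell_center_um,
                 cell_radius_um = cell_radius_um, cell_peak_um = cell_peak_um,
                 nucleus_fraction = nucleus_fraction,
                 nucleus_e_kpa = nucleus_e_kpa,
                 periphery_e_kpa = periphery_e_kpa,
                 ring = ring, fibers = fibers,
                 substrate_e_kpa = substrate_e_kpa,
                 plane_tilt_deg = plane_tilt_deg,
                 plane_azimuth_deg = plane_azimuth_deg,
                 decay = decay, noise_fraction = noise_fraction,
                 baseline_offset_v = baseline_offset_v,
                 baseline_tilt_v_per_um = baseline_tilt_v_per_um,
                 set_point_nn = set_point_nn, z_length_um = z_length_um,
                 sample_rate_hz = sample_rate_hz,
                 speed_um_per_s = speed_um_per_s,
                 probe_radius_um = probe_radius_um,
                 spring_constant_n_per_m = spring_constant_n_per_m,
                 sensitivity_nm_per_v = sensitivity_nm_per_v,
                 temperature_k = temperature_k,
                 poisson_ratio = poisson_ratio),
            class = "phantom_spec")
}

#' Named phantom presets
#'
#' Two reference phantoms used throughout the test battery:
#' \describe{
#'   \item{`"dmso-like"`}{structured cell with a soft nucleus (2 kPa),
#'     stiffer periphery (4 kPa), a stiff perinuclear ring (6 kPa) and two
#'     stress fibers (8 kPa); whole-cell stiffness relaxes to 40 percent of
#'     its initial value (time constant 25 min), i.e. a 60 percent median
#'     decrease over 2 h.}
#'   \item{`"peg-like"`}{taller, rounder, homogeneous cell (3 kPa
#'     throughout) whose stiffness relaxes only to 80 percent (time
#'     constant 40 min), i.e. at most a 20 percent decrease.}
#' }
#'
#' @param name `"dmso-like"` or `"peg-like"`.
#' @param seed Integer seed.
#' @param n_rows,n_cols Grid shape override (defaults 64 x 64).
#' @param ... Further overrides passed to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
phantom_preset <- function(name = c("dmso-like", "peg-like"), seed,
                           n_rows = 64L, n_cols = 64L, ...) {
  name <- match.arg(name)
  if (name == "dmso-like") {
    phantom_spec(seed = seed, n_rows = n_rows, n_cols = n_cols,
                 cell_radius_um = 30, cell_peak_um = 4,
                 nucleus_fraction = 0.55,
                 nucleus_e_kpa = 2, periphery_e_kpa = 4,
                 ring = list(radius_fraction = 0.78, width_fraction = 0.10,
                             e_kpa = 6),
                 fibers = list(
                   list(from_um = c(28, 28), to_um = c(72, 72),
                        width_um = 2.5, e_kpa = 8),
                   list(from_um = c(30, 70), to_um = c(70, 30),
                        width_um = 2.5, e_kpa = 8)),
                 decay = list(final_fraction = 0.4, tau_min = 25),
                 ...)
  } else {
    phantom_spec(seed = seed, n_rows = n_rows, n_cols = n_cols,
                 cell_radius_um = 25, cell_peak_um = 6,
                 nucleus_fraction = 1, nucleus_e_kpa = 3,
                 periphery_e_kpa = 3, ring = NULL, fibers = NULL,
                 decay = list(final_fraction = 0.8, tau_min = 40),
                 ...)
  }
}

# Decay factor for one compartment at time t (minutes).
.decay_factor <- function(decay, compartment, time_min) {
  pick <- function(x) {
    if (length(x) == 1L && is.null(names(x))) return(x)
    if (!is.null(names(x)) && compartment %in% names(x)) return(x[[compartment]])
    x[[1L]]
  }
  f <- pick(decay$final_fraction)
  tau <- pick(decay$tau_min)
  if (!is.finite(tau)) return(1)
  f + (1 - f) * exp(-time_min / tau)
}

#' Render the ground-truth fields of a phantom
#'
#' Evaluates the true height and elasticity fields on the acquisition grid
#' at a given post-thaw time. The cell is a spherical cap; inside its
#' footprint the modulus is the compartment value (fibers over ring over
#' nucleus over periphery), decayed by the per-compartment time profile;
#' outside it is the substrate modulus, undecayed.
#'
#' @param spec A [phantom_spec()].
#' @param time_min Minutes post thaw; 0 applies no decay.
#' @return A list of matrices: `height_um` (cap height above the dish),
#'   `e_kpa`, `compartment` (character), `plane_um` (tilted dish plane)
#'   and the grid coordinates `x_um`, `y_um`.
#' @export
render_phantom <- function(spec, time_min = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  x <- (seq_len(nc) - 0.5) * spec$extent_um[1] / nc
  y <- (seq_len(nr) - 0.5) * spec$extent_um[2] / nr
  X <- matrix(rep(x, each = nr), nr, nc)
  Y <- matrix(rep(y, times = nc), nr, nc)
  dx <- X - spec$cell_center_um[1]
  dy <- Y - spec$cell_center_um[2]
  r <- sqrt(dx^2 + dy^2)

  rb <- spec$cell_radius_um; h <- spec$cell_peak_um
  Rs <- (rb^2 + h^2) / (2 * h)           # cap sphere radius
  height <- matrix(0, nr, nc)
  inside <- r < rb
  height[inside] <- sqrt(Rs^2 - r[inside]^2) - (Rs - h)

  comp <- matrix("substrate", nr, nc)
  comp[inside] <- "periphery"
  comp[inside & r <= spec$nucleus_fraction * rb] <- "nucleus"
  if (!is.null(spec$ring)) {
    rr <- spec$ring$radius_fraction * rb
    wr <- spec$ring$width_fraction * rb
    comp[inside & abs(r - rr) <= wr / 2] <- "ring"
  }
  if (!is.null(spec$fibers)) {
    for (fb in spec$fibers) {
      p1 <- fb$from_um; p2 <- fb$to_um
      v <- p2 - p1
      len2 <- sum(v^2)
      tt <- pmin(1, pmax(0, ((X - p1[1]) * v[1] + (Y - p1[2]) * v[2]) / len2))
      dist <- sqrt((X - (p1[1] + tt * v[1]))^2 + (Y - (p1[2] + tt * v[2]))^2)
      comp[inside & dist <= fb$width_um / 2] <- "fiber"
    }
  }
  e0 <- c(substrate = spec$substrate_e_kpa,
          periphery = spec$periphery_e_kpa,
          nucleus = spec$nucleus_e_kpa,
          ring = if (!is.null(spec$ring)) spec$ring$e_kpa else NA_real_,
          fiber = if (!is.null(spec$fibers)) spec$fibers[[1]]$e_kpa else NA_real_)
  E <- matrix(NA_real_, nr, nc)
  for (cmp in unique(as.vector(comp))) {
    f <- if (cmp == "substrate") 1 else .decay_factor(spec$decay, cmp, time_min)
    E[comp == cmp] <- e0[[cmp]] * f
  }
  tilt <- tan(spec$plane_tilt_deg * pi / 180)
  az <- spec$plane_azimuth_deg * pi / 180
  plane <- tilt * (X * cos(az) + Y * sin(az))
  list(height_um = height, e_kpa = E, compartment = comp,
       plane_um = plane, x_um = X, y_um = Y)
}

# Solve delta + P(delta)/k = travel for each sample of one curve, in
# um/nN/kPa units (k_nn_per_um = spring constant in nN/um). Safeguarded
# Newton using the exact contact stiffness dP/ddelta = 2 a E/(1-nu^2).
.solve_indentation <- function(travel_um, e_kpa, R_um, k_nn_per_um,
                               poisson_ratio = 0.5, tol = 1e-12,
                               maxit = 100L) {
  estar <- e_kpa / (1 - poisson_ratio^2)
  n <- length(travel_um)
  delta <- travel_um / 2
  lo <- numeric(n); up <- travel_um
  active <- travel_um > 0
  delta[!active] <- 0
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    d <- delta[active]
    a <- .contact_radius_newton(d, R_um)
    shape <- ((R_um^2 + a^2) / 2) * log((R_um + a) / (R_um - a)) - a * R_um
    P <- estar * shape
    f <- d + P / k_nn_per_um - travel_um[active]
    pos <- f > 0
    up[active][pos] <- d[pos]
    lo[active][!pos] <- d[!pos]
    fp <- 1 + 2 * estar * a / k_nn_per_um
    dn <- d - f / fp
    bad <- !is.finite(dn) | dn <= lo[active] | dn >= up[active]
    dn[bad] <- (lo[active][bad] + up[active][bad]) / 2
    conv <- abs(dn - d) <= tol * pmax(dn, 1e-6)
    delta[active] <- dn
    active[active] <- !conv
  }
  delta
}

# Indentation depth at which the load reaches `p_nn`, by scalar bisection
# on the monotone load curve.
.depth_at_force <- function(p_nn, e_kpa, R_um, poisson_ratio = 0.5) {
  estar <- e_kpa / (1 - poisson_ratio^2)
  f <- function(d) estar * .sneddon_shape(d, R_um) - p_nn
  stats::uniroot(f, lower = 0, upper = 13 * R_um, tol = 1e-12)$root
}

# Noise-free approach for one grid point: piezo positions z_um
# (decreasing), surface contact height z_c. The approach is truncated when
# the load reaches the set point; the trigger sample is recorded at the
# exact (off-grid) crossing piezo position, as the instrument's relative
# set-point trigger does. Returns truncated piezo positions and deflection
# (um), plus `reached` = FALSE when the set point is beyond the Z-length.
.forward_curve <- function(z_um, z_c, e_kpa, spec) {
  k_nn_per_um <- spec$spring_constant_n_per_m * 1000
  d_sp <- .depth_at_force(spec$set_point_nn, e_kpa, spec$probe_radius_um,
                          spec$poisson_ratio)
  t_sp <- d_sp + spec$set_point_nn / k_nn_per_um
  travel <- pmax(z_c - z_um, 0)
  keep <- travel < t_sp
  z_app <- z_um[keep]
  tr <- travel[keep]
  reached <- any(!keep)
  if (reached) {
    z_app <- c(z_app, z_c - t_sp)
    tr <- c(tr, t_sp)
  }
  delta <- .solve_indentation(tr, e_kpa, spec$probe_radius_um,
                              k_nn_per_um, spec$poisson_ratio)
  d_um <- tr - delta
  list(z_app = z_app, d_um = d_um, force_nn = d_um * k_nn_per_um,
       delta_um = delta, reached = reached)
}

# Build one force_curve from a noise-free forward model plus baseline and
# noise.
.make_curve <- function(fwd, spec, z_ref, grid_index, timestamp_s) {
  z_app <- fwd$z_app
  n_app <- length(z_app)
  d_nm <- fwd$d_um * 1000
  base_v <- spec$baseline_offset_v +
    spec$baseline_tilt_v_per_um * (z_app - z_ref)
  sd_v <- spec$noise_fraction * spec$set_point_nn /
    spec$spring_constant_n_per_m / spec$sensitivity_nm_per_v
  v_app <- d_nm / spec$sensitivity_nm_per_v + base_v +
    if (sd_v > 0) rnorm(n_app, 0, sd_v) else 0
  v_ret <- rev(d_nm / spec$sensitivity_nm_per_v + base_v) +
    if (sd_v > 0) rnorm(n_app, 0, sd_v) else 0
  force_curve(piezo_height_um = c(z_app, rev(z_app)),
              deflection = c(v_app, v_ret),
              deflection_unit = "V",
              segment = rep(c("approach", "retract"), each = n_app),
              sample_rate_hz = spec$sample_rate_hz,
              grid_index = grid_index,
              timestamp_s = timestamp_s)
}

#' Simulate a complete force map from a phantom
#'
#' For every grid point, ramps the piezo over the Z-length, computes the
#' self-consistent indentation and cantilever deflection from the local
#' true modulus through the spherical contact model (`delta + P(delta)/k =
#' travel`), adds the linear photodiode baseline and Gaussian deflection
#' noise, and truncates the approach when the noise-free force reaches the
#' set point. The retract segment mirrors the approach (no hysteresis is
#' modelled). Reproducible: the RNG stream is derived from `spec$seed` and
#' the timepoint.
#'
#' Ground truth is attached as attributes (`truth`: true modulus, height,
#' contact height and contact index per point) but never written to the
#' exchange archive, so the fitter cannot see it.
#'
#' @param spec A [phantom_spec()].
#' @param time_min Minutes post thaw (selects the decayed elasticity field
#'   and offsets the RNG stream).
#' @return A [force_map()] with a `truth` attribute.
#' @export
simulate_force_map <- function(spec, time_min = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  ph <- render_phantom(spec, time_min)
  nr <- spec$n_rows; nc <- spec$n_cols
  z_c <- ph$plane_um + ph$height_um
  z_ref <- max(z_c) + 1.5
  dz <- spec$speed_um_per_s / spec$sample_rate_hz
  n_max <- floor(spec$z_length_um / dz)
  z_um <- z_ref - (seq_len(n_max) - 1L) * dz
  probe <- probe_geometry(radius_um = spec$probe_radius_um)
  calib <- calibration_record(spec$sensitivity_nm_per_v,
                              spec$spring_constant_n_per_m,
                              spec$temperature_k)
  seed_eff <- (spec$seed + 1000L * (round(time_min) %% 1000L)) %% .Machine$integer.max
  true_idx <- matrix(NA_integer_, nr, nc)
  unreached <- matrix(FALSE, nr, nc)
  curves <- .with_seed(seed_eff, {
    out <- vector("list", nr * nc)
    t_per_curve <- 2 * n_max / spec$sample_rate_hz
    for (li in seq_len(nr * nc)) {
      r <- ((li - 1L) %/% nc) + 1L
      cc <- ((li - 1L) %% nc) + 1L
      fwd <- .forward_curve(z_um, z_c[r, cc], ph$e_kpa[r, cc], spec)
      true_idx[r, cc] <- which(z_um < z_c[r, cc])[1]
      unreached[r, cc] <- !fwd$reached
      out[[li]] <- .make_curve(fwd, spec, z_ref, c(r, cc),
                               timestamp_s = (li - 1L) * t_per_curve)
    }
    out
  })
  map <- force_map(curves, nr, nc, extent_um = spec$extent_um,
                   probe = probe, calib = calib,
                   set_point_nn = spec$set_point_nn,
                   timestamp_min = time_min, seed = spec$seed)
  attr(map, "truth") <- list(e_kpa = ph$e_kpa, height_um = ph$height_um,
                             contact_z_um = z_c, contact_index = true_idx,
                             compartment = ph$compartment,
                             set_point_unreached = unreached)
  map
}

#' Simulate a single indentation curve
#'
#' Convenience wrapper around the same forward model as
#' [simulate_force_map()] for one sample of known modulus: useful for
#' parameter-recovery studies on individual curves.
#'
#' @param e_kpa True Young's modulus, kPa.
#' @param seed Seed for the noise draws.
#' @param noise_fraction Deflection noise SD as a fraction of the set point.
#' @param free_travel_um Free ramp before contact, um.
#' @param outlier_fraction Fraction of approach samples replaced by gross
#'   outliers (amplitude ~ half the set point), for robustness studies.
#' @param ... Overrides passed to [phantom_spec()] (instrument parameters).
#' @return A list: `curve` (a [force_curve()]), `calib`, `probe`,
#'   `set_point_nn`, `true_contact_index` (within the approach segment) and
#'   `true_z0_um`.
#' @export
simulate_force_curve <- function(e_kpa, seed = 1L, noise_fraction = 0,
                                 free_travel_um = 3,
                                 outlier_fraction = 0, ...) {
  spec <- phantom_spec(seed = seed, noise_fraction = noise_fraction, ...)
  dz <- spec$speed_um_per_s / spec$sample_rate_hz
  n_max <- floor(spec$z_length_um / dz)
  z_ref <- free_travel_um
  z_um <- z_ref - (seq_len(n_max) - 1L) * dz
  z_c <- 0
  curve <- .with_seed(spec$seed, {
    fwd <- .forward_curve(z_um, z_c, e_kpa, spec)
    cur <- .make_curve(fwd, spec, z_ref, c(1L, 1L), 0)
    if (outlier_fraction > 0) {
      app <- which(cur$segment == "approach")
      n_out <- max(1L, round(outlier_fraction * length(app)))
      pick <- sample(app, n_out)
      # one-sided positive spikes, as debris or transient sticking produce
      amp_v <- 0.5 * spec$set_point_nn / spec$spring_constant_n_per_m /
        spec$sensitivity_nm_per_v
      cur$deflection[pick] <- cur$deflection[pick] + amp_v
    }
    cur
  })
  list(curve = curve,
       calib = calibration_record(spec$sensitivity_nm_per_v,
                                  spec$spring_constant_n_per_m),
       probe = probe_geometry(spec$probe_radius_um),
       set_point_nn = spec$set_point_nn,
       true_contact_index = which(z_um < z_c)[1],
       true_z0_um = z_c)
}
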