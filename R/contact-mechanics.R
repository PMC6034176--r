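#' @importFrom stats median mad coef lm optimize rnorm sd shapiro.test var
#' @importFrom data.table data.table fread fwrite rbindlist setattr set copy as.data.table
#' @importFrom utils head tail
NULL

# Internal unit system is SI (m, N, Pa). Public interfaces use the reporting
# units of AFM cell mechanics: lengths in um, forces in nN, moduli in kPa,
# spring constants in N/m (1 N/m == 1 nN/nm), sensitivity in nm/V.
.UM  <- 1e-6  # m per um
.NN  <- 1e-9  # N per nN
.NM  <- 1e-9  # m per nm
.KPA <- 1e3   # Pa per kPa
.KB  <- 1.380649e-23  # Boltzmann constant, J/K

#' Spherical probe geometry
#'
#' Describes the colloidal (spherical) indenter. Only spherical probes are
#' supported; the pipeline is built around a silica microsphere of radius
#' 3.31 um (6.62 um diameter), the default here.
#'
#' @param radius_um Probe radius in micrometres; must be positive.
#' @param shape Probe shape; only `"spherical"` is implemented.
#' @return An object of class `probe_geometry`.
#' @export
#' @examples
#' probe_geometry()           # the 3.31 um colloidal probe
#' probe_geometry(radius_um = 5)
probe_geometry <- function(radius_um = 3.31, shape = c("spherical")) {
  shape <- match.arg(shape)
  if (!is.numeric(radius_um) || length(radius_um) != 1L || !is.finite(radius_um) ||
      radius_um <= 0) {
    stop("probe radius must be a single positive number (um)", call. = FALSE)
  }
  structure(list(radius_um = radius_um, shape = shape),
            class = "probe_geometry")
}

#' Elastic material parameters
#'
#' Young's modulus and Poisson ratio of the indented half-space. Cells are
#' treated as incompressible, so the Poisson ratio defaults to 0.5.
#'
#' @param young_modulus_kpa Young's modulus in kPa; must be positive.
#' @param poisson_ratio Poisson ratio, in `[0, 0.5]`.
#' @return An object of class `material_params`.
#' @export
material_params <- function(young_modulus_kpa, poisson_ratio = 0.5) {
  if (!is.numeric(young_modulus_kpa) || length(young_modulus_kpa) != 1L ||
      !is.finite(young_modulus_kpa) || young_modulus_kpa <= 0) {
    stop("young_modulus_kpa must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(poisson_ratio) || length(poisson_ratio) != 1L ||
      poisson_ratio < 0 || poisson_ratio > 0.5) {
    stop("poisson_ratio must lie in [0, 0.5]", call. = FALSE)
  }
  structure(list(young_modulus_kpa = young_modulus_kpa,
                 poisson_ratio = poisson_ratio),
            class = "material_params")
}

#' Indentation depth of a rigid sphere at a given contact radius
#'
#' For a rigid sphere of radius `R` pressed into an elastic half-space the
#' exact axisymmetric contact solution relates indentation depth and contact
#' radius by `delta = (a/2) * log((R + a)/(R - a))`. The relation is strictly
#' increasing in `a` and diverges as `a -> R`.
#'
#' @param a Contact radius (same length unit as `R`); vectorised.
#' @param R Sphere radius; a single positive number.
#' @return Indentation depth(s) in the unit of `a` and `R`.
#' @seealso [contact_radius_from_indentation()] for the numerical inverse.
#' @export
#' @examples
#' indentation_from_contact_radius(1.0, R = 3.31)
indentation_from_contact_radius <- function(a, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("R must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(a)) || any(a < 0) || any(a >= R)) {
    stop("contact radius must satisfy 0 <= a < R", call. = FALSE)
  }
  (a / 2) * log((R + a) / (R - a))
}

# Safeguarded vectorised Newton iteration for the inverse a(delta) of
# delta(a) = (a/2) log((R+a)/(R-a)). Monotone with a log singularity at
# a = R; the Newton step is rejected in favour of bisection whenever it
# leaves the current bracket, so convergence is guaranteed.
.contact_radius_newton <- function(delta, R, tol = 1e-13, maxit = 200L) {
  n <- length(delta)
  a <- pmin(sqrt(delta * R), R * (1 - 1e-12))  # Hertz-limit initial guess
  lo <- numeric(n)
  up <- rep(R * (1 - 1e-12), n)
  active <- delta > 0
  a[!active] <- 0
  for (it in seq_len(maxit)) {
    if (!any(active)) break
    ai <- a[active]
    L <- log((R + ai) / (R - ai))
    f <- (ai / 2) * L - delta[active]
    fp <- L / 2 + ai * R / (R^2 - ai^2)
    pos <- f > 0
    up[active][pos] <- ai[pos]
    lo[active][!pos] <- ai[!pos]
    step <- f / fp
    anew <- ai - step
    bad <- !is.finite(anew) | anew <= lo[active] | anew >= up[active]
    anew[bad] <- (lo[active][bad] + up[active][bad]) / 2
    conv <- abs(anew - ai) <= tol * pmax(anew, R * 1e-3)
    a[active] <- anew
    active[active] <- !conv
  }
  if (any(active)) {
    stop("contact-radius inversion failed to converge for ",
         sum(active), " value(s); max residual bracket width ",
         format(max((up - lo)[active])), call. = FALSE)
  }
  a
}

#' Contact radius at a given indentation depth (numerical inverse)
#'
#' Inverts the sphere contact relation `delta(a) = (a/2) log((R+a)/(R-a))`
#' to relative accuracy better than 1e-12, returning the unique contact
#' radius in `[0, R)`. Uses a bracketed, safeguarded Newton iteration.
#'
#' @param delta Indentation depth(s), non-negative, same unit as `R`.
#' @param R Sphere radius; single positive number.
#' @return Contact radius/radii in `[0, R)`.
#' @export
#' @examples
#' a <- contact_radius_from_indentation(0.5, R = 3.31)
#' indentation_from_contact_radius(a, R = 3.31)  # recovers 0.5
contact_radius_from_indentation <- function(delta, R) {
  if (!is.numeric(R) || length(R) != 1L || R <= 0) {
    stop("R must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(delta)) || any(delta < 0)) {
    stop("indentation depth must be finite and >= 0", call. = FALSE)
  }
  .contact_radius_newton(delta, R)
}

# Geometric load factor of the Sneddon sphere solution, in length^2 units:
# P = E/(1-nu^2) * shape(delta), shape = ((R^2+a^2)/2) log((R+a)/(R-a)) - aR.
# With E in kPa and lengths in um the product is exactly in nN
# (1 kPa * um^2 = 1e3 Pa * 1e-12 m^2 = 1e-9 N), a identity pinned by tests.
.sneddon_shape <- function(delta, R) {
  a <- .contact_radius_newton(delta, R)
  ((R^2 + a^2) / 2) * log((R + a) / (R - a)) - a * R
}

#' Load on a spherical indenter (Sneddon solution)
#'
#' Evaluates the exact spherical-punch load
#' `P = E/(1 - nu^2) * [ ((R^2 + a^2)/2) log((R+a)/(R-a)) - aR ]`,
#' where the contact radius `a` is obtained from the indentation depth by
#' [contact_radius_from_indentation()]. The load is zero at zero depth,
#' strictly increasing and convex in depth, and linear in the modulus.
#'
#' Depths beyond twice the probe radius are accepted mathematically but
#' flagged with a warning, since the contact geometry is no longer
#' physically meaningful there; the QC filter cascade removes such fits.
#'
#' @param delta_um Indentation depth(s) in um, non-negative; vectorised.
#' @param material A [material_params()] object.
#' @param probe A [probe_geometry()] object.
#' @return Load(s) in nN.
#' @seealso [hertz_force()] for the small-depth parabolic approximation.
#' @export
#' @examples
#' sneddon_force(0.5, material_params(5), probe_geometry())
sneddon_force <- function(delta_um, material, probe) {
  stopifnot(inherits(material, "material_params"),
            inherits(probe, "probe_geometry"))
  if (any(!is.finite(delta_um)) || any(delta_um < 0)) {
    stop("indentation depth must be finite and >= 0", call. = FALSE)
  }
  if (any(delta_um > 2 * probe$radius_um)) {
    warning("indentation exceeds twice the probe radius; ",
            "the contact model is not physically valid there", call. = FALSE)
  }
  delta_m <- delta_um * .UM
  R_m <- probe$radius_um * .UM
  E_pa <- material$young_modulus_kpa * .KPA
  P_n <- E_pa / (1 - material$poisson_ratio^2) * .sneddon_shape(delta_m, R_m)
  P_n / .NN
}

#' Load on a spherical indenter (Hertz parabolic approximation)
#'
#' Small-depth limit `P = (4/3) * E/(1 - nu^2) * sqrt(R) * delta^(3/2)`,
#' which approximates the sphere by a paraboloid. Used as an analytic
#' verification limit for [sneddon_force()]: the two agree within 1 percent
#' for depths below about 1 percent of the probe radius, and the sphere
#' carries less load than the paraboloid at depth.
#'
#' @inheritParams sneddon_force
#' @return Load(s) in nN.
#' @export
hertz_force <- function(delta_um, material, probe) {
  stopifnot(inherits(material, "material_params"),
            inherits(probe, "probe_geometry"))
  if (any(!is.finite(delta_um)) || any(delta_um < 0)) {
    stop("indentation depth must be finite and >= 0", call. = FALSE)
  }
  delta_m <- delta_um * .UM
  R_m <- probe$radius_um * .UM
  E_pa <- material$young_modulus_kpa * .KPA
  P_n <- (4 / 3) * E_pa / (1 - material$poisson_ratio^2) *
    sqrt(R_m) * delta_m^1.5
  P_n / .NN
}
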