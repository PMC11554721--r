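#' Elastin material parameters
#'
#' Parameters of the compressible neo-Hookean matrix representing elastin:
#' an isochoric shear term and a volumetric penalty. The volumetric response
#' of the whole mixture is carried by this penalty (the fiber constituents
#' are quasi-one-dimensional).
#'
#' @param mu_e Shear-modulus-like parameter (kPa).
#' @param kappa Volumetric penalty modulus (kPa); default ten times `mu_e`.
#' @param lambda_z_e Axial deposition (pre-)stretch of elastin, dimensionless.
#' @return An object of class `elastin_params`.
#' @export
elastin_params <- function(mu_e = 89.71, kappa = 10 * mu_e, lambda_z_e = 1.62) {
  stopifnot(mu_e > 0, kappa > 0, lambda_z_e > 0)
  structure(list(mu_e = mu_e, kappa = kappa, lambda_z_e = lambda_z_e),
            class = "elastin_params")
}

#' Fiber family parameters
#'
#' Fung-type exponential fiber family (collagen or passive smooth muscle).
#' `angle_deg` is measured from the circumferential axis in the
#' circumferential-axial plane; `lambda_h` is the deposition (homeostatic)
#' elastic stretch at which new mass is incorporated, `T_days` the mean
#' survival time governing turnover, and `phi0` the initial mass fraction.
#'
#' @param c1 Fung stiffness (kPa).
#' @param c2 Fung exponent (dimensionless).
#' @param angle_deg Orientation from the circumferential axis (degrees).
#' @param lambda_h Deposition (homeostatic) stretch.
#' @param T_days Mean survival time (days).
#' @param phi0 Initial mass fraction in the mixture.
#' @param name Optional family label.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(c1, c2, angle_deg = 0, lambda_h = 1.25,
                         T_days = 70, phi0 = 0.1, name = NULL) {
  stopifnot(c1 > 0, c2 >= 0, T_days > 0, phi0 >= 0, phi0 <= 1, lambda_h > 0)
  structure(list(c1 = c1, c2 = c2, angle_deg = angle_deg,
                 lambda_h = lambda_h, T_days = T_days, phi0 = phi0,
                 name = name %||% sprintf("fiber_%g", angle_deg)),
            class = "fiber_params")
}

#' Active smooth muscle parameters
#'
#' Parameters of the active (contractile) smooth muscle stress. The active
#' reference configuration remodels fast, so the active stretch equals 1 at
#' every converged quasi-static equilibrium while its derivative with
#' respect to total stretch remains 1/lambda.
#'
#' @param sigma_max Maximal active stress (kPa).
#' @param lambda_max Stretch of maximal force generation.
#' @param lambda_0 Stretch of minimal force generation.
#' @param y_con0 Baseline contraction level in \[0, 1\].
#' @param enabled Logical; if `FALSE` the active contribution is 0.
#' @return An object of class `active_params`.
#' @export
active_params <- function(sigma_max = 170, lambda_max = 1.1, lambda_0 = 0.4,
                          y_con0 = 0.5, enabled = TRUE) {
  stopifnot(lambda_max > lambda_0, y_con0 >= 0, y_con0 <= 1, sigma_max >= 0)
  structure(list(sigma_max = sigma_max, lambda_max = lambda_max,
                 lambda_0 = lambda_0, y_con0 = y_con0, enabled = enabled),
            class = "active_params")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Elastin stress and strain energy
#'
#' Evaluates the elastin strain energy (isochoric/volumetric split) and the
#' density-weighted stress for a given elastic deformation gradient of
#' elastin. The Kirchhoff (reference-volume) stress
#' `tau = 2 rho * F_e (dW/dC_e) F_e^T` is returned together with the
#' elastin-level Cauchy stress `tau / det(F_e)`; mixture assembly divides
#' the Kirchhoff form by the determinant of the *total* deformation
#' gradient instead.
#'
#' @param F_e 3x3 elastic deformation gradient of elastin (including
#'   prestretch).
#' @param rho0_e Referential density weight (use the normalized density
#'   `rho0^e(s)/rho0(0)`, i.e. the initial mass fraction at s = 0).
#' @param params An [elastin_params()] object.
#' @return List with `kirchhoff`, `cauchy` (3x3 matrices) and `energy`
#'   (kPa, per unit reference volume, weighted by `rho0_e`).
#' @export
elastin_stress <- function(F_e, rho0_e = 1, params = elastin_params()) {
  J <- det(F_e)
  if (!is.finite(J) || J <= 0) {
    stop("invalid elastic deformation of elastin: det(F_e) must be positive",
         call. = FALSE)
  }
  b <- F_e %*% t(F_e)
  I1bar <- J^(-2 / 3) * sum(diag(b))
  tau_iso <- params$mu_e * J^(-2 / 3) * (b - sum(diag(b)) / 3 * diag(3))
  tau_vol <- params$kappa * (J - 1) * J * diag(3)
  W <- params$mu_e / 2 * (I1bar - 3) + params$kappa / 2 * (J - 1)^2
  tau <- rho0_e * (tau_iso + tau_vol)
  list(kirchhoff = tau, cauchy = tau / J, energy = rho0_e * W)
}

#' Fiber Cauchy stress from the fourth pseudo-invariant
#'
#' Fiber-direction Cauchy stress of a Fung-type fiber family,
#' `sigma = rho * c1 * I4e * (I4e - 1) * exp(c2 (I4e - 1)^2)`, i.e.
#' `2 I4e dW/dI4e` with the per-mass energy weighted by `rho_weight`.
#' Also returns the derivative with respect to `I4e`, needed by the
#' remodeling evolution law.
#'
#' @param I4e Fourth pseudo-invariant of the elastic Cauchy-Green tensor
#'   (square of the elastic fiber stretch), must be positive.
#' @param params A [fiber_params()] object.
#' @param rho_weight Density weighting (default 1: per-unit-reference-mass
#'   convention; the same convention must be used for the homeostatic
#'   target so that the remodeling law is consistent).
#' @return List with `sigma` (kPa) and `dsigma_dI4e` (kPa).
#' @export
fiber_stress <- function(I4e, params, rho_weight = 1) {
  if (any(!is.finite(I4e)) || any(I4e <= 0)) {
    stop("invalid fiber invariant: I4e must be positive", call. = FALSE)
  }
  g <- exp(params$c2 * (I4e - 1)^2)
  sigma <- rho_weight * params$c1 * I4e * (I4e - 1) * g
  dsigma <- rho_weight * params$c1 * g *
    ((2 * I4e - 1) + 2 * params$c2 * I4e * (I4e - 1)^2)
  list(sigma = sigma, dsigma_dI4e = dsigma)
}

# Length-tension factor of the active stress at lambda_act = 1:
# d/dlambda_act [lambda_act + (lambda_max - lambda_act)^3/(lambda_max - lambda_0)^2]
.active_factor <- function(params) {
  1 - 3 * (params$lambda_max - 1)^2 / (params$lambda_max - params$lambda_0)^2
}

#' Active smooth muscle circumferential Cauchy stress
#'
#' Active stress under the fast-muscle-remodeling assumption: the active
#' reference stretch tracks the total fiber stretch so the active stretch
#' `lambda_act` equals 1 at every converged equilibrium while
#' `d lambda_act / d lambda = 1/lambda`. The resulting stress is linear in
#' both the contraction level and the normalized smooth muscle density.
#'
#' @param y_con Contraction level (>= 0), set by signaling.
#' @param rho_ratio `rho0^m(s)/rho0(0)`, the smooth muscle referential
#'   density normalized by the initial *mixture* density.
#' @param params An [active_params()] object.
#' @return Scalar circumferential Cauchy stress (kPa, reference-volume
#'   convention; divide by det(F) for the mixture partial stress).
#' @export
active_stress <- function(y_con, rho_ratio, params = active_params()) {
  stopifnot(y_con >= 0, rho_ratio >= 0)
  if (!isTRUE(params$enabled)) return(0)
  rho_ratio * params$sigma_max * y_con * .active_factor(params)
}

#' Active smooth muscle stretch at equilibrium
#'
#' The active stretch is the total fiber stretch divided by the evolving
#' active reference stretch. Because the reference remodels fast and tracks
#' the current stretch, this ratio is identically 1 in any converged
#' quasi-static equilibrium; it is computed here as the explicit ratio so
#' that the contract is checkable rather than assumed.
#'
#' @param lambda Total stretch in the muscle fiber direction.
#' @param lambda_act_hat Active reference stretch; defaults to `lambda`
#'   (fast remodeling).
#' @return The active stretch `lambda / lambda_act_hat`.
#' @export
active_stretch <- function(lambda, lambda_act_hat = lambda) {
  stopifnot(lambda > 0, lambda_act_hat > 0)
  lambda / lambda_act_hat
}

#' Material point state
#'
#' Bundles the per-point constituent state of the homogenized constrained
#' mixture: elastin (normalized density and diagonal prestretch), fiber
#' families (normalized densities and remodeling stretches) and the active
#' muscle state.
#'
#' @param elastin_nu Normalized referential elastin density
#'   `rho0^e(s)/rho0(0)`.
#' @param Ge Length-3 diagonal (radial, circumferential, axial) of the
#'   elastin elastic prestretch tensor at s = 0.
#' @param elastin An [elastin_params()] object.
#' @param fibers List of [fiber_params()] objects.
#' @param fiber_nu Numeric vector of normalized fiber densities.
#' @param lambda_r Numeric vector of remodeling stretches per family.
#' @param active An [active_params()] object or `NULL`.
#' @param y_con Current contraction level.
#' @param nu_total Normalized total referential density
#'   `rho0(s)/rho0(0)` driving the radial growth tensor.
#' @return An object of class `material_point`.
#' @export
material_point <- function(elastin_nu, Ge, elastin, fibers, fiber_nu,
                           lambda_r, active = NULL, y_con = 0,
                           nu_total = elastin_nu + sum(fiber_nu)) {
  stopifnot(length(Ge) == 3, length(fibers) == length(fiber_nu),
            length(lambda_r) == length(fibers), nu_total > 0)
  structure(list(elastin_nu = elastin_nu, Ge = Ge, elastin = elastin,
                 fibers = fibers, fiber_nu = fiber_nu, lambda_r = lambda_r,
                 active = active, y_con = y_con, nu_total = nu_total),
            class = "material_point")
}

#' Mixture Cauchy stress at a material point
#'
#' Sums the elastin, fiber-family, and (if enabled) active smooth muscle
#' contributions, each evaluated on its own elastic deformation obtained by
#' removing the shared radial growth tensor and the constituent's
#' remodeling (or prestretch) tensor from the total deformation gradient.
#'
#' @param point A [material_point()].
#' @param F Total 3x3 deformation gradient of the mixture (axes ordered
#'   radial, circumferential, axial; growth direction is radial).
#' @return List with `sigma` (3x3 Cauchy stress, kPa), `trace`, and
#'   `fiber_sigma` (per-family fiber-direction Cauchy stresses in the
#'   per-unit-reference-mass convention used by the remodeling law).
#' @export
mixture_stress <- function(point, F) {
  if (!inherits(point, "material_point")) {
    stop("`point` must be a material_point", call. = FALSE)
  }
  J <- det(F)
  if (!is.finite(J) || J <= 0) {
    stop("invalid deformation: det(F) must be positive", call. = FALSE)
  }
  Fg <- growth_tensor(growth_state(point$nu_total, 1))
  Fg_inv <- diag(1 / diag(Fg))
  sig <- matrix(0, 3, 3)

  # elastin: F_e^e = F Fg^-1 Ge, Ge diagonal prestretch
  Fe_e <- F %*% Fg_inv %*% diag(point$Ge)
  el <- elastin_stress(Fe_e, point$elastin_nu, point$elastin)
  sig <- sig + el$kirchhoff / J

  nf <- length(point$fibers)
  fiber_sigma <- numeric(nf)
  names(fiber_sigma) <- vapply(point$fibers, function(p) p$name, "")
  for (i in seq_len(nf)) {
    p <- point$fibers[[i]]
    a0 <- fiber_direction(p$angle_deg)
    Fr <- remodeling_tensor(remodeling_state(point$lambda_r[i], a0))
    Fe <- elastic_part(F, Fg, Fr)
    Fgr <- Fr %*% Fg
    agr <- drop(Fgr %*% a0)
    agr <- agr / sqrt(sum(agr^2))
    v <- drop(Fe %*% agr)
    I4e <- sum(v^2)
    fs <- fiber_stress(I4e, p)
    fiber_sigma[i] <- fs$sigma
    # 2 W' (Fe a)(Fe a)^T = sigma_hat * m m^T with unit m
    sig <- sig + (point$fiber_nu[i] / J) * fs$sigma * tcrossprod(v / sqrt(I4e))
  }

  if (!is.null(point$active) && isTRUE(point$active$enabled)) {
    i_m <- which(vapply(point$fibers, function(p) p$angle_deg, 0) == 0)[1]
    if (is.na(i_m)) stop("active stress requires a circumferential family",
                         call. = FALSE)
    nu_m <- point$fiber_nu[i_m]
    s_act <- active_stress(point$y_con, nu_m, point$active)
    e_t <- c(0, 1, 0)
    sig <- sig + (s_act / J) * tcrossprod(e_t)
  }

  list(sigma = sig, trace = sum(diag(sig)), fiber_sigma = fiber_sigma)
}

#' Unit fiber direction in the reference configuration
#'
#' @param angle_deg Angle from the circumferential axis (degrees), in the
#'   circumferential-axial plane.
#' @return Length-3 unit vector in (radial, circumferential, axial) axes.
#' @export
fiber_direction <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(0, cos(a), sin(a))
}
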