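#' Constituent turnover rates driven by signaling
#'
#' Net referential-density rates of the structural constituents. Smooth
#' muscle cells proliferate and die at a common basal rate so the net rate
#' is proportional to the normalized signaling deviation; collagen is
#' produced by the intramural cells (production scales with the current
#' cell density) and degrades first-order, with the prefactor
#' `rho_c0/rho_m0` ensuring the initial state is homeostatic. Elastin is
#' neither produced nor degraded.
#'
#' @param rho_m,rho_c Current referential densities of smooth muscle and
#'   total collagen (any consistent unit).
#' @param rho_m0,rho_c0 Their initial values.
#' @param T_m,T_c Mean survival times (days).
#' @param dpsi_m,dpsi_c Normalized deviations of the proliferation and
#'   collagen-production network outputs.
#' @return List with `drho_m` and `drho_c` (density per day).
#' @export
constituent_rates <- function(rho_m, rho_c, rho_m0, rho_c0, T_m, T_c,
                              dpsi_m, dpsi_c) {
  stopifnot(all(rho_m > 0), all(rho_c > 0), rho_m0 > 0, rho_c0 > 0)
  drho_m <- rho_m / T_m * dpsi_m
  drho_c <- (rho_c0 / rho_m0) * rho_m * (1 + dpsi_c) / T_c - rho_c / T_c
  list(drho_m = drho_m, drho_c = drho_c)
}

#' Distribute a total collagen rate over fiber families
#'
#' The relative distribution of the collagen fiber families is constant in
#' time: every family shares the same relative rate
#' `rho_dot^cj / rho^cj = rho_dot^c / rho^c`, so family mass fractions of
#' collagen never drift.
#'
#' @param drho_c_total Net rate of total collagen density.
#' @param family_rho Numeric vector (or matrix, families in columns) of
#'   current per-family densities.
#' @return Per-family rates with the same shape as `family_rho`.
#' @export
collagen_family_split <- function(drho_c_total, family_rho) {
  tot <- if (is.matrix(family_rho)) rowSums(family_rho) else sum(family_rho)
  stopifnot(all(tot > 0))
  family_rho * (drho_c_total / tot)
}

#' Phenomenological stress-driven mass production
#'
#' Fallback rate law of the purely mechanical (uncoupled) constrained
#' mixture model: `drho/ds = rho * k * (sigma - sigma_h)/sigma_h`.
#'
#' @param rho Current referential density.
#' @param k_rate Gain (1/days).
#' @param sigma Current fiber Cauchy stress.
#' @param sigma_h Homeostatic fiber stress (non-zero).
#' @return Density rate.
#' @export
phenomenological_rate <- function(rho, k_rate, sigma, sigma_h) {
  stopifnot(all(sigma_h != 0))
  rho * k_rate * (sigma - sigma_h) / sigma_h
}

#' Quasi-steady profile of a diffusible species across the wall
#'
#' Solves the one-dimensional radial steady reaction-diffusion problem
#' `div(D grad c) = c/T` on the referential wall domain with an influx
#' boundary condition at the endothelium, `-D dc/dr = q_in` (with
#' `q_in = eta * Qdot0 * (1 + dpsi)`), and an outflux at the outer wall
#' equal to `xi` times the (instantaneous) influx per unit area. The
#' solver is a conservative finite-volume scheme, so the global balance
#' influx - outflux = total degradation holds to machine precision.
#' Species kinetics (seconds) are orders of magnitude faster than the
#' growth-and-remodeling step (days), hence the quasi-steady treatment.
#'
#' @param D0 Diffusion coefficient (um^2/s), > 0.
#' @param T_surv Mean survival time (s), > 0 and finite.
#' @param q_in Influx per unit inner-surface area (umol um^-2 s^-1).
#' @param xi Outflux fraction at the outer wall in `[0, 1]`.
#' @param r_inner Referential inner radius (um).
#' @param thickness Referential wall thickness (um).
#' @param n Number of finite-volume cells.
#' @param cylindrical If `FALSE`, curvature terms are disabled (planar
#'   slab), used for closed-form verification.
#' @return List with `r` (cell centers), `conc` (umol/um^3), `conc_nM`,
#'   `influx_total`, `outflux_total`, `degradation_total` (per unit axial
#'   length and radian for the cylindrical case).
#' @export
diffusible_steady_solve <- function(D0, T_surv, q_in, xi, r_inner, thickness,
                                    n = 101, cylindrical = TRUE) {
  stopifnot(D0 > 0, r_inner > 0, thickness > 0, n >= 3, xi >= 0, xi <= 1)
  if (!is.finite(T_surv) || T_surv <= 0) {
    stop("configuration error: diffusible species needs finite positive T_surv (no absorption makes the pure-flux problem ill-posed)",
         call. = FALSE)
  }
  h <- thickness / n
  faces <- r_inner + h * (0:n)
  centers <- (faces[-1] + faces[-(n + 1)]) / 2
  w_face <- if (cylindrical) faces else rep(1, n + 1)
  w_cell <- if (cylindrical) centers else rep(1, n)

  # Thomas algorithm on the tridiagonal FV system
  aW <- D0 * w_face[1:n] / h        # coupling to cell i-1 (0 at boundary)
  aE <- D0 * w_face[2:(n + 1)] / h  # coupling to cell i+1 (0 at boundary)
  aW[1] <- 0
  aE[n] <- 0
  aP <- aW + aE + w_cell * h / T_surv
  b <- numeric(n)
  b[1] <- q_in * w_face[1]
  b[n] <- -xi * q_in * w_face[n + 1]

  # forward elimination / back substitution
  cp <- numeric(n)
  dp <- numeric(n)
  cp[1] <- aE[1] / aP[1]
  dp[1] <- b[1] / aP[1]
  for (i in 2:n) {
    m <- aP[i] - aW[i] * cp[i - 1]
    cp[i] <- aE[i] / m
    dp[i] <- (b[i] + aW[i] * dp[i - 1]) / m
  }
  conc <- numeric(n)
  conc[n] <- dp[n]
  for (i in (n - 1):1) conc[i] <- dp[i] + cp[i] * conc[i + 1]

  list(r = centers, conc = conc, conc_nM = conc * 1e18,
       influx_total = q_in * w_face[1],
       outflux_total = xi * q_in * w_face[n + 1],
       degradation_total = sum(conc * w_cell * h) / T_surv)
}

#' Forward-Euler update of structural density fields
#'
#' Structural constituents do not diffuse, so the update is pointwise.
#' Densities that would become negative are floored at zero with a
#' warning.
#'
#' @param fields Numeric vector or matrix of referential densities.
#' @param rates Rates with the same shape (density per day).
#' @param ds Step size (days), > 0.
#' @return Updated fields.
#' @export
density_step <- function(fields, rates, ds) {
  stopifnot(ds > 0)
  out <- fields + ds * rates
  if (any(out < 0)) {
    warning("density_step: density floored at 0 (production/degradation imbalance)",
            call. = FALSE)
    out[out < 0] <- 0
  }
  out
}
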