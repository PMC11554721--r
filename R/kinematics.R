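#' Growth state
#'
#' @param nu_ratio Current over initial total referential density,
#'   `rho0(s)/rho0(0)`.
#' @param a_g Unit growth direction in the reference configuration; either
#'   a length-3 vector or the default radial direction.
#' @return Object of class `growth_state`.
#' @export
growth_state <- function(nu_ratio, a_g = c(1, 0, 0)) {
  if (length(a_g) == 1) a_g <- c(1, 0, 0)
  stopifnot(nu_ratio > 0, abs(sum(a_g^2) - 1) < 1e-12)
  structure(list(nu_ratio = nu_ratio, a_g = a_g), class = "growth_state")
}

#' Transversely isotropic growth tensor
#'
#' `F_g = (rho0(s)/rho0(0)) a_g (x) a_g + (I - a_g (x) a_g)`: all added or
#' removed mass changes the geometry along the single growth direction, so
#' `det(F_g)` equals the total-density ratio.
#'
#' @param g A [growth_state()].
#' @return 3x3 symmetric growth tensor.
#' @export
growth_tensor <- function(g) {
  P <- tcrossprod(g$a_g)
  g$nu_ratio * P + (diag(3) - P)
}

#' Remodeling state of a fiber family
#'
#' @param lambda_r Inelastic remodeling stretch (> 0).
#' @param a_0 Unit fiber direction in the reference configuration.
#' @return Object of class `remodeling_state`.
#' @export
remodeling_state <- function(lambda_r, a_0) {
  if (!is.finite(lambda_r) || lambda_r <= 0) {
    stop("invalid remodeling state: lambda_r must be positive", call. = FALSE)
  }
  stopifnot(abs(sum(a_0^2) - 1) < 1e-12)
  structure(list(lambda_r = lambda_r, a_0 = a_0), class = "remodeling_state")
}

#' Incompressible remodeling tensor
#'
#' `F_r = lambda_r a0 (x) a0 + lambda_r^(-1/2) (I - a0 (x) a0)`;
#' its determinant is exactly 1 (remodeling redistributes mass without
#' changing volume).
#'
#' @param r A [remodeling_state()].
#' @return 3x3 remodeling tensor with unit determinant.
#' @export
remodeling_tensor <- function(r) {
  P <- tcrossprod(r$a_0)
  r$lambda_r * P + (1 / sqrt(r$lambda_r)) * (diag(3) - P)
}

#' Elastic part of the deformation gradient
#'
#' `F_e = F F_g^-1 F_r^-1` with the composition order `F_gr = F_r F_g`.
#'
#' @param F Total deformation gradient.
#' @param F_g Growth tensor.
#' @param F_r Remodeling tensor of the constituent.
#' @return 3x3 elastic deformation gradient.
#' @export
elastic_part <- function(F, F_g, F_r) {
  dets <- c(det(F), det(F_g), det(F_r))
  if (any(!is.finite(dets)) || any(dets <= 0)) {
    stop("elastic_part: all deformation gradients must have positive determinant",
         call. = FALSE)
  }
  F %*% solve(F_g) %*% solve(F_r)
}

#' Remodeling-stretch evolution rate
#'
#' Scalar reduction of the remodeling evolution law:
#' `dlambda_r/ds = (rho_dot/rho + 1/T) * lambda_r / (2 I4e) *
#' (dsigma/dI4e)^-1 * (sigma - sigma_h)`. Mass turnover shifts the
#' constituent's stress-free configuration toward the state where its
#' fiber Cauchy stress equals the homeostatic target.
#'
#' @param sigma Current fiber Cauchy stress (kPa).
#' @param sigma_h Homeostatic fiber stress (kPa), same convention.
#' @param rho_dot_over_rho Relative net mass production rate (1/days).
#' @param T_days Mean survival time (days).
#' @param lambda_r Current remodeling stretch.
#' @param I4e Current elastic fourth invariant.
#' @param dsigma_dI4e Stress derivative from [fiber_stress()].
#' @return Rate `dlambda_r/ds` (1/days).
#' @export
remodeling_rate <- function(sigma, sigma_h, rho_dot_over_rho, T_days,
                            lambda_r, I4e, dsigma_dI4e) {
  stopifnot(I4e > 0, T_days > 0, lambda_r > 0)
  if (any(dsigma_dI4e == 0 & sigma != sigma_h)) {
    stop("singular remodeling: dsigma/dI4e = 0 with sigma != sigma_h",
         call. = FALSE)
  }
  (rho_dot_over_rho + 1 / T_days) * lambda_r / (2 * I4e) *
    (sigma - sigma_h) / dsigma_dI4e
}

#' Homeostatic initialization of a fiber family
#'
#' Sets the initial remodeling stretch to `1/lambda_h` so that, with the
#' mixture at identity deformation, the elastic part of the fiber
#' deformation carries exactly the deposition stretch `lambda_h` along the
#' fiber and `1/sqrt(lambda_h)` transversely (unit determinant).
#'
#' @param params A [fiber_params()] object.
#' @return List with the initial `remodeling_state` and `F_e0` (3x3).
#' @export
init_homeostatic <- function(params) {
  stopifnot(params$lambda_h > 0)
  a0 <- fiber_direction(params$angle_deg)
  rs <- remodeling_state(1 / params$lambda_h, a0)
  P <- tcrossprod(a0)
  F_e0 <- params$lambda_h * P + (1 / sqrt(params$lambda_h)) * (diag(3) - P)
  list(remodeling = rs, F_e0 = F_e0)
}
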