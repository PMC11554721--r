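#' Vessel geometry
#'
#' Reference (initial, in vivo) geometry of the axisymmetric vessel
#' segment and the radial discretization: `n_radial` nodes spanning the
#' wall, with material points (quadrature cells) at the midpoints between
#' consecutive nodes.
#'
#' @param A Initial inner radius (mm).
#' @param H Initial wall thickness (mm).
#' @param L Segment length (mm); carried for bookkeeping only (axial
#'   stretch is fixed at 1).
#' @param n_radial Number of radial nodes (>= 3); default 5 (4 cells).
#' @return Object of class `vessel_geometry`.
#' @export
vessel_geometry <- function(A = 0.647, H = 0.04, L = 0.04, n_radial = 5) {
  stopifnot(A > 0, H > 0, L > 0, n_radial >= 3)
  R_nodes <- seq(A, A + H, length.out = n_radial)
  structure(list(A = A, H = H, L = L, n_radial = n_radial,
                 R_nodes = R_nodes,
                 R_cells = (R_nodes[-1] + R_nodes[-n_radial]) / 2,
                 dR = H / (n_radial - 1)),
            class = "vessel_geometry")
}

#' Load state
#'
#' @param gamma Pressure ratio p/p0.
#' @param epsilon Flow-rate ratio Q/Q0.
#' @param p0 Baseline luminal pressure (kPa).
#' @return Object of class `load_state`.
#' @export
load_state <- function(gamma = 1, epsilon = 1, p0 = 14) {
  stopifnot(gamma > 0, epsilon > 0, p0 >= 0)
  structure(list(gamma = gamma, epsilon = epsilon, p0 = p0),
            class = "load_state")
}

#' Wall-shear-stress ratio
#'
#' Normalized mean wall shear stress for fully developed laminar flow of a
#' Newtonian fluid, `tau_w = 4 mu Q / (pi a^3)`: viscosity and the
#' absolute flow rate cancel in the ratio, leaving
#' `epsilon / (r_inner/A)^3`.
#'
#' @param epsilon Flow-rate ratio Q/Q0.
#' @param r_inner Current inner radius.
#' @param A Initial inner radius.
#' @return `tau_w / tau_w0`.
#' @export
wss_ratio <- function(epsilon, r_inner, A) {
  stopifnot(r_inner > 0, A > 0)
  epsilon / (r_inner / A)^3
}

#' Assemble a vessel wall
#'
#' Bundles geometry and the per-cell constituent states into the object
#' consumed by the equilibrium and prestress solvers. Families are
#' ordered smooth muscle first, then the collagen families.
#'
#' @param geometry A [vessel_geometry()].
#' @param elastin An [elastin_params()].
#' @param fibers List of [fiber_params()] (smooth muscle first).
#' @param active An [active_params()] or `NULL`.
#' @param phi_e Initial elastin mass fraction.
#' @return Object of class `gr_wall`: per-cell normalized densities
#'   (`dens`, elastin in column 1), remodeling stretches (`lam_r`),
#'   elastin prestretch diagonals (`Ge`), contraction levels (`y_con`)
#'   and, after prestressing, homeostatic fiber stresses (`sigma_h`).
#' @export
vessel_wall <- function(geometry, elastin, fibers, active = NULL,
                        phi_e = 0.34) {
  nc <- geometry$n_radial - 1
  nf <- length(fibers)
  phis <- vapply(fibers, function(p) p$phi0, 0)
  dens <- cbind(rep(phi_e, nc),
                matrix(rep(phis, each = nc), nc, nf))
  colnames(dens) <- c("e", vapply(fibers, function(p) p$name, ""))
  lam_r <- matrix(rep(1 / vapply(fibers, function(p) p$lambda_h, 0),
                      each = nc), nc, nf)
  colnames(lam_r) <- colnames(dens)[-1]
  Ge <- matrix(rep(c(1 / sqrt(elastin$lambda_z_e), 1 / sqrt(elastin$lambda_z_e),
                     elastin$lambda_z_e), each = nc), nc, 3)
  y0 <- if (!is.null(active) && isTRUE(active$enabled)) active$y_con0 else 0
  structure(list(geometry = geometry, elastin = elastin, fibers = fibers,
                 active = active, dens = dens, lam_r = lam_r, Ge = Ge,
                 y_con = rep(y0, nc), sigma_h = NULL,
                 nu0 = rowSums(dens)),
            class = "gr_wall")
}

# Per-cell kinematics and stresses for a trial nodal radius vector.
# Everything is diagonal in (r, theta, z): F = diag(dr/dR, r/R, 1),
# growth radial, fibers in the theta-z plane. Returns vectors over cells.
cell_state <- function(wall, r_nodes) {
  g <- wall$geometry
  nc <- g$n_radial - 1
  lam_rad <- diff(r_nodes) / g$dR
  r_c <- (r_nodes[-1] + r_nodes[-(nc + 1)]) / 2
  lam_t <- r_c / g$R_cells
  J <- lam_rad * lam_t
  # growth ratio rho0(s)/rho0(0): radial eigenvalue of the growth tensor
  g_ratio <- rowSums(wall$dens) / wall$nu0

  # elastin, F_e^e = F Fg^-1 Ge (all diagonal)
  er <- lam_rad / g_ratio * wall$Ge[, 1]
  et <- lam_t * wall$Ge[, 2]
  ez <- wall$Ge[, 3]
  Je <- er * et * ez
  I1 <- er^2 + et^2 + ez^2
  mu <- wall$elastin$mu_e
  kap <- wall$elastin$kappa
  vol <- kap * (Je - 1) * Je
  nu_e <- wall$dens[, 1]
  tau_r <- nu_e * (mu * Je^(-2 / 3) * (er^2 - I1 / 3) + vol)
  tau_t <- nu_e * (mu * Je^(-2 / 3) * (et^2 - I1 / 3) + vol)
  tau_z <- nu_e * (mu * Je^(-2 / 3) * (ez^2 - I1 / 3) + vol)
  srr <- tau_r / J
  stt <- tau_t / J
  szz <- tau_z / J

  nf <- length(wall$fibers)
  fiber_sig <- matrix(0, nc, nf)
  fiber_dsig <- matrix(0, nc, nf)
  fiber_I4e <- matrix(0, nc, nf)
  for (f in seq_len(nf)) {
    p <- wall$fibers[[f]]
    ca <- cos(p$angle_deg * pi / 180)
    sa <- sin(p$angle_deg * pi / 180)
    lam_fib2 <- lam_t^2 * ca^2 + sa^2
    I4e <- lam_fib2 / wall$lam_r[, f]^2
    fs <- fiber_stress(I4e, p)
    fiber_sig[, f] <- fs$sigma
    fiber_dsig[, f] <- fs$dsigma_dI4e
    fiber_I4e[, f] <- I4e
    mt2 <- lam_t^2 * ca^2 / lam_fib2
    mz2 <- sa^2 / lam_fib2
    stt <- stt + wall$dens[, f + 1] / J * fs$sigma * mt2
    szz <- szz + wall$dens[, f + 1] / J * fs$sigma * mz2
  }
  colnames(fiber_sig) <- colnames(wall$lam_r)
  colnames(fiber_dsig) <- colnames(wall$lam_r)
  colnames(fiber_I4e) <- colnames(wall$lam_r)

  if (!is.null(wall$active) && isTRUE(wall$active$enabled)) {
    act <- wall$active$sigma_max * wall$y_con * .active_factor(wall$active) *
      wall$dens[, 2]  # smooth muscle is family 1 (column 2 of dens)
    stt <- stt + act / J
  }

  list(r_c = r_c, lam_rad = lam_rad, lam_t = lam_t, J = J,
       srr = srr, stt = stt, szz = szz,
       fiber_sigma = fiber_sig, fiber_dsigma = fiber_dsig,
       fiber_I4e = fiber_I4e)
}

# Finite-volume equilibrium residual: control volumes around nodes, cell
# stresses at midpoints, traction BCs at the two surfaces. The residual
# sum telescopes so that p * r_inner equals the midpoint-rule integral of
# the hoop stress at convergence.
wall_residual <- function(wall, r_nodes, pressure, cs = NULL) {
  n <- wall$geometry$n_radial
  if (is.null(cs)) cs <- cell_state(wall, r_nodes)
  r_c <- cs$r_c
  res <- numeric(n)
  res[1] <- r_c[1] * cs$srr[1] + r_nodes[1] * pressure -
    cs$stt[1] * (r_c[1] - r_nodes[1])
  if (n > 2) {
    i <- 2:(n - 1)
    res[i] <- r_c[i] * cs$srr[i] - r_c[i - 1] * cs$srr[i - 1] -
      (cs$stt[i - 1] * (r_nodes[i] - r_c[i - 1]) +
         cs$stt[i] * (r_c[i] - r_nodes[i]))
  }
  res[n] <- -r_c[n - 1] * cs$srr[n - 1] -
    cs$stt[n - 1] * (r_nodes[n] - r_c[n - 1])
  res
}

#' Solve radial equilibrium of the vessel wall
#'
#' Newton solution of the axisymmetric thick-walled-cylinder equilibrium
#' `d sigma_rr / dr + (sigma_rr - sigma_tt)/r = 0` with traction boundary
#' conditions `sigma_rr = -gamma p0` at the inner and `0` at the outer
#' surface, discretized conservatively over the radial nodes (axial
#' stretch fixed at 1). The unknowns are the current radial positions of
#' the nodes.
#'
#' @param wall A [vessel_wall()] (typically after [prestress_vessel()]).
#' @param load A [load_state()].
#' @param r_init Optional initial guess for the nodal radii (defaults to
#'   the reference positions).
#' @param tol Relative residual tolerance (scaled by `max(1, p0 * A)`).
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `gr_vessel_state`: nodal radii, inner radius,
#'   thickness, per-cell kinematics and stresses, fiber stresses and
#'   invariants, wall-shear-stress ratio, residual norm and iteration
#'   count.
#' @export
equilibrium_solve <- function(wall, load = load_state(), r_init = NULL,
                              tol = 5e-11, max_iter = 60) {
  g <- wall$geometry
  n <- g$n_radial
  r <- r_init %||% g$R_nodes
  p <- load$gamma * load$p0
  scale <- max(1, load$p0 * g$A)
  res <- wall_residual(wall, r, p)
  rnorm <- max(abs(res)) / scale
  hist <- rnorm
  it <- 0
  while (rnorm > tol && it < max_iter) {
    it <- it + 1
    Jm <- matrix(0, n, n)
    for (j in seq_len(n)) {
      eps <- 1e-7 * max(abs(r[j]), g$H)
      rp <- r
      rp[j] <- rp[j] + eps
      Jm[, j] <- (wall_residual(wall, rp, p) - res) / eps
    }
    step <- tryCatch(solve(Jm, -res), error = function(e) {
      stop("equilibrium solver failure: singular tangent (residual ",
           signif(rnorm, 3), ")", call. = FALSE)
    })
    alpha <- 1
    repeat {
      r_new <- r + alpha * step
      if (all(diff(r_new) > 0) && r_new[1] > 0) {
        res_new <- wall_residual(wall, r_new, p)
        if (max(abs(res_new)) / scale < rnorm || alpha < 1e-4) break
      }
      alpha <- alpha / 2
      if (alpha < 1e-6) {
        stop("equilibrium solver failure: line search stalled (residual history: ",
             paste(signif(hist, 3), collapse = ", "), ")", call. = FALSE)
      }
    }
    r <- r_new
    res <- res_new
    rnorm <- max(abs(res)) / scale
    hist <- c(hist, rnorm)
  }
  if (rnorm > tol) {
    stop("equilibrium solver failure: no convergence after ", max_iter,
         " iterations (residual history: ",
         paste(signif(hist, 3), collapse = ", "), ")", call. = FALSE)
  }
  cs <- cell_state(wall, r)
  structure(list(
    r_nodes = r, r_inner = r[1], r_outer = r[n], h = r[n] - r[1],
    cells = cs, load = load,
    wss_ratio = wss_ratio(load$epsilon, r[1], g$A),
    trace = cs$srr + cs$stt + cs$szz,
    residual_norm = rnorm, iterations = it), class = "gr_vessel_state")
}

#' Midpoint-rule wall tension
#'
#' Integral of the circumferential stress across the wall with the same
#' quadrature the equilibrium residual uses; at convergence it equals
#' `p * r_inner` (global force balance of the half cylinder).
#'
#' @param state A `gr_vessel_state`.
#' @return Scalar wall tension (kPa mm).
#' @export
wall_tension <- function(state) {
  sum(state$cells$stt * diff(state$r_nodes))
}

#' Iterative elastin prestressing
#'
#' Determines the elastin elastic prestretch field such that the loaded
#' reference configuration is itself the equilibrium (and homeostatic)
#' state. The prestretch is the incompressible uniaxial guess
#' `diag(1/sqrt(lz), 1/sqrt(lz), lz)` composed with an accumulated
#' correction; because every equilibrium correction is the gradient of a
#' radial map, the accumulated correction is parametrized by the nodal
#' values of a single radial deposition map and solved for directly by
#' Newton iteration on the condition that the mixture equilibrium
#' residual vanishes at identity deformation. External pressure and the
#' deposition stretches of all constituents are applied gradually over
#' `n_ramp` load increments.
#'
#' @param wall A freshly assembled [vessel_wall()].
#' @param load A [load_state()] (the baseline load; `gamma` is taken as
#'   the ramp target 1).
#' @param n_ramp Number of ramp increments.
#' @param tol Convergence tolerance on the mean nodal displacement
#'   normalized by the reference wall thickness (checked by re-solving
#'   the equilibrium from the converged prestretch).
#' @param max_iter Maximum Newton iterations per increment.
#' @return List with the prestressed `wall` (including the homeostatic
#'   fiber stresses `sigma_h`), the verification `state`, total
#'   `iterations` and the final normalized mean displacement `disp`.
#' @export
prestress_vessel <- function(wall, load = load_state(), n_ramp = 5,
                             tol = 1e-6, max_iter = 60) {
  g <- wall$geometry
  nc <- g$n_radial - 1
  n <- g$n_radial
  lz_full <- wall$elastin$lambda_z_e
  lh_full <- vapply(wall$fibers, function(p) p$lambda_h, 0)
  fam_names <- colnames(wall$lam_r)

  apply_prestress <- function(wall, rho, t) {
    lz <- 1 + t * (lz_full - 1)
    lh <- 1 + t * (lh_full - 1)
    P_rad <- diff(rho) / g$dR
    P_circ <- (rho[-1] + rho[-n]) / 2 / g$R_cells
    wall$Ge <- cbind(P_rad / sqrt(lz), P_circ / sqrt(lz), rep(lz, nc))
    wall$lam_r <- matrix(rep(1 / lh, each = nc), nc, length(lh),
                         dimnames = list(NULL, fam_names))
    wall
  }
  resfun <- function(rho, t) {
    wall_residual(apply_prestress(wall, rho, t), g$R_nodes,
                  t * load$p0)
  }

  scale <- max(1, load$p0 * g$A)
  newton <- function(rho, t) {
    res <- resfun(rho, t)
    for (it in seq_len(max_iter)) {
      if (max(abs(res)) / scale < 1e-10) {
        return(list(rho = rho, ok = TRUE, it = it - 1))
      }
      # central differences at a fixed strain perturbation: the thin-wall
      # tangent is ill-conditioned, so Jacobian noise must stay small
      Jm <- matrix(0, n, n)
      eps <- 1e-4 * g$dR
      for (j in seq_len(n)) {
        rp <- rho
        rp[j] <- rp[j] + eps
        rm <- rho
        rm[j] <- rm[j] - eps
        Jm[, j] <- (resfun(rp, t) - resfun(rm, t)) / (2 * eps)
      }
      step <- tryCatch(solve(Jm, -res), error = function(e) NULL)
      if (is.null(step)) return(list(rho = rho, ok = FALSE, it = it))
      mx <- max(abs(step))
      if (mx > 0.1 * g$A) step <- step * (0.1 * g$A / mx)
      alpha <- 1
      ok <- FALSE
      while (alpha > 1e-5) {
        rho_new <- rho + alpha * step
        if (all(diff(rho_new) > 0) && rho_new[1] > 0) {
          res_new <- resfun(rho_new, t)
          if (max(abs(res_new)) < 0.995 * max(abs(res))) {
            ok <- TRUE
            break
          }
        }
        alpha <- alpha / 2
      }
      if (!ok) return(list(rho = rho, ok = FALSE, it = it))
      rho <- rho_new
      res <- res_new
    }
    list(rho = rho, ok = max(abs(res)) / scale < 1e-10, it = max_iter)
  }

  # continuation in the load/deposition-stretch factor t, with adaptive
  # refinement when a Newton solve at the trial increment fails
  rho <- g$R_nodes
  t_cur <- 0
  dt <- 1 / n_ramp
  total_it <- 0
  while (t_cur < 1) {
    t_try <- min(t_cur + dt, 1)
    out <- newton(rho, t_try)
    total_it <- total_it + out$it
    if (out$ok) {
      rho <- out$rho
      t_cur <- t_try
      dt <- dt * 1.5
    } else {
      dt <- dt / 2
      if (dt < 1e-4) {
        stop(sprintf(
          "prestress failure: continuation stalled at load factor %.4f",
          t_cur), call. = FALSE)
      }
    }
  }
  wall <- apply_prestress(wall, rho, 1)
  state <- equilibrium_solve(wall, load_state(1, load$epsilon, load$p0),
                             r_init = g$R_nodes)
  disp <- mean(abs(state$r_nodes - g$R_nodes)) / g$H
  if (disp >= tol) {
    stop(sprintf(
      "prestress failure: normalized mean displacement %.3e exceeds %g",
      disp, tol), call. = FALSE)
  }
  wall$sigma_h <- vapply(seq_along(wall$fibers), function(f) {
    fiber_stress(lh_full[f]^2, wall$fibers[[f]])$sigma
  }, 0)
  names(wall$sigma_h) <- fam_names
  list(wall = wall, state = state, iterations = total_it, disp = disp)
}
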