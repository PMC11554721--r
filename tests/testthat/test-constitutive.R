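test_that("elastin stress vanishes at identity and for pure volume preservation", {
  el <- elastin_params(mu_e = 89.71, lambda_z_e = 1.62)
  res <- elastin_stress(diag(3), rho0_e = 0.34, params = el)
  expect_equal(res$cauchy, matrix(0, 3, 3))
  expect_equal(res$energy, 0)
  # any isochoric deformation has zero volumetric contribution
  F_iso <- diag(c(1.1, 1 / sqrt(1.1), 1 / sqrt(1.1)))
  res_iso <- elastin_stress(F_iso, 1, el)
  expect_equal(det(F_iso), 1, tolerance = 1e-12)
  # energy then equals the isochoric term alone
  I1bar <- sum(diag(F_iso %*% t(F_iso)))
  expect_equal(res_iso$energy, el$mu_e / 2 * (I1bar - 3), tolerance = 1e-12)
  expect_error(elastin_stress(diag(c(-1, 1, 1))), "det")
})

test_that("elastin stress matches finite differences of the energy", {
  set.seed(42)
  el <- elastin_params()
  for (rep in 1:5) {
    F_e <- random_spd_F()
    res <- elastin_stress(F_e, rho0_e = 0.34, params = el)
    # first Piola-Kirchhoff by central differences of the energy
    P <- matrix(0, 3, 3)
    h <- 1e-6
    for (i in 1:3) for (j in 1:3) {
      Fp <- F_e; Fp[i, j] <- Fp[i, j] + h
      Fm <- F_e; Fm[i, j] <- Fm[i, j] - h
      P[i, j] <- (elastin_stress(Fp, 0.34, el)$energy -
                    elastin_stress(Fm, 0.34, el)$energy) / (2 * h)
    }
    tau_fd <- P %*% t(F_e)
    expect_equal(res$kirchhoff, tau_fd, tolerance = 1e-6)
  }
})

test_that("fiber stress is zero at unit invariant with a finite derivative", {
  p <- table1_collagen()
  fs <- fiber_stress(1, p)
  expect_equal(fs$sigma, 0)
  expect_equal(fs$dsigma_dI4e, p$c1)
  expect_error(fiber_stress(-0.5, p), "positive")
})

test_that("fiber stress derivative matches finite differences and is monotone", {
  p <- table1_collagen()
  for (I4e in c(1.1, 1.5625, 2.5, 4)) {
    h <- 1e-6 * I4e
    fd <- (fiber_stress(I4e + h, p)$sigma - fiber_stress(I4e - h, p)$sigma) /
      (2 * h)
    expect_equal(fiber_stress(I4e, p)$dsigma_dI4e, fd, tolerance = 1e-6)
  }
  grid <- seq(1 + 1e-6, 4, length.out = 200)
  sig <- fiber_stress(grid, p)$sigma
  expect_true(all(diff(sig) > 0))
  sig_m <- fiber_stress(grid, table1_smc())$sigma
  expect_true(all(diff(sig_m) > 0))
})

test_that("Table-1 collagen stress at the deposition stretch matches the analytic energy derivative", {
  # independent route: differentiate W = c1/(4 c2) (exp(c2 (I4-1)^2) - 1)
  # symbolically and evaluate 2 I4 dW/dI4 at I4 = lambda_h^2
  c1 <- 234.9; c2 <- 4.08; I4 <- 1.25^2
  dW <- c1 / (4 * c2) * exp(c2 * (I4 - 1)^2) * c2 * 2 * (I4 - 1)
  expect_equal(fiber_stress(I4, table1_collagen())$sigma, 2 * I4 * dW,
               tolerance = 1e-12)
})

test_that("active stress is linear in contraction level and density, zero when disabled", {
  ap <- active_params(sigma_max = 170, lambda_max = 1.1, lambda_0 = 0.4,
                      y_con0 = 0.5)
  expect_equal(active_stress(0, 1, ap), 0)
  s1 <- active_stress(0.3, 1, ap)
  expect_equal(active_stress(0.6, 1, ap), 2 * s1)
  expect_equal(active_stress(0.3, 0.5, ap), s1 / 2)
  off <- active_params(enabled = FALSE)
  expect_identical(active_stress(1, 1, off), 0)
  # basal tone at y_con0 reproduces the configured value
  expect_equal(active_stress(ap$y_con0, 1, ap),
               0.5 * 170 * (1 - 3 * 0.1^2 / 0.7^2))
})

test_that("the active stretch ratio is exactly one under fast muscle remodeling", {
  for (lam in c(0.9, 1, 1.1, 1.5)) {
    expect_identical(active_stretch(lam), 1)
  }
  expect_equal(active_stretch(1.2, 1.1), 1.2 / 1.1)
})

test_that("mixture stress sums constituents and vanishes for zero densities", {
  el <- elastin_params()
  fibs <- list(table1_smc(), table1_collagen())
  pt0 <- material_point(elastin_nu = 0, Ge = c(1, 1, 1), elastin = el,
                        fibers = fibs, fiber_nu = c(0, 0),
                        lambda_r = c(1 / 1.2, 1 / 1.25), nu_total = 1)
  res0 <- mixture_stress(pt0, diag(c(1.05, 1.02, 1)))
  expect_equal(res0$sigma, matrix(0, 3, 3))
  pt <- material_point(elastin_nu = 0.34, Ge = c(0.9, 1.05, 1.62),
                       elastin = el, fibers = fibs,
                       fiber_nu = c(0.33, 0.29),
                       lambda_r = c(1 / 1.2, 1 / 1.25), nu_total = 1.02)
  res <- mixture_stress(pt, diag(c(1.03, 1.01, 1)))
  expect_equal(res$trace, sum(diag(res$sigma)), tolerance = 1e-12)
  expect_true(all(res$fiber_sigma > 0))
})

test_that("general mixture stress agrees with the vectorized solver path", {
  set.seed(7)
  wall <- table1_wall()
  pre <- prestressed_table1()
  wall <- pre$wall
  # monotone perturbed nodal radii (inner shift + positive spacings)
  g0 <- wall$geometry
  r_nodes <- g0$A * (1 + stats::runif(1, 0, 0.03)) +
    c(0, cumsum(diff(g0$R_nodes) * stats::runif(4, 0.9, 1.1)))
  cs <- vesselgr:::cell_state(wall, r_nodes)
  g <- wall$geometry
  for (i in c(1, 3)) {
    lam_rad <- diff(r_nodes)[i] / g$dR
    lam_t <- (r_nodes[i] + r_nodes[i + 1]) / 2 / g$R_cells[i]
    F <- diag(c(lam_rad, lam_t, 1))
    pt <- material_point(
      elastin_nu = wall$dens[i, 1], Ge = wall$Ge[i, ], elastin = wall$elastin,
      fibers = wall$fibers, fiber_nu = wall$dens[i, -1],
      lambda_r = wall$lam_r[i, ],
      nu_total = sum(wall$dens[i, ]) / wall$nu0[i])
    res <- mixture_stress(pt, F)
    expect_equal(diag(res$sigma), c(cs$srr[i], cs$stt[i], cs$szz[i]),
                 tolerance = 1e-10)
    expect_equal(unname(res$fiber_sigma), unname(cs$fiber_sigma[i, ]),
                 tolerance = 1e-10)
  }
})
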