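test_that("constituent rates preserve the homeostatic state and track cell density", {
  r0 <- constituent_rates(rho_m = 0.33, rho_c = 0.29, rho_m0 = 0.33,
                          rho_c0 = 0.29, T_m = 70, T_c = 70,
                          dpsi_m = 0, dpsi_c = 0)
  expect_equal(r0$drho_m, 0)
  expect_equal(r0$drho_c, 0)
  # more cells at unchanged signaling means net collagen production
  r1 <- constituent_rates(0.33 * 1.1, 0.29, 0.33, 0.29, 70, 70, 0, 0)
  expect_gt(r1$drho_c, 0)
  # smooth muscle net rate is proportional to the signaling deviation
  r2 <- constituent_rates(0.33, 0.29, 0.33, 0.29, 70, 70, 0.2, 0)
  expect_equal(r2$drho_m, 0.33 / 70 * 0.2)
})

test_that("collagen family fractions never drift under the proportional split", {
  set.seed(31)
  fam <- c(c0 = 0.01848, c90 = 0.02211, cp = 0.1447, cm = 0.1447)
  frac0 <- fam / sum(fam)
  for (step in 1:10) {
    dpsi <- stats::rnorm(1, sd = 0.3)
    total_rate <- sum(fam) / 70 * dpsi
    rates <- collagen_family_split(total_rate, fam)
    expect_equal(sum(rates), total_rate, tolerance = 1e-14)
    fam <- fam + 7 * rates
  }
  expect_lt(max(abs(fam / sum(fam) - frac0)), 1e-12)
  expect_equal(collagen_family_split(0, fam), fam * 0)
})

test_that("phenomenological rate is linear in the stress deviation and zero at target", {
  expect_equal(phenomenological_rate(0.3, 0.05, 200, 200), 0)
  r1 <- phenomenological_rate(0.3, 0.05, 220, 200)
  expect_equal(phenomenological_rate(0.3, 0.05, 240, 200), 2 * r1,
               tolerance = 1e-14)
  expect_equal(r1, 0.3 * 0.05 * 0.1)
})

test_that("quasi-steady slab solution matches the cosh/sinh closed form", {
  D <- 3300; Ts <- 15; q <- 1.06e-14; xi <- 0.3; L <- 40
  sol <- diffusible_steady_solve(D, Ts, q, xi, r_inner = 647, thickness = L,
                                 n = 801, cylindrical = FALSE)
  l <- sqrt(D * Ts)
  # c = a cosh(x/l) + b sinh(x/l); -D c'(0) = q, -D c'(L) = xi q
  b <- -q * l / D
  a <- (-xi * q * l / D - b * cosh(L / l)) / sinh(L / l)
  x <- sol$r - 647
  cf <- a * cosh(x / l) + b * sinh(x / l)
  expect_equal(sol$conc, cf, tolerance = 1e-6)
})

test_that("cylindrical solver matches the Bessel closed form and conserves mass", {
  D <- 3300; Ts <- 15; q <- 0.2 * 5.3e-14; xi <- 0.9
  sol <- diffusible_steady_solve(D, Ts, q, xi, 647, 40, n = 201)
  l <- sqrt(D * Ts)
  rin <- 647; rout <- 687
  A <- matrix(c(-D * besselI(rin / l, 1) / l, D * besselK(rin / l, 1) / l,
                -D * besselI(rout / l, 1) / l, D * besselK(rout / l, 1) / l),
              2, 2, byrow = TRUE)
  ab <- solve(A, c(q, xi * q))
  cf <- ab[1] * besselI(sol$r / l, 0) + ab[2] * besselK(sol$r / l, 0)
  expect_equal(sol$conc, cf, tolerance = 1e-6)
  bal <- sol$influx_total - sol$outflux_total - sol$degradation_total
  expect_lt(abs(bal) / sol$influx_total, 1e-8)
  expect_true(all(sol$conc > 0))
})

test_that("NO and ET1 profiles are physiological and nearly linear at Table-2 parameters", {
  p <- default_params()$biochem
  for (sp in list(c(p$D_NO, p$T_NO, p$Q0_NO), c(p$D_ET1, p$T_ET1, p$Q0_ET1))) {
    sol <- diffusible_steady_solve(sp[1], sp[2], p$eta * sp[3], p$xi,
                                   647, 40, n = 101)
    expect_gt(mean(sol$conc_nM), 30)
    expect_lt(mean(sol$conc_nM), 1000)
    # near-linear: deviation from the end-to-end secant below 5% of the mean
    nn <- length(sol$conc)
    line <- sol$conc[1] + (sol$conc[nn] - sol$conc[1]) *
      (sol$r - sol$r[1]) / (sol$r[nn] - sol$r[1])
    expect_lt(max(abs(sol$conc - line)) / mean(sol$conc), 0.05)
  }
  # doubling the resolution barely changes the profile
  a <- diffusible_steady_solve(p$D_NO, p$T_NO, p$eta * p$Q0_NO, p$xi,
                               647, 40, n = 101)
  b <- diffusible_steady_solve(p$D_NO, p$T_NO, p$eta * p$Q0_NO, p$xi,
                               647, 40, n = 202)
  at_mid <- stats::approx(a$r, a$conc, xout = 667)$y
  bt_mid <- stats::approx(b$r, b$conc, xout = 667)$y
  expect_lt(abs(at_mid - bt_mid) / at_mid, 1e-3)
})

test_that("degradation-free pure-flux problems are rejected", {
  expect_error(diffusible_steady_solve(3300, Inf, 1e-14, 1, 647, 40),
               "ill-posed")
})

test_that("density step is a plain pointwise Euler update with a floor at zero", {
  f <- matrix(c(0.3, 0.2, 0.1, 0.05), 2, 2)
  expect_identical(density_step(f, f * 0, 7), f)
  r <- matrix(0.01, 2, 2)
  expect_equal(density_step(f, r, 7), f + 0.07)
  expect_warning(out <- density_step(f, -f, 7), "floored")
  expect_true(all(out >= 0))
  # constant negative deviation drives density monotonically toward zero
  rho <- 0.33
  prev <- rho
  for (k in 1:50) {
    rho <- density_step(rho, rho / 70 * (-0.2), 7)
    expect_lt(rho, prev)
    prev <- rho
  }
  expect_gt(rho, 0)
})
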