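# shared builders for the test suite; everything is generated in code

table1_wall <- function(n_radial = 5, active = FALSE) {
  cfg <- simulation_config(
    params = merge_params_test(default_params(),
                               list(geometry = list(n_radial = n_radial))),
    mode = "phenomenological", active = active, scenario = "test")
  vesselgr:::build_wall(cfg)
}

merge_params_test <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_params_test(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

# a neutral wall: no deposition stretches, no prestress, no pressure needed
neutral_wall <- function(n_radial = 5) {
  p <- default_params()
  p$material$lambda_z_e <- 1
  p$material$lambda_h_c <- 1
  p$material$lambda_h_m <- 1
  cfg <- simulation_config(
    params = merge_params_test(p, list(geometry = list(n_radial = n_radial))),
    mode = "phenomenological", scenario = "test")
  vesselgr:::build_wall(cfg)
}

table1_collagen <- function() {
  fiber_params(c1 = 234.9, c2 = 4.08, angle_deg = 0, lambda_h = 1.25,
               T_days = 70, phi0 = 0.1, name = "collagen")
}

table1_smc <- function() {
  fiber_params(c1 = 261.4, c2 = 0.24, angle_deg = 0, lambda_h = 1.2,
               T_days = 70, phi0 = 0.33, name = "m")
}

# prestressed Table-1 wall, cached per session (prestressing is deterministic)
prestressed_table1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- prestress_vessel(table1_wall(), load_state(1, 1, 14))
    }
    cache
  }
})

random_spd_F <- function() {
  # well-conditioned random deformation gradient with positive determinant
  A <- matrix(stats::rnorm(9, sd = 0.08), 3, 3)
  diag(3) + A + 0.05 * crossprod(A)
}
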