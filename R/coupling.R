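as_schedule <- function(x) {
  if (is.function(x)) x else function(s) x
}

#' Build a coupled simulation configuration
#'
#' Collects the parameter set, signaling networks, module toggles and the
#' load schedule into a validated configuration for [run_gr()]. Load
#' perturbations are applied as sustained steps at s = 0+ when given as
#' scalars; functions of G&R time (days) are also accepted.
#'
#' @param params Parameter list from [default_params()] or [load_config()].
#' @param mode `"signaling"` (network-driven turnover) or
#'   `"phenomenological"` (stress-driven rate law, uncoupled model).
#' @param intramural Intramural-cell [signaling_network()] (required in
#'   signaling mode).
#' @param ec Endothelial-cell network, or `NULL`.
#' @param diffusion Solve NO/ET1 reaction-diffusion (requires `ec`).
#' @param active Enable active smooth muscle stress.
#' @param gamma,epsilon Pressure and flow ratios (scalar step values or
#'   functions of time in days).
#' @param angii Exogenous AngII input level applied at s = 0+ (the
#'   network is baselined at its declared AngII baseline).
#' @param s_sigma Sensitivity of the stress input scaling.
#' @param k_rate Gain of the phenomenological rate law (1/days).
#' @param t_end_norm Simulated duration in units of the smooth muscle
#'   turnover time `T_m`.
#' @param outputs Mapping of network output nodes: list with `collagen`
#'   (one or more node names, averaged before the deviation is taken),
#'   `proliferation`, and optionally `actomyosin`.
#' @param scenario Label stored with the run.
#' @return Object of class `gr_config`.
#' @export
simulation_config <- function(params = default_params(),
                              mode = c("signaling", "phenomenological"),
                              intramural = NULL, ec = NULL,
                              diffusion = FALSE, active = FALSE,
                              gamma = 1, epsilon = 1, angii = NULL,
                              s_sigma = params$signaling$s_sigma,
                              k_rate = 0.01,
                              t_end_norm = 10,
                              outputs = list(collagen = c("colI", "colIII"),
                                             proliferation = "proliferation",
                                             actomyosin = "actomyosin"),
                              scenario = "custom") {
  mode <- match.arg(mode)
  if (mode == "signaling" && is.null(intramural)) {
    stop("config error: signaling mode requires an intramural network",
         call. = FALSE)
  }
  if (diffusion && is.null(ec)) {
    stop("config error: diffusion requires an endothelial network (or prescribed fluxes)",
         call. = FALSE)
  }
  structure(list(params = params, mode = mode, intramural = intramural,
                 ec = ec, diffusion = diffusion, active = active,
                 gamma = as_schedule(gamma), epsilon = as_schedule(epsilon),
                 angii = angii, s_sigma = s_sigma, k_rate = k_rate,
                 t_end_norm = t_end_norm, outputs = outputs,
                 scenario = scenario),
            class = "gr_config")
}

build_wall <- function(config) {
  p <- config$params
  m <- p$material
  g <- p$geometry
  fibers <- list(
    fiber_params(m$c1_m, m$c2_m, 0, m$lambda_h_m, m$T_m, m$phi_m, "m"),
    fiber_params(m$c1_c, m$c2_c, 0, m$lambda_h_c, m$T_c, m$phi_c0, "c0"),
    fiber_params(m$c1_c, m$c2_c, 90, m$lambda_h_c, m$T_c, m$phi_c90, "c90"),
    fiber_params(m$c1_c, m$c2_c, m$alpha0_deg, m$lambda_h_c, m$T_c,
                 m$phi_cd, "cp"),
    fiber_params(m$c1_c, m$c2_c, -m$alpha0_deg, m$lambda_h_c, m$T_c,
                 m$phi_cd, "cm"))
  act <- if (config$active) {
    active_params(p$active$sigma_max, p$active$lambda_max, p$active$lambda_0,
                  p$active$y_con0, enabled = TRUE)
  } else NULL
  vessel_wall(vessel_geometry(g$A, g$H, g$L, g$n_radial),
              elastin_params(m$mu_e, m$kappa, m$lambda_z_e),
              fibers, act, phi_e = m$phi_e)
}

midwall_value <- function(values, geom) {
  stats::approx(geom$R_cells, values, xout = geom$A + geom$H / 2,
                rule = 2)$y
}

solve_species <- function(config, species, dpsi) {
  b <- config$params$biochem
  g <- config$params$geometry
  if (species == "NO") {
    D <- b$D_NO; Ts <- b$T_NO; Q0 <- b$Q0_NO
  } else {
    D <- b$D_ET1; Ts <- b$T_ET1; Q0 <- b$Q0_ET1
  }
  q_in <- b$eta * Q0 * (1 + dpsi)
  diffusible_steady_solve(D, Ts, q_in, b$xi,
                          r_inner = g$A * 1000, thickness = g$H * 1000,
                          n = b$n_diff, cylindrical = TRUE)
}

sample_at_cells <- function(profile, geom) {
  stats::approx(profile$r, profile$conc, xout = geom$R_cells * 1000,
                rule = 2)$y
}

#' Initialize a coupled simulation
#'
#' Prestresses the vessel, baselines the signaling networks, computes the
#' homeostatic diffusible-species profiles, and prepares the state object
#' advanced by [staggered_step()].
#'
#' @param config A [simulation_config()].
#' @return Object of class `gr_sim` (mutable simulation state).
#' @export
init_simulation <- function(config) {
  p <- config$params
  wall <- build_wall(config)
  pre <- prestress_vessel(wall, load_state(1, 1, p$load$p0))
  wall <- pre$wall
  geom <- wall$geometry
  state0 <- pre$state

  nets <- list()
  if (config$mode == "signaling") {
    nets$intramural <- baseline_init(config$intramural)
    if (!is.null(config$ec)) nets$ec <- baseline_init(config$ec)
  }

  conc <- NULL
  if (config$diffusion) {
    conc <- list()
    for (sp in c("NO", "ET1")) {
      prof <- solve_species(config, sp, 0)
      conc[[sp]] <- list(profile = prof,
                         cells = sample_at_cells(prof, geom),
                         base_cells = sample_at_cells(prof, geom))
    }
  }

  smc_passive0 <- wall$sigma_h[["m"]]
  act0 <- if (config$active) {
    wall$active$sigma_max * wall$active$y_con0 * .active_factor(wall$active)
  } else 0
  baseline <- list(
    trace = midwall_value(state0$trace, geom),
    smc = smc_passive0 + act0,
    dens0 = wall$dens[1, ],  # uniform at s = 0
    nu_m0 = wall$dens[1, "m"],
    nu_c0 = sum(wall$dens[1, c("c0", "c90", "cp", "cm")]))

  nc <- geom$n_radial - 1
  sim <- list(config = config, wall = wall, geom = geom, s = 0, step = 0,
              state = state0, nets = nets, conc = conc, baseline = baseline,
              dpsi = list(c = rep(0, nc), m = rep(0, nc), act = rep(0, nc),
                          NO = 0, ET1 = 0),
              y_con_new = wall$y_con, rates = NULL,
              prestress = list(iterations = pre$iterations, disp = pre$disp),
              records = list())
  sim$records[[1]] <- record_row(sim)
  class(sim) <- "gr_sim"
  sim
}

record_row <- function(sim) {
  g <- sim$geom
  st <- sim$state
  cfg <- sim$config
  T_m <- cfg$params$material$T_m
  smc_pass <- midwall_value(st$cells$fiber_sigma[, "m"], g)
  act <- if (cfg$active) {
    sim$wall$active$sigma_max * midwall_value(sim$wall$y_con, g) *
      .active_factor(sim$wall$active)
  } else 0
  tibble::tibble(
    step = sim$step, s = sim$s, s_norm = sim$s / T_m,
    gamma = cfg$gamma(sim$s), epsilon = cfg$epsilon(sim$s),
    r_inner_norm = st$r_inner / g$A,
    h_norm = st$h / g$H,
    trace_norm = midwall_value(st$trace, g) / sim$baseline$trace,
    smc_stress_norm = (smc_pass + act) / sim$baseline$smc,
    wss_ratio = st$wss_ratio,
    y_con = midwall_value(sim$wall$y_con, g),
    dpsi_c = midwall_value(sim$dpsi$c, g),
    dpsi_m = midwall_value(sim$dpsi$m, g),
    dpsi_act = midwall_value(sim$dpsi$act, g),
    dpsi_NO = sim$dpsi$NO, dpsi_ET1 = sim$dpsi$ET1,
    NO_nM = if (!is.null(sim$conc)) mean(sim$conc$NO$cells) * 1e18 else NA_real_,
    ET1_nM = if (!is.null(sim$conc)) mean(sim$conc$ET1$cells) * 1e18 else NA_real_,
    nu_total = midwall_value(rowSums(sim$wall$dens) / sim$wall$nu0, g))
}

substep_mechanics <- function(sim) {
  cfg <- sim$config
  s_new <- sim$s + cfg$params$time$ds
  load <- load_state(cfg$gamma(s_new), cfg$epsilon(s_new),
                     cfg$params$load$p0)
  sim$state <- equilibrium_solve(sim$wall, load, r_init = sim$state$r_nodes)
  sim
}

substep_signaling <- function(sim) {
  cfg <- sim$config
  if (cfg$mode != "signaling") return(sim)
  sg <- cfg$params$signaling
  net <- sim$nets$intramural
  nc <- sim$geom$n_radial - 1
  input_names <- net$nodes$name[net$nodes$role == "input"]
  baselines <- stats::setNames(net$nodes$baseline[net$nodes$role == "input"],
                               input_names)
  sig_m <- sim$state$cells$fiber_sigma[, "m"]
  out <- cfg$outputs
  col_nodes <- out$collagen
  y0 <- net$y0
  col0 <- mean(y0[col_nodes])
  dpsi_c <- dpsi_m <- dpsi_act <- numeric(nc)
  for (i in seq_len(nc)) {
    inp <- baselines
    if ("stress" %in% input_names) {
      inp[["stress"]] <- scale_input(sig_m[i], sim$wall$sigma_h[["m"]],
                                     cfg$s_sigma, baselines[["stress"]])
    }
    if (!is.null(sim$conc)) {
      if ("NO" %in% input_names) {
        inp[["NO"]] <- scale_input(sim$conc$NO$cells[i],
                                   sim$conc$NO$base_cells[i],
                                   sg$s_NO, baselines[["NO"]])
      }
      if ("ET1" %in% input_names) {
        inp[["ET1"]] <- scale_input(sim$conc$ET1$cells[i],
                                    sim$conc$ET1$base_cells[i],
                                    sg$s_ET1, baselines[["ET1"]])
      }
    }
    if (!is.null(cfg$angii) && "AngII" %in% input_names) {
      inp[["AngII"]] <- cfg$angii
    }
    y <- steady_state(net, fixed_inputs = inp)
    dpsi_c[i] <- delta_psi(mean(y[col_nodes]), col0)
    dpsi_m[i] <- delta_psi(y[[out$proliferation]], y0[[out$proliferation]])
    if (cfg$active && !is.null(out$actomyosin) &&
        out$actomyosin %in% names(y)) {
      dpsi_act[i] <- delta_psi(y[[out$actomyosin]], y0[[out$actomyosin]])
    }
  }
  sim$dpsi$c <- dpsi_c
  sim$dpsi$m <- dpsi_m
  sim$dpsi$act <- dpsi_act
  if (!is.null(sim$nets$ec)) {
    ecn <- sim$nets$ec
    y_wss <- scale_input(sim$state$wss_ratio, 1, sg$s_tau, sg$y_wss0)
    y <- steady_state(ecn, fixed_inputs = c(wss = y_wss))
    sim$dpsi$NO <- delta_psi(y[["NO"]], ecn$y0[["NO"]])
    sim$dpsi$ET1 <- delta_psi(y[["ET1"]], ecn$y0[["ET1"]])
  }
  if (cfg$active) {
    y_con0 <- cfg$params$active$y_con0
    beta <- log((1 - y_con0) / y_con0)
    sim$y_con_new <- 1 / (1 + exp(beta - sg$s_con * sim$dpsi$act))
  }
  sim
}

substep_biochemistry <- function(sim) {
  cfg <- sim$config
  if (!is.null(sim$conc)) {
    for (sp in c("NO", "ET1")) {
      prof <- solve_species(cfg, sp, sim$dpsi[[sp]])
      sim$conc[[sp]]$profile <- prof
      sim$conc[[sp]]$cells <- sample_at_cells(prof, sim$geom)
    }
  }
  dens <- sim$wall$dens
  col_idx <- c("c0", "c90", "cp", "cm")
  rates <- matrix(0, nrow(dens), 5,
                  dimnames = list(NULL, c("m", col_idx)))
  if (cfg$mode == "signaling") {
    mt <- cfg$params$material
    cr <- constituent_rates(
      rho_m = dens[, "m"], rho_c = rowSums(dens[, col_idx]),
      rho_m0 = sim$baseline$nu_m0, rho_c0 = sim$baseline$nu_c0,
      T_m = mt$T_m, T_c = mt$T_c,
      dpsi_m = sim$dpsi$m, dpsi_c = sim$dpsi$c)
    rates[, "m"] <- cr$drho_m
    rates[, col_idx] <- collagen_family_split(cr$drho_c, dens[, col_idx])
  } else {
    for (f in seq_along(sim$wall$fibers)) {
      nm <- colnames(sim$wall$lam_r)[f]
      rates[, nm] <- phenomenological_rate(
        dens[, nm], cfg$k_rate,
        sim$state$cells$fiber_sigma[, nm], sim$wall$sigma_h[[nm]])
    }
  }
  sim$rates <- rates
  sim
}

advance_state <- function(sim) {
  cfg <- sim$config
  ds <- cfg$params$time$ds
  fam <- colnames(sim$wall$lam_r)
  dens_f <- sim$wall$dens[, fam, drop = FALSE]
  rr <- sim$rates / pmax(dens_f, 1e-12)
  for (f in seq_along(fam)) {
    nm <- fam[f]
    rate <- remodeling_rate(
      sigma = sim$state$cells$fiber_sigma[, nm],
      sigma_h = sim$wall$sigma_h[[nm]],
      rho_dot_over_rho = rr[, nm],
      T_days = sim$wall$fibers[[f]]$T_days,
      lambda_r = sim$wall$lam_r[, nm],
      I4e = sim$state$cells$fiber_I4e[, nm],
      dsigma_dI4e = sim$state$cells$fiber_dsigma[, nm])
    sim$wall$lam_r[, nm] <- sim$wall$lam_r[, nm] + ds * rate
  }
  sim$wall$dens[, fam] <- density_step(dens_f, sim$rates, ds)
  if (cfg$active) sim$wall$y_con <- sim$y_con_new
  sim$s <- sim$s + ds
  sim$step <- sim$step + 1
  sim
}

#' Advance the coupled simulation by one G&R step
#'
#' Executes the staggered scheme: (1) mechanical equilibrium from the
#' previous constituent state under the current load, (2) signaling
#' steady states at every material point using the fresh stresses and the
#' previous concentrations, (3) reaction-diffusion and turnover rates
#' using the fresh mechanics and signaling, then advances remodeling
#' stretches and densities by forward Euler. `order` exists so that the
#' documented ordering is testable; changing it changes which fields a
#' sub-step sees.
#'
#' @param sim A `gr_sim` from [init_simulation()].
#' @param order Permutation of `c("mechanics", "signaling",
#'   "biochemistry")`.
#' @return The advanced `gr_sim`.
#' @export
staggered_step <- function(sim, order = c("mechanics", "signaling",
                                          "biochemistry")) {
  if (!setequal(order, c("mechanics", "signaling", "biochemistry"))) {
    stop("order must be a permutation of mechanics/signaling/biochemistry",
         call. = FALSE)
  }
  for (sub in order) {
    sim <- switch(sub,
                  mechanics = substep_mechanics(sim),
                  signaling = substep_signaling(sim),
                  biochemistry = substep_biochemistry(sim))
  }
  sim <- advance_state(sim)
  sim$records[[length(sim$records) + 1]] <- record_row(sim)
  sim
}

#' Run a coupled G&R simulation
#'
#' @param config A [simulation_config()].
#' @param order Sub-step ordering, see [staggered_step()].
#' @return Object of class `gr_run` with the tidy `timeseries` tibble,
#'   the final wall/state, the baseline record and a run manifest.
#' @export
run_gr <- function(config, order = c("mechanics", "signaling",
                                     "biochemistry")) {
  sim <- init_simulation(config)
  n_steps <- ceiling(config$t_end_norm * config$params$material$T_m /
                       config$params$time$ds)
  for (k in seq_len(n_steps)) {
    sim <- staggered_step(sim, order)
  }
  ts <- dplyr::bind_rows(sim$records)
  manifest <- list(
    scenario = config$scenario,
    config_hash = rlang::hash(list(config$params, config$mode,
                                   config$scenario, config$s_sigma,
                                   config$k_rate, config$t_end_norm)),
    package_version = as.character(utils::packageVersion("vesselgr")),
    r_version = R.version.string,
    n_steps = n_steps,
    n_radial = config$params$geometry$n_radial,
    ds_days = config$params$time$ds,
    prestress_iterations = sim$prestress$iterations,
    prestress_disp = sim$prestress$disp)
  structure(list(timeseries = ts, config = config, wall = sim$wall,
                 state = sim$state, baseline = sim$baseline,
                 prestress = sim$prestress, manifest = manifest),
            class = "gr_run")
}

#' Theoretical ideal adaptation markers
#'
#' For a sustained pressure ratio `gamma` and flow ratio `epsilon`, a
#' vessel restoring its baseline wall shear stress and hoop stress should
#' adapt its inner radius to `epsilon^(1/3) A` and its thickness to
#' `gamma epsilon^(1/3) H`.
#'
#' @param gamma Pressure ratio.
#' @param epsilon Flow ratio.
#' @return Tibble with `a_ratio` and `h_ratio`.
#' @export
ideal_adaptation <- function(gamma, epsilon) {
  stopifnot(all(gamma > 0), all(epsilon > 0))
  tibble::tibble(a_ratio = epsilon^(1 / 3), h_ratio = gamma * epsilon^(1 / 3))
}

#' Scenario presets
#'
#' @return Tibble listing the available presets and what they toggle.
#' @export
list_scenarios <- function() {
  tibble::tibble(
    scenario = c("angii_hypertension", "ec_communication",
                 "sensitivity_sweep", "uncoupled"),
    description = c(
      "Intramural network, passive SMC; pressure step with optional exogenous AngII",
      "EC layer + NO/ET1 diffusion + active SMC; pressure or flow step",
      "Three-node network with adjustable stress sensitivity; pressure steps",
      "Phenomenological stress-driven rates (no signaling)"))
}

#' Run a preset scenario
#'
#' Assembles the preset's configuration (networks, toggles, loads),
#' applies overrides, and runs the coupled simulation.
#'
#' @param scenario Preset name, see [list_scenarios()].
#' @param overrides Named list overriding configuration fields: any of
#'   `gamma`, `epsilon`, `angii`, `s_sigma`, `k_rate`, `t_end_norm`, or a
#'   nested `params` list merged onto [default_params()].
#' @param t_end_norm Simulated duration in units of `T_m`.
#' @return A `gr_run`.
#' @export
run_scenario <- function(scenario = c("angii_hypertension",
                                      "ec_communication",
                                      "sensitivity_sweep", "uncoupled"),
                         overrides = list(), t_end_norm = 10) {
  scenario <- match.arg(scenario)
  params <- default_params()
  if (!is.null(overrides$params)) {
    params <- merge_params(params, overrides$params)
    validate_params(params)
  }
  get <- function(name, default) overrides[[name]] %||% default
  cfg <- switch(scenario,
    angii_hypertension = simulation_config(
      params = params, mode = "signaling",
      intramural = fixture_network("intramural_standin", params),
      diffusion = FALSE, active = FALSE,
      gamma = get("gamma", 1.15), epsilon = get("epsilon", 1),
      angii = get("angii", 0),
      s_sigma = get("s_sigma", params$signaling$s_sigma),
      t_end_norm = get("t_end_norm", t_end_norm),
      scenario = scenario),
    ec_communication = simulation_config(
      params = params, mode = "signaling",
      intramural = fixture_network("intramural_standin", params),
      ec = fixture_network("ec_standin", params),
      diffusion = TRUE, active = TRUE,
      gamma = get("gamma", 1), epsilon = get("epsilon", 1),
      angii = NULL,
      s_sigma = get("s_sigma", params$signaling$s_sigma),
      t_end_norm = get("t_end_norm", t_end_norm),
      scenario = scenario),
    sensitivity_sweep = {
      net <- fixture_network("three_node", params)
      simulation_config(
        params = params, mode = "signaling", intramural = net,
        diffusion = FALSE, active = FALSE,
        gamma = get("gamma", 1), epsilon = get("epsilon", 1),
        s_sigma = get("s_sigma", 0.5),
        t_end_norm = get("t_end_norm", t_end_norm),
        outputs = list(collagen = "collagen",
                       proliferation = "proliferation"),
        scenario = scenario)
    },
    uncoupled = simulation_config(
      params = params, mode = "phenomenological",
      gamma = get("gamma", 1), epsilon = get("epsilon", 1),
      k_rate = get("k_rate", 0.01),
      t_end_norm = get("t_end_norm", t_end_norm),
      scenario = scenario))
  run_gr(cfg)
}
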