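#' Default simulation parameters (murine descending thoracic aorta)
#'
#' Radially averaged single-layer parameter set for a mouse descending
#' thoracic aorta: geometry, mixture composition, constitutive moduli,
#' deposition stretches, turnover times, baseline pressure and time step,
#' plus the cell-signaling defaults, active muscle parameters and the
#' NO/ET1 diffusion-reaction parameters with endothelial flux fractions.
#'
#' @return Nested named list of parameters (units documented per field:
#'   kPa, mm, days for the mechanics; um, s, umol for diffusible species).
#' @export
default_params <- function() {
  mu_e <- 89.71
  list(
    geometry = list(A = 0.647, H = 0.04, L = 0.04, n_radial = 5),
    material = list(
      rho0 = 1050,                      # mixture density, kg/m^3
      phi_e = 0.34, phi_m = 0.33,
      phi_c0 = 0.01848, phi_c90 = 0.02211, phi_cd = 0.1447,  # each diagonal family
      alpha0_deg = 29.91,
      mu_e = mu_e, kappa = 10 * mu_e,
      c1_c = 234.9, c2_c = 4.08,
      c1_m = 261.4, c2_m = 0.24,
      lambda_z_e = 1.62, lambda_h_c = 1.25, lambda_h_m = 1.2,
      T_m = 70, T_c = 70),
    load = list(p0 = 14.0),
    time = list(ds = 7),
    signaling = list(
      s_sigma = 0.5, tau = 1, W = 1, EC50 = 0.55, n = 1.25, y_max = 1,
      y_wss0 = 0.5, y_integrins0 = 0.2, y_sacs0 = 0.2, y_stress0 = 0.2,
      y_angii0 = 0.0,
      s_tau = 0.5, s_NO = 0.75, s_ET1 = 0.75, s_con = 1.0,
      y_NO0 = 0.5, y_ET10 = 0.5),
    active = list(sigma_max = 170, lambda_max = 1.1, lambda_0 = 0.4,
                  y_con0 = 0.5),
    biochem = list(
      D_NO = 3300, T_NO = 15, Q0_NO = 5.3e-14,
      D_ET1 = 300, T_ET1 = 120, Q0_ET1 = 1.0e-14,
      eta = 0.2, xi = 0.9, n_diff = 101)
  )
}

#' Fixture signaling networks
#'
#' Deterministic, self-contained network definitions used by the scenario
#' presets and tests:
#' \describe{
#'   \item{`three_node`}{One stress input activating cell proliferation
#'     and collagen production (tau = 1, W = 1, EC50 = 0.5, n = 1.4);
#'     the stress baseline input is 0.5 (sigmoid midpoint).}
#'   \item{`five_node`}{Two inputs (stress, NO) and three outputs
#'     (proliferation f+(stress), collagen AND-NOT(stress, NO),
#'     contraction f-(NO)).}
#'   \item{`ec_standin`}{Reduced endothelial-cell stand-in: wall shear
#'     stress in; NO (activated by WSS) and ET1 (inhibited by WSS) out.}
#'   \item{`intramural_standin`}{Reduced intramural-cell stand-in with
#'     the full input/output signature of the published 50-node network
#'     (inputs stress, NO, ET1, AngII, integrins, SACs; outputs colI,
#'     colIII, proliferation, actomyosin) but documented reduced
#'     internals: a two-stage kinase cascade (mapk, tgfb) amplifies the
#'     stress input before it reaches the synthetic outputs, collagen
#'     synthesis is additionally driven by AngII and inhibited by NO,
#'     proliferation by AngII and an ET1/mechanosensing (integrins AND
#'     SACs) branch, and actomyosin activity is promoted by ET1 and
#'     inhibited by NO. Input edges use the Table-style defaults
#'     (EC50 = 0.55, n = 1.25); cascade and output edges use the generic
#'     normalized-Hill defaults (EC50 = 0.5, n = 1.4). Modulating edge
#'     weights are reduced (AngII 0.1, NO-on-collagen 0.5, ET1 and
#'     mechanosensing 0.25) so that side inputs modulate rather than
#'     drown the stress pathway; see the methods vignette for the gain
#'     calculation behind these choices.}
#' }
#'
#' @param preset One of `"three_node"`, `"five_node"`, `"ec_standin"`,
#'   `"intramural_standin"`.
#' @param params Parameter list, see [default_params()].
#' @return A [signaling_network()].
#' @export
fixture_network <- function(preset = c("three_node", "five_node",
                                       "ec_standin", "intramural_standin"),
                            params = default_params()) {
  preset <- match.arg(preset)
  sg <- params$signaling
  e55 <- function(src, sign = "activating") {
    net_edge(src, W = sg$W, n = sg$n, EC50 = sg$EC50, sign = sign)
  }
  node <- function(name, role, baseline = NA_real_) {
    data.frame(name = name, tau = sg$tau, y_max = sg$y_max, role = role,
               baseline = baseline, stringsAsFactors = FALSE)
  }
  switch(preset,
    three_node = signaling_network(
      nodes = rbind(node("stress", "input", 0.5),
                    node("proliferation", "output"),
                    node("collagen", "output")),
      influences = list(
        proliferation = net_edge("stress", W = 1, n = 1.4, EC50 = 0.5),
        collagen = net_edge("stress", W = 1, n = 1.4, EC50 = 0.5))),
    five_node = signaling_network(
      nodes = rbind(node("stress", "input", 0.5),
                    node("NO", "input", 0.5),
                    node("proliferation", "output"),
                    node("collagen", "output"),
                    node("contraction", "output")),
      influences = list(
        proliferation = net_edge("stress", W = 1, n = 1.4, EC50 = 0.5),
        collagen = net_gate("AND_NOT",
                            net_edge("stress", W = 1, n = 1.4, EC50 = 0.5),
                            net_edge("NO", W = 1, n = 1.4, EC50 = 0.5)),
        contraction = net_edge("NO", W = 1, n = 1.4, EC50 = 0.5,
                               sign = "inhibiting"))),
    ec_standin = signaling_network(
      nodes = rbind(node("wss", "input", sg$y_wss0),
                    node("NO", "output"),
                    node("ET1", "output")),
      influences = list(
        NO = e55("wss"),
        ET1 = e55("wss", sign = "inhibiting"))),
    intramural_standin = {
      g50 <- function(src, W = 1) net_edge(src, W = W, n = 1.4, EC50 = 0.5)
      e55w <- function(src, W) net_edge(src, W = W, n = sg$n, EC50 = sg$EC50)
      # steep high-EC50 edges: low baseline contribution, strong relative
      # slope around a 0.5 input (paracrine modulators)
      steep <- function(src, W) net_edge(src, W = W, n = 2, EC50 = 0.65)
      signaling_network(
        nodes = rbind(node("stress", "input", sg$y_stress0),
                      node("NO", "input", sg$y_NO0),
                      node("ET1", "input", sg$y_ET10),
                      node("AngII", "input", sg$y_angii0),
                      node("integrins", "input", sg$y_integrins0),
                      node("SACs", "input", sg$y_sacs0),
                      node("mapk", "internal"),
                      node("tgfb", "internal"),
                      node("colI", "output"),
                      node("colIII", "output"),
                      node("proliferation", "output"),
                      node("actomyosin", "output")),
        influences = list(
          mapk = net_gate("AND_NOT", e55("stress"), steep("NO", 1)),
          tgfb = g50("mapk"),
          colI = g50("tgfb"),
          colIII = net_gate("OR", g50("tgfb"), e55w("AngII", 0.1)),
          proliferation = net_gate("OR",
                                   net_gate("OR", g50("tgfb"),
                                            e55w("AngII", 0.1)),
                                   net_gate("OR", steep("ET1", 0.5),
                                            net_gate("AND",
                                                     e55w("integrins", 0.25),
                                                     e55w("SACs", 0.25)))),
          actomyosin = net_gate("AND_NOT", e55("ET1"), e55("NO"))))
    }
  )
}

merge_params <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- merge_params(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a simulation configuration
#'
#' Reads a YAML override file (possibly empty) and merges it onto the
#' defaults; unspecified fields keep the [default_params()] values.
#' Basic schema validation is performed (positivity, mass fractions
#' summing to 1 within 1e-4).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list merged after the file.
#' @return Validated parameter list of class `gr_params`; attribute
#'   `defaulted` names the top-level groups left entirely at defaults.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  params <- default_params()
  given <- character(0)
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    y <- yaml::read_yaml(path)
    if (!is.null(y)) {
      params <- merge_params(params, y)
      given <- names(y)
    }
  }
  if (length(overrides)) {
    params <- merge_params(params, overrides)
    given <- union(given, names(overrides))
  }
  validate_params(params)
  structure(params, class = c("gr_params", "list"),
            defaulted = setdiff(names(default_params()), given))
}

validate_params <- function(p) {
  check <- function(ok, field, constraint) {
    if (!ok) stop(sprintf("config error: field '%s' violates constraint: %s",
                          field, constraint), call. = FALSE)
  }
  g <- p$geometry
  check(g$A > 0 && g$H > 0 && g$L > 0, "geometry", "A, H, L > 0")
  check(g$n_radial >= 3, "geometry$n_radial", ">= 3")
  m <- p$material
  phis <- m$phi_e + m$phi_m + m$phi_c0 + m$phi_c90 + 2 * m$phi_cd
  check(abs(phis - 1) < 1e-4, "material$phi_*",
        sprintf("mass fractions must sum to 1 (got %.5f)", phis))
  check(m$mu_e > 0 && m$kappa > 0, "material$mu_e/kappa", "> 0")
  check(m$T_m > 0 && m$T_c > 0, "material$T_m/T_c", "> 0")
  check(p$time$ds > 0, "time$ds", "> 0")
  check(p$load$p0 >= 0, "load$p0", ">= 0")
  b <- p$biochem
  check(b$eta >= 0 && b$eta <= 1, "biochem$eta", "in [0, 1]")
  check(b$xi >= 0 && b$xi <= 1, "biochem$xi", "in [0, 1]")
  hill_B(p$signaling$EC50, p$signaling$n)  # B positivity
  invisible(TRUE)
}

#' @rdname load_config
#' @param params A parameter list.
#' @export
write_config <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Write / read a tidy time-series record
#'
#' Writes the long-format time series of a run to CSV and a JSON run
#' manifest (configuration hash, package and R versions, problem sizes,
#' solver statistics) next to it.
#'
#' @param run A `gr_run` object from [run_scenario()] or [run_gr()].
#' @param path Output CSV path; the manifest is written to the same path
#'   with extension `_manifest.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(run, path) {
  long <- generics::tidy(run)
  utils::write.csv(long, path, row.names = FALSE)
  manifest_path <- sub("\\.csv$", "", path)
  manifest_path <- paste0(manifest_path, "_manifest.json")
  jsonlite::write_json(run$manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
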