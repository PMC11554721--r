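#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a G&R run into long format
#'
#' One row per step per reported quantity, ready for faceted plotting or
#' CSV export.
#'
#' @param x A `gr_run`.
#' @param ... Unused.
#' @return A tibble with columns `step`, `s`, `s_norm`, `quantity`,
#'   `value`.
#' @export
tidy.gr_run <- function(x, ...) {
  x$timeseries |>
    tidyr::pivot_longer(-c("step", "s", "s_norm"),
                        names_to = "quantity", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' One-row summary of a G&R run
#'
#' Final normalized geometry and stresses, the ideal-adaptation markers
#' for the applied load, and simple stability diagnostics (late-time
#' drift of thickness and stress).
#'
#' @param x A `gr_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.gr_run <- function(x, ...) {
  ts <- x$timeseries
  last <- ts[nrow(ts), ]
  tail_n <- max(2, min(20, nrow(ts) %/% 5))
  tail_ts <- ts[(nrow(ts) - tail_n + 1):nrow(ts), ]
  ideal <- ideal_adaptation(last$gamma, last$epsilon)
  tibble::tibble(
    scenario = x$config$scenario,
    s_norm_end = last$s_norm,
    r_inner_norm = last$r_inner_norm,
    h_norm = last$h_norm,
    trace_norm = last$trace_norm,
    smc_stress_norm = last$smc_stress_norm,
    wss_ratio = last$wss_ratio,
    a_ideal = ideal$a_ratio,
    h_ideal = ideal$h_ratio,
    dh_late = diff(range(tail_ts$h_norm)),
    dtrace_late = diff(range(tail_ts$trace_norm)),
    prestress_disp = x$prestress$disp)
}

#' Plot the evolution of a G&R run
#'
#' Faceted evolution of the normalized mixture stress trace, smooth
#' muscle stress, wall thickness and inner radius over normalized time,
#' with dashed baselines and ideal-adaptation markers for the geometric
#' panels.
#'
#' @param object A `gr_run`.
#' @param quantities Which columns of the time series to facet.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gr_run <- function(object,
                            quantities = c("trace_norm", "smc_stress_norm",
                                           "h_norm", "r_inner_norm"),
                            ...) {
  ts <- object$timeseries
  long <- ts |>
    tidyr::pivot_longer(dplyr::all_of(quantities),
                        names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, levels = quantities)
  last <- ts[nrow(ts), ]
  ideal <- ideal_adaptation(last$gamma, last$epsilon)
  markers <- tibble::tibble(
    quantity = factor(c("h_norm", "r_inner_norm"), levels = quantities),
    value = c(ideal$h_ratio, ideal$a_ratio),
    s_norm = max(ts$s_norm))
  markers <- markers[markers$quantity %in% quantities, ]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$s_norm, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = markers, shape = 4, size = 3,
                        colour = "red3") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = expression(s / T^m), y = "normalized value",
                  title = object$config$scenario)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a diffusible-species profile
#'
#' @param profile Result of [diffusible_steady_solve()].
#' @param species Label for the title.
#' @return A ggplot object.
#' @export
plot_species_profile <- function(profile, species = "species") {
  df <- tibble::tibble(r = profile$r, conc_nM = profile$conc_nM)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$conc_nM)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "referential radius (um)", y = "concentration (nM)",
                  title = paste("quasi-steady profile:", species))
}

#' @export
print.gr_run <- function(x, ...) {
  g <- glance(x)
  cat("<gr_run>", x$config$scenario, "\n")
  cat(sprintf("  steps: %d (to s/T^m = %.1f), n_radial = %d\n",
              nrow(x$timeseries) - 1, g$s_norm_end,
              x$config$params$geometry$n_radial))
  cat(sprintf("  final: r/A = %.4f, h/H = %.4f, trace/trace0 = %.4f, wss = %.4f\n",
              g$r_inner_norm, g$h_norm, g$trace_norm, g$wss_ratio))
  cat(sprintf("  ideal adaptation: a/A = %.4f, h/H = %.4f\n",
              g$a_ideal, g$h_ideal))
  invisible(x)
}

#' @export
print.gr_network <- function(x, ...) {
  cat("<gr_network>", nrow(x$nodes), "nodes,",
      length(x$influences), "influenced nodes",
      if (isTRUE(x$dag)) "(acyclic)" else "(cyclic)", "\n")
  roles <- split(x$nodes$name, x$nodes$role)
  for (r in names(roles)) {
    cat(sprintf("  %s: %s\n", r, paste(roles[[r]], collapse = ", ")))
  }
  invisible(x)
}

#' @importFrom rlang .data
NULL
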