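# ggplot2 quick-look methods for the main result types.

#' Plot a surface response
#'
#' Panels the available observables: probe displacement timecourses,
#' steady-state surface profile, force relaxation.
#'
#' @param object A `surface_response`.
#' @param which One of `"probes"`, `"profile"`, `"force"`, `"pressure"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.surface_response <- function(object,
                                      which = c("probes", "profile",
                                                "force", "pressure"),
                                      ...) {
  which <- match.arg(which)
  if (is.null(object[[which]]))
    abort(sprintf("This response carries no '%s' series.", which))
  switch(which,
    probes = ggplot2::ggplot(object$probes,
                             ggplot2::aes(.data$t_s, .data$u_z_um,
                                          colour = factor(.data$probe_um))) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "vertical displacement (um)",
                    colour = "distance (um)"),
    profile = ggplot2::ggplot(object$profile,
                              ggplot2::aes(.data$r_um, .data$u_z_um)) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::labs(x = "distance from stimulus (um)",
                    y = "steady-state vertical displacement (um)"),
    force = ggplot2::ggplot(object$force,
                            ggplot2::aes(.data$t_s, .data$force_nN)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "time (s)", y = "indenter reaction force (nN)"),
    pressure = ggplot2::ggplot(object$pressure,
                               ggplot2::aes(.data$r_um, .data$p_Pa)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "distance from sink (um)", y = "pore pressure (Pa)"))
}

#' Plot steady pressure profiles of a cortex-permeability sweep
#'
#' @param sweep The tibble returned by [simulate_depressurisation()].
#' @return A ggplot of pressure recovery versus distance, one curve per
#'   cortex diffusion constant.
#' @export
plot_pressure_sweep <- function(sweep) {
  df <- purrr::map2_dfr(sweep$D1_um2_s, sweep$response, function(D1, resp) {
    dplyr::mutate(resp$pressure, D1_um2_s = D1)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$r_um, .data$recovery,
                                   colour = factor(.data$D1_um2_s))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from sink (um)",
                  y = "pressure recovery (fraction of drawdown)",
                  colour = "cortex D1 (um^2/s)")
}

#' Plot the objective landscape explored by a fit
#'
#' @param object A `poro_fit`.
#' @param ... Unused.
#' @return A ggplot of the stage-1 grid with the optimum marked.
#' @export
autoplot.poro_fit <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(.data$E, .data$D,
                               fill = log10(.data$objective))) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$E_Pa, y = object$D_um2_s,
                      colour = "red", shape = 4, size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "E (Pa)", y = "D (um^2/s)",
                  fill = "log10 objective")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
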