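#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a titration summary
#'
#' @param x A `titration_summary`.
#' @param time Keep only this measurement time (default: all).
#' @param ... Unused.
#' @return The per-condition summary tibble: one row per (pMHC, TCR, B,
#'   coupling, time) with `mean_cell_kd`, `sd_cell_kd`, replicate counts
#'   and the high-variance `flagged` marker.
#' @export
tidy.titration_summary <- function(x, time = NULL, ...) {
  out <- x$summary
  if (!is.null(time)) out <- dplyr::filter(out, .data$time %in% !!time)
  out
}

#' One-row-per-curve view of a titration summary
#'
#' @param x A `titration_summary`.
#' @param ... Unused.
#' @return The minima tibble: per curve, whether an interior minimum is
#'   `present`, the argmin pMHC density and the minimum `cellKD`.
#' @export
glance.titration_summary <- function(x, ...) {
  x$minima
}

#' Plot a titration summary
#'
#' Mean cellKD versus pMHC density (log-log), one errorbar per replicate
#' SD, faceted by measurement time, coloured by whatever varies (TCR
#' density, binding coefficient or coupling).
#'
#' @param object A `titration_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.titration_summary <- function(object, ...) {
  df <- dplyr::filter(object$summary, !.data$flagged)
  df$arm <- interaction(df$tcr, df$B, df$coupling, drop = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pmhc, y = .data$mean_cell_kd,
                                   colour = .data$arm, group = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_cell_kd - .data$sd_cell_kd,
      ymax = .data$mean_cell_kd + .data$sd_cell_kd), width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$time), labeller = "label_both") +
    ggplot2::labs(x = "pMHC density (molecules/µm²)",
                  y = expression({}^cell * K[D] ~ "(molecules/µm²)"),
                  colour = "arm (TCR.B.coupling)") +
    ggplot2::theme_minimal()
}

#' Plot the molecular pattern of a state
#'
#' Renders the synapse snapshot: free molecules faint, TCR-pMHC complexes
#' green and LFA-1-ICAM-1 complexes red, on the active disk.
#'
#' @param object A `synapse_state`.
#' @param complexes_only Hide free molecules.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synapse_state <- function(object, complexes_only = FALSE, ...) {
  df <- agent_table(object)
  df$what <- ifelse(df$bound,
                    ifelse(df$species %in% c("TCR", "pMHC"),
                           "TCR-pMHC", "LFA-1-ICAM-1"),
                    paste0("free ", df$species))
  df <- df[!(df$bound & df$species %in% c("pMHC", "ICAM1")), ] # one per pair
  if (complexes_only) df <- df[df$bound, ]
  cols <- c("TCR-pMHC" = "#1b9e2f", "LFA-1-ICAM-1" = "#d62728",
            "free TCR" = "#a6dba0", "free pMHC" = "#c2a5cf",
            "free LFA1" = "#fdae6b", "free ICAM1" = "#9ecae1")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$what)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_manual(values = cols) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = NULL,
                  title = sprintf("t = %.0f s", object$clock)) +
    ggplot2::theme_minimal()
}

#' Plot a radial profile
#'
#' @param profile Result of [radial_profile()].
#' @return A ggplot object: per-annulus density versus mid-annulus radius.
#' @export
plot_radial_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$r_mid, y = .data$density,
                                        colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "radius (µm)",
                  y = "density (molecules/µm²)") +
    ggplot2::theme_minimal()
}
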