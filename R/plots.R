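#' Plot a correlation curve
#'
#' @param object An [fcs_curve()].
#' @param ... Unused.
#' @return A ggplot with logarithmic lag axis (error bars when `sigma` is
#'   present).
#' @method autoplot fcs_curve
#' @export
autoplot.fcs_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_s, y = .data$g)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)))
  if ("sigma" %in% names(object))
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$g - .data$sigma, ymax = .data$g + .data$sigma),
      linewidth = 0.3, alpha = 0.5)
  p
}

#' Plot an FCS fit with residuals
#'
#' @param object An `fcs_fit`.
#' @param ... Unused.
#' @return A ggplot overlaying data and fitted curve.
#' @method autoplot fcs_fit
#' @export
autoplot.fcs_fit <- function(object, ...) {
  aug <- augment(object)
  ggplot2::ggplot(aug, ggplot2::aes(x = .data$lag_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$g), size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "red3") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)),
                  subtitle = sprintf("%d species, reduced chi^2 = %.3g",
                                     nrow(object$model$species),
                                     object$chi2_red))
}

#' Plot a titration report
#'
#' Diffusion coefficient of the dominant species against pH, with the
#' slow-species percentage as a bar underlay.
#'
#' @param object A `titration_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot titration_report
#' @export
autoplot.titration_report <- function(object, ...) {
  scale <- max(object$D1, na.rm = TRUE)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ph)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$slow_fraction * scale),
                      fill = "grey80", width = 0.15) +
    ggplot2::geom_point(ggplot2::aes(y = .data$D1)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$D1), linewidth = 0.3) +
    ggplot2::scale_y_continuous(
      name = expression(D[1] ~ (mu * m^2 / s)),
      sec.axis = ggplot2::sec_axis(~ . / scale * 100,
                                   name = "slow fraction (%)")) +
    ggplot2::labs(x = "pH")
}

#' Plot a free-energy landscape
#'
#' @param object A `fel_grid` from [free_energy_landscape()].
#' @param ... Unused.
#' @return A ggplot raster of `delta_g_kT` (unvisited bins blank).
#' @method autoplot fel_grid
#' @export
autoplot.fel_grid <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$pc1_mid, y = .data$pc2_mid,
                               fill = .data$delta_g_kT)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = expression(Delta * G ~ (k[B] * T))) +
    ggplot2::labs(x = "PC1", y = "PC2")
}

#' Scree plot of a trajectory PCA
#'
#' @param object A `pca_result`.
#' @param n_modes Number of leading modes to show.
#' @param ... Unused.
#' @return A ggplot of the eigenvalue spectrum.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, n_modes = 10, ...) {
  td <- utils::head(tidy(object), n_modes)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mode, y = .data$eigenvalue_nm2)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mode", y = expression(eigenvalue ~ (nm^2)))
}
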