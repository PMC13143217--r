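#' Plot a rhodopsin fit
#'
#' Mean replicate absorbance (points) with the fitted Govardovskii template
#' (line) and the fitted peak marked.
#'
#' @param object A `rhodopsin_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rhodopsin_fit <- function(object, ...) {
  spec <- object$mean_spectrum
  keep <- spec$wavelength_nm >= object$window[1] &
    spec$wavelength_nm <= object$window[2]
  tmpl <- govardovskii_absorbance(
    object$lambda_max_hat,
    grid = seq(object$window[1], object$window[2], by = 0.5),
    beta_band = object$beta_band)
  ggplot2::ggplot(spec[keep, ],
                  ggplot2::aes(x = .data$wavelength_nm, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = tmpl, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$lambda_max_hat,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(
      x = "Wavelength (nm)", y = "Relative absorbance",
      title = sprintf("%s: λ_max %.1f nm (95%% CI %.1f–%.1f)",
                      object$pigment_name, object$lambda_max_hat,
                      object$ci_low, object$ci_high)) +
    ggplot2::theme_minimal()
}

#' Plot a contrast sensitivity function
#'
#' Sensitivity against spatial frequency on log--log axes, with the peak and
#' (when present) the high cut-off frequency marked.
#'
#' @param object A `csf` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.csf <- function(object, ...) {
  p <- ggplot2::ggplot(object$points,
                       ggplot2::aes(x = .data$spatial_frequency_cpd,
                                    y = .data$sensitivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Spatial frequency (cpd)", y = "Contrast sensitivity",
                  title = sprintf("Individual %s", object$individual_id)) +
    ggplot2::theme_minimal()
  if (!is.na(object$cutoff_frequency_cpd)) {
    p <- p + ggplot2::geom_vline(xintercept = object$cutoff_frequency_cpd,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a marker contrast matrix as a heatmap
#'
#' Inverse Michelson contrast between every material pair; pairs detectable
#' by the bird (inverse contrast at or below its peak sensitivity) are
#' outlined.
#'
#' @param object A `contrast_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.contrast_matrix <- function(object, ...) {
  pairs <- tidy(object)
  both <- dplyr::bind_rows(
    pairs,
    dplyr::rename(pairs, material_a = "material_b", material_b = "material_a"))
  ggplot2::ggplot(both, ggplot2::aes(x = .data$material_a,
                                     y = .data$material_b,
                                     fill = .data$inverse_cm)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(both, .data$detectable),
                       colour = "black", linewidth = 0.8, fill = NA) +
    ggplot2::scale_fill_viridis_c(name = "1/Cm") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s (%s)", object$marker,
                                  object$component)) +
    ggplot2::theme_minimal()
}

#' Plot a visual-field map
#'
#' Binocular width as a function of elevation, with interpolated (blocked)
#' elevations highlighted.
#'
#' @param object A `visual_field_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.visual_field_map <- function(object, ...) {
  ggplot2::ggplot(object$binocular_by_elevation,
                  ggplot2::aes(x = .data$elevation_deg,
                               y = .data$binocular_width_deg)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$interpolated)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "black",
                                            `TRUE` = "orange"),
                                 name = "interpolated") +
    ggplot2::labs(x = "Elevation (deg)", y = "Binocular width (deg)") +
    ggplot2::theme_minimal()
}

#' Plot effective cone sensitivities
#'
#' Normalized effective sensitivity curves (pigment x droplet) for a cone
#' configuration table.
#'
#' @param cones Cone configuration tibble (default [black_grouse_cones()]).
#' @param grid Wavelength grid (default [default_grid()]).
#' @param beta_band Include the template beta band? Default `TRUE`.
#' @return A ggplot object.
#' @export
plot_cone_sensitivities <- function(cones = black_grouse_cones(),
                                    grid = default_grid(),
                                    beta_band = TRUE) {
  curves <- purrr::pmap_dfr(cones, function(cone, lambda_max, droplet_type,
                                            lambda_mid, k, ...) {
    lm <- if (is.na(lambda_mid)) "auto" else lambda_mid
    kk <- if (is.null(k) || is.na(k)) NULL else k
    tidy(effective_sensitivity(lambda_max, droplet_type, lambda_mid = lm,
                               k = kk, grid = grid, beta_band = beta_band,
                               cone_name = cone))
  })
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$wavelength_nm,
                                       y = .data$value,
                                       colour = .data$cone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Wavelength (nm)",
                  y = "Normalized effective sensitivity") +
    ggplot2::theme_minimal()
}
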