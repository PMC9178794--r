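#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: lateral field
#' maps (thickness / order parameter) as rasters, fitted surfaces as
#' height rasters, census series as count-versus-time traces with plateau
#' and disruption annotation, and diffusion estimates as MSD curves with
#' the fitted Einstein slope.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot.
#' @name bilayr-autoplot
NULL

#' @rdname bilayr-autoplot
#' @method autoplot field_map
#' @export
autoplot.field_map <- function(object, ...) {
  df <- tidy(object)
  lab <- if (object$quantity == "thickness_nm") "thickness (nm)" else "order parameter"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' @rdname bilayr-autoplot
#' @method autoplot surface_grid
#' @export
autoplot.surface_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "height (nm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)")
}

#' @rdname bilayr-autoplot
#' @param k_sd,persistence,window Annotation parameters, as in
#'   [detect_disruption()].
#' @method autoplot census_series
#' @export
autoplot.census_series <- function(object, k_sd = 5, persistence = 5,
                                   window = 10, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ps)", y = "waters in slab")
  if (nrow(object) > 2 * window) {
    ann <- census_annotate(object, k_sd = k_sd, persistence = persistence,
                           window = window)
    p <- p + ggplot2::geom_hline(yintercept = ann$plateau_mean,
                                 linetype = "dashed", colour = "steelblue")
    if (!is.na(ann$disruption_time)) {
      p <- p + ggplot2::geom_vline(xintercept = ann$disruption_time,
                                   linetype = "dotted", colour = "firebrick")
    }
  }
  p
}

#' @rdname bilayr-autoplot
#' @method autoplot diffusion_estimate
#' @export
autoplot.diffusion_estimate <- function(object, ...) {
  df <- object$msd
  in_fit <- df$lag_ps >= object$fit_window_ps[1] &
    df$lag_ps <= object$fit_window_ps[2]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ps, y = .data$msd_nm2)) +
    ggplot2::geom_line() +
    ggplot2::geom_smooth(data = df[in_fit, ], method = "lm",
                         formula = y ~ x, se = FALSE, colour = "firebrick") +
    ggplot2::labs(x = "lag (ps)", y = expression(MSD~(nm^2)))
}

#' @rdname bilayr-autoplot
#' @method autoplot distance_map
#' @export
autoplot.distance_map <- function(object, ...) {
  df <- tidy(object)
  df$residue_i <- factor(df$residue_i, levels = object$residues)
  df$residue_j <- factor(df$residue_j, levels = object$residues)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_i, y = .data$residue_j,
                                   fill = .data$distance)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "min distance (nm)", direction = -1) +
    ggplot2::labs(x = NULL, y = NULL)
}
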