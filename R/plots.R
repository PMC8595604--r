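# matrix -> long tibble for raster plotting
raster_tibble <- function(m, pitch = 1) {
  n1 <- nrow(m); n2 <- ncol(m)
  tibble(
    x = rep((seq_len(n1) - (n1 / 2 + 1)) * pitch, times = n2),
    y = rep((seq_len(n2) - (n2 / 2 + 1)) * pitch, each = n1),
    value = as.vector(m)
  )
}

#' Plot a pupil or focal field
#'
#' Raster of amplitude or phase over the grid (NA units on the pupil
#' plane, micrometres on the focal plane).
#'
#' @param object A `pupil_field`.
#' @param what `"amplitude"`, `"phase"`, or `"intensity"`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pupil_field <- function(object, what = c("amplitude", "phase", "intensity"),
                                 ...) {
  what <- match.arg(what)
  m <- switch(what,
              amplitude = Mod(object$values),
              intensity = Mod(object$values)^2,
              phase = wrap_phase(Arg(object$values)))
  pitch <- if (object$plane == "pupil") {
    2 * na_edge(object$config) / object$config$grid_n
  } else focal_pitch(object$config)
  unit <- if (object$plane == "pupil") "NA" else "µm"
  ggplot2::ggplot(raster_tibble(m, pitch),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = what) +
    ggplot2::labs(x = paste0("x (", unit, ")"), y = paste0("y (", unit, ")"),
                  title = sprintf("%s plane %s", object$plane, what)) +
    ggplot2::theme_minimal()
}

#' Plot an axial (XZ) section of a PSF volume
#'
#' @param object A `psf_volume`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.psf_volume <- function(object, ...) {
  d <- dim(object$values)
  xz <- object$values[, d[2] %/% 2 + 1, ]
  df <- tibble(
    x = rep((seq_len(d[1]) - (d[1] / 2 + 1)) * object$pitch_lateral,
            times = d[3]),
    z = rep(object$z_planes, each = d[1]),
    value = as.vector(xz)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$x, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "signal") +
    ggplot2::labs(x = "z (µm)", y = "x (µm)",
                  title = sprintf("axial section (%s-photon)", object$excitation)) +
    ggplot2::theme_minimal()
}

#' Plot a tuning curve fit
#'
#' Per-direction mean responses with the fitted bimodal Gaussian overlaid.
#'
#' @param object A `tuning_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tuning_fit <- function(object, ...) {
  p <- ggplot2::ggplot(object$data,
                       ggplot2::aes(x = .data$direction, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "grating direction (deg)", y = "response (ΔF/F₀)") +
    ggplot2::theme_minimal()
  if (object$converged) {
    e <- object$estimate
    grid <- tibble(direction = seq(0, 360, by = 2))
    grid$response <- tuning_curve(grid$direction, e$r_offset, e$r_pref,
                                  e$r_oppo, e$theta_pref, e$sigma)
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p
}

#' Plot a mode-sensitivity scan
#'
#' Peak-signal ratios per Zernike mode, grouped by azimuthal index class.
#'
#' @param scan Tibble from [mode_sensitivity_scan()].
#' @return A ggplot object.
#' @export
plot_mode_sensitivity <- function(scan) {
  scan$mode <- sprintf("Z(%d,%d)", scan$n, scan$m)
  scan$m_class <- ifelse(abs(scan$m) <= 1, "|m| ≤ 1", "|m| ≥ 2")
  ggplot2::ggplot(scan, ggplot2::aes(
    x = stats::reorder(.data$mode, .data$n * 100 + .data$m),
    y = .data$peak_ratio, fill = .data$m_class)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = NULL, y = "two-photon peak ratio", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
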