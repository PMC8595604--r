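#' Wrap phase values to (-pi, pi]
#'
#' Single phase-wrap convention used repo-wide. [slm_export()] maps the
#' equivalent [0, 2*pi) interval linearly onto 8-bit levels 0..255.
#'
#' @param phase Numeric vector/matrix of phases in radians.
#' @return Wrapped phases in (-pi, pi].
#' @export
wrap_phase <- function(phase) {
  out <- (phase + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Quantize a phase map to 8-bit SLM levels
#'
#' Maps phase (any wrap) to integer levels: `round(phase mod 2pi / 2pi * 256) mod 256`.
#'
#' @param phase Phase matrix in radians.
#' @return Integer matrix of levels in 0..255.
#' @export
slm_export <- function(phase) {
  lev <- round((phase %% (2 * pi)) / (2 * pi) * 256) %% 256
  storage.mode(lev) <- "integer"
  lev
}

#' Compute the focal-plane corrective phase pattern for a Bessel focus
#'
#' The core pipeline: a measured pupil-plane corrective wavefront (waves)
#' is truncated to the objective pupil disk, decomposed into the first
#' `n_modes` Zernike modes, tip/tilt/defocus are removed (tip/tilt would
#' walk the ring illumination off the physical annular mask; defocus would
#' skew the axial profile), the smooth rebuilt wavefront is given the
#' annular amplitude of the mask, and the complex field is Fourier
#' propagated to the focal plane. The phase of that focal field - the
#' amplitude is discarded, since the focal-plane SLM is phase-only - is the
#' corrective pattern that both generates and corrects the Bessel focus.
#' The pattern is validated automatically by [validate_focal_pattern()].
#'
#' @param pupil_wavefront Real matrix (`grid_n` square), corrective
#'   wavefront in waves on the pupil plane. May be segmented/discontinuous;
#'   a large fit residual is recorded as a warning in the bundle.
#' @param mask An [annular_mask()].
#' @param config An [optical_config()].
#' @param n_modes Zernike modes used for smoothing (default 55).
#' @param residual_warn Residual RMS (waves) above which a warning is
#'   stored in the bundle (default 0.1).
#' @return An object of class `correction_bundle`: list with
#'   `input_wavefront`, `fit` (a `zernike_fit`), `edited_coefficients`,
#'   `smooth_wavefront`, `masked_pupil` (`pupil_field`), `focal_phase`
#'   (matrix, wrapped to (-pi, pi]), `validation` (tibble from
#'   [validate_focal_pattern()]), `warnings` (character), plus `mask` and
#'   `config`.
#' @examples
#' cfg <- optical_config(grid_n = 128)
#' w <- 0.5 * zernike_surface(3, 3, cfg)
#' bundle <- compute_focal_correction(w, annular_mask(config = cfg), cfg)
#' bundle$validation
#' @export
compute_focal_correction <- function(pupil_wavefront, mask, config,
                                     n_modes = 55, residual_warn = 0.1) {
  stopifnot(all(dim(pupil_wavefront) == c(config$grid_n, config$grid_n)))
  mask <- derive_annulus_na(mask, config)
  warnings <- character(0)

  # truncate to the pupil disk, then smooth with the modal fit
  disk <- pupil_disk_mask(config)
  truncated <- pupil_wavefront
  truncated[!disk] <- 0
  fit <- fit_zernike(truncated, config, n_modes = n_modes)
  if (fit$residual_rms > residual_warn) {
    warnings <- c(warnings, sprintf(
      "Zernike fit residual RMS %.3g waves exceeds %.3g (segmented input?)",
      fit$residual_rms, residual_warn))
  }
  edited <- remove_modes(fit, c("tip", "tilt", "defocus"))
  smooth <- zernike_reconstruct(edited, config)

  # annular amplitude x corrective phase, propagated to the focal plane
  pupil <- make_pupil_grid(config)
  pupil <- apply_annulus(pupil, mask)
  pupil <- apply_wavefront(pupil, smooth)
  focal <- propagate(pupil, "pupil_to_focal")
  focal_phase <- wrap_phase(Arg(focal$values))

  validation <- validate_focal_pattern(focal_phase, mask, smooth, config)

  structure(
    list(input_wavefront = pupil_wavefront,
         fit = fit,
         edited_coefficients = edited,
         smooth_wavefront = smooth,
         masked_pupil = pupil,
         focal_phase = focal_phase,
         validation = validation,
         warnings = warnings,
         mask = mask,
         config = config),
    class = "correction_bundle"
  )
}

#' @export
print.correction_bundle <- function(x, ...) {
  cat("<correction_bundle>\n")
  cat(sprintf("  annulus NA %.3f-%.3f; fit residual RMS %.3g waves\n",
              x$mask$na_inner, x$mask$na_outer, x$fit$residual_rms))
  cat(sprintf("  validation: containment %.3f (vs ideal %.3f), phase agreement %.3f\n",
              x$validation$containment, x$validation$containment_ideal,
              x$validation$phase_agreement))
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Validate a focal-plane pattern by inverse propagation
#'
#' Back-propagates the phase-only pattern (uniform amplitude across the
#' grid, `exp(i * pattern)`) to the pupil plane and measures how well it
#' replicates (a) the annular amplitude - the fraction of pupil-plane
#' energy landing inside the ring - and (b) the corrective phase within
#' the ring, as the intensity-weighted circular agreement
#' `|sum w exp(i(phi_rec - phi_exp))| / sum w`, which is 1 for perfect
#' replication up to a global phase and ~0 for unrelated phases.
#' The ideal containment (same statistic for the pattern computed from a
#' zero wavefront) is reported alongside for reference.
#'
#' @param pattern Real phase matrix (radians) on the focal plane.
#' @param mask An [annular_mask()].
#' @param expected_wavefront Real matrix (waves) expected inside the ring.
#' @param config An [optical_config()].
#' @param containment_ideal Optional precomputed ideal containment; when
#'   `NULL` it is computed from the zero-wavefront pattern.
#' @return One-row tibble: `containment`, `containment_ideal`,
#'   `containment_ratio`, `phase_agreement`, `centroid_offset_px`.
#' @export
validate_focal_pattern <- function(pattern, mask, expected_wavefront, config,
                                   containment_ideal = NULL) {
  mask <- derive_annulus_na(mask, config)
  ring <- annulus_mask_logical(mask, config)

  back <- new_pupil_field(exp(1i * pattern), config, plane = "focal")
  back <- propagate(back, "focal_to_pupil")
  inten <- Mod(back$values)^2
  containment <- sum(inten[ring]) / sum(inten)

  # energy centroid of the recovered pupil illumination, in pixels
  ax <- seq_len(config$grid_n) - (config$grid_n / 2 + 1)
  cx <- sum(matrix(ax, length(ax), length(ax)) * inten) / sum(inten)
  cy <- sum(t(matrix(ax, length(ax), length(ax))) * inten) / sum(inten)

  w <- inten[ring]
  dphi <- Arg(back$values)[ring] - 2 * pi * expected_wavefront[ring]
  phase_agreement <- Mod(sum(w * exp(1i * dphi))) / sum(w)

  if (is.null(containment_ideal)) {
    ideal <- ideal_axicon_containment(mask, config)
  } else {
    ideal <- containment_ideal
  }

  tibble(containment = containment,
         containment_ideal = ideal,
         containment_ratio = containment / ideal,
         phase_agreement = phase_agreement,
         centroid_offset_px = sqrt(cx^2 + cy^2))
}

# Containment of the zero-aberration (pure Bessel-generating) pattern,
# cached per (mask NAs, grid) within a session.
ideal_axicon_containment <- local({
  cache <- new.env(parent = emptyenv())
  function(mask, config) {
    key <- paste(signif(mask$na_inner, 8), signif(mask$na_outer, 8),
                 config$grid_n, config$pupil_oversampling, config$na_objective)
    if (!is.null(cache[[key]])) return(cache[[key]])
    pupil <- apply_annulus(make_pupil_grid(config), mask)
    focal <- propagate(pupil, "pupil_to_focal")
    pat <- wrap_phase(Arg(focal$values))
    ring <- annulus_mask_logical(mask, config)
    back <- propagate(new_pupil_field(exp(1i * pat), config, "focal"),
                      "focal_to_pupil")
    inten <- Mod(back$values)^2
    val <- sum(inten[ring]) / sum(inten)
    cache[[key]] <- val
    val
  }
})
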