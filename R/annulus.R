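#' Annular mask specification
#'
#' Physical transmissive annular mask placed in a plane conjugate to the
#' objective back pupil. The inner/outer diameters at the mask plane are
#' mapped to numerical apertures at the pupil through the relay-lens
#' magnification and the objective pupil radius; see [derive_annulus_na()].
#'
#' Defaults are the hardware mask modelled throughout: inner diameter
#' 1.015 mm, outer diameter 1.2 mm.
#'
#' @param inner_diameter,outer_diameter Mask diameters in mm at the mask
#'   plane; `0 < inner < outer`.
#' @param config Optional [optical_config()]; when supplied the derived NAs
#'   are computed immediately.
#' @return An object of class `annular_mask`.
#' @examples
#' annular_mask(config = optical_config())
#' @export
annular_mask <- function(inner_diameter = 1.015, outer_diameter = 1.2,
                         config = NULL) {
  if (!(inner_diameter > 0 && outer_diameter > inner_diameter)) {
    stop("need 0 < inner_diameter < outer_diameter", call. = FALSE)
  }
  spec <- structure(
    list(inner_diameter = inner_diameter, outer_diameter = outer_diameter,
         magnification_to_pupil = NA_real_,
         na_inner = NA_real_, na_outer = NA_real_),
    class = "annular_mask"
  )
  if (!is.null(config)) spec <- derive_annulus_na(spec, config)
  spec
}

#' Nominal-NA annulus
#'
#' Convenience constructor for an idealized annulus given directly in NA
#' units (e.g. a thin ring for analytic comparisons), bypassing the mask
#' geometry.
#'
#' @param na_inner,na_outer Numerical apertures of the ring edges.
#' @return An `annular_mask` with the NAs set and no physical diameters.
#' @examples
#' thin_annulus(0.4) # 5%-wide ring centred on NA 0.4
#' @export
#' @rdname annular_mask_na
annular_mask_na <- function(na_inner, na_outer) {
  stopifnot(na_inner >= 0, na_outer > na_inner)
  structure(
    list(inner_diameter = NA_real_, outer_diameter = NA_real_,
         magnification_to_pupil = NA_real_,
         na_inner = na_inner, na_outer = na_outer),
    class = "annular_mask"
  )
}

#' @param na_center Ring centre in NA units.
#' @param rel_width Full ring width as a fraction of `na_center`.
#' @export
#' @rdname annular_mask_na
thin_annulus <- function(na_center = 0.4, rel_width = 0.05) {
  half <- na_center * rel_width / 2
  annular_mask_na(na_center - half, na_center + half)
}

#' @export
print.annular_mask <- function(x, ...) {
  cat("<annular_mask>\n")
  if (!is.na(x$inner_diameter)) {
    cat(sprintf("  mask plane : %.3f / %.3f mm diameters\n",
                x$inner_diameter, x$outer_diameter))
  }
  if (!is.na(x$na_inner)) {
    cat(sprintf("  pupil NA   : %.4f - %.4f", x$na_inner, x$na_outer))
    if (!is.na(x$magnification_to_pupil)) {
      cat(sprintf(" (relay magnification %.4f)", x$magnification_to_pupil))
    }
    cat("\n")
  }
  invisible(x)
}

#' Map the physical mask onto pupil numerical apertures
#'
#' The mask radii are magnified by the relay chain (product of f2/f1 over
#' lens pairs from mask to pupil) and divided by the objective back-pupil
#' radius ([pupil_radius_mm()]) to give the annulus NAs:
#' `na = na_objective * radius_mm * magnification / pupil_radius_mm`.
#'
#' @param mask An [annular_mask()].
#' @param config An [optical_config()].
#' @return The mask with `magnification_to_pupil`, `na_inner`, `na_outer`
#'   filled in. Errors if the annulus would exceed the objective pupil.
#' @examples
#' derive_annulus_na(annular_mask(), optical_config())
#' @export
derive_annulus_na <- function(mask, config) {
  if (is.na(mask$inner_diameter)) {
    return(mask) # nominal-NA annulus: nothing to derive
  }
  mag <- relay_magnification(config)
  r_pupil <- pupil_radius_mm(config)
  mask$magnification_to_pupil <- mag
  mask$na_inner <- config$na_objective * (mask$inner_diameter / 2 * mag) / r_pupil
  mask$na_outer <- config$na_objective * (mask$outer_diameter / 2 * mag) / r_pupil
  if (mask$na_outer > config$na_objective + 1e-9) {
    stop("annulus exceeds the objective pupil NA", call. = FALSE)
  }
  mask
}

#' Impose the annular amplitude mask on a pupil field
#'
#' Zeroes the amplitude outside `[na_inner, na_outer]`; phase inside the
#' ring is untouched. Idempotent.
#'
#' @param field A `pupil_field` on the pupil plane.
#' @param mask An `annular_mask` with NAs derived (or derivable from the
#'   field's config).
#' @return A `pupil_field`.
#' @export
apply_annulus <- function(field, mask) {
  mask <- derive_annulus_na(mask, field$config)
  r <- na_grids(field$config)$r
  keep <- r >= mask$na_inner & r <= mask$na_outer
  if (!any(keep)) {
    stop("annulus empty after discretization; increase grid_n", call. = FALSE)
  }
  field$values[!keep] <- 0 + 0i
  field
}

# Logical ring mask on the grid
annulus_mask_logical <- function(mask, config) {
  mask <- derive_annulus_na(mask, config)
  r <- na_grids(config)$r
  r >= mask$na_inner & r <= mask$na_outer
}

#' Concentric binary phase grating (axicon analogue)
#'
#' The SLM pattern that generates a Bessel focus without aberration
#' correction: concentric rings alternating between phase 0 and pi with a
#' fixed radial period, which diffracts most energy into the +/-1 orders
#' forming a ring at the mask plane.
#'
#' @param period_px Radial period in pixels per cycle (>= 4).
#' @param grid_n Pattern side in pixels.
#' @return An object of class `binary_axicon`: list with `phase` (matrix of
#'   0 / pi), `period_px`, `grid_n`.
#' @examples
#' pat <- binary_axicon(22.5, 256)
#' mean(pat$phase > 0) # ~0.5 duty cycle
#' @export
binary_axicon <- function(period_px = 22.5, grid_n = 1152L) {
  if (period_px < 4) {
    stop("period_px < 4 under-samples the grating", call. = FALSE)
  }
  grid_n <- as.integer(grid_n)
  idx <- seq_len(grid_n) - (grid_n / 2 + 1)
  r <- sqrt(outer(idx^2, idx^2, "+"))
  phase <- ifelse((r / (period_px / 2)) %% 2 >= 1, pi, 0)
  structure(list(phase = phase, period_px = period_px, grid_n = grid_n),
            class = "binary_axicon")
}

#' @export
print.binary_axicon <- function(x, ...) {
  cat(sprintf("<binary_axicon> %d px, period %.1f px/cycle, pi-fraction %.3f\n",
              x$grid_n, x$period_px, mean(x$phase > 0)))
  invisible(x)
}
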