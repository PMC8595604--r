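#' Optical system configuration
#'
#' Bundles the physical parameters of the two-photon microscope model: the
#' excitation wavelength, immersion refractive index, objective numerical
#' aperture and magnification, tube-lens focal length, the relay-lens chain
#' between the annular-mask plane and the objective back pupil, and the
#' numerical sampling of the pupil grid.
#'
#' Defaults describe the instrument modelled throughout the package: 940 nm
#' excitation, a 25x / 1.05-NA water-dipping objective (n = 1.33) with a
#' 200-mm tube lens, and the relay chain 750/350, 30/30, 30/150 and
#' 120/240 mm from mask to pupil.
#'
#' The pupil is sampled on a `grid_n` x `grid_n` Cartesian grid whose edge
#' sits at `pupil_oversampling * na_objective` in NA units, so the pupil
#' disk diameter is `grid_n / pupil_oversampling` pixels and the focal-plane
#' pixel pitch after a discrete Fourier transform is
#' `wavelength / (2 * pupil_oversampling * na_objective)` micrometres.
#'
#' @param wavelength Excitation wavelength in micrometres.
#' @param n_medium Immersion refractive index.
#' @param na_objective Objective numerical aperture; must be below `n_medium`.
#' @param objective_magnification Nominal objective magnification.
#' @param tube_lens_focal Tube-lens focal length in mm; with the
#'   magnification it sets the back-pupil radius
#'   `na_objective * tube_lens_focal / objective_magnification`.
#' @param relay_focals Numeric vector, even length: focal lengths (mm) of the
#'   relay-lens pairs in order from the mask plane to the pupil plane. Each
#'   consecutive pair (f1, f2) contributes magnification f2/f1.
#' @param grid_n Pixels per side of the square pupil grid (even).
#' @param pupil_oversampling Zero-padding factor: ratio of grid-edge NA to
#'   `na_objective`. Must be >= 1.
#' @return An object of class `optical_config` (a named list).
#' @examples
#' cfg <- optical_config()
#' cfg$na_objective
#' pupil_radius_mm(cfg)
#' @export
optical_config <- function(wavelength = 0.94,
                           n_medium = 1.33,
                           na_objective = 1.05,
                           objective_magnification = 25,
                           tube_lens_focal = 200,
                           relay_focals = c(750, 350, 30, 30, 30, 150, 120, 240),
                           grid_n = 256L,
                           pupil_oversampling = 2) {
  stopifnot(wavelength > 0, n_medium > 0)
  if (na_objective <= 0 || na_objective >= n_medium) {
    stop("`na_objective` must satisfy 0 < NA < n_medium", call. = FALSE)
  }
  grid_n <- as.integer(grid_n)
  if (grid_n < 16L || grid_n %% 2L != 0L) {
    stop("`grid_n` must be an even integer >= 16", call. = FALSE)
  }
  if (pupil_oversampling < 1) {
    stop("`pupil_oversampling` must be >= 1", call. = FALSE)
  }
  if (length(relay_focals) %% 2L != 0L || any(relay_focals <= 0)) {
    stop("`relay_focals` must be positive and given in pairs", call. = FALSE)
  }
  structure(
    list(
      wavelength = wavelength,
      n_medium = n_medium,
      na_objective = na_objective,
      objective_magnification = objective_magnification,
      tube_lens_focal = tube_lens_focal,
      relay_focals = relay_focals,
      grid_n = grid_n,
      pupil_oversampling = pupil_oversampling
    ),
    class = "optical_config"
  )
}

#' @export
print.optical_config <- function(x, ...) {
  cat("<optical_config>\n")
  cat(sprintf("  wavelength   : %.3f um\n", x$wavelength))
  cat(sprintf("  medium index : %.3f\n", x$n_medium))
  cat(sprintf("  objective    : %gx / %.2f NA, tube lens %g mm\n",
              x$objective_magnification, x$na_objective, x$tube_lens_focal))
  cat(sprintf("  pupil radius : %.2f mm; relay magnification %.4f\n",
              pupil_radius_mm(x), relay_magnification(x)))
  cat(sprintf("  grid         : %d px, oversampling %gx (disk %g px across)\n",
              x$grid_n, x$pupil_oversampling, x$grid_n / x$pupil_oversampling))
  invisible(x)
}

#' Back-pupil radius of the objective in millimetres
#'
#' `na_objective * tube_lens_focal / objective_magnification`.
#'
#' @param config An [optical_config()].
#' @return Pupil radius in mm.
#' @export
pupil_radius_mm <- function(config) {
  config$na_objective * config$tube_lens_focal / config$objective_magnification
}

#' Relay magnification from the mask plane to the objective pupil
#'
#' Product of f2/f1 over consecutive relay-lens pairs in `relay_focals`.
#'
#' @param config An [optical_config()].
#' @return Dimensionless magnification.
#' @export
relay_magnification <- function(config) {
  f <- config$relay_focals
  prod(f[seq(2, length(f), by = 2)] / f[seq(1, length(f), by = 2)])
}

#' Read or write an optical configuration as JSON or YAML
#'
#' The file holds the fields of [optical_config()] by name; format is chosen
#' from the file extension (`.json`, `.yaml`/`.yml`).
#'
#' @param path File path.
#' @return `read_optical_config()` returns an [optical_config()];
#'   `write_optical_config()` returns `path` invisibly.
#' @export
read_optical_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lst <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  known <- names(formals(optical_config))
  do.call(optical_config, lst[intersect(names(lst), known)])
}

#' @rdname read_optical_config
#' @param config An [optical_config()] to write.
#' @export
write_optical_config <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  lst <- unclass(config)
  switch(ext,
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml = yaml::write_yaml(lst, path),
    stop("unsupported config format: ", ext, call. = FALSE)
  )
  invisible(path)
}
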