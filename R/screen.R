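#' Thin sample-aberration phase screen
#'
#' Sample-induced aberrations arise inside the specimen, displaced axially
#' from both the pupil and the focal plane. This helper builds a smooth
#' Zernike-shaped phase screen on the focal-plane (sample-space) grid:
#' the polynomial spans a disk of radius `radius_um` and is held at its
#' rim value outside, in radians. Pair it with
#' [apply_sample_screen()], which places the screen at an axial distance
#' `z_um` from the focus by propagating the field there and back with the
#' Debye defocus kernel.
#'
#' @param config An [optical_config()].
#' @param n,m Zernike indices of the screen shape.
#' @param waves Peak amplitude in waves.
#' @param radius_um Screen disk radius in micrometres; choose it
#'   comparable to the beam footprint at the screen's axial position.
#' @return Phase matrix (radians) on the focal grid.
#' @export
sample_screen <- function(config, n, m, waves, radius_um) {
  N <- config$grid_n
  ax <- (seq_len(N) - (N / 2 + 1)) * focal_pitch(config)
  x <- matrix(ax, N, N); y <- t(x)
  rho <- pmin(sqrt(x^2 + y^2) / radius_um, 1)
  th <- atan2(y, x)
  az <- if (m > 0) cos(m * th) else if (m < 0) sin(-m * th) else 1
  2 * pi * waves * zernike_radial(n, m, rho) * az
}

#' Insert a phase screen at an axial plane in sample space
#'
#' Propagates a pupil-plane field to the plane `z_um` above the focus
#' (Debye defocus kernel + Fourier transform), multiplies by the screen
#' phase, and propagates back to the pupil. The returned pupil field
#' carries both the phase and the amplitude distortion the screen imprints
#' - the distortion a phase-only pupil corrector cannot undo.
#'
#' @param field A `pupil_field` on the pupil plane.
#' @param screen Phase matrix (radians) from [sample_screen()].
#' @param z_um Axial distance of the screen from the focal plane (um).
#' @return A `pupil_field` on the pupil plane.
#' @export
apply_sample_screen <- function(field, screen, z_um) {
  stopifnot(field$plane == "pupil")
  ker <- debye_kernels(field$config)
  phase_z <- exp(1i * ker$kz * z_um)
  v <- field$values * phase_z
  at_screen <- fft2_centered(v)
  back <- fft2_centered(at_screen * exp(1i * screen), inverse = TRUE)
  field$values <- back * Conj(phase_z)
  field
}

#' Compare pupil-plane and focal-plane AO against a displaced sample screen
#'
#' Reproduces the motivating contrast for focal-plane correction of Bessel
#' foci: a phase screen displaced from the pupil distorts both the phase
#' and the amplitude of the annular field, and a phase-only correction at
#' the pupil repairs only the phase part, while the focal-plane corrective
#' pattern computed from the same measured wavefront recovers more of the
#' two-photon peak.
#'
#' The default measured wavefront mimics Gaussian-beam pupil sensing: the
#' Zernike-smoothed pupil phase of the screen-distorted full-pupil beam.
#' That default is only valid while the distorted pupil phase stays within
#' half a wave of flat (no unwrapping is attempted); for stronger screens
#' supply `w_meas` explicitly, e.g. from [reconstruct_wavefront()].
#'
#' @param screen Phase matrix (radians) from [sample_screen()].
#' @param z_um Axial position of the screen (um from focus).
#' @param config An [optical_config()].
#' @param mask An [annular_mask()].
#' @param n_modes Modes for the wavefront smoothing (default 55).
#' @param w_meas Optional measured pupil wavefront (matrix, waves); when
#'   `NULL` it is sensed numerically as described above.
#' @return One-row tibble of two-photon Bessel peaks normalized to the
#'   screen-free system: `no_ao`, `pupil_ao`, `focal_ao`.
#' @export
compare_correction_strategies <- function(screen, z_um, config,
                                          mask = annular_mask(config = config),
                                          n_modes = 55, w_meas = NULL) {
  mask <- derive_annulus_na(mask, config)
  if (is.null(w_meas)) {
    # sense: full-pupil beam through the screen, smoothed pupil phase
    sensed <- apply_sample_screen(make_pupil_grid(config), screen, z_um)
    disk <- pupil_disk_mask(config)
    wf <- matrix(0, config$grid_n, config$grid_n)
    wf[disk] <- Arg(sensed$values)[disk] / (2 * pi)
    w_meas <- zernike_reconstruct(fit_zernike(wf, config, n_modes), config)
  }

  ideal <- compute_focal_correction(matrix(0, config$grid_n, config$grid_n),
                                    mask, config)
  focal <- compute_focal_correction(-w_meas, mask, config)

  launch <- function(pattern, pupil_phase_waves = NULL, with_screen = TRUE) {
    p <- propagate(new_pupil_field(exp(1i * pattern), config, "focal"),
                   "focal_to_pupil")
    p <- apply_annulus(p, mask)
    if (!is.null(pupil_phase_waves)) p <- apply_wavefront(p, pupil_phase_waves)
    if (with_screen) p <- apply_sample_screen(p, screen, z_um)
    zs <- z_search_grid(apply_annulus(make_pupil_grid(config), mask))
    peak_two_photon(p, zs)
  }
  ref <- launch(ideal$focal_phase, with_screen = FALSE)
  tibble(
    no_ao = launch(ideal$focal_phase) / ref,
    pupil_ao = launch(ideal$focal_phase, pupil_phase_waves = -w_meas) / ref,
    focal_ao = launch(focal$focal_phase) / ref
  )
}
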