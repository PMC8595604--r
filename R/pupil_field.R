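#' Complex field sampled on the objective back pupil
#'
#' A `pupil_field` stores a complex-valued square matrix sampled in NA
#' (numerical-aperture) units, together with its [optical_config()] and a
#' plane tag (`"pupil"` or `"focal"`). The grid is centred: the zero
#' coordinate sits at index `grid_n/2 + 1` so forward and inverse centred
#' FFTs round-trip exactly.
#'
#' @name pupil_field
NULL

new_pupil_field <- function(values, config, plane = "pupil") {
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  structure(
    list(values = values, config = config, plane = plane),
    class = "pupil_field"
  )
}

#' @export
print.pupil_field <- function(x, ...) {
  cat(sprintf("<pupil_field> %d x %d, plane = %s\n",
              nrow(x$values), ncol(x$values), x$plane))
  cat(sprintf("  energy %.4g; NA at grid edge %.3f\n",
              field_energy(x), na_edge(x$config)))
  invisible(x)
}

# NA value at the grid edge (half-width of the sampled NA square)
na_edge <- function(config) config$pupil_oversampling * config$na_objective

# Centred 1-D NA coordinate of the grid (zero at index N/2 + 1)
na_axis <- function(config) {
  n <- config$grid_n
  (seq_len(n) - (n / 2 + 1)) * (2 * na_edge(config) / n)
}

# Matrices of radial NA coordinate and azimuth over the grid
na_grids <- function(config) {
  ax <- na_axis(config)
  x <- matrix(ax, config$grid_n, config$grid_n)
  y <- t(x)
  list(x = x, y = y, r = sqrt(x^2 + y^2), theta = atan2(y, x))
}

# Logical mask of the objective pupil disk
pupil_disk_mask <- function(config) {
  na_grids(config)$r <= config$na_objective + 1e-12
}

# Fractional pixel coverage of the pupil disk (supersampled edge), for
# quadrature-accurate disk integrals.
disk_coverage <- function(config, supersample = 8) {
  g <- na_grids(config)
  dna <- 2 * na_edge(config) / config$grid_n
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample * dna
  cover <- matrix(0, config$grid_n, config$grid_n)
  for (a in offs) for (b in offs) {
    cover <- cover + (sqrt((g$x + a)^2 + (g$y + b)^2) <= config$na_objective)
  }
  cover / supersample^2
}

#' Focal-plane pixel pitch of the sampled system
#'
#' Lateral pixel size (micrometres) of the plane conjugate to the focal
#' plane, fixed by Fourier reciprocity of the pupil sampling:
#' `wavelength / (2 * pupil_oversampling * na_objective)`.
#'
#' @param config An [optical_config()].
#' @return Pitch in micrometres.
#' @export
focal_pitch <- function(config) {
  config$wavelength / (2 * na_edge(config))
}

#' Total energy of a sampled field
#'
#' Sum of squared moduli over the grid (pixel area taken as 1 grid unit, so
#' energy is preserved exactly by the unitary transform in [propagate()]).
#'
#' @param field A `pupil_field`.
#' @return Nonnegative scalar.
#' @export
field_energy <- function(field) {
  sum(Mod(field$values)^2)
}

#' Uniform unit-amplitude pupil field
#'
#' Builds the ideal back-pupil field: amplitude 1 and phase 0 inside the
#' `na_objective` disk, exactly zero outside. Errors if the disk would be
#' sampled by fewer than 8 pixels across.
#'
#' @param config An [optical_config()].
#' @return A `pupil_field` on the pupil plane.
#' @examples
#' p <- make_pupil_grid(optical_config(grid_n = 128))
#' field_energy(p) # = number of pixels in the disk
#' @export
make_pupil_grid <- function(config) {
  px_across <- config$grid_n / config$pupil_oversampling
  if (px_across < 8) {
    stop("grid_n too small to sample the pupil disk at this oversampling",
         call. = FALSE)
  }
  vals <- matrix(0 + 0i, config$grid_n, config$grid_n)
  vals[pupil_disk_mask(config)] <- 1 + 0i
  new_pupil_field(vals, config, plane = "pupil")
}

#' Apply a wavefront (in waves) as a phase factor to a pupil field
#'
#' Multiplies the field by `exp(2i * pi * wavefront)`; pixels outside the
#' pupil disk stay untouched (they are zero for masked fields).
#'
#' @param field A `pupil_field` on the pupil plane.
#' @param wavefront Real matrix of the same size, in waves.
#' @return A `pupil_field`.
#' @export
apply_wavefront <- function(field, wavefront) {
  stopifnot(all(dim(wavefront) == dim(field$values)))
  field$values <- field$values * exp(2i * pi * wavefront)
  field
}

#' Fourier propagation between pupil and focal planes
#'
#' Unitary centred discrete Fourier transform connecting the objective back
#' pupil and the plane conjugate to the focal plane. Energy is conserved
#' exactly (Parseval), and forward followed by inverse reproduces the input
#' to machine precision. The focal-plane pixel pitch is [focal_pitch()].
#'
#' @param field A `pupil_field` (either plane).
#' @param direction `"auto"` (toggle by plane tag), `"pupil_to_focal"`, or
#'   `"focal_to_pupil"`.
#' @return A `pupil_field` on the conjugate plane.
#' @export
propagate <- function(field,
                      direction = c("auto", "pupil_to_focal", "focal_to_pupil")) {
  direction <- match.arg(direction)
  if (direction == "auto") {
    direction <- if (field$plane == "pupil") "pupil_to_focal" else "focal_to_pupil"
  }
  inverse <- direction == "focal_to_pupil"
  field$values <- fft2_centered(field$values, inverse = inverse)
  field$plane <- if (inverse) "pupil" else "focal"
  field
}

# Centred unitary 2-D FFT: DC at (N/2+1, N/2+1) on both sides.
fft2_centered <- function(m, inverse = FALSE) {
  n <- nrow(m)
  if (n != ncol(m) || n %% 2L != 0L) {
    stop("field must be square with even side", call. = FALSE)
  }
  sh <- c((n / 2 + 1):n, 1:(n / 2)) # fftshift == ifftshift for even n
  out <- fft(m[sh, sh], inverse = inverse)[sh, sh] / n
  out
}
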