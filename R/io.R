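#' Read and write wavefront maps
#'
#' Wavefront maps (waves) travel either as whitespace-delimited text
#' matrices or as single-plane 32-bit TIFF. The format is chosen from the
#' extension: `.tif`/`.tiff` versus anything else (text). TIFF samples
#' use the fixed affine convention `stored = waves / 16 + 0.5` (i.e.
#' [0, 1] spans -8..+8 waves), so signed maps survive the round trip;
#' maps beyond +-8 waves are clipped with a warning. Text matrices carry
#' the values verbatim.
#'
#' @param path File path.
#' @return `read_wavefront()`: a numeric matrix.
#' @export
read_wavefront <- function(path) {
  if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
    return((unclass(m) - 0.5) * 16)
  }
  as.matrix(read.table(path))
}

#' @rdname read_wavefront
#' @param wavefront Numeric matrix in waves.
#' @export
write_wavefront <- function(wavefront, path) {
  if (tolower(tools::file_ext(path)) %in% c("tif", "tiff")) {
    if (max(abs(wavefront)) > 8) {
      warning("wavefront values beyond +-8 waves are clipped in TIFF output")
    }
    stored <- pmin(pmax(wavefront / 16 + 0.5, 0), 1)
    tiff::writeTIFF(stored, path, bits.per.sample = 32, reduce = FALSE)
  } else {
    write.table(format(wavefront, digits = 10), path,
                row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write Zernike coefficient tables as CSV
#'
#' Columns `n`, `m`, `waves`.
#'
#' @param path File path.
#' @return `read_zernike_csv()`: tibble with `mode`, `n`, `m`, `label`,
#'   `waves` in the package's fixed ordering (absent modes zero).
#' @export
read_zernike_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("n", "m", "waves") %in% names(df)))
  n_modes <- max(55, sum(seq_len(max(df$n) + 1)))
  out <- zernike_index_table(n_modes)
  out$waves <- 0
  idx <- match(paste(df$n, df$m), paste(out$n, out$m))
  if (anyNA(idx)) stop("invalid Zernike (n, m) pairs in file", call. = FALSE)
  out$waves[idx] <- df$waves
  out
}

#' @rdname read_zernike_csv
#' @param coefficients Tibble with columns `n`, `m`, `waves` (e.g. from
#'   [fit_zernike()]).
#' @export
write_zernike_csv <- function(coefficients, path) {
  if (inherits(coefficients, "zernike_fit")) {
    coefficients <- coefficients$coefficients
  }
  write.csv(coefficients[, c("n", "m", "waves")], path, row.names = FALSE)
  invisible(path)
}

#' Export a phase pattern as an 8-bit SLM TIFF
#'
#' Quantizes with [slm_export()] (0..2*pi across 256 levels) and writes an
#' 8-bit grayscale TIFF.
#'
#' @param phase Phase matrix in radians.
#' @param path Output path.
#' @export
write_slm_tiff <- function(phase, path) {
  lev <- slm_export(phase)
  tiff::writeTIFF(lev / 255, path, bits.per.sample = 8)
  invisible(path)
}

#' Read and write ROI traces as long-format CSV
#'
#' Columns `roi`, `frame`, `value`.
#'
#' @param path File path.
#' @return `read_traces_csv()`: tibble (`roi`, `frame`, `value`).
#' @export
read_traces_csv <- function(path) {
  df <- as_tibble(read.csv(path))
  stopifnot(all(c("roi", "frame", "value") %in% names(df)))
  df[, c("roi", "frame", "value")]
}

#' @rdname read_traces_csv
#' @param traces Tibble with `roi`, `frame`, `value`.
#' @export
write_traces_csv <- function(traces, path) {
  write.csv(as.data.frame(traces)[, c("roi", "frame", "value")], path,
            row.names = FALSE)
  invisible(path)
}

#' Export a PSF volume as a multi-page 32-bit TIFF
#'
#' One page per z-plane, values scaled to unit maximum.
#'
#' @param psf A `psf_volume`.
#' @param path Output path.
#' @export
write_psf_tiff <- function(psf, path) {
  v <- psf$values / max(psf$values)
  pages <- lapply(seq_len(dim(v)[3]), function(i) v[, , i])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}
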