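#' Acquisition protocol for a diffusion-weighted MRS experiment
#'
#' Bundles the diffusion weightings, per-b shot counts and timing/grid
#' parameters that define a dMRS acquisition. The default instance is a
#' STEAM-type protocol with nine b-values from 0.4 to 25.1 ms/um^2,
#' shot counts rising from 160 to 480 at high b (where attenuation makes
#' single shots noisier), gradient duration delta = 6 ms, diffusion time
#' Delta = 120 ms, 5 kHz spectral width and 4096 complex points.
#'
#' @param b_values Numeric vector of diffusion weightings (ms/um^2),
#'   strictly ascending.
#' @param shots_per_b Positive integer vector, one shot count per b-value.
#' @param delta Diffusion gradient duration (ms).
#' @param big_delta Diffusion time (ms).
#' @param spectral_width Receiver bandwidth (Hz).
#' @param n_points Number of complex time-domain points.
#' @param te Echo time (ms).
#' @param tm Mixing time (ms).
#' @param field_mhz Proton frequency (MHz); sets the Hz-per-ppm scale.
#' @param center_ppm Chemical shift at the center of the spectral window
#'   (ppm); the carrier sits on water.
#'
#' @return An object of class `dmrs_protocol` (a named list).
#' @examples
#' p <- acq_protocol()
#' p$b_values
#' @export
acq_protocol <- function(b_values = c(0.4, 1.5, 6.0, 7.6, 9.3, 13.3, 15.6, 20.8, 25.1),
                         shots_per_b = c(160L, 160L, 160L, 160L, 160L, 320L, 480L, 480L, 480L),
                         delta = 6,
                         big_delta = 120,
                         spectral_width = 5000,
                         n_points = 4096L,
                         te = 15,
                         tm = 112,
                         field_mhz = 400.2,
                         center_ppm = 4.7) {
  b_values <- as.numeric(b_values)
  shots_per_b <- as.integer(shots_per_b)
  if (length(b_values) == 0 || anyNA(b_values) || any(b_values < 0)) {
    stop("`b_values` must be non-negative and free of NA.", call. = FALSE)
  }
  if (is.unsorted(b_values, strictly = TRUE)) {
    stop("`b_values` must be strictly ascending.", call. = FALSE)
  }
  if (length(shots_per_b) != length(b_values)) {
    stop("`shots_per_b` must have one entry per b-value.", call. = FALSE)
  }
  if (any(shots_per_b < 1L)) stop("`shots_per_b` must be positive.", call. = FALSE)
  timings <- c(delta = delta, big_delta = big_delta, spectral_width = spectral_width,
               n_points = n_points, te = te, tm = tm, field_mhz = field_mhz)
  if (any(timings <= 0)) {
    stop("All protocol timings and grid parameters must be > 0.", call. = FALSE)
  }
  structure(
    list(
      b_values = b_values,
      shots_per_b = shots_per_b,
      delta = delta,
      big_delta = big_delta,
      spectral_width = spectral_width,
      n_points = as.integer(n_points),
      te = te,
      tm = tm,
      field_mhz = field_mhz,
      center_ppm = center_ppm
    ),
    class = "dmrs_protocol"
  )
}

#' @export
print.dmrs_protocol <- function(x, ...) {
  cat("<dmrs_protocol>\n")
  cat("  b-values (ms/um^2):", paste(format(x$b_values), collapse = ", "), "\n")
  cat("  shots per b:       ", paste(x$shots_per_b, collapse = ", "), "\n")
  cat(sprintf("  delta/Delta: %g/%g ms, TE/TM: %g/%g ms\n", x$delta, x$big_delta, x$te, x$tm))
  cat(sprintf("  grid: %d pts @ %g Hz (%.1f ppm span at %.1f MHz)\n",
              x$n_points, x$spectral_width, x$spectral_width / x$field_mhz, x$field_mhz))
  invisible(x)
}

#' Chemical-shift axis of a protocol's spectral grid
#'
#' Spectra in this package are stored in frequency order (negative to
#' positive offset from the carrier after an fftshift), so the returned
#' ppm axis is ascending.
#'
#' @param protocol A [acq_protocol()] object.
#' @return Numeric vector of length `n_points`, ppm at each spectral sample.
#' @export
ppm_axis <- function(protocol) {
  n <- protocol$n_points
  f <- (seq_len(n) - 1 - n %/% 2) * protocol$spectral_width / n
  protocol$center_ppm + f / protocol$field_mhz
}

#' Time axis (s) of a protocol's FID grid
#' @param protocol A [acq_protocol()] object.
#' @return Numeric vector of length `n_points`, seconds.
#' @export
time_axis <- function(protocol) {
  (seq_len(protocol$n_points) - 1) / protocol$spectral_width
}

# FID -> fftshifted spectrum (columns = shots). No 1/N scaling: a unit
# time-domain amplitude gives a spectral integral of ~1 x n_points bins.
spec_from_fid <- function(fid) {
  if (is.matrix(fid)) {
    sh <- nrow(fid) %/% 2
    s <- stats::mvfft(fid)
    s[c((sh + 1):nrow(s), 1:sh), , drop = FALSE]
  } else {
    sh <- length(fid) %/% 2
    s <- stats::fft(fid)
    s[c((sh + 1):length(s), 1:sh)]
  }
}

# Inverse of spec_from_fid.
fid_from_spec <- function(spec) {
  if (is.matrix(spec)) {
    n <- nrow(spec)
    sh <- n - n %/% 2
    s <- spec[c((sh + 1):n, 1:sh), , drop = FALSE]
    stats::mvfft(s, inverse = TRUE) / n
  } else {
    n <- length(spec)
    sh <- n - n %/% 2
    s <- spec[c((sh + 1):n, 1:sh)]
    stats::fft(s, inverse = TRUE) / n
  }
}

# Logical mask for a ppm window on the protocol grid.
ppm_mask <- function(protocol, ppm_lo, ppm_hi) {
  ax <- ppm_axis(protocol)
  ax >= ppm_lo & ax <= ppm_hi
}
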