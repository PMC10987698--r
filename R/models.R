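#' Powder-averaged signal of randomly oriented sticks
#'
#' Orientation average of one-dimensional Gaussian diffusion along sticks
#' (neurites, astrocytic processes) distributed isotropically:
#' \deqn{S/S_0 = \sqrt{\pi / (4 b D_{intra})}\, \mathrm{erf}(\sqrt{b D_{intra}})}
#' which equals the orientation integral
#' \eqn{\int_0^1 \exp(-b D_{intra} u^2)\, du}. The limit at `b = 0` is 1.
#'
#' @param b Diffusion weighting (ms/um^2), non-negative; vectorized.
#' @param d_intra Intra-stick diffusivity (um^2/ms), > 0; vectorized.
#' @return Unitless signal fraction in (0, 1].
#' @examples
#' sticks_attenuation(c(0, 1, 25.1), 0.3)
#' @export
sticks_attenuation <- function(b, d_intra) {
  if (any(b < 0)) stop("`b` must be non-negative.", call. = FALSE)
  if (any(d_intra <= 0)) stop("`d_intra` must be > 0.", call. = FALSE)
  x <- b * d_intra
  out <- numeric(length(x))
  # series around x = 0: erf(sqrt(x)) * sqrt(pi/(4x)) = 1 - x/3 + x^2/10 - ...
  small <- x < 1e-6
  out[small] <- 1 - x[small] / 3 + x[small]^2 / 10
  xl <- x[!small]
  out[!small] <- sqrt(pi / (4 * xl)) * pracma::erf(sqrt(xl))
  out
}

# First zero of erf in the upper-right complex quadrant, by Newton iteration.
# Cached after first evaluation; |erf(z1)| < 1e-12 is asserted.
erf_first_zero <- local({
  z1 <- NULL
  function() {
    if (!is.null(z1)) return(z1)
    z <- complex(real = 1.45, imaginary = 1.88)
    for (i in 1:60) {
      step <- pracma::erfz(z) / (2 / sqrt(pi) * exp(-z^2))
      z <- z - step
      if (Mod(step) < 1e-15) break
    }
    stopifnot(Mod(pracma::erfz(z)) < 1e-12)
    z1 <<- z
    z1
  }
})

#' Radius of convergence of the cumulant expansion for sticks diffusion
#'
#' Under the randomly-oriented-sticks model the cumulant series of the
#' log-signal in b converges only up to
#' \eqn{b_c = |z_1|^2 / D}, where \eqn{z_1} is the first zero of the error
#' function in the complex plane (found here by Newton iteration;
#' \eqn{|z_1|^2 \approx 5.6422}). With an assumed diffusivity of
#' 0.3 um^2/ms this gives about 19 ms/um^2.
#'
#' @param d_assumed Assumed diffusivity (um^2/ms), > 0.
#' @return b_c in ms/um^2.
#' @examples
#' radius_of_convergence(0.3) # ~18.8, rounds to 19
#' @export
radius_of_convergence <- function(d_assumed) {
  if (any(d_assumed <= 0)) stop("`d_assumed` must be > 0.", call. = FALSE)
  Mod(erf_first_zero())^2 / d_assumed
}

#' Characteristic two-dimensional diffusion length
#'
#' \eqn{\ell = \sqrt{4 D \Delta}}: the root-mean-square displacement over
#' the diffusion time in two dimensions, used to relate measured metabolite
#' diffusivities to cellular length scales.
#'
#' @param d Diffusivity (um^2/ms), >= 0.
#' @param big_delta Diffusion time (ms), > 0.
#' @return Length in um.
#' @examples
#' diffusion_length(0.15, 120) # ~8.5 um
#' @export
diffusion_length <- function(d, big_delta) {
  if (any(d < 0)) stop("`d` must be non-negative.", call. = FALSE)
  if (any(big_delta <= 0)) stop("`big_delta` must be > 0.", call. = FALSE)
  sqrt(4 * d * big_delta)
}

#' Restrict a b-value grid to the cumulant convergence radius
#'
#' Applies the `b <= b_c` cutoff used when fitting the kurtosis expansion,
#' with b_c rounded to 3 significant figures before the comparison so the
#' cutoff is stable against floating-point noise in the grid.
#'
#' @param b_values Numeric vector of b-values (ms/um^2).
#' @param d_assumed Assumed diffusivity used to compute b_c (um^2/ms).
#' @return The retained (ascending) b-values.
#' @examples
#' b_within_convergence(acq_protocol()$b_values, 0.3) # drops 20.8 and 25.1
#' @export
b_within_convergence <- function(b_values, d_assumed = 0.3) {
  bc <- signif(radius_of_convergence(d_assumed), 3)
  sort(b_values[b_values <= bc])
}
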