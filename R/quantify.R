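# Polynomial baseline columns on the fit window: orthogonal (Legendre-like)
# polynomials of a scaled coordinate in [-1, 1].
baseline_columns <- function(n, order) {
  if (order < 0) return(NULL)
  x <- seq(-1, 1, length.out = n)
  cols <- stats::poly(x, degree = max(order, 1), raw = FALSE)
  out <- cbind(1 / sqrt(n), cols[, seq_len(order), drop = FALSE])
  unname(out[, seq_len(order + 1), drop = FALSE])
}

# Fine frequency/phase estimate in the time domain (spectral-registration
# style): the phase of data x conj(template) is ~ phi + 2 pi f t; solve the
# weighted linear regression with the product magnitude as weight. Exact
# for matched templates, used to polish the coarse cross-correlation pass.
est_fine_fp <- function(spec, tmpl, protocol) {
  v <- fid_from_spec(spec)
  u <- fid_from_spec(tmpl)
  z <- v * Conj(u)
  w <- Mod(z)
  ph <- Arg(z)
  t <- time_axis(protocol)
  sw <- sum(w); swt <- sum(w * t); swtt <- sum(w * t^2)
  swp <- sum(w * ph); swtp <- sum(w * t * ph)
  det <- sw * swtt - swt^2
  if (!is.finite(det) || det <= 0) return(c(freq = 0, phase = 0))
  slope <- (sw * swtp - swt * swp) / det
  inter <- (swtt * swp - swt * swtp) / det
  c(freq = slope / (2 * pi), phase = inter)
}

# Align an averaged spectrum to the basis grid against a template:
# frequency by magnitude cross-correlation (sub-bin), zero-order phase
# from the complex inner product. Removes the common-mode drift that
# per-shot alignment to the block median cannot see. The template starts
# as the equal-weight metabolite sum and is refined from the fitted
# composition by fit_spectrum(), which removes the composition-mismatch
# bias of a one-shot template estimate.
align_to_template <- function(spectrum, tmpl, protocol,
                              window = c(1.8, 4.2), max_shift_hz = 25) {
  idx <- which(ppm_mask(protocol, window[1], window[2]))
  df <- protocol$spectral_width / protocol$n_points
  max_lag <- max(1L, ceiling(max_shift_hz / df))
  fshift <- est_freq_bins(Mod(tmpl), cbind(Mod(spectrum)), idx, max_lag) * df
  t <- time_axis(protocol)
  spec <- as.vector(apply_freq_correction(cbind(spectrum), fshift, t))
  phase <- Arg(sum(spec[idx] * Conj(tmpl[idx])))
  list(spectrum = spec * exp(-1i * phase), freq_hz = fshift, phase_rad = phase)
}

#' Relative Cramer-Rao lower bounds for a linear spectral model
#'
#' For the linear model `y = A x + noise` with i.i.d. Gaussian noise of SD
#' `noise_sd`, the Fisher information is `A'A / sigma^2`; the CRLB of each
#' amplitude is the square root of the corresponding diagonal element of
#' `sigma^2 (A'A)^{-1}`, reported relative to the amplitude in percent.
#' Zero amplitudes yield an infinite relative CRLB (flagged, not NaN).
#'
#' @param design Real design matrix (rows = spectral points, columns =
#'   fitted components).
#' @param noise_sd Noise standard deviation (> 0).
#' @param amplitudes Fitted amplitudes, one per column.
#' @return Relative CRLB in percent, one per column.
#' @export
crlb <- function(design, noise_sd, amplitudes) {
  if (noise_sd <= 0) stop("`noise_sd` must be > 0.", call. = FALSE)
  if (length(amplitudes) != ncol(design)) {
    stop("One amplitude per design column is required.", call. = FALSE)
  }
  cov <- noise_sd^2 * solve(crossprod(design))
  sd_abs <- sqrt(pmax(diag(cov), 0))
  ifelse(amplitudes > 0, 100 * sd_abs / amplitudes, Inf)
}

#' Linear-combination fit of a spectrum against a basis set
#'
#' Fits the real part of the (aligned) spectrum over the fit window as a
#' non-negative linear combination of the metabolite and macromolecule
#' basis spectra plus a smooth polynomial baseline (unconstrained sign),
#' by non-negative least squares. Amplitude CRLBs are computed for the
#' linear model conditional on the fixed lineshape.
#'
#' @param spectrum Complex spectrum on the basis grid.
#' @param basis A [make_basis()] basis set.
#' @param noise_sd Noise SD of the real channel of `spectrum`; if `NULL`,
#'   estimated as the SD of the real part over `noise_window`.
#' @param baseline_order Polynomial baseline order (>= 0; `-1` disables).
#' @param fit_window ppm range used for fitting.
#' @param noise_window Signal-free ppm range for the noise estimate.
#' @param align If `TRUE`, frequency/phase-align the spectrum to the basis
#'   before fitting.
#' @return Object of class `dmrs_quant`: `table` (tibble metabolite,
#'   amplitude, crlb_pct), `mm_amplitude`, `residual_rms`, `fitted_snr`,
#'   `noise_sd`, alignment estimates.
#' @export
fit_spectrum <- function(spectrum, basis, noise_sd = NULL,
                         baseline_order = 2, fit_window = c(0.2, 4.3),
                         noise_window = c(8.5, 10.5), align = TRUE) {
  protocol <- basis$protocol
  if (length(spectrum) != protocol$n_points) {
    stop("Spectrum and basis are on different grids.", call. = FALSE)
  }
  freq_hz <- 0; phase_rad <- 0
  if (is.null(noise_sd)) {
    nw <- ppm_mask(protocol, noise_window[1], noise_window[2])
    if (sum(nw) < 16) {
      stop("Noise window [", noise_window[1], ", ", noise_window[2],
           "] ppm has too few points on this grid; pass `noise_sd` or widen it.",
           call. = FALSE)
    }
    noise_sd <- stats::sd(Re(spectrum)[nw])
  }
  idx <- which(ppm_mask(protocol, fit_window[1], fit_window[2]))
  comp_names <- colnames(basis$spectra)
  A_comp <- Re(basis$spectra[idx, , drop = FALSE])
  qrA <- qr(A_comp)
  if (qrA$rank < ncol(A_comp)) {
    cors <- suppressWarnings(stats::cor(A_comp))
    diag(cors) <- 0
    worst <- which(abs(cors) == max(abs(cors), na.rm = TRUE), arr.ind = TRUE)[1, ]
    stop("Basis is rank-deficient; most collinear pair: ",
         comp_names[worst[1]], " and ", comp_names[worst[2]], ".", call. = FALSE)
  }
  B <- baseline_columns(length(idx), baseline_order)
  nb <- if (is.null(B)) 0 else ncol(B)
  # sign-split baseline columns so NNLS leaves them unconstrained
  A_nn <- if (is.null(B)) A_comp else cbind(A_comp, B, -B)
  solve_nnls <- function(spec) {
    y <- Re(spec)[idx]
    x <- pracma::lsqnonneg(A_nn, y)$x
    amps <- x[seq_along(comp_names)]
    base_coef <- if (nb > 0) {
      x[length(comp_names) + seq_len(nb)] - x[length(comp_names) + nb + seq_len(nb)]
    } else numeric(0)
    fitted <- as.vector(A_comp %*% amps) +
      if (nb > 0) as.vector(B %*% base_coef) else 0
    list(amps = amps, base_coef = base_coef, resid = y - fitted)
  }
  if (align) {
    # pass 1: equal-weight metabolite template; then refine the template
    # from the fitted composition and re-align, which converges to an
    # unbiased phase/frequency on basis-matched data
    tmpl <- rowSums(basis$spectra[, basis$metabolites, drop = FALSE])
    t <- time_axis(protocol)
    for (pass in 1:8) {
      if (pass == 1) {
        # coarse: magnitude cross-correlation, robust to multi-bin shifts
        al <- align_to_template(spectrum, tmpl, protocol)
        spectrum <- al$spectrum
        dfp <- c(freq = al$freq_hz, phase = al$phase_rad)
      } else {
        # fine: time-domain linear-phase polish against the fitted template
        dfp <- est_fine_fp(spectrum, tmpl, protocol)
        spectrum <- as.vector(apply_freq_correction(cbind(spectrum), dfp["freq"], t)) *
          exp(-1i * dfp["phase"])
      }
      freq_hz <- freq_hz + dfp["freq"]
      phase_rad <- phase_rad + dfp["phase"]
      sol <- solve_nnls(spectrum)
      tmpl <- as.vector(basis$spectra %*% sol$amps)
      if (pass > 1 && abs(dfp["freq"]) < 1e-5 && abs(dfp["phase"]) < 1e-7) break
    }
    freq_hz <- unname(freq_hz); phase_rad <- unname(phase_rad)
  } else {
    sol <- solve_nnls(spectrum)
  }
  amps <- sol$amps; base_coef <- sol$base_coef; resid <- sol$resid
  design_full <- if (is.null(B)) A_comp else cbind(A_comp, B)
  crlbs <- if (noise_sd > 0) {
    crlb(design_full, noise_sd, c(amps, base_coef))[seq_along(comp_names)]
  } else {
    rep(0, length(comp_names))
  }
  met <- seq_along(basis$metabolites)
  structure(
    list(
      table = tibble::tibble(metabolite = basis$metabolites,
                             amplitude = amps[met],
                             crlb_pct = crlbs[met]),
      mm_amplitude = amps[length(comp_names)],
      baseline_coef = base_coef,
      residual_rms = sqrt(mean(resid^2)),
      fitted_snr = if (noise_sd > 0) {
        max(Re(spectrum)[ppm_mask(protocol, 1.8, 4.2)]) / noise_sd
      } else Inf,
      noise_sd = noise_sd,
      freq_hz = freq_hz,
      phase_rad = phase_rad
    ),
    class = "dmrs_quant"
  )
}

#' @export
print.dmrs_quant <- function(x, ...) {
  cat("<dmrs_quant> residual RMS", format(x$residual_rms, digits = 4),
      "| SNR", format(x$fitted_snr, digits = 3), "\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.dmrs_quant <- function(x, ...) x$table

#' @export
glance.dmrs_quant <- function(x, ...) {
  tibble::tibble(residual_rms = x$residual_rms, fitted_snr = x$fitted_snr,
                 noise_sd = x$noise_sd, mm_amplitude = x$mm_amplitude,
                 freq_hz = x$freq_hz, phase_rad = x$phase_rad)
}

#' Quantify a table of averaged spectra
#'
#' Runs [fit_spectrum()] on every row of an averaged-spectra table and
#' returns the tidy long contract consumed by the diffusion module.
#'
#' @param spectra Averaged tibble from [average_shots()].
#' @param basis Basis set.
#' @param ... Passed to [fit_spectrum()].
#' @return Tibble with columns animal, week, b_value, metabolite,
#'   amplitude, crlb_pct (plus residual_rms and fitted_snr per spectrum).
#' @export
quantify_spectra <- function(spectra, basis, ...) {
  purrr::map_dfr(seq_len(nrow(spectra)), function(i) {
    q <- fit_spectrum(spectra$spectrum[[i]], basis, ...)
    dplyr::mutate(q$table,
                  animal = spectra$animal[i], week = spectra$week[i],
                  b_value = spectra$b_value[i],
                  residual_rms = q$residual_rms, fitted_snr = q$fitted_snr,
                  .before = 1)
  })
}

#' CRLB-based metabolite filtering
#'
#' Applies the reporting rules used for in vivo metabolite quality
#' control, selecting metabolite names (never individual values):
#' * `mode = "mrs"` — retain a metabolite iff its relative CRLB is below
#'   25% at week 0 for every animal (a purposely loose criterion that
#'   keeps low-concentration metabolites);
#' * `mode = "dmrs"` — retain iff the relative CRLB is below 6% at the
#'   lowest b-value for every animal (strict, to limit error propagation
#'   into the diffusion fits).
#' Both thresholds are strict (`<`): a CRLB exactly at the threshold
#' excludes the metabolite.
#'
#' @param quant Tidy quantification table (animal, week, b_value,
#'   metabolite, crlb_pct).
#' @param mode `"mrs"` or `"dmrs"`.
#' @param threshold Override of the mode's default threshold (percent).
#' @return Character vector of retained metabolite names.
#' @export
filter_metabolites <- function(quant, mode = c("dmrs", "mrs"), threshold = NULL) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- if (mode == "mrs") 25 else 6
  animals <- unique(quant$animal)
  if (mode == "mrs") {
    sub <- quant[quant$week == "week0", ]
    if (nrow(sub) == 0) stop("No week0 rows for the MRS CRLB rule.", call. = FALSE)
  } else {
    if (!"b_value" %in% names(quant) || all(is.na(quant$b_value))) {
      stop("dMRS filtering needs b_value coverage.", call. = FALSE)
    }
    sub <- quant[quant$b_value == min(quant$b_value), ]
  }
  miss <- setdiff(animals, unique(sub$animal))
  if (length(miss) > 0) {
    stop("Missing coverage for animal(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- sub |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(ok = all(.data$crlb_pct < threshold), .groups = "drop")
  sort(keep$metabolite[keep$ok])
}
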