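# Frequency-shift estimate by magnitude-spectrum cross-correlation against
# a reference, over a contiguous window `idx`, searching +/- max_lag bins
# with parabolic sub-bin interpolation. Returns shifts in bins.
est_freq_bins <- function(mag_ref, mag_shots, idx, max_lag) {
  n <- nrow(mag_shots)
  lags <- -max_lag:max_lag
  lags <- lags[idx[1] + lags >= 1 & idx[length(idx)] + lags <= n]
  r <- mag_ref[idx]
  cc <- vapply(lags, function(l) {
    as.vector(crossprod(mag_shots[idx + l, , drop = FALSE], r))
  }, numeric(ncol(mag_shots)))
  cc <- matrix(cc, nrow = ncol(mag_shots)) # shots x lags
  best <- max.col(cc, ties.method = "first")
  shift <- numeric(ncol(mag_shots))
  for (s in seq_len(ncol(mag_shots))) {
    j <- best[s]
    if (j > 1 && j < length(lags)) {
      y0 <- cc[s, j - 1]; y1 <- cc[s, j]; y2 <- cc[s, j + 1]
      denom <- y0 - 2 * y1 + y2
      d <- if (abs(denom) > 0) 0.5 * (y0 - y2) / denom else 0
      d <- max(min(d, 0.5), -0.5)
      shift[s] <- lags[j] + d
    } else {
      shift[s] <- lags[j]
    }
  }
  shift
}

# A shot is "shifted by +f Hz" when its spectral content sits f Hz above
# the reference; the estimator returns that +f, and the correction
# multiplies the FID by exp(-2i pi f t).
apply_freq_correction <- function(spec, freq_hz, t) {
  fids <- fid_from_spec(spec)
  ramp <- exp(outer(-2i * pi * t, freq_hz))
  spec_from_fid(fids * ramp)
}

# Slope/intercept of a per-shot phase series via unit phasors: the slope
# comes from the mean increment phasor (robust to 2*pi wraps), the
# intercept from the mean de-trended phasor.
phasor_trend <- function(phase, ok) {
  idx <- seq_along(phase) - 1
  z <- exp(1i * phase[ok])
  if (sum(ok) < 2) return(rep(0, length(phase)))
  slope <- Arg(mean(z[-1] * Conj(z[-length(z)])))
  inter <- Arg(mean(z * exp(-1i * slope * idx[ok])))
  inter + slope * idx
}

#' Correct per-shot phase and frequency drifts
#'
#' For each b-value block, every shot is aligned to the pointwise median
#' spectrum of its block (median of real and imaginary parts — robust to
#' dropout shots): the frequency offset is estimated per shot by
#' cross-correlating magnitude spectra over a reference ppm window to the
#' nearest spectral bin, then polished sub-bin — together with the
#' zero-order phase — by locating the spectral peak of the time-domain
#' cross-signal against the leave-one-out mean shot (a matched-filter
#' estimate that approaches the single-shot information limit). Because
#' scanner drift is slow, the
#' applied correction is by default the linear-in-shot-index trend fitted
#' through the raw per-shot estimates (`smooth = "linear"`; the phase
#' trend is fitted on unit phasors, robust to wrapping). This keeps the
#' estimation noise of individual low-SNR shots — which would otherwise
#' scramble the average at strong diffusion weighting — out of the
#' correction, while the raw estimates are still reported per shot.
#' `smooth = "none"` applies the raw estimates. All-zero shots are
#' flagged and left untouched.
#'
#' @param shot_table Shot table (tibble with `shots` list-column and
#'   attribute `"protocol"`).
#' @param ref_window ppm window used for estimation.
#' @param max_shift_hz Frequency search half-range (Hz).
#' @param smooth `"linear"` (default) or `"none"`; how raw estimates map
#'   to the applied correction.
#' @return List with `shots` (corrected table) and `estimates` (tibble:
#'   animal, week, b_value, shot_index, freq_hz, phase_rad — raw
#'   estimates; freq_applied, phase_applied — corrections actually
#'   applied; flagged).
#' @export
correct_drifts <- function(shot_table, ref_window = c(1.8, 4.2),
                           max_shift_hz = 25, smooth = c("linear", "none")) {
  smooth <- match.arg(smooth)
  protocol <- attr(shot_table, "protocol")
  if (is.null(protocol)) stop("Shot table lacks a protocol attribute.", call. = FALSE)
  t <- time_axis(protocol)
  df <- protocol$spectral_width / protocol$n_points
  idx <- which(ppm_mask(protocol, ref_window[1], ref_window[2]))
  max_lag <- max(1L, ceiling(max_shift_hz / df))
  est_all <- vector("list", nrow(shot_table))
  for (i in seq_len(nrow(shot_table))) {
    spec <- shot_table$shots[[i]]
    n_shots <- ncol(spec)
    if (n_shots < 2) stop("Drift correction needs >= 2 shots per b-value.", call. = FALSE)
    flagged <- colSums(Mod(spec)) == 0
    # the median reference is only ever used inside the estimation window
    # (plus the lag margin), so restrict the row medians to it
    ridx <- max(1L, idx[1] - max_lag):min(nrow(spec), idx[length(idx)] + max_lag)
    ref <- rep(0i, nrow(spec))
    ref[ridx] <- complex(real = apply(Re(spec[ridx, , drop = FALSE]), 1, stats::median),
                         imaginary = apply(Im(spec[ridx, , drop = FALSE]), 1, stats::median))
    ok <- !flagged
    sidx <- seq_len(n_shots) - 1
    # coarse per-shot frequency from magnitude cross-correlation over the
    # reference window, taken to the nearest spectral bin ...
    kbins <- round(est_freq_bins(Mod(ref), Mod(spec), idx, max_lag))
    kbins[flagged] <- 0
    coarse <- kbins * df
    # an integer-bin shift in frequency is an exact modulation in time
    fids <- fid_from_spec(spec)
    fids[, ok] <- fids[, ok, drop = FALSE] *
      exp(outer(-2i * pi * t, coarse[ok]))
    # ... polished per shot against the leave-one-out mean of the
    # coarse-aligned shots. The cross-signal Z(t) = shot x conj(reference)
    # carries the residual offset as a phase ramp exp(2i pi df t); the
    # offset is located as the peak of |FFT(Z)| (zero-padded, parabolic
    # sub-bin interpolation — a matched-filter estimate), and the
    # zero-order phase as the phase of the de-ramped sum of Z. The FID
    # noise tail is excluded: it carries no phase information but would
    # dominate the estimate's variance. Full FIDs are used rather than
    # spectrally windowed ones, whose window-edge terms corrupt the
    # early-time phase ramp.
    S <- rowSums(fids[, ok, drop = FALSE])
    Z <- fids * Conj(S - fids) # per-column scale is irrelevant
    Z[, flagged] <- 0i
    env <- Mod(S)
    Z[env < 0.05 * max(env), ] <- 0i
    np <- nrow(Z)
    pad <- 2L * np
    C <- stats::mvfft(rbind(Z, matrix(0i, pad - np, n_shots)))
    mag <- Mod(C)
    i0 <- max.col(t(mag), ties.method = "first")
    im <- ifelse(i0 == 1, pad, i0 - 1)
    ip <- ifelse(i0 == pad, 1, i0 + 1)
    cix <- function(ii) mag[cbind(ii, seq_len(n_shots))]
    y0 <- cix(im); y1 <- cix(i0); y2 <- cix(ip)
    den <- y0 - 2 * y1 + y2
    dd <- ifelse(abs(den) > 0, pmax(pmin(0.5 * (y0 - y2) / den, 0.5), -0.5), 0)
    k <- i0 - 1
    k <- ifelse(k > pad / 2, k - pad, k)
    fine <- (k + dd) * protocol$spectral_width / pad
    fine[flagged] <- 0
    phase <- Arg(colSums(Z * exp(outer(-2i * pi * t, fine))))
    freq <- coarse + fine
    freq[flagged] <- NA_real_
    phase[flagged] <- NA_real_
    freq_app <- if (smooth == "linear" && sum(ok) >= 2) {
      co <- stats::coef(stats::lm(freq[ok] ~ sidx[ok]))
      co[1] + co[2] * sidx
    } else freq
    phase_app <- if (smooth == "linear") {
      phasor_trend(ifelse(is.na(phase), 0, phase), ok)
    } else phase
    freq_app[flagged] <- NA_real_
    phase_app[flagged] <- NA_real_
    if (any(ok)) {
      # fids already carry the coarse shift; apply the remainder
      fids[, ok] <- fids[, ok, drop = FALSE] *
        exp(outer(-2i * pi * t, freq_app[ok] - coarse[ok]))
      fids[, ok] <- sweep(fids[, ok, drop = FALSE], 2,
                          exp(-1i * phase_app[ok]), `*`)
      spec[, ok] <- spec_from_fid(fids[, ok, drop = FALSE])
    }
    shot_table$shots[[i]] <- spec
    est_all[[i]] <- tibble::tibble(
      animal = shot_table$animal[i], week = shot_table$week[i],
      b_value = shot_table$b_value[i], shot_index = seq_len(n_shots) - 1L,
      freq_hz = freq, phase_rad = phase,
      freq_applied = freq_app, phase_applied = phase_app, flagged = flagged
    )
  }
  list(shots = shot_table, estimates = dplyr::bind_rows(est_all))
}

# Magnitude-spectrum integral over the metabolite window, per shot.
shot_integrals <- function(spec, protocol, window) {
  idx <- which(ppm_mask(protocol, window[1], window[2]))
  colSums(Mod(spec[idx, , drop = FALSE]))
}

#' Reject outlier shots with manifest signal drops
#'
#' A shot is removed when its magnitude-spectrum integral over the
#' metabolite window falls below `(1 - drop_threshold)` times the median
#' integral of the shots at the same b-value — i.e. by default when it has
#' lost strictly more than 50% of its signal. A shot at exactly the
#' threshold is retained. If more than half of the shots at any b-value
#' would be removed, the block is considered unusable and an error is
#' raised (a defensive invariant: the median reference itself caps the
#' removable fraction at one half).
#'
#' @param shot_table Shot table.
#' @param drop_threshold Fractional signal drop beyond which a shot is
#'   rejected (default 0.5).
#' @param window ppm window of the signal integral.
#' @return List with `shots` (retained) and `report` (tibble: animal,
#'   week, b_value, n_shots, n_removed, removed list-column).
#' @export
reject_outliers <- function(shot_table, drop_threshold = 0.5,
                            window = c(0.5, 4.2)) {
  protocol <- attr(shot_table, "protocol")
  if (is.null(protocol)) stop("Shot table lacks a protocol attribute.", call. = FALSE)
  rep_all <- vector("list", nrow(shot_table))
  for (i in seq_len(nrow(shot_table))) {
    spec <- shot_table$shots[[i]]
    if (ncol(spec) < 3) stop("Outlier rejection needs >= 3 shots.", call. = FALSE)
    ints <- shot_integrals(spec, protocol, window)
    med <- stats::median(ints)
    removed <- which(ints < (1 - drop_threshold) * med)
    if (length(removed) > ncol(spec) / 2) {
      stop(sprintf(
        "More than half of the shots at b = %g would be rejected; data unusable.",
        shot_table$b_value[i]), call. = FALSE)
    }
    if (length(removed) > 0) {
      shot_table$shots[[i]] <- spec[, -removed, drop = FALSE]
    }
    rep_all[[i]] <- tibble::tibble(
      animal = shot_table$animal[i], week = shot_table$week[i],
      b_value = shot_table$b_value[i], n_shots = ncol(spec),
      n_removed = length(removed), removed = list(as.integer(removed) - 1L)
    )
  }
  list(shots = shot_table, report = dplyr::bind_rows(rep_all))
}

#' Average retained shots into one spectrum per b-value
#'
#' @param shot_table Shot table (after correction/rejection).
#' @return Tibble with columns animal, week, b_value, `spectrum`
#'   (list-column of complex vectors) and `n_shots` (effective shot count
#'   for noise bookkeeping); protocol carried in the attribute.
#' @export
average_shots <- function(shot_table) {
  protocol <- attr(shot_table, "protocol")
  out <- purrr::map_dfr(seq_len(nrow(shot_table)), function(i) {
    spec <- shot_table$shots[[i]]
    if (is.null(spec) || ncol(spec) < 1) {
      stop("No shots to average at b = ", shot_table$b_value[i], call. = FALSE)
    }
    tibble::tibble(
      animal = shot_table$animal[i], week = shot_table$week[i],
      b_value = shot_table$b_value[i],
      spectrum = list(rowMeans(spec)),
      n_shots = ncol(spec)
    )
  })
  attr(out, "protocol") <- protocol
  out
}

#' Full preprocessing chain: correct, reject, average
#'
#' @param shot_table Shot table.
#' @param drop_threshold Passed to [reject_outliers()].
#' @param ref_window Passed to [correct_drifts()].
#' @return List with `spectra` (averaged tibble), `drift_estimates`,
#'   `rejection_report`.
#' @export
preprocess_shots <- function(shot_table, drop_threshold = 0.5,
                             ref_window = c(1.8, 4.2)) {
  cd <- correct_drifts(shot_table, ref_window = ref_window)
  ro <- reject_outliers(cd$shots, drop_threshold = drop_threshold)
  list(spectra = average_shots(ro$shots),
       drift_estimates = cd$estimates,
       rejection_report = ro$report)
}
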