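noisy_truth <- function() ground_truth(phase_drift = 0, freq_drift = 0, dropout_p = 0)

test_that("clean identical shots yield zero drift estimates", {
  st <- simulate_shots(test_protocol(8L), test_basis(), truth_conc(), truth_d(),
                       clean_truth(), seed = 1)
  cd <- correct_drifts(st)
  expect_lt(max(abs(cd$estimates$freq_hz)), 1e-6)
  expect_lt(max(abs(cd$estimates$phase_rad)), 1e-6)
})

test_that("an injected frequency offset is recovered at default SNR", {
  p <- test_protocol(16L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       noisy_truth(), seed = 4)[1, ]
  attr(st, "protocol") <- p
  t <- time_axis(p)
  # single-shot estimate: shift shot 5 by +2 Hz; the per-shot estimator
  # works at the single-shot information limit (sigma ~ 0.4 Hz at this
  # per-shot SNR), so the check allows three such sigmas
  st$shots[[1]][, 5] <- as.vector(
    dwmrs:::apply_freq_correction(st$shots[[1]][, 5, drop = FALSE], -2, t))
  est <- correct_drifts(st, smooth = "none")$estimates
  expect_equal(est$freq_hz[5], 2, tolerance = 1.2)
  expect_lt(max(abs(est$freq_hz[-5])), 1.2)

  # block-level: a cumulative 0.25 Hz/shot drift (4 Hz over the block) is
  # recovered by the applied trend-smoothed correction; shot-to-shot
  # averaging brings the slope error well under the single-shot limit
  tr2 <- ground_truth(freq_drift = 0.25, phase_drift = 0, dropout_p = 0)
  st2 <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                        tr2, seed = 4)[1, ]
  attr(st2, "protocol") <- p
  est2 <- correct_drifts(st2)$estimates
  slope <- stats::coef(stats::lm(freq_applied ~ shot_index, data = est2))[2]
  expect_lt(abs(unname(slope) - 0.25), 0.06)
})

test_that("an injected 30-degree phase on one shot is recovered at default SNR", {
  p <- test_protocol(16L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       noisy_truth(), seed = 5)[1, ]
  attr(st, "protocol") <- p
  st$shots[[1]][, 3] <- st$shots[[1]][, 3] * exp(1i * 30 * pi / 180)
  est <- correct_drifts(st)$estimates
  expect_equal(est$phase_rad[3] * 180 / pi, 30, tolerance = 3)
})

test_that("drift correction is idempotent", {
  p <- test_protocol(16L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       ground_truth(dropout_p = 0), seed = 6)
  cd1 <- correct_drifts(st)
  cd2 <- correct_drifts(cd1$shots)
  # the second pass should find (and apply) essentially no residual drift
  expect_lt(max(abs(cd2$estimates$freq_applied)), 0.2)
  expect_lt(max(abs(cd2$estimates$phase_applied)), 0.05)
})

test_that("all-zero shots are flagged and left uncorrected", {
  st <- simulate_shots(test_protocol(8L), test_basis(), truth_conc(), truth_d(),
                       clean_truth(), seed = 1)[1, ]
  attr(st, "protocol") <- test_protocol(8L)
  st$shots[[1]][, 2] <- 0i
  est <- correct_drifts(st)$estimates
  expect_true(est$flagged[2])
  expect_true(is.na(est$freq_hz[2]))
})

test_that("shots below the signal-drop threshold are removed, boundary retained", {
  p <- test_protocol(8L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       clean_truth(), seed = 1)[1, ]
  attr(st, "protocol") <- p
  st$shots[[1]][, 2] <- 0.4 * st$shots[[1]][, 2]  # 60% drop -> removed
  st$shots[[1]][, 4] <- 0.5 * st$shots[[1]][, 4]  # exactly 50% -> retained
  ro <- reject_outliers(st)
  expect_equal(ro$report$removed[[1]], 1L) # 0-based index of shot 2
  expect_equal(ncol(ro$shots$shots[[1]]), 7)
})

test_that("equal shots produce no rejections and rejection is order-invariant", {
  p <- test_protocol(8L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       noisy_truth(), seed = 7)[1, ]
  attr(st, "protocol") <- p
  ro <- reject_outliers(st)
  expect_equal(ro$report$n_removed, 0L)
  # permute shots; the retained set must be the same shots
  st2 <- st
  perm <- c(3, 1, 4, 2, 8, 7, 5, 6)
  st2$shots[[1]] <- st$shots[[1]][, perm]
  st2$shots[[1]][, 1] <- 0.2 * st2$shots[[1]][, 1] # drop shot (orig 3)
  st3 <- st2
  perm2 <- rev(seq_len(8))
  st3$shots[[1]] <- st2$shots[[1]][, perm2]
  r2 <- reject_outliers(st2)
  r3 <- reject_outliers(st3)
  expect_equal(r2$report$n_removed, 1L)
  expect_equal(r3$report$n_removed, 1L)
  expect_equal(sort(Mod(colSums(r2$shots$shots[[1]]))),
               sort(Mod(colSums(r3$shots$shots[[1]]))), tolerance = 1e-12)
})

test_that("rejection is capped at half the shots by the median reference", {
  # with a median-referenced threshold at most half the shots can sit
  # below it; exactly half must pass without tripping the unusable-data
  # guard, and a majority of corrupted shots drags the median down so the
  # block survives rather than being silently gutted
  p <- test_protocol(8L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       clean_truth(), seed = 1)[1, ]
  attr(st, "protocol") <- p
  st$shots[[1]][, 1:4] <- 0.1 * st$shots[[1]][, 1:4]
  ro <- reject_outliers(st)
  expect_equal(ro$report$n_removed, 4L)
  st$shots[[1]][, 5] <- 0.1 * st$shots[[1]][, 5]
  ro2 <- reject_outliers(st)
  expect_equal(ro2$report$n_removed, 0L)
})

test_that("averaging identical shots returns the shot and tracks shot counts", {
  p <- test_protocol(8L)
  st <- simulate_shots(p, test_basis(p), truth_conc(), truth_d(),
                       clean_truth(), seed = 1)
  av <- average_shots(st)
  expect_equal(av$spectrum[[1]], st$shots[[1]][, 1], tolerance = 1e-12)
  expect_equal(av$n_shots, rep(8L, 9))
})

test_that("averaging reduces noise like 1/sqrt(N)", {
  p <- test_protocol(16L)
  basis <- test_basis(p)
  clean <- average_shots(simulate_shots(p, basis, truth_conc(), truth_d(),
                                        clean_truth(), seed = 1))$spectrum[[1]]
  sds <- sapply(1:20, function(s) {
    st <- simulate_shots(p, basis, truth_conc(), truth_d(), noisy_truth(),
                         seed = 100 + s)
    av <- average_shots(st)$spectrum[[1]]
    stats::sd(Re(av - clean))
  })
  noise_shot <- attr(simulate_shots(p, basis, truth_conc(), truth_d(),
                                    noisy_truth(), seed = 1), "noise_sd")
  expected <- noise_shot * sqrt(p$n_points) / sqrt(16)
  expect_equal(mean(sds), expected, tolerance = 0.1)
})

test_that("preprocessing artifact-laden data matches the artifact-free chain within 2%", {
  p <- test_protocol(24L)
  basis <- test_basis(p)
  artifacts <- ground_truth(noise_sd = 0) # default drift/dropout, no noise
  st_art <- simulate_shots(p, basis, truth_conc(), truth_d(), artifacts, seed = 9)
  st_clean <- simulate_shots(p, basis, truth_conc(), truth_d(), clean_truth(), seed = 9)
  q_art <- quantify_spectra(preprocess_shots(st_art)$spectra, basis)
  q_clean <- quantify_spectra(average_shots(st_clean), basis)
  j <- dplyr::inner_join(q_art, q_clean, by = c("b_value", "metabolite"))
  expect_lt(max(abs(j$amplitude.x / j$amplitude.y - 1)), 0.02)
})
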