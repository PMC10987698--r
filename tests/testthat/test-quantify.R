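clean_avg_spectrum <- function(p = test_protocol(), b = 0.4, conc = truth_conc(),
                               d = truth_d()) {
  basis <- test_basis(p)
  amps <- dwmrs:::component_amplitudes(basis, conc)
  att <- dwmrs:::attenuation_vector(basis, amps, b, d, ground_truth())
  truth <- (amps * att)[seq_along(basis$metabolites)]
  names(truth) <- basis$metabolites
  list(spec = as.vector(basis$spectra %*% (amps * att)),
       truth = truth, basis = basis)
}

test_that("a noiseless basis-matched spectrum is recovered to better than 0.1%", {
  cs <- clean_avg_spectrum()
  q <- fit_spectrum(cs$spec, cs$basis, noise_sd = 1e-8)
  expect_equal(q$table$amplitude, unname(cs$truth), tolerance = 1e-3 / 10)
})

test_that("doubling all concentrations doubles all amplitudes", {
  cs1 <- clean_avg_spectrum()
  cs2 <- clean_avg_spectrum(conc = 2 * truth_conc())
  q1 <- fit_spectrum(cs1$spec, cs1$basis, noise_sd = 1e-8)
  q2 <- fit_spectrum(cs2$spec, cs2$basis, noise_sd = 1e-8)
  expect_equal(q2$table$amplitude, 2 * q1$table$amplitude, tolerance = 1e-6)
})

test_that("CRLB matches the closed form for one isolated resonance", {
  p <- test_protocol()
  basis <- make_basis("NAA", p, linewidth = 6)
  idx <- which(dwmrs:::ppm_mask(p, 0.2, 4.3))
  A <- cbind(Re(basis$spectra[idx, "NAA"]))
  sigma <- 0.37
  out <- crlb(A, sigma, amplitudes = 2)
  closed <- 100 * sigma / sqrt(sum(A^2)) / 2
  expect_equal(out, closed, tolerance = 1e-10)
})

test_that("CRLB scales as sigma and halves when the shot count quadruples", {
  cs <- clean_avg_spectrum()
  sigma <- 5
  q1 <- fit_spectrum(cs$spec, cs$basis, noise_sd = sigma)
  # quadrupling shots halves the averaged-spectrum noise SD
  q4 <- fit_spectrum(cs$spec, cs$basis, noise_sd = sigma / 2)
  expect_equal(q4$table$crlb_pct, q1$table$crlb_pct / 2, tolerance = 1e-6)
  expect_error(crlb(cbind(1:3), 0, 1), "> 0")
})

test_that("zero amplitudes report infinite relative CRLB, flagged not NaN", {
  out <- crlb(diag(2), 0.1, amplitudes = c(1, 0))
  expect_true(is.infinite(out[2]))
  expect_false(any(is.nan(out)))
})

test_that("a collinear basis raises an error naming the offending pair", {
  p <- test_protocol()
  basis <- test_basis(p)
  basis$spectra[, "Glu"] <- basis$spectra[, "Gln"]
  expect_error(fit_spectrum(rnorm(p$n_points) + 0i, basis, noise_sd = 1),
               "collinear.*(Gln|Glu).*(Gln|Glu)")
})

test_that("fit residual RMS tracks the injected noise level", {
  cs <- clean_avg_spectrum()
  p <- test_protocol()
  sigma <- 4
  set.seed(21)
  rms <- replicate(12, {
    spec <- cs$spec + complex(real = rnorm(p$n_points, sd = sigma),
                              imaginary = rnorm(p$n_points, sd = sigma))
    fit_spectrum(spec, cs$basis, noise_sd = sigma)$residual_rms
  })
  expect_equal(mean(rms), sigma, tolerance = 0.1)
})

test_that("amplitudes fall within their reported CRLB at working SNR", {
  cs <- clean_avg_spectrum()
  p <- test_protocol()
  basis <- cs$basis
  set.seed(31)
  sigma <- max(Re(cs$spec)) / 40
  hits <- replicate(200, {
    spec <- cs$spec + complex(real = rnorm(p$n_points, sd = sigma),
                              imaginary = rnorm(p$n_points, sd = sigma))
    q <- fit_spectrum(spec, basis, noise_sd = sigma)
    gln <- q$table[q$table$metabolite == "Gln", ]
    abs(gln$amplitude - cs$truth["Gln"]) <=
      2 * gln$crlb_pct / 100 * cs$truth["Gln"]
  })
  # 2-sigma CRLB interval should cover ~95%; require at least 90%
  expect_gte(mean(hits), 0.9)
})

test_that("CRLB filtering applies the strict per-animal rules", {
  grid <- tidyr::expand_grid(animal = sprintf("a%d", 1:5),
                             week = c("week0", "week6"),
                             b_value = c(0.4, 6),
                             metabolite = c("Gln", "NAA", "Asc"))
  quant <- dplyr::mutate(grid, crlb_pct = 1)
  # NAA: one animal at 7% at the lowest b -> excluded in dmrs mode
  quant$crlb_pct[quant$metabolite == "NAA" & quant$animal == "a5" &
                   quant$b_value == 0.4] <- 7
  # Asc: exactly 6.0 at lowest b -> excluded (strict below)
  quant$crlb_pct[quant$metabolite == "Asc" & quant$b_value == 0.4] <- 6
  expect_equal(filter_metabolites(quant, "dmrs"), "Gln")
  # mrs mode: week0-only rule at 25%
  quant2 <- dplyr::mutate(grid, crlb_pct = 10)
  quant2$crlb_pct[quant2$metabolite == "Asc" & quant2$week == "week0"] <- 26
  quant2$crlb_pct[quant2$metabolite == "NAA" & quant2$week == "week6"] <- 80
  expect_equal(filter_metabolites(quant2, "mrs"), c("Gln", "NAA"))
  expect_error(filter_metabolites(quant[quant$animal != "a1" |
                                          quant$b_value != 0.4, ], "dmrs"),
               "a1")
})

test_that("the seven reported metabolites survive dmrs filtering at default SNR", {
  runs <- accept_runs()
  expect_setequal(runs[[1]]$retained,
                  c("Gln", "Glu", "Ins", "Tau", "NAA", "tCr", "tCho"))
})
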