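sticks_curve <- function(d, b = acq_protocol()$b_values, b0 = 0.4) {
  tibble::tibble(b_value = b,
                 s_norm = sticks_attenuation(b, d) / sticks_attenuation(b0, d),
                 b_norm = b0)
}

test_that("decay curves normalize at the lowest b and are order-invariant", {
  quant <- tidyr::expand_grid(animal = "a1", week = "week0",
                              metabolite = c("NAA", "Gln"),
                              b_value = c(0.4, 1.5, 6.0))
  quant$amplitude <- rep(c(5, 5, 5, 8, 4, 2), times = 1)
  cur <- build_decays(quant)
  expect_equal(cur$s_norm[cur$metabolite == "NAA"], c(1, 1, 1))
  shuffled <- quant[sample(nrow(quant)), ]
  expect_equal(build_decays(shuffled), cur)
  expect_equal(unique(cur$b_norm), 0.4)
})

test_that("decay construction validates coverage and positivity", {
  quant <- tidyr::expand_grid(animal = "a1", week = "week0",
                              metabolite = c("NAA", "Gln"),
                              b_value = c(0.4, 1.5, 6.0))
  quant$amplitude <- 1
  expect_error(build_decays(quant[-2, ]), "Missing b-value")
  quant$amplitude[quant$metabolite == "Gln" & quant$b_value == 0.4] <- -1
  expect_error(build_decays(quant, "Gln"), "Non-positive amplitude")
})

test_that("a noiseless sticks cohort yields curves equal to the forward model", {
  p <- test_protocol()
  basis <- test_basis(p)
  st <- simulate_shots(p, basis, truth_conc(), truth_d(), clean_truth(), seed = 1)
  q <- quantify_spectra(average_shots(st), basis)
  cur <- build_decays(q)
  for (m in c("Gln", "NAA")) {
    d <- truth_d()[m]
    sub <- cur[cur$metabolite == m, ]
    expect_equal(sub$s_norm,
                 sticks_attenuation(sub$b_value, d) / sticks_attenuation(0.4, d),
                 tolerance = 1e-6)
  }
})

test_that("sticks fit recovers noiseless diffusivities to 1e-6 and is monotone", {
  for (d in c(0.2, 0.5, 1.0)) {
    f <- fit_sticks(sticks_curve(d))
    expect_equal(f$d_intra, d, tolerance = 1e-6)
    expect_true(f$converged)
  }
  f1 <- fit_sticks(sticks_curve(0.3))
  f2 <- fit_sticks(sticks_curve(0.6))
  expect_gt(f2$d_intra, f1$d_intra)
})

test_that("sticks fit is calibrated: small bias, honest standard errors", {
  set.seed(42)
  d_true <- 0.5
  s0 <- sticks_curve(d_true)
  ests <- replicate(200, {
    cv <- s0
    cv$s_norm <- pmax(cv$s_norm + rnorm(nrow(cv), sd = 0.02), 1e-3)
    f <- fit_sticks(cv)
    c(f$d_intra, f$std_error)
  })
  expect_lt(abs(mean(ests[1, ]) / d_true - 1), 0.02)
  expect_equal(stats::sd(ests[1, ]), mean(ests[2, ]), tolerance = 0.3)
})

test_that("the cumulant fit is exact on a monoexponential decay", {
  b <- acq_protocol()$b_values
  cv <- tibble::tibble(b_value = b, s_norm = exp(-(b - 0.4) * 0.12), b_norm = 0.4)
  f <- fit_cumulant(cv)
  expect_equal(f$adc, 0.12, tolerance = 1e-10)
  expect_equal(f$kurtosis, 0, tolerance = 1e-7)
})

test_that("the convergence cutoff restricts the printed grid to b <= 15.6", {
  f <- fit_cumulant(sticks_curve(0.45), d_assumed = 0.3)
  expect_equal(f$b_max_used, 15.6)
  expect_equal(f$b_c, 18.8)
})

test_that("low-b cumulant fit of sticks data recovers D = d/3 and K = 2.4", {
  bl <- seq(0.005, 0.15, length.out = 30)
  f <- fit_cumulant(sticks_curve(0.45, b = bl, b0 = bl[1]))
  expect_equal(f$adc, 0.45 / 3, tolerance = 0.01)
  expect_equal(f$kurtosis, 2.4, tolerance = 0.01)
})

test_that("cumulant truncation error grows as the b-range approaches b_c", {
  errs <- sapply(c(2, 6, 12, 18), function(bmax) {
    bl <- seq(0.05, bmax, length.out = 25)
    f <- fit_cumulant(sticks_curve(0.45, b = bl, b0 = bl[1]), d_assumed = 5.6 / bmax)
    abs(f$adc - 0.15)
  })
  expect_true(all(diff(errs) > 0))
})

test_that("non-positive normalized signals are reported with their b-value", {
  cv <- sticks_curve(0.4)
  cv$s_norm[5] <- -0.01
  expect_error(fit_cumulant(cv), "b = 9.3")
})

test_that("fits are invariant to uniform rescaling of raw amplitudes", {
  quant <- tidyr::expand_grid(animal = "a1", week = "week0", metabolite = "Gln",
                              b_value = acq_protocol()$b_values)
  quant$amplitude <- 7.3 * sticks_attenuation(quant$b_value, 0.42)
  f1 <- fit_sticks(build_decays(quant))
  quant$amplitude <- 1000 * quant$amplitude
  f2 <- fit_sticks(build_decays(quant))
  expect_equal(f1$d_intra, f2$d_intra, tolerance = 1e-10)
})

test_that("group fitting returns concordant aggregation routes", {
  b <- acq_protocol()$b_values
  cur <- dplyr::bind_rows(lapply(sprintf("a%d", 1:4), function(a) {
    dplyr::mutate(sticks_curve(0.4), animal = a, week = "week0",
                  metabolite = "Gln")
  }))
  g <- fit_group(cur, "sticks")
  # identical animals: group fit equals every individual fit, SD is 0
  expect_equal(g$group$value, g$individual$value[1], tolerance = 1e-8)
  expect_equal(g$summary$sd, 0, tolerance = 1e-8)
  expect_error(fit_group(cur[cur$animal == "a1", ], "sticks"), ">= 2 animals")
  # mismatched grids abort
  cur2 <- cur
  cur2$b_value[cur2$animal == "a1"][1] <- 0.5
  expect_error(fit_group(cur2, "sticks"), "mismatched")
})

test_that("individual-mean and group-average fits agree under noise", {
  set.seed(99)
  cur <- dplyr::bind_rows(lapply(sprintf("a%d", 1:5), function(a) {
    cv <- sticks_curve(0.4)
    cv$s_norm <- pmax(cv$s_norm + rnorm(nrow(cv), sd = 0.01), 1e-3)
    dplyr::mutate(cv, animal = a, week = "week0", metabolite = "Gln")
  }))
  g <- fit_group(cur, "sticks")
  expect_equal(g$summary$mean, g$group$value, tolerance = 0.05)
})
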