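# dwmrs

Simulation and analysis of **diffusion-weighted MR spectroscopy (dMRS)**
metabolite signal decays in paired animal cohorts.

Water diffusion MRI sees every compartment at once; dMRS instead follows
the diffusion attenuation of individual metabolite signals, and because
metabolites are compartmentalized (NAA and glutamate largely neuronal,
myo-inositol and glutamine largely astrocytic) their apparent diffusion
reports cell-type-specific microstructure. `dwmrs` implements the full
chain for a two-timepoint paired cohort with a hepatic-encephalopathy-like
contrast — a severalfold glutamine rise, osmolyte depletion, increased
metabolite diffusivities — as tested, reusable R functions:

1. **Simulation** (`simulate_cohort()`, `simulate_shots()`): shot-level
   complex spectra from a Lorentzian metabolite basis plus macromolecule
   background, per-metabolite diffusion attenuation, phase/frequency
   drift, amplitude dropouts and complex Gaussian noise, with animal-level
   log-normal effects and a recorded ground truth.
2. **Preprocessing** (`correct_drifts()`, `reject_outliers()`,
   `average_shots()`): per-shot frequency/phase alignment to the block
   median (trend-smoothed), rejection of shots with >50% signal drop,
   complex averaging.
3. **Quantification** (`fit_spectrum()`, `crlb()`,
   `filter_metabolites()`): non-negative linear-combination fit against
   the basis with polynomial baseline, relative Cramér–Rao lower bounds,
   and the two CRLB reporting rules (25% at week 0; 6% at the lowest
   b-value, each for all animals).
4. **Diffusion modelling** (`build_decays()`, `fit_sticks()`,
   `fit_cumulant()`, `fit_group()`): normalized decays fitted with the
   randomly-oriented-sticks (powder-average) model

   S/S₀ = √(π / (4 b D_intra)) · erf(√(b D_intra))

   over the full b-range, and with the second-order cumulant expansion

   ln(S/S₀) = −bD + (bD)²K/6

   restricted to b ≤ b_c, where b_c = |z₁|²/D ≈ 5.6422/D is set by the
   first complex zero of the error function (≈ 19 ms/µm² for
   D = 0.3 µm²/ms).
5. **Cohort statistics** (`percent_change()`, `rm_anova()`):
   repeated-measures two-way ANOVA (disease × metabolite, subject as
   block) with Bonferroni-corrected per-metabolite post-hoc comparisons.

`run_pipeline()` chains all stages deterministically from one seed and
writes every intermediate product (quant CSV, curves CSV, fits JSON,
stats JSON, log) to a run directory. Results are tidy tibbles throughout,
with `tidy()`/`glance()` methods and ggplot2 `plot_*()`/`autoplot()`
helpers. A thin CLI over the same functions is in
`inst/scripts/dwmrs-cli.R` (subcommands `simulate`, `preprocess`,
`quantify`, `fit`, `stats`, `run-all`).

## Worked example

A reduced-grid cohort (1024 spectral points, 24 shots per b-value, three
animals) runs in under a minute; the full default protocol (4096 points,
160–480 shots, five animals) is what the acceptance checks use.

```r
library(dwmrs)

protocol <- acq_protocol(n_points = 1024L,
                         shots_per_b = rep(24L, 9))  # reduced grid for speed
config <- pipeline_config(protocol = protocol, n_animals = 3, seed = 42,
                          out_dir = file.path(tempdir(), "demo"))
run <- run_pipeline(config)
run
#> <dmrs_run> 3 animals, seed 42
#>   retained: Gln, Glu, Ins, NAA, Tau, tCho, tCr
#>   outputs:  /tmp/RtmpZ3mYX3/demo

tidy(run) |> dplyr::filter(parameter %in% c("conc", "d_intra"))
#> # A tibble: 14 × 5
#>    metabolite parameter mean_pct sd_pct     n
#>    <chr>      <chr>        <dbl>  <dbl> <int>
#>  1 Gln        conc        128.   113.       3
#>  2 Gln        d_intra      50.3    8.75     3
#>  3 Glu        conc          7.86   9.64     3
#>  4 Glu        d_intra      18.8   17.5      3
#>  5 Ins        conc        -32.2   23.6      3
#>  6 Ins        d_intra      65.5   12.4      3
#>  7 NAA        conc        -21.2   12.8      3
#>  8 NAA        d_intra      12.7   11.3      3
#>  9 Tau        conc         -9.88  16.0      3
#> 10 Tau        d_intra      25.0   16.8      3
#> 11 tCho       conc         -7.75   3.75     3
#> 12 tCho       d_intra      30.4   22.5      3
#> 13 tCr        conc         -9.72   6.19     3
#> 14 tCr        d_intra       7.69   9.21     3
```

All seven metabolites cleared the 6%-CRLB rule and are retained. The
percent-change table shows what a three-animal cohort recovers of the
configured contrast: glutamine concentration up strongly (+128 ± 113%
here, against a configured +178% with ≈95-point per-animal dispersion —
three animals leave a wide cohort spread), myo-inositol down (−32%),
glutamine intra-stick diffusivity up (+50%). The analytic quantities:

```r
radius_of_convergence(0.3)                      # b_c for assumed D = 0.3
#> [1] 18.80745
b_within_convergence(acq_protocol()$b_values, 0.3)
#> [1]  0.4  1.5  6.0  7.6  9.3 13.3 15.6
diffusion_length(0.15, 120)                     # sqrt(4 D Delta), µm
#> [1] 8.485281
```

The kurtosis fit therefore uses b-values up to 15.6 ms/µm², and a
metabolite with ADC ≈ 0.15 µm²/ms probes a ≈8.5 µm length scale over the
120 ms diffusion time.

See `vignette("dwmrs-methods")` for the models, parameter choices,
numerical decisions and limitations.

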