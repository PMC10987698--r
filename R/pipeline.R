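#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run: protocol, ground truth,
#' cohort size, preprocessing thresholds, quantification settings, fit
#' settings, statistics settings and the seed. The resolved configuration
#' is written next to the outputs of every run.
#'
#' @param protocol Acquisition protocol.
#' @param truth Ground-truth configuration.
#' @param n_animals Number of animals.
#' @param seed Integer seed for the whole run.
#' @param drop_threshold Outlier-rejection signal-drop threshold.
#' @param ref_window Drift-correction reference ppm window.
#' @param baseline_order Quantification baseline polynomial order.
#' @param fit_window Quantification ppm window.
#' @param d_assumed Assumed diffusivity for the cumulant b-range cutoff.
#' @param filter_mode CRLB filtering mode (`"dmrs"` or `"mrs"`).
#' @param n_comparisons Bonferroni override (default: retained metabolite
#'   count).
#' @param posthoc Post-hoc mode (`"pooled"` or `"paired"`).
#' @param out_dir Output directory for the run.
#' @return Object of class `dmrs_config`.
#' @export
pipeline_config <- function(protocol = acq_protocol(), truth = ground_truth(),
                            n_animals = 5, seed = 1,
                            drop_threshold = 0.5, ref_window = c(1.8, 4.2),
                            baseline_order = 2, fit_window = c(0.2, 4.3),
                            d_assumed = 0.3, filter_mode = "dmrs",
                            n_comparisons = NULL, posthoc = "pooled",
                            out_dir = tempfile("dwmrs_run_")) {
  stopifnot(inherits(protocol, "dmrs_protocol"), inherits(truth, "dmrs_truth"))
  if (n_animals < 2) stop("`n_animals` must be >= 2.", call. = FALSE)
  if (drop_threshold <= 0 || drop_threshold >= 1) {
    stop("`drop_threshold` must be in (0, 1).", call. = FALSE)
  }
  if (d_assumed <= 0) stop("`d_assumed` must be > 0.", call. = FALSE)
  seed <- as.integer(seed)
  structure(
    list(protocol = protocol, truth = truth, n_animals = n_animals,
         seed = seed, drop_threshold = drop_threshold, ref_window = ref_window,
         baseline_order = baseline_order, fit_window = fit_window,
         d_assumed = d_assumed, filter_mode = filter_mode,
         n_comparisons = n_comparisons, posthoc = posthoc, out_dir = out_dir),
    class = "dmrs_config"
  )
}

write_config_json <- function(config, path) {
  obj <- list(schema_version = SCHEMA_VERSION,
              protocol = unclass(config$protocol),
              truth = unclass(config$truth),
              n_animals = config$n_animals, seed = config$seed,
              drop_threshold = config$drop_threshold,
              ref_window = config$ref_window,
              baseline_order = config$baseline_order,
              fit_window = config$fit_window, d_assumed = config$d_assumed,
              filter_mode = config$filter_mode,
              n_comparisons = config$n_comparisons, posthoc = config$posthoc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full dMRS analysis pipeline on a simulated cohort
#'
#' Simulates the paired cohort defined by the configuration and pushes it
#' through every stage: per-shot drift correction, outlier rejection and
#' averaging; linear-combination quantification with CRLB computation;
#' CRLB-based metabolite filtering; decay-curve construction; sticks and
#' cumulant fits per animal and on group-averaged curves; percent-change
#' summaries and repeated-measures ANOVA. Shot-level data are generated
#' and reduced one animal-timepoint at a time, so memory stays bounded at
#' the full protocol. All stage outputs are written to `out_dir`
#' (`config.json`, `truth_record.csv`, `quant.csv`, `curves.csv`,
#' `fits.json`, `stats.json`, `log.txt`), and the run is deterministic
#' given the seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress console progress.
#' @return Object of class `dmrs_run`: tibbles `quant`, `curves`,
#'   `cohort_table`, `fits` (list), `stats` (list), `retained`,
#'   `truth_record`, reports, and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) {
    line <- sprintf(...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      logf("ERROR in stage '%s': %s", name, conditionMessage(e))
      stop(sprintf("Pipeline stage '%s' failed (%s): %s", name,
                   config$out_dir, conditionMessage(e)), call. = FALSE)
    })
  }
  cat("", file = log_path) # truncate
  logf("dwmrs pipeline; seed %d; %d animals", config$seed, config$n_animals)
  write_config_json(config, file.path(config$out_dir, "config.json"))
  write_protocol_json(config$protocol, file.path(config$out_dir, "protocol.json"))
  write_truth_json(config$truth, file.path(config$out_dir, "truth.json"))

  basis <- stage("basis", make_basis(config$truth$metabolites$metabolite, config$protocol))

  quant_acc <- list(); drift_acc <- list(); rej_acc <- list()
  res <- stage("simulate+preprocess+quantify", {
    iterate_cohort(config$protocol, config$truth, config$n_animals,
                   config$seed, basis, function(block) {
      attr(block, "protocol") <- config$protocol
      pp <- preprocess_shots(block, drop_threshold = config$drop_threshold,
                             ref_window = config$ref_window)
      q <- quantify_spectra(pp$spectra, basis,
                            baseline_order = config$baseline_order,
                            fit_window = config$fit_window)
      quant_acc[[length(quant_acc) + 1]] <<- q
      drift_acc[[length(drift_acc) + 1]] <<- pp$drift_estimates
      rej_acc[[length(rej_acc) + 1]] <<- pp$rejection_report
      logf("processed %s/%s: %d shots rejected",
           block$animal[1], block$week[1], sum(pp$rejection_report$n_removed))
    })
  })
  quant <- dplyr::bind_rows(quant_acc)
  rejection <- dplyr::bind_rows(rej_acc)
  drift <- dplyr::bind_rows(drift_acc)
  readr::write_csv(res$plan, file.path(config$out_dir, "truth_record.csv"))
  write_quant_csv(quant, file.path(config$out_dir, "quant.csv"))

  retained <- stage("filter", filter_metabolites(quant, mode = config$filter_mode))
  logf("retained metabolites (%s CRLB rule): %s", config$filter_mode,
       paste(retained, collapse = ", "))
  if (length(retained) == 0) stop("No metabolite passed the CRLB filter.", call. = FALSE)

  curves <- stage("decays", build_decays(quant, metabolites = retained))
  write_curves_csv(curves, file.path(config$out_dir, "curves.csv"))

  fits_ind <- stage("fits", fit_decays(curves, model = "both",
                                       d_assumed = config$d_assumed))
  nconv <- sum(!fits_ind$converged)
  if (nconv > 0) logf("WARNING: %d non-converged fits flagged", nconv)
  fit_summary <- fits_ind |>
    dplyr::group_by(.data$week, .data$metabolite, .data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  group_fits <- stage("group-fits", {
    grp <- tidyr::expand_grid(week = unique(curves$week), metabolite = retained)
    purrr::map_dfr(seq_len(nrow(grp)), function(i) {
      sub <- curves[curves$week == grp$week[i] & curves$metabolite == grp$metabolite[i], ]
      out <- list()
      for (mdl in c("sticks", "cumulant")) {
        g <- fit_group(sub, model = mdl, d_assumed = config$d_assumed)$group
        out <- c(out, list(dplyr::mutate(g, week = grp$week[i],
                                         metabolite = grp$metabolite[i],
                                         model = mdl, .before = 1)))
      }
      dplyr::bind_rows(out)
    })
  })
  fits <- list(d_assumed = config$d_assumed, individual = fits_ind,
               summary = fit_summary, group = group_fits)
  write_fits_json(fits, file.path(config$out_dir, "fits.json"))

  cohort_table <- stage("cohort-table", {
    conc <- quant |>
      dplyr::filter(.data$b_value == min(.data$b_value),
                    .data$metabolite %in% retained) |>
      dplyr::transmute(.data$animal, .data$week, .data$metabolite,
                       parameter = "conc", value = .data$amplitude)
    pars <- dplyr::select(fits_ind, "animal", "week", "metabolite",
                          "parameter", "value")
    dplyr::bind_rows(conc, pars)
  })

  stats <- stage("stats", {
    params <- unique(cohort_table$parameter)
    anova <- lapply(stats::setNames(params, params), function(p) {
      rm_anova(cohort_table, p, n_comparisons = config$n_comparisons,
               posthoc = config$posthoc)
    })
    list(anova = anova,
         percent_change = percent_change(cohort_table, strict = FALSE))
  })
  write_stats_json(stats, file.path(config$out_dir, "stats.json"))
  logf("pipeline complete")

  structure(
    list(quant = quant, retained = retained, curves = curves,
         fits = fits, cohort_table = cohort_table, stats = stats,
         truth_record = res$plan, noise_sd = res$noise_sd,
         rejection_report = rejection, drift_estimates = drift,
         config = config,
         paths = stats::setNames(
           file.path(config$out_dir,
                     c("config.json", "protocol.json", "truth.json",
                       "truth_record.csv", "quant.csv", "curves.csv",
                       "fits.json", "stats.json", "log.txt")),
           c("config", "protocol", "truth", "truth_record", "quant",
             "curves", "fits", "stats", "log"))),
    class = "dmrs_run"
  )
}

#' @export
print.dmrs_run <- function(x, ...) {
  cat("<dmrs_run>", x$config$n_animals, "animals, seed", x$config$seed, "\n")
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  cat("  outputs: ", x$config$out_dir, "\n")
  invisible(x)
}

#' Percent-change summary of a pipeline run
#'
#' @param x A `dmrs_run`.
#' @param ... Unused.
#' @return Tibble of per-metabolite percent changes by parameter.
#' @export
tidy.dmrs_run <- function(x, ...) x$stats$percent_change

#' @export
glance.dmrs_run <- function(x, ...) {
  purrr::map_dfr(x$stats$anova, glance)
}
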