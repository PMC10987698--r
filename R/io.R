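SCHEMA_VERSION <- "1"

check_schema <- function(obj, what) {
  v <- obj$schema_version
  if (is.null(v) || !identical(as.character(v), SCHEMA_VERSION)) {
    stop(sprintf("Unknown %s schema version '%s' (supported: %s).",
                 what, if (is.null(v)) "<missing>" else v, SCHEMA_VERSION),
         call. = FALSE)
  }
  invisible(obj)
}

#' Write / read an acquisition protocol as JSON
#' @param protocol A [acq_protocol()] object.
#' @param path File path.
#' @return `read_protocol_json()` returns a `dmrs_protocol`.
#' @export
write_protocol_json <- function(protocol, path) {
  obj <- c(list(schema_version = SCHEMA_VERSION), unclass(protocol))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(obj, "protocol")
  acq_protocol(b_values = obj$b_values, shots_per_b = obj$shots_per_b,
               delta = obj$delta, big_delta = obj$big_delta,
               spectral_width = obj$spectral_width, n_points = obj$n_points,
               te = obj$te, tm = obj$tm, field_mhz = obj$field_mhz,
               center_ppm = obj$center_ppm)
}

#' Write / read a ground-truth configuration as JSON
#' @param truth A [ground_truth()] object.
#' @param path File path.
#' @return `read_truth_json()` returns a `dmrs_truth`.
#' @export
write_truth_json <- function(truth, path) {
  obj <- c(list(schema_version = SCHEMA_VERSION), unclass(truth))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(obj, "truth")
  ground_truth(metabolites = tibble::as_tibble(obj$metabolites),
               animal_cv_conc = obj$animal_cv_conc,
               animal_cv_d = obj$animal_cv_d,
               target_snr = obj$target_snr,
               noise_sd = obj$noise_sd,
               phase_drift = obj$phase_drift, freq_drift = obj$freq_drift,
               dropout_p = obj$dropout_p, dropout_depth = obj$dropout_depth,
               mm_attenuates = obj$mm_attenuates, mm_d = obj$mm_d)
}

#' Write / read shot-level spectra as per-animal CSV files
#'
#' One file `shots_<animal>_<week>.csv` per animal and timepoint, long
#' format with columns `b_value, shot_index, point_index, real, imag`
#' (shot and point indices 0-based).
#'
#' @param shot_table Shot table (with `"protocol"` attribute).
#' @param dir Output directory (created if needed).
#' @param protocol Protocol used to rebuild the spectral matrices.
#' @return `read_shots_csv()` returns a shot table.
#' @export
write_shots_csv <- function(shot_table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- dplyr::distinct(shot_table[, c("animal", "week")])
  for (i in seq_len(nrow(groups))) {
    sub <- shot_table[shot_table$animal == groups$animal[i] &
                        shot_table$week == groups$week[i], ]
    rows <- purrr::map_dfr(seq_len(nrow(sub)), function(j) {
      spec <- sub$shots[[j]]
      tibble::tibble(
        b_value = sub$b_value[j],
        shot_index = rep(seq_len(ncol(spec)) - 1L, each = nrow(spec)),
        point_index = rep(seq_len(nrow(spec)) - 1L, times = ncol(spec)),
        real = as.vector(Re(spec)), imag = as.vector(Im(spec))
      )
    })
    readr::write_csv(rows, file.path(dir, sprintf("shots_%s_%s.csv",
                                                  groups$animal[i], groups$week[i])))
  }
  invisible(dir)
}

#' @rdname write_shots_csv
#' @export
read_shots_csv <- function(dir, protocol) {
  files <- list.files(dir, pattern = "^shots_.+_.+\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("No shots_<animal>_<week>.csv files in ", dir, call. = FALSE)
  out <- purrr::map_dfr(files, function(f) {
    meta <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    rows <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
    need <- c("b_value", "shot_index", "point_index", "real", "imag")
    if (!all(need %in% names(rows))) {
      stop("Malformed shots file ", basename(f), ": missing column(s) ",
           paste(setdiff(need, names(rows)), collapse = ", "), call. = FALSE)
    }
    bad <- which(!stats::complete.cases(rows[, need]) |
                   !is.finite(rows$real) | !is.finite(rows$imag))
    if (length(bad) > 0) {
      stop("Malformed row(s) in ", basename(f), " at line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "),
           " (1 header line + data).", call. = FALSE)
    }
    purrr::map_dfr(sort(unique(rows$b_value)), function(b) {
      sub <- rows[rows$b_value == b, ]
      sub <- sub[order(sub$shot_index, sub$point_index), ]
      n_shots <- length(unique(sub$shot_index))
      if (nrow(sub) != n_shots * protocol$n_points) {
        stop("Malformed shots file ", basename(f), ": b = ", b,
             " has an incomplete point grid.", call. = FALSE)
      }
      spec <- matrix(complex(real = sub$real, imaginary = sub$imag),
                     nrow = protocol$n_points)
      tibble::tibble(animal = meta[2], week = meta[3], b_value = b,
                     shots = list(spec), corrupt = list(integer(0)))
    })
  })
  attr(out, "protocol") <- protocol
  out
}

#' Write / read the tidy quantification table
#' @param quant Quant tibble.
#' @param path CSV path.
#' @export
write_quant_csv <- function(quant, path) {
  readr::write_csv(quant, path)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path) {
  quant <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("animal", "week", "b_value", "metabolite", "amplitude", "crlb_pct")
  if (!all(need %in% names(quant))) {
    stop("Malformed quant CSV: missing column(s) ",
         paste(setdiff(need, names(quant)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(quant$amplitude))
  if (length(bad) > 0) {
    stop("Malformed quant CSV: non-finite amplitude at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  quant
}

#' Write / read decay curves
#' @param curves Curve tibble from [build_decays()].
#' @param path CSV path.
#' @export
write_curves_csv <- function(curves, path) {
  readr::write_csv(curves, path)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  curves <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("animal", "week", "metabolite", "b_value", "s_norm", "b_norm")
  if (!all(need %in% names(curves))) {
    stop("Malformed curves CSV: missing column(s) ",
         paste(setdiff(need, names(curves)), collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(curves$s_norm) | curves$s_norm <= 0)
  if (length(bad) > 0) {
    stop("Malformed curves CSV: invalid s_norm at line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  curves
}

#' Write / read diffusion fit results as JSON
#' @param fits List with `individual`, `summary`, `group` tibbles and
#'   `d_assumed` (as produced by [run_pipeline()]).
#' @param path JSON path.
#' @export
write_fits_json <- function(fits, path) {
  obj <- list(schema_version = SCHEMA_VERSION, d_assumed = fits$d_assumed,
              individual = fits$individual, summary = fits$summary,
              group = fits$group)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_fits_json
#' @export
read_fits_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  check_schema(obj, "fits")
  list(d_assumed = obj$d_assumed,
       individual = tibble::as_tibble(obj$individual),
       summary = tibble::as_tibble(obj$summary),
       group = tibble::as_tibble(obj$group))
}

#' Write a cohort statistics report as JSON
#' @param stats Named list of `dmrs_anova` objects (per parameter) plus a
#'   `percent_change` tibble.
#' @param path JSON path.
#' @export
write_stats_json <- function(stats, path) {
  ser <- lapply(stats$anova, function(x) {
    list(parameter = x$parameter, n_comparisons = x$n_comparisons,
         posthoc_mode = x$posthoc_mode, anova = x$anova, posthoc = x$posthoc)
  })
  obj <- list(schema_version = SCHEMA_VERSION, anova = ser,
              percent_change = stats$percent_change)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' Write a full simulated cohort to its dataset directory
#'
#' Lays out the documented container: `protocol.json`, `truth.json`,
#' `truth_record.csv` and per-animal `shots_<animal>_<week>.csv`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_protocol_json(cohort$protocol, file.path(dir, "protocol.json"))
  readr::write_csv(cohort$truth_record, file.path(dir, "truth_record.csv"))
  write_shots_csv(cohort$shots, dir)
  invisible(dir)
}
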