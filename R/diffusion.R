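#' Build normalized metabolite decay curves from a quantification table
#'
#' Normalizes each metabolite's amplitude-vs-b series to its amplitude at
#' the lowest b-value, per animal and timepoint.
#'
#' @param quant Tidy quantification table (animal, week, b_value,
#'   metabolite, amplitude).
#' @param metabolites Optional subset of metabolites to keep.
#' @return Tidy curve table: animal, week, metabolite, b_value, s_norm,
#'   b_norm (the normalization b-value).
#' @export
build_decays <- function(quant, metabolites = NULL) {
  if (!is.null(metabolites)) quant <- quant[quant$metabolite %in% metabolites, ]
  grid <- sort(unique(quant$b_value))
  quant |>
    dplyr::group_by(.data$animal, .data$week, .data$metabolite) |>
    dplyr::group_modify(function(df, key) {
      if (!setequal(df$b_value, grid)) {
        stop("Missing b-value(s) for ", key$metabolite, " (", key$animal, "/",
             key$week, "): ", paste(setdiff(grid, df$b_value), collapse = ", "),
             call. = FALSE)
      }
      df <- df[order(df$b_value), ]
      a0 <- df$amplitude[1]
      if (!is.finite(a0) || a0 <= 0) {
        stop("Non-positive amplitude at the normalization b-value for ",
             key$metabolite, " (", key$animal, "/", key$week, ").", call. = FALSE)
      }
      tibble::tibble(b_value = df$b_value, s_norm = df$amplitude / a0,
                     b_norm = df$b_value[1])
    }) |>
    dplyr::ungroup()
}

#' Build one decay curve
#'
#' Single-group convenience wrapper around [build_decays()] for a quant
#' table already restricted to one animal and timepoint.
#'
#' @param quant Quant table for one animal/timepoint.
#' @param metabolite Metabolite name.
#' @return Curve tibble (b_value, s_norm, b_norm).
#' @export
build_decay <- function(quant, metabolite) {
  out <- build_decays(quant, metabolites = metabolite)
  out[, c("b_value", "s_norm", "b_norm")]
}

# Normalized sticks model: S(b)/S(b0).
sticks_norm <- function(b, d, b0) {
  sticks_attenuation(b, d) / sticks_attenuation(b0, d)
}

#' Fit the randomly-oriented-sticks model to a decay curve
#'
#' Bounded Levenberg-Marquardt least squares of the powder-average model
#' (normalized at the curve's normalization b-value, so the amplitude
#' factor is fixed at 1) over the full b-range. The intra-stick
#' diffusivity is bounded to (1e-4, 3] um^2/ms and initialized at three
#' times the two-point ADC of the first two b-values (the low-b
#' powder-average relation D = D_intra / 3).
#'
#' @param curve Curve tibble with columns `b_value`, `s_norm` and either a
#'   `b_norm` column or the first b taken as normalization point.
#' @return Object of class `dmrs_sticks_fit` with elements `d_intra`,
#'   `std_error`, `converged`, `residual_norm`, `n_points`, `b_max`.
#' @export
fit_sticks <- function(curve) {
  b <- curve$b_value; s <- curve$s_norm
  if (length(b) < 3) stop("Sticks fit needs >= 3 points.", call. = FALSE)
  if (any(s <= 0)) stop("Non-positive normalized signal.", call. = FALSE)
  b0 <- if ("b_norm" %in% names(curve)) curve$b_norm[1] else min(b)
  o <- order(b); b <- b[o]; s <- s[o]
  d_init <- init_d(b, s)
  lower <- 1e-4; upper <- 3
  res <- minpack.lm::nls.lm(
    par = list(d = min(max(3 * d_init, lower), upper)),
    lower = lower, upper = upper,
    fn = function(par) s - sticks_norm(b, par$d, b0),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  converged <- res$info %in% 1:4
  d_hat <- res$par$d
  dof <- length(b) - 1
  sigma2 <- sum(res$fvec^2) / max(dof, 1)
  jtj <- res$hessian # nls.lm returns t(J) %*% J
  se <- if (is.finite(jtj[1, 1]) && jtj[1, 1] > 0) sqrt(sigma2 / jtj[1, 1]) else NA_real_
  structure(
    list(d_intra = d_hat, std_error = se, converged = converged,
         residual_norm = sqrt(sum(res$fvec^2)), n_points = length(b),
         b_max = max(b), message = res$message),
    class = "dmrs_sticks_fit"
  )
}

# Two-point ADC from the lowest two b-values.
init_d <- function(b, s) {
  d0 <- log(s[1] / s[2]) / (b[2] - b[1])
  if (!is.finite(d0) || d0 <= 0) d0 <- 0.1
  d0
}

#' @export
print.dmrs_sticks_fit <- function(x, ...) {
  cat(sprintf("<sticks fit> D_intra = %.4f +/- %.4f um^2/ms (%s, %d pts, b <= %g)\n",
              x$d_intra, x$std_error, if (x$converged) "converged" else "NOT converged",
              x$n_points, x$b_max))
  invisible(x)
}

#' @export
tidy.dmrs_sticks_fit <- function(x, ...) {
  tibble::tibble(term = "d_intra", estimate = x$d_intra, std.error = x$std_error)
}

#' @export
glance.dmrs_sticks_fit <- function(x, ...) {
  tibble::tibble(d_intra = x$d_intra, std_error = x$std_error,
                 converged = x$converged, residual_norm = x$residual_norm,
                 n_points = x$n_points, b_max = x$b_max)
}

#' Fit the second-order cumulant (kurtosis) expansion to a decay curve
#'
#' Fits `ln(S/S0) = -bD + (bD)^2 K / 6` to the log of the normalized
#' signal, restricted to b-values within the convergence radius
#' `b <= b_c(d_assumed)` (b_c rounded to 3 significant figures before the
#' comparison). Because the curve is normalized at `b0`, the model is
#' evaluated as the difference of the expansion at b and at b0. The
#' problem is linear in `(D, D^2 K)` and is solved exactly by least
#' squares; standard errors come from the linear covariance with a delta-
#' method propagation for K.
#'
#' @param curve Curve tibble (`b_value`, `s_norm`, optional `b_norm`).
#' @param d_assumed Assumed diffusivity defining the convergence radius
#'   (um^2/ms).
#' @return Object of class `dmrs_cumulant_fit` with `adc`, `kurtosis`,
#'   standard errors, `b_max_used`, `residual_norm`, `converged` (flags
#'   estimates outside D in (1e-4, 3], K in [-1, 10]).
#' @export
fit_cumulant <- function(curve, d_assumed = 0.3) {
  b0 <- if ("b_norm" %in% names(curve)) curve$b_norm[1] else min(curve$b_value)
  bc <- signif(radius_of_convergence(d_assumed), 3)
  keep <- curve$b_value <= bc
  b <- curve$b_value[keep]; s <- curve$s_norm[keep]
  if (length(b) < 3) stop("Cumulant fit needs >= 3 points with b <= b_c.", call. = FALSE)
  bad <- which(s <= 0)
  if (length(bad) > 0) {
    stop("Non-positive normalized signal at b = ",
         paste(b[bad], collapse = ", "), "; log-signal undefined.", call. = FALSE)
  }
  o <- order(b); b <- b[o]; s <- s[o]
  y <- log(s)
  # ln s_norm = -(b - b0) D + ((b^2 - b0^2)/6) (D^2 K)
  X <- cbind(-(b - b0), (b^2 - b0^2) / 6)
  fit <- stats::lm.fit(X, y)
  th <- fit$coefficients
  D <- th[1]; th2 <- th[2]
  K <- if (abs(D) > 0) th2 / D^2 else NA_real_
  dof <- length(b) - 2
  sigma2 <- if (dof > 0) sum(fit$residuals^2) / dof else 0
  XtXinv <- tryCatch(solve(crossprod(X)), error = function(e) matrix(NA_real_, 2, 2))
  cov <- sigma2 * XtXinv
  se_D <- sqrt(cov[1, 1])
  g <- c(-2 * th2 / D^3, 1 / D^2)
  se_K <- sqrt(drop(t(g) %*% cov %*% g))
  converged <- is.finite(D) && D > 1e-4 && D <= 3 && is.finite(K) &&
    K >= -1 && K <= 10
  structure(
    list(adc = unname(D), kurtosis = unname(K),
         se_adc = unname(se_D), se_kurtosis = unname(se_K),
         b_max_used = max(b), b_c = bc, d_assumed = d_assumed,
         residual_norm = sqrt(sum(fit$residuals^2)),
         n_points = length(b), converged = converged),
    class = "dmrs_cumulant_fit"
  )
}

#' @export
print.dmrs_cumulant_fit <- function(x, ...) {
  cat(sprintf("<cumulant fit> ADC = %.4f +/- %.4f, K = %.3f +/- %.3f (b <= %g of b_c = %g)\n",
              x$adc, x$se_adc, x$kurtosis, x$se_kurtosis, x$b_max_used, x$b_c))
  invisible(x)
}

#' @export
tidy.dmrs_cumulant_fit <- function(x, ...) {
  tibble::tibble(term = c("adc", "kurtosis"),
                 estimate = c(x$adc, x$kurtosis),
                 std.error = c(x$se_adc, x$se_kurtosis))
}

#' @export
glance.dmrs_cumulant_fit <- function(x, ...) {
  tibble::tibble(adc = x$adc, kurtosis = x$kurtosis, se_adc = x$se_adc,
                 se_kurtosis = x$se_kurtosis, b_max_used = x$b_max_used,
                 residual_norm = x$residual_norm, converged = x$converged)
}

#' Fit decay curves for every animal/timepoint/metabolite
#'
#' @param curves Tidy curve table from [build_decays()].
#' @param model `"sticks"`, `"cumulant"` or `"both"`.
#' @param d_assumed Convergence-radius diffusivity for the cumulant fit.
#' @return Tidy tibble: animal, week, metabolite, parameter
#'   (`d_intra`, `adc`, `kurtosis`), value, std_error, converged.
#' @export
fit_decays <- function(curves, model = c("both", "sticks", "cumulant"),
                       d_assumed = 0.3) {
  model <- match.arg(model)
  curves |>
    dplyr::group_by(.data$animal, .data$week, .data$metabolite) |>
    dplyr::group_modify(function(df, key) {
      out <- list()
      if (model %in% c("both", "sticks")) {
        f <- fit_sticks(df)
        out <- c(out, list(tibble::tibble(parameter = "d_intra",
                                          value = f$d_intra,
                                          std_error = f$std_error,
                                          converged = f$converged)))
      }
      if (model %in% c("both", "cumulant")) {
        f <- fit_cumulant(df, d_assumed = d_assumed)
        out <- c(out, list(tibble::tibble(
          parameter = c("adc", "kurtosis"),
          value = c(f$adc, f$kurtosis),
          std_error = c(f$se_adc, f$se_kurtosis),
          converged = f$converged)))
      }
      dplyr::bind_rows(out)
    }) |>
    dplyr::ungroup()
}

#' Per-animal and group-averaged fits for one metabolite
#'
#' Fits the requested model on each animal's decay and on the
#' group-average curve (the pointwise mean of the normalized per-animal
#' curves), returning both aggregation routes.
#'
#' @param curves Curve table for one metabolite and timepoint (several
#'   animals).
#' @param model `"sticks"` or `"cumulant"`.
#' @param d_assumed Cumulant convergence-radius diffusivity.
#' @return List with `individual` (tidy per-animal parameters), `summary`
#'   (mean and SD across animals), `group` (fit of the averaged curve) and
#'   `group_curve`.
#' @export
fit_group <- function(curves, model = c("sticks", "cumulant"), d_assumed = 0.3) {
  model <- match.arg(model)
  animals <- unique(curves$animal)
  if (length(animals) < 2) stop("Group fitting needs >= 2 animals.", call. = FALSE)
  grids <- curves |>
    dplyr::group_by(.data$animal) |>
    dplyr::summarise(g = paste(sort(.data$b_value), collapse = ","), .groups = "drop")
  if (length(unique(grids$g)) != 1) {
    stop("Animals have mismatched b-grids; cannot average curves.", call. = FALSE)
  }
  fit_one <- function(df) {
    if (model == "sticks") {
      f <- fit_sticks(df)
      tibble::tibble(parameter = "d_intra", value = f$d_intra,
                     std_error = f$std_error, converged = f$converged)
    } else {
      f <- fit_cumulant(df, d_assumed = d_assumed)
      tibble::tibble(parameter = c("adc", "kurtosis"),
                     value = c(f$adc, f$kurtosis),
                     std_error = c(f$se_adc, f$se_kurtosis),
                     converged = f$converged)
    }
  }
  individual <- curves |>
    dplyr::group_by(.data$animal) |>
    dplyr::group_modify(~ fit_one(.x)) |>
    dplyr::ungroup()
  summary <- individual |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     n = dplyr::n(), .groups = "drop")
  group_curve <- curves |>
    dplyr::group_by(.data$b_value) |>
    dplyr::summarise(s_norm = mean(.data$s_norm),
                     b_norm = .data$b_norm[1], .groups = "drop")
  list(individual = individual, summary = summary,
       group = fit_one(group_curve), group_curve = group_curve)
}
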