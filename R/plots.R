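#' Plot a spectrum against chemical shift
#'
#' @param spectrum Complex spectrum on the protocol grid (or a row of an
#'   averaged-spectra table via `spectra` + `row`).
#' @param protocol Acquisition protocol.
#' @param ppm_range Plotted window (ppm), displayed with the conventional
#'   reversed axis.
#' @param part `"real"`, `"imag"` or `"mod"`.
#' @return A ggplot object.
#' @export
plot_spectrum <- function(spectrum, protocol, ppm_range = c(0.2, 4.3),
                          part = c("real", "imag", "mod")) {
  part <- match.arg(part)
  df <- tibble::tibble(ppm = ppm_axis(protocol),
                       value = switch(part, real = Re(spectrum),
                                      imag = Im(spectrum), mod = Mod(spectrum)))
  df <- df[df$ppm >= ppm_range[1] & df$ppm <= ppm_range[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ppm, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "chemical shift (ppm)", y = paste0(part, " signal (a.u.)")) +
    ggplot2::theme_minimal()
}

#' Plot metabolite diffusion decay curves
#'
#' Normalized signal versus b-value on a log scale, one panel per
#' metabolite, colored by timepoint, optionally overlaid with the sticks
#' model fitted to the group-average curve.
#'
#' @param curves Tidy curve table from [build_decays()].
#' @param overlay_sticks Overlay group sticks fits.
#' @return A ggplot object.
#' @export
plot_decays <- function(curves, overlay_sticks = TRUE) {
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$b_value, y = .data$s_norm,
                                            colour = .data$week)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~metabolite) +
    ggplot2::labs(x = "b (ms/µm²)", y = "normalized signal") +
    ggplot2::theme_minimal()
  if (overlay_sticks) {
    lines <- curves |>
      dplyr::group_by(.data$week, .data$metabolite) |>
      dplyr::group_modify(function(df, key) {
        gm <- df |>
          dplyr::group_by(.data$b_value) |>
          dplyr::summarise(s_norm = mean(.data$s_norm),
                           b_norm = .data$b_norm[1], .groups = "drop")
        d <- fit_sticks(gm)$d_intra
        bg <- seq(min(df$b_value), max(df$b_value), length.out = 80)
        tibble::tibble(b_value = bg,
                       s_norm = sticks_norm(bg, d, gm$b_norm[1]))
      }) |>
      dplyr::ungroup()
    p <- p + ggplot2::geom_line(data = lines, linewidth = 0.4)
  }
  p
}

#' Plot per-metabolite percent changes with dispersion
#'
#' @param object A `dmrs_anova` result.
#' @param ... Unused.
#' @return A ggplot object showing mean +/- SD percent change per
#'   metabolite, starred by Bonferroni-adjusted significance.
#' @export
autoplot.dmrs_anova <- function(object, ...) {
  df <- object$posthoc
  df$sig <- cut(df$p.adj, c(-Inf, 0.001, 0.01, 0.05, Inf),
                labels = c("***", "**", "*", ""))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metabolite, y = .data$mean_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_pct - .data$sd_pct,
                                        ymax = .data$mean_pct + .data$sd_pct),
                           width = 0.25) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sig), vjust = -0.8) +
    ggplot2::labs(y = sprintf("%s change week6 vs week0 (%%)", object$parameter),
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dmrs_run <- function(object, ...) {
  plot_decays(object$curves)
}
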