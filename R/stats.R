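#' Paired percent change between timepoints
#'
#' For each animal, computes `100 * (week6 - week0) / week0`, then the
#' mean and SD across animals, per metabolite and parameter.
#'
#' @param table Long cohort table with columns animal, week (`"week0"` /
#'   `"week6"`), metabolite, parameter, value.
#' @param metabolite,parameter Optional filters.
#' @param strict If `TRUE` (default) a non-positive week-0 value is an
#'   error; if `FALSE` the affected metabolite/parameter cell reports
#'   `NA` percent change instead (used for sign-indefinite parameters
#'   such as kurtosis).
#' @return Tibble: metabolite, parameter, mean_pct, sd_pct, n.
#' @examples
#' tab <- tidyr::expand_grid(animal = c("a1", "a2"), week = c("week0", "week6"),
#'                           metabolite = "Gln", parameter = "conc")
#' tab$value <- ifelse(tab$week == "week0", 2, 3)
#' percent_change(tab) # +50 +/- 0 %
#' @export
percent_change <- function(table, metabolite = NULL, parameter = NULL,
                           strict = TRUE) {
  if (!is.null(metabolite)) table <- table[table$metabolite %in% metabolite, ]
  if (!is.null(parameter)) table <- table[table$parameter %in% parameter, ]
  wide <- table |>
    tidyr::pivot_wider(id_cols = c("animal", "metabolite", "parameter"),
                       names_from = "week", values_from = "value")
  if (!all(c("week0", "week6") %in% names(wide))) {
    stop("Both week0 and week6 values are required.", call. = FALSE)
  }
  wide <- wide[stats::complete.cases(wide[, c("week0", "week6")]), ]
  bad <- wide[0, c("metabolite", "parameter")]
  if (any(wide$week0 <= 0)) {
    if (strict) {
      stop("Non-positive week0 value; percent change undefined.", call. = FALSE)
    }
    bad <- unique(wide[wide$week0 <= 0, c("metabolite", "parameter")])
    wide <- dplyr::anti_join(wide, bad, by = c("metabolite", "parameter"))
  }
  out <- wide |>
    dplyr::group_by(.data$metabolite, .data$parameter) |>
    dplyr::summarise(
      mean_pct = mean(100 * (.data$week6 - .data$week0) / .data$week0),
      sd_pct = stats::sd(100 * (.data$week6 - .data$week0) / .data$week0),
      n = dplyr::n(), .groups = "drop")
  if (strict && any(out$n < 2)) {
    stop("Percent change needs paired values for >= 2 animals.", call. = FALSE)
  }
  if (!strict && nrow(bad) > 0) {
    out <- dplyr::bind_rows(out, dplyr::mutate(bad, mean_pct = NA_real_,
                                               sd_pct = NA_real_, n = 0L))
  }
  out
}

# Balanced-design check; errors listing the missing cells.
check_balanced <- function(df) {
  cells <- tidyr::expand_grid(animal = unique(df$animal),
                              week = unique(df$week),
                              metabolite = unique(df$metabolite))
  have <- dplyr::distinct(df[, c("animal", "week", "metabolite")])
  miss <- dplyr::anti_join(cells, have, by = c("animal", "week", "metabolite"))
  if (nrow(miss) > 0) {
    stop("Unbalanced cohort table; missing cells: ",
         paste(sprintf("%s/%s/%s", miss$animal, miss$week, miss$metabolite),
               collapse = "; "), call. = FALSE)
  }
  invisible(df)
}

#' Repeated-measures two-way ANOVA with Bonferroni post-hoc tests
#'
#' Classical univariate repeated-measures ANOVA with disease (week) and
#' metabolite as within-subject factors and the animal as blocking
#' factor. Each main effect is tested against its interaction with the
#' subject; the week-by-metabolite interaction and the subject-matching
#' effect are tested against the three-way residual. Post-hoc per-
#' metabolite week6-vs-week0 comparisons are Bonferroni-corrected with
#' `n_comparisons` (default: the number of metabolites in the table).
#'
#' @param table Long cohort table (animal, week, metabolite, parameter,
#'   value), balanced.
#' @param parameter Which parameter to analyse (e.g. `"conc"`,
#'   `"d_intra"`, `"adc"`, `"kurtosis"`).
#' @param n_comparisons Bonferroni multiplier; defaults to the number of
#'   metabolites.
#' @param posthoc `"pooled"` uses the pooled within-subject error
#'   (week-by-subject and residual strata combined); `"paired"` runs
#'   per-metabolite paired t-tests.
#' @return Object of class `dmrs_anova` with `anova` (effects table),
#'   `posthoc` (per-metabolite comparisons with raw and adjusted p and
#'   percent changes) and metadata.
#' @export
rm_anova <- function(table, parameter, n_comparisons = NULL,
                     posthoc = c("pooled", "paired")) {
  posthoc <- match.arg(posthoc)
  df <- table[table$parameter == parameter, ]
  if (nrow(df) == 0) stop("No rows for parameter ", parameter, call. = FALSE)
  if (!all(is.finite(df$value))) stop("Non-finite values in cohort table.", call. = FALSE)
  check_balanced(df)
  df$animal <- factor(df$animal)
  df$week <- factor(df$week)
  df$metabolite <- factor(df$metabolite)
  a <- nlevels(df$animal); tt <- nlevels(df$week); m <- nlevels(df$metabolite)
  if (a < 2 || tt < 2 || m < 1) stop("Need >= 2 animals and 2 timepoints.", call. = FALSE)

  fit <- stats::aov(value ~ week * metabolite + Error(animal / (week * metabolite)),
                    data = df)
  sm <- summary(fit)
  pick <- function(stratum, term) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    tab[match(term, rn), , drop = FALSE]
  }
  ss <- function(stratum, term) pick(stratum, term)[1, "Sum Sq"]
  dfree <- function(stratum, term) pick(stratum, term)[1, "Df"]

  ss_subj <- ss("Error: animal", "Residuals"); df_subj <- dfree("Error: animal", "Residuals")
  ss_w <- ss("Error: animal:week", "week"); df_w <- dfree("Error: animal:week", "week")
  ss_aw <- ss("Error: animal:week", "Residuals"); df_aw <- dfree("Error: animal:week", "Residuals")
  ss_m <- ss("Error: animal:metabolite", "metabolite"); df_m <- dfree("Error: animal:metabolite", "metabolite")
  ss_am <- ss("Error: animal:metabolite", "Residuals"); df_am <- dfree("Error: animal:metabolite", "Residuals")
  ss_wm <- ss("Error: animal:week:metabolite", "week:metabolite"); df_wm <- dfree("Error: animal:week:metabolite", "week:metabolite")
  ss_res <- ss("Error: animal:week:metabolite", "Residuals"); df_res <- dfree("Error: animal:week:metabolite", "Residuals")

  f_row <- function(effect, ssn, dfn, ssd, dfd) {
    f <- (ssn / dfn) / (ssd / dfd)
    tibble::tibble(effect = effect, df1 = dfn, df2 = dfd, sum_sq = ssn,
                   statistic = f,
                   p.value = stats::pf(f, dfn, dfd, lower.tail = FALSE))
  }
  anova_tab <- dplyr::bind_rows(
    f_row("disease", ss_w, df_w, ss_aw, df_aw),
    f_row("metabolite", ss_m, df_m, ss_am, df_am),
    f_row("interaction", ss_wm, df_wm, ss_res, df_res),
    f_row("subject_matching", ss_subj, df_subj, ss_res, df_res)
  )

  mets <- levels(df$metabolite)
  if (is.null(n_comparisons)) n_comparisons <- length(mets)
  wk <- levels(df$week)
  wide <- tidyr::pivot_wider(df, id_cols = c("animal", "metabolite"),
                             names_from = "week", values_from = "value")
  diffs <- wide |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(diff = mean(.data[[wk[2]]] - .data[[wk[1]]]),
                     sd_diff = stats::sd(.data[[wk[2]]] - .data[[wk[1]]]),
                     .groups = "drop")
  if (posthoc == "pooled") {
    ms_pool <- (ss_aw + ss_res) / (df_aw + df_res)
    df_t <- df_aw + df_res
    diffs$t <- diffs$diff / sqrt(2 * ms_pool / a)
    diffs$df <- df_t
  } else {
    diffs$t <- diffs$diff / (diffs$sd_diff / sqrt(a))
    diffs$df <- a - 1
  }
  diffs$p.value <- 2 * stats::pt(abs(diffs$t), diffs$df, lower.tail = FALSE)
  diffs$p.adj <- pmin(1, diffs$p.value * n_comparisons)
  pc <- percent_change(df, parameter = parameter, strict = FALSE)
  posthoc_tab <- dplyr::left_join(diffs, pc[, c("metabolite", "mean_pct", "sd_pct")],
                                  by = "metabolite")

  structure(
    list(anova = anova_tab, posthoc = posthoc_tab, parameter = parameter,
         n_comparisons = n_comparisons, posthoc_mode = posthoc,
         n_animals = a),
    class = "dmrs_anova"
  )
}

#' @export
print.dmrs_anova <- function(x, ...) {
  cat("<dmrs_anova> parameter:", x$parameter,
      sprintf("(%d animals, Bonferroni n = %d, %s post-hoc)\n",
              x$n_animals, x$n_comparisons, x$posthoc_mode))
  print(x$anova)
  cat("Post-hoc week6 vs week0:\n")
  print(x$posthoc)
  invisible(x)
}

#' @export
tidy.dmrs_anova <- function(x, which = c("posthoc", "anova"), ...) {
  which <- match.arg(which)
  if (which == "anova") x$anova else x$posthoc
}

#' @export
glance.dmrs_anova <- function(x, ...) {
  w <- x$anova[x$anova$effect == "disease", ]
  tibble::tibble(parameter = x$parameter, f_disease = w$statistic,
                 p_disease = w$p.value, n_comparisons = x$n_comparisons,
                 n_animals = x$n_animals)
}
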