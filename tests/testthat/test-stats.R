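# Brute-force repeated-measures two-way sums of squares for a balanced
# (animal x week x metabolite) table; the oracle against which rm_anova's
# F statistics are checked.
rm_anova_bruteforce <- function(df) {
  A <- length(unique(df$animal)); Tt <- length(unique(df$week))
  M <- length(unique(df$metabolite))
  g <- mean(df$value)
  m_a <- tapply(df$value, df$animal, mean)
  m_t <- tapply(df$value, df$week, mean)
  m_m <- tapply(df$value, df$metabolite, mean)
  m_at <- tapply(df$value, list(df$animal, df$week), mean)
  m_am <- tapply(df$value, list(df$animal, df$metabolite), mean)
  m_tm <- tapply(df$value, list(df$week, df$metabolite), mean)
  ss_a <- Tt * M * sum((m_a - g)^2)
  ss_t <- A * M * sum((m_t - g)^2)
  ss_m <- A * Tt * sum((m_m - g)^2)
  ss_at <- M * sum((sweep(sweep(m_at, 1, m_a, `-`), 2, m_t, `-`) + g)^2)
  ss_am <- Tt * sum((sweep(sweep(m_am, 1, m_a, `-`), 2, m_m, `-`) + g)^2)
  ss_tm <- A * sum((sweep(sweep(m_tm, 1, m_t, `-`), 2, m_m, `-`) + g)^2)
  ss_tot <- sum((df$value - g)^2)
  ss_res <- ss_tot - ss_a - ss_t - ss_m - ss_at - ss_am - ss_tm
  df_at <- (A - 1) * (Tt - 1); df_am <- (A - 1) * (M - 1)
  df_res <- (A - 1) * (Tt - 1) * (M - 1)
  list(
    f_disease = (ss_t / (Tt - 1)) / (ss_at / df_at),
    f_metabolite = (ss_m / (M - 1)) / (ss_am / df_am),
    f_interaction = (ss_tm / ((Tt - 1) * (M - 1))) / (ss_res / df_res),
    f_subject = (ss_a / (A - 1)) / (ss_res / df_res)
  )
}

test_that("percent change reports paired mean and dispersion", {
  tab <- make_cohort_table(n_animals = 4, metabolites = "Gln", sd_noise = 0)
  tab$value <- ifelse(tab$week == "week0", 2, 3)
  pc <- percent_change(tab)
  expect_equal(pc$mean_pct, 50)
  expect_equal(pc$sd_pct, 0)
  tab$value <- 2
  pc0 <- percent_change(tab)
  expect_equal(pc0$mean_pct, 0)
  tab$value[1] <- -1
  expect_error(percent_change(tab), "Non-positive week0")
})

test_that("ANOVA F statistics match the brute-force sums-of-squares oracle", {
  # minimal 2-animal x 2-metabolite table with hand-set values
  toy <- tidyr::expand_grid(animal = c("a1", "a2"), week = c("week0", "week6"),
                            metabolite = c("X", "Y"))
  toy$parameter <- "conc"
  toy$value <- c(1.0, 2.1, 1.4, 2.9, 1.2, 2.5, 1.1, 3.2)
  res <- rm_anova(toy, "conc")
  bf <- rm_anova_bruteforce(toy)
  expect_equal(res$anova$statistic[res$anova$effect == "disease"],
               bf$f_disease, tolerance = 1e-10)
  expect_equal(res$anova$statistic[res$anova$effect == "metabolite"],
               bf$f_metabolite, tolerance = 1e-10)
  expect_equal(res$anova$statistic[res$anova$effect == "interaction"],
               bf$f_interaction, tolerance = 1e-10)
  expect_equal(res$anova$statistic[res$anova$effect == "subject_matching"],
               bf$f_subject, tolerance = 1e-10)
  # and on a larger random cohort
  tab <- make_cohort_table(n_animals = 5, metabolites = c("A", "B", "C", "D"),
                           effect = 0.2, seed = 8)
  res2 <- rm_anova(tab, "conc")
  bf2 <- rm_anova_bruteforce(tab)
  expect_equal(res2$anova$statistic,
               unname(unlist(bf2)), tolerance = 1e-10)
})

test_that("Bonferroni adjustment multiplies raw p by the comparison count, capped at 1", {
  tab <- make_cohort_table(n_animals = 5, metabolites = letters[1:3],
                           effect = 0.15, seed = 3)
  res <- rm_anova(tab, "conc", n_comparisons = 7)
  expect_equal(res$posthoc$p.adj, pmin(1, res$posthoc$p.value * 7))
  expect_true(all(res$posthoc$p.adj <= 1))
  expect_true(all(diff(res$posthoc$p.adj[order(res$posthoc$p.value)]) >= 0))
})

test_that("the ANOVA is invariant to metabolite relabeling", {
  tab <- make_cohort_table(n_animals = 4, metabolites = c("A", "B", "C"),
                           effect = 0.1, seed = 5)
  relab <- c(A = "Z", B = "Q", C = "M")
  tab2 <- dplyr::mutate(tab, metabolite = unname(relab[metabolite]))
  r1 <- rm_anova(tab, "conc")
  r2 <- rm_anova(tab2, "conc")
  expect_equal(r1$anova$statistic, r2$anova$statistic, tolerance = 1e-12)
})

test_that("unbalanced tables abort listing the missing cells", {
  tab <- make_cohort_table(n_animals = 3)
  tab <- tab[!(tab$animal == "a2" & tab$week == "week6" & tab$metabolite == "B"), ]
  expect_error(rm_anova(tab, "conc"), "a2/week6/B")
})

test_that("statistical power rises with the injected effect size", {
  pow <- sapply(c(0, 0.15, 0.4), function(eff) {
    hits <- sapply(1:40, function(s) {
      tab <- make_cohort_table(n_animals = 5, effect = eff, sd_noise = 0.15,
                               seed = 1000 + s)
      glance(rm_anova(tab, "conc"))$p_disease < 0.05
    })
    mean(hits)
  })
  expect_true(all(diff(pow) >= 0))
  expect_gt(pow[3], pow[1])
})

test_that("paired post-hoc mode matches t.test", {
  tab <- make_cohort_table(n_animals = 6, metabolites = c("A", "B"),
                           effect = 0.2, seed = 12)
  res <- rm_anova(tab, "conc", posthoc = "paired")
  w <- tidyr::pivot_wider(tab[tab$metabolite == "A", ], id_cols = "animal",
                          names_from = "week", values_from = "value")
  tt <- t.test(w$week6, w$week0, paired = TRUE)
  row <- res$posthoc[res$posthoc$metabolite == "A", ]
  expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(row$p.value, tt$p.value, tolerance = 1e-10)
})
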