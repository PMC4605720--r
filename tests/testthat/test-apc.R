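test_that("noiseless expected counts are recovered exactly by the fit", {
  # noiseless data needs no small-count mask; fitting every cell keeps all
  # cohort levels estimable so the drift convention matches the generator's
  params <- recovery_params()
  tab <- noiseless_table(params)
  fit <- fit_apc(tab, default_config(exclude_masked = FALSE))

  expect_equal(fit$period_effects, params$period_effects_true, tolerance = 1e-8)
  expect_equal(fit$cohort_effects, params$cohort_effects_true, tolerance = 1e-8)
  # the recovered age profile matches the generating population hazard
  h_true <- true_unconditional_hazard(params)$values
  h_est <- population_hazard(fit)$values
  expect_equal(h_est, h_true, tolerance = 1e-8)
})

test_that("masking an extreme cohort shifts the drift convention but not the
           fitted means", {
  # with the default mask the youngest cohort (one sub-threshold cell) is not
  # estimable, so the zero-trend constraint acts on the remaining cohorts and
  # the effects are a drift-shifted representative of the same likelihood
  params <- recovery_params()
  tab <- noiseless_table(params)
  masked <- fit_apc(tab, default_config())
  full <- fit_apc(tab, default_config(exclude_masked = FALSE))
  expect_true(anyNA(masked$cohort_effects))
  kept <- masked$kept
  expect_equal(masked$fitted[kept], full$fitted[kept], tolerance = 1e-6)
  # the period effects differ from the truth by an exactly linear drift term
  resid <- masked$period_effects - params$period_effects_true
  expect_lt(max(abs(diff(diff(resid)))), 1e-6)
})

test_that("anchored effects are exactly zero and the cohort trend vanishes", {
  fit <- fit_apc(fixture_registry(), default_config())
  expect_identical(unname(fit$age_effects[fit$anchors["i"]]), 0)
  expect_identical(unname(fit$period_effects[fit$anchors["j"]]), 0)
  expect_identical(unname(fit$cohort_effects[fit$anchors["k"]]), 0)
  K <- length(fit$cohort_effects)
  kbar <- (K + 1) / 2
  trend <- sum((seq_len(K) - kbar) * fit$cohort_effects, na.rm = TRUE)
  expect_lt(abs(trend), 1e-8)
  expect_equal(unname(fit$anchors),
               c(11L, 4L, cohort_index(11L, 4L, 16L)))
})

test_that("fitted expected counts sum to the observed total on kept cells", {
  tab <- fixture_registry()
  fit <- fit_apc(tab, default_config())
  expect_equal(sum(fit$fitted[fit$kept]), sum(tab$cases[fit$kept]),
               tolerance = 1e-8)
})

test_that("fitted means are invariant to the choice of anchors", {
  tab <- fixture_registry()
  f1 <- fit_apc(tab, default_config(age_index = 11L, period_index = 4L))
  f2 <- fit_apc(tab, default_config(age_index = 8L, period_index = 3L))
  kept <- f1$kept
  expect_equal(f1$fitted[kept], f2$fitted[kept], tolerance = 1e-8)
  expect_equal(f1$deviance, f2$deviance, tolerance = 1e-8)
})

test_that("levels with no retained cells get NA effects and zero hazard", {
  tab <- fixture_registry()  # age row 1 is entirely below the case threshold
  fit <- fit_apc(tab, default_config())
  expect_true(is.na(fit$age_effects[1]))
  h <- population_hazard(fit)
  expect_identical(h$values[1], 0)
  expect_identical(h$se[1], 0)
  est <- !is.na(fit$age_effects)
  expect_true(all(h$values[est] > 0))
  expect_true(all(h$se[est & seq_len(16) != 11] >= 0))
})

test_that("disabling the mask fits every cell", {
  tab <- fixture_registry()
  fit <- fit_apc(tab, default_config(exclude_masked = FALSE))
  expect_true(all(fit$kept))
  expect_false(anyNA(fit$age_effects))
})

test_that("an anchor without retained cells is refused", {
  tab <- fixture_registry()
  expect_error(fit_apc(tab, default_config(age_index = 1L)),
               "anchored age row 1 has no retained cells")
})

test_that("a registry with an all-zero person-years row cannot occur, and a
           zero-retention table is refused", {
  g <- age_grid(20L, 5L, 3L)
  pg <- period_grid(1975L, 5L, 2L)
  tab <- registry_table(matrix(2L, 3, 2), matrix(1e5, 3, 2), g, pg)
  expect_error(fit_apc(tab, run_config(n = 3L, J = 2L, age_index = 2L,
                                       period_index = 1L)),
               "no cells retained")
})

test_that("a single period reduces to an age-only fit", {
  g <- age_grid(20L, 5L, 4L)
  pg <- period_grid(1975L, 5L, 1L)
  mu <- matrix(c(100, 200, 400, 800), 4, 1)
  tab <- registry_table(mu, matrix(1e6, 4, 1), g, pg, real_cases = TRUE)
  fit <- fit_apc(tab, run_config(n = 4L, J = 1L, age_index = 2L,
                                 period_index = 1L))
  expect_identical(fit$period_effects, 0)
  expect_true(all(fit$cohort_effects == 0))
  expect_equal(exp(fit$intercept), 200 / 1e6, tolerance = 1e-10)
  expect_equal(fit$age_effects, log(c(100, 200, 400, 800) / 200),
               tolerance = 1e-8)
})

test_that("effect confidence intervals have zero width at the anchors", {
  fit <- fit_apc(fixture_registry(), default_config())
  cis <- effect_cis(fit)
  expect_equal(cis$age$se[11], 0)
  expect_equal(cis$period$lower95[4], 0)
  expect_equal(cis$period$upper95[4], 0)
  expect_true(all(cis$cohort$upper95 >= cis$cohort$lower95, na.rm = TRUE))
  # display convention: zeroing periods before the anchor changes nothing else
  cis2 <- effect_cis(fit, zero_before_anchor_period = TRUE)
  expect_true(all(cis2$period$estimate[1:3] == 0))
  expect_equal(cis2$age, cis$age)
})

test_that("effects export as one tidy row per parameter", {
  fit <- fit_apc(fixture_registry(), default_config())
  f <- withr::local_tempfile(fileext = ".tsv")
  export_effects(fit, f)
  df <- utils::read.delim(f)
  expect_equal(nrow(df), 16 + 7 + 22)
  expect_setequal(unique(df$family), c("age", "period", "cohort"))
})
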