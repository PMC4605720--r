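test_that("cumulative hazard conventions match hand-computed sums", {
  g <- age_grid(20L, 5L, 4L)
  v <- c(0.01, 0.02, 0.03, 0.04)
  H <- cumulative_hazard(hazard_curve(v, age_grid = g), "left")
  expect_equal(H$at_interval, 5 * c(0, 0.01, 0.03, 0.06))
  expect_equal(H$overall, 5 * 0.1)
  Hm <- cumulative_hazard(hazard_curve(v, age_grid = g), "midpoint")
  expect_equal(Hm$at_interval, H$at_interval + 5 * v / 2)
})

test_that("left convention keeps the first-order denominator positive", {
  g <- age_grid(20L, 5L, 4L)
  h_U <- hazard_curve(c(0.001, 0.002, 0.003, 0.004), age_grid = g)
  H <- cumulative_hazard(h_U, "left")
  expect_true(all(H$overall - H$at_interval > 0))
  h <- individual_hazard_approx(h_U, H)
  expect_true(all(h$values > 0))
  # an inconsistent pair (cumulative mass exceeding the stated overall) is
  # refused with the offending intervals named
  H_bad <- H
  H_bad$overall <- H$at_interval[3]
  expect_error(individual_hazard_approx(h_U, H_bad),
               "nonpositive denominator.*interval\\(s\\) 3, 4")
})

test_that("susceptible fraction inverts the overall cumulative hazard", {
  s <- susceptible_fraction(0.0265)
  expect_equal(s$p_first_order, 0.0265)
  expect_equal(s$p_exact, 1 - exp(-0.0265))
  expect_lt(s$p_exact, s$p_first_order)
  expect_error(susceptible_fraction(-1), "nonnegative")
})

test_that("constant population hazard gives the 1/(remaining span) rule", {
  # h_U constant c: H_UO - H_U(t_i) = width * c * (n - i + 1), so the
  # first-order individual hazard is 1 / (width * (n - i + 1))
  g <- age_grid(20L, 5L, 8L)
  h_U <- hazard_curve(rep(3e-4, 8), age_grid = g)
  h <- individual_hazard_approx(h_U, cumulative_hazard(h_U, "left"))
  expect_equal(h$values, 1 / (5 * (8:1)))
})

test_that("forward and inverse susceptibility maps are exact inverses", {
  h <- test_conditional_curve()
  H <- cumulative_hazard(h, "left")
  for (p in c(1e-4, 0.01, 0.3, 0.9)) {
    h_U <- unconditional_hazard_exact(h, H, p)
    H_U <- population_cumulative_hazard(H, p)
    back <- individual_hazard_exact(h_U, H_U, p)
    expect_lt(max(abs(back$values - h$values) / h$values), 1e-10)
  }
})

test_that("everyone susceptible (p = 1) collapses the mixture", {
  h <- test_conditional_curve()
  H <- cumulative_hazard(h, "left")
  h_U <- unconditional_hazard_exact(h, H, 1)
  expect_equal(h_U$values, h$values)
  H_U <- population_cumulative_hazard(H, 1)
  expect_equal(H_U$at_interval, H$at_interval)
  back <- individual_hazard_exact(h_U, H_U, 1)
  expect_equal(back$values, h$values)
})

test_that("the small-p population hazard matches p * h * exp(-H)", {
  p <- 0.01
  h <- test_conditional_curve()
  H <- cumulative_hazard(h, "left")
  h_U <- unconditional_hazard_exact(h, H, p)
  approx <- p * h$values * exp(-H$at_interval)
  expect_lt(max(abs(h_U$values - approx) / h_U$values), 2 * p)
})

test_that("the first-order estimator tracks the exact inverse for small p", {
  params <- sim_params(p_true = 0.01)
  h_U <- true_unconditional_hazard(params)
  H_U <- cumulative_hazard(h_U, "left")
  h_approx <- individual_hazard_approx(h_U, H_U)
  p_exact <- 1 - exp(-H_U$overall)
  h_exact <- individual_hazard_exact(h_U, H_U, p_exact)
  rel <- abs(h_approx$values - h_exact$values) / h_exact$values
  expect_lt(max(rel), 3 * p_exact)
})

test_that("error propagation matches the closed form for a lone interval", {
  # single nonzero hazard c with SE s: D = width * c, and
  # SE^2[h] = (c/D)^2 (s^2/c^2 + width^2 s^2 / D^2) = 2 s^2 / (width c)^2
  g <- age_grid(20L, 5L, 4L)
  cval <- 2e-4; s <- 3e-5
  h_U <- hazard_curve(c(0, 0, 0, cval), se = c(0, 0, 0, s), age_grid = g)
  H <- cumulative_hazard(h_U, "left")
  se <- individual_hazard_se(h_U, H)
  expect_equal(se[4], sqrt(2) * s / (5 * cval), tolerance = 1e-12)
  expect_identical(se[1:3], rep(0, 3))
})

test_that("a supplied hazard covariance changes the propagated errors", {
  g <- age_grid(20L, 5L, 4L)
  h_U <- hazard_curve(rep(2e-4, 4), se = rep(3e-5, 4), age_grid = g)
  H <- cumulative_hazard(h_U, "left")
  se_indep <- individual_hazard_se(h_U, H)
  # perfectly correlated errors inflate the variance of the remaining mass
  cov_full <- outer(h_U$se, h_U$se)
  se_corr <- individual_hazard_se(h_U, H, hazard_cov = cov_full)
  expect_true(all(se_corr[-4] > se_indep[-4]))
  expect_equal(individual_hazard_se(h_U, H, hazard_cov = diag(h_U$se^2)),
               se_indep, tolerance = 1e-12)
})

test_that("survival curves satisfy the mixture identities", {
  p <- 0.02
  h <- test_conditional_curve()
  rates <- survival_curves(h, p)
  S <- rates$resistance
  expect_equal(S[1], 1)                      # left convention: S(t_1) = 1
  expect_true(all(diff(S) < 0))
  expect_equal(rates$population_resistance, 1 - p + p * S)
  expect_true(all(rates$population_resistance >= 1 - p))
  expect_equal(rates$density, h$values * S)
  expect_equal(individual_survival_from_population(rates$population_resistance, p),
               S, tolerance = 1e-12)
  # zero hazard: nobody presents, everyone resists
  h0 <- hazard_curve(rep(0, 16), kind = "conditional")
  r0 <- survival_curves(h0, p)
  expect_true(all(r0$resistance == 1))
  expect_true(all(r0$population_resistance == 1))
})

test_that("survival standard errors follow the delta method", {
  g <- age_grid(20L, 5L, 3L)
  h <- hazard_curve(c(0.01, 0.02, 0.03), se = c(0.001, 0.002, 0.003),
                    age_grid = g, kind = "conditional")
  r <- survival_curves(h, 0.01)
  S <- r$resistance
  expect_equal(r$se_resistance,
               S * 5 * c(0, sqrt(0.001^2), sqrt(0.001^2 + 0.002^2)),
               tolerance = 1e-12)
})

test_that("curve export writes symmetric 95% bounds at the chosen scale", {
  g <- age_grid(20L, 5L, 3L)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_curve(c(1e-4, 2e-4, 3e-4), c(1e-5, 2e-5, 3e-5), g, f, scale = 1e5)
  df <- utils::read.delim(f)
  expect_equal(df$value, c(10, 20, 30))
  expect_equal(df$upper95 - df$value, df$value - df$lower95, tolerance = 1e-9)
  expect_equal(df$upper95, df$value + qnorm(0.975) * df$se, tolerance = 1e-9)
})

test_that("curve constructors reject invalid values", {
  expect_error(hazard_curve(rep(-1, 16)), "nonnegative")
  expect_error(hazard_curve(rep(1, 5)), "grid size")
  expect_error(individual_hazard_exact(test_conditional_curve(),
                                       cumulative_hazard(test_conditional_curve()),
                                       p = 0), "p must be in")
})
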