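# Synthetic registry generator
#
# Generates case-count matrices with exactly the statistical structure the
# pipeline assumes: a known individual (conditional) hazard, a known
# susceptible fraction p, known anchored period and cohort effects, and
# Poisson sampling against a person-years template. Defaults emulate
# stomach-cancer incidence in men at SEER scale: a Gompertz individual
# hazard (about 10% per year by the mid-70s) and p around 1%, which puts
# the population hazard near 5-6 per 10,000 person-years at ages 70-74.

#' Gompertz hazard family
#'
#' `h(t) = alpha * exp(beta * t)` with t age in years.
#'
#' @param alpha Hazard per person-year at age 0.
#' @param beta Exponential slope per year.
#' @return A hazard-family object usable in [sim_params()].
#' @export
gompertz_hazard <- function(alpha = 8e-6, beta = 0.13) {
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(family = "gompertz", alpha = alpha, beta = beta,
                 fn = function(t) alpha * exp(beta * t)),
            class = "hazard_family")
}

#' Piecewise-constant hazard family
#'
#' One hazard value per age interval of the grid; zero before the grid
#' starts.
#'
#' @param values Hazard per person-year, one per interval.
#' @param age_grid The grid the values refer to.
#' @return A hazard-family object usable in [sim_params()].
#' @export
piecewise_hazard <- function(values, age_grid = curehaz::age_grid()) {
  if (length(values) != age_grid$n) stop("need one value per age interval")
  if (any(values < 0)) stop("hazard values must be nonnegative")
  lo <- age_grid$lower
  width <- age_grid$width
  fn <- function(t) {
    idx <- findInterval(t, c(lo, lo[age_grid$n] + width))
    out <- numeric(length(t))
    inside <- idx >= 1 & idx <= age_grid$n
    out[inside] <- values[idx[inside]]
    out
  }
  structure(list(family = "piecewise", values = values, fn = fn),
            class = "hazard_family")
}

#' Simulation parameters for a synthetic registry
#'
#' @param p_true Susceptible fraction in (0, 0.5).
#' @param hazard A [gompertz_hazard()] or [piecewise_hazard()] giving the
#'   individual (conditional) hazard.
#' @param period_effects_true Length-J vector of log-scale period effects;
#'   the anchored entry must be zero.
#' @param cohort_effects_true Length-(n+J-1) vector of log-scale cohort
#'   effects; the anchored entry must be zero and the linear trend zero
#'   (the same constraints the fitter imposes, so recovery is well-posed).
#' @param population_template n-by-J person-years matrix (default: the
#'   embedded male population fixture).
#' @param age_grid,period_grid Grids.
#' @param period_index,age_index Anchors, matching the analysis config.
#' @param seed Master integer seed; per-table sub-seeds are derived from it
#'   deterministically (see [derive_subseed()]).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(p_true = 0.012,
                       hazard = gompertz_hazard(),
                       period_effects_true = NULL,
                       cohort_effects_true = NULL,
                       population_template = NULL,
                       age_grid = curehaz::age_grid(),
                       period_grid = curehaz::period_grid(),
                       period_index = 4L, age_index = 11L,
                       seed = 1L) {
  if (!is.finite(p_true) || p_true <= 0 || p_true >= 0.5)
    stop("p_true must be in (0, 0.5)")
  n <- age_grid$n
  J <- period_grid$J
  K <- n + J - 1L
  k_star <- as.integer(period_index) - as.integer(age_index) + n
  if (is.null(period_effects_true)) period_effects_true <- numeric(J)
  if (is.null(cohort_effects_true)) cohort_effects_true <- numeric(K)
  if (length(period_effects_true) != J) stop("period_effects_true must have length J")
  if (length(cohort_effects_true) != K) stop("cohort_effects_true must have length n+J-1")
  if (abs(period_effects_true[period_index]) > 1e-12)
    stop("anchored period effect must be zero")
  if (abs(cohort_effects_true[k_star]) > 1e-12)
    stop("anchored cohort effect must be zero")
  kbar <- (K + 1) / 2
  if (abs(sum((seq_len(K) - kbar) * cohort_effects_true)) > 1e-8)
    stop("cohort effects must have zero linear trend (the fitter's drift convention)")
  if (is.null(population_template))
    population_template <- load_fixture("men_entire_population")
  if (!identical(dim(population_template), c(n, J)))
    stop("population template must be ", n, "x", J)
  if (any(population_template <= 0)) stop("population template must be positive")
  structure(
    list(p_true = p_true, hazard = hazard,
         period_effects_true = period_effects_true,
         cohort_effects_true = cohort_effects_true,
         population_template = population_template,
         age_grid = age_grid, period_grid = period_grid,
         period_index = as.integer(period_index),
         age_index = as.integer(age_index),
         seed = as.integer(seed)),
    class = "sim_params"
  )
}

#' Project cohort effects onto the fitter's constraint space
#'
#' Utility for constructing admissible generating effects: returns the
#' closest (least-squares) vector with a zero entry at the anchor and zero
#' linear trend.
#'
#' @param x Numeric vector of proposed cohort effects.
#' @param anchor Index forced to zero.
#' @return Constrained vector of the same length.
#' @export
constrain_cohort_effects <- function(x, anchor) {
  K <- length(x)
  kbar <- (K + 1) / 2
  A <- rbind(as.numeric(seq_len(K) == anchor), seq_len(K) - kbar)
  # orthogonal projection onto the null space of A
  P <- diag(K) - t(A) %*% solve(A %*% t(A)) %*% A
  out <- drop(P %*% x)
  out[anchor] <- 0  # exact zero at the anchor (projection leaves ~1e-16)
  out
}

#' Deterministic sub-seed derivation
#'
#' Derives independent-looking 31-bit sub-seeds from a master seed and a
#' stream index with a splitmix-style mixing function, so multi-table
#' experiments are reproducible from one master seed.
#'
#' @param master Master integer seed.
#' @param index Stream index (1, 2, ...).
#' @return Integer in [0, 2^31).
#' @export
derive_subseed <- function(master, index) {
  z <- as.double(master) %% 2^31
  for (round in 1:3) {
    z <- (z * 69069 + as.double(index) * 362437 + 12345) %% 2^31
    z <- as.double(bitwXor(as.integer(z), as.integer(z %/% 2^13)))
  }
  as.integer(z %% 2^31)
}

#' True population hazard implied by the simulation parameters
#'
#' Evaluates the individual hazard at the age-interval midpoints, integrates
#' it from age 0 on a fine grid (step 0.01 year) to get the conditional
#' cumulative hazard, and applies the exact dichotomous-susceptibility
#' forward map `h_U(t) = p h(t) / (p + (1 - p) exp(H(t)))`.
#'
#' @param params A [sim_params()].
#' @return Unconditional [hazard_curve()] (zero SEs).
#' @export
true_unconditional_hazard <- function(params) {
  g <- params$age_grid
  t_mid <- g$midpoints
  h_mid <- params$hazard$fn(t_mid)
  step <- 0.01
  tt <- seq(0, max(t_mid), by = step)
  hh <- params$hazard$fn(tt)
  Hcum <- c(0, cumsum((hh[-1] + hh[-length(hh)]) / 2) * step)  # trapezoid
  H_mid <- stats::approx(tt, Hcum, xout = t_mid, rule = 2)$y
  p <- params$p_true
  values <- p * h_mid / (p + (1 - p) * exp(H_mid))
  hazard_curve(values, age_grid = g, kind = "unconditional")
}

#' Expected case counts for a synthetic registry
#'
#' `mu[i, j] = PY[i, j] * h_U(t_i) * exp(b_j + c_k)` with `k = j - i + n`.
#'
#' @param params A [sim_params()].
#' @return n-by-J matrix of expected counts (reals).
#' @export
expected_counts <- function(params) {
  h_U <- true_unconditional_hazard(params)$values
  n <- params$age_grid$n
  J <- params$period_grid$J
  mu <- matrix(0, n, J)
  for (j in seq_len(J)) {
    k <- j - seq_len(n) + n
    mu[, j] <- params$population_template[, j] * h_U *
      exp(params$period_effects_true[j] + params$cohort_effects_true[k])
  }
  mu
}

#' Simulate a synthetic registry table
#'
#' Draws `O[i, j] ~ Poisson(mu[i, j])` with the expected counts of
#' [expected_counts()], reproducibly from the master seed and a stream
#' index.
#'
#' @param params A [sim_params()].
#' @param stream Sub-seed stream index (use different streams for different
#'   tables under one master seed).
#' @return A [registry_table()] with the template person-years.
#' @export
simulate_counts <- function(params, stream = 1L) {
  mu <- expected_counts(params)
  sub <- derive_subseed(params$seed, stream)
  O <- with_local_seed(sub, function() {
    matrix(stats::rpois(length(mu), as.vector(mu)), nrow(mu), ncol(mu))
  })
  registry_table(O, params$population_template,
                 age_grid = params$age_grid, period_grid = params$period_grid,
                 label = sprintf("synthetic (p=%.4g, seed=%d, stream=%d)",
                                 params$p_true, params$seed, stream))
}

# run fn with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Simulate a pair of regions sharing the individual hazard
#'
#' Generates two registry tables from one individual (conditional) hazard
#' but susceptible fractions p and `p * p_scale` — the generative twin of
#' comparing two geographic regions whose populations differ only in the
#' relative size of the susceptible pool. Estimated individual presentation
#' rates should agree between the pair while the overall cumulative hazards
#' differ by approximately `p_scale`.
#'
#' @param params A [sim_params()] for region A.
#' @param p_scale Ratio of region B's susceptible fraction to region A's.
#' @return List of two [registry_table()]s, `a` and `b`.
#' @export
make_region_pair <- function(params, p_scale = 0.7) {
  p_b <- params$p_true * p_scale
  if (p_b <= 0 || p_b >= 0.5) stop("scaled susceptible fraction out of (0, 0.5)")
  params_b <- params
  params_b$p_true <- p_b
  list(a = simulate_counts(params, stream = 1L),
       b = simulate_counts(params_b, stream = 2L))
}
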