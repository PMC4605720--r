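# Dichotomous-susceptibility conversions
#
# The population is split into a susceptible pool of relative size p and an
# immune remainder. Writing S(t), h(t), H(t) for the conditional (individual)
# survival, hazard and cumulative hazard of susceptibles, the population
# (unconditional) quantities are
#   S_U(t) = 1 - p + p S(t)
#   h_U(t) = p h(t) / (p + (1 - p) exp(H(t)))
# and conversely
#   h(t)   = h_U(t) / (1 + (p - 1) exp(H_U(t))).
# The overall cumulative unconditional hazard H_UO = -log(1 - p), which for
# small p is p itself; the first-order estimator of the individual hazard is
#   h(t) = h_U(t) / (H_UO - H_U(t)).

#' Hazard curve over age intervals
#'
#' @param values Hazard values per person-year, one per age interval.
#' @param se Standard errors (same length; defaults to zeros).
#' @param age_grid The [age_grid()] the curve lives on.
#' @param kind `"unconditional"` (population) or `"conditional"` (individual).
#' @return An object of class `hazard_curve`.
#' @export
hazard_curve <- function(values, se = rep(0, length(values)),
                         age_grid = curehaz::age_grid(),
                         kind = c("unconditional", "conditional")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  se <- as.numeric(se)
  if (length(values) != age_grid$n)
    stop("curve length ", length(values), " != grid size ", age_grid$n)
  if (length(se) != length(values)) stop("se length mismatch")
  if (any(values < 0)) stop("hazard values must be nonnegative")
  if (any(se < 0)) stop("standard errors must be nonnegative")
  structure(list(values = values, se = se, age_grid = age_grid, kind = kind),
            class = "hazard_curve")
}

#' @export
print.hazard_curve <- function(x, ...) {
  cat(sprintf("%s hazard curve on %d intervals (per person-year); range %.3g-%.3g\n",
              x$kind, x$age_grid$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Cumulative hazard of a piecewise-constant curve
#'
#' Discretizes the integral of the hazard on the uniform age grid. Under the
#' default left-cumulative convention the value attached to interval i is the
#' hazard mass strictly before it, `H(t_i) = width * sum(values[1..i-1])`, so
#' `H(t_1) = 0` and `overall - H(t_i)` always includes interval i's own mass
#' (which keeps the first-order individual-hazard denominator positive). The
#' midpoint convention adds half of interval i's own mass.
#'
#' @param curve A [hazard_curve()].
#' @param convention `"left"` (default) or `"midpoint"`.
#' @return An object of class `cumulative_hazard` with `at_interval` (length
#'   n, dimensionless), `overall` (mass over the whole span), `width`, and
#'   `convention`.
#' @export
cumulative_hazard <- function(curve, convention = c("left", "midpoint")) {
  convention <- match.arg(convention)
  d <- curve$age_grid$width
  v <- curve$values
  below <- d * c(0, cumsum(v)[-length(v)])
  at <- switch(convention,
               left = below,
               midpoint = below + d * v / 2)
  structure(list(at_interval = at, overall = d * sum(v),
                 width = d, convention = convention,
                 age_grid = curve$age_grid),
            class = "cumulative_hazard")
}

#' @export
print.cumulative_hazard <- function(x, ...) {
  cat(sprintf("cumulative hazard (%s convention): overall %.5g over %d intervals\n",
              x$convention, x$overall, length(x$at_interval)))
  invisible(x)
}

#' Susceptible fraction from the overall cumulative hazard
#'
#' Under dichotomous susceptibility the overall cumulative unconditional
#' hazard satisfies `H_UO = -log(1 - p)`; inverting gives the exact
#' susceptible fraction `p = 1 - exp(-H_UO)`, and to first order in p,
#' `p = H_UO`. Both are returned; the first-order form is the default
#' downstream because the first-order individual-hazard estimator is derived
#' with it.
#'
#' @param H_UO Overall cumulative unconditional hazard (dimensionless, >= 0).
#' @param se_H_UO Optional standard error of `H_UO`.
#' @return An object of class `susceptibility_estimate` with `H_UO`,
#'   `p_first_order`, `p_exact`, `se_H_UO`.
#' @export
susceptible_fraction <- function(H_UO, se_H_UO = 0) {
  if (!is.finite(H_UO) || H_UO < 0) stop("H_UO must be a nonnegative number")
  structure(list(H_UO = H_UO,
                 p_first_order = H_UO,
                 p_exact = 1 - exp(-H_UO),
                 se_H_UO = se_H_UO),
            class = "susceptibility_estimate")
}

#' @export
print.susceptibility_estimate <- function(x, ...) {
  cat(sprintf("susceptible fraction: H_UO = %.5g (SE %.2g); p = %.5g (first order), %.5g (exact)\n",
              x$H_UO, x$se_H_UO, x$p_first_order, x$p_exact))
  invisible(x)
}

#' First-order individual hazard from the population hazard
#'
#' The small-p estimator of the individual (susceptibility-conditional)
#' cancer presentation rate: `h(t_i) = h_U(t_i) / (H_UO - H_U(t_i))`. The
#' cumulative hazard must use the left-cumulative convention so that the
#' denominator retains interval i's own mass and stays positive wherever the
#' population hazard is positive.
#'
#' @param h_U Unconditional [hazard_curve()].
#' @param H Its [cumulative_hazard()] (left convention).
#' @return Conditional [hazard_curve()]; intervals with zero population
#'   hazard get zero.
#' @export
individual_hazard_approx <- function(h_U, H) {
  denom <- H$overall - H$at_interval
  bad <- which(h_U$values > 0 & denom <= 0)
  if (length(bad) > 0L)
    stop("nonpositive denominator H_UO - H_U at interval(s) ",
         paste(bad, collapse = ", "),
         "; the cumulative hazard must use the left-cumulative convention")
  values <- ifelse(h_U$values > 0, h_U$values / denom, 0)
  hazard_curve(values, age_grid = h_U$age_grid, kind = "conditional")
}

#' Exact individual hazard from the population hazard
#'
#' Inverts the dichotomous-susceptibility relation exactly:
#' `h(t_i) = h_U(t_i) / (1 + (p - 1) exp(H_U(t_i)))`. The boundary p = 1
#' (everyone susceptible) returns the population hazard unchanged.
#'
#' @param h_U Unconditional [hazard_curve()].
#' @param H_U Its [cumulative_hazard()].
#' @param p Susceptible fraction, in (0, 1].
#' @return Conditional [hazard_curve()].
#' @export
individual_hazard_exact <- function(h_U, H_U, p) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  # 1 + (p - 1) e^{H_U} = 1 - e^{H_U + log(1-p)}, computed via expm1 to
  # avoid catastrophic cancellation as H_U approaches -log(1-p)
  denom <- if (p == 1) rep(1, length(H_U$at_interval))
           else -expm1(H_U$at_interval + log1p(-p))
  bad <- which(h_U$values > 0 & denom <= 0)
  if (length(bad) > 0L)
    stop("nonpositive denominator at interval(s) ",
         paste(bad, collapse = ", "),
         ": cumulative hazard exceeds -log(1-p); inputs are inconsistent")
  values <- ifelse(h_U$values > 0, h_U$values / denom, 0)
  hazard_curve(values, age_grid = h_U$age_grid, kind = "conditional")
}

#' Population hazard from the individual hazard
#'
#' The exact forward map of dichotomous susceptibility:
#' `h_U(t_i) = p h(t_i) / (p + (1 - p) exp(H(t_i)))`, where H is the
#' conditional cumulative hazard of h. The denominator is bounded below by
#' p, so the map is defined for any nonnegative curve.
#'
#' @param h Conditional [hazard_curve()].
#' @param H Its [cumulative_hazard()] (conditional).
#' @param p Susceptible fraction, in (0, 1].
#' @return Unconditional [hazard_curve()].
#' @export
unconditional_hazard_exact <- function(h, H, p) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  values <- p * h$values / (p + (1 - p) * exp(H$at_interval))
  hazard_curve(values, age_grid = h$age_grid, kind = "unconditional")
}

#' Exact population cumulative hazard from the individual one
#'
#' Composes the survival mixture with the log transform: the population
#' survival is `S_U = 1 - p + p exp(-H)`, so the population cumulative
#' hazard is `H_U = -log(1 - p + p exp(-H))`. Together with the hazard maps
#' this makes the population/individual conversion algebraically exact:
#' converting a conditional curve with [unconditional_hazard_exact()] and
#' back with [individual_hazard_exact()] using this transform recovers the
#' input to machine precision.
#'
#' @param H Conditional [cumulative_hazard()].
#' @param p Susceptible fraction in (0, 1].
#' @return A [cumulative_hazard()] on the population scale (same convention).
#' @export
population_cumulative_hazard <- function(H, p) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  tr <- function(x) -log(1 - p + p * exp(-x))
  structure(list(at_interval = tr(H$at_interval), overall = tr(H$overall),
                 width = H$width, convention = H$convention,
                 age_grid = H$age_grid),
            class = "cumulative_hazard")
}

#' Delta-method standard errors for the first-order individual hazard
#'
#' Propagates the population-hazard standard errors through the estimator
#' `h = h_U / (H_UO - H_U)`:
#' `SE^2[h] = (h_U / D)^2 (SE^2[h_U]/h_U^2 + SE^2[D]/D^2)` with
#' `D = H_UO - H_U(t_i)`. Under the left-cumulative convention D is the
#' hazard mass from interval i onward, so by default its variance is the
#' independent-interval sum `width^2 * sum(SE^2[h_U(t_m)], m >= i)`; when a
#' covariance matrix of the hazard values across intervals is supplied
#' (e.g. from the age-period-cohort fit) the full quadratic form is used
#' instead.
#'
#' @param h_U Unconditional [hazard_curve()] carrying standard errors.
#' @param H Its [cumulative_hazard()] (left convention).
#' @param hazard_cov Optional n-by-n covariance matrix of the hazard values.
#' @return Numeric vector of standard errors for the conditional hazard;
#'   zero where the population hazard is zero.
#' @export
individual_hazard_se <- function(h_U, H, hazard_cov = NULL) {
  n <- length(h_U$values)
  d <- h_U$age_grid$width
  D <- H$overall - H$at_interval
  bad <- which(h_U$values > 0 & D <= 0)
  if (length(bad) > 0L)
    stop("nonpositive denominator H_UO - H_U at interval(s) ",
         paste(bad, collapse = ", "))
  se2_D <- numeric(n)
  for (i in seq_len(n)) {
    tail <- i:n
    se2_D[i] <- if (is.null(hazard_cov)) {
      d^2 * sum(h_U$se[tail]^2)
    } else {
      d^2 * sum(hazard_cov[tail, tail])
    }
  }
  out <- numeric(n)
  pos <- h_U$values > 0
  out[pos] <- sqrt((h_U$values[pos] / D[pos])^2 *
                     (h_U$se[pos]^2 / h_U$values[pos]^2 +
                        se2_D[pos] / D[pos]^2))
  out
}

#' Individual and population survival, resistance and density curves
#'
#' From a conditional hazard curve and the susceptible fraction p, computes
#' the individual cancer resistance rate `S(t_i) = exp(-H(t_i))`, its
#' population analogue `S_U(t_i) = 1 - p + p S(t_i)` (floored at the immune
#' fraction 1 - p), and the conditional density `f(t_i) = h(t_i) S(t_i)`.
#' Standard errors for S use the delta method `SE[S] = S * SE[H]`, with
#' `SE[H(t_i)]` the independent-interval sum of the hazard-value variances
#' below interval i (left-cumulative convention).
#'
#' @param h Conditional [hazard_curve()] (may carry SEs).
#' @param p Susceptible fraction in (0, 1).
#' @param convention Cumulative-hazard convention, passed through.
#' @return An object of class `individual_rates` with fields `presentation`
#'   (the input hazard curve), `cumulative`, `resistance` (S), `se_resistance`,
#'   `population_resistance` (S_U), `density` (f), and `p`.
#' @export
survival_curves <- function(h, p, convention = "left") {
  if (!is.finite(p) || p <= 0 || p >= 1) stop("p must be in (0, 1)")
  H <- cumulative_hazard(h, convention = convention)
  S <- exp(-H$at_interval)
  d <- h$age_grid$width
  cum_below <- switch(convention,
                      left = function(i) if (i == 1L) integer(0) else 1:(i - 1L),
                      midpoint = function(i) 1:i)
  se_H <- vapply(seq_along(S), function(i) {
    idx <- cum_below(i)
    w <- if (convention == "midpoint") c(rep(1, length(idx) - 1), 0.5) else rep(1, length(idx))
    if (length(idx) == 0L) 0 else d * sqrt(sum((w * h$se[idx])^2))
  }, 0)
  structure(
    list(presentation = h,
         cumulative = H,
         resistance = S,
         se_resistance = S * se_H,
         population_resistance = 1 - p + p * S,
         density = h$values * S,
         p = p),
    class = "individual_rates"
  )
}

#' @export
print.individual_rates <- function(x, ...) {
  cat(sprintf("individual rates (p = %.4g): presentation %.3g-%.3g per person-year, resistance down to %.4f\n",
              x$p, min(x$presentation$values), max(x$presentation$values),
              min(x$resistance)))
  invisible(x)
}

#' Recover the individual survival from the population survival
#'
#' Inverts `S_U = 1 - p + p S` to `S = (S_U + p - 1)/p`.
#'
#' @param S_U Population survival values.
#' @param p Susceptible fraction in (0, 1].
#' @return Individual survival values.
#' @export
individual_survival_from_population <- function(S_U, p) {
  if (!is.finite(p) || p <= 0 || p > 1) stop("p must be in (0, 1]")
  (S_U + p - 1) / p
}

#' Export a curve with confidence bounds as TSV
#'
#' Hazard curves are written per 100,000 person-years; survival-type vectors
#' as probabilities. Columns: interval, value, se, lower95, upper95.
#'
#' @param values,se Numeric vectors over age intervals.
#' @param age_grid The grid providing interval labels.
#' @param path Output path.
#' @param scale Multiplier applied for display (1e5 for hazards, 1 for
#'   probabilities).
#' @return `path`, invisibly.
#' @export
export_curve <- function(values, se, age_grid, path, scale = 1e5) {
  z <- stats::qnorm(0.975)
  df <- data.frame(interval = age_grid$labels,
                   value = values * scale,
                   se = se * scale,
                   lower95 = (values - z * se) * scale,
                   upper95 = (values + z * se) * scale)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
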