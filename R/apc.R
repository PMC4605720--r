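# Anchored age-period-cohort model
#
# The incidence model is multiplicative on the log scale:
#   E O[i,j] = PY[i,j] * exp(mu + a_i + b_j + c_k),  k = j - i + n.
# Location non-identifiability is removed by anchoring a_{i*}, b_{j*} and
# c_{k*} (k* = j* - i* + n) to zero; the remaining linear drift (cohort is an
# exact linear combination of age and period) is resolved by constraining the
# cohort effects to zero linear trend, so the secular slope is carried by the
# age and period effects.

apc_param_names <- function(n, J, K, i_star, j_star, k_star,
                            age_ok = seq_len(n), period_ok = seq_len(J),
                            cohort_ok = seq_len(K)) {
  c("mu",
    paste0("age_", setdiff(intersect(seq_len(n), age_ok), i_star)),
    paste0("period_", setdiff(intersect(seq_len(J), period_ok), j_star)),
    paste0("cohort_", setdiff(intersect(seq_len(K), cohort_ok), k_star)))
}

# Design matrix over free coefficients (intercept + non-anchored dummies)
# for the given cell indices. Levels not named in *_ok (no retained cells)
# get no column.
apc_design <- function(i, j, n, J, i_star, j_star,
                       age_ok = seq_len(n), period_ok = seq_len(J),
                       cohort_ok = NULL) {
  K <- n + J - 1L
  k_star <- j_star - i_star + n
  k <- j - i + n
  if (is.null(cohort_ok)) cohort_ok <- seq_len(K)
  nm <- apc_param_names(n, J, K, i_star, j_star, k_star,
                        age_ok, period_ok, cohort_ok)
  X <- matrix(0, length(i), length(nm), dimnames = list(NULL, nm))
  X[, "mu"] <- 1
  for (col in seq_along(nm)) {
    p <- nm[col]
    if (startsWith(p, "age_")) {
      X[i == as.integer(sub("age_", "", p)), col] <- 1
    } else if (startsWith(p, "period_")) {
      X[j == as.integer(sub("period_", "", p)), col] <- 1
    } else if (startsWith(p, "cohort_")) {
      X[k == as.integer(sub("cohort_", "", p)), col] <- 1
    }
  }
  X
}

# Zero-drift constraint on cohort effects, as a row vector over the free
# coefficients: sum_k (k - kbar) c_k = 0 with kbar the mean cohort index.
apc_drift_constraint <- function(param_names, K) {
  w <- numeric(length(param_names))
  kbar <- (K + 1) / 2
  idx <- startsWith(param_names, "cohort_")
  w[idx] <- as.integer(sub("cohort_", "", param_names[idx])) - kbar
  w
}

#' Fit an anchored age-period-cohort model
#'
#' Maximizes the Poisson log-likelihood of the case counts with mean
#' `PY[i,j] * exp(mu + a_i + b_j + c_k)` subject to the anchoring constraints
#' `a[i*] = b[j*] = c[k*] = 0` (with `k* = j* - i* + n`) and a zero linear
#' trend in the cohort effects. The likelihood is concave in the identified
#' parameterization and is fitted by iteratively reweighted least squares;
#' the covariance of the free parameters is the inverse observed information
#' projected onto the constraint space.
#'
#' Cells excluded by the minimum-case mask get zero likelihood weight when
#' `config$exclude_masked` is `TRUE`. A level (age row, period or cohort)
#' left with no retained cell is not estimable: its effect is reported as
#' `NA` and [population_hazard()] assigns it zero hazard — appropriate for
#' sparse extremes of the age range, where the true hazard contribution is
#' negligible by construction of the mask. Anchor levels must retain at
#' least one cell. With a single period (J = 1) cohorts are completely
#' aliased with age, so the model reduces to an age-only log-linear fit with
#' zero period and cohort effects.
#'
#' @param table A [registry_table()].
#' @param config A [run_config()] carrying the anchors and mask policy.
#' @return An object of class `apc_fit` with fields `intercept` (log hazard
#'   per person-year at the anchors), `age_effects`, `period_effects`,
#'   `cohort_effects` (anchored entries exactly zero), `covariance` (over
#'   the free parameters, named), `anchors`, `drift_convention`, `fitted`
#'   (expected counts on the full grid), and convergence diagnostics.
#' @export
fit_apc <- function(table, config = run_config(n = table$age_grid$n,
                                               J = table$period_grid$J)) {
  findings <- validate_registry(table)
  if (length(findings) > 0L)
    stop("invalid registry table:\n  ", paste(findings, collapse = "\n  "))
  check_grid_compat(table$age_grid, table$period_grid)
  n <- table$age_grid$n
  J <- table$period_grid$J
  K <- n + J - 1L
  i_star <- config$age_index
  j_star <- config$period_index
  if (i_star < 1L || i_star > n) stop("age anchor out of range 1..", n)
  if (j_star < 1L || j_star > J) stop("period anchor out of range 1..", J)
  k_star <- j_star - i_star + n

  cells <- expand.grid(i = seq_len(n), j = seq_len(J))
  O <- table$cases[cbind(cells$i, cells$j)]
  PY <- table$person_years[cbind(cells$i, cells$j)]
  keep <- rep(TRUE, nrow(cells))
  if (isTRUE(config$exclude_masked)) {
    mask <- apply_min_case_mask(table, config$min_cases)
    keep <- mask[cbind(cells$i, cells$j)]
  }
  if (!any(keep)) stop("no cells retained for fitting")
  if (any(rowSums(table$person_years > 0) == 0))
    stop("empty age row in the registry table")
  # levels with at least one retained cell; the rest are not estimable and
  # are reported as NA (their hazard contribution downstream is zero)
  kk_all <- cells$j - cells$i + n
  age_ok <- sort(unique(cells$i[keep]))
  period_ok <- sort(unique(cells$j[keep]))
  cohort_ok <- sort(unique(kk_all[keep]))
  if (!(i_star %in% age_ok))
    stop("anchored age row ", i_star, " has no retained cells")
  if (!(j_star %in% period_ok))
    stop("anchored period ", j_star, " has no retained cells")
  if (!(k_star %in% cohort_ok))
    stop("anchored cohort ", k_star, " has no retained cells")

  single_period <- (J == 1L)
  if (single_period) {
    # age-only log-linear model: cohorts aliased with age
    nm <- c("mu", paste0("age_", setdiff(age_ok, i_star)))
    X <- matrix(0, sum(keep), length(nm), dimnames = list(NULL, nm))
    X[, "mu"] <- 1
    ii <- cells$i[keep]
    for (col in 2:length(nm)) {
      X[ii == as.integer(sub("age_", "", nm[col])), col] <- 1
    }
    elim <- 0L
    Xt <- X
    w <- numeric(length(nm))
  } else {
    X <- apc_design(cells$i[keep], cells$j[keep], n, J, i_star, j_star,
                    age_ok, period_ok, cohort_ok)
    nm <- colnames(X)
    w <- apc_drift_constraint(nm, K)
    # impose the drift constraint by eliminating one cohort coefficient:
    # the most extreme index (largest |k - kbar|, ties to the larger k)
    # among well-supported cohorts (>= 2 retained cells, so a lone-cell
    # cohort that is exactly collinear with an age or period dummy is left
    # for the QR to pivot out rather than smeared over every column)
    cand <- which(startsWith(nm, "cohort_"))
    kv <- as.integer(sub("cohort_", "", nm[cand]))
    support <- vapply(kv, function(k) sum(kk_all[keep] == k), 0L)
    cand2 <- cand[support >= 2L]
    kv2 <- kv[support >= 2L]
    if (length(cand2) == 0L) { cand2 <- cand; kv2 <- kv }
    elim <- cand2[order(-abs(w[cand2]), -kv2)][1]
    Xt <- X[, -elim, drop = FALSE] -
      outer(X[, elim], w[-elim] / w[elim])
  }

  fit <- withCallingHandlers(
    stats::glm.fit(x = Xt, y = O[keep], family = stats::poisson(),
                   offset = log(PY[keep]),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 200)),
    warning = function(wn) {
      if (grepl("non-integer", conditionMessage(wn)))
        invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) {
    est0 <- !is.na(fit$coefficients)
    score <- crossprod(Xt[, est0, drop = FALSE], O[keep] - fit$fitted.values)
    stop(sprintf(
      "age-period-cohort fit did not converge after 200 iterations; max |score| = %.3e",
      max(abs(score))))
  }

  # map the reduced coefficients back to the full free-parameter vector;
  # columns aliased under the mask pattern (pivoted out by the QR) stay NA
  beta <- fit$coefficients
  est <- !is.na(beta)
  q <- length(nm)
  free_idx <- if (elim > 0L) seq_len(q)[-elim] else seq_len(q)
  theta <- rep(NA_real_, q)
  names(theta) <- nm
  theta[free_idx[est]] <- beta[est]
  if (elim > 0L)
    theta[elim] <- -sum(w[free_idx[est]] * beta[est]) / w[elim]

  p1 <- seq_len(fit$rank)
  piv <- fit$qr$pivot[p1]
  nb <- length(beta)
  cov_beta <- matrix(0, nb, nb)
  cov_beta[piv, piv] <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
  A <- matrix(0, q, nb)
  A[cbind(free_idx, seq_len(nb))] <- 1
  if (elim > 0L) A[elim, ] <- -w[free_idx] / w[elim]
  cov_theta <- A %*% cov_beta %*% t(A)
  dimnames(cov_theta) <- list(nm, nm)

  pull <- function(prefix, len, star, ok) {
    v <- rep(NA_real_, len)   # NA marks levels with no retained cells
    v[ok] <- 0
    v[star] <- 0
    idx <- startsWith(nm, prefix)
    v[as.integer(sub(prefix, "", nm[idx]))] <- theta[nm[idx]]
    v
  }
  age_effects <- pull("age_", n, i_star, age_ok)
  period_effects <- pull("period_", J, j_star,
                         if (single_period) seq_len(J) else period_ok)
  cohort_effects <- pull("cohort_", K, k_star,
                         if (single_period) integer(0) else cohort_ok)
  if (single_period) cohort_effects[] <- 0

  eta <- theta["mu"] + age_effects[cells$i] + period_effects[cells$j] +
    cohort_effects[kk_all]
  fitted_full <- matrix(PY * exp(eta), n, J)

  structure(
    list(intercept = unname(theta["mu"]),
         age_effects = age_effects,
         period_effects = period_effects,
         cohort_effects = cohort_effects,
         covariance = cov_theta,
         theta = theta,
         anchors = c(i = i_star, j = j_star, k = k_star),
         drift_convention = "cohort effects constrained to zero linear trend",
         fitted = fitted_full,
         kept = matrix(keep, n, J),
         deviance = fit$deviance,
         iterations = fit$iter,
         age_grid = table$age_grid,
         period_grid = table$period_grid,
         label = table$label),
    class = "apc_fit"
  )
}

#' @export
print.apc_fit <- function(x, ...) {
  cat(sprintf(
    "anchored APC fit%s\n  anchors: age i*=%d, period j*=%d, cohort k*=%d\n  intercept (log hazard at anchors): %.4f\n  deviance: %.2f in %d iterations\n  drift: %s\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$anchors["i"], x$anchors["j"], x$anchors["k"],
    x$intercept, x$deviance, x$iterations, x$drift_convention))
  invisible(x)
}

# variance of mu + a_i per age interval, from the free-parameter covariance;
# zero for age rows not in the fit (their hazard is reported as zero)
apc_log_hazard_var <- function(apc) {
  diag(apc_log_hazard_cov(apc))
}

# covariance matrix of (mu + a_i) across age intervals
apc_log_hazard_cov <- function(apc) {
  n <- apc$age_grid$n
  nm <- colnames(apc$covariance)
  L <- matrix(0, n, length(nm), dimnames = list(NULL, nm))
  for (i in seq_len(n)) {
    if (is.na(apc$age_effects[i])) next
    L[i, "mu"] <- 1
    ai <- paste0("age_", i)
    if (ai %in% nm) L[i, ai] <- 1
  }
  L %*% apc$covariance %*% t(L)
}

#' Population (unconditional) hazard curve from an APC fit
#'
#' The population cancer hazard rate at age interval i is the incidence
#' corrected to the anchored period and cohort: `h_U(t_i) = exp(mu + a_i)`,
#' per person-year. Standard errors follow by the delta method,
#' `SE[h_U] = h_U * SE[mu + a_i]`.
#'
#' @param apc An [fit_apc()] result.
#' @param age_grid Age grid for the curve (defaults to the fit's grid).
#' @return A [hazard_curve()] of kind "unconditional", carrying the
#'   log-hazard covariance across intervals as attribute `log_cov`.
#' @export
population_hazard <- function(apc, age_grid = apc$age_grid) {
  values <- exp(apc$intercept + apc$age_effects)
  values[is.na(apc$age_effects)] <- 0  # rows with no retained cells
  se <- values * sqrt(pmax(apc_log_hazard_var(apc), 0))
  hc <- hazard_curve(values, se, age_grid, kind = "unconditional")
  attr(hc, "log_cov") <- apc_log_hazard_cov(apc)
  hc
}

#' 95% confidence intervals for APC effects
#'
#' Normal-theory intervals `estimate +/- 1.96 SE` for every effect, by
#' family. Anchored entries are reported with a zero-width interval. With
#' `zero_before_anchor_period = TRUE` the period effects preceding the
#' anchored period are displayed as zero without intervals (a presentation
#' convention for forward-anchored reports; it does not change the fit).
#'
#' @param apc An [fit_apc()] result.
#' @param zero_before_anchor_period Logical display convention, see above.
#' @return Named list of data frames (`age`, `period`, `cohort`) with columns
#'   `index`, `label`, `estimate`, `se`, `lower95`, `upper95`, `anchored`.
#' @export
effect_cis <- function(apc, zero_before_anchor_period = FALSE) {
  nm <- colnames(apc$covariance)
  se_of <- function(param) {
    if (param %in% nm) sqrt(max(apc$covariance[param, param], 0)) else 0
  }
  z <- stats::qnorm(0.975)
  family_df <- function(prefix, effects, star, labels) {
    len <- length(effects)
    se <- vapply(seq_len(len), function(ix) se_of(paste0(prefix, ix)), 0)
    est <- effects
    anchored <- seq_len(len) == star
    se[anchored] <- 0
    data.frame(index = seq_len(len), label = labels,
               estimate = est, se = se,
               lower95 = est - z * se, upper95 = est + z * se,
               anchored = anchored, stringsAsFactors = FALSE)
  }
  K <- length(apc$cohort_effects)
  cohort_labels <- paste0("k", seq_len(K))
  out <- list(
    age = family_df("age_", apc$age_effects, apc$anchors["i"],
                    apc$age_grid$labels),
    period = family_df("period_", apc$period_effects, apc$anchors["j"],
                       apc$period_grid$labels),
    cohort = family_df("cohort_", apc$cohort_effects, apc$anchors["k"],
                       cohort_labels)
  )
  if (isTRUE(zero_before_anchor_period)) {
    pre <- out$period$index < apc$anchors["j"]
    out$period$estimate[pre] <- 0
    out$period$se[pre] <- 0
    out$period$lower95[pre] <- 0
    out$period$upper95[pre] <- 0
  }
  out
}

#' Export APC effects and confidence intervals as tidy TSV
#'
#' One row per effect: family, index, label, estimate, se, lower95, upper95,
#' anchored.
#'
#' @param apc An [fit_apc()] result.
#' @param path Output path.
#' @param ... Passed to [effect_cis()].
#' @return `path`, invisibly.
#' @export
export_effects <- function(apc, path, ...) {
  cis <- effect_cis(apc, ...)
  rows <- do.call(rbind, lapply(names(cis), function(fam) {
    cbind(family = fam, cis[[fam]])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
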