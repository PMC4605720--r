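#' Run the full hazard-decomposition pipeline on one stratum
#'
#' Executes the whole analysis chain: crude rates and the minimum-case mask,
#' the anchored age-period-cohort fit, the population hazard curve, the
#' overall cumulative hazard and susceptible fraction, the first-order
#' individual presentation rates with delta-method standard errors, and the
#' individual resistance (survival) and density curves. When `out_dir` is
#' given, all exports plus a JSON run manifest are written there.
#'
#' @param table A [registry_table()]; alternatively pass `cases_path` and
#'   `population_path` to read TSV matrices.
#' @param config A [run_config()].
#' @param out_dir Optional output directory (created if missing).
#' @param cases_path,population_path Optional TSV inputs used when `table`
#'   is `NULL`.
#' @return An object of class `experiment_result` with fields `apc`,
#'   `rates`, `population_hazard`, `cumulative`, `susceptibility`,
#'   `individual`, and `manifest`.
#' @export
run_experiment <- function(table = NULL, config = run_config(),
                           out_dir = NULL,
                           cases_path = NULL, population_path = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(table)) {
    if (is.null(cases_path) || is.null(population_path))
      stop("provide either a registry table or both cases_path and population_path")
    ag <- age_grid(start_age = config$start_age, width = config$time_interval,
                   n = config$n)
    pg <- period_grid(start_year = config$start_year,
                      width = config$time_interval, J = config$J)
    table <- stage("registry_io", registry_table(
      read_matrix_tsv(cases_path, ag, pg),
      read_matrix_tsv(population_path, ag, pg),
      age_grid = ag, period_grid = pg,
      label = config$title))
  }
  rates <- stage("rates", crude_rates(table, min_cases = config$min_cases))
  apc <- stage("apc_model", fit_apc(table, config))
  h_U <- stage("population_hazard", population_hazard(apc))
  H <- stage("cumulative_hazard", cumulative_hazard(h_U, convention = "left"))
  # var(H_UO) needs the covariance of the fitted hazards across age rows
  # (they share the intercept, so an independence sum is too small)
  log_cov <- attr(h_U, "log_cov")
  hazard_cov <- outer(h_U$values, h_U$values) * log_cov
  se_H_UO <- table$age_grid$width * sqrt(max(sum(hazard_cov), 0))
  susc <- stage("susceptible_fraction", susceptible_fraction(H$overall, se_H_UO))
  h_ind <- stage("individual_hazard", individual_hazard_approx(h_U, H))
  h_ind$se <- stage("individual_hazard_se", individual_hazard_se(h_U, H))
  individual <- stage("survival_curves",
                      survival_curves(h_ind, susc$p_first_order))

  manifest <- list(
    title = config$title,
    label = table$label,
    grids = list(start_age = table$age_grid$start_age,
                 start_year = table$period_grid$start_year,
                 width = table$age_grid$width,
                 n = table$age_grid$n, J = table$period_grid$J),
    anchors = list(age_index = unname(apc$anchors["i"]),
                   period_index = unname(apc$anchors["j"]),
                   cohort_index = unname(apc$anchors["k"])),
    min_cases = config$min_cases,
    exclude_masked = config$exclude_masked,
    drift_convention = apc$drift_convention,
    seed = config$seed,
    H_UO = susc$H_UO,
    p_first_order = susc$p_first_order,
    p_exact = susc$p_exact,
    se_H_UO = susc$se_H_UO,
    deviance = apc$deviance,
    total_cases = sum(table$cases)
  )

  result <- structure(
    list(apc = apc, rates = rates, population_hazard = h_U,
         cumulative = H, susceptibility = susc, individual = individual,
         manifest = manifest, config = config),
    class = "experiment_result"
  )
  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment result [%s]\n", x$manifest$label))
  cat(sprintf("  H_UO = %.5g, p = %.5g (first order) / %.5g (exact)\n",
              x$susceptibility$H_UO, x$susceptibility$p_first_order,
              x$susceptibility$p_exact))
  cat(sprintf("  population hazard peak: %.3g per person-year at %s\n",
              max(x$population_hazard$values),
              x$population_hazard$age_grid$labels[which.max(x$population_hazard$values)]))
  invisible(x)
}

#' Write an experiment result directory
#'
#' Layout: `manifest.json`, `effects.tsv`, `population_hazard.tsv`,
#' `individual_rates.tsv`, `resistance.tsv` (plus `rates.tsv` with the crude
#' rates).
#'
#' @param result An [run_experiment()] result.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  export_effects(result$apc, file.path(out_dir, "effects.tsv"))
  g <- result$population_hazard$age_grid
  export_curve(result$population_hazard$values, result$population_hazard$se,
               g, file.path(out_dir, "population_hazard.tsv"), scale = 1e5)
  export_curve(result$individual$presentation$values,
               result$individual$presentation$se,
               g, file.path(out_dir, "individual_rates.tsv"), scale = 1e5)
  export_curve(result$individual$resistance, result$individual$se_resistance,
               g, file.path(out_dir, "resistance.tsv"), scale = 1)
  export_rate_table(result$rates, file.path(out_dir, "rates.tsv"))
  invisible(out_dir)
}

#' Read back the curves of a written experiment directory
#'
#' @param dir Directory written by [write_experiment()].
#' @return List with `manifest`, `individual_rates`, `resistance`,
#'   `population_hazard` data frames (values rescaled to per person-year for
#'   hazards).
#' @export
read_experiment <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rd <- function(f, scale) {
    df <- utils::read.delim(file.path(dir, f))
    df$value <- df$value / scale
    df$se <- df$se / scale
    df
  }
  list(manifest = man,
       population_hazard = rd("population_hazard.tsv", 1e5),
       individual_rates = rd("individual_rates.tsv", 1e5),
       resistance = rd("resistance.tsv", 1))
}

#' Compare individual rates between two strata
#'
#' Per-interval z-test on the difference of the individual presentation
#' rates (and, in parallel, the resistance rates) of two experiment results.
#' An interval is concordant when |difference| <= 1.96 * combined SE. The
#' report also carries the ratio of the two overall cumulative hazards,
#' which captures the population-level amplitude difference between the
#' strata.
#'
#' @param a,b [run_experiment()] results on the same age grid.
#' @return An object of class `invariance_report` with per-interval
#'   differences, z-scores and concordance flags for presentation and
#'   resistance rates, `summary` (fraction of concordant presentation-rate
#'   intervals among those where both SEs are positive), and `H_UO_ratio`
#'   (= b/a).
#' @export
compare_strata <- function(a, b) {
  ga <- a$population_hazard$age_grid
  gb <- b$population_hazard$age_grid
  if (!identical(ga[c("start_age", "width", "n")], gb[c("start_age", "width", "n")]))
    stop("age grid mismatch between the two results")

  ztab <- function(va, sa, vb, sb) {
    d <- vb - va
    se <- sqrt(sa^2 + sb^2)
    z <- ifelse(se > 0, d / se, ifelse(d == 0, 0, Inf))
    data.frame(interval = ga$labels, a = va, b = vb, difference = d,
               combined_se = se, z = z,
               concordant = abs(d) <= stats::qnorm(0.975) * se |
                 (se == 0 & d == 0))
  }
  pres <- ztab(a$individual$presentation$values, a$individual$presentation$se,
               b$individual$presentation$values, b$individual$presentation$se)
  res <- ztab(a$individual$resistance, a$individual$se_resistance,
              b$individual$resistance, b$individual$se_resistance)
  informative <- pres$combined_se > 0
  structure(
    list(presentation = pres, resistance = res,
         summary = mean(pres$concordant[informative]),
         informative = informative,
         H_UO_ratio = b$susceptibility$H_UO / a$susceptibility$H_UO),
    class = "invariance_report"
  )
}

#' @export
print.invariance_report <- function(x, ...) {
  cat(sprintf("invariance report: %.0f%% of informative intervals concordant (presentation rates)\n",
              100 * x$summary))
  cat(sprintf("  H_UO ratio (b/a): %.4f\n", x$H_UO_ratio))
  invisible(x)
}
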