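#' Crude age-specific incidence rates
#'
#' Computes the cellwise crude rate O/PY (events per person-year) with the
#' Poisson standard error sqrt(O)/PY, and the minimum-case retention mask.
#' Zero-count cells get rate 0 and SE 0 (flagged in `zero_cells`). Rates are
#' stored per person-year; `scale_report` (100,000) is a display multiplier
#' only.
#'
#' @param table A [registry_table()].
#' @param min_cases Retention threshold; cells with more cases than this are
#'   retained (see [apply_min_case_mask()]).
#' @return An object of class `rate_table` with fields `rates`, `se`,
#'   `mask`, `zero_cells`, `scale_report`, and the grids.
#' @export
crude_rates <- function(table, min_cases = 15L) {
  findings <- validate_registry(table)
  if (length(findings) > 0L)
    stop("invalid registry table:\n  ", paste(findings, collapse = "\n  "))
  rates <- table$cases / table$person_years
  se <- sqrt(table$cases) / table$person_years
  structure(
    list(rates = rates, se = se,
         mask = apply_min_case_mask(table, min_cases),
         zero_cells = table$cases == 0,
         scale_report = 1e5,
         age_grid = table$age_grid, period_grid = table$period_grid,
         label = table$label),
    class = "rate_table"
  )
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("crude rate table: %d x %d, %d cells retained by the case threshold\n",
              nrow(x$rates), ncol(x$rates), sum(x$mask)))
  invisible(x)
}

#' Minimum-case retention mask
#'
#' SEER practice retains five-year age intervals only where the number of
#' cases exceeds 15. The mask is advisory: by default masked-out cells get
#' zero weight in the age-period-cohort likelihood, but downstream code can
#' be configured to keep them.
#'
#' @param table A [registry_table()].
#' @param threshold Case-count threshold; retained means `cases > threshold`.
#' @return Logical n-by-J matrix, `TRUE` where the cell is retained.
#' @export
apply_min_case_mask <- function(table, threshold = 15L) {
  table$cases > threshold
}

#' Anchored birth-cohort index
#'
#' Maps an age-interval index i and period index j (both 1-based) to the
#' birth-cohort index k = j - i + n, so that cells on one anti-diagonal of
#' the registry matrix (one birth cohort) share one k. With n age intervals
#' and J periods, k ranges over 1..(n + J - 1).
#'
#' @param i Age-interval index (1-based), vectorized.
#' @param j Period index (1-based), vectorized.
#' @param n Number of age intervals.
#' @param J Optional number of periods; when given, j is range-checked
#'   against it.
#' @return Integer cohort index k.
#' @examples
#' cohort_index(11, 4, 16) # 9
#' cohort_index(11, 7, 16) # 12
#' @export
cohort_index <- function(i, j, n, J = NULL) {
  i <- as.integer(i); j <- as.integer(j); n <- as.integer(n)
  if (any(i < 1L) || any(i > n)) stop("age index i must be in 1..", n)
  if (any(j < 1L)) stop("period index j must be >= 1")
  if (!is.null(J) && any(j > as.integer(J))) stop("period index j must be <= ", J)
  j - i + n
}

#' Export a rate table as TSV (per 100,000 person-years)
#'
#' Writes rates and standard errors scaled per 100,000 person-years with four
#' decimal places, plus a sidecar `<path>.mask` file of 0/1 retention flags.
#'
#' @param rt A `rate_table`.
#' @param path Output path for the rate TSV.
#' @return `path`, invisibly.
#' @export
export_rate_table <- function(rt, path) {
  s <- rt$scale_report
  header <- paste(c("Interval",
                    paste0("rate_", rt$period_grid$labels),
                    paste0("se_", rt$period_grid$labels)), collapse = "\t")
  rows <- vapply(seq_len(nrow(rt$rates)), function(i) {
    paste(c(rt$age_grid$labels[i],
            sprintf("%.4f", rt$rates[i, ] * s),
            sprintf("%.4f", rt$se[i, ] * s)), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  writeLines(apply(rt$mask * 1L, 1, paste, collapse = "\t"),
             paste0(path, ".mask"))
  invisible(path)
}
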