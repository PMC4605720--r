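#' Age grid for registry matrices
#'
#' Defines the uniform five-year (by default) age intervals over which
#' registry case counts and person-years are tabulated. The default grid
#' covers ages 20--99 in sixteen intervals of width 5, the convention used
#' for adult cancers in SEER-style extracts.
#'
#' @param start_age Integer, youngest age of the first interval (years).
#' @param width Integer, interval width in years (the discretization step
#'   used for all cumulative-hazard sums).
#' @param n Integer, number of age intervals.
#' @return An object of class `age_grid` with fields `start_age`, `width`,
#'   `n`, interval `labels`, and `midpoints` (ages at interval centres,
#'   e.g. 72.5 for 70--74).
#' @examples
#' g <- age_grid()
#' g$n            # 16
#' g$midpoints[11] # 72.5
#' @export
age_grid <- function(start_age = 20L, width = 5L, n = 16L) {
  start_age <- as.integer(start_age)
  width <- as.integer(width)
  n <- as.integer(n)
  if (start_age < 0L) stop("start_age must be >= 0")
  if (width <= 0L) stop("width must be > 0")
  if (n < 2L) stop("n must be >= 2")
  lo <- start_age + width * (seq_len(n) - 1L)
  hi <- lo + width - 1L
  structure(
    list(
      start_age = start_age, width = width, n = n,
      lower = lo, upper = hi,
      labels = sprintf("%d-%d", lo, hi),
      midpoints = lo + (width - 1) / 2 + 0.5  # centre of [lo, lo+width)
    ),
    class = "age_grid"
  )
}

#' Calendar-period grid for registry matrices
#'
#' Defines the calendar periods (columns) of a registry matrix. The default
#' covers 1975--2009 in seven five-year periods. When used together with an
#' [age_grid()] for cohort indexing the two widths must agree.
#'
#' @param start_year First calendar year of the first period.
#' @param width Period width in years.
#' @param J Number of periods.
#' @return An object of class `period_grid` with fields `start_year`,
#'   `width`, `J`, and interval `labels`.
#' @examples
#' period_grid()$labels # "1975-1979" ... "2005-2009"
#' @export
period_grid <- function(start_year = 1975L, width = 5L, J = 7L) {
  start_year <- as.integer(start_year)
  width <- as.integer(width)
  J <- as.integer(J)
  if (width <= 0L) stop("width must be > 0")
  if (J < 1L) stop("J must be >= 1")
  lo <- start_year + width * (seq_len(J) - 1L)
  structure(
    list(
      start_year = start_year, width = width, J = J,
      lower = lo, upper = lo + width - 1L,
      labels = sprintf("%d-%d", lo, lo + width - 1L)
    ),
    class = "period_grid"
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("age grid: %d intervals of %d years, ages %d-%d\n",
              x$n, x$width, x$start_age, x$upper[x$n]))
  invisible(x)
}

#' @export
print.period_grid <- function(x, ...) {
  cat(sprintf("period grid: %d periods of %d years, %d-%d\n",
              x$J, x$width, x$start_year, x$upper[x$J]))
  invisible(x)
}

check_grid_compat <- function(age_grid, period_grid) {
  if (age_grid$width != period_grid$width)
    stop("age and period grids must share one interval width for cohort indexing (got ",
         age_grid$width, " and ", period_grid$width, ")")
  invisible(TRUE)
}
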