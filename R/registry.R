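#' Registry table: paired case and person-year matrices
#'
#' Bundles an age-by-period matrix of observed case counts `O[i, j]` with the
#' matching matrix of person-years at risk `Pop[i, j]`, the grids they live
#' on, and a free-text stratum label (site, sex, region).
#'
#' @param cases n-by-J matrix of nonnegative integer case counts.
#' @param person_years n-by-J matrix of positive person-years at risk.
#' @param age_grid An [age_grid()].
#' @param period_grid A [period_grid()].
#' @param label Stratum descriptor, free text.
#' @param real_cases Set `TRUE` for tables of real-valued expected counts
#'   (noiseless analyses); observed registries keep the default integer
#'   check.
#' @return An object of class `registry_table`.
#' @seealso [validate_registry()], [crude_rates()], [fit_apc()]
#' @export
registry_table <- function(cases, person_years,
                           age_grid = curehaz::age_grid(),
                           period_grid = curehaz::period_grid(),
                           label = "", real_cases = FALSE) {
  cases <- as.matrix(cases)
  person_years <- as.matrix(person_years)
  tab <- structure(
    list(cases = cases, person_years = person_years,
         age_grid = age_grid, period_grid = period_grid,
         label = as.character(label), real_cases = isTRUE(real_cases)),
    class = "registry_table"
  )
  findings <- validate_registry(tab)
  if (length(findings) > 0L)
    stop("invalid registry table:\n  ", paste(findings, collapse = "\n  "))
  dimnames(tab$cases) <- dimnames(tab$person_years) <-
    list(age_grid$labels, period_grid$labels)
  tab
}

#' Validate a registry table
#'
#' Checks the structural invariants of a registry table and returns one
#' finding (a character string) per violation rather than raising errors, so
#' callers can report all problems at once.
#'
#' @param table A `registry_table` (or a bare list with the same fields).
#' @return Character vector of findings; `character(0)` when everything holds.
#' @export
validate_registry <- function(table) {
  findings <- character(0)
  n <- table$age_grid$n
  J <- table$period_grid$J
  dc <- dim(table$cases)
  dp <- dim(table$person_years)
  if (!identical(dc, c(n, J)))
    findings <- c(findings, sprintf(
      "cases matrix is %dx%d, expected %dx%d from the grids", dc[1], dc[2], n, J))
  if (!identical(dp, c(n, J)))
    findings <- c(findings, sprintf(
      "person-years matrix is %dx%d, expected %dx%d from the grids", dp[1], dp[2], n, J))
  if (!identical(dc, dp))
    findings <- c(findings, "cases and person-years matrices differ in shape")
  if (any(!is.finite(table$cases)) || any(!is.finite(table$person_years))) {
    findings <- c(findings, "non-finite entries present")
    return(findings)
  }
  bad <- which(table$cases < 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bad)))
    findings <- c(findings, sprintf("negative case count at (i=%d, j=%d)",
                                    bad[r, 1], bad[r, 2]))
  if (!isTRUE(table$real_cases)) {
    bad <- which(abs(table$cases - round(table$cases)) > 1e-9, arr.ind = TRUE)
    for (r in seq_len(nrow(bad)))
      findings <- c(findings, sprintf("non-integer case count at (i=%d, j=%d)",
                                      bad[r, 1], bad[r, 2]))
  }
  bad <- which(table$person_years <= 0, arr.ind = TRUE)
  for (r in seq_len(nrow(bad)))
    findings <- c(findings, sprintf("non-positive person-years at (i=%d, j=%d)",
                                    bad[r, 1], bad[r, 2]))
  findings
}

#' @export
print.registry_table <- function(x, ...) {
  cat(sprintf("registry table%s: %d age intervals x %d periods, %s cases, %s person-years\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$age_grid$n, x$period_grid$J,
              format(sum(x$cases), big.mark = ","),
              format(sum(x$person_years), big.mark = ",")))
  invisible(x)
}

#' Read an age-by-period matrix from a tab-separated file
#'
#' Accepts the plain dialect written by [write_matrix_tsv()] as well as
#' registry-style layouts with a single header line and leading label columns
#' (age index, age-interval label): each data row contributes its trailing J
#' numeric fields; a first line whose trailing J fields are not all numeric
#' is treated as a header and skipped.
#'
#' @param path Path to the TSV file.
#' @param age_grid,period_grid Grids defining the expected n-by-J shape.
#' @return Numeric n-by-J matrix, rows = age intervals ascending,
#'   columns = periods ascending.
#' @export
read_matrix_tsv <- function(path, age_grid = curehaz::age_grid(),
                            period_grid = curehaz::period_grid()) {
  if (!file.exists(path)) stop("file not found: ", path)
  n <- age_grid$n
  J <- period_grid$J
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path)

  tail_fields <- function(line) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < J) return(NULL)
    f[(length(f) - J + 1L):length(f)]
  }
  numeric_row <- function(f) {
    !is.null(f) && all(!is.na(suppressWarnings(as.numeric(f))))
  }

  first <- tail_fields(lines[1])
  if (!numeric_row(first)) lines <- lines[-1]  # header line

  if (length(lines) != n)
    stop(sprintf("dimension mismatch in %s: expected %dx%d, found %d data rows",
                 path, n, J, length(lines)))
  out <- matrix(NA_real_, n, J)
  for (r in seq_len(n)) {
    f <- tail_fields(lines[r])
    if (is.null(f))
      stop(sprintf("dimension mismatch in %s: expected %d columns, row %d has fewer",
                   path, J, r))
    v <- suppressWarnings(as.numeric(f))
    if (anyNA(v)) {
      cidx <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at row %d, column %d of %s: '%s'",
                   r, cidx, path, f[cidx]))
    }
    out[r, ] <- v
  }
  out
}

#' Write an age-by-period matrix as plain TSV
#'
#' Integer-valued matrices are written as integers (round-trip exact);
#' other values are written with 15 significant digits.
#'
#' @param m Numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  m <- as.matrix(m)
  fmt_cell <- function(x) {
    if (is.finite(x) && abs(x - round(x)) < .Machine$double.eps * max(1, abs(x)))
      sprintf("%.0f", x)
    else
      format(x, digits = 15, scientific = FALSE, trim = TRUE)
  }
  rows <- apply(m, 1, function(r) paste(vapply(r, fmt_cell, ""), collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' Load an embedded registry fixture
#'
#' Two complete 16-by-7 matrices ship with the package: stomach-cancer case
#' counts in men ("stomach_men_entire_cases") and the matching male
#' population person-years ("men_entire_population"), both for the pooled
#' nine-area SEER region over 1975--2009.
#'
#' @param name One of `"stomach_men_entire_cases"`, `"men_entire_population"`.
#' @return Numeric 16-by-7 matrix.
#' @examples
#' load_fixture("stomach_men_entire_cases")[1, 1]  # 3
#' @export
load_fixture <- function(name) {
  known <- c("stomach_men_entire_cases", "men_entire_population")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  path <- system.file("extdata", paste0(name, ".tsv"), package = "curehaz",
                      mustWork = TRUE)
  read_matrix_tsv(path, age_grid(), period_grid())
}

#' Path of an embedded fixture file
#'
#' @param name Fixture name as in [load_fixture()].
#' @return File path of the installed TSV.
#' @export
fixture_path <- function(name) {
  known <- c("stomach_men_entire_cases", "men_entire_population")
  if (!name %in% known)
    stop("unknown fixture '", name, "'; available: ",
         paste(known, collapse = ", "))
  system.file("extdata", paste0(name, ".tsv"), package = "curehaz",
              mustWork = TRUE)
}

#' Registry table built from the embedded fixtures
#'
#' Convenience constructor pairing the stomach-cancer case fixture with the
#' male population fixture.
#'
#' @return A `registry_table`.
#' @export
fixture_registry <- function() {
  registry_table(load_fixture("stomach_men_entire_cases"),
                 load_fixture("men_entire_population"),
                 label = "stomach, men, entire region")
}

#' Run configuration
#'
#' Holds the analysis settings: grid origins, anchor indices for the
#' age-period-cohort fit (1-based, matching the printed tables), the
#' minimum-case threshold for retaining a cell, and an optional seed.
#'
#' @param title Experiment title.
#' @param start_age Youngest age of the first interval.
#' @param start_year First year of the first period.
#' @param time_interval Interval width (years), shared by ages and periods.
#' @param period_index Anchored period index j* (1-based).
#' @param age_index Anchored age index i* (1-based).
#' @param min_cases Cells with more than this many cases are retained
#'   (the SEER ">15 cases" convention).
#' @param exclude_masked Logical; if `TRUE` (default) sub-threshold cells get
#'   zero weight in the likelihood, if `FALSE` all cells are fitted.
#' @param n,J Grid sizes (used to range-check the anchors).
#' @param seed Optional integer seed recorded in manifests.
#' @return An object of class `run_config`.
#' @export
run_config <- function(title = "untitled", start_age = 20L, start_year = 1975L,
                       time_interval = 5L, period_index = 4L, age_index = 11L,
                       min_cases = 15L, exclude_masked = TRUE,
                       n = 16L, J = 7L, seed = NULL) {
  period_index <- as.integer(period_index)
  age_index <- as.integer(age_index)
  if (period_index < 1L || period_index > J)
    stop("period_index must be in 1..", J)
  if (age_index < 1L || age_index > n)
    stop("age_index must be in 1..", n)
  structure(
    list(title = title, start_age = as.integer(start_age),
         start_year = as.integer(start_year),
         time_interval = as.integer(time_interval),
         period_index = period_index, age_index = age_index,
         min_cases = as.integer(min_cases),
         exclude_masked = isTRUE(exclude_masked),
         n = as.integer(n), J = as.integer(J),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a flat key=value file
#'
#' Keys (case- and space-insensitive): Title, Start Age, Start Year,
#' Time Interval, Period Index, Age Index, Min Cases, Seed.
#'
#' @param path Path to the config file.
#' @param n,J Grid sizes for anchor range checks.
#' @return A [run_config()].
#' @export
read_run_config <- function(path, n = 16L, J = 7L) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- tolower(gsub("[ _]", "", trimws(sub("=.*$", "", lines))))
  vals <- trimws(sub("^[^=]*=", "", lines))
  get <- function(key, default) {
    hit <- which(keys == key)
    if (length(hit) == 0L) default else vals[hit[1]]
  }
  run_config(
    title = get("title", "untitled"),
    start_age = as.integer(get("startage", 20)),
    start_year = as.integer(get("startyear", 1975)),
    time_interval = as.integer(get("timeinterval", 5)),
    period_index = as.integer(get("periodindex", 4)),
    age_index = as.integer(get("ageindex", 11)),
    min_cases = as.integer(get("mincases", 15)),
    n = n, J = J,
    seed = {
      s <- get("seed", NA)
      if (is.na(suppressWarnings(as.integer(s)))) NULL else as.integer(s)
    }
  )
}

#' Write a run configuration as a flat key=value file
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- c(
    paste0("Title=", config$title),
    paste0("Start Age=", config$start_age),
    paste0("Start Year=", config$start_year),
    paste0("Time Interval=", config$time_interval),
    paste0("Period Index=", config$period_index),
    paste0("Age Index=", config$age_index),
    paste0("Min Cases=", config$min_cases)
  )
  if (!is.null(config$seed)) lines <- c(lines, paste0("Seed=", config$seed))
  writeLines(lines, path)
  invisible(path)
}
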