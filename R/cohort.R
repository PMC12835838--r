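#' Read an individual-level cohort from CSV
#'
#' Reads a delimited file of individual survey records, validates every cell
#' against the codebook's category labels, and returns a raw cohort tibble.
#' Missing values may be encoded as empty strings or the literal `"NA"`.
#'
#' @param path Path to a comma-delimited UTF-8 file with a header row naming
#'   every codebook variable and the outcome.
#' @param cb A [codebook()].
#' @return A tibble with one column per codebook variable plus the outcome,
#'   all character, with attribute `provenance = "raw"`.
#' @export
read_cohort <- function(path, cb) {
  stopifnot(inherits(cb, "maihda_codebook"))
  dat <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c("", "NA"), progress = FALSE
  )
  expected <- c(names(cb$variables), cb$outcome$name)
  missing_cols <- setdiff(expected, names(dat))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  unknown <- setdiff(names(dat), c("id", expected))
  if (length(unknown) > 0) {
    stop("cohort file has column(s) not in the codebook: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  dat <- dat[intersect(c("id", expected), names(dat))]
  validate_cohort_labels(dat, cb)
  as_cohort(dat, provenance = "raw")
}

as_cohort <- function(dat, provenance = c("raw", "filtered")) {
  provenance <- match.arg(provenance)
  out <- tibble::as_tibble(dat)
  attr(out, "provenance") <- provenance
  out
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
cohort_provenance <- function(cohort) {
  attr(cohort, "provenance") %||% "raw"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_cohort_labels <- function(dat, cb) {
  allowed <- c(
    purrr::map(cb$variables, "categories"),
    setNames(list(cb$outcome$categories), cb$outcome$name)
  )
  problems <- purrr::imap(allowed, function(labels, nm) {
    bad <- !is.na(dat[[nm]]) & !dat[[nm]] %in% labels
    if (any(bad)) {
      tibble::tibble(row = which(bad), variable = nm, value = dat[[nm]][bad])
    }
  })
  problems <- dplyr::bind_rows(problems)
  if (nrow(problems) > 0) {
    ex <- head(problems, 5)
    stop(
      "unknown category label(s):\n",
      paste(sprintf(
        "  row %d, %s = \"%s\"", ex$row, ex$variable, ex$value
      ), collapse = "\n"),
      if (nrow(problems) > 5) sprintf("\n  ... and %d more", nrow(problems) - 5),
      call. = FALSE
    )
  }
  invisible(dat)
}

#' Complete-case filter over key variables and the outcome
#'
#' Drops records that are missing — or carry a non-analytic category such as
#' "Did not know" — on any key variable or on the outcome, and reports the
#' exclusion accounting. The filter is idempotent: a filtered cohort passes
#' through unchanged with zero exclusions.
#'
#' @param cohort A cohort tibble (see [read_cohort()]).
#' @param cb The [codebook()] defining analytic categories and key variables.
#' @return A list with `cohort` (the filtered tibble, `provenance =
#'   "filtered"`) and `exclusions`, a list of class `exclusion_report`:
#'   `n_raw`, `n_excluded`, `n_retained`, `pct_excluded` (one decimal,
#'   half-up), and `per_variable`, a tibble of per-variable incomplete
#'   counts.
#' @export
filter_complete_cases <- function(cohort, cb) {
  stopifnot(inherits(cb, "maihda_codebook"))
  checked <- c(cb$key_variables, cb$outcome$name)
  incomplete_by_var <- purrr::map(setNames(checked, checked), function(nm) {
    labels <- if (nm == cb$outcome$name) {
      cb$outcome$categories
    } else {
      analytic_categories(cb, nm)
    }
    is.na(cohort[[nm]]) | !cohort[[nm]] %in% labels
  })
  drop <- Reduce(`|`, incomplete_by_var)
  n_raw <- nrow(cohort)
  n_excluded <- sum(drop)
  n_retained <- n_raw - n_excluded
  if (n_retained == 0) {
    stop("no analytic rows remain after complete-case filtering", call. = FALSE)
  }
  report <- structure(
    list(
      n_raw = n_raw,
      n_excluded = n_excluded,
      n_retained = n_retained,
      pct_excluded = round_half_up(100 * n_excluded / n_raw, 1),
      per_variable = tibble::tibble(
        variable = checked,
        n_incomplete = unname(purrr::map_int(incomplete_by_var, sum))
      )
    ),
    class = "exclusion_report"
  )
  list(
    cohort = as_cohort(cohort[!drop, , drop = FALSE], provenance = "filtered"),
    exclusions = report
  )
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf(
    "<exclusion_report> %d raw, %d excluded (%.1f%%), %d retained\n",
    x$n_raw, x$n_excluded, x$pct_excluded, x$n_retained
  ))
  invisible(x)
}

#' Serialize an exclusion report to JSON
#'
#' @param report An `exclusion_report` from [filter_complete_cases()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @export
exclusion_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "exclusion_report"))
  obj <- list(
    n_raw = report$n_raw,
    n_excluded = report$n_excluded,
    n_retained = report$n_retained,
    pct_excluded = report$pct_excluded,
    per_variable = report$per_variable
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' Descriptive frequency table
#'
#' Tabulates each variable's categories with counts and percentages, in the
#' style of a survey descriptive table. Percentages are computed over the
#' non-missing denominator of each variable and rounded half-up to one
#' decimal.
#'
#' @param cohort A cohort tibble.
#' @param cb Optional [codebook()]; when supplied, variables and categories
#'   appear in codebook order (including non-analytic categories that occur),
#'   otherwise all character columns are tabulated in data order.
#' @return A tibble with columns `variable`, `category`, `n`, `percent`.
#' @export
describe_cohort <- function(cohort, cb = NULL) {
  vars <- if (is.null(cb)) {
    names(cohort)[vapply(cohort, is.character, logical(1))]
  } else {
    intersect(c(names(cb$variables), cb$outcome$name), names(cohort))
  }
  purrr::map(setNames(vars, vars), function(nm) {
    x <- cohort[[nm]]
    x <- x[!is.na(x)]
    levels <- if (!is.null(cb)) {
      if (nm == cb$outcome$name) cb$outcome$categories else cb$variables[[nm]]$categories
    } else {
      unique(x)
    }
    counts <- table(factor(x, levels = levels))
    tibble::tibble(
      category = names(counts),
      n = as.integer(counts),
      percent = round_half_up(100 * as.integer(counts) / length(x), 1)
    ) |>
      dplyr::filter(.data$n > 0 | .data$category %in% x)
  }) |>
    dplyr::bind_rows(.id = "variable")
}

#' Cochran minimum sample size for a proportion
#'
#' The classical design-stage sample size for estimating a proportion by
#' simple random sampling: `n0 = z^2 p (1 - p) / epsilon^2`, with the
#' finite-population correction `n = n0 / (1 + (n0 - 1) / N)` when `N` is
#' bounded. Results are rounded up to the next integer; the finite
#' correction uses the unrounded `n0`.
#'
#' @param z Standard-normal percentile for the confidence level
#'   (1.96 for 95%).
#' @param epsilon Margin of error, as a proportion in (0, 1).
#' @param p Assumed population proportion in `[0, 1]` (0.5 is maximally
#'   conservative).
#' @param N Population size; `Inf` (default) for the unbounded formula.
#' @return Integer minimum sample size.
#' @examples
#' cochran_sample_size() # 385
#' cochran_sample_size(N = 1000) # 278
#' @export
cochran_sample_size <- function(z = 1.96, epsilon = 0.05, p = 0.5, N = Inf) {
  if (!is.finite(epsilon) || epsilon <= 0 || epsilon >= 1) {
    stop("epsilon must lie strictly between 0 and 1", call. = FALSE)
  }
  if (p < 0 || p > 1) stop("p must lie in [0, 1]", call. = FALSE)
  if (z <= 0) stop("z must be positive", call. = FALSE)
  if (N < 1) stop("N must be at least 1 when bounded", call. = FALSE)
  n0 <- z^2 * p * (1 - p) / epsilon^2
  if (is.infinite(N)) {
    as.integer(ceiling(n0))
  } else {
    as.integer(ceiling(n0 / (1 + (n0 - 1) / N)))
  }
}
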