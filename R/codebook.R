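#' Construct a codebook for an intersectional survey dataset
#'
#' A codebook defines the categorical social dimensions used to build
#' intersectional strata, the binary outcome, and which variables are
#' required for complete-case inclusion. Each variable carries an *ordered*
#' list of category labels; the order of the analytic categories fixes the
#' digit code each category receives in stratum IDs (see
#' [build_strata_schema()]). Categories can be flagged non-analytic (e.g.
#' `"No answer"`, `"Did not know"`): they are valid labels on input but are
#' treated as missing by the complete-case filter and never enter strata.
#'
#' @param variables Named list; one element per dimension, each a list with
#'   `categories` (character, ordered) and optionally `analytic` (logical of
#'   the same length, default all `TRUE`).
#' @param outcome List with `name`, `categories` (exactly 2 analytic labels),
#'   and `positive` (the label counted as the event).
#' @param key_variables Character vector of variable names required for
#'   complete-case inclusion. Defaults to all variables.
#'
#' @return An object of class `maihda_codebook`.
#' @seealso [study_codebook()] for the built-in digital-exclusion codebook.
#' @export
codebook <- function(variables, outcome, key_variables = names(variables)) {
  stopifnot(is.list(variables), length(variables) >= 1, !is.null(names(variables)))
  variables <- purrr::imap(variables, function(v, nm) {
    if (is.character(v)) v <- list(categories = v)
    if (is.null(v$analytic)) v$analytic <- rep(TRUE, length(v$categories))
    if (length(v$analytic) != length(v$categories)) {
      stop("analytic flags for '", nm, "' must match its categories", call. = FALSE)
    }
    if (length(v$categories) < 2) {
      stop("variable '", nm, "' must have at least 2 categories", call. = FALSE)
    }
    if (anyDuplicated(v$categories)) {
      stop("duplicate category labels in '", nm, "'", call. = FALSE)
    }
    analytic <- v$categories[v$analytic]
    if (is.null(v$reference)) v$reference <- analytic[1]
    if (!v$reference %in% analytic) {
      stop("reference for '", nm, "' must be an analytic category", call. = FALSE)
    }
    v[c("categories", "analytic", "reference")]
  })
  stopifnot(is.list(outcome), !is.null(outcome$name), !is.null(outcome$categories))
  if (length(outcome$categories) != 2) {
    stop("outcome must have exactly 2 analytic categories", call. = FALSE)
  }
  if (is.null(outcome$positive)) outcome$positive <- outcome$categories[1]
  if (!outcome$positive %in% outcome$categories) {
    stop("outcome positive label must be one of its categories", call. = FALSE)
  }
  if (!all(key_variables %in% names(variables))) {
    stop("key_variables must name codebook variables", call. = FALSE)
  }
  structure(
    list(variables = variables, outcome = outcome, key_variables = key_variables),
    class = "maihda_codebook"
  )
}

#' Codebook of the Brazilian digital-exclusion survey
#'
#' The default codebook mirrors the study design this package was written
#' around: five social dimensions — gender (2 analytic categories), race or
#' ethnicity (3), schooling (4), family income (4), and use of the public
#' health system, SUS (2) — and a binary outcome, whether the participant
#' sought COVID-19 information on the internet. "No answer" (gender) and
#' "Did not know" (income) are non-analytic. Analytic category order fixes
#' the stratum digit codes: e.g. Man = 1, Woman = 2; White = 1,
#' Black or Brown = 2, Other = 3.
#'
#' @return A `maihda_codebook`.
#' @examples
#' cb <- study_codebook()
#' names(cb$variables)
#' @export
study_codebook <- function() {
  codebook(
    variables = list(
      gender = list(
        categories = c("Man", "Woman", "No answer"),
        analytic = c(TRUE, TRUE, FALSE)
      ),
      race = list(
        categories = c("White", "Black or Brown", "Other"),
        reference = "Black or Brown"
      ),
      schooling = c(
        "No schooling", "Basic education",
        "Secondary education", "Higher education"
      ),
      income = list(
        categories = c(
          "Low income", "1-2 minimum wages", "2-3 minimum wages",
          "More than 3 minimum wages", "Did not know"
        ),
        analytic = c(TRUE, TRUE, TRUE, TRUE, FALSE)
      ),
      sus_use = c("Yes", "No")
    ),
    outcome = list(
      name = "sought_online",
      categories = c("Yes", "No"),
      positive = "Yes"
    )
  )
}

#' @export
print.maihda_codebook <- function(x, ...) {
  cat("<maihda_codebook>\n")
  for (nm in names(x$variables)) {
    v <- x$variables[[nm]]
    lab <- ifelse(v$analytic, v$categories, paste0("(", v$categories, ")"))
    cat(sprintf("  %-10s %s\n", nm, paste(lab, collapse = " | ")))
  }
  cat(sprintf(
    "  outcome: %s (%s; positive = %s)\n",
    x$outcome$name, paste(x$outcome$categories, collapse = "/"), x$outcome$positive
  ))
  cat("  key:", paste(x$key_variables, collapse = ", "), "\n")
  invisible(x)
}

analytic_categories <- function(cb, variable) {
  v <- cb$variables[[variable]]
  v$categories[v$analytic]
}

#' Read or write a codebook as YAML
#'
#' The YAML layout has a `variables` map (each with `categories` and optional
#' `analytic` flags), an `outcome` map (`name`, `categories`, `positive`),
#' and a `key_variables` list.
#'
#' @param path File path.
#' @param cb A `maihda_codebook`.
#' @return `read_codebook()` returns a `maihda_codebook`; `write_codebook()`
#'   returns `path` invisibly.
#' @export
read_codebook <- function(path) {
  y <- yaml::read_yaml(path)
  vars <- purrr::map(y$variables, function(v) {
    out <- list(
      categories = as.character(v$categories),
      analytic = if (is.null(v$analytic)) rep(TRUE, length(v$categories)) else as.logical(v$analytic)
    )
    if (!is.null(v$reference)) out$reference <- v$reference
    out
  })
  codebook(vars, y$outcome,
    key_variables = if (is.null(y$key_variables)) names(vars) else y$key_variables
  )
}

#' @rdname read_codebook
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "maihda_codebook"))
  yaml::write_yaml(
    list(variables = cb$variables, outcome = cb$outcome, key_variables = cb$key_variables),
    path
  )
  invisible(path)
}
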