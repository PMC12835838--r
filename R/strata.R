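#' Build the intersectional strata schema
#'
#' The schema is the full cross-classification of the codebook's analytic
#' categories: with dimensions of sizes (2, 3, 4, 4, 2) it defines
#' 2 x 3 x 4 x 4 x 2 = 192 possible intersectional strata. Each stratum gets
#' a digit-string ID with one digit per dimension, the digit being the
#' category's 1-based position in the codebook's ordered analytic list (so a
#' dimension may have at most 9 analytic categories).
#'
#' @param cb A [codebook()].
#' @return An object of class `strata_schema` with elements `dimensions`
#'   (named list of ordered analytic category labels) and `n_possible`.
#' @examples
#' build_strata_schema(study_codebook())$n_possible # 192
#' @export
build_strata_schema <- function(cb) {
  stopifnot(inherits(cb, "maihda_codebook"))
  dims <- purrr::imap(cb$variables[cb$key_variables], function(v, nm) {
    cats <- v$categories[v$analytic]
    if (length(cats) < 2) {
      stop("dimension '", nm, "' has fewer than 2 analytic categories", call. = FALSE)
    }
    if (length(cats) > 9) {
      stop("dimension '", nm, "' exceeds 9 analytic categories (single-digit IDs)",
        call. = FALSE
      )
    }
    cats
  })
  structure(
    list(dimensions = dims, n_possible = as.integer(prod(lengths(dims)))),
    class = "strata_schema"
  )
}

#' @export
print.strata_schema <- function(x, ...) {
  cat(sprintf(
    "<strata_schema> %d possible strata (%s)\n",
    x$n_possible, paste(lengths(x$dimensions), collapse = " x ")
  ))
  invisible(x)
}

#' Encode and decode digit-string stratum IDs
#'
#' `encode_stratum()` maps category labels to the digit-string ID (one digit
#' per dimension, in schema order); `decode_stratum()` inverts it. The two
#' form a bijection over all possible strata.
#'
#' @param labels A data frame (or tibble) with one column per schema
#'   dimension holding analytic category labels.
#' @param schema A [build_strata_schema()] result.
#' @return `encode_stratum()`: character vector of IDs. `decode_stratum()`:
#'   tibble of labels, one column per dimension.
#' @examples
#' sch <- build_strata_schema(study_codebook())
#' encode_stratum(
#'   data.frame(
#'     gender = "Woman", race = "White", schooling = "Secondary education",
#'     income = "1-2 minimum wages", sus_use = "Yes"
#'   ),
#'   sch
#' ) # "21321"
#' @export
encode_stratum <- function(labels, schema) {
  stopifnot(inherits(schema, "strata_schema"))
  digits <- purrr::imap(schema$dimensions, function(cats, nm) {
    idx <- match(labels[[nm]], cats)
    if (anyNA(idx) && !anyNA(labels[[nm]])) {
      bad <- unique(labels[[nm]][is.na(idx)])
      stop("cannot encode non-analytic or unknown '", nm, "' value(s): ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    idx
  })
  do.call(paste0, digits)
}

#' @rdname encode_stratum
#' @param id Character vector of digit-string stratum IDs.
#' @export
decode_stratum <- function(id, schema) {
  stopifnot(inherits(schema, "strata_schema"))
  ndim <- length(schema$dimensions)
  if (any(nchar(id) != ndim)) {
    stop("stratum IDs must have one digit per dimension (", ndim, ")", call. = FALSE)
  }
  out <- purrr::imap(schema$dimensions, function(cats, nm) {
    pos <- match(nm, names(schema$dimensions))
    d <- as.integer(substr(id, pos, pos))
    if (any(d < 1 | d > length(cats))) {
      stop("digit out of range for dimension '", nm, "'", call. = FALSE)
    }
    cats[d]
  })
  tibble::as_tibble(out)
}

#' Assign stratum IDs to a filtered cohort
#'
#' Adds a `stratum` column with the digit-string ID of each record's
#' intersectional cell.
#'
#' @param cohort A filtered cohort tibble (all key variables analytic,
#'   no missing values).
#' @param schema A [build_strata_schema()] result.
#' @return The cohort with a `stratum` character column appended.
#' @export
assign_strata <- function(cohort, schema) {
  ids <- encode_stratum(cohort, schema)
  if (anyNA(ids)) {
    stop("cohort contains missing values on stratum dimensions; filter first",
      call. = FALSE
    )
  }
  out <- dplyr::mutate(cohort, stratum = ids)
  attr(out, "provenance") <- cohort_provenance(cohort)
  out
}

#' Tabulate all possible strata with observed counts
#'
#' Materializes every possible stratum of the schema — observed or not — with
#' its category labels, observed count, and an `observed` flag. Unobserved
#' strata are kept (with `n_obs = 0`) so that downstream prediction can flag
#' them as prior-only.
#'
#' @param cohort A cohort tibble with a `stratum` column (see
#'   [assign_strata()]).
#' @param schema A [build_strata_schema()] result.
#' @return A tibble with `n_possible` rows: `stratum`, one column per
#'   dimension, `n_obs`, `observed`, ordered by stratum ID.
#' @export
tabulate_strata <- function(cohort, schema) {
  stopifnot(inherits(schema, "strata_schema"))
  all_cells <- tidyr::expand_grid(!!!schema$dimensions)
  all_cells$stratum <- encode_stratum(all_cells, schema)
  counts <- if (nrow(cohort) > 0 && "stratum" %in% names(cohort)) {
    dplyr::count(cohort, .data$stratum, name = "n_obs")
  } else {
    tibble::tibble(stratum = character(), n_obs = integer())
  }
  all_cells |>
    dplyr::left_join(counts, by = "stratum") |>
    dplyr::mutate(
      n_obs = dplyr::coalesce(.data$n_obs, 0L),
      observed = .data$n_obs > 0L
    ) |>
    dplyr::relocate("stratum") |>
    dplyr::arrange(.data$stratum)
}

#' Number of observed strata
#'
#' @param strata A strata table from [tabulate_strata()].
#' @return Integer count of strata with at least one observation.
#' @export
n_observed_strata <- function(strata) {
  sum(strata$n_obs > 0L)
}
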