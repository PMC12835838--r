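# Seeded synthetic cohorts with the statistical structure the MAIHDA
# analysis assumes: independent categorical dimensions drawn from survey
# marginals, an additive log-odds outcome model, a per-stratum interaction
# deviation drawn once for every possible cell, and per-variable missingness
# applied last.

default_marginals <- function() {
  # analytic-sample approximations: published descriptive counts
  # renormalized over analytic categories
  list(
    gender = c("Man" = 1600, "Woman" = 1001) / 2601,
    race = c("White" = 601, "Black or Brown" = 1942, "Other" = 109) / 2652,
    schooling = c(
      "No schooling" = 905, "Basic education" = 726,
      "Secondary education" = 871, "Higher education" = 148
    ) / 2650,
    income = c(
      "Low income" = 1655, "1-2 minimum wages" = 570,
      "2-3 minimum wages" = 157, "More than 3 minimum wages" = 94
    ) / 2476,
    sus_use = c("Yes" = 2433, "No" = 219) / 2652
  )
}

default_betas <- function() {
  # additive log-odds effects: natural logs of the reference survey's
  # fitted odds ratios, references Man / Black or Brown / No schooling /
  # Low income / SUS yes
  list(
    gender = c("Woman" = log(1.49)),
    race = c("White" = log(1.05), "Other" = log(1.35)),
    schooling = c(
      "Basic education" = log(1.78),
      "Secondary education" = log(3.37),
      "Higher education" = log(5.59)
    ),
    income = c(
      "1-2 minimum wages" = log(2.37),
      "2-3 minimum wages" = log(2.85),
      "More than 3 minimum wages" = log(4.54)
    ),
    sus_use = c("No" = log(0.92))
  )
}

default_missingness <- function() {
  # gender "No answer" and income "Did not know" shares of the reference
  # survey, plus a residual outcome rate chosen so the expected incomplete
  # share under independence matches its 9.3% complete-case exclusion
  c(gender = 51 / 2652, income = 176 / 2652, sought_online = 0.0096)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the Brazilian digital-exclusion survey this package was
#' designed around: category marginals from its descriptive table
#' (renormalized over analytic categories), additive log-odds effects equal
#' to the natural logs of its fitted odds ratios, a baseline log-odds of
#' `log(0.19)`, a small between-stratum interaction variance (0.033, the
#' residual variance implied by a full-model VPC of 1%), and missingness
#' rates reproducing its ~9.3% complete-case exclusion in expectation.
#'
#' @param n Cohort size (default 2652, the survey's raw sample).
#' @param cb Codebook (default [study_codebook()]).
#' @param marginals Named list of per-dimension category probability vectors
#'   (each summing to 1 over analytic categories).
#' @param beta0 Baseline log-odds of the outcome.
#' @param betas Named list of named numeric vectors: additive log-odds per
#'   non-reference category; omitted categories contribute 0.
#' @param sigma_int2 Between-stratum interaction variance (latent scale).
#' @param explicit_interactions Named numeric vector of extra log-odds for
#'   specific stratum IDs, e.g. `c("12111" = 1)`.
#' @param missingness Named numeric vector of per-variable missingness rates
#'   in `[0, 1)`; names are dimension names or the outcome name.
#' @param tilt Optional log-linear association between schooling and income
#'   index ranks (default 0 = independent dimensions), for stress tests.
#' @param seed Integer seed; the same config + seed always reproduces the
#'   same cohort.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 2652, cb = study_codebook(),
                             marginals = default_marginals(),
                             beta0 = log(0.19), betas = default_betas(),
                             sigma_int2 = 0.033,
                             explicit_interactions = NULL,
                             missingness = default_missingness(),
                             tilt = 0, seed = 1) {
  stopifnot(inherits(cb, "maihda_codebook"))
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (sigma_int2 < 0) stop("sigma_int2 must be non-negative", call. = FALSE)
  schema <- build_strata_schema(cb)
  for (nm in names(schema$dimensions)) {
    m <- marginals[[nm]]
    if (is.null(m)) stop("marginals missing for dimension '", nm, "'", call. = FALSE)
    if (!setequal(names(m), schema$dimensions[[nm]])) {
      stop("marginals for '", nm, "' must name its analytic categories", call. = FALSE)
    }
    if (abs(sum(m) - 1) > 1e-9) {
      stop("marginals for '", nm, "' must sum to 1", call. = FALSE)
    }
    if (any(m < 0)) stop("marginals must be non-negative", call. = FALSE)
  }
  for (nm in names(betas)) {
    if (!nm %in% names(schema$dimensions)) {
      stop("betas name unknown dimension '", nm, "'", call. = FALSE)
    }
    bad <- setdiff(names(betas[[nm]]), schema$dimensions[[nm]])
    if (length(bad) > 0) {
      stop("betas for '", nm, "' name unknown categories: ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (!is.null(explicit_interactions)) {
    stopifnot(is.numeric(explicit_interactions), !is.null(names(explicit_interactions)))
    if (any(nchar(names(explicit_interactions)) != length(schema$dimensions))) {
      stop("explicit_interactions must be named by stratum IDs", call. = FALSE)
    }
  }
  if (length(missingness) > 0) {
    ok_names <- c(names(schema$dimensions), cb$outcome$name)
    if (!all(names(missingness) %in% ok_names)) {
      stop("missingness names must be dimensions or the outcome", call. = FALSE)
    }
    if (any(missingness < 0 | missingness >= 1)) {
      stop("missingness rates must lie in [0, 1)", call. = FALSE)
    }
  }
  structure(
    list(
      n = as.integer(n), cb = cb, schema = schema, marginals = marginals,
      beta0 = beta0, betas = betas, sigma_int2 = sigma_int2,
      explicit_interactions = explicit_interactions,
      missingness = missingness, tilt = tilt, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Additive log-odds for rows of category labels.
additive_eta <- function(config, labels) {
  eta <- rep(config$beta0, nrow(labels))
  for (nm in names(config$betas)) {
    b <- config$betas[[nm]]
    hit <- match(labels[[nm]], names(b))
    eta <- eta + ifelse(is.na(hit), 0, b[hit])
  }
  eta
}

# Realized per-stratum deviations; the *first* draws under the config seed,
# so generate_population() and truth_record() agree.
realized_deviations <- function(config) {
  u <- rnorm(config$schema$n_possible) * sqrt(config$sigma_int2)
  cells <- tidyr::expand_grid(!!!config$schema$dimensions)
  ids <- encode_stratum(cells, config$schema)
  names(u) <- ids
  if (!is.null(config$explicit_interactions)) {
    tgt <- names(config$explicit_interactions)
    miss <- setdiff(tgt, ids)
    if (length(miss) > 0) {
      stop("explicit_interactions name unknown strata: ",
        paste(miss, collapse = ", "),
        call. = FALSE
      )
    }
    u[tgt] <- u[tgt] + config$explicit_interactions
  }
  u
}

#' Generate a synthetic cohort
#'
#' Draws category labels independently per dimension from the configured
#' marginals (optionally with a schooling-income association tilt), one
#' latent deviation per possible stratum from `Normal(0, sigma_int2)` plus
#' any explicit interactions, the binary outcome from the additive
#' log-odds model, and finally applies per-variable missingness. Identical
#' config and seed give identical output.
#'
#' @param config A [synthetic_config()].
#' @return A raw cohort tibble (`id`, one column per dimension, outcome)
#'   with the config attached as attribute `"config"`.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cb <- config$cb
  schema <- config$schema
  n <- config$n
  withr::with_seed(config$seed, {
    u <- realized_deviations(config)
    labels <- if (config$tilt != 0) {
      draw_dimensions_tilted(config)
    } else {
      tibble::as_tibble(purrr::map(config$marginals, function(m) {
        sample(names(m), n, replace = TRUE, prob = m)
      }))
    }
    stratum <- encode_stratum(labels, schema)
    eta <- additive_eta(config, labels) + unname(u[stratum])
    y <- rbinom(n, 1, plogis(eta))
    out_labels <- cb$outcome$categories
    positive <- cb$outcome$positive
    negative <- setdiff(out_labels, positive)[1]
    dat <- labels
    dat[[cb$outcome$name]] <- ifelse(y == 1, positive, negative)
    for (nm in names(config$missingness)) {
      rate <- config$missingness[[nm]]
      if (rate > 0) {
        dat[[nm]][stats::runif(n) < rate] <- NA_character_
      }
    }
  })
  dat <- dplyr::bind_cols(tibble::tibble(id = seq_len(n)), dat)
  out <- as_cohort(dat, provenance = "raw")
  attr(out, "config") <- config
  out
}

# Joint schooling-income draw under a log-linear tilt on category ranks;
# other dimensions stay independent.
draw_dimensions_tilted <- function(config) {
  n <- config$n
  m <- config$marginals
  ps <- m$schooling
  pi_ <- m$income
  joint <- outer(ps, pi_) *
    exp(config$tilt * outer(seq_along(ps) - 1, seq_along(pi_) - 1))
  joint <- joint / sum(joint)
  cell <- sample(length(joint), n, replace = TRUE, prob = as.vector(joint))
  row_i <- (cell - 1) %% length(ps) + 1
  col_i <- (cell - 1) %/% length(ps) + 1
  out <- purrr::imap(m, function(probs, nm) {
    if (nm == "schooling") {
      names(ps)[row_i]
    } else if (nm == "income") {
      names(pi_)[col_i]
    } else {
      sample(names(probs), n, replace = TRUE, prob = probs)
    }
  })
  tibble::as_tibble(out)
}

#' True stratum probabilities of a synthetic configuration
#'
#' The oracle table behind parameter-recovery tests: for every possible
#' stratum, the additive log-odds, the realized latent deviation (drawn
#' exactly as [generate_population()] draws it under the same seed), and
#' the implied additive and total true probabilities.
#'
#' @param config A [synthetic_config()].
#' @return A tibble with one row per possible stratum: `stratum`, dimension
#'   labels, `eta_additive`, `u`, `eta_total`, `p_additive`, `p_total`
#'   (probabilities as proportions). Attributes `beta0`, `betas`,
#'   `sigma_int2`, and `realized_var_u` carry the generating truth.
#' @export
truth_record <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  u <- withr::with_seed(config$seed, realized_deviations(config))
  cells <- tidyr::expand_grid(!!!config$schema$dimensions)
  cells$stratum <- encode_stratum(cells, config$schema)
  eta_add <- additive_eta(config, cells)
  out <- cells |>
    dplyr::mutate(
      eta_additive = eta_add,
      u = unname(u[.data$stratum]),
      eta_total = eta_add + .data$u,
      p_additive = plogis(eta_add),
      p_total = plogis(.data$eta_total)
    ) |>
    dplyr::relocate("stratum") |>
    dplyr::arrange(.data$stratum)
  attr(out, "beta0") <- config$beta0
  attr(out, "betas") <- config$betas
  attr(out, "sigma_int2") <- config$sigma_int2
  attr(out, "realized_var_u") <- var(out$u)
  out
}
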