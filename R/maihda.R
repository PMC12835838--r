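# The two-model MAIHDA workflow: a null random-intercept model captures
# total between-stratum inequality; a full model with additive main effects
# for every stratum dimension absorbs the additive part, leaving residual
# between-stratum variance attributable to intersectional interaction.

#' Variance partition coefficient on the latent scale
#'
#' Share of total latent-response variance lying between strata,
#' \eqn{100\,\sigma_u^2 / (\sigma_u^2 + \pi^2/3)}, with \eqn{\pi^2/3
#' \approx 3.29} the fixed level-1 residual of the logistic latent-response
#' formulation.
#'
#' @param sigma_u2 Between-stratum variance (log-odds scale), `>= 0`.
#' @return VPC in percent.
#' @export
vpc <- function(sigma_u2) {
  if (any(sigma_u2 < 0)) stop("sigma_u2 must be non-negative", call. = FALSE)
  100 * sigma_u2 / (sigma_u2 + pi^2 / 3)
}

#' Proportional change in variance
#'
#' Relative reduction of the between-stratum variance when additive main
#' effects enter the model: \eqn{100 (\sigma^2_{null} - \sigma^2_{full}) /
#' \sigma^2_{null}}. Its complement (100 − PCV) indexes the share of
#' between-stratum variance attributable to intersectional interactions.
#'
#' @param sigma_null Null-model between-stratum variance, `> 0`.
#' @param sigma_full Full-model between-stratum variance, `>= 0`.
#' @return PCV in percent.
#' @export
pcv <- function(sigma_null, sigma_full) {
  if (any(sigma_null <= 0)) {
    stop("pcv undefined: null-model variance must be positive", call. = FALSE)
  }
  if (any(sigma_full < 0)) stop("sigma_full must be non-negative", call. = FALSE)
  100 * (sigma_null - sigma_full) / sigma_null
}

#' Mann-Whitney AUC with midrank tie correction
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted one half — identical to exhaustive
#' concordant/discordant pair counting.
#'
#' @param scores Numeric prediction scores.
#' @param y Binary outcomes (0/1 or logical).
#' @return AUC as a proportion in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, y) {
  y <- as.numeric(y)
  stopifnot(length(scores) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC undefined: outcome is constant", call. = FALSE)
  }
  r <- rank(scores) # average ranks = midrank tie correction
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discriminatory accuracy of the intersectional strata
#'
#' Scores every individual with their stratum's predicted probability under
#' `fit` (fixed-effect linear predictor plus the stratum's empirical-Bayes
#' deviation; for a null model this is intercept + deviation) and computes
#' the tie-corrected Mann-Whitney AUC against the observed outcome.
#'
#' @param fit A converged [fit_glmm()] result.
#' @param cohort The filtered, stratified cohort the fit was estimated on.
#' @return AUC as a proportion.
#' @export
auc_discrimination <- function(fit, cohort) {
  stopifnot(inherits(fit, "maihda_glmm"))
  eb <- predict_random_effects(fit)
  eb_by <- setNames(eb$eb_value, eb$group)
  eta <- fixed_linear_predictor(fit, cohort) +
    eb_by[as.character(cohort[[fit$group_var]])]
  y <- cohort[[fit$outcome$name]] == fit$outcome$positive
  auc_mann_whitney(plogis(unname(eta)), y)
}

#' Stratum predicted probabilities with additive/interaction decomposition
#'
#' For every possible stratum: the total predicted probability from the full
#' model (fixed effects + empirical-Bayes stratum deviation), the additive
#' component from the fixed effects alone, and their difference — the
#' interaction component, the stratum's departure from additivity in
#' percentage points. A parallel null-model probability (null intercept +
#' null EB deviation) is attached for ranking and caterpillar output.
#' Unobserved strata are flagged and carry additive-only totals (prior-only
#' EB deviation of zero).
#'
#' @param null_fit,full_fit Converged [fit_glmm()] results for the null and
#'   full (additive main effects) models.
#' @param schema The [build_strata_schema()] result.
#' @param strata Optional strata table from [tabulate_strata()] (supplies
#'   `n_obs`); reconstructed from the fits when omitted.
#' @return A tibble with one row per possible stratum: `stratum`, the
#'   dimension labels, `n_obs`, `observed`, `p_null`, `p_additive`,
#'   `p_total`, `interaction` (all probabilities in percent), and `rank`
#'   (ascending by `p_total` among observed strata, ties by stratum ID).
#' @export
stratum_predictions <- function(null_fit, full_fit, schema, strata = NULL) {
  stopifnot(
    inherits(null_fit, "maihda_glmm"), inherits(full_fit, "maihda_glmm"),
    inherits(schema, "strata_schema")
  )
  if (is.null(strata)) {
    cells <- tidyr::expand_grid(!!!schema$dimensions)
    cells$stratum <- encode_stratum(cells, schema)
    counts <- tibble::tibble(
      stratum = full_fit$collapsed$group_levels,
      n_obs = as.integer(group_sum(
        full_fit$collapsed$n, full_fit$collapsed$gidx, full_fit$collapsed$G
      ))
    )
    strata <- cells |>
      dplyr::left_join(counts, by = "stratum") |>
      dplyr::mutate(
        n_obs = dplyr::coalesce(.data$n_obs, 0L),
        observed = .data$n_obs > 0
      ) |>
      dplyr::relocate("stratum") |>
      dplyr::arrange(.data$stratum)
  }
  re_full <- predict_random_effects(full_fit, groups = strata$stratum)
  re_null <- predict_random_effects(null_fit, groups = strata$stratum)
  eta_fix <- fixed_linear_predictor(full_fit, strata)
  eta_null <- fixed_linear_predictor(null_fit, strata)
  out <- strata |>
    dplyr::mutate(
      eta_additive = eta_fix,
      eb_full = re_full$eb_value,
      eb_null = re_null$eb_value,
      posterior_sd_full = re_full$posterior_sd,
      posterior_sd_null = re_null$posterior_sd,
      p_null = 100 * plogis(eta_null + re_null$eb_value),
      p_additive = 100 * plogis(eta_fix),
      p_total = 100 * plogis(eta_fix + re_full$eb_value),
      interaction = .data$p_total - .data$p_additive
    )
  ord <- order(out$p_total, out$stratum)
  rk <- rep(NA_integer_, nrow(out))
  obs_in_order <- ord[out$observed[ord]]
  rk[obs_in_order] <- seq_along(obs_in_order)
  out$rank <- rk
  out
}

#' Parametric-simulation confidence intervals for stratum probabilities
#'
#' Draws fixed effects from their asymptotic normal distribution and each
#' stratum's random-intercept deviation from its empirical-Bayes posterior
#' normal approximation, `B` times, and takes 2.5/97.5 percentiles of the
#' implied probabilities. Seeded and reproducible; the global RNG state is
#' left untouched.
#'
#' @param predictions A [stratum_predictions()] tibble.
#' @param null_fit,full_fit The fits the predictions came from.
#' @param B Number of simulation replicates (default 1000; a warning is
#'   attached below 100).
#' @param seed Integer seed (required).
#' @param level Confidence level (default 0.95).
#' @return `predictions` with `ci_lower`/`ci_upper` (total probability) and
#'   `ci_null_lower`/`ci_null_upper` (null-model probability) in percent.
#' @export
add_prediction_cis <- function(predictions, null_fit, full_fit, B = 1000,
                               seed, level = 0.95) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (B < 100) {
    warning("B = ", B, " simulation replicates is too few for stable percentiles",
      call. = FALSE
    )
  }
  if (!full_fit$hess_ok || !null_fit$hess_ok) {
    stop("cannot simulate CIs: fixed-effect covariance unavailable", call. = FALSE)
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  S <- nrow(predictions)
  Xfix <- build_fixed_design(predictions, full_fit$codebook, full_fit$fixed)
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, {
    beta_draws <- MASS::mvrnorm(B, full_fit$beta, full_fit$vcov_beta)
    eta_draws <- Xfix %*% t(beta_draws) # S x B
    u_draws <- matrix(
      rnorm(S * B, mean = predictions$eb_full, sd = predictions$posterior_sd_full),
      S, B
    )
    p_tot <- 100 * plogis(eta_draws + u_draws)
    b0_draws <- rnorm(B, null_fit$beta[1], null_fit$se_beta[1])
    u0_draws <- matrix(
      rnorm(S * B, mean = predictions$eb_null, sd = predictions$posterior_sd_null),
      S, B
    )
    p_null <- 100 * plogis(matrix(b0_draws, S, B, byrow = TRUE) + u0_draws)
  })
  qt <- unname(t(apply(p_tot, 1, quantile, probs = probs, names = FALSE)))
  qn <- unname(t(apply(p_null, 1, quantile, probs = probs, names = FALSE)))
  dplyr::mutate(predictions,
    ci_lower = qt[, 1], ci_upper = qt[, 2],
    ci_null_lower = qn[, 1], ci_null_upper = qn[, 2]
  )
}

#' Extreme strata by predicted probability
#'
#' The `k` observed strata with the lowest and the highest ranking
#' probability, in the style of a best/worst strata table. Ties are broken
#' by stratum ID (lexicographic), so output is deterministic.
#'
#' @param predictions A [stratum_predictions()] tibble.
#' @param k Number of strata per table (default 5).
#' @param by Ranking probability: `"null"` (default, null-model predicted
#'   probability, the convention for caterpillar-style summaries) or
#'   `"total"` (full-model prediction).
#' @return A list of two tibbles, `lowest` and `highest`, each sorted
#'   ascending; truncated with a warning if fewer than `2k` strata are
#'   observed.
#' @export
extremes <- function(predictions, k = 5, by = c("null", "total")) {
  by <- match.arg(by)
  col <- if (by == "null") "p_null" else "p_total"
  obs <- dplyr::filter(predictions, .data$observed)
  obs <- obs[order(obs[[col]], obs$stratum), , drop = FALSE]
  if (nrow(obs) < 2 * k) {
    warning("only ", nrow(obs), " observed strata; extreme tables truncated",
      call. = FALSE
    )
  }
  k_lo <- min(k, nrow(obs))
  k_hi <- min(k, max(nrow(obs) - k_lo, 0))
  list(
    lowest = utils::head(obs, k_lo),
    highest = utils::tail(obs, k_hi)
  )
}

#' Run the two-model intersectional MAIHDA workflow
#'
#' Fits the null model (random stratum intercept only) and the full model
#' (additive main effects for every stratum dimension plus the random
#' intercept), then derives the latent-scale VPC of each model, the PCV,
#' the discriminatory AUC of each model, and per-stratum predicted
#' probabilities with the additive/interaction decomposition.
#'
#' @param cohort A filtered cohort tibble; a `stratum` column is added via
#'   [assign_strata()] if absent.
#' @param cb The [codebook()].
#' @param nodes Gauss-Hermite node count for both fits (default 15).
#' @param ci_reps Parametric-simulation replicates for stratum CIs
#'   (default 1000; set 0 to skip).
#' @param seed Integer seed for the CI simulation; when `NULL` CIs are
#'   skipped.
#' @return An object of class `maihda`: `null_fit`, `full_fit`, `vpc_null`,
#'   `vpc_full`, `pcv`, `auc_null`, `auc_full`, `predictions`, `schema`,
#'   `strata`, `n_obs`, `n_observed_strata`. Supports [tidy()], [glance()],
#'   [autoplot()].
#' @export
run_maihda <- function(cohort, cb, nodes = 15, ci_reps = 1000, seed = NULL) {
  stopifnot(inherits(cb, "maihda_codebook"))
  schema <- build_strata_schema(cb)
  if (!"stratum" %in% names(cohort)) {
    cohort <- assign_strata(cohort, schema)
  }
  strata <- tabulate_strata(cohort, schema)
  if (n_observed_strata(strata) < 2) {
    stop("need at least 2 observed strata for MAIHDA", call. = FALSE)
  }
  null_fit <- tryCatch(
    fit_glmm(cohort, cb, fixed = NULL, nodes = nodes),
    error = function(e) stop("null model (model 1): ", conditionMessage(e), call. = FALSE)
  )
  full_fit <- tryCatch(
    fit_glmm(cohort, cb, fixed = names(schema$dimensions), nodes = nodes),
    error = function(e) stop("full model (model 2): ", conditionMessage(e), call. = FALSE)
  )
  preds <- stratum_predictions(null_fit, full_fit, schema, strata)
  if (!is.null(seed) && ci_reps > 0) {
    preds <- add_prediction_cis(preds, null_fit, full_fit, B = ci_reps, seed = seed)
  }
  structure(
    list(
      null_fit = null_fit, full_fit = full_fit,
      vpc_null = vpc(null_fit$sigma_u2),
      vpc_full = vpc(full_fit$sigma_u2),
      pcv = pcv(null_fit$sigma_u2, full_fit$sigma_u2),
      auc_null = auc_discrimination(null_fit, cohort),
      auc_full = auc_discrimination(full_fit, cohort),
      predictions = preds,
      schema = schema, strata = strata,
      n_obs = null_fit$n_obs,
      n_observed_strata = n_observed_strata(strata)
    ),
    class = "maihda"
  )
}

#' @export
print.maihda <- function(x, ...) {
  cat(sprintf(
    "<maihda> %d individuals in %d of %d possible strata\n",
    x$n_obs, x$n_observed_strata, x$schema$n_possible
  ))
  cat(sprintf(
    "  VPC: null %.1f%%, full %.1f%% | PCV %.1f%% | AUC: null %.3f, full %.3f\n",
    x$vpc_null, x$vpc_full, x$pcv, x$auc_null, x$auc_full
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.maihda <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  tidy(x$full_fit, exponentiate = exponentiate, conf.level = conf.level)
}

#' @exportS3Method generics::glance
glance.maihda <- function(x, ...) {
  tibble::tibble(
    vpc_null = x$vpc_null,
    vpc_full = x$vpc_full,
    pcv = x$pcv,
    auc_null = x$auc_null,
    auc_full = x$auc_full,
    sigma_u2_null = x$null_fit$sigma_u2,
    sigma_u2_full = x$full_fit$sigma_u2,
    nobs = x$n_obs,
    n_observed_strata = x$n_observed_strata
  )
}

#' Ranked null-model stratum probabilities (caterpillar data)
#'
#' Observed strata sorted ascending by null-model predicted probability —
#' the data behind the classic MAIHDA caterpillar plot.
#'
#' @param x A `maihda` result.
#' @return A tibble of observed strata with `rank_null` and `p_null`
#'   (plus null CIs when present), monotone non-decreasing in `p_null`.
#' @export
ranked_predictions <- function(x) {
  stopifnot(inherits(x, "maihda"))
  obs <- dplyr::filter(x$predictions, .data$observed)
  obs <- obs[order(obs$p_null, obs$stratum), , drop = FALSE]
  dplyr::mutate(obs, rank_null = dplyr::row_number()) |>
    dplyr::relocate("rank_null")
}

#' Caterpillar and decomposition plots for a MAIHDA result
#'
#' `type = "caterpillar"` draws observed strata ranked by null-model
#' predicted probability with 95% interval bars (when CIs were computed);
#' `type = "decomposition"` draws each observed stratum's interaction
#' component (total minus additive predicted probability).
#'
#' @param object A `maihda` result.
#' @param type Plot type.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.maihda <- function(object, type = c("caterpillar", "decomposition"), ...) {
  type <- match.arg(type)
  if (type == "caterpillar") {
    dat <- ranked_predictions(object)
    p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$rank_null, y = .data$p_null))
    if ("ci_null_lower" %in% names(dat)) {
      p <- p + ggplot2::geom_linerange(
        ggplot2::aes(ymin = .data$ci_null_lower, ymax = .data$ci_null_upper),
        color = "grey60"
      )
    }
    p +
      ggplot2::geom_point(size = 0.9) +
      ggplot2::labs(
        x = "Stratum rank (null model)",
        y = "Predicted probability (%)",
        title = "Ranked stratum probabilities, null model"
      ) +
      ggplot2::theme_minimal()
  } else {
    dat <- dplyr::filter(object$predictions, .data$observed)
    dat <- dat[order(dat$interaction, dat$stratum), , drop = FALSE]
    dat$idx <- seq_len(nrow(dat))
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$idx, y = .data$interaction)) +
      ggplot2::geom_col(width = 0.8) +
      ggplot2::labs(
        x = "Stratum (sorted)",
        y = "Interaction component (percentage points)",
        title = "Departure from additivity by stratum"
      ) +
      ggplot2::theme_minimal()
  }
}
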