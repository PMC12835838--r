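cb <- study_codebook()
schema <- build_strata_schema(cb)

additive_cohort <- function(n, seed, ...) {
  cfg <- synthetic_config(n = n, sigma_int2 = 0, missingness = c(), seed = seed, ...)
  assign_strata(generate_population(cfg), schema)
}

test_that("VPC and PCV follow the latent-scale formulas and their invariances", {
  expect_equal(vpc(0), 0)
  expect_equal(vpc(pi^2 / 3), 50)
  expect_equal(vpc(3.29), 50, tolerance = 1e-3)
  expect_equal(vpc(9.87), 75, tolerance = 1e-4) # 3 * 3.29 against 3.29
  expect_error(vpc(-0.1), "non-negative")
  # strictly increasing in the between-stratum variance
  s <- seq(0, 5, by = 0.25)
  expect_true(all(diff(vpc(s)) > 0))

  expect_equal(pcv(1, 1), 0)
  expect_equal(pcv(1, 0), 100)
  expect_equal(pcv(1, 0.03), 97)
  expect_error(pcv(0, 0.5), "positive")
  expect_error(pcv(1, -1), "non-negative")
  # invariant to common rescaling of both variances
  expect_equal(pcv(2.4, 0.6), pcv(2.4 * 7.3, 0.6 * 7.3))
})

test_that("Mann-Whitney AUC equals exhaustive pair counting, ties at one half", {
  expect_equal(auc_mann_whitney(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc_mann_whitney(c(0.9, 0.9, 0.1, 0.1), c(1, 1, 0, 0)), 1.0)

  set.seed(77)
  # 30-observation fixture with 3 score levels, then larger random fixtures
  s30 <- sample(c(0.2, 0.5, 0.8), 30, replace = TRUE)
  y30 <- rbinom(30, 1, s30)
  expect_equal(auc_mann_whitney(s30, y30), pair_count_auc(s30, y30))
  for (rep in 1:5) {
    n <- sample(20:200, 1)
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mann_whitney(s, y), pair_count_auc(s, y))
  }
  expect_error(auc_mann_whitney(c(0.1, 0.9), c(1, 1)), "constant")
})

test_that("purely additive cohorts collapse the full-model variance", {
  coh <- additive_cohort(20000, seed = 3)
  m <- run_maihda(coh, cb, ci_reps = 0)
  expect_gt(m$vpc_null, 10)
  expect_lt(m$vpc_full, 3)
  expect_gt(m$pcv, 90)
  obs <- dplyr::filter(m$predictions, observed)
  expect_lt(max(abs(obs$interaction)), 5)

  # decomposition identity holds exactly, every stratum
  expect_equal(m$predictions$p_additive + m$predictions$interaction,
    m$predictions$p_total,
    tolerance = 1e-12
  )
  # the decomposition is the inverse-logit arithmetic it claims to be
  expect_equal(m$predictions$p_additive,
    100 * plogis(m$predictions$eta_additive),
    tolerance = 1e-12
  )
  expect_equal(m$predictions$p_total,
    100 * plogis(m$predictions$eta_additive + m$predictions$eb_full),
    tolerance = 1e-12
  )
  # unobserved strata are additive-only (prior-only EB deviation)
  unobs <- dplyr::filter(m$predictions, !observed)
  expect_true(all(unobs$interaction == 0))
  expect_true(all(is.na(unobs$rank)))

  # glance/tidy surface the derived statistics
  gl <- glance(m)
  expect_equal(gl$pcv, m$pcv)
  expect_named(
    gl,
    c(
      "vpc_null", "vpc_full", "pcv", "auc_null", "auc_full",
      "sigma_u2_null", "sigma_u2_full", "nobs", "n_observed_strata"
    )
  )
  expect_equal(nrow(tidy(m)), length(m$full_fit$beta))
})

test_that("an injected interaction cell is the top departure from additivity", {
  cfg <- synthetic_config(
    n = 20000, sigma_int2 = 0,
    explicit_interactions = c("21211" = 1.0),
    missingness = c(), seed = 9
  )
  coh <- assign_strata(generate_population(cfg), schema)
  m <- run_maihda(coh, cb, ci_reps = 0)
  obs <- dplyr::filter(m$predictions, observed)
  expect_equal(obs$stratum[which.max(abs(obs$interaction))], "21211")
  expect_gt(obs$interaction[obs$stratum == "21211"], 0)
})

test_that("an outcome independent of all dimensions shows no stratum structure", {
  cfg <- synthetic_config(
    n = 4000, beta0 = 0, betas = list(), sigma_int2 = 0,
    missingness = c(), seed = 15
  )
  coh <- assign_strata(generate_population(cfg), schema)
  m <- run_maihda(coh, cb, ci_reps = 0)
  expect_lt(m$vpc_null, 5)
  expect_lt(m$auc_null, 0.6)
})

test_that("stratum CIs are seeded, collapse in the no-noise limit, and warn when B is small", {
  coh <- additive_cohort(3000, seed = 23)
  m <- run_maihda(coh, cb, ci_reps = 0)
  p1 <- add_prediction_cis(m$predictions, m$null_fit, m$full_fit, B = 300, seed = 42)
  p2 <- add_prediction_cis(m$predictions, m$null_fit, m$full_fit, B = 300, seed = 42)
  expect_identical(p1, p2)
  p3 <- add_prediction_cis(m$predictions, m$null_fit, m$full_fit, B = 300, seed = 43)
  expect_false(identical(p1$ci_lower, p3$ci_lower))
  expect_true(all(p1$ci_lower <= p1$p_total + 1e-9 & p1$p_total <= p1$ci_upper + 1e-9))

  expect_warning(
    add_prediction_cis(m$predictions, m$null_fit, m$full_fit, B = 50, seed = 1),
    "too few"
  )

  # degenerate limit: no parameter nor posterior uncertainty -> point CIs
  nf <- m$null_fit
  ff <- m$full_fit
  ff$vcov_beta[] <- 0
  nf$se_beta[] <- 0
  preds0 <- dplyr::mutate(m$predictions, posterior_sd_full = 0, posterior_sd_null = 0)
  p0 <- add_prediction_cis(preds0, nf, ff, B = 200, seed = 5)
  expect_equal(p0$ci_lower, p0$p_total, tolerance = 1e-9)
  expect_equal(p0$ci_upper, p0$p_total, tolerance = 1e-9)
  expect_equal(p0$ci_null_lower, p0$p_null, tolerance = 1e-9)
})

test_that("simulated stratum CIs cover the true probability at near-nominal rates", {
  # null-model coverage for one mid-sized stratum over 200 seeded replicates
  rcb <- tiny_codebook()
  rsch <- build_strata_schema(rcb)
  hits <- 0
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    cfg <- synthetic_config(
      n = 600, cb = rcb,
      marginals = uniform_marginals(rcb),
      beta0 = -0.4, betas = list(), sigma_int2 = 0.4,
      missingness = c(), seed = 5000 + r
    )
    coh <- assign_strata(generate_population(cfg), rsch)
    truth <- truth_record(cfg)
    fit <- fit_glmm(coh, rcb)
    preds <- stratum_predictions(fit, fit, rsch)
    preds <- add_prediction_cis(preds, fit, fit, B = 400, seed = r)
    p_true <- 100 * truth$p_total[truth$stratum == "11"]
    row <- preds[preds$stratum == "11", ]
    if (row$ci_null_lower <= p_true && p_true <= row$ci_null_upper) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.88)
})

test_that("extreme-strata tables sort, tie-break by ID, and truncate with warning", {
  toy <- tibble::tibble(
    stratum = c("11111", "11112", "11121"),
    observed = TRUE, n_obs = c(5L, 7L, 9L),
    p_null = c(20, 50, 80), p_total = c(22, 48, 81)
  )
  expect_no_warning(ex <- extremes(toy, k = 1))
  expect_equal(ex$lowest$stratum, "11111")
  expect_equal(ex$highest$stratum, "11121")

  ties <- dplyr::mutate(toy, p_null = 30, p_total = 30)
  expect_no_warning(ext <- extremes(ties, k = 1))
  expect_equal(ext$lowest$stratum, "11111") # lexicographically first
  expect_equal(ext$highest$stratum, "11121")

  expect_warning(extremes(toy, k = 2), "truncated")

  # on a default-effects cohort the lowest strata concentrate the
  # no-schooling / low-income profile
  cfg <- synthetic_config(n = 8000, missingness = c(), seed = 17)
  coh <- assign_strata(generate_population(cfg), schema)
  m <- run_maihda(coh, cb, ci_reps = 0)
  low <- extremes(m$predictions, k = 5)$lowest
  expect_gte(sum(low$schooling == "No schooling"), 4)
  expect_gte(sum(low$income == "Low income"), 4)
  hi <- extremes(m$predictions, k = 5)$highest
  expect_gte(sum(hi$schooling %in% c("Secondary education", "Higher education") |
    hi$income %in% c("2-3 minimum wages", "More than 3 minimum wages")), 4)
})

test_that("ranked null-model probabilities are monotone and feed the caterpillar plot", {
  coh <- additive_cohort(3000, seed = 29)
  m <- run_maihda(coh, cb, ci_reps = 200, seed = 11)
  rk <- ranked_predictions(m)
  expect_true(all(diff(rk$p_null) >= 0))
  expect_equal(rk$rank_null, seq_len(nrow(rk)))
  expect_equal(nrow(rk), m$n_observed_strata)
  p <- autoplot(m)
  expect_s3_class(p, "ggplot")
  p2 <- autoplot(m, type = "decomposition")
  expect_s3_class(p2, "ggplot")
})
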