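cb <- study_codebook()
schema <- build_strata_schema(cb)

make_fitted_cohort <- function(n, sigma_int2, seed, betas = default_betas()) {
  cfg <- synthetic_config(
    n = n, sigma_int2 = sigma_int2, betas = betas,
    missingness = c(), seed = seed
  )
  assign_strata(generate_population(cfg), schema)
}

test_that("adaptive quadrature matches dense numerical integration", {
  set.seed(101)
  X <- cbind(1, rbinom(6, 1, 0.5))
  y <- c(1, 0, 1, 0, 0, 1)
  g <- rep(c("s1", "s2"), each = 3)
  beta <- c(0.3, 0.0)
  ll <- marginal_loglik(beta, 0.4, X, y, g, nodes = 15)
  expect_equal(ll, trapezoid_loglik(beta, 0.4, X, y, g), tolerance = 1e-6)

  # a second fixture with unbalanced groups and larger variance
  X2 <- cbind(1, c(0, 0, 1, 1, 1, 0, 1, 0, 0, 1))
  y2 <- c(1, 1, 0, 1, 0, 0, 0, 1, 1, 0)
  g2 <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  ll2 <- marginal_loglik(c(-0.2, 0.5), 1.3, X2, y2, g2, nodes = 15)
  expect_equal(ll2, trapezoid_loglik(c(-0.2, 0.5), 1.3, X2, y2, g2), tolerance = 1e-6)

  # quadrature is converged: 15 vs 25 nodes indistinguishable
  expect_equal(ll, marginal_loglik(beta, 0.4, X, y, g, nodes = 25), tolerance = 1e-6)
  expect_equal(ll2, marginal_loglik(c(-0.2, 0.5), 1.3, X2, y2, g2, nodes = 25),
    tolerance = 1e-6
  )

  # sigma_u2 = 0 collapses to the ordinary logistic log-likelihood
  eta <- as.vector(X %*% beta)
  bern <- sum(y * plogis(eta, log.p = TRUE) + (1 - y) * plogis(-eta, log.p = TRUE))
  expect_equal(marginal_loglik(beta, 0, X, y, g), bern, tolerance = 1e-12)

  # logistic symmetry: flipping outcomes and negating coefficients
  expect_equal(
    marginal_loglik(-beta, 0.4, X, 1 - y, g),
    ll,
    tolerance = 1e-9
  )
})

test_that("zero-variance data drive the fit to the boundary and the logistic MLE", {
  coh <- make_fitted_cohort(2000, sigma_int2 = 0, seed = 21)
  fit <- fit_glmm(coh, cb, fixed = names(schema$dimensions))
  expect_true(fit$converged)
  expect_lt(fit$sigma_u2, 0.05)

  ref <- glm(
    I(sought_online == "Yes") ~ gender + race + schooling + income + sus_use,
    data = dplyr::mutate(coh,
      gender = factor(gender, c("Man", "Woman")),
      race = factor(race, c("Black or Brown", "White", "Other")),
      schooling = factor(schooling, c(
        "No schooling", "Basic education",
        "Secondary education", "Higher education"
      )),
      income = factor(income, c(
        "Low income", "1-2 minimum wages",
        "2-3 minimum wages", "More than 3 minimum wages"
      )),
      sus_use = factor(sus_use, c("Yes", "No"))
    ),
    family = binomial
  )
  if (fit$boundary) {
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
    expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
  }
  # truth recovery: every coefficient within 3 SEs of its generating value
  truth <- c(
    log(0.19), log(1.49), log(1.05), log(1.35), log(1.78), log(3.37),
    log(5.59), log(2.37), log(2.85), log(4.54), log(0.92)
  )
  expect_true(all(abs(fit$beta - truth) < 3 * fit$se_beta))
})

test_that("parameters of a 48-stratum binary-effect design are recovered", {
  rcb <- recovery_codebook()
  rsch <- build_strata_schema(rcb)
  cfg <- synthetic_config(
    n = 4000, cb = rcb, marginals = uniform_marginals(rcb),
    beta0 = -0.5, betas = list(g = c(B = 0.8)), sigma_int2 = 0.5,
    missingness = c(), seed = 31
  )
  coh <- assign_strata(generate_population(cfg), rsch)
  fit <- fit_glmm(coh, rcb, fixed = "g")
  expect_true(fit$converged)
  expect_lt(abs(fit$beta[["(Intercept)"]] - (-0.5)), 3 * fit$se_beta[["(Intercept)"]])
  expect_lt(abs(fit$beta[["gB"]] - 0.8), 3 * fit$se_beta[["gB"]])
  # MLE cannot be beaten by the generating parameters
  cd_ll <- marginal_loglik(
    c(-0.5, 0.8), 0.5,
    build_fixed_design(coh, rcb, "g"),
    coh$out == "Yes", coh$stratum
  )
  expect_gte(fit$loglik, cd_ll - 1e-6)
  expect_gt(fit$sigma_u2, 0.2)
  expect_lt(fit$sigma_u2, 1.1)
})

test_that("likelihood and estimates agree with an independent mixed-model implementation", {
  skip_if_not_installed("lme4")
  coh <- make_fitted_cohort(2000, sigma_int2 = 0.3, seed = 7)
  d <- dplyr::mutate(as.data.frame(coh),
    y = sought_online == "Yes",
    gender = stats::relevel(factor(gender), "Man"),
    race = stats::relevel(factor(race), "Black or Brown"),
    schooling = stats::relevel(factor(schooling), "No schooling"),
    income = stats::relevel(factor(income), "Low income"),
    sus_use = stats::relevel(factor(sus_use), "Yes")
  )

  null_fit <- fit_glmm(coh, cb)
  g0 <- lme4::glmer(y ~ 1 + (1 | stratum), d, family = binomial, nAGQ = 15)
  expect_equal(null_fit$loglik, as.numeric(logLik(g0)), tolerance = 1e-5)
  expect_equal(null_fit$sigma_u2, unname(lme4::VarCorr(g0)$stratum[1]), tolerance = 1e-3)

  full_fit <- fit_glmm(coh, cb, fixed = names(schema$dimensions))
  g1 <- lme4::glmer(
    y ~ gender + race + schooling + income + sus_use + (1 | stratum),
    d,
    family = binomial, nAGQ = 15
  )
  expect_equal(full_fit$loglik, as.numeric(logLik(g1)), tolerance = 1e-4)
  fe <- lme4::fixef(g1)[names(full_fit$beta)]
  expect_equal(unname(full_fit$beta), unname(fe), tolerance = 5e-3)
  # SEs agree only approximately: lme4's GLMM vcov rests on a coarser
  # finite-difference Hessian than the observed information used here
  se <- sqrt(diag(as.matrix(vcov(g1))))[names(full_fit$se_beta)]
  expect_equal(unname(full_fit$se_beta), unname(se), tolerance = 0.07)
})

test_that("degenerate inputs raise explicit errors", {
  one_stratum <- raw_cohort(tibble::tibble(
    gender = rep("Man", 10), race = "White", schooling = "No schooling",
    income = "Low income", sus_use = "Yes",
    sought_online = rep(c("Yes", "No"), 5)
  ))
  expect_error(
    fit_glmm(assign_strata(one_stratum, schema), cb),
    "unidentifiable"
  )
  const <- make_fitted_cohort(50, 0, seed = 3)
  const$sought_online <- "No"
  expect_error(fit_glmm(const, cb), "no variation")
  expect_error(
    fit_glmm(dplyr::select(const, -stratum), cb),
    "assign_strata"
  )
  expect_error(marginal_loglik(c(0), -1, matrix(1, 2), c(0, 1), c(1, 2)), "non-negative")
})

test_that("EB modes match a grid-search oracle and shrink toward zero", {
  toy <- raw_cohort(tibble::tibble(
    gender = rep(c("Man", "Woman", "Man"), times = c(12, 10, 8)),
    race = rep(c("White", "White", "Other"), times = c(12, 10, 8)),
    schooling = "Basic education", income = "Low income", sus_use = "Yes",
    sought_online = c(
      rep(c("Yes", "No"), c(9, 3)), # stratum 1: high
      rep(c("Yes", "No"), c(3, 7)), # stratum 2: low
      rep(c("Yes", "No"), c(4, 4)) # stratum 3: middling
    )
  ))
  coh <- assign_strata(toy, schema)
  fit <- fit_glmm(coh, cb)
  re <- predict_random_effects(fit)
  expect_equal(nrow(re), 3)
  expect_true(all(re$source == "data"))

  b0 <- fit$beta[["(Intercept)"]]
  s2 <- max(fit$sigma_u2, 1e-12)
  for (i in seq_len(nrow(re))) {
    rows <- coh$stratum == re$group[i]
    y <- as.numeric(coh$sought_online[rows] == "Yes")
    oracle <- grid_posterior_mode(rep(b0, sum(rows)), y, s2)
    expect_equal(re$eb_value[i], oracle, tolerance = 1e-3)
    # shrinkage: the mode is smaller than the raw log-odds residual
    raw <- qlogis(mean(y)) - b0
    expect_lt(abs(re$eb_value[i]), abs(raw) + 1e-9)
    expect_lte(re$posterior_sd[i], sqrt(s2) * (1 + 1e-8))
  }

  # a stratum whose empirical log-odds equals the fixed prediction has mode 0:
  # two identical strata force beta0 onto both, leaving zero residual
  sym <- raw_cohort(tibble::tibble(
    gender = rep(c("Man", "Woman"), each = 20),
    race = "White", schooling = "No schooling", income = "Low income",
    sus_use = "Yes",
    sought_online = rep(rep(c("Yes", "No"), c(7, 13)), 2)
  ))
  fs <- fit_glmm(assign_strata(sym, schema), cb)
  rs <- predict_random_effects(fs)
  expect_true(all(abs(rs$eb_value) < 1e-6))
})

test_that("EB shrinkage grows as stratum size falls, at equal empirical rates", {
  # three strata at 30% positive with sizes 10 / 50 / 200 (plus one
  # contrasting stratum), modes evaluated at fixed parameters
  sizes <- c(10, 50, 200, 100)
  rates <- c(0.3, 0.3, 0.3, 0.7)
  gen <- tibble::tibble(
    gender = rep(c("Man", "Woman", "Man", "Woman"), times = sizes),
    race = rep(c("White", "White", "Other", "Other"), times = sizes),
    schooling = "Basic education", income = "Low income", sus_use = "Yes",
    sought_online = unlist(purrr::map2(sizes, rates, function(n, r) {
      rep(c("Yes", "No"), c(r * n, (1 - r) * n))
    }))
  )
  coh <- assign_strata(raw_cohort(gen), schema)
  fit <- fit_glmm(coh, cb)
  fit$beta[] <- 0 # fixed evaluation point: beta0 = 0, sigma_u2 = 0.5
  fit$sigma_u2 <- 0.5
  re <- predict_random_effects(fit)
  same_rate <- re[re$group %in% unique(coh$stratum)[1:3], ]
  n_ord <- order(same_rate$n_obs)
  # |mode| grows with n: smaller strata are pulled harder toward zero
  expect_true(all(diff(abs(same_rate$eb_value[n_ord])) > 0))
  expect_true(all(abs(same_rate$eb_value) < abs(qlogis(0.3))))
})

test_that("Wald odds-ratio tables follow the normal-theory arithmetic", {
  coh <- make_fitted_cohort(400, 0.2, seed = 13)
  fit <- fit_glmm(coh, cb, fixed = "gender")
  # doctor the fit to frozen values: the table is pure arithmetic downstream
  fit$beta <- c(`(Intercept)` = 0, genderWoman = log(2))
  fit$se_beta <- c(`(Intercept)` = 0.1, genderWoman = 1e-12)
  tab <- wald_or_table(fit, level = 0.95)
  expect_equal(tab$or[1], 1.00, tolerance = 1e-12)
  expect_equal(tab$conf.low[1], exp(-qnorm(0.975) * 0.1), tolerance = 1e-12)
  expect_equal(round(tab$conf.low[1], 2), 0.82)
  expect_equal(round(tab$conf.high[1], 2), 1.22)
  # se -> 0 collapses the interval onto the point estimate
  expect_equal(tab$conf.low[2], 2, tolerance = 1e-9)
  expect_equal(tab$conf.high[2], 2, tolerance = 1e-9)
  # missing SE yields NA bounds, not fabricated ones
  fit$se_beta[2] <- NA_real_
  tab2 <- wald_or_table(fit)
  expect_true(is.na(tab2$conf.low[2]) && is.na(tab2$conf.high[2]))
  expect_equal(tab2$or[2], 2)

  # tidy()/glance() expose the same quantities
  td <- tidy(fit, exponentiate = TRUE)
  expect_equal(td$estimate, tab2$or)
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$n_obs)
  expect_equal(gl$sigma_u2, fit$sigma_u2)
})
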