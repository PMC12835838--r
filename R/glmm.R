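# Random-intercept logistic model fit by maximum likelihood with adaptive
# Gauss-Hermite quadrature. One scalar random intercept per group (here: per
# intersectional stratum); fixed effects enter through an arbitrary design
# matrix. All likelihood work happens on data collapsed to unique
# (group, design-row) cells with binomial sufficient statistics, so cost
# scales with the number of strata, not individuals.

gh_rule <- function(nodes) {
  stopifnot(nodes >= 1)
  gh <- pracma::gaussHermite(nodes)
  list(z = gh$x, logw = log(gh$w), z2 = gh$x^2)
}

collapse_glmm_data <- function(X, y, group) {
  stopifnot(is.matrix(X), nrow(X) == length(y), length(group) == length(y))
  if (any(!is.finite(X))) stop("design matrix contains non-finite values", call. = FALSE)
  gf <- if (is.factor(group)) droplevels(group) else factor(group)
  gidx <- as.integer(gf)
  key <- do.call(paste, c(list(gidx), asplit(X, 2), list(sep = "\1")))
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(
    Xu = X[first, , drop = FALSE],
    n = as.numeric(tabulate(map, nbins = sum(first))),
    s = as.numeric(rowsum(as.numeric(y), map)[, 1]),
    gidx = gidx[first],
    G = nlevels(gf),
    group_levels = levels(gf),
    n_obs = length(y)
  )
}

group_sum <- function(x, gidx, G) {
  # fast path: at most one design pattern per group (always true when the
  # design is stratum-constant, as in MAIHDA)
  if (!anyDuplicated(gidx)) {
    out <- numeric(G)
    out[gidx] <- x
    return(out)
  }
  out <- numeric(G)
  r <- rowsum(x, gidx)
  out[as.integer(rownames(r))] <- r[, 1]
  out
}

# Matrix analogue: column-wise group sums of a K x Q matrix into G x Q.
group_sum_mat <- function(M, gidx, G) {
  if (!anyDuplicated(gidx)) {
    out <- matrix(0, G, ncol(M))
    out[gidx, ] <- M
    return(out)
  }
  out <- matrix(0, G, ncol(M))
  r <- rowsum(M, gidx)
  out[as.integer(rownames(r)), ] <- r
  out
}

# Bernoulli log-likelihood contributions summed per group, at per-group
# offsets u (vector of length G).
bern_group_loglik <- function(eta, s, n, gidx, G, u) {
  etau <- eta + u[gidx]
  group_sum(s * plogis(etau, log.p = TRUE) + (n - s) * plogis(-etau, log.p = TRUE),
    gidx, G
  )
}

# Posterior modes and curvature scales of the per-group random intercepts,
# by safeguarded Newton on the log joint density. Returns modes u, scales
# tau = (-h'')^{-1/2}, and the log joint at the mode.
posterior_modes <- function(eta, cd, sigma_u2, tol = 1e-10, max_iter = 100,
                            u_init = NULL) {
  G <- cd$G
  u <- if (is.null(u_init)) numeric(G) else u_init
  ldens <- function(u) {
    bern_group_loglik(eta, cd$s, cd$n, cd$gidx, G, u) - u^2 / (2 * sigma_u2)
  }
  h <- ldens(u)
  for (iter in seq_len(max_iter)) {
    etau <- eta + u[cd$gidx]
    p <- plogis(etau)
    score <- group_sum(cd$s - cd$n * p, cd$gidx, G) - u / sigma_u2
    curv <- -group_sum(cd$n * p * (1 - p), cd$gidx, G) - 1 / sigma_u2
    delta <- -score / curv
    # step-halving safeguard: the log joint must not decrease
    step <- rep(1, G)
    for (half in 1:30) {
      u_new <- u + step * delta
      h_new <- ldens(u_new)
      worse <- h_new < h - 1e-12
      if (!any(worse)) break
      step[worse] <- step[worse] / 2
    }
    u <- u_new
    h <- h_new
    if (max(abs(step * delta)) < tol) break
  }
  etau <- eta + u[cd$gidx]
  p <- plogis(etau)
  curv <- -group_sum(cd$n * p * (1 - p), cd$gidx, G) - 1 / sigma_u2
  list(u = u, tau = sqrt(-1 / curv))
}

# central-difference gradient; `free` masks out parameters held at a bound
fd_gradient <- function(f, par, free = rep(TRUE, length(par)), h = 1e-6) {
  vapply(seq_along(par), function(j) {
    if (!free[j]) {
      return(0)
    }
    hp <- h * (1 + abs(par[j]))
    up <- par
    dn <- par
    up[j] <- par[j] + hp
    dn[j] <- par[j] - hp
    (f(up) - f(dn)) / (2 * hp)
  }, numeric(1))
}

marginal_loglik_collapsed <- function(beta, sigma_u2, cd, gh, cache = NULL) {
  eta <- as.vector(cd$Xu %*% beta)
  if (any(!is.finite(eta))) return(-Inf)
  if (sigma_u2 < 1e-12) {
    return(sum(cd$s * plogis(eta, log.p = TRUE) + (cd$n - cd$s) * plogis(-eta, log.p = TRUE)))
  }
  # warm-start the per-stratum mode search from the previous evaluation
  pm <- posterior_modes(eta, cd, sigma_u2, u_init = if (is.null(cache)) NULL else cache$u)
  if (!is.null(cache)) cache$u <- pm$u
  sd_u <- sqrt(sigma_u2)
  Q <- length(gh$z)
  U <- pm$u + sqrt(2) * outer(pm$tau, gh$z) # G x Q node locations
  ETA <- eta + U[cd$gidx, , drop = FALSE]
  TERMS <- cd$s * plogis(ETA, log.p = TRUE) + (cd$n - cd$s) * plogis(-ETA, log.p = TRUE)
  H <- group_sum_mat(TERMS, cd$gidx, cd$G) + dnorm(U, 0, sd_u, log = TRUE) +
    rep(gh$logw + gh$z2, each = cd$G)
  m <- apply(H, 1, max)
  sum(log(sqrt(2) * pm$tau) + m + log(rowSums(exp(H - m))))
}

#' Marginal log-likelihood of the random-intercept logistic model
#'
#' Computes the maximized-over-nothing marginal log-likelihood
#' \deqn{\sum_g \log \int \prod_{i \in g}
#'   \mathrm{Bern}(y_i \mid \mathrm{logit}^{-1}(x_i'\beta + u))\,
#'   \phi(u; 0, \sigma_u^2)\, du,}
#' each one-dimensional integral evaluated by Gauss–Hermite quadrature
#' centered and scaled at the per-group posterior mode (adaptive quadrature).
#' At `sigma_u2 = 0` the integral collapses and the value equals the
#' ordinary logistic log-likelihood.
#'
#' @param beta Fixed-effect coefficient vector (log-odds scale).
#' @param sigma_u2 Between-group variance on the latent scale, `>= 0`.
#' @param X Design matrix (rows = observations), conformable with `beta`.
#' @param y Binary outcome vector (0/1 or logical).
#' @param group Grouping vector (one level per random intercept).
#' @param nodes Number of quadrature nodes (default 15).
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(beta, sigma_u2, X, y, group, nodes = 15) {
  if (sigma_u2 < 0) stop("sigma_u2 must be non-negative", call. = FALSE)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)", call. = FALSE)
  cd <- collapse_glmm_data(X, y, group)
  marginal_loglik_collapsed(beta, sigma_u2, cd, gh_rule(nodes))
}

build_fixed_design <- function(data, cb, fixed) {
  if (is.null(fixed) || length(fixed) == 0) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  stopifnot(all(fixed %in% names(cb$variables)))
  df <- purrr::map(setNames(fixed, fixed), function(nm) {
    cats <- analytic_categories(cb, nm)
    ref <- cb$variables[[nm]]$reference
    factor(data[[nm]], levels = c(ref, setdiff(cats, ref)))
  })
  df <- as.data.frame(df, check.names = FALSE)
  if (anyNA(df)) stop("non-analytic or missing values on fixed-effect terms", call. = FALSE)
  model.matrix(~., df)
}

#' Fit a random-intercept logistic model over intersectional strata
#'
#' Maximum-likelihood estimation of a binary-outcome model with one random
#' intercept per group (stratum) and optional categorical fixed effects, via
#' adaptive Gauss–Hermite quadrature ([marginal_loglik()]) and quasi-Newton
#' optimization on \eqn{(\beta, \log\sigma_u)}. Standard errors come from
#' the observed information (numerical Hessian of the marginal
#' log-likelihood at the optimum).
#'
#' @param cohort A filtered cohort tibble with a `stratum` column
#'   ([assign_strata()]) and the outcome column.
#' @param cb The [codebook()] (supplies analytic categories, reference
#'   categories, and the outcome's positive label).
#' @param fixed Character vector of dimension names to enter as fixed main
#'   effects, or `NULL` (default) for the intercept-only null model.
#' @param group Name of the grouping column (default `"stratum"`).
#' @param nodes Gauss–Hermite node count (default 15).
#' @param start Optional starting values `list(beta =, sigma_u =)`.
#' @return An object of class `maihda_glmm`: coefficients `beta` with
#'   `se_beta` and `vcov_beta`, the between-stratum variance `sigma_u2`,
#'   `loglik`, `converged` and `boundary` flags, counts, and the collapsed
#'   data needed for prediction. Supports [tidy()], [glance()],
#'   [predict_random_effects()], [wald_or_table()].
#' @export
fit_glmm <- function(cohort, cb, fixed = NULL, group = "stratum",
                     nodes = 15, start = NULL) {
  stopifnot(inherits(cb, "maihda_codebook"))
  if (!group %in% names(cohort)) {
    stop("cohort lacks grouping column '", group, "'; run assign_strata() first",
      call. = FALSE
    )
  }
  yy <- cohort[[cb$outcome$name]]
  if (anyNA(yy) || !all(yy %in% cb$outcome$categories)) {
    stop("outcome contains missing or non-analytic values; filter first", call. = FALSE)
  }
  y <- as.numeric(yy == cb$outcome$positive)
  if (length(unique(y)) < 2) {
    stop("outcome shows no variation; model is not estimable", call. = FALSE)
  }
  X <- build_fixed_design(cohort, cb, fixed)
  cd <- collapse_glmm_data(X, y, cohort[[group]])
  if (cd$G < 2) {
    stop("only one stratum present: grouping variance is unidentifiable", call. = FALSE)
  }
  gh <- gh_rule(nodes)
  p <- ncol(X)

  # starting values: ordinary logistic fit on the collapsed data
  if (is.null(start)) {
    glm0 <- suppressWarnings(
      glm.fit(cd$Xu, cd$s / cd$n, weights = cd$n, family = binomial())
    )
    start <- list(beta = coef(glm0), sigma_u = 0.3)
  }
  theta_lo <- log(1e-5)
  cache <- new.env(parent = emptyenv())
  obj <- function(par) {
    -marginal_loglik_collapsed(par[seq_len(p)], exp(2 * par[p + 1]), cd, gh, cache)
  }
  opt <- nlminb(
    start = c(start$beta, log(start$sigma_u)),
    objective = obj,
    lower = c(rep(-Inf, p), theta_lo),
    upper = c(rep(Inf, p), log(20)),
    control = list(eval.max = 5000, iter.max = 2000, rel.tol = 1e-12)
  )
  beta <- setNames(unname(opt$par[seq_len(p)]), colnames(X))
  theta <- unname(opt$par[p + 1])
  boundary <- theta <= theta_lo + 1e-4 || exp(2 * theta) < 1e-6
  sigma_u2 <- if (boundary) 0 else exp(2 * theta)
  loglik <- -opt$objective
  converged <- opt$convergence == 0 && is.finite(loglik)
  if (!converged && is.finite(loglik)) {
    # nlminb can report "false convergence" at a genuine optimum (notably
    # near the variance boundary); verify with the score itself
    grad <- fd_gradient(obj, opt$par, free = c(rep(TRUE, p), !boundary))
    converged <- max(abs(grad)) < 1e-4 * (1 + abs(loglik))
  }
  if (boundary) {
    # profile out the variance: refit beta at sigma_u2 = 0
    ref <- nlminb(beta, function(b) -marginal_loglik_collapsed(b, 0, cd, gh))
    if (-ref$objective >= loglik - 1e-6) {
      beta[] <- ref$par
      loglik <- max(loglik, -ref$objective)
      converged <- converged || ref$convergence == 0
    }
  }

  # observed information over beta at the estimated variance (the usual
  # mixed-model convention: fixed-effect SEs conditional on sigma_u2)
  vcov_beta <- matrix(NA_real_, p, p, dimnames = list(names(beta), names(beta)))
  se_beta <- setNames(rep(NA_real_, p), names(beta))
  separation <- FALSE
  hess_ok <- FALSE
  H <- try(
    optimHess(beta, function(b) -marginal_loglik_collapsed(b, sigma_u2, cd, gh, cache)),
    silent = TRUE
  )
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) {
      vcov_beta <- V
      se_beta[] <- sqrt(diag(V))
      hess_ok <- TRUE
    }
  }
  if (any(abs(beta) > 15) || any(is.finite(se_beta) & se_beta > 50)) {
    separation <- TRUE
    warning("possible complete separation: inflated coefficient or SE", call. = FALSE)
  }
  if (!converged) {
    warning("optimizer did not report convergence (code ", opt$convergence, ")",
      call. = FALSE
    )
  }

  structure(
    list(
      beta = beta, se_beta = se_beta, vcov_beta = vcov_beta,
      sigma_u2 = sigma_u2, loglik = loglik,
      converged = converged, boundary = boundary, separation = separation,
      hess_ok = hess_ok,
      n_obs = cd$n_obs, n_groups = cd$G, nodes = nodes,
      fixed = fixed, group_var = group,
      outcome = cb$outcome, codebook = cb,
      collapsed = cd,
      optimizer = list(
        convergence = opt$convergence, message = opt$message,
        iterations = opt$iterations, evaluations = opt$evaluations
      )
    ),
    class = "maihda_glmm"
  )
}

#' @export
print.maihda_glmm <- function(x, ...) {
  cat(sprintf(
    "<maihda_glmm> %s model: %d obs in %d strata, %d-node AGQ\n",
    if (is.null(x$fixed)) "null (random intercept only)" else "fixed + random intercept",
    x$n_obs, x$n_groups, x$nodes
  ))
  cat(sprintf(
    "  logLik %.3f | sigma_u2 %.4f%s | converged: %s\n",
    x$loglik, x$sigma_u2, if (x$boundary) " (boundary)" else "", x$converged
  ))
  print(round(x$beta, 4))
  invisible(x)
}

#' Empirical-Bayes stratum random-effect predictions
#'
#' Posterior modes (conditional modes) of each stratum's random intercept at
#' the fitted parameters, with a curvature-based posterior spread. Strata
#' with data shrink toward zero under the normal prior; strata absent from
#' the data (when requested through `groups`) are prior-only with
#' `eb_value = 0` and `posterior_sd = sqrt(sigma_u2)`.
#'
#' @param fit A [fit_glmm()] result.
#' @param method `"mode"` (default, the conditional mode) or `"mean"`
#'   (posterior mean by adaptive quadrature).
#' @param groups Optional character vector of group labels to report
#'   (defaults to the groups present in the fit); labels not in the fit are
#'   returned as prior-only rows.
#' @return A tibble: `group`, `n_obs`, `eb_value` (log-odds deviation),
#'   `posterior_sd`, `source` (`"data"` or `"prior"`).
#' @export
predict_random_effects <- function(fit, method = c("mode", "mean"), groups = NULL) {
  stopifnot(inherits(fit, "maihda_glmm"))
  method <- match.arg(method)
  cd <- fit$collapsed
  eta <- as.vector(cd$Xu %*% fit$beta)
  sigma_u2 <- max(fit$sigma_u2, 1e-12)
  pm <- posterior_modes(eta, cd, sigma_u2)
  eb <- pm$u
  if (method == "mean") {
    gh <- gh_rule(fit$nodes)
    den <- matrix(0, cd$G, length(gh$z))
    uks <- outer(pm$u, rep(1, length(gh$z))) + sqrt(2) * outer(pm$tau, gh$z)
    for (k in seq_along(gh$z)) {
      den[, k] <- gh$logw[k] + gh$z2[k] +
        bern_group_loglik(eta, cd$s, cd$n, cd$gidx, cd$G, uks[, k]) +
        dnorm(uks[, k], 0, sqrt(sigma_u2), log = TRUE)
    }
    m <- apply(den, 1, max)
    w <- exp(den - m)
    eb <- rowSums(w * uks) / rowSums(w)
  }
  n_by_group <- group_sum(cd$n, cd$gidx, cd$G)
  out <- tibble::tibble(
    group = cd$group_levels,
    n_obs = as.integer(n_by_group),
    eb_value = ifelse(n_by_group > 0, eb, 0),
    posterior_sd = ifelse(n_by_group > 0, pm$tau, sqrt(fit$sigma_u2)),
    source = ifelse(n_by_group > 0, "data", "prior")
  )
  if (!is.null(groups)) {
    out <- tibble::tibble(group = as.character(groups)) |>
      dplyr::left_join(out, by = "group") |>
      dplyr::mutate(
        n_obs = dplyr::coalesce(.data$n_obs, 0L),
        eb_value = dplyr::coalesce(.data$eb_value, 0),
        posterior_sd = dplyr::coalesce(.data$posterior_sd, sqrt(fit$sigma_u2)),
        source = dplyr::coalesce(.data$source, "prior")
      )
  }
  out
}

#' Odds-ratio table with Wald confidence intervals
#'
#' @param fit A converged [fit_glmm()] result with finite standard errors.
#' @param level Confidence level (default 0.95).
#' @return A tibble: `term`, `estimate` (log-odds), `std.error`, `or`,
#'   `conf.low`, `conf.high` (odds-ratio scale). Terms without a standard
#'   error get `NA` bounds rather than fabricated ones.
#' @export
wald_or_table <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "maihda_glmm"))
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    term = names(fit$beta),
    estimate = unname(fit$beta),
    std.error = unname(fit$se_beta),
    or = exp(unname(fit$beta)),
    conf.low = exp(unname(fit$beta) - z * unname(fit$se_beta)),
    conf.high = exp(unname(fit$beta) + z * unname(fit$se_beta))
  )
}

#' @exportS3Method generics::tidy
tidy.maihda_glmm <- function(x, exponentiate = FALSE, conf.level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf.level) / 2)
  out <- tibble::tibble(
    term = names(x$beta),
    estimate = unname(x$beta),
    std.error = unname(x$se_beta),
    statistic = unname(x$beta / x$se_beta),
    p.value = 2 * stats::pnorm(-abs(unname(x$beta / x$se_beta))),
    conf.low = unname(x$beta - z * x$se_beta),
    conf.high = unname(x$beta + z * x$se_beta)
  )
  if (exponentiate) {
    out <- dplyr::mutate(out, dplyr::across(
      c("estimate", "conf.low", "conf.high"), exp
    ))
  }
  out
}

#' @exportS3Method generics::glance
glance.maihda_glmm <- function(x, ...) {
  tibble::tibble(
    sigma_u2 = x$sigma_u2,
    logLik = x$loglik,
    nobs = x$n_obs,
    n_groups = x$n_groups,
    nodes = x$nodes,
    converged = x$converged,
    boundary = x$boundary
  )
}

#' Serialize a fitted model to JSON
#'
#' @param fit A [fit_glmm()] result.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @export
glmm_fit_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "maihda_glmm"))
  obj <- list(
    beta = as.list(fit$beta),
    se_beta = as.list(fit$se_beta),
    sigma_u2 = fit$sigma_u2,
    loglik = fit$loglik,
    converged = fit$converged,
    boundary = fit$boundary,
    n_obs = fit$n_obs,
    n_groups = fit$n_groups,
    nodes = fit$nodes,
    fixed = fit$fixed
  )
  if (is.null(path)) {
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
  }
}

# Fixed-effect linear predictor for new category-label rows, using the
# fit's codebook references.
fixed_linear_predictor <- function(fit, newdata) {
  X <- build_fixed_design(newdata, fit$codebook, fit$fixed)
  as.vector(X %*% fit$beta)
}
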