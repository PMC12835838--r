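# Shared fixtures and brute-force oracles, built in code at test time.

# A minimal 2 x 2 codebook for cheap strata tests.
tiny_codebook <- function() {
  codebook(
    variables = list(g = c("A", "B"), h = c("X", "Y")),
    outcome = list(name = "out", categories = c("Yes", "No"), positive = "Yes")
  )
}

# A 2 x 4 x 3 x 2 = 48-cell codebook for parameter-recovery fixtures.
recovery_codebook <- function() {
  codebook(
    variables = list(
      g = c("A", "B"),
      w = c("w1", "w2", "w3", "w4"),
      v = c("v1", "v2", "v3"),
      z = c("z1", "z2")
    ),
    outcome = list(name = "out", categories = c("Yes", "No"), positive = "Yes")
  )
}

uniform_marginals <- function(cb) {
  purrr::map(cb$variables, function(v) {
    cats <- v$categories[v$analytic]
    setNames(rep(1 / length(cats), length(cats)), cats)
  })
}

# Raw cohort tibble from a plain data frame.
raw_cohort <- function(df) {
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- "raw"
  out
}

# Dense-trapezoid oracle for the per-group marginal likelihood integral.
trapezoid_loglik <- function(beta, sigma_u2, X, y, group, n_grid = 20001) {
  sum(vapply(split(seq_along(y), group), function(ix) {
    f <- vapply(
      seq(-10 * sqrt(sigma_u2), 10 * sqrt(sigma_u2), length.out = n_grid),
      function(u) {
        eta <- as.vector(X[ix, , drop = FALSE] %*% beta) + u
        exp(sum(y[ix] * plogis(eta, log.p = TRUE) +
          (1 - y[ix]) * plogis(-eta, log.p = TRUE)) +
          dnorm(u, 0, sqrt(sigma_u2), log = TRUE))
      }, numeric(1)
    )
    h <- 20 * sqrt(sigma_u2) / (n_grid - 1)
    log(sum((f[-1] + f[-n_grid]) / 2) * h)
  }, numeric(1)))
}

# Exhaustive concordant/discordant pair-count AUC (ties count one half).
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  total <- 0
  for (a in pos) {
    total <- total + sum(a > neg) + 0.5 * sum(a == neg)
  }
  total / (length(pos) * length(neg))
}

# Grid-search oracle for a stratum's posterior mode of the random intercept.
grid_posterior_mode <- function(eta, y, sigma_u2, step = 1e-4, lim = 6) {
  grid <- seq(-lim, lim, by = step)
  obj <- vapply(grid, function(u) {
    sum(y * plogis(eta + u, log.p = TRUE) + (1 - y) * plogis(-(eta + u), log.p = TRUE)) +
      dnorm(u, 0, sqrt(sigma_u2), log = TRUE)
  }, numeric(1))
  grid[which.max(obj)]
}
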