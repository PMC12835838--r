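# End-to-end entry points tying the stages into one reproducible pipeline:
# simulate a cohort to disk, analyze a cohort file (or tibble) through
# filter -> strata -> null fit -> full fit -> derived statistics, and the
# design-stage sample-size helper. Tables are written as CSV with
# one-decimal percent formatting; summary/provenance JSON keeps full
# precision.

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

fmt_pct <- function(x) sprintf("%.1f", round_half_up(x, 1))

provenance_json <- function(path, config, seed = NULL, timings = NULL) {
  obj <- list(
    package = "intermaihda",
    version = as.character(utils::packageVersion("intermaihda")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    stage_timings = timings
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

config_as_list <- function(config) {
  list(
    n = config$n,
    marginals = purrr::map(config$marginals, as.list),
    beta0 = config$beta0,
    betas = purrr::map(config$betas, as.list),
    sigma_int2 = config$sigma_int2,
    explicit_interactions = if (is.null(config$explicit_interactions)) {
      NULL
    } else {
      as.list(config$explicit_interactions)
    },
    missingness = as.list(config$missingness),
    tilt = config$tilt,
    seed = config$seed
  )
}

#' Simulate a synthetic cohort to disk
#'
#' Writes the generated cohort, its truth table, and a provenance JSON
#' (config echo + seed) sufficient to re-execute bit-identically.
#'
#' @param config A [synthetic_config()].
#' @param output_dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
maihda_simulate <- function(config, output_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_population(config)
  truth <- truth_record(config)
  paths <- list(
    cohort = file.path(output_dir, "cohort.csv"),
    truth = file.path(output_dir, "truth.csv"),
    provenance = file.path(output_dir, "provenance.json")
  )
  readr::write_csv(cohort, paths$cohort, na = "")
  readr::write_csv(truth, paths$truth)
  provenance_json(paths$provenance, config_as_list(config), seed = config$seed)
  stage_log("simulate", "wrote %d rows to %s", nrow(cohort), paths$cohort)
  invisible(paths)
}

#' Run the full MAIHDA pipeline and write publication-shaped outputs
#'
#' Reads a cohort (CSV path or tibble), applies the complete-case filter,
#' assigns strata, fits the null and full models, derives VPC/PCV/AUC and
#' stratum predictions, and writes: `exclusion_report.json`,
#' `descriptive_table.csv`, `coefficients.csv` (term, OR, CI),
#' `stratum_predictions.csv`, `ranked_null.csv` (caterpillar data),
#' `extremes_lowest.csv` / `extremes_highest.csv`, `summary.json`, and
#' `provenance.json`. Each stage is logged to stderr with counts.
#'
#' @param input Path to a cohort CSV, or a raw cohort tibble.
#' @param cb Codebook (default [study_codebook()]).
#' @param output_dir Output directory (created if needed).
#' @param nodes Quadrature nodes (default 15).
#' @param ci_reps CI simulation replicates (default 1000; 0 skips CIs).
#' @param seed Integer seed for the CI simulation (default 1).
#' @param k Number of strata in each extremes table (default 5).
#' @return Invisibly, the [run_maihda()] result.
#' @export
maihda_analyze <- function(input, cb = study_codebook(), output_dir,
                           nodes = 15, ci_reps = 1000, seed = 1, k = 5) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }

  cohort <- if (is.character(input)) read_cohort(input, cb) else input
  stage_log("read", "%d raw records", nrow(cohort))
  tick("read")

  filt <- filter_complete_cases(cohort, cb)
  stage_log(
    "filter", "%d retained, %d excluded (%.1f%%)",
    filt$exclusions$n_retained, filt$exclusions$n_excluded,
    filt$exclusions$pct_excluded
  )
  exclusion_report_json(filt$exclusions, file.path(output_dir, "exclusion_report.json"))
  desc <- describe_cohort(cohort, cb)
  desc_out <- dplyr::mutate(desc, percent = fmt_pct(.data$percent))
  readr::write_csv(desc_out, file.path(output_dir, "descriptive_table.csv"))
  tick("filter")

  schema <- build_strata_schema(cb)
  cohort_s <- assign_strata(filt$cohort, schema)
  strata <- tabulate_strata(cohort_s, schema)
  stage_log(
    "strata", "%d of %d possible strata observed",
    n_observed_strata(strata), schema$n_possible
  )
  readr::write_csv(strata, file.path(output_dir, "strata.csv"))
  tick("strata")

  result <- run_maihda(cohort_s, cb,
    nodes = nodes,
    ci_reps = ci_reps, seed = if (ci_reps > 0) seed else NULL
  )
  stage_log(
    "fit", "VPC null %.1f%% -> full %.1f%%, PCV %.1f%%, AUC %.3f/%.3f",
    result$vpc_null, result$vpc_full, result$pcv, result$auc_null, result$auc_full
  )
  tick("fit")

  readr::write_csv(
    wald_or_table(result$full_fit),
    file.path(output_dir, "coefficients.csv")
  )
  pred_out <- dplyr::mutate(result$predictions, dplyr::across(
    dplyr::any_of(c(
      "p_null", "p_additive", "p_total", "interaction",
      "ci_lower", "ci_upper", "ci_null_lower", "ci_null_upper"
    )),
    fmt_pct
  ))
  readr::write_csv(pred_out, file.path(output_dir, "stratum_predictions.csv"))
  ranked <- ranked_predictions(result)
  readr::write_csv(ranked, file.path(output_dir, "ranked_null.csv"))
  ext <- extremes(result$predictions, k = k)
  readr::write_csv(ext$lowest, file.path(output_dir, "extremes_lowest.csv"))
  readr::write_csv(ext$highest, file.path(output_dir, "extremes_highest.csv"))

  summary_obj <- c(
    as.list(glance(result)),
    list(
      n_raw = filt$exclusions$n_raw,
      n_excluded = filt$exclusions$n_excluded,
      pct_excluded = filt$exclusions$pct_excluded,
      n_possible_strata = schema$n_possible
    )
  )
  jsonlite::write_json(summary_obj, file.path(output_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  tick("report")
  provenance_json(
    file.path(output_dir, "provenance.json"),
    config = list(
      input = if (is.character(input)) input else "<in-memory cohort>",
      nodes = nodes, ci_reps = ci_reps, seed = seed, k = k
    ),
    seed = seed, timings = timings
  )
  stage_log("done", "outputs in %s", output_dir)
  invisible(result)
}

#' Design-stage minimum sample size
#'
#' Convenience wrapper around [cochran_sample_size()] for pipeline use.
#'
#' @inheritParams cochran_sample_size
#' @export
maihda_sample_size <- function(z = 1.96, epsilon = 0.05, p = 0.5, N = Inf) {
  cochran_sample_size(z = z, epsilon = epsilon, p = p, N = N)
}

#' Read a pipeline run configuration from YAML
#'
#' The YAML may contain either an `input` path or a `synthetic` block
#' (passed to [synthetic_config()]), plus `codebook` (path), `output_dir`,
#' `nodes`, `ci_reps`, `seed`, and `k`.
#'
#' @param path YAML file path.
#' @return A named list with a `synthetic_config` under `$synthetic` when
#'   present.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$input) && !is.null(y$synthetic)) {
    stop("run config must give exactly one of 'input' or 'synthetic'", call. = FALSE)
  }
  if (is.null(y$input) && is.null(y$synthetic)) {
    stop("run config must give an 'input' path or a 'synthetic' block", call. = FALSE)
  }
  cb <- if (is.null(y$codebook)) study_codebook() else read_codebook(y$codebook)
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    # YAML 1.1 coerces a bare `n` key to boolean FALSE; undo that
    names(s)[names(s) %in% c("FALSE", "no")] <- "n"
    args <- list(cb = cb)
    for (nm in c("n", "beta0", "sigma_int2", "tilt", "seed")) {
      if (!is.null(s[[nm]])) args[[nm]] <- s[[nm]]
    }
    if (!is.null(s$marginals)) args$marginals <- purrr::map(s$marginals, unlist)
    if (!is.null(s$betas)) args$betas <- purrr::map(s$betas, unlist)
    if (!is.null(s$missingness)) args$missingness <- unlist(s$missingness)
    if (!is.null(s$explicit_interactions)) {
      args$explicit_interactions <- unlist(s$explicit_interactions)
    }
    y$synthetic <- do.call(synthetic_config, args)
  }
  y$cb <- cb
  y
}
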