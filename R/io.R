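#' Read / write subject-level cohort CSV
#'
#' The on-disk cohort schema is one row per subject with header columns
#' `id`, `time`, `event`, then covariates (UTF-8). [write_cohort_csv()]
#' writes numbers at 6 significant digits; [read_cohort_csv()] validates the
#' required columns and returns a tibble.
#'
#' @param path File path.
#' @param data Subject-level data frame.
#' @return `read_cohort_csv()`: a tibble; `write_cohort_csv()`: `path`,
#'   invisibly.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("cohort file not found: ", path))
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  miss <- setdiff(c("id", "time", "event"), names(df))
  if (length(miss) > 0) {
    abort(paste0("cohort CSV is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  df
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(data, path) {
  out <- as.data.frame(data)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

fmt6 <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

run_log <- function(dir, lines) {
  stamp <- format(Sys.time(), "%Y-%m-%d %H:%M:%S")
  writeLines(paste0("[", stamp, "] ", lines), file.path(dir, "run.log"))
}

#' Simulate a cohort to disk
#'
#' Thin pipeline wrapper over [synthetic_config()] + [simulate_cohort()]:
#' writes `cohort.csv` in the schema [read_cohort_csv()] expects and a
#' YAML `manifest.yaml` recording the generative truth and the seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param n,J,seed,... Passed to [synthetic_config()] / [simulate_cohort()].
#' @return Invisibly, the cohort tibble.
#' @export
run_simulate <- function(out_dir, n, J = 24, seed = 1, ...) {
  if (!is.numeric(n) || n < 1) abort("`n` must be a positive integer.")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- synthetic_config(n = n, J = J, ...)
  cohort <- simulate_cohort(config, seed = seed)
  write_cohort_csv(cohort, file.path(out_dir, "cohort.csv"))
  man <- attr(cohort, "manifest")
  man$coefficients <- as.data.frame(man$coefficients)
  yaml::write_yaml(man, file.path(out_dir, "manifest.yaml"))
  run_log(out_dir, c(
    paste0("simulate: n=", n, " J=", J, " seed=", seed),
    paste0("events=", sum(cohort$event)),
    paste0("config hash=", rlang::hash(config))))
  invisible(cohort)
}

#' Fit the path system from files and write all artefacts
#'
#' Reads a subject-level cohort CSV and a YAML model config, fits the path
#' system, and writes four artefacts to `out_dir`: `coefficients.csv`
#' (per-equation direct effects with SE, z, p, plus residual-variance rows),
#' `decomposition.csv` (direct, per-path indirect, totals and the mediation
#' proportion; estimates also rounded to 3 decimals for presentation),
#' `curves.csv` (per-period hazard and survival at the baseline and at the
#' cohort-mean covariate profile), and a timestamped `run.log`.
#'
#' @param data_csv Path to the cohort CSV.
#' @param config_yaml Path to the model config (see [read_path_config()]).
#' @param out_dir Output directory.
#' @param vcov_type,na_action Passed to [fit_path_system()].
#' @param bootstrap If > 0, also writes `bootstrap.csv` with percentile CIs
#'   from that many replicates.
#' @param standardize `"raw"` or `"ystar"`; writes `standardized.csv` with
#'   the latent-response view of the outcome equation.
#' @param seed Seed recorded in the log and used for the bootstrap.
#' @return Invisibly, a list with the `path_model_fit` and the
#'   decomposition.
#' @export
run_fit <- function(data_csv, config_yaml, out_dir, vcov_type = "robust",
                    na_action = "complete", bootstrap = 0,
                    standardize = "raw", seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- read_cohort_csv(data_csv)
  spec <- read_path_config(config_yaml)
  dropped <- sum(!complete.cases(data))
  fit <- fit_path_system(data, spec, vcov_type = vcov_type,
                         na_action = na_action)

  co <- tidy(fit)
  rv <- tibble::tibble(equation = names(fit$resid_var),
                       term = "residual_variance",
                       estimate = unlist(fit$resid_var))
  utils::write.csv(fmt6(dplyr::bind_rows(co, rv)),
                   file.path(out_dir, "coefficients.csv"), row.names = FALSE)

  dec <- decompose(fit)
  dec_out <- dplyr::mutate(tibble::as_tibble(dec),
                           estimate_3dp = round(.data$estimate, 3))
  dec_out <- dplyr::bind_rows(
    fmt6(dec_out),
    tibble::tibble(effect = "mediation_proportion", label = spec$exposure,
                   estimate = signif(attr(dec, "mediation_proportion"), 6)))
  utils::write.csv(dec_out, file.path(out_dir, "decomposition.csv"),
                   row.names = FALSE)

  mean_profile <- colMeans(data[fit$dtsm$covariates])
  curves <- dplyr::bind_rows(
    dplyr::mutate(predict_curve(fit$dtsm), profile = "baseline"),
    dplyr::mutate(predict_curve(fit$dtsm, mean_profile), profile = "cohort_mean"))
  utils::write.csv(fmt6(as.data.frame(curves)),
                   file.path(out_dir, "curves.csv"), row.names = FALSE)

  if (!identical(standardize, "raw")) {
    utils::write.csv(fmt6(standardize_latent(fit, standardize)),
                     file.path(out_dir, "standardized.csv"), row.names = FALSE)
  }
  if (bootstrap > 0) {
    bs <- bootstrap_indirect(data, spec, B = bootstrap, seed = seed,
                             vcov_type = vcov_type)
    utils::write.csv(fmt6(bs), file.path(out_dir, "bootstrap.csv"),
                     row.names = FALSE)
  }
  run_log(out_dir, c(
    paste0("fit: data=", data_csv, " config=", config_yaml, " seed=", seed),
    paste0("config hash=", rlang::hash(spec)),
    paste0("n=", nrow(data), " events=", fit$dtsm$n_events,
           " dropped=", dropped),
    paste0("converged=", fit$dtsm$converged,
           " loglik=", signif(fit$dtsm$loglik, 6)),
    paste0("lpm out-of-range: ",
           paste(names(fit$lpm_out_of_range),
                 unlist(fit$lpm_out_of_range), sep = "=", collapse = " "))))
  invisible(list(fit = fit, decomposition = dec))
}

#' Decompose from a coefficient file alone
#'
#' Runs the mediation engine directly on supplied coefficient estimates —
#' no subject-level data needed — which reproduces a published decomposition
#' from its printed direct-effects table.
#'
#' @param coefficients_csv CSV with columns `equation`, `term`, `estimate`,
#'   `std.error`.
#' @param config_yaml Model config naming the equations and exposure.
#' @param out_csv Where to write the decomposition (optional).
#' @param within_equation Passed to [decompose()].
#' @return The `mediation_decomposition`, invisibly if `out_csv` is given.
#' @export
run_decompose <- function(coefficients_csv, config_yaml, out_csv = NULL,
                          within_equation = FALSE) {
  if (!file.exists(coefficients_csv)) {
    abort(paste0("coefficients file not found: ", coefficients_csv))
  }
  ct <- tibble::as_tibble(utils::read.csv(coefficients_csv,
                                          stringsAsFactors = FALSE))
  need <- c("equation", "term", "estimate", "std.error")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) {
    abort(paste0("coefficients file missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  spec <- read_path_config(config_yaml)
  dec <- decompose(ct, spec = spec, within_equation = within_equation)
  if (is.null(out_csv)) return(dec)
  out <- dplyr::mutate(tibble::as_tibble(dec),
                       estimate_3dp = round(.data$estimate, 3))
  out <- dplyr::bind_rows(
    fmt6(out),
    tibble::tibble(effect = "mediation_proportion", label = spec$exposure,
                   estimate = signif(attr(dec, "mediation_proportion"), 6)))
  utils::write.csv(out, out_csv, row.names = FALSE)
  invisible(dec)
}
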