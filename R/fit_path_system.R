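#' Fit a recursive path system with a discrete-time survival outcome
#'
#' Estimates each equation of the system separately, which is the maximum
#' likelihood solution for a recursive system with independent errors:
#' linear (probability) equations by least squares with
#' heteroskedasticity-robust standard errors, and the survival equation by
#' [fit_dtsm()] on the person-period expansion. Cross-equation parameter
#' covariances are taken as zero (the likelihood factorizes across
#' equations); within-equation covariance blocks are retained.
#'
#' @param data Subject-level data frame: `id`, the spec's `time` and `event`
#'   columns, and every variable named in the spec.
#' @param spec A [path_model_spec()].
#' @param vcov_type Passed to [fit_dtsm()] for the outcome equation;
#'   `"robust"` also selects HC1 robust errors for the linear equations
#'   (`"model"` selects the classical least-squares covariance).
#' @param ... Further arguments to [expand_person_period()] (e.g.
#'   `na_action`).
#' @return An object of class `path_model_fit`: a per-equation coefficient
#'   table (see [tidy()]), per-equation covariance blocks, residual variances
#'   of the linear equations, the embedded `dtsm_fit`, and bookkeeping on
#'   out-of-range linear-probability predictions. Pass to [decompose()] for
#'   the mediation decomposition.
#' @export
fit_path_system <- function(data, spec, vcov_type = c("robust", "model"), ...) {
  vcov_type <- match.arg(vcov_type)
  spec <- validate_path_spec(spec)
  data <- tibble::as_tibble(data)
  vars <- unique(unlist(lapply(spec$equations, function(eq)
    c(setdiff(eq$dependent, spec$outcome), eq$regressors))))
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0) {
    abort(paste0("data is missing variable(s): ", paste(miss, collapse = ", ")))
  }

  coef_rows <- list()
  vcovs <- list()
  resid_var <- list()
  lpm_out_of_range <- list()
  dtsm <- NULL

  for (eq in spec$equations) {
    if (eq$link == "linear") {
      fml <- stats::reformulate(eq$regressors, response = eq$dependent)
      fit <- tryCatch(lm(fml, data = data), error = function(e)
        abort(paste0("equation for ", eq$dependent, " failed: ",
                     conditionMessage(e))))
      V <- if (vcov_type == "robust") sandwich::vcovHC(fit, type = "HC1")
           else stats::vcov(fit)
      est <- coef(fit)
      if (anyNA(est)) {
        abort(paste0("equation for ", eq$dependent,
                     " is rank deficient (dropped: ",
                     paste(names(est)[is.na(est)], collapse = ", "), ")."))
      }
      term <- sub("^\\(Intercept\\)$", "intercept", names(est))
      coef_rows[[eq$dependent]] <- tibble::tibble(
        equation = eq$dependent, term = term, estimate = unname(est),
        std.error = sqrt(diag(V)))
      dimnames(V) <- list(term, term)
      vcovs[[eq$dependent]] <- V
      resid_var[[eq$dependent]] <- mean(stats::residuals(fit)^2)
      fv <- stats::fitted(fit)
      lpm_out_of_range[[eq$dependent]] <- sum(fv < 0 | fv > 1)
    } else {
      pp <- expand_person_period(data, J_max = spec$J_max,
                                 time = spec$time, event = spec$event, ...)
      dtsm <- fit_dtsm(pp, covariates = eq$regressors,
                       baseline = spec$baseline,
                       free = if (spec$proportional) character() else eq$regressors,
                       vcov_type = vcov_type)
      keep <- dtsm$info$col[dtsm$info$type != "baseline"]
      td <- tidy(dtsm)
      td <- td[td$term %in% keep, ]
      coef_rows[[eq$dependent]] <- tibble::tibble(
        equation = eq$dependent, term = td$term, estimate = td$estimate,
        std.error = td$std.error)
      vcovs[[eq$dependent]] <- dtsm$vcov[keep, keep, drop = FALSE]
    }
  }

  oor <- unlist(lpm_out_of_range)
  if (length(oor) > 0 && any(oor > 0)) {
    inform(paste0("Linear-probability fitted values outside [0, 1]: ",
                  paste0(names(oor)[oor > 0], " (", oor[oor > 0], ")",
                         collapse = ", "), "."))
  }

  structure(list(
    spec = spec,
    coefficients = dplyr::bind_rows(coef_rows),
    vcov = vcovs,
    resid_var = resid_var,
    lpm_out_of_range = lpm_out_of_range,
    dtsm = dtsm,
    n_subjects = nrow(data),
    vcov_type = vcov_type
  ), class = "path_model_fit")
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat("Recursive path system with discrete-time survival outcome\n")
  cat(sprintf("  subjects: %d  equations: %d  outcome: %s\n",
              x$n_subjects, length(x$spec$equations), x$spec$outcome))
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy a fitted path system
#'
#' One row per (equation, regressor) coefficient, in equation order, with
#' Wald statistics — the layout of a direct-effects table.
#'
#' @param x A `path_model_fit`.
#' @param ... Unused.
#' @method tidy path_model_fit
#' @export
tidy.path_model_fit <- function(x, ...) {
  dplyr::mutate(x$coefficients,
                statistic = .data$estimate / .data$std.error,
                p.value = 2 * pnorm(-abs(.data$statistic)))
}

#' Fit statistics for a path system
#'
#' @param x A `path_model_fit`.
#' @param ... Unused.
#' @method glance path_model_fit
#' @export
glance.path_model_fit <- function(x, ...) {
  tibble::tibble(n_subjects = x$n_subjects,
                 n_equations = length(x$spec$equations),
                 n_events = if (!is.null(x$dtsm)) x$dtsm$n_events else NA_integer_,
                 logLik_outcome = if (!is.null(x$dtsm)) x$dtsm$loglik else NA_real_,
                 lpm_out_of_range = sum(unlist(x$lpm_out_of_range)))
}

#' Latent-response standardized view of the outcome equation
#'
#' The survival indicators are generated by a latent propensity crossing a
#' threshold, so the hazard-equation coefficients can be read as linear
#' effects on that latent response. The default `"raw"` convention reports
#' them as estimated on the logit-latent scale, treating the latent response
#' as having unit standard deviation — this is the metric on which the
#' product-of-coefficients decomposition operates. The `"ystar"` convention
#' instead divides by the model-implied latent-response standard deviation,
#' `sqrt(var(kappa'x) + pi^2/3)`, which rescales per-unit effects to the
#' standardized latent outcome.
#'
#' @param fit A `path_model_fit`.
#' @param method `"raw"` (default) or `"ystar"`.
#' @return A tibble of outcome-equation coefficients with columns `term`,
#'   `estimate`, `std.error`, `std_estimate`, `std_std.error`, and the
#'   scaling factor as an attribute.
#' @export
standardize_latent <- function(fit, method = c("raw", "ystar")) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "path_model_fit"))
  if (is.null(fit$dtsm)) abort("fit has no survival outcome equation.")
  co <- fit$coefficients[fit$coefficients$equation == fit$spec$outcome, ]
  scale <- if (method == "raw") 1 else sqrt(fit$dtsm$var_lp + pi^2 / 3)
  out <- dplyr::mutate(co, std_estimate = .data$estimate / scale,
                       std_std.error = .data$std.error / scale)
  attr(out, "scale") <- scale
  attr(out, "method") <- method
  out
}
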