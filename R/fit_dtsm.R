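#' Fit the discrete-time survival model with logistic hazard
#'
#' Maximum-likelihood estimation of the discrete-time hazard model
#' `logit(h_ij) = beta_j + kappa' x_i` on a person-period table. The `u`
#' indicators are Bernoulli given the linear logit predictor, so the joint
#' log-likelihood is the sum of per-row logistic contributions; it is
#' maximized by Newton iteration with the analytic gradient and Hessian.
#'
#' The baseline hazard may be unstructured (one free intercept per period),
#' constant, or piecewise constant over user-supplied groups of periods.
#' With `proportional = TRUE` each covariate has a single coefficient shared
#' across periods (the proportional hazard-odds model, implemented by shared
#' design-matrix columns so the equality constraints hold exactly);
#' covariates named in `free` instead receive one coefficient per period,
#' which is what the proportionality test relaxes.
#'
#' Periods with no events cannot support a finite intercept under the
#' unstructured baseline; their intercept is fixed at -15 (hazard
#' essentially zero) with a warning, keeping the fit finite and reproducible.
#'
#' @param table A `person_period` tibble from [expand_person_period()].
#' @param covariates Character vector of covariate columns entering the
#'   hazard equation (default: none, the baseline-only model).
#' @param baseline `"unstructured"`, `"constant"`, or a list of integer
#'   vectors partitioning `1..J_max` into piecewise-constant groups.
#' @param free Character vector (subset of `covariates`) whose coefficients
#'   are period-specific rather than constant.
#' @param vcov_type `"robust"` (default) for the sandwich estimator clustered
#'   by subject, or `"model"` for the inverse observed information.
#' @param tol Convergence tolerance on the maximum absolute score.
#' @param max_iter Maximum Newton iterations before declaring non-convergence.
#'
#' @return An object of class `dtsm_fit`: coefficients, covariance matrix,
#'   log-likelihood, convergence diagnostics, and the information needed to
#'   predict hazard and survival curves. Use [tidy()] for a coefficient
#'   table, [glance()] for fit statistics, [predict_curve()] for curves.
#' @export
fit_dtsm <- function(table, covariates = character(),
                     baseline = "unstructured", free = character(),
                     vcov_type = c("robust", "model"),
                     tol = 1e-8, max_iter = 50L) {
  vcov_type <- match.arg(vcov_type)
  stopifnot(inherits(table, "person_period"))
  miss <- setdiff(covariates, names(table))
  if (length(miss) > 0) {
    abort(paste0("covariate(s) not in table: ", paste(miss, collapse = ", ")))
  }
  if (length(setdiff(free, covariates)) > 0) {
    abort("`free` must be a subset of `covariates`.")
  }
  u <- table$u
  if (sum(u) == 0 || sum(u) == length(u)) {
    abort("degenerate table: need at least one event and one non-event row.")
  }

  des <- build_dtsm_design(table, baseline, covariates, free)
  X <- des$X
  off <- des$offset

  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    abort(paste0("design matrix is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", ")))
  }

  nm <- newton_logit(u, X, off, tol = tol, max_iter = max_iter)
  if (!nm$converged) {
    abort(paste0("DTSM fit failed to converge after ", max_iter,
                 " iterations (max |score| = ", format(nm$max_grad),
                 ", max |coef| = ", format(max(abs(nm$beta))),
                 "); possible separation."))
  }

  p_hat <- plogis(drop(X %*% nm$beta) + off)
  Hinv <- chol2inv(chol(nm$hessian))
  V <- if (vcov_type == "robust") {
    sc <- X * (u - p_hat)                       # per-row score contributions
    G <- rowsum(sc, group = table$id)           # per-subject scores
    Hinv %*% crossprod(G) %*% Hinv
  } else {
    Hinv
  }
  dimnames(V) <- list(colnames(X), colnames(X))

  # between-subject variance of the covariate part of the linear predictor,
  # used by the latent-response standardization
  var_lp <- 0
  if (length(covariates) > 0) {
    first <- !duplicated(table$id)
    cov_cols <- des$info$col[des$info$type != "baseline"]
    lp_cov <- drop(X[first, cov_cols, drop = FALSE] %*%
                     nm$beta[cov_cols])
    var_lp <- var(lp_cov)
  }

  structure(list(
    coefficients = setNames(nm$beta, colnames(X)),
    vcov = V,
    vcov_type = vcov_type,
    loglik = nm$loglik,
    n_params = ncol(X),
    converged = TRUE,
    iterations = nm$iter,
    max_grad = nm$max_grad,
    baseline = baseline,
    covariates = covariates,
    free = free,
    info = des$info,
    fixed_periods = des$fixed_periods,
    J_max = attr(table, "J_max"),
    n_subjects = length(unique(table$id)),
    n_rows = nrow(table),
    n_events = sum(u),
    var_lp = var_lp
  ), class = "dtsm_fit")
}

# Design matrix for the DTSM: baseline columns, shared covariate columns,
# and period-specific columns for freed covariates. Zero-event periods under
# a period-specific intercept get a -15 offset instead of a free column.
build_dtsm_design <- function(table, baseline, covariates, free) {
  J <- attr(table, "J_max")
  period <- table$period
  ev_by_period <- tapply(table$u, factor(period, levels = seq_len(J)), sum)
  ev_by_period[is.na(ev_by_period)] <- 0
  fixed_periods <- integer()
  offset <- numeric(nrow(table))

  if (identical(baseline, "constant")) {
    B <- matrix(1, nrow(table), 1, dimnames = list(NULL, "baseline"))
    info <- tibble::tibble(col = "baseline", type = "baseline",
                           periods = list(seq_len(J)))
  } else {
    groups <- if (identical(baseline, "unstructured")) {
      as.list(seq_len(J))
    } else if (is.list(baseline)) {
      got <- sort(unlist(baseline))
      if (!identical(as.integer(got), seq_len(J))) {
        abort("piecewise `baseline` groups must partition 1..J_max.")
      }
      baseline
    } else {
      abort("`baseline` must be \"unstructured\", \"constant\", or a list of period groups.")
    }
    keep <- vapply(groups, function(g) sum(ev_by_period[g]) > 0, logical(1))
    if (any(!keep)) {
      fixed_periods <- sort(unlist(groups[!keep]))
      warn(paste0("No events in period(s) ", paste(fixed_periods, collapse = ", "),
                  "; intercept fixed at -15 (hazard ~ 0)."))
      offset[period %in% fixed_periods] <- -15
      groups <- groups[keep]
    }
    nm <- vapply(groups, function(g) {
      if (length(g) == 1) paste0("period_", g)
      else paste0("period_", min(g), "_", max(g))
    }, character(1))
    B <- vapply(groups, function(g) as.numeric(period %in% g),
                numeric(nrow(table)))
    colnames(B) <- nm
    info <- tibble::tibble(col = nm, type = "baseline", periods = groups)
  }

  Xc <- NULL
  shared <- setdiff(covariates, free)
  if (length(shared) > 0) {
    Xc <- as.matrix(table[shared])
    info <- dplyr::bind_rows(info, tibble::tibble(
      col = shared, type = "covariate", periods = list(seq_len(J))))
  }
  Xf <- NULL
  if (length(free) > 0) {
    est_periods <- which(ev_by_period > 0)
    cols <- list()
    for (v in free) {
      for (j in est_periods) {
        cols[[paste0(v, ":period_", j)]] <- table[[v]] * (period == j)
      }
      info <- dplyr::bind_rows(info, tibble::tibble(
        col = paste0(v, ":period_", est_periods), type = "free",
        periods = as.list(est_periods)))
    }
    Xf <- do.call(cbind, cols)
  }

  X <- cbind(B, Xc, Xf)
  list(X = X, offset = offset, info = info, fixed_periods = fixed_periods)
}

# Newton-Raphson for the Bernoulli-logit log-likelihood with offset;
# step-halving safeguards each iteration.
newton_logit <- function(u, X, offset, tol = 1e-8, max_iter = 50L) {
  beta <- numeric(ncol(X))
  ll <- function(b) {
    eta <- drop(X %*% b) + offset
    sum(u * eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    p <- plogis(eta)
    g <- drop(crossprod(X, u - p))
    H <- crossprod(X * sqrt(p * (1 - p)))
    if (max(abs(g)) < tol) {
      return(list(beta = beta, loglik = ll_old, hessian = H,
                  converged = max(abs(beta)) < 30, iter = it - 1L,
                  max_grad = max(abs(g))))
    }
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) {
      return(list(beta = beta, loglik = ll_old, hessian = H,
                  converged = FALSE, iter = it, max_grad = max(abs(g))))
    }
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      ll_new <- ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) break
    }
    beta <- beta + alpha * step
    ll_old <- ll(beta)
  }
  eta <- drop(X %*% beta) + offset
  p <- plogis(eta)
  g <- drop(crossprod(X, u - p))
  H <- crossprod(X * sqrt(p * (1 - p)))
  list(beta = beta, loglik = ll_old, hessian = H,
       converged = max(abs(g)) < tol && max(abs(beta)) < 30,
       iter = max_iter, max_grad = max(abs(g)))
}

#' @export
print.dtsm_fit <- function(x, ...) {
  cat("Discrete-time survival model (logistic hazard)\n")
  cat(sprintf("  subjects: %d  person-periods: %d  events: %d\n",
              x$n_subjects, x$n_rows, x$n_events))
  cat(sprintf("  baseline: %s  log-likelihood: %.3f  (vcov: %s)\n",
              if (is.list(x$baseline)) "piecewise" else x$baseline,
              x$loglik, x$vcov_type))
  print(tidy(x), n = 12)
  invisible(x)
}

#' Tidy a discrete-time survival model fit
#'
#' @param x A `dtsm_fit` object.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy dtsm_fit
#' @export
tidy.dtsm_fit <- function(x, ...) {
  est <- x$coefficients
  se <- sqrt(diag(x$vcov))
  z <- est / se
  tibble::tibble(term = names(est), estimate = unname(est),
                 std.error = unname(se), statistic = unname(z),
                 p.value = 2 * pnorm(-abs(z)))
}

#' Fit statistics for a discrete-time survival model
#'
#' @param x A `dtsm_fit` object.
#' @param ... Unused.
#' @method glance dtsm_fit
#' @export
glance.dtsm_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n_params = x$n_params,
                 AIC = -2 * x$loglik + 2 * x$n_params,
                 n_subjects = x$n_subjects, n_events = x$n_events,
                 n_person_periods = x$n_rows, converged = x$converged)
}

#' Predicted hazard and survival curve for a covariate profile
#'
#' Applies the inverse logit to `beta_j + kappa' x` period by period and
#' accumulates survival as the product of continuation probabilities. With
#' an all-zero profile the result is the baseline hazard.
#'
#' @param fit A `dtsm_fit` object.
#' @param profile Named numeric vector or list giving a value for every
#'   covariate in the fit. Defaults to all zeros (the baseline profile).
#' @return A `hazard_curve` tibble with columns `period`, `logit`, `hazard`,
#'   `survival`.
#' @export
predict_curve <- function(fit, profile = NULL) {
  stopifnot(inherits(fit, "dtsm_fit"))
  profile <- unlist(profile %||% setNames(numeric(length(fit$covariates)),
                                          fit$covariates))
  miss <- setdiff(fit$covariates, names(profile))
  if (length(miss) > 0) {
    abort(paste0("profile is missing covariate(s): ", paste(miss, collapse = ", ")))
  }
  J <- fit$J_max
  logit_j <- rep(-15, J)
  for (k in seq_len(nrow(fit$info))) {
    row <- fit$info[k, ]
    co <- fit$coefficients[[row$col]]
    pds <- row$periods[[1]]
    if (row$type == "baseline") {
      logit_j[pds] <- co
    } else if (row$type == "covariate") {
      logit_j <- logit_j + co * profile[[sub(":period_\\d+$", "", row$col)]]
    } else {
      v <- sub(":period_\\d+$", "", row$col)
      logit_j[pds] <- logit_j[pds] + co * profile[[v]]
    }
  }
  h <- hazard_from_logit(logit_j)
  structure(tibble::tibble(period = seq_len(J), logit = logit_j, hazard = h,
                           survival = survival_from_hazard(h)),
            class = c("hazard_curve", class(tibble::tibble())))
}

#' Likelihood-ratio test of the proportionality assumption
#'
#' Compares the proportional model, in which `covariate` has one coefficient
#' shared by all periods, against the relaxed model in which its coefficient
#' is free to differ across periods. Twice the log-likelihood gap is referred
#' to a chi-square distribution with one degree of freedom per freed
#' parameter. Both fits use the model-based likelihood; the test is invariant
#' to the vcov choice.
#'
#' @inheritParams fit_dtsm
#' @param covariate Name of the covariate whose proportionality is tested.
#' @return A tibble with `statistic`, `df`, `p.value`, plus the two
#'   log-likelihoods. If the relaxed model does not converge the test
#'   abstains with an error describing the failure.
#' @export
test_proportionality <- function(table, covariates, covariate,
                                 baseline = "unstructured", ...) {
  if (!covariate %in% covariates) {
    abort("`covariate` must be one of `covariates`.")
  }
  fit0 <- fit_dtsm(table, covariates, baseline = baseline, ...)
  fit1 <- tryCatch(
    fit_dtsm(table, covariates, baseline = baseline, free = covariate, ...),
    error = function(e) abort(paste0(
      "proportionality test abstains: relaxed model failed (", conditionMessage(e), ")"))
  )
  df <- fit1$n_params - fit0$n_params
  lr <- max(0, 2 * (fit1$loglik - fit0$loglik))
  tibble::tibble(covariate = covariate, statistic = lr, df = df,
                 p.value = if (df > 0) pchisq(lr, df, lower.tail = FALSE) else NA_real_,
                 loglik_constrained = fit0$loglik, loglik_free = fit1$loglik)
}
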