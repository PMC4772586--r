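#' Product-of-coefficients indirect effect along one path
#'
#' In the linear system (with the survival equation read on its latent
#' response metric) the natural indirect effect transmitted along a chain
#' `exposure -> m1 -> ... -> outcome` is the product of the fitted
#' coefficients of its edges.
#'
#' @param path Character vector naming the chain, e.g.
#'   `c("affluence", "emergency", "hazard")`, as produced by
#'   [enumerate_paths()].
#' @param fit A `path_model_fit`, or a coefficient data frame with columns
#'   `equation`, `term`, `estimate` (and `std.error` for [delta_se()]).
#' @return The product of the edge coefficients (a scalar).
#' @export
indirect_effect <- function(path, fit) {
  prod(edge_coefficients(path, fit)$estimate)
}

#' Delta-method standard error of a product of coefficients
#'
#' First-order delta method for the product along one path:
#' `Var = sum_k (prod of other coefficients)^2 Var(coef_k)`, plus covariance
#' cross-terms only where two edges of the path are estimated within the same
#' equation and `within_equation = TRUE`. Coefficients from different
#' equations of the recursive system are uncorrelated (the likelihood
#' factorizes), so the default zero-cross-covariance convention is exact
#' across equations.
#'
#' @inheritParams indirect_effect
#' @param within_equation Include within-equation covariance terms (requires
#'   a `path_model_fit`, or `vcov` blocks).
#' @param vcov Optional named list of per-equation covariance matrices when
#'   `fit` is a plain coefficient table.
#' @return The delta-method standard error (a scalar).
#' @export
delta_se <- function(path, fit, within_equation = FALSE, vcov = NULL) {
  ec <- edge_coefficients(path, fit)
  grad <- vapply(seq_len(nrow(ec)), function(k) prod(ec$estimate[-k]),
                 numeric(1))
  V <- param_cov(ec, fit, within_equation, vcov)
  sqrt(drop(t(grad) %*% V %*% grad))
}

# Coefficients of the edges of a chain: edge a -> b lives in equation b,
# term a.
edge_coefficients <- function(path, fit) {
  ct <- coef_table(fit)
  stopifnot(is.character(path), length(path) >= 2)
  out <- purrr::map2_dfr(path[-length(path)], path[-1], function(a, b) {
    row <- ct[ct$equation == b & ct$term == a, ]
    if (nrow(row) != 1) {
      abort(paste0("no fitted coefficient for edge ", a, " -> ", b, "."))
    }
    row
  })
  out
}

coef_table <- function(fit) {
  if (inherits(fit, "path_model_fit")) return(fit$coefficients)
  fit <- tibble::as_tibble(fit)
  need <- c("equation", "term", "estimate")
  if (!all(need %in% names(fit))) {
    abort("coefficient table needs columns equation, term, estimate (and std.error).")
  }
  fit
}

# Covariance matrix of a set of coefficients under the stated convention:
# block-diagonal by equation; diagonal-only unless within_equation = TRUE.
param_cov <- function(ec, fit, within_equation, vcov = NULL) {
  k <- nrow(ec)
  if (is.null(ec$std.error)) abort("std.error column is required for SEs.")
  V <- diag(ec$std.error^2, k)
  if (within_equation) {
    blocks <- if (inherits(fit, "path_model_fit")) fit$vcov else vcov
    if (is.null(blocks)) {
      abort("within_equation = TRUE needs per-equation vcov blocks.")
    }
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (ec$equation[i] == ec$equation[j]) {
        B <- blocks[[ec$equation[i]]]
        V[i, j] <- V[j, i] <- B[ec$term[i], ec$term[j]]
      }
    }
  }
  V
}

#' Mediation decomposition of the exposure effect
#'
#' Decomposes the total effect of the exposure on the (latent-response)
#' hazard into the natural direct effect and the natural indirect effect
#' along every exposure-to-outcome path, computed by the
#' product-of-coefficients method with delta-method standard errors. The
#' total effect is the sum of the direct and all indirect effects, and the
#' mediation proportion is total indirect over total effect.
#'
#' `decompose()` is generic: apply it to a [fit_path_system()] result, or to
#' a plain coefficient table (columns `equation`, `term`, `estimate`,
#' `std.error`) together with a `spec` — the latter route reproduces a
#' published decomposition directly from printed coefficient estimates.
#'
#' @param x A `path_model_fit` or a coefficient data frame.
#' @param ... Passed between methods.
#' @return A `mediation_decomposition` tibble: one row per effect (`direct`,
#'   each indirect path, `total_indirect`, `total_effect`) with `estimate`,
#'   `std.error`, `statistic`, `p.value` and 95% confidence limits. The
#'   mediation proportion and an inconsistent-mediation flag are attached as
#'   attributes and shown by `print()`.
#' @export
decompose <- function(x, ...) UseMethod("decompose")

#' @rdname decompose
#' @param spec A [path_model_spec()] describing the system (`data.frame`
#'   method only).
#' @param within_equation Include within-equation covariance terms in the
#'   delta method (default `FALSE`, the zero-cross-covariance convention).
#' @param vcov Optional named list of per-equation covariance matrices
#'   (`data.frame` method only).
#' @export
decompose.data.frame <- function(x, spec, within_equation = FALSE,
                                 vcov = NULL, ...) {
  decompose_impl(coef_table(x), spec, within_equation, vcov)
}

#' @rdname decompose
#' @export
decompose.path_model_fit <- function(x, within_equation = FALSE, ...) {
  decompose_impl(x$coefficients, x$spec, within_equation, x$vcov)
}

decompose_impl <- function(ct, spec, within_equation, vcov) {
  spec <- validate_path_spec(spec)
  paths <- enumerate_paths(spec)
  direct_row <- ct[ct$equation == spec$outcome & ct$term == spec$exposure, ]
  if (nrow(direct_row) != 1) {
    abort(paste0("exposure \"", spec$exposure,
                 "\" has no direct coefficient in the outcome equation."))
  }

  # parameter vector: every distinct coefficient entering the decomposition
  keys <- unique(dplyr::bind_rows(
    direct_row[, c("equation", "term")],
    purrr::map_dfr(paths, function(p) edge_coefficients(p, ct)[, c("equation", "term")])))
  pars <- dplyr::left_join(keys, ct, by = c("equation", "term"))
  key_of <- function(eq, tm) match(paste(eq, tm), paste(pars$equation, pars$term))
  V <- param_cov(pars, NULL, within_equation, vcov)

  path_grad <- function(p) {
    ec <- edge_coefficients(p, ct)
    g <- numeric(nrow(pars))
    for (k in seq_len(nrow(ec))) {
      g[key_of(ec$equation[k], ec$term[k])] <- prod(ec$estimate[-k])
    }
    g
  }
  se_of <- function(g) sqrt(drop(t(g) %*% V %*% g))

  g_direct <- numeric(nrow(pars))
  g_direct[key_of(spec$outcome, spec$exposure)] <- 1

  rows <- list(tibble::tibble(
    effect = "direct", label = spec$exposure,
    estimate = direct_row$estimate, std.error = direct_row$std.error))
  g_ti <- numeric(nrow(pars))
  for (p in paths) {
    g <- path_grad(p)
    g_ti <- g_ti + g
    rows[[length(rows) + 1L]] <- tibble::tibble(
      effect = "indirect", label = paste(p, collapse = " -> "),
      estimate = indirect_effect(p, ct), std.error = se_of(g))
  }
  ti <- sum(vapply(paths, indirect_effect, numeric(1), fit = ct))
  rows[[length(rows) + 1L]] <- tibble::tibble(
    effect = "total_indirect", label = "all indirect paths",
    estimate = ti, std.error = se_of(g_ti))
  te <- direct_row$estimate + ti
  rows[[length(rows) + 1L]] <- tibble::tibble(
    effect = "total_effect", label = spec$exposure,
    estimate = te, std.error = se_of(g_ti + g_direct))

  out <- dplyr::bind_rows(rows)
  out <- dplyr::mutate(out,
    statistic = ifelse(.data$std.error > 0, .data$estimate / .data$std.error, NA_real_),
    p.value = 2 * pnorm(-abs(.data$statistic)),
    conf.low = .data$estimate - qnorm(0.975) * .data$std.error,
    conf.high = .data$estimate + qnorm(0.975) * .data$std.error)

  prop <- if (te == 0) NA_real_ else ti / te
  inconsistent <- isTRUE(!is.na(prop) && (prop < 0 || prop > 1))
  structure(out,
            mediation_proportion = prop,
            inconsistent_mediation = inconsistent,
            exposure = spec$exposure, outcome = spec$outcome,
            class = c("mediation_decomposition", class(out)))
}

#' @export
print.mediation_decomposition <- function(x, ...) {
  cat(sprintf("Mediation decomposition: %s -> %s\n",
              attr(x, "exposure"), attr(x, "outcome")))
  NextMethod()
  prop <- attr(x, "mediation_proportion")
  if (is.na(prop)) {
    cat("Mediation proportion: undefined (total effect is zero)\n")
  } else {
    cat(sprintf("Mediation proportion: %.3f%s\n", prop,
                if (attr(x, "inconsistent_mediation"))
                  " (inconsistent mediation: direct and indirect effects oppose)"
                else ""))
  }
  invisible(x)
}

#' @method glance mediation_decomposition
#' @export
glance.mediation_decomposition <- function(x, ...) {
  tibble::tibble(
    mediation_proportion = attr(x, "mediation_proportion"),
    inconsistent_mediation = attr(x, "inconsistent_mediation"),
    n_indirect_paths = sum(x$effect == "indirect"),
    total_effect = x$estimate[x$effect == "total_effect"])
}

#' Bootstrap confidence intervals for the mediation decomposition
#'
#' Nonparametric bootstrap resampling subjects with replacement: each
#' replicate refits the full path system and recomputes the decomposition.
#' Percentile intervals and bootstrap standard errors cross-check the
#' delta-method Wald intervals. Replicates whose fit fails are logged and
#' skipped; more than 10% failures aborts.
#'
#' @inheritParams fit_path_system
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed; results are reproducible given `seed`.
#' @return A tibble with one row per decomposition effect: the original
#'   `estimate`, `boot_se`, and percentile `conf.low`/`conf.high`; the
#'   number of failed replicates is attached as attribute `n_failed`.
#' @export
bootstrap_indirect <- function(data, spec, B = 500, seed = 1,
                               vcov_type = "robust", ...) {
  if (!is.numeric(B) || B < 100) abort("`B` must be at least 100.")
  data <- tibble::as_tibble(data)
  base <- decompose(fit_path_system(data, spec, vcov_type = vcov_type, ...))
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = B, ncol = nrow(base))
  n_failed <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(data), replace = TRUE)
    rep_data <- data[idx, ]
    rep_data$id <- seq_len(nrow(rep_data))   # resampled subjects are distinct
    d <- tryCatch(
      suppressMessages(decompose(
        fit_path_system(rep_data, spec, vcov_type = vcov_type, ...))),
      error = function(e) NULL)
    if (is.null(d) || !identical(d$label, base$label)) {
      n_failed <- n_failed + 1L
      if (n_failed > 0.1 * B) {
        abort(paste0("bootstrap aborted: ", n_failed, " of ", b,
                     " replicates failed."))
      }
    } else {
      draws[b, ] <- d$estimate
    }
  }
  ok <- stats::complete.cases(draws)
  out <- tibble::tibble(
    effect = base$effect, label = base$label, estimate = base$estimate,
    boot_se = apply(draws[ok, , drop = FALSE], 2, sd),
    conf.low = apply(draws[ok, , drop = FALSE], 2, quantile, probs = 0.025),
    conf.high = apply(draws[ok, , drop = FALSE], 2, quantile, probs = 0.975))
  attr(out, "n_failed") <- n_failed
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}
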