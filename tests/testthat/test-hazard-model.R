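test_that("link functions obey their identities", {
  expect_equal(hazard_from_logit(0), 0.5)
  expect_lt(hazard_from_logit(-20), 1e-8)
  h <- seq(0.1, 0.9, by = 0.1)
  expect_equal(hazard_from_logit(qlogis(h)), h)

  expect_equal(survival_from_hazard(c(0.5, 0.5)), c(0.5, 0.25))
  expect_equal(survival_from_hazard(rep(0, 5)), rep(1, 5))
  set.seed(3)
  hh <- runif(24)
  loop <- numeric(24)
  s <- 1
  for (k in 1:24) { s <- s * (1 - hh[k]); loop[k] <- s }
  expect_equal(survival_from_hazard(hh), loop, tolerance = 1e-15)
  expect_error(survival_from_hazard(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("the no-covariate unstructured fit is saturated on the life table", {
  cohort <- sim_dtsm_cohort(300, 8, qlogis(0.15), 0.5, seed = 21)
  pp <- expand_person_period(cohort, J_max = 8)
  fit <- fit_dtsm(pp, baseline = "unstructured")
  lt <- risk_set_counts(pp)
  expect_equal(predict_curve(fit)$hazard, lt$hazard, tolerance = 1e-10)
  # likelihood factorizes into per-row Bernoulli contributions
  p_row <- lt$hazard[pp$period]
  expect_equal(fit$loglik,
               sum(log(ifelse(pp$u == 1, p_row, 1 - p_row))),
               tolerance = 1e-10)
})

test_that("the proportional fit matches pooled logistic regression", {
  cohort <- sim_dtsm_cohort(400, 6, qlogis(0.12), 0.6, seed = 8)
  cohort$x2 <- rbinom(400, 1, 0.4)
  pp <- expand_person_period(cohort, J_max = 6)
  fit <- fit_dtsm(pp, covariates = c("x", "x2"))
  g <- glm(u ~ 0 + factor(period) + x + x2, family = binomial, data = pp,
           control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)[c("x", "x2")]), unname(coef(g)[c("x", "x2")]),
               tolerance = 1e-7)
  expect_equal(fit$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
  # cluster-robust sandwich agrees with the generic sandwich estimator
  Vo <- sandwich::vcovCL(g, cluster = pp$id, type = "HC0", cadjust = FALSE)
  expect_equal(unname(sqrt(diag(fit$vcov))[c("x", "x2")]),
               unname(sqrt(diag(Vo))[c("x", "x2")]), tolerance = 1e-6)
  # model-based errors match glm's information matrix
  fit_m <- fit_dtsm(pp, covariates = c("x", "x2"), vcov_type = "model")
  expect_equal(unname(sqrt(diag(fit_m$vcov))["x"]),
               unname(sqrt(diag(vcov(g)))["x"]), tolerance = 1e-6)
})

test_that("baseline structures give the stated parameter counts and constraints", {
  cohort <- sim_dtsm_cohort(300, 8, qlogis(0.15), 0.4, seed = 4)
  pp <- expand_person_period(cohort, J_max = 8)
  expect_equal(fit_dtsm(pp, baseline = "constant")$n_params, 1L)
  expect_equal(fit_dtsm(pp, baseline = "unstructured")$n_params, 8L)
  pw <- fit_dtsm(pp, baseline = list(1:4, 5:8))
  expect_equal(pw$n_params, 2L)
  # piecewise fit holds the hazard constant within each group
  h <- predict_curve(pw)$hazard
  expect_equal(h[1:4], rep(h[1], 4))
  expect_error(fit_dtsm(pp, baseline = list(1:3, 5:8)), "partition")
})

test_that("zero-event periods are fixed at a near-zero hazard with a warning", {
  cohort <- tibble::tibble(id = 1:40, time = rep(c(1L, 4L), 20),
                           event = rep(c(1L, 0L), 20))
  pp <- expand_person_period(cohort, J_max = 4)
  expect_warning(fit <- fit_dtsm(pp, baseline = "unstructured"), "fixed at -15")
  expect_equal(fit$fixed_periods, 2:4)
  h <- predict_curve(fit)$hazard
  expect_equal(h[1], 0.5, tolerance = 1e-8)
  expect_lt(max(h[2:4]), 1e-6)
})

test_that("predicted curves are linear in the covariate profile", {
  cohort <- sim_dtsm_cohort(500, 6, qlogis(0.1), 0.5, seed = 12)
  pp <- expand_person_period(cohort, J_max = 6)
  fit <- fit_dtsm(pp, covariates = "x")
  base <- predict_curve(fit)                       # all-zero profile
  expect_equal(base$logit,
               unname(fit$coefficients[paste0("period_", 1:6)]))
  shifted <- predict_curve(fit, c(x = 2))
  expect_equal(shifted$logit - base$logit,
               rep(2 * fit$coefficients[["x"]], 6))
  expect_true(all(diff(base$survival) <= 0))
  expect_error(predict_curve(fit, c(zz = 1)), "missing covariate")
})

test_that("predicted survival tracks the empirical survivor proportions", {
  cohort <- sim_dtsm_cohort(4000, 8, qlogis(0.12), 0.5, seed = 30)
  pp <- expand_person_period(cohort, J_max = 8)
  fit <- fit_dtsm(pp, covariates = "x")
  # model-implied marginal survival, averaged over the sampled profiles
  S_model <- rowMeans(sapply(cohort$x, function(v)
    predict_curve(fit, c(x = v))$survival))
  lt <- risk_set_counts(pp)
  S_emp <- cumprod(1 - lt$hazard)
  expect_lt(max(abs(S_model - S_emp)), 0.01)
})

test_that("degenerate designs are rejected with diagnostics", {
  cohort <- sim_dtsm_cohort(100, 4, qlogis(0.2), 0.3, seed = 2)
  cohort$x_dup <- cohort$x * 2
  pp <- expand_person_period(cohort, J_max = 4)
  expect_error(fit_dtsm(pp, covariates = c("x", "x_dup")),
               "rank deficient.*x_dup")
  expect_error(fit_dtsm(pp, covariates = "nope"), "nope")
  no_events <- expand_person_period(
    tibble::tibble(id = 1:5, time = 3L, event = 0L), J_max = 3)
  expect_error(fit_dtsm(no_events), "degenerate")
  # perfectly separating covariate -> explicit failure
  sep <- dplyr::mutate(pp, s = as.numeric(u))
  expect_error(fit_dtsm(sep, covariates = "s"), "converge|separation")
})

test_that("the proportionality LR statistic is nonnegative with the right df", {
  cohort <- sim_dtsm_cohort(600, 6, qlogis(0.15), 0.4, seed = 19)
  pp <- expand_person_period(cohort, J_max = 6)
  out <- test_proportionality(pp, covariates = "x", covariate = "x")
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 5L)       # six period-specific coefficients vs one
  expect_equal(out$statistic,
               2 * (out$loglik_free - out$loglik_constrained),
               tolerance = 1e-10)
  expect_error(test_proportionality(pp, covariates = "x", covariate = "y"),
               "covariate")
})
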