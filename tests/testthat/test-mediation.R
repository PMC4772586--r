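# Two-equation coefficient fixture used below
toy_coefs <- function(a = 2, b = 3, direct = 1,
                      se_a = 0.1, se_b = 0.2, se_d = 0.3) {
  tibble::tibble(
    equation = c("m", "hazard", "hazard"),
    term = c("xx", "m", "xx"),
    estimate = c(a, b, direct),
    std.error = c(se_a, se_b, se_d))
}

test_that("products of published coefficients reproduce the example's indirect effects", {
  ct <- colon_coefficients()
  expect_equal(indirect_effect(c("affluence", "emergency", "hazard"), ct),
               -0.302 * 0.411)
  expect_equal(round(indirect_effect(c("affluence", "emergency", "hazard"), ct), 3),
               -0.124)
  expect_equal(
    indirect_effect(c("affluence", "emergency", "caseload", "hazard"), ct),
    -0.302 * -0.063 * -0.173)
  expect_equal(round(
    indirect_effect(c("affluence", "emergency", "caseload", "hazard"), ct), 3),
    -0.003)
  ct0 <- dplyr::mutate(ct, estimate = ifelse(term == "emergency" &
                                               equation == "hazard", 0, estimate))
  expect_equal(indirect_effect(c("affluence", "emergency", "hazard"), ct0), 0)
  expect_error(indirect_effect(c("affluence", "nope", "hazard"), ct), "no fitted")
})

test_that("delta-method standard errors match the closed form and the example", {
  ct <- colon_coefficients()
  expect_equal(delta_se(c("affluence", "emergency", "hazard"), ct),
               sqrt(0.411^2 * 0.062^2 + 0.302^2 * 0.084^2))
  expect_equal(round(delta_se(c("affluence", "emergency", "hazard"), ct), 3),
               0.036)
  expect_equal(round(delta_se(c("affluence", "caseload", "hazard"), ct), 3),
               0.043)
  # random two-edge products against the closed form
  set.seed(9)
  for (i in 1:10) {
    tc <- toy_coefs(rnorm(1), rnorm(1), se_a = runif(1), se_b = runif(1))
    expect_equal(delta_se(c("xx", "m", "hazard"), tc),
                 sqrt(tc$estimate[2]^2 * tc$std.error[1]^2 +
                        tc$estimate[1]^2 * tc$std.error[2]^2))
  }
  zero_se <- toy_coefs(se_a = 0, se_b = 0, se_d = 0)
  expect_equal(delta_se(c("xx", "m", "hazard"), zero_se), 0)
})

test_that("decomposition is additive for arbitrary coefficient sets", {
  spec <- colon_path_spec()
  set.seed(41)
  for (i in 1:15) {
    ct <- colon_coefficients()
    ct$estimate <- rnorm(nrow(ct))
    ct$std.error <- runif(nrow(ct), 0.01, 0.3)
    dec <- decompose(ct, spec = spec)
    expect_equal(dec$estimate[dec$effect == "total_effect"],
                 dec$estimate[dec$effect == "direct"] +
                   sum(dec$estimate[dec$effect == "indirect"]))
    expect_equal(sum(dec$estimate[dec$effect == "indirect"]),
                 dec$estimate[dec$effect == "total_indirect"])
  }
})

test_that("degenerate decompositions are flagged", {
  # no indirect path: total effect = direct, proportion 0
  spec <- path_model_spec(
    exposure = "xx",
    equations = list(
      path_equation("m", "z"),
      path_equation("hazard", c("xx", "m"), link = "discrete_time_logit")))
  ct <- tibble::tibble(equation = c("m", "hazard", "hazard"),
                       term = c("z", "xx", "m"),
                       estimate = c(0.5, -0.4, 0.2),
                       std.error = c(0.1, 0.1, 0.1))
  dec <- decompose(ct, spec = spec)
  expect_equal(dec$estimate[dec$effect == "total_effect"], -0.4)
  expect_equal(attr(dec, "mediation_proportion"), 0)

  # exactly offsetting direct and indirect -> undefined proportion
  tc <- toy_coefs(a = 2, b = 3, direct = -6)
  expect_true(is.na(attr(decompose(tc, spec = toy_path_spec()),
                         "mediation_proportion")))
  # opposite signs -> inconsistent-mediation flag
  tc2 <- toy_coefs(a = 2, b = 3, direct = -20)
  expect_true(attr(decompose(tc2, spec = toy_path_spec()),
                   "inconsistent_mediation"))
})

test_that("within-equation covariance terms enter only when requested", {
  tc <- toy_coefs()
  # both hazard-equation coefficients appear in the total-effect gradient
  Vb <- matrix(c(0.2^2, 0.05, 0.05, 0.3^2), 2, 2,
               dimnames = list(c("m", "xx"), c("m", "xx")))
  blocks <- list(m = matrix(0.1^2, 1, 1, dimnames = list("xx", "xx")),
                 hazard = Vb)
  d0 <- decompose(tc, spec = toy_path_spec())
  d1 <- decompose(tc, spec = toy_path_spec(), within_equation = TRUE,
                  vcov = blocks)
  v0 <- d0$std.error[d0$effect == "total_effect"]^2
  v1 <- d1$std.error[d1$effect == "total_effect"]^2
  # gradient is (b, a, 1) = (3, 2, 1); the cross term adds 2 * a * 1 * cov
  expect_equal(v1 - v0, 2 * 2 * 1 * 0.05)
  # single-path SEs are unchanged: edges live in different equations
  expect_equal(d0$std.error[d0$effect == "indirect"],
               d1$std.error[d1$effect == "indirect"])
})

test_that("total effect agrees with a refit that omits the mediators", {
  cohort <- sim_toy_mediation(8000, seed = 14)
  dec <- decompose(fit_path_system(cohort, toy_path_spec()))
  pp <- expand_person_period(cohort, J_max = 8)
  marginal <- fit_dtsm(pp, covariates = "xx", baseline = "constant")
  te <- dec$estimate[dec$effect == "total_effect"]
  expect_lt(abs(te - marginal$coefficients[["xx"]]),
            2 * dec$std.error[dec$effect == "total_effect"])
})

test_that("a spec with no mediator equations reduces to the hazard fit", {
  cohort <- sim_toy_mediation(1500, seed = 6)
  spec <- path_model_spec(
    exposure = "xx",
    equations = list(path_equation("hazard", c("xx", "m"),
                                   link = "discrete_time_logit")),
    J_max = 8, baseline = "constant")
  fit <- fit_path_system(cohort, spec)
  pp <- expand_person_period(cohort, J_max = 8)
  alone <- fit_dtsm(pp, covariates = c("xx", "m"), baseline = "constant")
  expect_equal(fit$coefficients$estimate,
               unname(alone$coefficients[fit$coefficients$term]))
  expect_equal(fit$dtsm$loglik, alone$loglik)
})

test_that("least-squares equations equal the normal-equations solution", {
  df <- tibble::tibble(id = 1:4, time = rep(2L, 4), event = c(1L, 0L, 1L, 0L),
                       xx = c(0, 1, 2, 3), m = c(0.1, 0.9, 1.8, 3.3))
  fit <- fit_path_system(df, toy_path_spec(J_max = 2))
  X <- cbind(1, df$xx)
  beta_hat <- solve(t(X) %*% X, t(X) %*% df$m)
  est <- fit$coefficients[fit$coefficients$equation == "m", ]
  expect_equal(est$estimate, drop(beta_hat), tolerance = 1e-10)
})

test_that("latent-response standardization conventions behave as documented", {
  cohort <- sim_toy_mediation(2000, seed = 23)
  fit <- fit_path_system(cohort, toy_path_spec())
  raw <- standardize_latent(fit, "raw")
  expect_equal(raw$std_estimate, raw$estimate)        # identity convention
  ys <- standardize_latent(fit, "ystar")
  scale <- attr(ys, "scale")
  expect_gt(scale, sqrt(pi^2 / 3) - 1e-12)
  expect_equal(ys$std_estimate, ys$estimate / scale)
  # rescaling a covariate by c divides its per-unit effect by c,
  # leaving the per-SD effect unchanged
  cohort2 <- dplyr::mutate(cohort, xx = xx * 4)
  fit2 <- fit_path_system(cohort2, toy_path_spec())
  ys2 <- standardize_latent(fit2, "ystar")
  k1 <- ys$std_estimate[ys$term == "xx"]
  k2 <- ys2$std_estimate[ys2$term == "xx"]
  expect_equal(k2, k1 / 4, tolerance = 1e-6)
  expect_equal(k2 * sd(cohort2$xx), k1 * sd(cohort$xx), tolerance = 1e-6)
})

test_that("the bootstrap is reproducible and tracks the delta-method SE", {
  cohort <- sim_toy_mediation(1000, seed = 31)
  spec <- toy_path_spec()
  expect_error(bootstrap_indirect(cohort, spec, B = 10), "at least 100")
  b1 <- bootstrap_indirect(cohort, spec, B = 120, seed = 99)
  b2 <- bootstrap_indirect(cohort, spec, B = 120, seed = 99)
  expect_identical(b1, b2)
  dec <- decompose(fit_path_system(cohort, spec))
  idx <- which(dec$effect == "indirect")
  expect_lt(max(abs(b1$boot_se[idx] / dec$std.error[idx] - 1)), 0.25)
})
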