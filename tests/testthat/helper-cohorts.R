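# Shared fixtures, built in code.

toy_cohort <- function() {
  tibble::tibble(
    id = 1:6,
    time = c(3L, 2L, 5L, 1L, 4L, 4L),
    event = c(1L, 0L, 1L, 1L, 0L, 1L),
    x = c(0.2, -1.0, 0.5, 1.2, -0.3, 0.0))
}

# Single-covariate discrete-time cohort drawn directly from the hazard walk;
# kappa may vary by period (for proportionality scenarios).
sim_dtsm_cohort <- function(n, J, beta0, kappa, seed) {
  set.seed(seed)
  kappa <- rep_len(kappa, J)
  beta0 <- rep_len(beta0, J)
  x <- rnorm(n)
  h <- plogis(matrix(beta0, n, J, byrow = TRUE) + outer(x, kappa))
  ev <- matrix(rbinom(n * J, 1, h), n, J)
  first <- apply(ev == 1, 1, function(z) if (any(z)) which.max(z) else NA_integer_)
  tibble::tibble(
    id = seq_len(n),
    time = as.integer(ifelse(is.na(first), J, first)),
    event = as.integer(!is.na(first)),
    x = x)
}

# Continuous-time exponential-hazard cohort; discretized on demand.
sim_continuous_cohort <- function(n, lambda0, beta, horizon, seed) {
  set.seed(seed)
  x <- rnorm(n)
  t_event <- stats::rexp(n, rate = lambda0 * exp(beta * x))
  tibble::tibble(id = seq_len(n), t = pmin(t_event, horizon),
                 event = as.integer(t_event <= horizon), x = x)
}

discretize_cohort <- function(cont, width, horizon) {
  J <- horizon / width
  tibble::tibble(
    id = cont$id,
    time = as.integer(pmin(ceiling(cont$t / width), J)),
    event = cont$event,
    x = cont$x)
}

# A small three-variable linear-system spec for mediation tests.
toy_path_spec <- function(J_max = 8, baseline = "constant") {
  path_model_spec(
    exposure = "xx",
    equations = list(
      path_equation("m", c("xx")),
      path_equation("hazard", c("xx", "m"), link = "discrete_time_logit")),
    J_max = J_max, baseline = baseline)
}

sim_toy_mediation <- function(n, J = 8, a = 0.3, b = 0.8, direct = 0.5,
                              beta0 = qlogis(0.08), seed = 1) {
  set.seed(seed)
  xx <- runif(n)
  m <- rbinom(n, 1, pmin(pmax(0.2 + a * xx, 0), 1))
  h <- plogis(beta0 + direct * xx + b * m)
  ev <- matrix(rbinom(n * J, 1, h), n, J)
  first <- apply(ev == 1, 1, function(z) if (any(z)) which.max(z) else NA_integer_)
  tibble::tibble(
    id = seq_len(n),
    time = as.integer(ifelse(is.na(first), J, first)),
    event = as.integer(!is.na(first)),
    xx = xx, m = m)
}
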