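#' Expand subject-level survival records into person-period form
#'
#' Restructures one-row-per-subject discrete time-to-event data into the
#' person-period layout on which the discrete-time hazard likelihood is
#' defined: one row per subject per at-risk period, with a binary event
#' indicator `u`. A subject contributes rows for periods `1..min(time, J_max)`
#' and nothing afterwards — periods after the event (or after censoring) are
#' missing by construction, which is how the discrete-time model treats them.
#'
#' Subjects whose event falls beyond `J_max` are recoded as censored at
#' `J_max` (all `u = 0`), i.e. follow-up is administratively truncated.
#' Censored subjects are taken to be at risk for the whole of their final
#' period, so their last row is retained with `u = 0`.
#'
#' @param data A data frame with one row per subject: an `id` column, a
#'   positive integer `time` column (period of event or censoring, 1-based),
#'   a binary `event` column (1 = event in period `time`, 0 = censored at the
#'   end of period `time`), and any number of time-invariant covariate
#'   columns.
#' @param J_max Maximum number of periods retained; events after `J_max` are
#'   treated as censoring at `J_max`.
#' @param time_varying Optional long-format data frame of time-varying
#'   covariates with columns `id`, `period`, and one column per covariate.
#'   Every subject must supply values for all periods up to their `time`.
#' @param id,time,event Column names in `data` (tidyverse-style defaults).
#' @param na_action How to treat subjects with missing covariate values:
#'   `"complete"` (default) drops them with a message recording the count;
#'   `"modal"` imputes the modal category (or median for continuous
#'   covariates) per column.
#'
#' @return A tibble of class `person_period` with columns `id`, `period`,
#'   `u`, then covariates; attributes `J_max`, `n_subjects` and `n_dropped`.
#' @examples
#' cohort <- tibble::tibble(id = 1:3, time = c(3, 2, 30),
#'                          event = c(1, 0, 1), x = c(0.2, -1, 0.5))
#' expand_person_period(cohort, J_max = 24)
#' @export
expand_person_period <- function(data, J_max, time_varying = NULL,
                                 id = "id", time = "time", event = "event",
                                 na_action = c("complete", "modal")) {
  na_action <- match.arg(na_action)
  data <- tibble::as_tibble(data)
  need <- c(id, time, event)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(J_max) || length(J_max) != 1 || J_max < 1 || J_max != floor(J_max)) {
    abort("`J_max` must be a positive integer scalar.")
  }
  tt <- data[[time]]
  ev <- data[[event]]
  if (any(!is.finite(tt)) || any(tt < 1) || any(tt != floor(tt))) {
    bad <- data[[id]][!is.finite(tt) | tt < 1 | tt != floor(tt)]
    abort(paste0("`time` must be a positive integer; offending subject(s): ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  if (!all(ev %in% c(0, 1))) {
    abort("`event` must be coded 0 (censored) / 1 (event).")
  }

  covars <- setdiff(names(data), need)
  n_dropped <- 0L
  if (length(covars) > 0 && anyNA(data[covars])) {
    if (na_action == "complete") {
      keep <- complete.cases(data[covars])
      n_dropped <- sum(!keep)
      inform(paste0("Dropped ", n_dropped,
                    " subject(s) with missing covariate values (complete-case)."))
      data <- data[keep, , drop = FALSE]
      tt <- data[[time]]
      ev <- data[[event]]
    } else {
      data[covars] <- lapply(data[covars], impute_modal)
    }
  }
  if (nrow(data) == 0) abort("No subjects left after missing-data handling.")

  # administrative truncation: events beyond J_max become censoring at J_max
  t_obs <- pmin(tt, J_max)
  u_last <- as.integer(ev == 1 & tt <= J_max)

  idx <- rep.int(seq_len(nrow(data)), t_obs)
  period <- sequence(t_obs)
  u <- integer(length(idx))
  u[cumsum(t_obs)] <- u_last

  pp <- tibble::tibble(id = data[[id]][idx], period = period, u = u)
  if (length(covars) > 0) pp <- dplyr::bind_cols(pp, data[idx, covars, drop = FALSE])

  if (!is.null(time_varying)) {
    time_varying <- tibble::as_tibble(time_varying)
    if (!all(c("id", "period") %in% names(time_varying))) {
      abort("`time_varying` must have `id` and `period` columns.")
    }
    tv_cols <- setdiff(names(time_varying), c("id", "period"))
    merged <- dplyr::left_join(pp, time_varying, by = c("id", "period"))
    if (anyNA(merged[tv_cols])) {
      bad <- unique(merged$id[!complete.cases(merged[tv_cols])])
      abort(paste0("time-varying covariates shorter than observed follow-up for subject(s): ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    pp <- merged
  }

  structure(pp,
            J_max = as.integer(J_max),
            n_subjects = nrow(data),
            n_dropped = n_dropped,
            class = c("person_period", class(pp)))
}

impute_modal <- function(x) {
  if (!anyNA(x)) return(x)
  if (is.numeric(x) && length(unique(stats::na.omit(x))) > 10) {
    x[is.na(x)] <- stats::median(x, na.rm = TRUE)
  } else {
    tab <- table(x)
    mode_val <- names(tab)[which.max(tab)]
    if (is.numeric(x)) mode_val <- as.numeric(mode_val)
    x[is.na(x)] <- mode_val
  }
  x
}

#' Per-period risk sets, event counts and life-table hazards
#'
#' Tallies, for each period, the number of subjects still at risk and the
#' number experiencing the event, and forms the life-table hazard estimate
#' `events / at_risk`. For an unstructured baseline with no covariates the
#' fitted model reproduces these hazards exactly (the model is saturated).
#'
#' @param table A `person_period` tibble from [expand_person_period()].
#' @return A tibble with columns `period`, `at_risk`, `events`, `hazard`
#'   (`NA` for empty periods).
#' @export
risk_set_counts <- function(table) {
  stopifnot(inherits(table, "person_period"))
  J <- attr(table, "J_max")
  out <- table %>%
    dplyr::group_by(period = .data$period) %>%
    dplyr::summarise(at_risk = dplyr::n(), events = sum(.data$u), .groups = "drop")
  out <- tidyr::complete(out, period = seq_len(J),
                         fill = list(at_risk = 0L, events = 0L))
  dplyr::mutate(out, hazard = ifelse(.data$at_risk > 0,
                                     .data$events / .data$at_risk, NA_real_))
}
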