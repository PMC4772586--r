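#' Specify a recursive path model with a discrete-time survival outcome
#'
#' Describes the equation system: an ordered set of linear-probability (or
#' linear) equations for the mediators, terminated by a single equation with
#' the `discrete_time_logit` link for the survival outcome. The implied
#' directed graph must be acyclic and the outcome terminal; exposure effects
#' then decompose into a direct path plus products of coefficients along
#' every exposure-to-outcome chain.
#'
#' @param exposure Name of the exposure variable (must be exogenous).
#' @param equations List of equations from [path_equation()], exactly one of
#'   which has link `"discrete_time_logit"`.
#' @param time,event Column names holding the event/censoring period and the
#'   event indicator in subject-level data.
#' @param J_max Number of discrete periods retained (administrative
#'   truncation).
#' @param baseline,proportional Passed to [fit_dtsm()] for the outcome
#'   equation.
#' @return A validated object of class `path_model_spec`.
#' @examples
#' spec <- path_model_spec(
#'   exposure = "affluence",
#'   equations = list(
#'     path_equation("emergency", c("affluence", "age10")),
#'     path_equation("caseload", c("affluence", "age10", "emergency")),
#'     path_equation("hazard",
#'                   c("affluence", "age10", "emergency", "caseload"),
#'                   link = "discrete_time_logit")),
#'   J_max = 24)
#' enumerate_paths(spec)
#' @export
path_model_spec <- function(exposure, equations, time = "time",
                            event = "event", J_max = 24,
                            baseline = "unstructured", proportional = TRUE) {
  spec <- structure(list(exposure = exposure, equations = equations,
                         time = time, event = event, J_max = J_max,
                         baseline = baseline, proportional = proportional),
                    class = "path_model_spec")
  validate_path_spec(spec)
}

#' Declare one equation of a path model
#'
#' @param dependent Name of the dependent variable.
#' @param regressors Character vector of regressor names.
#' @param link `"linear"` (least squares; for binary dependents this is the
#'   linear probability model) or `"discrete_time_logit"` (the survival
#'   outcome equation).
#' @export
path_equation <- function(dependent, regressors,
                          link = c("linear", "discrete_time_logit")) {
  link <- match.arg(link)
  stopifnot(is.character(dependent), length(dependent) == 1,
            is.character(regressors), length(regressors) >= 1)
  list(dependent = dependent, regressors = regressors, link = link)
}

#' Validate a path model specification
#'
#' Checks that exactly one equation carries the survival link and is
#' terminal, that no equation is a self-loop, and that the directed graph of
#' the system is acyclic; equations are re-ordered topologically if needed so
#' that every regressor is exogenous or the dependent of an earlier equation.
#'
#' @param spec A `path_model_spec` (or a bare list with the same fields).
#' @return The checked (possibly re-ordered) `path_model_spec`.
#' @export
validate_path_spec <- function(spec) {
  eqs <- spec$equations
  deps <- vapply(eqs, `[[`, character(1), "dependent")
  links <- vapply(eqs, `[[`, character(1), "link")
  if (anyDuplicated(deps)) {
    abort(paste0("duplicate equation for: ", deps[duplicated(deps)][1]))
  }
  n_surv <- sum(links == "discrete_time_logit")
  if (n_surv != 1) {
    abort("exactly one equation must have link \"discrete_time_logit\".")
  }
  outcome <- deps[links == "discrete_time_logit"]
  for (eq in eqs) {
    if (eq$dependent %in% eq$regressors) {
      abort(paste0("self-loop: ", eq$dependent, " regressed on itself."))
    }
    if (outcome %in% eq$regressors) {
      abort(paste0("the survival outcome (", outcome,
                   ") cannot appear as a regressor (in the equation for ",
                   eq$dependent, ")."))
    }
  }

  # cycle check on endogenous dependencies, naming any cycle found
  edges <- lapply(eqs, function(eq) intersect(eq$regressors, deps))
  names(edges) <- deps
  state <- setNames(rep(0L, length(deps)), deps)   # 0 unseen, 1 active, 2 done
  order <- character()
  visit <- function(v, trail) {
    if (state[[v]] == 1L) {
      cycle <- c(trail[which(trail == v):length(trail)], v)
      abort(paste0("cyclic dependency: ", paste(cycle, collapse = " -> ")))
    }
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in edges[[v]]) visit(w, c(trail, v))
    state[[v]] <<- 2L
    order <<- c(order, v)
  }
  for (v in deps) visit(v, character())
  spec$equations <- eqs[match(order, deps)]
  spec$outcome <- outcome
  if (!is.null(spec$exposure) && spec$exposure %in% deps) {
    abort("the exposure must be exogenous (it has its own equation).")
  }
  spec
}

#' Enumerate indirect exposure-to-outcome paths
#'
#' Lists every directed chain from the exposure to the survival outcome that
#' passes through at least one mediator, each exactly once, ordered by length
#' (shorter first) and then lexicographically.
#'
#' @param spec A validated `path_model_spec`.
#' @return A list of character vectors, each a chain
#'   `c(exposure, mediators..., outcome)`.
#' @export
enumerate_paths <- function(spec) {
  spec <- validate_path_spec(spec)
  deps <- vapply(spec$equations, `[[`, character(1), "dependent")
  all_regs <- unique(unlist(lapply(spec$equations, `[[`, "regressors")))
  if (!spec$exposure %in% all_regs) {
    abort(paste0("exposure \"", spec$exposure, "\" does not appear in any equation."))
  }
  children <- function(v) {
    deps[vapply(spec$equations, function(eq) v %in% eq$regressors, logical(1))]
  }
  paths <- list()
  walk <- function(v, chain) {
    for (w in children(v)) {
      if (w == spec$outcome) {
        if (length(chain) >= 2) paths[[length(paths) + 1L]] <<- c(chain, w)
      } else {
        walk(w, c(chain, w))
      }
    }
  }
  walk(spec$exposure, spec$exposure)
  if (length(paths) == 0) return(list())
  key <- vapply(paths, function(p) paste(p, collapse = " -> "), character(1))
  paths[order(lengths(paths), key)]
}

#' Read a path model specification from a YAML config file
#'
#' The config mirrors [path_model_spec()]: top-level `exposure`, an
#' `outcome` block (`time`, `event`, `J_max`, `baseline`, `proportional`),
#' and an `equations` list of `{dependent, regressors, link}` entries.
#'
#' @param path Path to a YAML file.
#' @return A validated `path_model_spec`.
#' @export
read_path_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$exposure) || is.null(cfg$equations)) {
    abort("config must define `exposure` and `equations`.")
  }
  out <- cfg$outcome %||% list()
  eqs <- lapply(cfg$equations, function(e) {
    path_equation(e$dependent, unlist(e$regressors), e$link %||% "linear")
  })
  path_model_spec(
    exposure = cfg$exposure, equations = eqs,
    time = out$time %||% "time", event = out$event %||% "event",
    J_max = out$J_max %||% 24, baseline = out$baseline %||% "unstructured",
    proportional = out$proportional %||% TRUE)
}
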