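#' Hazard probability from a logit
#'
#' Inverse-logit link relating the linear predictor of the discrete-time
#' model to the per-period hazard probability, `h = 1 / (1 + exp(-logit))`.
#'
#' @param logit Numeric vector of log-odds.
#' @return Probabilities in (0, 1), strictly increasing in `logit`.
#' @export
hazard_from_logit <- function(logit) {
  stopifnot(is.numeric(logit))
  plogis(logit)
}

#' Survival probabilities from a discrete hazard sequence
#'
#' The discrete-time survivor function is the cumulative product of the
#' per-period continuation probabilities: `S_j = prod_{k<=j} (1 - h_k)`.
#'
#' @param h Numeric vector of per-period hazard probabilities in \[0, 1\].
#' @return Numeric vector of the same length: survival through each period.
#' @examples
#' survival_from_hazard(c(0.5, 0.5)) # 0.50 0.25
#' @export
survival_from_hazard <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h < 0 | h > 1)) {
    abort("`h` must be hazard probabilities in [0, 1].")
  }
  cumprod(1 - h)
}
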