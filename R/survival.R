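# Exponential survival as a function of time-to-care. A single rate
# parameter lambda (per minute) captures how quickly the chance of
# surviving an emergency decays while the patient is still travelling.

#' Survival probability under delayed care
#'
#' `S(t) = exp(-lambda * t)`: the probability of surviving when care is
#' reached after `t` minutes. `t = Inf` (unreachable) gives 0.
#'
#' @param lam Rate parameter, per minute; > 0.
#' @param t Time to care in minutes; >= 0, may be `Inf`.
#' @return Probability in (0, 1\]. Vectorised.
#' @examples
#' survival_prob(0.056, c(0, 30, 60))
#' @export
survival_prob <- function(lam, t) {
  stopifnot(all(lam > 0))
  if (any(t < 0)) stop("negative time to care")
  exp(-lam * t)
}

#' Draw the survival rate parameter
#'
#' lambda is uncertain; it is drawn from a Normal(lambda_mean, lambda_sd)
#' truncated to positive values by rejection (clipping would put an atom
#' at zero and distort the shape). Warns when the untruncated normal puts
#' more than half its mass below zero, which signals a misconfigured sd.
#'
#' @param lambda_mean Mean rate per minute (default 0.056, an elicited
#'   value for severe postpartum haemorrhage).
#' @param lambda_sd Standard deviation (default 0.01; `0` makes the draw
#'   degenerate at the mean).
#' @param n Number of draws.
#' @return Positive rate draws, per minute.
#' @export
sample_lambda <- function(lambda_mean = 0.056, lambda_sd = 0.01, n = 1) {
  stopifnot(lambda_mean > 0, lambda_sd >= 0)
  if (lambda_sd == 0) return(rep(lambda_mean, n))
  if (stats::pnorm(0, lambda_mean, lambda_sd) > 0.25)
    warning("a large share of the lambda distribution's mass is below zero ",
            "and will be rejected; check survival.lambda_sd")
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n, lambda_mean, lambda_sd)
    out <- c(out, draw[draw > 0])
  }
  out[seq_len(n)]
}
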