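# Transfer-time rules. Without an ambulance the journey takes t + tau
# (travel plus waiting delay). With the service, the ambulance makes a
# round trip from its facility hub: 2*s*t, with s the ambulance speed
# multiplier. Which time applies with the service available depends on
# the patient's choice rule.

#' Transfer-choice scenario
#'
#' How patients choose between the ambulance and informal transport once
#' the service exists: `"fastest"` takes whichever is quicker (perfect
#' knowledge; an upper bound on benefit), `"ambulance"` always takes the
#' ambulance (even when slower), `"random"` takes the ambulance with
#' probability `random_weight`, implemented as the expectation (mixture)
#' since cells carry expected fractional cases.
#'
#' @param choice_rule One of `"fastest"`, `"ambulance"`, `"random"`.
#' @param random_weight Probability of choosing the ambulance under
#'   `"random"` (default 0.5).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(choice_rule = c("fastest", "ambulance", "random"),
                          random_weight = 0.5) {
  choice_rule <- match.arg(choice_rule)
  stopifnot(random_weight >= 0, random_weight <= 1)
  structure(list(choice_rule = choice_rule, random_weight = random_weight),
            class = "scenario_spec")
}

#' Ambulance transfer time
#'
#' Round trip from a facility-based hub at speed multiplier `s`:
#' `2 * s * t` minutes (call-out delay assumed zero; `theta` adds a fixed
#' call-out delay, beyond the default model).
#'
#' @param t One-way travel time (minutes); >= 0.
#' @param s Speed multiplier in (0, 1]; `s = 0.6` means the ambulance cuts
#'   one-way travel time by 40%.
#' @param theta Fixed call-out delay (minutes), default 0.
#' @return Minutes. Vectorised.
#' @export
t_ambulance <- function(t, s, theta = 0) {
  stopifnot(all(t >= 0), all(s > 0), all(s <= 1), theta >= 0)
  2 * s * t + theta
}

#' Informal-transport transfer time
#'
#' Travel time plus the waiting delay spent locating a vehicle:
#' `t + tau`.
#'
#' @param t One-way travel time (minutes); >= 0.
#' @param tau Waiting delay (minutes); >= 0.
#' @return Minutes. Vectorised.
#' @export
t_informal <- function(t, tau) {
  stopifnot(all(t >= 0), all(tau >= 0))
  t + tau
}

#' Per-cell survival with and without the ambulance service
#'
#' Baseline survival is `S0 = S(t + tau)`. With the service, `S1` follows
#' the choice rule: `fastest` gives `S(min(t + tau, 2st))`, `ambulance`
#' gives `S(2st)`, `random` the `w`-mixture of the two. Under `fastest`,
#' `S1 >= S0` always; under `ambulance` the service can cost lives when
#' the round trip exceeds the informal journey.
#'
#' @param t One-way travel time (minutes); may be `Inf` (both survival
#'   probabilities 0).
#' @param tau Waiting delay (minutes).
#' @param s Speed multiplier in (0, 1].
#' @param lam Survival rate parameter (per minute).
#' @param scenario A [scenario_spec()].
#' @param theta Ambulance call-out delay (minutes), default 0.
#' @return A list with numeric components `S0` and `S1`, vectorised over
#'   cells.
#' @export
cell_survival_pair <- function(t, tau, s, lam, scenario, theta = 0) {
  stopifnot(inherits(scenario, "scenario_spec"))
  t0 <- t_informal(t, tau)
  t1_amb <- t_ambulance(t, s, theta)
  S0 <- survival_prob(lam, t0)
  S_amb <- survival_prob(lam, t1_amb)
  S1 <- switch(scenario$choice_rule,
    fastest = pmax(S0, S_amb),        # S(min(a,b)) = max(S(a), S(b))
    ambulance = S_amb,
    random = scenario$random_weight * S_amb +
             (1 - scenario$random_weight) * S0)
  list(S0 = S0, S1 = S1)
}
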