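# Theory-of-Planned-Behaviour stock-flow dynamics, per agent.
#
# Intention is a stock fed by three flows — attitudes (moderated by
# education), norms (the BMI gap to the same-gender network neighbourhood,
# gated by the satisficing value) and perceived behavioural control (a
# default modified by past dieting success). A constant fraction of the
# Intention stock activates per month and, after an optional lag, feeds the
# Behaviour stock. Both stocks decay. Once Behaviour crosses its threshold
# and the agent perceives itself significantly overweight relative to its
# neighbourhood, it starts a diet of stochastic duration.

#' Behavioural (TPB) parameter set
#'
#' Flow gains, decays and the dieting state-machine parameters. The
#' `theta_norms` gain is split by gender and age group (a 2 x 6 matrix);
#' its defaults are the calibrated norm gains reported for the final model.
#' Decay rates, the behaviour threshold and the activation fraction are
#' structural free parameters with conservative defaults.
#'
#' @param theta_norms 2 x 6 matrix (male/female x age groups) of norms-flow
#'   gains, per month per BMI unit of gap.
#' @param theta_pbc global pbc-flow gain (per month).
#' @param theta_attitude global attitudes-flow gain (per month).
#' @param theta_sv satisficing scale; 1 reproduces the anchors sv(20)=0,
#'   sv(30)=1, sv(40)=4.
#' @param theta_lag activation lag, whole months >= 0.
#' @param theta_dietTime mean dieting duration in months (> 0).
#' @param intention_decay,behaviour_decay per-month fractional decay in
#'   \[0, 1).
#' @param behaviour_threshold Behaviour-stock level that triggers dieting.
#' @param pbc_default initial perceived-behavioural-control value.
#' @param diet_restriction fractional intake reduction while dieting, in
#'   (0, 1).
#' @param adherence_prob per-month probability of actually adhering to the
#'   restriction, in (0, 1].
#' @param activation_fraction fraction of the Intention stock activated per
#'   month.
#' @return list of class `obesnet_behaviour_params`.
#' @export
behaviour_params <- function(theta_norms = rbind(
                               male   = c(1.95, 1.87, 4.91, 2.99, 3.69, 1.52),
                               female = c(2.84, 3.85, 1.02, 4.99, 0.87, 3.725)
                             ),
                             theta_pbc = 0.1,
                             theta_attitude = 0.5,
                             theta_sv = 1,
                             theta_lag = 1L,
                             theta_dietTime = 3,
                             intention_decay = 0.1,
                             behaviour_decay = 0.1,
                             behaviour_threshold = 6,
                             pbc_default = 1,
                             diet_restriction = 0.1,
                             adherence_prob = 0.8,
                             activation_fraction = 0.25) {
  if (is.vector(theta_norms) && length(theta_norms) == 1) {
    theta_norms <- matrix(theta_norms, 2, 6)
  }
  dimnames(theta_norms) <- list(GENDERS, AGE_GROUPS)
  p <- list(theta_norms = theta_norms, theta_pbc = theta_pbc,
            theta_attitude = theta_attitude, theta_sv = theta_sv,
            theta_lag = as.integer(round(theta_lag)),
            theta_dietTime = theta_dietTime,
            intention_decay = intention_decay,
            behaviour_decay = behaviour_decay,
            behaviour_threshold = behaviour_threshold,
            pbc_default = pbc_default,
            diet_restriction = diet_restriction,
            adherence_prob = adherence_prob,
            activation_fraction = activation_fraction)
  class(p) <- "obesnet_behaviour_params"
  validate_behaviour_params(p)
  p
}

validate_behaviour_params <- function(p) {
  if (!is.matrix(p$theta_norms) || !identical(dim(p$theta_norms), c(2L, 6L))) {
    stopf("behaviour params: theta_norms must be a 2 x 6 matrix (gender x age group)")
  }
  if (p$intention_decay < 0 || p$intention_decay >= 1 ||
      p$behaviour_decay < 0 || p$behaviour_decay >= 1) {
    stopf("behaviour params: decays must lie in [0, 1)")
  }
  if (p$theta_lag < 0) stopf("behaviour params: theta_lag must be >= 0 months")
  if (p$theta_dietTime <= 0) stopf("behaviour params: theta_dietTime must be > 0")
  if (p$diet_restriction <= 0 || p$diet_restriction >= 1) {
    stopf("behaviour params: diet_restriction must lie in (0, 1)")
  }
  if (p$adherence_prob <= 0 || p$adherence_prob > 1) {
    stopf("behaviour params: adherence_prob must lie in (0, 1]")
  }
  if (p$activation_fraction < 0 || p$activation_fraction > 1) {
    stopf("behaviour params: activation_fraction must lie in [0, 1]")
  }
  invisible(p)
}

#' Satisficing value
#'
#' The minimum BMI gap an individual must perceive before their
#' neighbourhood influences them, growing quadratically with their own BMI:
#' `sv(b) = theta_sv * max(0, (b - 20) / 10)^2`. With the default scale 1
#' this gives sv(20) = 0, sv(30) = 1 and sv(40) = 4 — a person with BMI 40
#' does not recognise a BMI difference until it exceeds 4 units.
#'
#' @param bmi BMI value(s), > 0.
#' @param theta_sv scale coefficient.
#' @return non-negative threshold(s) in BMI units.
#' @export
#' @examples
#' satisficing_value(c(20, 30, 40))
satisficing_value <- function(bmi, theta_sv = 1) {
  if (any(bmi <= 0)) stopf("satisficing_value(): bmi must be > 0")
  theta_sv * pmax(0, (bmi - 20) / 10)^2
}

# Age-proximity weight for a neighbour's contribution to the norms flow:
# contributions are down-weighted with the age distance to the focal agent.
age_weight <- function(age_focal, age_neighbour) {
  1 / (1 + abs(age_focal - age_neighbour) / 10)
}

# Same-gender age-weighted neighbourhood mean BMI; NA when the agent has no
# same-gender neighbours.
neighbourhood_mean_bmi <- function(p_row, neighbours) {
  same <- neighbours[neighbours$gender == p_row$gender, , drop = FALSE]
  if (nrow(same) == 0) return(NA_real_)
  w <- age_weight(p_row$age, same$age)
  sum(w * bmi_of(same)) / sum(w)
}

#' Norms inflow
#'
#' The neighbourhood-driven flow into Intention. The agent compares its BMI
#' with the age-weighted mean BMI of its same-gender network neighbours;
#' the excess only flows once it exceeds the agent's satisficing value:
#' zero if `d <= sv(BMI)`, else `theta_norms[gender, agegroup] * d` where
#' `d = BMI - weighted neighbourhood mean`.
#'
#' @param p_row single-row agent data frame.
#' @param neighbours agent data frame of the agent's network neighbours.
#' @param params [behaviour_params()].
#' @return flow per month (>= 0).
#' @export
norms_inflow <- function(p_row, neighbours, params) {
  m <- neighbourhood_mean_bmi(p_row, neighbours)
  if (is.na(m)) return(0)
  b <- bmi_of(p_row)
  d <- b - m
  if (d <= satisficing_value(b, params$theta_sv)) return(0)
  g <- match(p_row$gender, GENDERS)
  a <- as.integer(age_group(p_row$age))
  params$theta_norms[g, a] * d
}

#' Attitudes inflow
#'
#' Cognitive drive toward dieting, moderated by education level and by how
#' overweight the agent is:
#' `theta_attitude * (education / 5) * min(1, max(0, BMI - 25) / 5)`.
#'
#' @param p_row single-row agent data frame (education in 1..5).
#' @param params [behaviour_params()].
#' @return flow per month (>= 0).
#' @export
attitudes_inflow <- function(p_row, params) {
  if (any(!p_row$education %in% 1:5)) {
    stopf("attitudes_inflow(): education must be an integer in 1..5")
  }
  overweight <- pmin(1, pmax(0, bmi_of(p_row) - 25) / 5)
  params$theta_attitude * (p_row$education / 5) * overweight
}

# Perceived behavioural control: a default value modified by the agent's
# accumulated dieting success (net kg lost across completed diets), bounded
# by a tanh transform so the modifier stays in (0, 2).
pbc_value <- function(success_score, pbc_default) {
  pbc_default * (1 + tanh(success_score / 5))
}

#' Perceived-behavioural-control inflow
#'
#' `theta_pbc * pbc_default * (1 + tanh(success_score / 5))`: neutral
#' history gives the default flow, sustained success can at most double it
#' and sustained failure drives it to zero.
#'
#' @param p_row single-row agent data frame.
#' @param params [behaviour_params()].
#' @return flow per month (>= 0).
#' @export
pbc_inflow <- function(p_row, params) {
  params$theta_pbc * pbc_value(p_row$success_score, params$pbc_default)
}

#' Advance the Intention/Behaviour stocks one month
#'
#' Discrete (Euler, dt = 1 month) update: the Intention stock decays, takes
#' the three inflows and emits `activation_fraction * intention` into a lag
#' buffer of length `theta_lag`; the Behaviour stock decays and receives the
#' buffer output from `theta_lag` months ago. Both stocks are floored at 0.
#'
#' @param s stock state: list with `intention`, `behaviour` and
#'   `activation_buffer` (numeric vector of length `theta_lag`).
#' @param inflows numeric: total inflow into Intention this month (sum of
#'   attitudes, norms, pbc).
#' @param params [behaviour_params()].
#' @return updated stock state.
#' @export
update_stocks <- function(s, inflows, params) {
  act_out <- params$activation_fraction * s$intention
  lag <- params$theta_lag
  if (lag == 0) {
    arrival <- act_out
    buffer <- numeric(0)
  } else {
    buffer <- s$activation_buffer
    if (length(buffer) != lag) {
      stopf("update_stocks(): activation buffer must have length theta_lag = %d", lag)
    }
    arrival <- buffer[1]
    buffer <- c(buffer[-1], act_out)
  }
  list(
    intention = max(0, s$intention * (1 - params$intention_decay) +
                      sum(inflows) - act_out),
    behaviour = max(0, s$behaviour * (1 - params$behaviour_decay) + arrival),
    activation_buffer = buffer
  )
}

#' Initial stock state
#'
#' @param params [behaviour_params()].
#' @param intention,behaviour starting levels.
#' @return stock-state list for [update_stocks()].
#' @export
init_stocks <- function(params, intention = 0, behaviour = 0) {
  list(intention = intention, behaviour = behaviour,
       activation_buffer = numeric(params$theta_lag))
}

# Diet duration draw: geometric with mean theta_dietTime modified by the
# success history, minimum 1 month.
draw_diet_duration <- function(theta_dietTime, success_score) {
  m <- max(1, theta_dietTime * (1 + tanh(success_score / 5)))
  1L + rgeom(length(m), prob = 1 / m)
}

#' Dieting-state transition
#'
#' An agent in the NORMAL state starts dieting when its Behaviour stock has
#' reached the threshold AND it perceives itself significantly overweight
#' relative to its immediate contacts: the gap between its BMI and the
#' same-gender age-weighted neighbourhood mean must exceed its satisficing
#' value. On transition the dieting duration is drawn from a geometric
#' distribution (mean `theta_dietTime`, modified by dieting success,
#' minimum 1 month) and the Behaviour stock resets to 0.
#'
#' Consumes the caller's RNG stream.
#'
#' @param p_row single-row agent data frame in state NORMAL.
#' @param neighbours agent data frame of current network neighbours.
#' @param params [behaviour_params()].
#' @param require_gap if `FALSE` (the network-off counterfactual) the
#'   neighbourhood condition is dropped and only the threshold matters.
#' @return updated single-row agent data frame.
#' @export
maybe_transition <- function(p_row, neighbours, params, require_gap = TRUE) {
  stopifnot(p_row$state == "NORMAL")
  if (p_row$behaviour < params$behaviour_threshold) return(p_row)
  if (require_gap) {
    m <- neighbourhood_mean_bmi(p_row, neighbours)
    if (is.na(m)) return(p_row)
    b <- bmi_of(p_row)
    if (b - m <= satisficing_value(b, params$theta_sv)) return(p_row)
  }
  p_row$state <- "DIETING"
  p_row$diet_months_remaining <-
    draw_diet_duration(params$theta_dietTime, p_row$success_score)
  p_row$diet_start_weight <- p_row$weight
  p_row$behaviour <- 0
  p_row
}
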