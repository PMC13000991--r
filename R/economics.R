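#' @title Cost and effectiveness accrual, ICER and dominance
#' @description Discounted accrual of state costs, treatment-event costs and
#'   the varnish application cost along a cohort trajectory; effectiveness
#'   accrual in four modes; strategy comparison with incremental
#'   cost-effectiveness ratio and dominance classification; net monetary
#'   benefit.
#' @name economics
NULL

.effect_modes <- c("ever_cavity_avoided", "cavity_free_time",
                   "expected_cavities", "daly")

# which direction each mode's outcome points: larger is better (benefit) or
# worse (harm)
effect_direction <- function(mode) {
  switch(mode,
         ever_cavity_avoided = "benefit",
         cavity_free_time = "benefit",
         expected_cavities = "harm",
         daly = "harm",
         stop("unknown effectiveness mode: ", mode))
}

#' Build a reward schedule from a parameter set
#'
#' State costs (the routine-visit cost, identical for all three states),
#' treatment-event costs, the per-cycle varnish application cost, and the
#' annual DALY disability weight.
#'
#' @param params An `fv_parameter_set`.
#' @param accrual When state costs are accrued: `"cycle_end"` (default;
#'   occupancy after the cycle's transitions) or `"cycle_start"`. Treatment
#'   events are always attributed from start-of-cycle cavity occupancy, and
#'   every cycle's rewards are discounted with that cycle's end-of-cycle
#'   factor.
#' @return An object of class `fv_reward_schedule`.
#' @export
reward_schedule <- function(params, accrual = c("cycle_end", "cycle_start")) {
  accrual <- match.arg(accrual)
  v <- params$values
  sc <- stats::setNames(rep(v[["c_routine"]], 3), health_states())
  structure(list(
    state_cost = sc,
    event_costs = c(gic = v[["c_gic"]], hall = v[["c_hall"]],
                    ext = v[["c_ext"]]),
    fv_cost_per_cycle = v[["c_fv"]],
    daly_weight = v[["daly_weight"]],
    accrual = accrual), class = "fv_reward_schedule")
}

#' Discount factor at an integer cycle boundary
#'
#' @param cycle_index Cycle number (0 = model entry).
#' @param annual_rate Annual discount rate (> -1).
#' @param cycle_length_years Cycle length in years.
#' @return `(1 + annual_rate)^(-cycle_index * cycle_length_years)`.
#' @export
#' @examples
#' discount_factor(8, 0.05, 0.5)  # 1.05^-4
discount_factor <- function(cycle_index, annual_rate, cycle_length_years) {
  if (annual_rate <= -1) stop("annual_rate must exceed -1")
  if (any(cycle_index < 0)) stop("cycle_index must be non-negative")
  (1 + annual_rate)^(-cycle_index * cycle_length_years)
}

#' Accumulate discounted costs along a trajectory
#'
#' Per cycle t = 1..n, the cohort accrues occupancy-weighted state costs,
#' expected treatment-event costs, and (varnish arm only) the application
#' cost, all multiplied by the cycle-t discount factor.
#'
#' @param traj An `fv_trajectory`.
#' @param schedule An `fv_reward_schedule`.
#' @param arm `"standard"` or `"fv"`; defaults to the trajectory's arm. The
#'   varnish application cost accrues every cycle regardless of state
#'   (visits are semiannual).
#' @param annual_rate Annual discount rate.
#' @param cycle_length_years Cycle length in years.
#' @return Total discounted cost per child, in Reais.
#' @export
accumulate_costs <- function(traj, schedule, arm = traj$model$arm,
                             annual_rate = 0.05, cycle_length_years = 0.5) {
  stopifnot(inherits(traj, "fv_trajectory"),
            inherits(schedule, "fv_reward_schedule"))
  if (any(traj$occupancy < -1e-12)) stop("negative occupancy in trajectory")
  n <- traj$n_cycles
  if (n == 0) return(0)
  t <- seq_len(n)
  disc <- discount_factor(t, annual_rate, cycle_length_years)
  occ <- if (schedule$accrual == "cycle_end") traj$occupancy[t + 1, , drop = FALSE]
         else traj$occupancy[t, , drop = FALSE]
  state_part <- as.vector(occ %*% schedule$state_cost)
  event_part <- as.vector(traj$events %*%
                            schedule$event_costs[colnames(traj$events)])
  fv_part <- if (arm == "fv") schedule$fv_cost_per_cycle else 0
  sum(disc * (state_part + event_part + fv_part))
}

#' Accumulate effectiveness along a trajectory
#'
#' Modes:
#' \describe{
#'   \item{ever_cavity_avoided}{probability of never developing a cavity,
#'     `(1 - p)^n`, undiscounted (a terminal, not a flow, quantity).}
#'   \item{cavity_free_time}{discounted years spent in the no-cavity state.}
#'   \item{expected_cavities}{discounted expected new-cavity entries
#'     (first or relapse) per child.}
#'   \item{daly}{discounted disability-adjusted life years accrued while in
#'     the cavity state: occupancy x cycle length x annual weight.}
#' }
#'
#' @param traj An `fv_trajectory`.
#' @param mode One of the modes above.
#' @param params An `fv_parameter_set` (supplies the DALY weight and cycle
#'   length).
#' @param annual_rate Annual discount rate (outcomes are discounted with the
#'   same factor as costs).
#' @return Effectiveness per child in the mode's units.
#' @export
accumulate_effectiveness <- function(traj, mode, params,
                                     annual_rate = 0.05) {
  stopifnot(inherits(traj, "fv_trajectory"))
  mode <- match.arg(mode, .effect_modes)
  v <- params$values
  n <- traj$n_cycles
  cl <- v[["cycle_length_years"]]
  if (n == 0 && mode != "ever_cavity_avoided") return(0)
  t <- seq_len(n)
  disc <- discount_factor(t, annual_rate, cl)
  switch(mode,
    ever_cavity_avoided =
      (1 - traj$model$probs$p_nocav_cavity)^n,
    cavity_free_time =
      sum(disc * traj$occupancy[t + 1, "no_cavity"] * cl),
    expected_cavities =
      sum(disc * traj$new_cavity_inflow),
    daly =
      sum(disc * traj$occupancy[t + 1, "cavity"] * cl * v[["daly_weight"]]))
}

#' Compare two strategies: increments, ICER and dominance
#'
#' Incremental cost is intervention minus comparator. For benefit outcomes
#' incremental effectiveness is intervention minus comparator; for harm
#' outcomes (DALYs, expected cavities) it is comparator minus intervention,
#' i.e. the amount of harm avoided. The ICER is the ratio; when the
#' incremental effect is zero the ICER is undefined (NA) and dominance is
#' judged on cost alone.
#'
#' @param cost_std,eff_std Comparator (standard care) accumulated cost and
#'   effectiveness.
#' @param cost_fv,eff_fv Intervention (standard care plus varnish)
#'   accumulated cost and effectiveness.
#' @param outcome_direction `"benefit"` or `"harm"`.
#' @return An object of class `fv_cea_result` with per-arm values,
#'   `incr_cost`, `incr_effect`, `icer` and a `dominance` label among
#'   `"dominant"`, `"dominated"`, `"no dominance"`.
#' @export
#' @examples
#' compare_strategies(203.40853, 1.5474046, 334.67498, 1.5663489, "benefit")
compare_strategies <- function(cost_std, eff_std, cost_fv, eff_fv,
                               outcome_direction = c("benefit", "harm")) {
  outcome_direction <- match.arg(outcome_direction)
  stopifnot(is.finite(cost_std), is.finite(eff_std),
            is.finite(cost_fv), is.finite(eff_fv))
  d_cost <- cost_fv - cost_std
  d_eff <- if (outcome_direction == "benefit") eff_fv - eff_std
           else eff_std - eff_fv
  icer <- if (d_eff == 0) NA_real_ else d_cost / d_eff
  dominance <-
    if ((d_cost <= 0 && d_eff > 0) || (d_cost < 0 && d_eff >= 0)) "dominant"
    else if ((d_cost >= 0 && d_eff < 0) || (d_cost > 0 && d_eff <= 0))
      "dominated"
    else "no dominance"
  structure(list(cost_std = cost_std, eff_std = eff_std,
                 cost_fv = cost_fv, eff_fv = eff_fv,
                 incr_cost = d_cost, incr_effect = d_eff, icer = icer,
                 outcome_direction = outcome_direction,
                 dominance = dominance),
            class = "fv_cea_result")
}

#' Net monetary benefit
#'
#' `wtp * incremental effect - incremental cost`; non-negative exactly when
#' the intervention is cost-effective at that willingness to pay.
#'
#' @param d_cost Incremental cost (Reais).
#' @param d_effect Incremental effect (outcome units, avoided for harm
#'   outcomes).
#' @param wtp Willingness to pay per outcome unit (Reais).
#' @return Net monetary benefit in Reais.
#' @export
net_monetary_benefit <- function(d_cost, d_effect, wtp) {
  wtp * d_effect - d_cost
}

#' Run the full two-arm cost-effectiveness analysis
#'
#' Builds both transition models, propagates the cohort over the configured
#' horizon, accrues discounted costs and effectiveness in the requested mode,
#' and compares the strategies.
#'
#' @param params An `fv_parameter_set`.
#' @param mode Effectiveness mode; see [accumulate_effectiveness()].
#' @param fv_overrides Optional named list of direct varnish-arm probability
#'   overrides (see [build_transition_model()]).
#' @param accrual State-cost accrual timing; see [reward_schedule()].
#' @return An `fv_cea_result`; the two trajectories are attached as
#'   attribute `"trajectories"`.
#' @export
#' @examples
#' ps <- load_parameter_table()
#' run_cea(ps, mode = "ever_cavity_avoided")
run_cea <- function(params, mode = "ever_cavity_avoided",
                    fv_overrides = NULL, accrual = "cycle_end") {
  mode <- match.arg(mode, .effect_modes)
  v <- params$values
  n <- v[["n_cycles"]]
  rate <- v[["discount_rate_annual"]]
  cl <- v[["cycle_length_years"]]
  sched <- reward_schedule(params, accrual = accrual)
  traj_std <- propagate(build_transition_model(params, "standard"), n)
  traj_fv <- propagate(build_transition_model(params, "fv",
                                              overrides = fv_overrides), n)
  res <- compare_strategies(
    accumulate_costs(traj_std, sched, "standard", rate, cl),
    accumulate_effectiveness(traj_std, mode, params, rate),
    accumulate_costs(traj_fv, sched, "fv", rate, cl),
    accumulate_effectiveness(traj_fv, mode, params, rate),
    outcome_direction = effect_direction(mode))
  res$mode <- mode
  attr(res, "trajectories") <- list(standard = traj_std, fv = traj_fv)
  res
}

#' Write a CEA result as a two-row strategy table
#'
#' Columns mirror a conventional cost-effectiveness table:
#' `strategy,accumulated_cost,effectiveness,incr_cost,incr_effect,icer,dominance`.
#'
#' @param result An `fv_cea_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cea <- function(result, path) {
  stopifnot(inherits(result, "fv_cea_result"))
  out <- data.frame(
    strategy = c("standard care", "standard care plus FV"),
    accumulated_cost = c(result$cost_std, result$cost_fv),
    effectiveness = c(result$eff_std, result$eff_fv),
    incr_cost = c(NA, result$incr_cost),
    incr_effect = c(NA, result$incr_effect),
    icer = c(NA, result$icer),
    dominance = c(NA, result$dominance))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.fv_cea_result <- function(x, ...) {
  cat("Cost-effectiveness comparison",
      if (!is.null(x$mode)) paste0("(", x$mode, ")"), "\n")
  cat(sprintf("  standard care:   cost %10.2f  effect %.7f\n",
              x$cost_std, x$eff_std))
  cat(sprintf("  care plus FV:    cost %10.2f  effect %.7f\n",
              x$cost_fv, x$eff_fv))
  cat(sprintf("  incremental:     cost %10.2f  effect %.7f\n",
              x$incr_cost, x$incr_effect))
  cat(sprintf("  ICER: %s Reais per unit (%s)\n",
              if (is.na(x$icer)) "undefined" else sprintf("%.2f", x$icer),
              x$dominance))
  invisible(x)
}
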