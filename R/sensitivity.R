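#' @title Deterministic and probabilistic sensitivity analysis
#' @description Distribution fitting from published means and 95% CIs
#'   (beta for probabilities by method of moments, gamma for costs with a
#'   20% coefficient of variation, lognormal for the relative risk), one-way
#'   deterministic sensitivity analysis with tornado ranking, Monte-Carlo
#'   probabilistic sensitivity analysis, and cost-effectiveness
#'   acceptability curves.
#' @name sensitivity
NULL

# alpha + beta above this cap is numerically a point mass
.beta_cap <- 1e9

#' Fit a beta distribution from a mean and 95% CI
#'
#' The standard deviation is taken as the CI width over 2 x 1.96 and the
#' shape parameters follow by method of moments, so the fitted mean equals
#' the source mean by construction. A zero-width interval (or a fit beyond
#' the numerical cap on alpha + beta) degenerates to a fixed value.
#'
#' @param mean Mean probability in (0, 1).
#' @param low,high 95% confidence bounds.
#' @param sd_scale Multiplier on the implied standard deviation (1 = as
#'   published; 0 collapses to a point mass).
#' @return An `fv_distribution`: list with `family` (`"beta"` or `"fixed"`),
#'   shape parameters, and the source `mean`, `low`, `high`, `sd`.
#' @export
#' @examples
#' fit_beta_from_mean_ci(0.63, 0.49, 0.74)
fit_beta_from_mean_ci <- function(mean, low, high, sd_scale = 1) {
  if (!(mean > 0 && mean < 1)) stop("mean must lie strictly in (0, 1)")
  if (low > high) stop("low must not exceed high")
  s <- (high - low) / (2 * 1.96) * sd_scale
  if (s == 0)
    return(structure(list(family = "fixed", value = mean, mean = mean,
                          low = low, high = high, sd = 0),
                     class = "fv_distribution"))
  if (s^2 >= mean * (1 - mean))
    stop("variance too large for a beta distribution with mean ", mean)
  f <- mean * (1 - mean) / s^2 - 1
  shape1 <- mean * f
  shape2 <- (1 - mean) * f
  if (shape1 + shape2 > .beta_cap)
    return(structure(list(family = "fixed", value = mean, mean = mean,
                          low = low, high = high, sd = s),
                     class = "fv_distribution"))
  structure(list(family = "beta", shape1 = shape1, shape2 = shape2,
                 mean = mean, low = low, high = high, sd = s),
            class = "fv_distribution")
}

#' Fit a gamma distribution with a 20% coefficient of variation
#'
#' Cost uncertainty is modelled as a standard deviation equal to 20% of the
#' point estimate, giving shape `(1/0.2)^2 = 25` and scale `mean/25`.
#'
#' @param mean Mean cost (> 0), in Reais.
#' @param sd_scale Multiplier on the 20% standard deviation.
#' @return An `fv_distribution` with `family = "gamma"`, `shape`, `scale`.
#' @export
#' @examples
#' fit_gamma_cv20(118.50)  # shape 25, scale 4.74
fit_gamma_cv20 <- function(mean, sd_scale = 1) {
  if (!(mean > 0)) stop("mean cost must be positive")
  s <- 0.2 * mean * sd_scale
  if (s == 0)
    return(structure(list(family = "fixed", value = mean, mean = mean,
                          sd = 0), class = "fv_distribution"))
  shape <- (mean / s)^2
  structure(list(family = "gamma", shape = shape, scale = mean / shape,
                 mean = mean, sd = s), class = "fv_distribution")
}

#' Fit a lognormal distribution to a relative risk and its 95% CI
#'
#' `meanlog` is the log of the point estimate (so the fitted median equals
#' the source relative risk) and `sdlog` is the log-CI width over 2 x 1.96.
#'
#' @param rr Relative risk point estimate (> 0).
#' @param low,high 95% confidence bounds (> 0).
#' @param sd_scale Multiplier on `sdlog`.
#' @return An `fv_distribution` with `family = "lognormal"` (or `"fixed"`
#'   when the interval has zero width).
#' @export
#' @examples
#' fit_lognormal_rr(0.88, 0.81, 0.95)
fit_lognormal_rr <- function(rr, low, high, sd_scale = 1) {
  if (!(low > 0 && rr > 0 && high > 0)) stop("relative-risk bounds must be positive")
  if (!(low <= rr && rr <= high)) stop("need low <= rr <= high")
  sdlog <- (log(high) - log(low)) / (2 * 1.96) * sd_scale
  if (sdlog == 0)
    return(structure(list(family = "fixed", value = rr, mean = rr,
                          low = low, high = high, sd = 0),
                     class = "fv_distribution"))
  structure(list(family = "lognormal", meanlog = log(rr), sdlog = sdlog,
                 mean = rr, low = low, high = high),
            class = "fv_distribution")
}

#' Fit the appropriate distribution for one registry parameter
#'
#' Dispatches on the parameter's declared family: beta from the mean and
#' published CI, gamma with the 20% coefficient of variation, lognormal from
#' the relative-risk CI, or a fixed point mass.
#'
#' @param params An `fv_parameter_set`.
#' @param id Parameter id.
#' @param sd_scale Standard-deviation multiplier passed through to the fit.
#' @return An `fv_distribution`.
#' @export
fit_distribution <- function(params, id, sd_scale = 1) {
  row <- params$table[params$table$id == id, ]
  if (nrow(row) != 1) stop("unknown parameter id: ", id)
  switch(row$distribution,
    beta = fit_beta_from_mean_ci(row$baseline, row$low, row$high, sd_scale),
    gamma = fit_gamma_cv20(row$baseline, sd_scale),
    lognormal = fit_lognormal_rr(row$baseline, row$low, row$high, sd_scale),
    fixed = structure(list(family = "fixed", value = row$baseline,
                           mean = row$baseline, sd = 0),
                      class = "fv_distribution"),
    stop("no distribution rule for family: ", row$distribution))
}

#' Draw from a fitted distribution
#'
#' @param spec An `fv_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n = 1) {
  stopifnot(inherits(spec, "fv_distribution"))
  switch(spec$family,
         beta = stats::rbeta(n, spec$shape1, spec$shape2),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         fixed = rep(spec$value, n),
         stop("unknown family: ", spec$family))
}

#' Parameters varied in the one-way deterministic sensitivity analysis
#'
#' Every registry row with a non-degenerate published bound pair and a
#' non-fixed distribution, except the varnish-arm derived rows: those are
#' formula rows (their published bounds are exactly the standard-arm bounds
#' times the relative risk), so the underlying variable — the standard-arm
#' probability or the relative risk itself — is what the one-way analysis
#' varies, and the variation propagates into the varnish arm through the
#' product derivation. [one_way_dsa()] still accepts a derived row's id
#' directly for scenario exploration.
#'
#' @param params An `fv_parameter_set`.
#' @return Character vector of parameter ids.
#' @export
dsa_parameters <- function(params) {
  tab <- params$table
  ids <- tab$id[tab$distribution != "fixed" & tab$low < tab$high]
  setdiff(ids, names(.fv_override_map))
}

# ids of the varnish-arm derived probabilities -> the model probability they
# override directly
.fv_override_map <- c(p_nocav_cavity_fv = "p_nocav_cavity",
                      f_gic_fv = "f_gic",
                      f_hall_fv = "f_hall",
                      p_prev_cavity_fv = "p_prev_cavity")

# ICER with a single parameter pinned to `value`
.icer_at <- function(params, id, value, mode, accrual) {
  if (id %in% names(.fv_override_map)) {
    ov <- stats::setNames(list(value), .fv_override_map[[id]])
    run_cea(params, mode, fv_overrides = ov, accrual = accrual)$icer
  } else {
    run_cea(set_parameter(params, id, value), mode, accrual = accrual)$icer
  }
}

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Recomputes the full two-arm analysis with the parameter pinned at its
#' lower and at its upper published bound, all other parameters at baseline.
#' Standard-care probabilities and the relative risk propagate into the
#' varnish arm through the product derivation; the varnish-arm derived
#' probabilities use their published bounds as direct overrides.
#'
#' @param params An `fv_parameter_set`.
#' @param outcome_mode Effectiveness mode (see [accumulate_effectiveness()]).
#' @param varied_id Parameter id to vary.
#' @param accrual State-cost accrual timing.
#' @return A one-row data.frame: `parameter`, `icer_low`, `icer_high`,
#'   `width` (absolute ICER range; NA if undefined at a bound) and
#'   `increases_icer` (whether raising the parameter raises the ICER).
#' @export
one_way_dsa <- function(params, outcome_mode, varied_id,
                        accrual = "cycle_end") {
  row <- params$table[params$table$id == varied_id, ]
  if (nrow(row) != 1) stop("unknown parameter id: ", varied_id)
  icer_low <- .icer_at(params, varied_id, row$low, outcome_mode, accrual)
  icer_high <- .icer_at(params, varied_id, row$high, outcome_mode, accrual)
  data.frame(parameter = varied_id,
             icer_low = icer_low, icer_high = icer_high,
             width = abs(icer_high - icer_low),
             increases_icer = isTRUE(icer_high > icer_low))
}

#' Tornado table over every varied parameter
#'
#' @param params An `fv_parameter_set`.
#' @param outcome_mode Effectiveness mode.
#' @param accrual State-cost accrual timing.
#' @return Data.frame of [one_way_dsa()] rows sorted by decreasing width.
#' @export
#' @examples
#' ps <- load_parameter_table()
#' head(tornado(ps, "ever_cavity_avoided"), 3)
tornado <- function(params, outcome_mode = "ever_cavity_avoided",
                    accrual = "cycle_end") {
  rows <- lapply(dsa_parameters(params), function(id)
    one_way_dsa(params, outcome_mode, id, accrual))
  out <- do.call(rbind, rows)
  out[order(-out$width), , drop = FALSE]
}

# ids sampled in the PSA (everything with a non-fixed distribution on the
# standard arm plus the shared mix, costs and the relative risk; the
# varnish-arm probabilities are re-derived per draw)
.psa_ids <- c("p_nocav_cavity", "q_gic", "q_hall", "s_gic", "s_hall",
              "p_prev_cavity", "eff_rr",
              "c_routine", "c_gic", "c_hall", "c_ext", "c_fv")

# single-draw CEA for both outcomes sharing one pair of trajectories
.cea_both_outcomes <- function(params, accrual) {
  v <- params$values
  n <- v[["n_cycles"]]; rate <- v[["discount_rate_annual"]]
  cl <- v[["cycle_length_years"]]
  sched <- reward_schedule(params, accrual = accrual)
  tr_s <- propagate(build_transition_model(params, "standard"), n)
  tr_f <- propagate(build_transition_model(params, "fv"), n)
  c_s <- accumulate_costs(tr_s, sched, "standard", rate, cl)
  c_f <- accumulate_costs(tr_f, sched, "fv", rate, cl)
  c(d_cost = c_f - c_s,
    d_eff_cavity =
      accumulate_effectiveness(tr_f, "ever_cavity_avoided", params, rate) -
      accumulate_effectiveness(tr_s, "ever_cavity_avoided", params, rate),
    d_eff_daly =
      accumulate_effectiveness(tr_s, "daly", params, rate) -
      accumulate_effectiveness(tr_f, "daly", params, rate))
}

#' Probabilistic sensitivity analysis by Monte-Carlo simulation
#'
#' Per iteration, every eligible parameter is drawn independently from its
#' fitted distribution (beta probabilities, gamma costs, lognormal relative
#' risk), complements are closed after sampling, both arms are rebuilt and
#' the incremental cost and incremental effectiveness for the cavity-avoided
#' and DALY-avoided outcomes are recorded. Draws violating a chance-node
#' constraint (treatment mix summing above one, or a derived varnish
#' probability above one) are rejected and redrawn, with the rejection count
#' retained. Each iteration uses a deterministic substream of the root seed,
#' so any iteration is reproducible in isolation and the whole run is
#' byte-identical under the same seed.
#'
#' @param params An `fv_parameter_set`.
#' @param n_iter Number of Monte-Carlo iterations.
#' @param seed Integer root seed.
#' @param sd_scale Multiplier on every fitted standard deviation (0
#'   reproduces the deterministic base case exactly).
#' @param accrual State-cost accrual timing.
#' @return An `fv_psa_samples` object: `$samples` (data.frame with columns
#'   `iteration`, `d_cost`, `d_eff_cavity`, `d_eff_daly`), `$draws` (matrix
#'   of sampled parameter values), `$rejections`, `$seed`, and the
#'   deterministic base-case ICERs (`$icer_cavity`, `$icer_daly`).
#' @export
#' @examples
#' ps <- load_parameter_table()
#' psa <- run_psa(ps, n_iter = 50, seed = 1)
run_psa <- function(params, n_iter = 1000, seed = 1, sd_scale = 1,
                    accrual = "cycle_end") {
  if (n_iter < 1) stop("n_iter must be at least 1")
  fits <- lapply(stats::setNames(.psa_ids, .psa_ids), fit_distribution,
                 params = params, sd_scale = sd_scale)
  draws <- matrix(NA_real_, n_iter, length(.psa_ids),
                  dimnames = list(NULL, .psa_ids))
  out <- matrix(NA_real_, n_iter, 3,
                dimnames = list(NULL,
                                c("d_cost", "d_eff_cavity", "d_eff_daly")))
  rejections <- 0L
  for (k in seq_len(n_iter)) {
    set.seed((seed + k * 10007L) %% 2147483647L)
    for (attempt in seq_len(1000L)) {
      drawn <- vapply(fits, sample_distribution, numeric(1), n = 1)
      ok <- drawn[["q_gic"]] + drawn[["q_hall"]] <= 1 &&
        drawn[["eff_rr"]] * max(drawn[["p_nocav_cavity"]],
                                1 - drawn[["s_gic"]],
                                1 - drawn[["s_hall"]],
                                drawn[["p_prev_cavity"]]) <= 1
      if (ok) break
      rejections <- rejections + 1L
      if (attempt == 1000L)
        stop("PSA iteration ", k, ": 1000 consecutive draws rejected")
    }
    draws[k, ] <- drawn
    ps_k <- params
    for (id in .psa_ids) ps_k <- set_parameter(ps_k, id, drawn[[id]])
    out[k, ] <- .cea_both_outcomes(ps_k, accrual)
  }
  base_cav <- run_cea(params, "ever_cavity_avoided", accrual = accrual)
  base_daly <- run_cea(params, "daly", accrual = accrual)
  structure(list(
    samples = data.frame(iteration = seq_len(n_iter),
                         d_cost = out[, "d_cost"],
                         d_eff_cavity = out[, "d_eff_cavity"],
                         d_eff_daly = out[, "d_eff_daly"]),
    draws = draws, n_iter = n_iter, seed = seed, sd_scale = sd_scale,
    rejections = rejections,
    icer_cavity = base_cav$icer, icer_daly = base_daly$icer),
    class = "fv_psa_samples")
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the acceptance probability is the
#' fraction of Monte-Carlo iterations whose net monetary benefit
#' `wtp x incremental effect - incremental cost` is non-negative.
#'
#' @param psa An `fv_psa_samples` object.
#' @param wtp_grid Numeric grid of willingness-to-pay values; defaults to 0
#'   up to twice the deterministic base-case ICER in 200 steps.
#' @param outcome `"cavity"` or `"daly"`.
#' @return An `fv_ceac` data.frame with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL, outcome = c("cavity", "daly")) {
  stopifnot(inherits(psa, "fv_psa_samples"))
  outcome <- match.arg(outcome)
  if (nrow(psa$samples) == 0) stop("empty PSA sample set")
  if (is.null(wtp_grid)) {
    top <- 2 * switch(outcome, cavity = psa$icer_cavity,
                      daly = psa$icer_daly)
    if (!is.finite(top) || top <= 0) top <- 2e5
    wtp_grid <- seq(0, top, length.out = 201)
  }
  if (length(wtp_grid) == 0) stop("willingness-to-pay grid is empty")
  d_eff <- switch(outcome, cavity = psa$samples$d_eff_cavity,
                  daly = psa$samples$d_eff_daly)
  d_cost <- psa$samples$d_cost
  prob <- vapply(wtp_grid, function(w)
    mean(net_monetary_benefit(d_cost, d_eff, w) >= 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("fv_ceac", "data.frame"), outcome = outcome)
}

#' Write the tornado table to CSV
#' @param tor Data.frame from [tornado()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_tornado <- function(tor, path) {
  utils::write.csv(tor[, c("parameter", "icer_low", "icer_high", "width")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write PSA incremental samples to CSV
#' @param psa An `fv_psa_samples` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_psa_samples <- function(psa, path) {
  stopifnot(inherits(psa, "fv_psa_samples"))
  out <- psa$samples
  names(out) <- c("iteration", "d_cost", "d_effect_cavity", "d_effect_daly")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an acceptability curve to CSV
#' @param curve An `fv_ceac` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("wtp", "probability")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @export
print.fv_psa_samples <- function(x, ...) {
  cat("PSA sample set:", x$n_iter, "iterations, seed", x$seed, "\n")
  cat(sprintf("  mean incremental cost %.2f; mean incremental effect %.5f (cavity), %.7f (DALY)\n",
              mean(x$samples$d_cost), mean(x$samples$d_eff_cavity),
              mean(x$samples$d_eff_daly)))
  cat("  rejected draws:", x$rejections, "\n")
  invisible(x)
}
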