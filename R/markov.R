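#' @title Markov cohort engine
#' @description Builds per-arm 3x3 transition matrices over the health states
#'   no-cavity, cavity and previous-cavity, and propagates a cohort through
#'   six-month cycles, tracking state occupancy, new-cavity inflow and
#'   expected treatment events.
#' @name markov_engine
NULL

#' Health state labels
#'
#' The model has exactly three states. Children enter in `no_cavity`;
#' `previous_cavity` marks a history of an open cavity (resolved by a
#' glass-ionomer restoration, a Hall-technique crown, or extraction) with no
#' cavity at present. There is no direct edge from `no_cavity` to
#' `previous_cavity`.
#'
#' @return Character vector of the three state names, in matrix order.
#' @export
health_states <- function() c("no_cavity", "cavity", "previous_cavity")

#' Build a per-arm transition model
#'
#' Rows of the cycle transition matrix:
#' \itemize{
#'   \item no-cavity: stays with `1 - p`, progresses to cavity with `p`
#'     (`p_nocav_cavity`, multiplied by the relative risk in the varnish arm);
#'     no direct edge to previous-cavity.
#'   \item cavity: treatment is resolved within the cycle. The child remains
#'     in cavity with the expected failure mass
#'     `q_gic * f_gic + q_hall * f_hall` and moves to previous-cavity with the
#'     complement `q_gic * s_gic + q_hall * s_hall + q_ext` (extraction always
#'     resolves the cavity).
#'   \item previous-cavity: relapses to cavity with `p_prev_cavity`, stays
#'     otherwise.
#' }
#'
#' @param params An `fv_parameter_set`.
#' @param arm `"standard"` or `"fv"`.
#' @param overrides Optional named list replacing individual arm
#'   probabilities after derivation (names among `p_nocav_cavity`, `f_gic`,
#'   `f_hall`, `p_prev_cavity`); used by the deterministic sensitivity
#'   analysis to apply the published varnish-arm bounds directly.
#' @return An object of class `fv_transition_model`: arm label, the 3x3
#'   row-stochastic matrix, and the retained treatment mix and success
#'   probabilities used for event attribution.
#' @export
#' @examples
#' ps <- load_parameter_table()
#' m <- build_transition_model(ps, "standard")
#' m$matrix
build_transition_model <- function(params, arm = c("standard", "fv"),
                                   overrides = NULL) {
  arm <- match.arg(arm)
  pr <- derive_fv_probabilities(params)[[arm]]
  if (!is.null(overrides)) {
    bad <- setdiff(names(overrides),
                   c("p_nocav_cavity", "f_gic", "f_hall", "p_prev_cavity"))
    if (length(bad) > 0)
      stop("cannot override: ", paste(bad, collapse = ", "))
    pr[names(overrides)] <- overrides
    pr$s_gic <- 1 - pr$f_gic
    pr$s_hall <- 1 - pr$f_hall
  }
  stay_cavity <- pr$q_gic * pr$f_gic + pr$q_hall * pr$f_hall
  resolve <- pr$q_gic * pr$s_gic + pr$q_hall * pr$s_hall + pr$q_ext
  mat <- rbind(
    c(1 - pr$p_nocav_cavity, pr$p_nocav_cavity, 0),
    c(0, stay_cavity, resolve),
    c(0, pr$p_prev_cavity, 1 - pr$p_prev_cavity))
  dimnames(mat) <- list(health_states(), health_states())
  if (any(mat < -1e-15 | mat > 1 + 1e-15))
    stop("transition model for arm '", arm,
         "' has an entry outside [0, 1]")
  mat <- pmin(pmax(mat, 0), 1)
  if (any(abs(rowSums(mat) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  structure(list(arm = arm, matrix = mat, probs = pr,
                 mix = c(gic = pr$q_gic, hall = pr$q_hall, ext = pr$q_ext),
                 success = c(gic = pr$s_gic, hall = pr$s_hall, ext = 1)),
            class = "fv_transition_model")
}

#' Propagate a cohort through the model
#'
#' Occupancy at cycle t is the occupancy at t - 1 right-multiplied by the
#' transition matrix. Treatment events in cycle t are attributed from the
#' cavity occupancy at the start of the cycle (cycle t - 1) times the
#' treatment mix; new-cavity inflow counts entries into the cavity state from
#' no-cavity and previous-cavity (a failed restoration keeps the child in
#' cavity and is not a new entry).
#'
#' @param model An `fv_transition_model`.
#' @param n_cycles Number of cycles (>= 0).
#' @param init Initial occupancy vector; defaults to the whole cohort
#'   caries-free.
#' @return An object of class `fv_trajectory`: `$occupancy` is a
#'   `(n_cycles + 1) x 3` matrix (rows cycle 0..n), `$new_cavity_inflow` and
#'   `$events` (columns gic, hall, ext) have one row per cycle 1..n.
#' @export
propagate <- function(model, n_cycles, init = c(1, 0, 0)) {
  stopifnot(inherits(model, "fv_transition_model"))
  if (n_cycles < 0 || n_cycles != round(n_cycles))
    stop("n_cycles must be a non-negative integer")
  if (length(init) != 3 || any(init < 0) || abs(sum(init) - 1) > 1e-10)
    stop("init must be a length-3 occupancy distribution summing to 1")
  occ <- matrix(0, n_cycles + 1, 3,
                dimnames = list(paste0("cycle", 0:n_cycles), health_states()))
  occ[1, ] <- init
  inflow <- numeric(n_cycles)
  events <- matrix(0, n_cycles, 3,
                   dimnames = list(NULL, c("gic", "hall", "ext")))
  M <- model$matrix
  p <- model$probs
  for (t in seq_len(n_cycles)) {
    prev <- occ[t, ]
    occ[t + 1, ] <- prev %*% M
    inflow[t] <- prev[1] * p$p_nocav_cavity + prev[3] * p$p_prev_cavity
    events[t, ] <- prev[2] * model$mix
  }
  structure(list(occupancy = occ, new_cavity_inflow = inflow,
                 events = events, model = model, n_cycles = n_cycles),
            class = "fv_trajectory")
}

#' Probability of ever developing a cavity
#'
#' With no inflow into the no-cavity state, the probability of remaining
#' caries-free for `n_cycles` cycles is `(1 - p)^n`, so the ever-cavity
#' probability is its complement. The between-arm difference of the
#' caries-free probabilities is the headline "cavities prevented per child"
#' quantity.
#'
#' @param p_nc Per-cycle no-cavity to cavity probability.
#' @param n_cycles Number of cycles.
#' @return `1 - (1 - p_nc)^n_cycles`.
#' @export
#' @examples
#' ever_cavity_probability(0.06873, 8)
ever_cavity_probability <- function(p_nc, n_cycles) {
  if (any(p_nc < 0 | p_nc > 1)) stop("p_nc must lie in [0, 1]")
  1 - (1 - p_nc)^n_cycles
}

#' Write a cohort trajectory to CSV
#'
#' Long format: one row per cycle and state with the occupancy fraction;
#' inflow and event columns are attached to the rows of their cycle (zero at
#' cycle 0).
#'
#' @param traj An `fv_trajectory`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fv_trajectory"))
  n <- traj$n_cycles
  cyc <- rep(0:n, each = 3)
  st <- rep(health_states(), n + 1)
  inflow <- c(0, traj$new_cavity_inflow)[cyc + 1]
  ev <- rbind(c(0, 0, 0), traj$events)[cyc + 1, , drop = FALSE]
  out <- data.frame(cycle = cyc, state = st,
                    occupancy = as.vector(t(traj$occupancy)),
                    new_cavity_inflow = inflow,
                    gic_events = ev[, "gic"], hall_events = ev[, "hall"],
                    ext_events = ev[, "ext"])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.fv_transition_model <- function(x, ...) {
  cat("Transition model, arm:", x$arm, "\n")
  print(round(x$matrix, 6))
  invisible(x)
}

#' @export
print.fv_trajectory <- function(x, ...) {
  cat("Cohort trajectory,", x$n_cycles, "cycles, arm:", x$model$arm, "\n")
  cat("End occupancy:",
      paste(sprintf("%s %.4f", health_states(),
                    x$occupancy[x$n_cycles + 1, ]), collapse = ", "), "\n")
  invisible(x)
}
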