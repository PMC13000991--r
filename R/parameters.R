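#' @title Parameter registry
#' @description Functions to load, validate, write and derive the model's
#'   parameter set: per-cycle transition probabilities, treatment mix and
#'   success probabilities, the fluoride-varnish relative risk, unit costs in
#'   2022 Brazilian Reais, and the model constants (discount rate, horizon,
#'   cycle length, DALY weight, willingness-to-pay thresholds).
#' @name parameters
NULL

.param_roles <- c("probability", "cost", "relative-risk", "disability-weight",
                  "rate", "count")
.param_arms <- c("standard", "fv", "both")
.param_dists <- c("beta", "gamma", "lognormal", "fixed")

# ids every parameter set must carry
.required_ids <- c(
  "p_nocav_cavity", "q_gic", "q_hall", "s_gic", "s_hall", "p_prev_cavity",
  "p_nocav_cavity_fv", "f_gic_fv", "f_hall_fv", "p_prev_cavity_fv",
  "eff_rr", "c_routine", "c_gic", "c_hall", "c_ext", "c_fv",
  "daly_weight", "discount_rate_annual", "n_cycles", "cycle_length_years",
  "wtp_daly", "wtp_cavity")

#' Path to the packaged default parameter table
#'
#' The packaged file carries the published baseline values, 95% CI / one-way
#' sensitivity bounds and distribution families for every model parameter.
#'
#' @return Path to the CSV shipped with the package.
#' @export
default_parameter_file <- function() {
  system.file("extdata", "table1_parameters.csv", package = "fvcea",
              mustWork = TRUE)
}

#' Load and validate a parameter table
#'
#' Reads a CSV with columns `id,role,arm,baseline,low,high,distribution,note`
#' (one record per parameter) and returns a validated parameter set. Missing
#' required parameters and bound violations are reported by name.
#'
#' @param path Path to a parameter CSV; defaults to the packaged table.
#' @return An object of class `fv_parameter_set`: a list with the record
#'   table (`$table`) and a named vector of baseline values (`$values`).
#' @export
#' @examples
#' ps <- load_parameter_table()
#' ps$values[["p_nocav_cavity"]]
load_parameter_table <- function(path = default_parameter_file()) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "role", "arm", "baseline", "low", "high",
              "distribution", "note")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop("parameter file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  miss <- setdiff(.required_ids, tab$id)
  if (length(miss) > 0)
    stop("missing parameter id(s): ", paste(miss, collapse = ", "))
  dup <- tab$id[duplicated(tab$id)]
  if (length(dup) > 0)
    stop("duplicated parameter id(s): ", paste(unique(dup), collapse = ", "))
  ps <- structure(
    list(table = tab[needed],
         values = stats::setNames(as.numeric(tab$baseline), tab$id)),
    class = "fv_parameter_set")
  validate_parameter_set(ps)
  ps
}

#' Write a parameter set back to CSV
#'
#' Round-trips exactly with [load_parameter_table()]: the written file reloads
#' to a field-by-field identical parameter set.
#'
#' @param ps An `fv_parameter_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_table <- function(ps, path) {
  stopifnot(inherits(ps, "fv_parameter_set"))
  utils::write.csv(ps$table, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Validate a parameter set
#'
#' Checks per-record bound invariants (probabilities in \[0,1\] with
#' low <= baseline <= high, non-negative costs, positive relative risks),
#' chance-node closure (q_gic + q_hall <= 1), the 4-year horizon identity
#' n_cycles x cycle_length_years = 4, and that the stored fluoride-varnish
#' probabilities equal the standard-care x relative-risk products.
#'
#' @param ps An `fv_parameter_set`.
#' @return `ps`, invisibly; otherwise an error naming the offending
#'   parameter and bound.
#' @export
validate_parameter_set <- function(ps) {
  stopifnot(inherits(ps, "fv_parameter_set"))
  tab <- ps$table
  bad_role <- setdiff(unique(tab$role), .param_roles)
  if (length(bad_role) > 0)
    stop("unknown parameter role(s): ", paste(bad_role, collapse = ", "))
  bad_dist <- setdiff(unique(tab$distribution), .param_dists)
  if (length(bad_dist) > 0)
    stop("unknown distribution(s): ", paste(bad_dist, collapse = ", "))
  bad_arm <- setdiff(unique(tab$arm), .param_arms)
  if (length(bad_arm) > 0)
    stop("unknown arm label(s): ", paste(bad_arm, collapse = ", "))
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    ok <- is.finite(r$baseline) && is.finite(r$low) && is.finite(r$high)
    if (!ok) stop("non-finite value for parameter '", r$id, "'")
    if (r$role == "probability" &&
        !(0 <= r$low && r$low <= r$baseline && r$baseline <= r$high &&
          r$high <= 1))
      stop("parameter '", r$id,
           "': probability must satisfy 0 <= low <= baseline <= high <= 1")
    if (r$role == "cost" &&
        !(0 <= r$low && r$low <= r$baseline && r$baseline <= r$high))
      stop("parameter '", r$id,
           "': cost must satisfy 0 <= low <= baseline <= high")
    if (r$role == "relative-risk" &&
        !(0 < r$low && r$low <= r$baseline && r$baseline <= r$high))
      stop("parameter '", r$id,
           "': relative risk must satisfy 0 < low <= baseline <= high")
  }
  v <- ps$values
  if (v[["q_gic"]] + v[["q_hall"]] > 1 + 1e-12)
    stop("treatment mix node: q_gic + q_hall exceeds 1")
  horizon <- v[["n_cycles"]] * v[["cycle_length_years"]]
  if (abs(horizon - 4) > 1e-9 && !isTRUE(attr(ps, "free_horizon")))
    stop("n_cycles x cycle_length_years is ", horizon,
         ", expected the 4-year horizon")
  derived <- derive_fv_probabilities(ps)
  stored <- c(p_nocav_cavity = v[["p_nocav_cavity_fv"]],
              f_gic = v[["f_gic_fv"]],
              f_hall = v[["f_hall_fv"]],
              p_prev_cavity = v[["p_prev_cavity_fv"]])
  drift <- abs(stored - unlist(derived$fv[names(stored)]))
  if (any(drift > 1e-9))
    stop("stored fluoride-varnish probabilities disagree with the ",
         "standard x relative-risk products for: ",
         paste(names(stored)[drift > 1e-9], collapse = ", "))
  invisible(ps)
}

#' Replace one parameter's baseline value
#'
#' Used by the sensitivity analyses; the derived fluoride-varnish products are
#' recomputed downstream, so overriding e.g. `p_nocav_cavity` or `eff_rr`
#' flows into the varnish arm.
#'
#' @param ps An `fv_parameter_set`.
#' @param id Parameter id.
#' @param value New baseline value.
#' @return A modified `fv_parameter_set` (validation is not re-run: sampled or
#'   bound values legitimately break the stored-product identity).
#' @export
set_parameter <- function(ps, id, value) {
  stopifnot(inherits(ps, "fv_parameter_set"))
  if (!id %in% names(ps$values)) stop("unknown parameter id: ", id)
  ps$values[[id]] <- value
  ps$table$baseline[ps$table$id == id] <- value
  ps
}

#' Close complementary branch probabilities at a chance node
#'
#' Each chance node's unstated branch receives one minus the sum of its
#' stated siblings, so the closed branch set sums to exactly one.
#'
#' @param stated Named numeric vector of the stated branch probabilities.
#' @param node Node label used in error messages.
#' @return The stated vector with an extra `complement` element.
#' @export
#' @examples
#' close_complements(c(q_gic = 0.873, q_hall = 0.004))  # complement 0.123
close_complements <- function(stated, node = "chance node") {
  if (any(stated < 0)) stop(node, ": negative branch probability")
  total <- sum(stated)
  if (total > 1 + 1e-12)
    stop(node, ": stated branch probabilities sum to ", format(total),
         " which exceeds 1")
  c(stated, complement = max(0, 1 - total))
}

#' Derive the fluoride-varnish arm's probabilities
#'
#' The varnish relative risk multiplies exactly four probabilities: the
#' no-cavity to cavity progression, the glass-ionomer and Hall-technique
#' failure probabilities, and the previous-cavity to cavity progression.
#' The treatment mix (q_gic, q_hall, q_ext) is unchanged between arms.
#'
#' @param ps An `fv_parameter_set`.
#' @param eff_rr Relative risk; defaults to the value stored in `ps`.
#' @return A list with `$standard` and `$fv`, each a named list with elements
#'   `p_nocav_cavity`, `f_gic`, `f_hall`, `p_prev_cavity`, `q_gic`, `q_hall`,
#'   `q_ext`, `s_gic`, `s_hall`.
#' @export
derive_fv_probabilities <- function(ps, eff_rr = ps$values[["eff_rr"]]) {
  v <- ps$values
  if (!is.finite(eff_rr) || eff_rr <= 0)
    stop("eff_rr must be a positive finite relative risk")
  mix <- close_complements(c(q_gic = v[["q_gic"]], q_hall = v[["q_hall"]]),
                           node = "treatment mix")
  std <- list(
    p_nocav_cavity = v[["p_nocav_cavity"]],
    f_gic = 1 - v[["s_gic"]],
    f_hall = 1 - v[["s_hall"]],
    p_prev_cavity = v[["p_prev_cavity"]],
    q_gic = mix[["q_gic"]], q_hall = mix[["q_hall"]],
    q_ext = mix[["complement"]],
    s_gic = v[["s_gic"]], s_hall = v[["s_hall"]])
  scaled <- c("p_nocav_cavity", "f_gic", "f_hall", "p_prev_cavity")
  fv <- std
  for (nm in scaled) {
    prod <- std[[nm]] * eff_rr
    if (prod > 1)
      stop("derived fluoride-varnish probability '", nm, "' = ",
           format(prod), " exceeds 1")
    fv[[nm]] <- prod
  }
  fv$s_gic <- 1 - fv$f_gic
  fv$s_hall <- 1 - fv$f_hall
  list(standard = std, fv = fv)
}

#' @export
print.fv_parameter_set <- function(x, ...) {
  cat("Parameter set:", nrow(x$table), "parameters\n")
  cat(sprintf("  horizon: %g cycles of %g years, discount %g%%/yr\n",
              x$values[["n_cycles"]], x$values[["cycle_length_years"]],
              100 * x$values[["discount_rate_annual"]]))
  print(x$table[, c("id", "role", "arm", "baseline", "low", "high",
                    "distribution")], row.names = FALSE)
  invisible(x)
}
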