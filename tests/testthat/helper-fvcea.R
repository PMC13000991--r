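# shared fixtures: the packaged baseline parameter set and values frozen from
# an independent brute-force propagation oracle (per-cycle matrix products
# computed outside the package code paths)

baseline_params <- function() load_parameter_table()

# end-of-horizon occupancy after 8 cycles, frozen from the hand-built oracle
oracle_end_std <- c(no_cavity = 0.5657243893, cavity = 0.1580405166,
                    previous_cavity = 0.2762350941)
oracle_end_fv <- c(no_cavity = 0.6070708243, cavity = 0.1309281476,
                   previous_cavity = 0.2620010281)

# undiscounted sums frozen from the same oracle
oracle_expected_cavities_r0 <- 0.6864862261  # NO/PREV inflow, 8 cycles
oracle_daly_r0 <- 0.0046935702               # 0.01 * 0.5 * sum cavity occ

# independent re-propagation used by property tests on random parameter sets
oracle_propagate <- function(M, n, init = c(1, 0, 0)) {
  occ <- matrix(0, n + 1, 3)
  occ[1, ] <- init
  for (t in seq_len(n)) occ[t + 1, ] <- occ[t, ] %*% M
  occ
}
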