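test_that("discount factors follow the annual-rate closed form", {
  expect_equal(discount_factor(0, 0.05, 0.5), 1)
  expect_equal(discount_factor(2, 0.05, 0.5), 1 / 1.05)
  expect_equal(discount_factor(8, 0.05, 0.5), 1.05^-4)
  expect_equal(discount_factor(8, 0.05, 0.5), 0.822702, tolerance = 1e-6)
  expect_equal(discount_factor(0:8, 0, 0.5), rep(1, 9))
  expect_error(discount_factor(1, -1.5, 0.5), "exceed -1")
})

test_that("single-cycle cost accrual matches hand arithmetic", {
  ps <- baseline_params()
  sched <- reward_schedule(ps)
  m <- build_transition_model(ps, "standard")
  # all mass held in no-cavity: force a degenerate model via p = 0
  ps0 <- set_parameter(ps, "p_nocav_cavity", 0)
  tr0 <- propagate(build_transition_model(ps0, "standard"), 1)
  expect_equal(accumulate_costs(tr0, sched, "standard", 0, 0.5), 118.50)
  # all mass entering the cycle in cavity, start-of-cycle accrual isolates
  # the treated cycle: state cost + expected treatment cost
  tr_c <- propagate(m, 1, init = c(0, 1, 0))
  sched_start <- reward_schedule(ps, accrual = "cycle_start")
  cost_std <- accumulate_costs(tr_c, sched_start, "standard", 0, 0.5)
  expect_equal(cost_std,
               118.50 + 0.873 * 179.50 + 0.004 * 254.50 + 0.123 * 172.50)
  expect_equal(cost_std, 297.439)
  # the varnish arm adds the application cost on top
  expect_equal(accumulate_costs(tr_c, sched_start, "fv", 0, 0.5),
               297.439 + 78.00)
})

test_that("zero discount reduces accrual to plain sums, and cost is monotone in unit costs", {
  ps <- baseline_params()
  m <- build_transition_model(ps, "standard")
  tr <- propagate(m, 8)
  sched <- reward_schedule(ps)
  undisc <- accumulate_costs(tr, sched, "standard", 0, 0.5)
  t <- 1:8
  by_hand <- sum(tr$occupancy[t + 1, ] %*% sched$state_cost) +
    sum(tr$events %*% sched$event_costs)
  expect_equal(undisc, by_hand)
  # monotone in every unit cost and the varnish add-on
  for (id in c("c_routine", "c_gic", "c_hall", "c_ext")) {
    up <- set_parameter(ps, id, ps$values[[id]] + 50)
    expect_gt(accumulate_costs(tr, reward_schedule(up), "standard", 0.05, 0.5),
              accumulate_costs(tr, sched, "standard", 0.05, 0.5))
  }
  expect_gt(accumulate_costs(tr, sched, "fv", 0.05, 0.5),
            accumulate_costs(tr, sched, "standard", 0.05, 0.5))
})

test_that("effectiveness modes match their frozen oracle values", {
  ps <- baseline_params()
  tr <- propagate(build_transition_model(ps, "standard"), 8)
  expect_equal(accumulate_effectiveness(tr, "daly", ps, 0),
               oracle_daly_r0, tolerance = 1e-8)
  expect_equal(accumulate_effectiveness(tr, "daly", ps, 0),
               0.0046936, tolerance = 1e-4)
  expect_equal(accumulate_effectiveness(tr, "expected_cavities", ps, 0),
               oracle_expected_cavities_r0, tolerance = 1e-9)
  expect_equal(accumulate_effectiveness(tr, "ever_cavity_avoided", ps, 0.05),
               (1 - 0.06873)^8)
  # p = 0 keeps the whole cohort caries-free
  ps0 <- set_parameter(ps, "p_nocav_cavity", 0)
  tr0 <- propagate(build_transition_model(ps0, "standard"), 8)
  expect_equal(accumulate_effectiveness(tr0, "ever_cavity_avoided", ps0, 0.05),
               1)
  expect_equal(accumulate_effectiveness(tr0, "cavity_free_time", ps0, 0),
               8 * 0.5)
  expect_error(accumulate_effectiveness(tr, "qaly", ps, 0.05),
               "should be one of")
})

test_that("strategy comparison reproduces the published incremental table", {
  res <- compare_strategies(203.40853, 1.5474046, 334.67498, 1.5663489,
                            "benefit")
  expect_equal(res$incr_cost, 131.26645)
  expect_equal(res$incr_effect, 0.01894424, tolerance = 1e-5)
  expect_equal(res$icer, 6929.095, tolerance = 1e-4 * 6929.095)
  expect_equal(res$dominance, "no dominance")
  res_d <- compare_strategies(203.408527, 0.0013445, 334.674981, 0.0011641,
                              "harm")
  expect_equal(res_d$incr_effect, 0.00018041, tolerance = 1e-4)
  expect_equal(res_d$icer, 727604.842, tolerance = 1e-4 * 727604.842)
  # incremental cost over the 4-year horizon rounds to R$33 per child-year
  expect_equal(round(res$incr_cost / 4), 33)
})

test_that("dominance classification covers all quadrants and is antisymmetric", {
  expect_equal(compare_strategies(100, 1, 100, 2, "benefit")$dominance,
               "dominant")
  expect_equal(compare_strategies(100, 2, 100, 1, "benefit")$dominance,
               "dominated")
  expect_equal(compare_strategies(100, 1, 90, 1, "benefit")$dominance,
               "dominant")
  expect_equal(compare_strategies(100, 1, 200, 2, "benefit")$dominance,
               "no dominance")
  # zero incremental effect: ICER undefined, cost decides
  tie <- compare_strategies(100, 1, 150, 1, "benefit")
  expect_true(is.na(tie$icer))
  expect_equal(tie$dominance, "dominated")
  # swapping the arms negates both increments and mirrors dominance
  a <- compare_strategies(100, 1, 120, 1.5, "benefit")
  b <- compare_strategies(120, 1.5, 100, 1, "benefit")
  expect_equal(b$incr_cost, -a$incr_cost)
  expect_equal(b$incr_effect, -a$incr_effect)
  swap <- c(dominant = "dominated", dominated = "dominant",
            "no dominance" = "no dominance")
  expect_equal(unname(swap[a$dominance]), b$dominance)
})

test_that("net monetary benefit is linear in WTP and vanishes at the ICER", {
  dC <- 131.26645; dE <- 0.01894424
  expect_equal(net_monetary_benefit(dC, dE, dC / dE), 0, tolerance = 1e-9)
  expect_equal(net_monetary_benefit(dC, dE, 0), -dC)
  expect_equal(net_monetary_benefit(dC, dE, 60), 60 * dE - dC)
  expect_equal(net_monetary_benefit(dC, dE, 60), -130.13, tolerance = 1e-2)
  wtps <- c(0, 1000, 5000, 20000)
  nmb <- net_monetary_benefit(dC, dE, wtps)
  expect_equal(diff(nmb) / diff(wtps), rep(dE, 3))
})

test_that("run_cea ties the pipeline together and its CSV mirrors the table layout", {
  ps <- baseline_params()
  res <- run_cea(ps, "ever_cavity_avoided")
  expect_s3_class(res, "fv_cea_result")
  expect_gt(res$incr_cost, 0)
  expect_gt(res$incr_effect, 0)
  expect_equal(res$icer, res$incr_cost / res$incr_effect)
  expect_equal(res$dominance, "no dominance")
  # DALY mode: avoided harm is positive under a protective relative risk
  res_d <- run_cea(ps, "daly")
  expect_gt(res_d$incr_effect, 0)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_cea(res, tmp)
  out <- utils::read.csv(tmp)
  expect_named(out, c("strategy", "accumulated_cost", "effectiveness",
                      "incr_cost", "incr_effect", "icer", "dominance"))
  expect_equal(nrow(out), 2)
  expect_equal(out$incr_cost[2], res$incr_cost)
})
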