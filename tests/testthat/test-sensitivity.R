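test_that("beta method-of-moments fit reproduces the published CIs", {
  f1 <- fit_beta_from_mean_ci(0.06873, 0.0665, 0.0710)
  expect_equal(f1$sd, (0.0710 - 0.0665) / (2 * 1.96))
  expect_equal(f1$sd, 0.0011480, tolerance = 1e-4)
  expect_equal(f1$shape1, 3338.2, tolerance = 1e-3 * 3338)
  expect_equal(f1$shape2, 45231, tolerance = 1e-3 * 45231)
  # fitted mean reproduces the source mean by construction
  expect_equal(f1$shape1 / (f1$shape1 + f1$shape2), 0.06873)
  f2 <- fit_beta_from_mean_ci(0.63, 0.49, 0.74)
  expect_equal(f2$sd, 0.063776, tolerance = 1e-5)
  expect_equal(f2$shape1, 35.5, tolerance = 0.1)
  expect_equal(f2$shape2, 20.9, tolerance = 0.1)
  # degenerate limits
  expect_equal(fit_beta_from_mean_ci(0.5, 0.5, 0.5)$family, "fixed")
  tiny <- fit_beta_from_mean_ci(0.5, 0.5 - 1e-7, 0.5 + 1e-7)
  expect_equal(tiny$family, "fixed")  # alpha = beta beyond the cap
  expect_error(fit_beta_from_mean_ci(0.5, 0, 2), "variance too large")
  expect_error(fit_beta_from_mean_ci(1.2, 0.1, 0.2), "strictly in")
})

test_that("gamma cost fit uses a 20% coefficient of variation", {
  g <- fit_gamma_cv20(118.50)
  expect_equal(g$shape, 25)
  expect_equal(g$scale, 4.74)
  expect_equal(fit_gamma_cv20(78.00)$scale, 3.12)
  expect_equal(g$shape * g$scale, 118.50)  # mean preserved
  expect_error(fit_gamma_cv20(-5), "positive")
})

test_that("lognormal relative-risk fit matches the closed form", {
  ln <- fit_lognormal_rr(0.88, 0.81, 0.95)
  expect_equal(ln$meanlog, -0.127833, tolerance = 1e-5)
  expect_equal(ln$sdlog, 0.040670, tolerance = 1e-4)
  expect_equal(exp(ln$meanlog), 0.88)  # median equals the source RR
  expect_equal(fit_lognormal_rr(0.88, 0.88, 0.88)$family, "fixed")
  expect_error(fit_lognormal_rr(0.88, -0.1, 0.95), "positive")
})

test_that("samplers recover their target moments at n = 10000", {
  set.seed(42)
  n <- 10000
  fb <- fit_beta_from_mean_ci(0.06873, 0.0665, 0.0710)
  xb <- sample_distribution(fb, n)
  expect_lt(abs(mean(xb) - 0.06873), 3 * fb$sd / sqrt(n))
  fg <- fit_gamma_cv20(118.50)
  xg <- sample_distribution(fg, n)
  expect_lt(abs(mean(xg) - 118.50), 3 * fg$sd / sqrt(n))
  fl <- fit_lognormal_rr(0.88, 0.81, 0.95)
  xl <- sample_distribution(fl, n)
  # median of a lognormal is exp(meanlog); SE of the median ~ 1.2533 SE mean
  expect_equal(stats::median(xl), 0.88, tolerance = 3 * 1.2533 *
                 stats::sd(xl) / sqrt(n) / 0.88)
  # mean matches the lognormal closed form exp(mu + sigma^2/2)
  expect_lt(abs(mean(xl) - 0.88073), 3 * stats::sd(xl) / sqrt(n))
})

test_that("one-way DSA pins a single parameter at its published bounds", {
  ps <- baseline_params()
  # the varnish application cost enters only the incremental cost, so the
  # ICER rises strictly with it
  entry <- one_way_dsa(ps, "ever_cavity_avoided", "c_fv")
  expect_true(entry$increases_icer)
  expect_gt(entry$icer_high, entry$icer_low)
  base_icer <- run_cea(ps, "ever_cavity_avoided")$icer
  expect_lt(entry$icer_low, base_icer)
  expect_gt(entry$icer_high, base_icer)
  # a degenerate bound pair has zero width
  ps_fix <- ps
  ps_fix$table$low[ps_fix$table$id == "c_fv"] <- 78
  ps_fix$table$high[ps_fix$table$id == "c_fv"] <- 78
  expect_equal(one_way_dsa(ps_fix, "ever_cavity_avoided", "c_fv")$width, 0)
  expect_error(one_way_dsa(ps, "ever_cavity_avoided", "nope"), "unknown")
})

test_that("varnish effectiveness has the widest tornado bar for both outcomes", {
  ps <- baseline_params()
  for (mode in c("ever_cavity_avoided", "daly")) {
    tor <- tornado(ps, mode)
    expect_equal(tor$parameter[1], "eff_rr")
    expect_true(all(tor$width >= 0, na.rm = TRUE))
    expect_setequal(tor$parameter, dsa_parameters(ps))
  }
})

test_that("PSA is byte-identical under a fixed seed and logs rejections", {
  ps <- baseline_params()
  a <- run_psa(ps, n_iter = 40, seed = 123)
  b <- run_psa(ps, n_iter = 40, seed = 123)
  expect_identical(a$samples, b$samples)
  expect_identical(a$draws, b$draws)
  expect_gte(a$rejections, 0)
  c <- run_psa(ps, n_iter = 40, seed = 124)
  expect_false(identical(a$samples$d_cost, c$samples$d_cost))
  # iteration substreams: a longer run reproduces the shorter run's head
  d <- run_psa(ps, n_iter = 10, seed = 123)
  expect_identical(d$samples, a$samples[1:10, ])
  expect_identical(d$draws, a$draws[1:10, , drop = FALSE])
})

test_that("sampled relative risks have the lognormal mean", {
  ps <- baseline_params()
  psa <- run_psa(ps, n_iter = 400, seed = 5)
  rr <- psa$draws[, "eff_rr"]
  expect_lt(abs(mean(rr) - 0.88073), 3 * stats::sd(rr) / sqrt(length(rr)))
})

test_that("zero-variance PSA reproduces the deterministic base case exactly", {
  ps <- baseline_params()
  psa <- run_psa(ps, n_iter = 5, seed = 9, sd_scale = 0)
  base_cav <- run_cea(ps, "ever_cavity_avoided")
  base_daly <- run_cea(ps, "daly")
  expect_equal(psa$samples$d_cost, rep(base_cav$incr_cost, 5))
  expect_equal(psa$samples$d_eff_cavity, rep(base_cav$incr_effect, 5))
  expect_equal(psa$samples$d_eff_daly, rep(base_daly$incr_effect, 5))
})

test_that("acceptability curve is a probability, monotone, with the right limits", {
  ps <- baseline_params()
  psa <- run_psa(ps, n_iter = 300, seed = 11)
  curve <- ceac(psa, outcome = "cavity")
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
  # all incremental costs positive: nothing is acceptable at WTP = 0
  expect_true(all(psa$samples$d_cost > 0))
  expect_equal(curve$probability[1], 0)
  if (all(psa$samples$d_eff_cavity > 0))
    expect_true(all(diff(curve$probability) >= 0))
  # a huge WTP accepts every iteration with positive incremental effect
  huge <- ceac(psa, wtp_grid = 1e9, outcome = "cavity")
  expect_equal(huge$probability, mean(psa$samples$d_eff_cavity > 0))
  # the curve crosses 0.5 in the vicinity of the deterministic ICER
  cross <- curve$wtp[min(which(curve$probability >= 0.5))]
  expect_lt(abs(cross - psa$icer_cavity), 0.15 * psa$icer_cavity)
  expect_error(ceac(psa, wtp_grid = numeric(0)), "empty")
})
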