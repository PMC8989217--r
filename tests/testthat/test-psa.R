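test_that("normal ranges are read as 95% intervals", {
  fit <- fit_distribution(parameter_estimate("tm_encounters", 4.76, 4.046,
                                             5.474, "normal"))
  expect_identical(fit$family, "normal")
  expect_equal(fit$pars$mean, 4.76)
  expect_equal(fit$pars$sd, (5.474 - 4.046) / 3.92, tolerance = 1e-12)
  expect_equal(fit$pars$sd, 0.36429, tolerance = 1e-4)
})

test_that("beta and gamma method-of-moments fits recover mean and variance", {
  est <- parameter_estimate("p_comply", 0.59, 0.502, 0.679, "beta")
  fit <- fit_distribution(est)
  m <- 0.59
  v <- ((0.679 - 0.502) / 3.92)^2
  # independent moment oracle: alpha = m*(m(1-m)/v - 1), beta = (1-m)*(...)
  expect_equal(fit$pars$shape1, m * (m * (1 - m) / v - 1), tolerance = 1e-12)
  expect_equal(fit$pars$shape2, (1 - m) * (m * (1 - m) / v - 1),
               tolerance = 1e-12)
  a <- fit$pars$shape1; b <- fit$pars$shape2
  expect_equal(a / (a + b), m, tolerance = 1e-9)
  expect_equal(a * b / ((a + b)^2 * (a + b + 1)), v, tolerance = 1e-9)

  gam <- fit_distribution(param_estimate(canon, "cost_hosp_cd"))
  expect_identical(gam$family, "gamma")
  expect_equal(gam$pars$shape / gam$pars$rate, 9389, tolerance = 1e-9)
  expect_equal(gam$pars$shape / gam$pars$rate^2,
               ((10797 - 7981) / 3.92)^2, tolerance = 1e-9)
})

test_that("lognormal fits anchor the natural-scale median at base", {
  fit <- fit_distribution(param_estimate(canon, "rr_tm"))
  expect_identical(fit$family, "lognormal")
  expect_equal(exp(fit$pars$meanlog), 0.364, tolerance = 1e-12)
  expect_equal(fit$pars$sdlog, (log(0.419) - log(0.310)) / 3.92,
               tolerance = 1e-12)
  set.seed(31)
  x <- sample_distribution(fit, 40000)
  expect_true(all(x > 0))
  expect_equal(median(x), 0.364, tolerance = 0.01)
})

test_that("degenerate and infeasible fits are handled", {
  # zero-width published range collapses to a point mass
  fit <- fit_distribution(param_estimate(canon, "m_uc"))
  expect_identical(fit$family, "point")
  expect_identical(sample_distribution(fit, 5), rep(0.003, 5))
  # beta moment fit infeasible when sd^2 >= mean(1-mean)
  expect_error(
    fit_distribution(parameter_estimate("p_avoid", 0.02, 0, 0.9, "beta")),
    "infeasible for 'p_avoid'")
})

test_that("sampled parameter means (medians for lognormal) recover base", {
  psa <- run_psa(canon, default_strategies(), n_draws = 4000, seed = 11)
  for (nm in c("h_uc", "p_comply", "cost_hosp_cd", "tm_encounters")) {
    x <- psa$draws[, nm]
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - param_estimate(canon, nm)$base), 3 * se)
  }
  expect_equal(median(psa$draws[, "rr_avoid"]), 1.156, tolerance = 0.005)
})

test_that("identical seeds reproduce the PSA bit-for-bit", {
  a <- run_psa(canon, default_strategies(), n_draws = 200, seed = 99)
  b <- run_psa(canon, default_strategies(), n_draws = 200, seed = 99)
  expect_identical(a$draws, b$draws)
  expect_identical(a$outcomes, b$outcomes)
  expect_identical(a$comparisons, b$comparisons)
  c <- run_psa(canon, default_strategies(), n_draws = 200, seed = 100)
  expect_false(identical(a$draws, c$draws))
})

test_that("a point-mass PSA equals the deterministic base case exactly", {
  pm <- point_mass_params()
  psa <- run_psa(pm, default_strategies(), n_draws = 50, seed = 1)
  strat <- default_strategies()
  for (nm in names(strat)) {
    det <- expected_outcomes(canon, strat[[nm]])
    expect_identical(unique(psa$outcomes$cost[, nm]), det$cost)
    expect_identical(unique(psa$outcomes$qalys[, nm]), det$qalys)
  }
  s <- psa$comparisons$sc_tm_vs_sc$summary
  expect_identical(s$sd_delta_cost, 0)
  expect_identical(s$sd_delta_qalys, 0)
})

test_that("PSA means stay consistent with the deterministic increments", {
  psa <- run_psa(canon, default_strategies(), n_draws = 4000, seed = 17)
  det <- comparison_table(canon)
  for (i in 1:2) {
    s <- psa$comparisons[[i]]$summary
    se_dq <- s$sd_delta_qalys / sqrt(psa$n_draws)
    expect_lt(abs(s$mean_delta_qalys - det$delta_qalys[i]), 3 * se_dq)
    q <- s$quadrants
    expect_equal(sum(q), 1, tolerance = 1e-12)
  }
})

test_that("invalid draws are rejected and redrawn, not clipped", {
  risky <- set_param(canon, "h_cd", 0.98, low = 0.9, high = 0.999,
                     family = "beta")
  psa <- run_psa(risky, default_strategies(), n_draws = 500, seed = 5)
  expect_gt(psa$rejected, 0)
  f <- (psa$draws[, "p_avoid"] * psa$draws[, "rr_avoid"] +
          (1 - psa$draws[, "p_avoid"]))
  expect_true(all(psa$draws[, "h_cd"] * f <= 1))
})

test_that("CE-plane export has one row per draw and carries the WTP slope", {
  psa <- run_psa(canon, default_strategies(), n_draws = 150, seed = 3)
  ce <- ce_plane_export(psa, "sc_tm_vs_sc")
  expect_identical(nrow(ce), 150L)
  expect_identical(attr(ce, "wtp"), 46450)
  expect_identical(ce$delta_cost, unname(psa$comparisons$sc_tm_vs_sc$delta_cost))
  # point-mass run: all scatter rows identical
  ce0 <- ce_plane_export(run_psa(point_mass_params(), default_strategies(),
                                 n_draws = 20, seed = 1), "sc_tm_vs_sc")
  expect_identical(nrow(unique(ce0[, -1])), 1L)
})
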