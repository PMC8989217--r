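test_that("population-average hospitalization multipliers", {
  expect_equal(hospitalization_multiplier(0.261, 1.156),
               0.261 * 1.156 + 0.739, tolerance = 1e-12)
  expect_equal(hospitalization_multiplier(0, 1.156), 1)
  expect_equal(hospitalization_multiplier(1, 1.156), 1.156)
  expect_equal(telemonitoring_multiplier(0.59, 0.364),
               0.59 * 0.364 + 0.41, tolerance = 1e-12)
  expect_equal(telemonitoring_multiplier(0, 0.364), 1)
  expect_equal(telemonitoring_multiplier(1, 0.364), 0.364)
})

test_that("telemonitoring programme cost formula", {
  expect_equal(tm_program_cost(50, 4.76, 0.25, 101), 170.19)
  expect_equal(tm_program_cost(0, 0, 0.25, 101), 0)
  expect_equal(tm_program_cost(58, 5.474, 0.288, 116), 58 + 5.474 * 0.288 * 116)
  expect_equal(tm_program_cost(58, 5.474, 0.288, 116), 240.875, tolerance = 1e-5)
})

test_that("per-disease branch outcomes match hand-expanded arithmetic", {
  sc0 <- strategy(FALSE, FALSE)
  uc <- disease_branch_outcome("uc", 1, canon, sc0)
  # (1-h)*u_out + h*(1-s)*(1-m)*u_hosp + h*s*(1-m)*u_surg at the base values
  expect_equal(uc$qalys,
               (1 - 0.186) * 0.83 + 0.186 * (1 - 0.051) * (1 - 0.003) * 0.55 +
                 0.186 * 0.051 * (1 - 0.003) * 0.40,
               tolerance = 1e-12)
  expect_equal(uc$qalys, 0.776194, tolerance = 1e-6)

  # CD cost: visits+meds+imaging for everyone, endoscopy/ward/surgery/death
  # only with admission
  cd <- disease_branch_outcome("cd", 1, canon, sc0)
  expect_equal(cd$cost,
               1129 + 2894 + 485 +
                 0.225 * (3328 + 9389 + 0.331 * 5534 + 0.018 * 44596),
               tolerance = 1e-12)
  expect_equal(cd$cost, 7962.084, tolerance = 1e-6)
  expect_equal(cd$hosp_per100py, 22.5)
  expect_equal(cd$mort_per100py, 100 * 0.225 * 0.018)
})

test_that("a collapsed tree accrues the single state's utility", {
  p <- set_param(canon, "h_uc", 1)
  p <- set_param(p, "m_uc", 0)
  p <- set_param(p, "u_hosp", 0.6)
  p <- set_param(p, "u_surg", 0.6)
  out <- disease_branch_outcome("uc", 1, p, strategy(FALSE, FALSE))
  expect_equal(out$qalys, 0.6, tolerance = 1e-12)
})

test_that("degenerate utilities and zero mortality give exactly one QALY", {
  p <- canon
  for (u in c("u_out", "u_hosp", "u_surg")) p <- set_param(p, u, 1)
  for (m in c("m_uc", "m_cd")) p <- set_param(p, m, 0)
  for (s in default_strategies())
    expect_equal(expected_outcomes(p, s)$qalys, 1, tolerance = 1e-12)
})

test_that("neutral avoidance parameters make the pandemic arm identical", {
  p <- set_param(canon, "rr_avoid", 1)
  p <- set_param(p, "visit_reduction", 0, family = "point")
  a <- expected_outcomes(p, strategy(FALSE, FALSE))
  b <- expected_outcomes(p, strategy(TRUE, FALSE))
  expect_identical(a$hosp_per100py, b$hosp_per100py)
  expect_identical(a$mort_per100py, b$mort_per100py)
  expect_identical(a$cost, b$cost)
  expect_identical(a$qalys, b$qalys)
})

test_that("outcomes respond monotonically to the avoidance and compliance levers", {
  sc <- strategy(TRUE, FALSE)
  rr_grid <- seq(1.05, 1.329, length.out = 7)
  outs <- lapply(rr_grid, function(r)
    expected_outcomes(set_param(canon, "rr_avoid", r), sc))
  qal <- vapply(outs, `[[`, 0, "qalys")
  cost <- vapply(outs, `[[`, 0, "cost")
  expect_true(all(diff(qal) < 0))
  expect_true(all(diff(cost) > 0))

  tm <- strategy(TRUE, TRUE)
  pc_grid <- seq(0.1, 0.9, length.out = 7)
  outs <- lapply(pc_grid, function(pc)
    expected_outcomes(set_param(canon, "p_comply", pc), tm))
  hosp <- vapply(outs, `[[`, 0, "hosp_per100py")
  qal <- vapply(outs, `[[`, 0, "qalys")
  expect_true(all(diff(hosp) < 0))
  expect_true(all(diff(qal) > 0))
})

test_that("branch weights of the QALY states are conserved", {
  # survivors' three state weights plus the death weight sum to one
  for (d in c("uc", "cd")) {
    v <- base_values(canon)
    h <- v[[paste0("h_", d)]]
    s <- v[[paste0("s_", d)]]
    m <- v[[paste0("m_", d)]]
    w <- c((1 - h), h * (1 - s) * (1 - m), h * s * (1 - m), h * m)
    expect_equal(sum(w), 1, tolerance = 1e-12)
  }
})

test_that("impossible effective probabilities and strategies are rejected", {
  p <- set_param(canon, "h_cd", 0.9)
  expect_error(disease_branch_outcome("cd", 1.2, p, strategy(TRUE, FALSE)),
               "exceeds 1")
  expect_error(strategy(avoidance = FALSE, telemonitoring = TRUE),
               "requires avoidance")
})
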