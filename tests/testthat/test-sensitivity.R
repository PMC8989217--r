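pair_avoid <- list(strategy(FALSE, FALSE), strategy(TRUE, FALSE))
pair_tm <- list(strategy(TRUE, FALSE), strategy(TRUE, TRUE))

test_that("sweeping any parameter for an identical pair gives zero curves", {
  same <- list(strategy(TRUE, FALSE), strategy(TRUE, FALSE))
  sw <- sweep_parameter(canon, "rr_avoid", same, n_grid = 11)
  expect_true(all(sw$delta_cost == 0))
  expect_true(all(sw$delta_qalys == 0))
})

test_that("avoidance loses QALYs over the whole published rr range", {
  sw <- sweep_parameter(canon, "rr_avoid", pair_avoid)
  expect_length(sw$grid, 101)
  expect_true(all(diff(sw$grid) > 0))
  expect_true(all(sw$delta_qalys < 0))
})

test_that("telemonitoring saves cost over the whole compliance range", {
  sw <- sweep_parameter(canon, "p_comply", pair_tm)
  expect_true(all(sw$delta_cost < 0))
  expect_null(sw$thresholds$delta_cost)
})

test_that("sweep curves are stable under grid refinement", {
  fine <- sweep_parameter(canon, "rr_avoid", pair_avoid, n_grid = 101)
  coarse <- sweep_parameter(canon, "rr_avoid", pair_avoid, n_grid = 51)
  shared <- seq(1, 101, by = 2) # every second fine point is a coarse point
  expect_equal(fine$grid[shared], coarse$grid, tolerance = 1e-12)
  expect_equal(fine$delta_cost[shared], coarse$delta_cost, tolerance = 1e-12)
  expect_equal(fine$delta_qalys[shared], coarse$delta_qalys,
               tolerance = 1e-12)
})

test_that("bisection thresholds match the closed-form roots", {
  v <- base_values(canon)
  # weighted all-patient visit cost and hospitalization-linked cost bundle
  V <- v[["p_uc"]] * v[["cost_visit_uc"]] +
    (1 - v[["p_uc"]]) * v[["cost_visit_cd"]]
  bundle <- function(d)
    v[[paste0("h_", d)]] *
      (v[[paste0("cost_endoscopy_", d)]] + v[[paste0("cost_hosp_", d)]] +
         v[[paste0("s_", d)]] * v[[paste0("cost_surgery_", d)]] +
         v[[paste0("m_", d)]] * v[[paste0("cost_death_", d)]])
  H <- v[["p_uc"]] * bundle("uc") + (1 - v[["p_uc"]]) * bundle("cd")

  # incremental cost of avoidance is affine in rr_avoid:
  # p_avoid*(rr-1)*H - p_avoid*visit_reduction*V = 0
  rr_root <- 1 + v[["visit_reduction"]] * V / H
  got <- find_threshold(canon, "rr_avoid", "delta_cost", pair_avoid,
                        interval = c(1, 1.329))
  expect_equal(got, rr_root, tolerance = 1e-5)
  expect_equal(got, 1.095, tolerance = 1e-3)

  # ... and affine in visit_reduction: root = (rr-1)*H/V
  vr_root <- (v[["rr_avoid"]] - 1) * H / V
  got <- find_threshold(canon, "visit_reduction", "delta_cost", pair_avoid,
                        interval = c(0, 1))
  expect_equal(got, vr_root, tolerance = 1e-5)
  expect_equal(got, 0.430, tolerance = 1.5e-3)
})

test_that("no sign change yields no threshold; undefined ICER errors", {
  expect_null(find_threshold(canon, "p_comply", "delta_cost", pair_tm))
  # base case of the telemonitoring comparison is dominant: ICER undefined
  expect_error(find_threshold(canon, "p_comply", "icer_minus_wtp", pair_tm),
               "not finite")
})

test_that("tornado ranks parameters by descending span, point inputs last", {
  tor <- tornado(canon, pair_tm, "nmb")
  expect_identical(nrow(tor), nrow(canon))
  expect_true(all(diff(tor$span) <= 0))
  pts <- canon$name[canon$low == canon$high]
  expect_true(all(tor$span[tor$parameter %in% pts] == 0))
  # every zero-span entry (point inputs, and inputs that cancel between the
  # arms) ranks after every entry with positive span
  expect_lt(max(which(tor$span > 0)), min(which(tor$span == 0)))

  single <- tornado(canon, pair_tm, "nmb", names = "rr_tm")
  expect_identical(nrow(single), 1L)
  expect_identical(single$parameter, "rr_tm")
  expect_gt(single$span, 0)
})
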