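# constraint used throughout: neutrophil-style lower bound N >= 1 on [12, 32]
lower1 <- state_constraint("path", "X", "lower", threshold = 1,
                           window = c(12, 32))

test_that("quadratic path penalty is zero iff feasible and linear in rho", {
  feas <- make_synthetic_observable("constant", value = 2, t0 = 0, tf = 32)
  expect_equal(quadratic_path_penalty(feas, lower1, 10), 0)
  expect_equal(quadratic_path_penalty(feas, lower1, 1e6), 0)

  # g = 1 - 0.5 = 0.5 constant on a window of length 20, rho = 10:
  # rho/2 * 0.5^2 * 20 = 25
  viol <- make_synthetic_observable("constant", value = 0.5, t0 = 0, tf = 32)
  expect_equal(quadratic_path_penalty(viol, lower1, 10), 25, tolerance = 1e-10)
  expect_equal(quadratic_path_penalty(viol, lower1, 100),
               10 * quadratic_path_penalty(viol, lower1, 10),
               tolerance = 1e-12)
})

test_that("point, mean-value and duration penalties follow the rho/2 max(0,g)^2 form", {
  # point: N(tf) >= 3
  con_pt <- state_constraint("point", "X", "lower", threshold = 3,
                             window = 32)
  ok <- make_synthetic_observable("constant", value = 3.5, t0 = 0, tf = 32)
  bad <- make_synthetic_observable("constant", value = 2, t0 = 0, tf = 32)
  expect_equal(point_penalty(ok, con_pt, 1e4), 0)
  expect_equal(point_penalty(bad, con_pt, 1e4), 5000)

  # mean value: S_mean <= 100 on [6, 24]; S constant 110, rho 100 -> 5000
  con_mean <- state_constraint("mean_value", "X", "upper", threshold = 100,
                               window = c(6, 24))
  s110 <- make_synthetic_observable("constant", value = 110, t0 = 0, tf = 24)
  expect_equal(point_penalty(s110, con_mean, 100), 5000, tolerance = 1e-9)

  # duration: at most 5 below 1.5; crossings give tau exactly
  con_dur <- state_constraint("duration", "X", sub_threshold = 1.5,
                              max_duration = 5)
  tau5 <- make_synthetic_observable("crossing", t_down = 10, t_up = 15,
                                    t0 = 0, tf = 32)
  tau7 <- make_synthetic_observable("crossing", t_down = 10, t_up = 17,
                                    t0 = 0, tf = 32)
  never <- make_synthetic_observable("constant", value = 2, t0 = 0, tf = 32)
  expect_equal(duration_penalty(tau5, con_dur, 1e4), 0, tolerance = 1e-6)
  expect_equal(duration_penalty(tau7, con_dur, 1e4), 2e4, tolerance = 1e-6)
  expect_equal(duration_penalty(never, con_dur, 1e4), 0)
})

test_that("mean_value integrates correctly", {
  s100 <- make_synthetic_observable("constant", value = 100, t0 = 0, tf = 24)
  s0 <- make_synthetic_observable("constant", value = 0, t0 = 0, tf = 24)
  lin <- make_synthetic_observable("linear", t0 = 0, tf = 24)
  expect_equal(mean_value(s100, "X", c(6, 24)), 100, tolerance = 1e-12)
  expect_equal(mean_value(s0, "X", c(6, 24)), 0)
  expect_equal(mean_value(lin, "X", c(6, 24)), 15, tolerance = 1e-12)
  expect_error(mean_value(lin, "X", c(6, 6)), "zero-length")
})

test_that("PHR penalty matches its printed form and reduces to the quadratic one", {
  # lambda = 0, g = 0.5 on window length 20, rho = 10 -> 25
  viol <- make_synthetic_observable("constant", value = 0.5, t0 = 0, tf = 32)
  expect_equal(phr_penalty(viol, lower1, NULL, 10), 25, tolerance = 1e-10)

  # lambda = 2, rho = 4, g = -10 on window length 1: max term vanishes,
  # value = -lambda^2/(2 rho) = -0.5
  con01 <- state_constraint("path", "X", "lower", threshold = 1,
                            window = c(0, 1))
  deep <- make_synthetic_observable("constant", value = 11, t0 = 0, tf = 1)
  expect_equal(phr_penalty(deep, con01, 2, 4), -0.5, tolerance = 1e-12)

  # lambda = 2, rho = 4, g = 0: max{0, 2}^2 - 4 = 0
  onb <- make_synthetic_observable("constant", value = 1, t0 = 0, tf = 1)
  expect_equal(phr_penalty(onb, con01, 2, 4), 0, tolerance = 1e-12)

  expect_error(phr_penalty(viol, lower1, -1, 10), "nonnegative")

  # property: lambda = 0 recovers the quadratic penalty on random curves
  set.seed(PROPERTY_SEED)
  for (i in 1:25) {
    tr <- random_synthetic_trajectory(0, 32)
    p_q <- quadratic_path_penalty(tr, lower1, 10)
    p_al <- phr_penalty(tr, lower1, NULL, 10)
    p_al0 <- phr_penalty(tr, lower1, list(times = c(12, 32), values = c(0, 0)),
                         10)
    expect_equal(p_al, p_q, tolerance = 1e-10)
    expect_equal(p_al0, p_q, tolerance = 1e-10)
  }
})

test_that("PFV/rho is a rho-free violation measure", {
  set.seed(PROPERTY_SEED + 1)
  for (i in 1:10) {
    tr <- random_synthetic_trajectory(0, 32)
    p1 <- quadratic_path_penalty(tr, lower1, 13)
    p2 <- quadratic_path_penalty(tr, lower1, 130)
    expect_equal(p1 / 13, p2 / 130, tolerance = 1e-10)
  }
})

test_that("assembled objective decomposes exactly and detects feasibility", {
  ex <- example_problem("tumor_myelo")
  obj <- assemble_objective(ex$problem, penalty_config(1e4),
                            rtol = 1e-8, atol = 1e-10)
  # untreated: neutrophils stay at baseline 7, penalty identically zero,
  # cost is the untreated tumor burden
  b0 <- obj(rep(0, 4))
  expect_equal(unname(b0$PFV), 0)
  expect_gt(b0$CFV, 0)
  expect_true(b0$feasible)
  # the recommended starting dose of 10 per group is feasible
  b10 <- obj(rep(10, 4))
  expect_equal(unname(b10$PFV), 0)
  expect_true(b10$feasible)
  # exact decomposition
  expect_identical(b10$OFV, b10$CFV + sum(b10$PFV))

  b <- obj(rep(60, 4))
  expect_identical(b$OFV, b$CFV + sum(b$PFV))
  expect_gt(b$PFV[["N_path"]], 0)
  expect_false(b$feasible)
})

test_that("cost_value requires the matching quadrature state", {
  tr <- make_synthetic_observable("constant", value = 1, t0 = 0, tf = 32)
  expect_error(cost_value(tr, cost_functional("X", c(12, 32))),
               "quadrature state")
  # point costs read the dense output directly
  expect_equal(cost_value(tr, cost_functional("X", 20, type = "point")), 1)
})
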