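toy_ev <- function(time, amount, kind = "bolus", duration = NA_real_) {
  data.frame(time = time, amount = amount, compartment = 1L, kind = kind,
             duration = duration)
}

test_that("bolus and infusion handling match the closed forms", {
  m <- build_example_model("toy_1cpt")
  tr <- simulate_pkpd(m, toy_ev(0, 100), 0, 24, support_times = 10)
  expect_equal(obs_at(tr, "C", 10), 100 * exp(-1), tolerance = 1e-8)

  tr2 <- simulate_pkpd(m, toy_ev(0, 10, "infusion", 1), 0, 24,
                       support_times = c(0.5, 1, 2))
  expect_equal(tr2$observables[, "C"],
               toy_infusion_C(tr2$times, 10, 1),
               tolerance = 1e-6)
  # concentration is continuous across the infusion end (kink, no jump)
  expect_equal(obs_at(tr2, "C", 1 - 1e-9), obs_at(tr2, "C", 1 + 1e-9),
               tolerance = 1e-6)
})

test_that("doubling all event amounts doubles the concentration pointwise", {
  m <- build_example_model("toy_1cpt")
  ev1 <- toy_ev(c(0, 6), c(50, 30))
  ev2 <- ev1; ev2$amount <- 2 * ev2$amount
  t1 <- simulate_pkpd(m, ev1, 0, 24, support_times = 6)
  t2 <- simulate_pkpd(m, ev2, 0, 24, support_times = 6)
  expect_equal(t2$observables[, "C"], 2 * t1$observables[, "C"],
               tolerance = 1e-6)
})

test_that("augmented quadrature agrees with dense-output trapezoids", {
  m <- build_example_model("toy_1cpt")
  spec <- integral_functional("C", c(2, 20), name = "CF")
  tr <- simulate_pkpd(m, toy_ev(0, 100), 0, 24, functionals = list(spec))
  q_aug <- unname(tr$augmented[["CF"]])
  q_trap <- optidose:::trapz_window(tr, "C", c(2, 20))
  q_exact <- 100 / 0.1 * (exp(-0.1 * 2) - exp(-0.1 * 20))
  expect_equal(q_aug, q_exact, tolerance = 1e-8)
  expect_equal(q_trap, q_aug, tolerance = 1e-4)
})

test_that("halving tolerances leaves quadrature values stable", {
  m <- build_example_model("toy_1cpt")
  spec <- integral_functional("C", name = "CF")
  v <- vapply(c(1e-8, 1e-10), function(rt) {
    tr <- simulate_pkpd(m, toy_ev(0, 100), 0, 24, functionals = list(spec),
                        rtol = rt, atol = rt * 1e-2)
    unname(tr$augmented[["CF"]])
  }, numeric(1))
  expect_equal(v[1], v[2], tolerance = 1e-6)
})

test_that("duration states time threshold undershoots exactly", {
  # synthetic curve with known crossings: below 1.5 on (10, 20) only
  tr <- make_synthetic_observable("crossing", t0 = 0, tf = 32, level = 1.5,
                                  t_down = 10, t_up = 20)
  expect_equal(duration_below(tr$times, tr$observables[, "X"], 1.5), 10,
               tolerance = 1e-9)
  # constants: always below / never below
  lo <- make_synthetic_observable("constant", value = 1.0, t0 = 0, tf = 32)
  hi <- make_synthetic_observable("constant", value = 2.0, t0 = 0, tf = 32)
  expect_equal(duration_below(lo$times, lo$observables[, "X"], 1.5), 32)
  expect_equal(duration_below(hi$times, hi$observables[, "X"], 1.5), 0)

  # within a simulation: C = 100 e^{-ke t} drops below level c at
  # t = log(100/c)/ke and stays below until tf
  m <- build_example_model("toy_1cpt")
  cthr <- 20
  t_cross <- log(100 / cthr) / 0.1
  tr2 <- simulate_pkpd(m, toy_ev(0, 100), 0, 24,
                       functionals = list(duration_state("C", cthr)))
  expect_equal(unname(tr2$augmented[["tau"]]), 24 - t_cross,
               tolerance = 2e-2)
  # smoothed surrogate approaches the exact value
  tr3 <- simulate_pkpd(m, toy_ev(0, 100), 0, 24,
                       functionals = list(duration_state("C", cthr,
                                                         smoothing_eps = 0.01)))
  expect_equal(unname(tr3$augmented[["tau"]]), 24 - t_cross,
               tolerance = 5e-2)
})

test_that("simulation rejects malformed requests", {
  m <- build_example_model("toy_1cpt")
  expect_error(simulate_pkpd(m, toy_ev(30, 10), 0, 24), "outside")
  expect_error(
    simulate_pkpd(m, NULL, 0, 24,
                  functionals = list(integral_functional("C", c(-5, 10)))),
    "window")
  # trajectory export round-trips through CSV
  tr <- simulate_pkpd(m, toy_ev(0, 10), 0, 24)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  tab <- read.csv(f)
  expect_equal(tab$TIME, tr$times)
  expect_equal(tab$C, unname(tr$observables[, "C"]))
})
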