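test_that("dose expansion maps groups to amounts and preserves times", {
  ex <- example_problem("tumor_myelo")
  sc <- ex$problem$scenario
  expect_equal(nrow(sc$records), 16L)
  expect_equal(sc$records$group, rep(1:4, each = 4))

  D <- c(141.2, 42.9, 89.1, 71.2)
  ev <- expand_doses(D, sc)
  expect_equal(nrow(ev), 16L)
  expect_equal(ev$amount, rep(D, each = 4))
  expect_equal(ev$time, sc$records$time)

  # single-record identity
  sc1 <- dosing_scenario(dose_record(0, group = 1L), 0, 10,
                         mode = "optimize_doses", m = 1L,
                         D_min = 0, D_max = 100)
  expect_equal(expand_doses(50, sc1)$amount, 50)

  # weekly dose groups: first seven events share the first dose
  bm <- example_problem("biomarker_idr")$problem$scenario
  ev2 <- expand_doses(1:6, bm)
  expect_equal(nrow(ev2), 42L)
  expect_equal(ev2$amount[1:7], rep(1, 7))
  expect_equal(ev2$amount[36:42], rep(6, 7))
})

test_that("dose expansion is linear and conserves total administered amount", {
  set.seed(PROPERTY_SEED)
  sc <- example_problem("biomarker_idr")$problem$scenario
  for (rep in 1:5) {
    D <- runif(sc$m, 0, 20)
    a <- runif(1, 0.1, 3)
    ev <- expand_doses(D, sc)
    ev_scaled <- expand_doses(a * D, sc)
    expect_equal(ev_scaled$amount, a * ev$amount)
    expect_equal(sum(ev$amount),
                 sum(sc$records$bioavailability * D[sc$records$group]))
  }
})

test_that("interval expansion reproduces the lag construction", {
  sc <- example_problem("antibiotic_interval")$problem$scenario
  ev <- expand_intervals(13.06, sc)
  expect_equal(ev$time, c(0, 13.06))
  expect_equal(ev$amount, c(50, 50))
  expect_equal(expand_intervals(12, sc)$time[2], 12)

  # gap exactly theta between the two administrations
  for (th in c(6, 9.5, 20)) {
    tt <- expand_intervals(th, sc)$time
    expect_equal(diff(tt), th)
  }

  # degenerate all-at-zero schedule is allowed but flagged
  ev0 <- expand_intervals(0, sc)
  expect_equal(ev0$time, c(0, 0))
  expect_true(attr(ev0, "degenerate"))

  # administration extending beyond tf is an infeasible scenario
  expect_error(expand_intervals(23.5, sc), "beyond tf")
})

test_that("scenario validation reports invariant violations", {
  sc <- example_problem("tumor_myelo")$problem$scenario
  expect_length(validate_scenario(sc), 0L)

  bad <- sc
  bad$D_min[2] <- bad$D_max[2] + 1
  expect_length(validate_scenario(bad), 1L)
  expect_match(validate_scenario(bad), "D_min > D_max")

  late <- sc
  late$records$time[1] <- sc$tf + 1
  expect_length(validate_scenario(late), 1L)
  expect_match(validate_scenario(late), "outside")

  gap <- sc
  gap$records$group[gap$records$group == 3L] <- 2L
  expect_match(validate_scenario(gap), "not used")

  expect_error(dosing_scenario(dose_record(0), 10, 5,
                               mode = "optimize_doses", m = 1L,
                               D_min = 0, D_max = 1),
               "invalid dosing scenario")
})

test_that("expansion rejects malformed input", {
  sc <- example_problem("tumor_myelo")$problem$scenario
  expect_error(expand_doses(c(1, 2), sc), "m = 4")
  expect_error(expand_doses(c(1, 2, NA, 4), sc), "finite")
  expect_error(expand_intervals(5, sc), "optimize_intervals")
  expect_error(expand_doses(5, example_problem("antibiotic_interval")$problem$scenario),
               "optimize_doses")
  expect_error(dose_record(0, kind = "infusion"), "duration")
  expect_error(dose_record(0, amount = -1), "nonnegative")
})
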