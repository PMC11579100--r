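test_that("bundled example problems are well-formed", {
  for (nm in c("tumor_myelo", "tumor_myelo_final", "tumor_myelo_three",
               "biomarker_idr", "antibiotic_ar", "antibiotic_interval")) {
    ex <- example_problem(nm)
    expect_s3_class(ex$problem, "ocp_problem")
    expect_length(validate_scenario(ex$problem$scenario), 0L)
    expect_true(all(diff(ex$rho_schedule) > 0))
  }
  tm <- example_problem("tumor_myelo")$problem$scenario
  expect_equal(nrow(tm$records), 16L)
  expect_equal(range(tm$records$time), c(12, 27))
  bm <- example_problem("biomarker_idr")$problem$scenario
  expect_equal(nrow(bm$records), 42L)
  expect_equal(bm$records$group, rep(1:6, each = 7))
  ab <- example_problem("antibiotic_ar")$problem$scenario
  expect_equal(ab$records$kind, rep("infusion", 2))
  expect_equal(example_problem("tumor_myelo_three")$problem$constraints[[3]]$kind,
               "duration")
})

test_that("recommended starting doses are feasible", {
  for (nm in c("tumor_myelo", "biomarker_idr", "antibiotic_ar",
               "antibiotic_interval")) {
    ex <- example_problem(nm)
    obj <- assemble_objective(ex$problem, penalty_config(1e4),
                              rtol = 1e-8, atol = 1e-10)
    b <- obj(rep_len(ex$D_init, ex$problem$scenario$m))
    expect_true(b$feasible, label = paste(nm, "start feasible"))
  }
})

test_that("constrained states respond monotonically to dose over the relevant range", {
  # tumor: higher uniform doses suppress neutrophils further
  ex <- example_problem("tumor_myelo")
  obj <- assemble_objective(ex$problem, penalty_config(1e4),
                            rtol = 1e-8, atol = 1e-10)
  minN <- vapply(c(10, 30, 60), function(d) obj(rep(d, 4))$margins[["N_path"]],
                 numeric(1))
  expect_true(all(diff(minN) < 0))

  # biomarker: higher doses push B further below the elevated baseline
  ex2 <- example_problem("biomarker_idr")
  obj2 <- assemble_objective(ex2$problem, penalty_config(1e4),
                             rtol = 1e-8, atol = 1e-10)
  maxB <- vapply(c(2, 6, 12), function(d) obj2(rep(d, 6))$margins[["B_path"]],
                 numeric(1))
  expect_true(all(diff(maxB) < 0))

  # antibiotic: higher doses reduce the mean bacterial count
  ex3 <- example_problem("antibiotic_ar")
  obj3 <- assemble_objective(ex3$problem, penalty_config(1e4),
                             rtol = 1e-8, atol = 1e-10)
  Sm <- vapply(c(20, 40, 80), function(d) obj3(d)$margins[["S_mean"]],
               numeric(1))
  expect_true(all(diff(Sm) < 0))
  # and delaying the second fixed dose lets bacteria regrow
  ex4 <- example_problem("antibiotic_interval")
  obj4 <- assemble_objective(ex4$problem, penalty_config(1e4),
                             rtol = 1e-8, atol = 1e-10)
  Sm4 <- vapply(c(8, 14, 20), function(th) obj4(th)$margins[["S_mean"]],
                numeric(1))
  expect_true(all(diff(Sm4) > 0))
})
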