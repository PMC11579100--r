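test_that("finite-difference gradients are accurate and box-aware", {
  # smooth analytic oracle
  f <- function(x) sin(x[1]) + x[2]^2 + x[1] * x[2]
  gf <- function(x) c(cos(x[1]) + x[2], 2 * x[2] + x[1])
  for (x in list(c(0.3, -1), c(2, 5), c(-1, 0))) {
    expect_equal(finite_difference_gradient(f, x), gf(x), tolerance = 1e-6)
  }
  # constant objective
  expect_equal(finite_difference_gradient(function(x) 42, c(1, 2, 3)),
               c(0, 0, 0))
  # penalized toy objective vs its analytic derivative:
  # OFV(D) = a D + rho/2 max(0, c - k D)^2 with a, k from the closed form
  ke <- 0.1; V <- 1; Tf <- 24; cthr <- 2; rho <- 1e3
  a <- (1 - exp(-ke * Tf)) / (ke * V)
  k <- exp(-ke * Tf) / V
  ofv <- function(D) a * D + rho / 2 * max(0, cthr - k * D)^2
  dofv <- function(D) a - rho * max(0, cthr - k * D) * k
  for (D in c(5, 15, 21, 30)) {
    expect_equal(finite_difference_gradient(ofv, D), dofv(D),
                 tolerance = 1e-5)
  }
  # at a bound the stencil falls back to a one-sided difference
  g <- finite_difference_gradient(function(x) x^2, 1, lower = 1, upper = 2)
  expect_equal(g, 2, tolerance = 1e-5)
})

test_that("penalized solves recover the analytic toy optima", {
  toy <- make_toy_problem("point_constraint_1cpt")
  fit <- solve_penalized(toy$problem, penalty_config(1e5), toy$D_init,
                         control = ctl_fast)
  expect_true(fit$converged)
  expect_equal(unname(fit$D_star), toy$optimum, tolerance = 0.05 / toy$optimum)
  expect_lte(fit$gradient_norm, 1e-4 * (1 + abs(fit$breakdown$OFV)))
  # the constraint is active at the optimum
  expect_equal(unname(fit$margins), 2, tolerance = 1e-2)

  # the path-constrained variant binds at the window end, same optimum;
  # the active region shrinks to a boundary point, so a larger rho is
  # needed for the same accuracy than in the point-constrained case
  toyp <- make_toy_problem("path_constraint_1cpt")
  fitp <- solve_penalized(toyp$problem, penalty_config(1e7), toyp$D_init,
                          control = ctl_fast)
  expect_equal(unname(fitp$D_star), toyp$optimum, tolerance = 0.1 / toyp$optimum)

  # without constraints the AUC is monotone in dose: D* = D_min
  toyu <- make_toy_problem("unconstrained_1cpt")
  fitu <- solve_penalized(toyu$problem, penalty_config(10), toyu$D_init,
                          control = ctl_fast)
  expect_equal(unname(fitu$D_star), toyu$problem$scenario$D_min[1],
               tolerance = 1e-6)

  # interval mode: the trough bound is active at the analytic gap
  toyi <- make_toy_problem("interval_1cpt")
  fiti <- solve_penalized(toyi$problem, penalty_config(1e5), toyi$D_init,
                          control = ctl_fast)
  expect_equal(unname(fiti$D_star), toyi$optimum, tolerance = 0.05 / toyi$optimum)
})

test_that("infeasible starting doses trigger the recommended warning", {
  toy <- make_toy_problem("point_constraint_1cpt")
  expect_warning(
    solve_penalized(toy$problem, penalty_config(1e4), 6,
                    control = list(rtol = 1e-8, atol = 1e-10, maxit = 2)),
    "infeasible")
})

test_that("continuation warm-starts and is invariant for inactive constraints", {
  # make the constraint trivially slack: every dose in the box satisfies it
  toy <- make_toy_problem("point_constraint_1cpt")
  toy$problem$constraints[[1]]$threshold <- 0.01
  path <- continuation(toy$problem, c(10, 100, 1000), toy$D_init,
                       control = ctl_fast)
  D <- vapply(path$fits, function(f) unname(f$D_star), numeric(1))
  expect_equal(D, rep(D[1], 3), tolerance = 1e-8)
  expect_true(all(vapply(path$fits, function(f) sum(f$breakdown$PFV), 1) == 0))
})

test_that("augmented Lagrangian with frozen multipliers equals the penalty method", {
  toy <- make_toy_problem("point_constraint_1cpt")
  sched <- c(100, 1000)
  path_pen <- suppressWarnings(
    continuation(toy$problem, sched, toy$D_init, control = ctl_fast))
  path_al <- augmented_lagrangian(toy$problem, toy$D_init, rho = 100,
                                  outer_iters = 2, rho_factor = 10,
                                  update_multipliers = FALSE,
                                  control = ctl_fast)
  expect_identical(vapply(path_al$fits, function(f) unname(f$D_star),
                          numeric(1)),
                   vapply(path_pen$fits, function(f) unname(f$D_star),
                          numeric(1)))
})

test_that("multiplier updates converge to the analytic Lagrange multiplier", {
  toy <- make_toy_problem("point_constraint_1cpt")
  al <- augmented_lagrangian(toy$problem, toy$D_init, rho = 100,
                             outer_iters = 4, control = ctl_fast)
  lam <- al$lambda[[1]]
  expect_equal(lam, toy$multiplier, tolerance = 1e-2)
  final <- al$fits[[4]]
  expect_equal(unname(final$D_star), toy$optimum, tolerance = 1e-3)
  # a constraint slack from the start keeps its multiplier at zero
  toy$problem$constraints[[1]]$threshold <- 0.01
  al0 <- augmented_lagrangian(toy$problem, toy$D_init, rho = 100,
                              outer_iters = 2, control = ctl_fast)
  expect_equal(al0$lambda[[1]], 0)
})

test_that("the grid oracle corroborates the derivative-based solver", {
  toy <- make_toy_problem("point_constraint_1cpt")
  pen <- penalty_config(1e4)
  fit <- solve_penalized(toy$problem, pen, toy$D_init, control = ctl_fast)
  ora <- grid_oracle(toy$problem, pen, seq(5, 100, by = 2.5),
                     control = ctl_fast)
  expect_lt(abs(unname(fit$D_star) - ora$D_star), 0.1)
  # analytic penalized optimum: a = rho (c - k D) k
  ke <- 0.1; V <- 1; Tf <- 24; cthr <- 2
  a <- (1 - exp(-ke * Tf)) / (ke * V); k <- exp(-ke * Tf) / V
  D_rho <- (cthr - a / (1e4 * k)) / k
  expect_equal(ora$D_star, D_rho, tolerance = 1e-3)
  expect_error(grid_oracle(example_problem("tumor_myelo")$problem, pen, 1:5),
               "at most 2")
})

test_that("feasibility reports name the violators", {
  toy <- make_toy_problem("point_constraint_1cpt")
  fit <- solve_penalized(toy$problem, penalty_config(1e4), toy$D_init,
                         control = ctl_fast)
  rep_ok <- feasibility_report(fit, tolerance = 1)
  expect_true(any(grepl("feasible-within-tolerance", rep_ok)))

  # evaluate far inside the infeasible region
  bad <- solve_penalized(toy$problem, penalty_config(1e4), toy$D_init,
                         control = c(ctl_fast, list(maxit = 1)))
  bad$breakdown$PFV[1] <- 99
  rep_bad <- feasibility_report(bad, tolerance = 1e-3)
  expect_true(any(grepl("INFEASIBLE", rep_bad)))

  un <- make_toy_problem("unconstrained_1cpt")
  fitu <- solve_penalized(un$problem, penalty_config(10), un$D_init,
                          control = c(ctl_fast, list(maxit = 1)))
  expect_match(feasibility_report(fitu), "unconstrained")
})

test_that("the fitted-model interface behaves like a classic R fit", {
  toy <- make_toy_problem("point_constraint_1cpt")
  fit <- solve_penalized(toy$problem, penalty_config(1e4), toy$D_init,
                         control = ctl_fast)
  expect_s3_class(fit, "optidose_fit")
  expect_named(coef(fit), "D1")
  expect_output(print(fit), "optimal doses")
  expect_output(summary(fit), "constraint")
  tr <- predict(fit)
  expect_s3_class(tr, "pkpd_trajectory")
  tr2 <- predict(fit, doses = 30)
  expect_equal(obs_at(tr2, "C", 0), 30, tolerance = 1e-8)
  expect_s3_class(simulate(fit), "pkpd_trajectory")
  grDevices::pdf(NULL)
  on.exit(grDevices::dev.off())
  expect_silent(plot(fit))
  # trace bookkeeping
  expect_equal(nrow(fit$trace), fit$n_evaluations)
  expect_true(all(abs(fit$trace$OFV -
                        (fit$trace$CFV + fit$trace[[4]])) < 1e-12))
})
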