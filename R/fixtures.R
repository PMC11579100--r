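#' Wrap sampled observable values as a trajectory
#'
#' Builds an object satisfying the trajectory contract from explicit
#' observable values on a grid, so that penalty and quadrature operations
#' can be exercised against curves whose integrals are known in closed
#' form.
#'
#' @param times increasing numeric grid.
#' @param values numeric vector (one observable) or named list of vectors.
#' @param name observable name when `values` is a bare vector.
#' @return A `"pkpd_trajectory"` without states or augmented values.
#' @export
synthetic_trajectory <- function(times, values, name = "X") {
  if (!is.list(values)) values <- stats::setNames(list(values), name)
  obs <- do.call(cbind, values)
  colnames(obs) <- names(values)
  new_trajectory(times, obs, model_name = "synthetic")
}

#' Generate a synthetic observable with known analytic properties
#'
#' Three shapes cover the unit-test needs of the penalty and quadrature
#' operations:
#' \describe{
#'   \item{`constant`}{`X(t) = value`; windowed integrals are
#'     `value * length`.}
#'   \item{`linear`}{`X(t) = t`; the mean over `[a, b]` is `(a + b)/2`.}
#'   \item{`crossing`}{piecewise-linear curve that crosses `level` exactly
#'     once downward at `t_down` and once upward at `t_up`, so the time
#'     spent below `level` is exactly `t_up - t_down`.}
#' }
#' The grid always contains the knots, so piecewise-linear quadrature on
#' the returned trajectory is exact.
#'
#' @param spec `"constant"`, `"linear"` or `"crossing"`.
#' @param t0,tf horizon.
#' @param value constant level (`constant`).
#' @param level crossing threshold (`crossing`).
#' @param t_down,t_up crossing times (`crossing`), `t0 < t_down < t_up < tf`.
#' @param hi,lo curve values away from / between the crossings (`crossing`).
#' @param n grid size.
#' @param name observable name.
#' @return A `"pkpd_trajectory"`.
#' @export
make_synthetic_observable <- function(spec = c("constant", "linear",
                                               "crossing"),
                                      t0 = 0, tf = 32, value = 0.5,
                                      level = 1.5, t_down = 10, t_up = 20,
                                      hi = 2.5, lo = 0.5, n = 201L,
                                      name = "X") {
  spec <- match.arg(spec)
  tt <- seq(t0, tf, length.out = n)
  if (spec == "constant") {
    return(synthetic_trajectory(tt, rep(value, n), name))
  }
  if (spec == "linear") {
    return(synthetic_trajectory(tt, tt, name))
  }
  stopifnot(t0 < t_down, t_down < t_up, t_up < tf, lo < level, level < hi)
  mid <- (t_down + t_up) / 2
  knots_t <- c(t0, t_down, mid, t_up, tf)
  knots_v <- c(hi, level, lo, level, hi)
  tt <- sort(unique(c(tt, knots_t)))
  vv <- stats::approx(knots_t, knots_v, xout = tt)$y
  synthetic_trajectory(tt, vv, name)
}

#' Random smooth synthetic trajectory
#'
#' A low-frequency random curve (sum of a few random sinusoids plus a
#' random offset) used by property-style tests that must hold on arbitrary
#' trajectories, e.g. the identity between the augmented-Lagrangian penalty
#' at zero multiplier and the quadratic penalty. Uses the current RNG
#' state; set a seed outside.
#'
#' @param t0,tf horizon.
#' @param n grid size.
#' @param name observable name.
#' @param amplitude scale of the random components.
#' @return A `"pkpd_trajectory"`.
#' @export
random_synthetic_trajectory <- function(t0 = 0, tf = 20, n = 201L,
                                        name = "X", amplitude = 2) {
  tt <- seq(t0, tf, length.out = n)
  k <- 3L
  a <- stats::rnorm(k, sd = amplitude / k)
  ph <- stats::runif(k, 0, 2 * pi)
  fr <- stats::runif(k, 0.5, 2) * 2 * pi / (tf - t0)
  off <- stats::rnorm(1, sd = amplitude / 2)
  vv <- off + Reduce(`+`, lapply(seq_len(k),
                                 function(j) a[j] * sin(fr[j] * tt + ph[j])))
  synthetic_trajectory(tt, vv, name)
}

#' Analytic toy optimal dosing problems
#'
#' Small one-compartment problems whose optimal dose (or interval) and,
#' where meaningful, Lagrange multiplier are known in closed form; these
#' serve as independent oracles for the penalized solver.
#'
#' \describe{
#'   \item{`point_constraint_1cpt`}{minimize the drug AUC over `[0, T]`
#'     subject to `C(T) >= c_min` with a single bolus at `t = 0` on
#'     `toy_1cpt` (`C(t) = D e^{-ke t} / V`). The constraint is active at
#'     the optimum: `D* = c_min V e^{ke T}`; the associated multiplier is
#'     `mu = (1 - e^{-ke T}) e^{ke T} / ke`.}
#'   \item{`path_constraint_1cpt`}{minimize AUC subject to `C(t) >= c_min`
#'     on `[T/2, T]`; `C` decays monotonically, so the path constraint
#'     binds at the right endpoint and `D*` equals the point-constraint
#'     optimum.}
#'   \item{`unconstrained_1cpt`}{no constraint; the AUC is strictly
#'     increasing in the dose, so `D* = D_min`.}
#'   \item{`interval_1cpt`}{two fixed boluses of amount `A`, the second at
#'     the optimized gap `theta`; minimize AUC over `[0, T]` (decreasing in
#'     `theta`) subject to the trough bound `C(T) <= c_max` (increasing in
#'     `theta`): the trough is active and
#'     `theta* = T + log(c_max V / A - e^{-ke T}) / ke`.}
#' }
#'
#' @param kind one of the four problem names above.
#' @return List with `problem` (an [ocp_problem()]), `optimum` (closed-form
#'   `D*`/`theta*`), `multiplier` (or `NA`), a feasible `D_init`, and a
#'   suggested `rho_schedule`.
#' @export
make_toy_problem <- function(kind = c("point_constraint_1cpt",
                                      "path_constraint_1cpt",
                                      "unconstrained_1cpt",
                                      "interval_1cpt")) {
  kind <- match.arg(kind)
  model <- build_example_model("toy_1cpt")
  ke <- model$theta[["ke"]]; V <- model$theta[["V"]]
  Tf <- 24
  if (kind == "interval_1cpt") {
    A <- 10; c_max <- 5
    rec <- rbind(dose_record(0, amount = A, group = 1L),
                 dose_record(0, amount = A, group = 2L))
    sc <- dosing_scenario(rec, 0, Tf, mode = "optimize_intervals", m = 1L,
                          D_min = 1, D_max = 20, time_unit = "h")
    prob <- ocp_problem(model, sc,
                        cost_functional("C", c(0, Tf)),
                        state_constraint("point", "C", "upper",
                                         threshold = c_max, window = Tf),
                        name = "toy interval")
    theta_star <- Tf + log(c_max * V / A - exp(-ke * Tf)) / ke
    return(list(problem = prob, optimum = theta_star, multiplier = NA_real_,
                D_init = 8, rho_schedule = c(10, 1e3, 1e5)))
  }
  rec <- dose_record(0, group = 1L)
  sc <- dosing_scenario(rec, 0, Tf, mode = "optimize_doses", m = 1L,
                        D_min = 5, D_max = 100, time_unit = "h")
  cost <- cost_functional("C", c(0, Tf))
  if (kind == "unconstrained_1cpt") {
    prob <- ocp_problem(model, sc, cost, list(), name = "toy unconstrained")
    return(list(problem = prob, optimum = sc$D_min[1], multiplier = 0,
                D_init = 50, rho_schedule = c(10, 1e3)))
  }
  c_min <- 2
  con <- if (kind == "point_constraint_1cpt") {
    state_constraint("point", "C", "lower", threshold = c_min, window = Tf)
  } else {
    state_constraint("path", "C", "lower", threshold = c_min,
                     window = c(Tf / 2, Tf))
  }
  prob <- ocp_problem(model, sc, cost, con, name = paste("toy", kind))
  D_star <- c_min * V * exp(ke * Tf)
  mu <- (1 - exp(-ke * Tf)) * exp(ke * Tf) / ke
  list(problem = prob, optimum = D_star, multiplier = mu, D_init = 40,
       rho_schedule = c(10, 1e3, 1e5))
}
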