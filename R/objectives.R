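#' Define a cost functional
#'
#' The secondary target of the dosing task, minimized subject to the state
#' constraints: either the integral of an observable over a window (e.g.
#' tumor-weight burden, drug AUC) or an observable value at a single time.
#'
#' @param observable name of a model observable.
#' @param window numeric `c(a, b)` (for `type = "point"`, `a = b`).
#' @param type `"integral"` or `"point"`.
#' @return An object of class `"cost_functional"`.
#' @export
cost_functional <- function(observable, window,
                            type = c("integral", "point")) {
  type <- match.arg(type)
  if (length(window) == 1) window <- c(window, window)
  stopifnot(window[1] <= window[2])
  structure(list(observable = observable, window = as.numeric(window),
                 type = type), class = "cost_functional")
}

#' Define a state constraint
#'
#' All constraints are normalized internally to the form `g <= 0`: a lower
#' bound `obs >= threshold` becomes `g = threshold - obs`, an upper bound
#' `obs <= threshold` becomes `g = obs - threshold`. Four kinds are
#' supported:
#' \describe{
#'   \item{`path`}{`g(y(t)) <= 0` for all `t` in `window` (e.g. neutrophils
#'     `N >= 1` throughout treatment, or biomarker `B <= B_tar` after day 14).}
#'   \item{`point`}{`g` at the single time `window[1]` (e.g. `N(tf) >= 3`).}
#'   \item{`mean_value`}{the running mean of the observable over `window`
#'     bounded by `threshold` (e.g. mean bacterial count `<= 100`).}
#'   \item{`duration`}{the total time the observable spends below
#'     `sub_threshold` within `window` must not exceed `max_duration`
#'     (e.g. at most 5 days of neutrophils below 1.5).}
#' }
#'
#' @param kind one of `"path"`, `"point"`, `"mean_value"`, `"duration"`.
#' @param observable name of a model observable.
#' @param direction `"lower"` (observable must stay above `threshold`) or
#'   `"upper"` (below); ignored for `kind = "duration"`, which is always an
#'   upper bound on the accumulated duration.
#' @param threshold finite scalar (for `duration`, use `max_duration`).
#' @param window numeric `c(t1, t2)`; a scalar for point constraints;
#'   `NULL` for `duration` means the full horizon.
#' @param max_duration maximal allowed duration (`duration` kind only).
#' @param sub_threshold level whose undershoot is timed (`duration` kind).
#' @param smoothing_eps smoothing width handed to [duration_state()]
#'   (`duration` kind; 0 = exact crossing detection).
#' @param name label used in reports; autogenerated if `NULL`.
#' @return An object of class `"ocp_constraint"`.
#' @export
state_constraint <- function(kind = c("path", "point", "mean_value",
                                      "duration"),
                             observable,
                             direction = c("lower", "upper"),
                             threshold = NA_real_, window = NULL,
                             max_duration = NULL, sub_threshold = NULL,
                             smoothing_eps = 0, name = NULL) {
  kind <- match.arg(kind)
  direction <- match.arg(direction)
  if (kind == "duration") {
    stopifnot(is.numeric(max_duration), is.numeric(sub_threshold))
    direction <- "upper"
    threshold <- max_duration
  } else {
    stopifnot(is.finite(threshold))
  }
  if (!is.null(window)) {
    if (length(window) == 1) window <- c(window, window)
    stopifnot(window[1] <= window[2])
  }
  if (kind %in% c("path", "mean_value") &&
      (is.null(window) || window[1] >= window[2])) {
    if (kind == "mean_value") stop("mean_value needs a window of positive length",
                                   call. = FALSE)
    stop("path constraints need a window [t1, t2] with t1 < t2", call. = FALSE)
  }
  if (kind == "point" && is.null(window)) {
    stop("point constraints need a time", call. = FALSE)
  }
  if (is.null(name)) {
    name <- switch(kind,
                   path = sprintf("%s_%s_%g", observable, direction, threshold),
                   point = sprintf("%s_at_%g", observable, window[1]),
                   mean_value = sprintf("%s_mean", observable),
                   duration = sprintf("%s_below_%g", observable, sub_threshold))
  }
  structure(list(kind = kind, observable = observable, direction = direction,
                 threshold = as.numeric(threshold),
                 window = if (is.null(window)) NULL else as.numeric(window),
                 max_duration = if (is.null(max_duration)) NULL else
                   as.numeric(max_duration),
                 sub_threshold = if (is.null(sub_threshold)) NULL else
                   as.numeric(sub_threshold),
                 smoothing_eps = smoothing_eps, name = name),
            class = "ocp_constraint")
}

# signed constraint function g(x) <= 0 applied to an observable value
g_of <- function(con) {
  th <- con$threshold
  if (con$direction == "lower") function(x) th - x else function(x) x - th
}

#' Penalty configuration
#'
#' Holds the penalty parameters: one `rho > 0` per constraint (recycled from
#' a scalar), an optional increasing continuation schedule, and optional
#' multiplier functions `lambda` (one per constraint, all-zero by default)
#' for the augmented-Lagrangian penalty. For path constraints `lambda` is a
#' piecewise-linear function given by `list(times, values)` on the
#' constraint window; for point-like constraints it is a scalar.
#'
#' @param rho positive scalar or vector (one entry per constraint).
#' @param schedule optional strictly increasing numeric vector of `rho`
#'   values for continuation (applied multiplicatively to the per-constraint
#'   ratios if `rho` is a vector).
#' @param lambda optional list of multipliers, `NULL` entries meaning zero.
#' @param feasibility_tol PFV level below which a constraint counts as
#'   satisfied in reports.
#' @return An object of class `"penalty_config"`.
#' @export
penalty_config <- function(rho = 1e4, schedule = NULL, lambda = NULL,
                           feasibility_tol = 1e-2) {
  stopifnot(all(rho > 0))
  if (!is.null(schedule)) {
    stopifnot(all(diff(schedule) > 0), all(schedule > 0))
  }
  structure(list(rho = rho, schedule = schedule, lambda = lambda,
                 feasibility_tol = feasibility_tol),
            class = "penalty_config")
}

# evaluate a lambda spec at times tt (piecewise linear; scalar/NULL allowed)
lambda_at <- function(lambda, tt) {
  if (is.null(lambda)) return(rep(0, length(tt)))
  if (is.numeric(lambda) && length(lambda) == 1) return(rep(lambda, length(tt)))
  v <- stats::approx(lambda$times, lambda$values, xout = tt, rule = 2)$y
  v
}

check_lambda <- function(lambda) {
  vals <- if (is.null(lambda)) 0 else if (is.numeric(lambda)) lambda
          else lambda$values
  if (any(vals < 0)) stop("multiplier lambda must be nonnegative",
                          call. = FALSE)
  invisible(TRUE)
}

# ---- evaluation on trajectories --------------------------------------------

#' Cost function value of a trajectory
#'
#' Reads the cost quadrature state `CF` accumulated during simulation
#' (integral cost), or evaluates the observable at the cost time point.
#'
#' @param traj a `"pkpd_trajectory"`.
#' @param cost a [cost_functional()].
#' @return Scalar CFV.
#' @export
cost_value <- function(traj, cost) {
  if (cost$type == "point") {
    return(obs_at(traj, cost$observable, cost$window[1]))
  }
  if (!"CF" %in% names(traj$augmented)) {
    stop("trajectory carries no cost quadrature state 'CF'; simulate with ",
         "the cost functional attached", call. = FALSE)
  }
  unname(traj$augmented[["CF"]])
}

#' Quadratic path-constraint penalty
#'
#' `P = rho/2 * integral over the window of max(0, g)^2 dt`, evaluated from
#' the trajectory's dense observable series by trapezoidal quadrature. This
#' dense-output route is deliberately independent of the augmented
#' quadrature state used inside the optimizer, so the two can cross-check
#' each other.
#'
#' @param traj a `"pkpd_trajectory"` (simulated or synthetic).
#' @param con a path [state_constraint()].
#' @param rho positive penalty parameter.
#' @return Scalar PFV, nonnegative; zero iff the constraint holds almost
#'   everywhere on the window (up to quadrature tolerance).
#' @export
quadratic_path_penalty <- function(traj, con, rho) {
  stopifnot(con$kind == "path", rho > 0)
  g <- g_of(con)
  rho / 2 * trapz_window(traj, con$observable, con$window,
                         transform = function(x) pmax(0, g(x))^2)
}

#' Powell--Hestenes--Rockafellar augmented-Lagrangian penalty
#'
#' `P_AL = 1/(2 rho) * integral of ( max(0, lambda(t) + rho g)^2 -
#' lambda(t)^2 ) dt` over the constraint window. With `lambda = 0` this
#' reduces exactly to the quadratic penalty; with positive multipliers it
#' can be negative where the constraint holds strictly.
#'
#' @param traj a `"pkpd_trajectory"`.
#' @param con a path [state_constraint()].
#' @param lambda multiplier: `NULL`/scalar or `list(times, values)`
#'   interpolated piecewise-linearly on the window; must be nonnegative.
#' @param rho positive penalty parameter.
#' @return Scalar penalty value (may be negative).
#' @export
phr_penalty <- function(traj, con, lambda, rho) {
  stopifnot(con$kind == "path", rho > 0)
  check_lambda(lambda)
  g <- g_of(con)
  w <- con$window
  t1 <- max(w[1], traj$t0); t2 <- min(w[2], traj$tf)
  idx <- traj$times > t1 & traj$times < t2
  tt <- c(t1, traj$times[idx], t2)
  gg <- g(obs_at(traj, con$observable, tt))
  ll <- lambda_at(lambda, tt)
  vv <- (pmax(0, ll + rho * gg)^2 - ll^2) / (2 * rho)
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Mean value of an observable over a window
#'
#' @param traj a `"pkpd_trajectory"`.
#' @param observable observable name.
#' @param window numeric `c(a, b)` with `a < b`.
#' @return The window integral divided by the window length.
#' @export
mean_value <- function(traj, observable, window) {
  if (diff(window) <= 0) stop("mean over a zero-length window", call. = FALSE)
  trapz_window(traj, observable, window) / diff(window)
}

# scalar constraint quantity: point value, mean, or accumulated duration
constraint_quantity <- function(traj, con) {
  switch(con$kind,
         point = obs_at(traj, con$observable, con$window[1]),
         mean_value = mean_value(traj, con$observable, con$window),
         duration = {
           nm <- paste0("TAU_", con$name)
           if (nm %in% names(traj$augmented)) unname(traj$augmented[[nm]])
           else duration_below(traj$times, traj$observables[, con$observable],
                               con$sub_threshold)
         },
         stop("no scalar quantity for kind '", con$kind, "'", call. = FALSE))
}

#' Point-type penalty (point, mean-value and duration constraints)
#'
#' `P = rho/2 * max(0, signed violation)^2`, where the signed violation is
#' `threshold - q` (lower bound) or `q - threshold` (upper bound) and `q`
#' is the constraint's scalar quantity: the observable at the constraint
#' time, its windowed mean, or the accumulated below-threshold duration.
#'
#' @param traj a `"pkpd_trajectory"`.
#' @param con a `point`, `mean_value` or `duration` [state_constraint()].
#' @param rho positive penalty parameter.
#' @return Scalar PFV `>= 0`.
#' @export
point_penalty <- function(traj, con, rho) {
  stopifnot(con$kind %in% c("point", "mean_value", "duration"), rho > 0)
  q <- constraint_quantity(traj, con)
  rho / 2 * max(0, g_of(con)(q))^2
}

#' Duration-constraint penalty
#'
#' Convenience wrapper for `point_penalty()` on a duration constraint:
#' `P = rho/2 * max(0, tau(tf) - max_duration)^2`, with `tau` the time the
#' observable spent below `sub_threshold`.
#'
#' @inheritParams point_penalty
#' @return Scalar PFV `>= 0`.
#' @export
duration_penalty <- function(traj, con, rho) {
  stopifnot(con$kind == "duration")
  point_penalty(traj, con, rho)
}

# worst-case constraint margin on the trajectory (reported to the user):
# for a lower path bound the minimum of the observable over the window, etc.
constraint_margin <- function(traj, con) {
  if (con$kind == "path") {
    w <- con$window
    idx <- traj$times >= w[1] - 1e-12 & traj$times <= w[2] + 1e-12
    vals <- traj$observables[idx, con$observable]
    if (con$direction == "lower") min(vals) else max(vals)
  } else {
    constraint_quantity(traj, con)
  }
}

# ---- objective assembly -----------------------------------------------------

#' Assemble the penalized objective of an optimal dosing problem
#'
#' Returns a function `D -> objective breakdown` that performs exactly one
#' simulation per evaluation: the cost integral and every path-penalty
#' integral ride along as augmented quadrature states, point-like penalties
#' are evaluated from the dense solution, and the objective function value
#' is `OFV = CFV + sum of PFVs`.
#'
#' @param problem an [ocp_problem()].
#' @param penalty a [penalty_config()]; its `lambda` entries switch a path
#'   constraint to the augmented-Lagrangian penalty (all-`NULL` lambdas give
#'   the pure quadratic penalty).
#' @param rtol,atol,grid_points simulation controls, see [simulate_pkpd()].
#' @param keep_trajectory if `TRUE` the full trajectory is attached to each
#'   breakdown (used for reporting; the optimizer leaves it off).
#' @return A function of the dose (or interval) vector returning a list with
#'   `CFV`, `PFV` (named), `PFV_over_rho`, `OFV`, `margins`, `feasible` and
#'   optionally `trajectory`.
#' @export
assemble_objective <- function(problem, penalty, rtol = 1e-10, atol = 1e-12,
                               grid_points = 200L, keep_trajectory = FALSE) {
  sc <- problem$scenario
  cons <- problem$constraints
  k <- length(cons)
  rho <- rep_len(penalty$rho, max(k, 1L))
  lambda <- penalty$lambda
  if (is.null(lambda)) lambda <- vector("list", k)

  specs <- list()
  support <- numeric()
  if (problem$cost$type == "integral") {
    specs <- c(specs, list(integral_functional(problem$cost$observable,
                                               problem$cost$window,
                                               name = "CF")))
  } else {
    support <- c(support, problem$cost$window[1])
  }
  for (i in seq_len(k)) {
    con <- cons[[i]]
    if (con$kind == "path") {
      g <- g_of(con)
      r <- rho[i]
      li <- lambda[[i]]
      check_lambda(li)
      if (is.null(li)) {
        tr <- local({
          gi <- g; ri <- r
          function(x) ri / 2 * pmax(0, gi(x))^2
        })
        specs <- c(specs, list(integral_functional(con$observable, con$window,
                                                   transform = tr,
                                                   name = paste0("PF_", con$name))))
      } else {
        tt2 <- local({
          gi <- g; ri <- r; lam <- li
          function(t, x) {
            l <- lambda_at(lam, t)
            (pmax(0, l + ri * gi(x))^2 - l^2) / (2 * ri)
          }
        })
        sp <- integral_functional(con$observable, con$window,
                                  name = paste0("PF_", con$name))
        sp$time_transform <- tt2
        specs <- c(specs, list(sp))
      }
    } else if (con$kind == "mean_value") {
      specs <- c(specs, list(integral_functional(con$observable, con$window,
                                                 name = paste0("MV_", con$name))))
    } else if (con$kind == "duration") {
      specs <- c(specs, list(duration_state(con$observable, con$sub_threshold,
                                            smoothing_eps = con$smoothing_eps,
                                            name = paste0("TAU_", con$name))))
      if (!is.null(con$window)) support <- c(support, con$window)
    } else if (con$kind == "point") {
      support <- c(support, con$window[1])
    }
  }

  function(D) {
    ev <- if (sc$mode == "optimize_doses") expand_doses(D, sc)
          else expand_intervals(D, sc)
    traj <- simulate_pkpd(problem$model, ev, sc$t0, sc$tf,
                          functionals = specs,
                          support_times = c(sc$support_times, support),
                          rtol = rtol, atol = atol, grid_points = grid_points)
    CFV <- cost_value(traj, problem$cost)
    PFV <- numeric(k)
    margins <- numeric(k)
    nm <- character(k)
    for (i in seq_len(k)) {
      con <- cons[[i]]
      nm[i] <- con$name
      margins[i] <- constraint_margin(traj, con)
      if (con$kind == "path") {
        PFV[i] <- unname(traj$augmented[[paste0("PF_", con$name)]])
      } else if (con$kind == "mean_value") {
        q <- unname(traj$augmented[[paste0("MV_", con$name)]]) / diff(con$window)
        margins[i] <- q
        li <- lambda[[i]]
        PFV[i] <- if (is.null(li)) rho[i] / 2 * max(0, g_of(con)(q))^2
                  else phr_scalar(g_of(con)(q), li, rho[i])
      } else if (con$kind == "duration") {
        q <- unname(traj$augmented[[paste0("TAU_", con$name)]])
        margins[i] <- q
        li <- lambda[[i]]
        PFV[i] <- if (is.null(li)) rho[i] / 2 * max(0, q - con$max_duration)^2
                  else phr_scalar(q - con$max_duration, li, rho[i])
      } else { # point
        q <- obs_at(traj, con$observable, con$window[1])
        margins[i] <- q
        li <- lambda[[i]]
        PFV[i] <- if (is.null(li)) rho[i] / 2 * max(0, g_of(con)(q))^2
                  else phr_scalar(g_of(con)(q), li, rho[i])
      }
    }
    names(PFV) <- nm
    names(margins) <- nm
    out <- list(D = D, CFV = CFV, PFV = PFV, PFV_over_rho = PFV / rho[seq_len(k)],
                OFV = CFV + sum(PFV), margins = margins,
                feasible = all(pmax(PFV, 0) <= penalty$feasibility_tol))
    if (keep_trajectory) out$trajectory <- traj
    out
  }
}

# scalar PHR penalty for point-like constraints
phr_scalar <- function(g, lambda, rho) {
  check_lambda(lambda)
  l <- if (is.null(lambda)) 0 else as.numeric(lambda)[1]
  (max(0, l + rho * g)^2 - l^2) / (2 * rho)
}
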