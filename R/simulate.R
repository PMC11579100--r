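#' Quadrature specification: windowed integral of a transformed observable
#'
#' Describes an augmented quadrature state `y_Q` with
#' `d y_Q/dt = transform(observable(t))` inside the window and 0 outside,
#' `y_Q(t0) = 0`; its value is read at `tf`. This is the mechanism by which
#' cost function values (CFV) and penalty function values (PFV) are computed
#' alongside the model states — the same device as accumulating an AUC from
#' a concentration.
#'
#' @param observable name of a model observable.
#' @param window numeric `c(a, b)` within the horizon; `NULL` means the full
#'   horizon (resolved at simulation time).
#' @param transform scalar function applied to the observable value inside
#'   the window (default identity).
#' @param name name under which the value appears in `trajectory$augmented`.
#' @return A quadrature spec (list) consumed by [simulate_pkpd()].
#' @export
integral_functional <- function(observable, window = NULL,
                                transform = identity, name = NULL) {
  if (!is.null(window)) {
    stopifnot(length(window) == 2, window[1] <= window[2])
  }
  list(kind = "integral", observable = observable, window = window,
       transform = transform,
       name = if (is.null(name)) paste0("int_", observable) else name)
}

#' Quadrature specification: time spent below a threshold
#'
#' The duration state `tau` integrates the indicator of
#' `observable < threshold`: `d tau/dt = 1` while the observable is below
#' the threshold, 0 otherwise. With `smoothing_eps = 0` the indicator is
#' integrated exactly from the dense solution by locating the threshold
#' crossings (piecewise-linear root finding on the reporting grid); with
#' `smoothing_eps > 0` a logistic surrogate
#' `1 / (1 + exp((x - threshold)/eps))` is integrated as a smooth augmented
#' state, which is more forgiving inside a derivative-based optimizer. An
#' area-below-threshold alternative (`integral of max(0, threshold - x)`)
#' is available via [integral_functional()] with
#' `transform = function(x) pmax(0, threshold - x)`.
#'
#' @param observable name of a model observable.
#' @param threshold finite scalar level.
#' @param smoothing_eps nonnegative smoothing width in observable units;
#'   0 selects exact crossing-based integration.
#' @param name name of the resulting augmented value (default `"tau"`).
#' @return A quadrature spec (list) consumed by [simulate_pkpd()].
#' @export
duration_state <- function(observable, threshold, smoothing_eps = 0,
                           name = "tau") {
  stopifnot(is.finite(threshold), smoothing_eps >= 0)
  list(kind = "duration", observable = observable, threshold = threshold,
       eps = smoothing_eps, name = name, window = NULL)
}

#' Build a trajectory object
#'
#' Internal constructor shared by the simulator and by the synthetic
#' trajectories used in tests.
#' @keywords internal
new_trajectory <- function(times, observables, states = NULL,
                           augmented = numeric(), t0 = times[1],
                           tf = times[length(times)], diagnostics = list(),
                           model_name = NA_character_) {
  structure(list(times = times, states = states, observables = observables,
                 augmented = augmented, t0 = t0, tf = tf,
                 diagnostics = diagnostics, model_name = model_name),
            class = "pkpd_trajectory")
}

#' @export
print.pkpd_trajectory <- function(x, ...) {
  cat(sprintf("PK/PD trajectory (%s): %d time points on [%g, %g]\n",
              x$model_name, length(x$times), x$t0, x$tf))
  if (length(x$augmented)) {
    cat("  augmented values at tf:\n")
    for (nm in names(x$augmented)) {
      cat(sprintf("    %-12s %.6g\n", nm, x$augmented[[nm]]))
    }
  }
  invisible(x)
}

#' Simulate a PK/PD model under a resolved administration schedule
#'
#' Integrates the model ODE with `deSolve::lsoda`, restarting at every
#' administration event, infusion endpoint, quadrature-window endpoint and
#' support time, so that discontinuities never fall inside a solver step.
#' A bolus of amount `a` into compartment `k` at time `s` is applied as the
#' state jump `y_k(s+) = y_k(s-) + a`; an infusion contributes the constant
#' rate `amount / duration` to the input vector `u_k` while active.
#' Augmented quadrature states (see [integral_functional()],
#' [duration_state()]) are integrated alongside and reported at `tf`.
#'
#' @param model a [pkpd_model()].
#' @param events `data.frame` of resolved events (`time`, `amount`,
#'   `compartment`, `kind`, `duration`) from [expand_doses()] /
#'   [expand_intervals()], or `NULL` for no dosing.
#' @param t0,tf horizon endpoints.
#' @param functionals list of quadrature specs.
#' @param support_times additional mandatory grid times.
#' @param rtol,atol solver tolerances. The defaults (1e-10, 1e-12) are
#'   deliberately tight: the optimizer differentiates the objective by finite
#'   differences, so quadrature values must be accurate well below the
#'   differencing step.
#' @param grid_points number of reporting-grid points across the horizon
#'   (breakpoints are always added).
#' @return An object of class `"pkpd_trajectory"` with fields `times`,
#'   `states` (matrix), `observables` (matrix), `augmented` (named values
#'   at `tf`), `diagnostics`.
#' @export
simulate_pkpd <- function(model, events, t0, tf, functionals = list(),
                          support_times = numeric(), rtol = 1e-10,
                          atol = 1e-12, grid_points = 200L) {
  stopifnot(t0 < tf, rtol > 0, atol > 0)
  if (is.null(events)) {
    events <- data.frame(time = numeric(), amount = numeric(),
                         compartment = integer(), kind = character(),
                         duration = numeric())
  }
  if (nrow(events) && is.unsorted(events$time)) {
    events <- events[order(events$time), , drop = FALSE]
  }
  if (nrow(events) && (min(events$time) < t0 - 1e-12 ||
                       max(events$time) > tf + 1e-12)) {
    stop("event outside the horizon [t0, tf]", call. = FALSE)
  }
  # resolve windows; split specs into ODE-integrated and post-processed
  for (i in seq_along(functionals)) {
    f <- functionals[[i]]
    if (is.null(f$window)) functionals[[i]]$window <- c(t0, tf)
    w <- functionals[[i]]$window
    if (w[1] < t0 - 1e-9 || w[2] > tf + 1e-9) {
      stop(sprintf("functional '%s': window [%g, %g] outside horizon",
                   f$name, w[1], w[2]), call. = FALSE)
    }
  }
  is_ode_spec <- vapply(functionals, function(f) {
    f$kind == "integral" || (f$kind == "duration" && f$eps > 0)
  }, logical(1))
  ode_specs <- functionals[is_ode_spec]
  post_specs <- functionals[!is_ode_spec]

  n <- model$n
  n_aug <- length(ode_specs)
  theta <- model$theta
  obs_funs <- model$observables

  # mandatory breakpoints
  inf_ev <- events[events$kind == "infusion", , drop = FALSE]
  brk <- c(t0, tf, events$time,
           if (nrow(inf_ev)) inf_ev$time + inf_ev$duration,
           unlist(lapply(functionals, function(f) f$window)),
           support_times)
  brk <- sort(unique(pmin(pmax(brk, t0), tf)))
  brk <- brk[c(TRUE, diff(brk) > 1e-12)]
  grid <- sort(unique(c(brk, seq(t0, tf, length.out = grid_points))))

  # segment-constant environment for the rhs closure
  u_now <- numeric(n)
  rate_active <- logical(n_aug)
  windows <- lapply(ode_specs, function(f) f$window)
  rates <- lapply(ode_specs, function(f) {
    if (f$kind == "integral") {
      obs <- f$observable
      if (!is.null(f$time_transform)) {   # integrand also depends on t
        tr2 <- f$time_transform
        function(t, y) tr2(t, obs_funs[[obs]](y, theta))
      } else {
        tr <- f$transform
        function(t, y) tr(obs_funs[[obs]](y, theta))
      }
    } else { # smoothed duration
      obs <- f$observable; th <- f$threshold; eps <- f$eps
      function(t, y) 1 / (1 + exp((obs_funs[[obs]](y, theta) - th) / eps))
    }
  })
  deriv <- function(t, y, p) {
    yn <- y[seq_len(n)]
    dy <- model$rhs(t, yn, theta, u_now)
    if (n_aug) {
      daug <- numeric(n_aug)
      for (j in seq_len(n_aug)) {
        if (rate_active[j]) daug[j] <- rates[[j]](t, yn)
      }
      list(c(dy, daug))
    } else list(dy)
  }

  y <- c(model$y0(theta), numeric(n_aug))
  rows <- vector("list", length(brk))
  bolus <- events[events$kind == "bolus", , drop = FALSE]
  n_calls <- 0L
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    jb <- which(abs(bolus$time - a) <= 1e-12)
    for (j in jb) {
      k <- bolus$compartment[j]
      y[k] <- y[k] + bolus$amount[j]
    }
    if (nrow(inf_ev)) {
      act <- inf_ev$time <= a + 1e-12 & inf_ev$time + inf_ev$duration >= b - 1e-12
      u_now[] <- 0
      for (j in which(act)) {
        k <- inf_ev$compartment[j]
        u_now[k] <- u_now[k] + inf_ev$amount[j] / inf_ev$duration[j]
      }
    }
    if (n_aug) {
      mid <- (a + b) / 2
      rate_active <- vapply(windows, function(w) mid >= w[1] && mid <= w[2],
                            logical(1))
    }
    tt <- grid[grid >= a - 1e-12 & grid <= b + 1e-12]
    tt[1] <- a; tt[length(tt)] <- b
    sol <- deSolve::lsoda(y, tt, deriv, parms = NULL, rtol = rtol, atol = atol)
    if (nrow(sol) < length(tt) || any(!is.finite(sol[nrow(sol), -1]))) {
      stop(sprintf("integration failed near t = %g (non-finite state or solver error)",
                   sol[nrow(sol), 1]), call. = FALSE)
    }
    n_calls <- n_calls + 1L
    y <- unname(sol[nrow(sol), -1])
    # keep [a, b): the final row of each segment is re-emitted (post-jump)
    # as the first row of the next, keeping the grid strictly increasing
    rows[[i]] <- sol[-nrow(sol), , drop = FALSE]
  }
  last <- matrix(c(tf, y), nrow = 1)
  out <- rbind(do.call(rbind, rows), last)
  times <- out[, 1]
  states <- out[, 1 + seq_len(n), drop = FALSE]
  colnames(states) <- names(model$y0(theta))
  obs <- compute_observables(model, states)

  augmented <- if (n_aug) {
    stats::setNames(y[n + seq_len(n_aug)],
                    vapply(ode_specs, `[[`, "", "name"))
  } else stats::setNames(numeric(0), character(0))
  for (f in post_specs) {      # exact duration states from dense output
    tau <- duration_below(times, obs[, f$observable], f$threshold)
    augmented[f$name] <- tau
  }
  new_trajectory(times, obs, states = states, augmented = augmented,
                 t0 = t0, tf = tf,
                 diagnostics = list(rtol = rtol, atol = atol,
                                    n_segments = n_calls,
                                    grid_points = grid_points),
                 model_name = model$name)
}

#' Time spent below a threshold, from a sampled curve
#'
#' Computes the total time a piecewise-linear interpolant of `values` lies
#' strictly below `threshold`, locating each crossing by linear inverse
#' interpolation within its bracketing interval.
#'
#' @param times increasing numeric vector.
#' @param values numeric vector of the same length.
#' @param threshold scalar.
#' @return Scalar duration in the units of `times`.
#' @export
duration_below <- function(times, values, threshold) {
  stopifnot(length(times) == length(values), length(times) >= 2)
  v <- values - threshold
  tot <- 0
  for (i in seq_len(length(times) - 1L)) {
    dt <- times[i + 1L] - times[i]
    v1 <- v[i]; v2 <- v[i + 1L]
    if (v1 < 0 && v2 < 0) {
      tot <- tot + dt
    } else if (v1 < 0 && v2 >= 0) {
      tot <- tot + dt * v1 / (v1 - v2)
    } else if (v1 >= 0 && v2 < 0) {
      tot <- tot + dt * v2 / (v2 - v1)
    }
  }
  tot
}

#' Interpolate an observable series at arbitrary times
#'
#' @param traj a `"pkpd_trajectory"`.
#' @param observable observable name.
#' @param t numeric times (clamped to the trajectory range).
#' @return Numeric values of the observable at `t` (linear interpolation on
#'   the dense grid).
#' @export
obs_at <- function(traj, observable, t) {
  if (is.null(traj$observables) || !observable %in% colnames(traj$observables)) {
    stop(sprintf("trajectory carries no observable '%s'", observable),
         call. = FALSE)
  }
  stats::approx(traj$times, traj$observables[, observable], xout = t,
                rule = 2)$y
}

#' Trapezoidal integral of an observable over a window
#' @keywords internal
trapz_window <- function(traj, observable, window, transform = identity) {
  t1 <- max(window[1], traj$t0); t2 <- min(window[2], traj$tf)
  idx <- traj$times > t1 & traj$times < t2
  tt <- c(t1, traj$times[idx], t2)
  vv <- transform(obs_at(traj, observable, tt))
  sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
}

#' Export a trajectory as a tidy CSV table
#'
#' Writes one row per grid time with a `TIME` column followed by the state
#' and observable columns, mirroring the save-to-table workflow used to
#' check that penalty values are (close to) zero.
#'
#' @param traj a `"pkpd_trajectory"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(TIME = traj$times)
  if (!is.null(traj$states)) df <- cbind(df, as.data.frame(traj$states))
  df <- cbind(df, as.data.frame(traj$observables))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
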