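#' Define a state-constrained optimal dosing problem
#'
#' Bundles the PK/PD model, the dosing scenario (administration plan, mode
#' and dose box), the cost functional (secondary target) and the state
#' constraints (top-priority targets) into one problem object:
#' minimize `J(D)` over `D_min <= D <= D_max` subject to the model ODE and
#' `g(y(t, D)) <= 0` on the constraint windows.
#'
#' @param model a [pkpd_model()].
#' @param scenario a [dosing_scenario()].
#' @param cost a [cost_functional()].
#' @param constraints list of [state_constraint()] objects (may be empty).
#' @param name optional problem label.
#' @return An object of class `"ocp_problem"`.
#' @export
ocp_problem <- function(model, scenario, cost, constraints = list(),
                        name = model$name) {
  if (inherits(constraints, "ocp_constraint")) constraints <- list(constraints)
  obs <- names(model$observables)
  used <- c(cost$observable,
            vapply(constraints, `[[`, "", "observable"))
  missing <- setdiff(used, obs)
  if (length(missing)) {
    stop("observable(s) not defined by the model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (con in constraints) {
    if (!is.null(con$window) &&
        (con$window[1] < scenario$t0 - 1e-9 ||
         con$window[2] > scenario$tf + 1e-9)) {
      stop(sprintf("constraint '%s': window outside [t0, tf]", con$name),
           call. = FALSE)
    }
  }
  structure(list(model = model, scenario = scenario, cost = cost,
                 constraints = constraints, name = name),
            class = "ocp_problem")
}

#' @export
print.ocp_problem <- function(x, ...) {
  cat(sprintf("Optimal dosing problem '%s'\n", x$name))
  cat(sprintf("  mode: %s, m = %d, horizon [%g, %g] %s\n",
              x$scenario$mode, x$scenario$m, x$scenario$t0, x$scenario$tf,
              x$scenario$time_unit))
  cat(sprintf("  cost: %s of '%s' on [%g, %g]\n", x$cost$type,
              x$cost$observable, x$cost$window[1], x$cost$window[2]))
  for (con in x$constraints) {
    cat(sprintf("  constraint [%s] %s\n", con$kind, con$name))
  }
  invisible(x)
}

default_control <- function(control) {
  utils::modifyList(list(reltol = 1e-5, pgtol = 0, maxit = 200L,
                         fd_step = 1e-6, rtol = 1e-10, atol = 1e-12,
                         grid_points = 200L, quiet = FALSE), control)
}

#' Central finite-difference gradient with box projection
#'
#' Per-coordinate central differences with step
#' `relative_step * max(|x_i|, 1)`; stencil points falling outside the box
#' trigger a one-sided difference from inside, as does a failing objective
#' evaluation at a stencil point.
#'
#' @param f scalar objective function.
#' @param x evaluation point.
#' @param relative_step relative step size.
#' @param lower,upper box bounds (recycled).
#' @return Numeric gradient vector.
#' @export
finite_difference_gradient <- function(f, x, relative_step = 1e-6,
                                       lower = -Inf, upper = Inf) {
  m <- length(x)
  lower <- rep_len(lower, m); upper <- rep_len(upper, m)
  h <- relative_step * pmax(abs(x), 1)
  g <- numeric(m)
  f0 <- NULL
  safe <- function(z) tryCatch(f(z), error = function(e) NA_real_)
  for (i in seq_len(m)) {
    xp <- x; xm <- x
    xp[i] <- min(x[i] + h[i], upper[i])
    xm[i] <- max(x[i] - h[i], lower[i])
    fp <- safe(xp); fm <- safe(xm)
    if (is.na(fp) || xp[i] == x[i]) {           # one-sided backward
      if (is.null(f0)) f0 <- f(x)
      g[i] <- (f0 - fm) / (x[i] - xm[i])
    } else if (is.na(fm) || xm[i] == x[i]) {    # one-sided forward
      if (is.null(f0)) f0 <- f(x)
      g[i] <- (fp - f0) / (xp[i] - x[i])
    } else {
      g[i] <- (fp - fm) / (xp[i] - xm[i])
    }
  }
  g
}

# gradient with components pointing out of the box at active bounds removed
projected_gradient <- function(g, x, lower, upper, tol = 1e-8) {
  at_lo <- x <= lower + tol & g > 0
  at_hi <- x >= upper - tol & g < 0
  g[at_lo | at_hi] <- 0
  g
}

#' Solve one penalized (unconstrained) optimal dosing problem
#'
#' Minimizes `OFV(D) = CFV(D) + sum of PFV(D)` over the dose box with a
#' projected quasi-Newton method (`L-BFGS-B`) and central finite-difference
#' gradients; every objective evaluation is one simulation. Starting from
#' doses whose penalty values are not (close to) zero is allowed but
#' triggers a warning — infeasible starts with large penalties are a known
#' source of numerical difficulties.
#'
#' @param problem an [ocp_problem()].
#' @param penalty a [penalty_config()].
#' @param D_init numeric start vector within the bounds.
#' @param control list of solver controls: `reltol` (relative OFV change at
#'   convergence, default `1e-5`), `maxit`, `fd_step`, simulation `rtol`,
#'   `atol`, `grid_points`, `quiet`.
#' @return An object of class `"optidose_fit"`; see [optidose()].
#' @export
solve_penalized <- function(problem, penalty, D_init, control = list()) {
  ctl <- default_control(control)
  sc <- problem$scenario
  D_init <- rep_len(as.numeric(D_init), sc$m)
  if (any(D_init < sc$D_min - 1e-12 | D_init > sc$D_max + 1e-12)) {
    stop("D_init outside the dose bounds", call. = FALSE)
  }
  obj <- assemble_objective(problem, penalty, rtol = ctl$rtol,
                            atol = ctl$atol, grid_points = ctl$grid_points)
  tr_env <- new.env(parent = emptyenv())
  tr_env$rows <- list(); tr_env$n <- 0L
  fn <- function(D) {
    b <- obj(D)
    tr_env$n <- tr_env$n + 1L
    tr_env$rows[[tr_env$n]] <- c(eval = tr_env$n, D, CFV = b$CFV,
                                 b$PFV, OFV = b$OFV)
    b$OFV
  }
  b0 <- obj(D_init)
  if (length(b0$PFV) && !b0$feasible && !isTRUE(ctl$quiet)) {
    warning(sprintf("initial doses are infeasible (max PFV = %.3g); feasible starts are recommended",
                    max(b0$PFV)), call. = FALSE)
  }
  gr <- function(D) finite_difference_gradient(fn, D, ctl$fd_step,
                                               sc$D_min, sc$D_max)
  run_qn <- function(par0) {
    stats::optim(par0, fn, gr, method = "L-BFGS-B",
                 lower = sc$D_min, upper = sc$D_max,
                 control = list(maxit = ctl$maxit,
                                factr = ctl$reltol / .Machine$double.eps,
                                pgtol = ctl$pgtol))
  }
  best_seen <- function() {
    tr <- do.call(rbind, tr_env$rows)
    i <- which.min(tr[, "OFV"])
    list(D = unname(tr[i, 1 + seq_len(sc$m)]), OFV = tr[i, "OFV"])
  }
  opt <- run_qn(D_init)
  status <- if (opt$convergence == 0) "converged" else "not converged"
  # the line search can terminate abnormally at kinks of the penalty
  # (max{0, g}^2 is C^1 but not C^2); restart once from the best point seen
  if (opt$convergence != 0) {
    bs <- best_seen()
    start2 <- if (bs$OFV < opt$value) bs$D else opt$par
    opt2 <- run_qn(start2)
    gain <- min(opt$value, bs$OFV) - opt2$value
    if (opt2$value <= opt$value) opt <- opt2
    status <- if (opt$convergence == 0) {
      "converged"
    } else if (gain <= ctl$reltol * (1 + abs(opt$value))) {
      # no further progress at the requested relative tolerance
      "converged (line-search stall within tolerance)"
    } else "not converged"
  }
  # never report a worse point than the best evaluated one
  bs <- best_seen()
  if (bs$OFV < opt$value) {
    opt$par <- bs$D
    opt$value <- bs$OFV
  }
  obj_keep <- assemble_objective(problem, penalty, rtol = ctl$rtol,
                                 atol = ctl$atol,
                                 grid_points = ctl$grid_points,
                                 keep_trajectory = TRUE)
  b <- obj_keep(opt$par)
  g <- finite_difference_gradient(fn, opt$par, ctl$fd_step, sc$D_min, sc$D_max)
  pg <- projected_gradient(g, opt$par, sc$D_min, sc$D_max)
  trace <- as.data.frame(do.call(rbind, tr_env$rows))
  nmD <- if (sc$mode == "optimize_doses") paste0("D", seq_len(sc$m))
         else paste0("theta", seq_len(sc$m))
  names(trace)[2:(1 + sc$m)] <- nmD
  structure(list(D_star = stats::setNames(opt$par, nmD),
                 breakdown = b[c("CFV", "PFV", "PFV_over_rho", "OFV")],
                 trajectory = b$trajectory, margins = b$margins,
                 gradient = g, gradient_norm = sqrt(sum(pg^2)),
                 n_evaluations = tr_env$n,
                 converged = startsWith(status, "converged"),
                 status = status,
                 feasible = b$feasible, trace = trace,
                 optim = opt[c("convergence", "message", "counts")],
                 problem = problem, penalty = penalty, control = ctl),
            class = "optidose_fit")
}

#' Penalty continuation: solve a series of problems with increasing rho
#'
#' Solves the penalized problem for each penalty parameter of a strictly
#' increasing schedule, warm-starting every stage from the previous optimum.
#' As `rho` grows the iterates approach the solution of the original
#' state-constrained problem; `PFV / rho` measures the remaining constraint
#' violation on a `rho`-free scale and should tend to zero.
#'
#' @param problem an [ocp_problem()].
#' @param rho_schedule strictly increasing positive vector (e.g.
#'   `c(10, 100, 1000, 1e4)`).
#' @param D_init start vector for the first stage.
#' @param control see [solve_penalized()].
#' @param feasibility_tol forwarded to [penalty_config()].
#' @return An object of class `"optidose_path"`: list of stage fits plus a
#'   `summary` data frame (rho, CFV, PFV, PFV/rho, margins, doses).
#' @export
continuation <- function(problem, rho_schedule, D_init, control = list(),
                         feasibility_tol = 1e-2) {
  stopifnot(length(rho_schedule) >= 1, all(diff(rho_schedule) > 0))
  fits <- vector("list", length(rho_schedule))
  D <- D_init
  ctl <- control
  for (s in seq_along(rho_schedule)) {
    pen <- penalty_config(rho = rho_schedule[s],
                          feasibility_tol = feasibility_tol)
    fit <- tryCatch(solve_penalized(problem, pen, D, ctl),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning(sprintf("continuation stage %d (rho = %g) failed: %s",
                      s, rho_schedule[s], conditionMessage(fit)),
              call. = FALSE)
      fits <- fits[seq_len(s - 1L)]
      return(structure(list(fits = fits, rho_schedule = rho_schedule,
                            completed = s - 1L, failed = TRUE,
                            summary = path_summary(fits, rho_schedule)),
                       class = "optidose_path"))
    }
    fits[[s]] <- fit
    D <- unname(fit$D_star)
    ctl$quiet <- TRUE   # warm starts of later stages may be mildly infeasible
  }
  final <- fits[[length(fits)]]
  wl <- vapply(problem$constraints, function(con) {
    if (!is.null(con$window)) max(diff(con$window), 1) else 1
  }, numeric(1))
  if (length(wl) && any(final$breakdown$PFV_over_rho > 1e-6 * wl)) {
    warning("PFV/rho still above tolerance at the final stage; the penalty parameter needs to be further increased",
            call. = FALSE)
  }
  structure(list(fits = fits, rho_schedule = rho_schedule,
                 completed = length(fits), failed = FALSE,
                 summary = path_summary(fits, rho_schedule)),
            class = "optidose_path")
}

path_summary <- function(fits, rho_schedule) {
  if (!length(fits)) return(data.frame())
  do.call(rbind, lapply(seq_along(fits), function(s) {
    f <- fits[[s]]
    base <- data.frame(rho = rho_schedule[s], CFV = f$breakdown$CFV,
                       PFV = sum(f$breakdown$PFV),
                       PFV_over_rho = sum(f$breakdown$PFV_over_rho))
    if (length(f$margins)) {
      m <- as.data.frame(as.list(f$margins))
      names(m) <- paste0("margin_", names(f$margins))
      base <- cbind(base, m)
    }
    cbind(base, as.data.frame(as.list(f$D_star)))
  }))
}

#' @export
print.optidose_path <- function(x, ...) {
  cat(sprintf("Penalty continuation: %d stage(s)%s\n", x$completed,
              if (isTRUE(x$failed)) " (terminated early)" else ""))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Safeguarded augmented-Lagrangian outer loop
#'
#' Alternates a penalized solve (with the Powell--Hestenes--Rockafellar
#' penalty) and the first-order multiplier update
#' `lambda+ = min(max(0, lambda + rho * g(y(t, D*))), lambda_max)` applied
#' pointwise on each path-constraint window (and to the scalar multiplier
#' of each point-like constraint). With `update_multipliers = FALSE` the
#' multipliers stay at zero and the iterates coincide with the plain
#' penalty method.
#'
#' @param problem an [ocp_problem()].
#' @param D_init start vector.
#' @param rho penalty parameter of the first outer iteration.
#' @param outer_iters number of outer iterations.
#' @param rho_factor multiplicative increase of `rho` per outer iteration
#'   (1 keeps it fixed).
#' @param lambda_max safeguard cap on the multipliers.
#' @param update_multipliers logical; `FALSE` freezes `lambda` at 0.
#' @param lambda_grid_points grid size of the piecewise-linear multiplier
#'   per path-constraint window.
#' @param control see [solve_penalized()].
#' @return An `"optidose_path"` whose elements additionally carry the
#'   multiplier state in `$lambda`.
#' @export
augmented_lagrangian <- function(problem, D_init, rho = 1e2, outer_iters = 5L,
                                 rho_factor = 1, lambda_max = 1e6,
                                 update_multipliers = TRUE,
                                 lambda_grid_points = 51L, control = list()) {
  cons <- problem$constraints
  k <- length(cons)
  lambda <- lapply(cons, function(con) {
    if (con$kind == "path") {
      tt <- seq(con$window[1], con$window[2], length.out = lambda_grid_points)
      list(times = tt, values = numeric(length(tt)))
    } else 0
  })
  all_zero <- function(l) {
    vals <- if (is.numeric(l)) l else l$values
    all(vals == 0)
  }
  fits <- vector("list", outer_iters)
  rhos <- numeric(outer_iters)
  D <- D_init
  r <- rho
  ctl <- control
  for (it in seq_len(outer_iters)) {
    lam <- lambda
    for (i in seq_len(k)) if (all_zero(lam[[i]])) lam[i] <- list(NULL)
    pen <- penalty_config(rho = r, lambda = lam)
    fit <- solve_penalized(problem, pen, D, ctl)
    fit$lambda <- lambda
    fits[[it]] <- fit
    rhos[it] <- r
    D <- unname(fit$D_star)
    ctl$quiet <- TRUE
    if (update_multipliers) {
      traj <- fit$trajectory
      for (i in seq_len(k)) {
        con <- cons[[i]]
        if (con$kind == "path") {
          g <- g_of(con)(obs_at(traj, con$observable, lambda[[i]]$times))
          lambda[[i]]$values <- pmin(pmax(0, lambda[[i]]$values + r * g),
                                     lambda_max)
          if (any(lambda[[i]]$values >= lambda_max)) { # diverging: reset
            lambda[[i]]$values[] <- 0
          }
        } else {
          g <- switch(con$kind,
                      point = g_of(con)(obs_at(traj, con$observable,
                                               con$window[1])),
                      mean_value = g_of(con)(mean_value(traj, con$observable,
                                                        con$window)),
                      duration = constraint_quantity(traj, con) - con$max_duration)
          lambda[[i]] <- min(max(0, lambda[[i]] + r * g), lambda_max)
          if (lambda[[i]] >= lambda_max) lambda[[i]] <- 0
        }
      }
    }
    r <- r * rho_factor
  }
  structure(list(fits = fits, rho_schedule = rhos, completed = outer_iters,
                 failed = FALSE, lambda = lambda,
                 summary = path_summary(fits, rhos)),
            class = "optidose_path")
}

#' Brute-force grid oracle (1 or 2 optimized parameters)
#'
#' Exhaustively evaluates the penalized objective on a grid, then refines
#' the best cell by golden-section search (coordinate-wise in two
#' dimensions). Intended as an independent verification route for the
#' derivative-based solver, not as a production optimizer.
#'
#' @param problem an [ocp_problem()] with `m <= 2`.
#' @param penalty a [penalty_config()].
#' @param grid numeric vector (1-D) or list of two numeric vectors (2-D).
#' @param refine logical; golden-section refinement of the best cell.
#' @param control simulation controls as in [solve_penalized()].
#' @return List with `D_star`, `OFV`, and the evaluated `grid`/`values`.
#' @export
grid_oracle <- function(problem, penalty, grid, refine = TRUE,
                        control = list()) {
  ctl <- default_control(control)
  m <- problem$scenario$m
  if (m > 2) stop("grid_oracle supports at most 2 optimized parameters",
                  call. = FALSE)
  obj <- assemble_objective(problem, penalty, rtol = ctl$rtol,
                            atol = ctl$atol, grid_points = ctl$grid_points)
  f <- function(D) obj(D)$OFV
  if (m == 1) {
    g1 <- if (is.list(grid)) grid[[1]] else grid
    vals <- vapply(g1, function(d) f(d), numeric(1))
    i <- which.min(vals)
    best <- g1[i]; fbest <- vals[i]
    if (refine) {
      lo <- g1[max(i - 1L, 1L)]; hi <- g1[min(i + 1L, length(g1))]
      if (hi > lo) {
        o <- stats::optimize(f, lower = lo, upper = hi, tol = 1e-6 * (hi - lo))
        if (o$objective < fbest) { best <- o$minimum; fbest <- o$objective }
      }
    }
    list(D_star = best, OFV = fbest, grid = g1, values = vals)
  } else {
    stopifnot(is.list(grid), length(grid) == 2)
    g1 <- grid[[1]]; g2 <- grid[[2]]
    vals <- outer(seq_along(g1), seq_along(g2),
                  Vectorize(function(i, j) f(c(g1[i], g2[j]))))
    ij <- arrayInd(which.min(vals), dim(vals))
    best <- c(g1[ij[1]], g2[ij[2]]); fbest <- min(vals)
    if (refine) {
      for (pass in 1:2) {
        for (d in 1:2) {
          gd <- if (d == 1) g1 else g2
          i <- findInterval(best[d], gd)
          lo <- gd[max(i - 1L, 1L)]; hi <- gd[min(i + 1L, length(gd))]
          if (hi > lo) {
            o <- stats::optimize(function(z) {
              D <- best; D[d] <- z; f(D)
            }, lower = lo, upper = hi, tol = 1e-6 * (hi - lo))
            if (o$objective < fbest) { best[d] <- o$minimum; fbest <- o$objective }
          }
        }
      }
    }
    list(D_star = best, OFV = fbest, grid = grid, values = vals)
  }
}

#' Per-constraint feasibility report
#'
#' Summarizes, for a solved problem, each constraint's penalty value,
#' `PFV / rho`, worst margin over its window (e.g. the minimum neutrophil
#' level) and a feasibility verdict; the largest violator is named when the
#' solution is infeasible.
#'
#' @param fit an `"optidose_fit"`.
#' @param tolerance PFV level counting as satisfied (defaults to the fit's
#'   penalty configuration).
#' @return Character vector of report lines (also printed), invisibly.
#' @export
feasibility_report <- function(fit, tolerance = NULL) {
  if (is.null(tolerance)) tolerance <- fit$penalty$feasibility_tol
  cons <- fit$problem$constraints
  if (!length(cons)) {
    lines <- "no state constraints: unconstrained problem"
    cat(lines, "\n")
    return(invisible(lines))
  }
  PFV <- fit$breakdown$PFV
  lines <- character()
  for (i in seq_along(cons)) {
    con <- cons[[i]]
    verdict <- if (PFV[i] <= tolerance) "feasible-within-tolerance" else "VIOLATED"
    lines <- c(lines, sprintf(
      "constraint '%s' [%s]: PFV = %.4g, PFV/rho = %.4g, margin = %.4f (threshold %g) -> %s",
      con$name, con$kind, PFV[i], fit$breakdown$PFV_over_rho[i],
      fit$margins[i],
      if (con$kind == "duration") con$max_duration else con$threshold,
      verdict))
  }
  if (any(PFV > tolerance)) {
    worst <- cons[[which.max(PFV)]]$name
    lines <- c(lines, sprintf("verdict: INFEASIBLE; largest violator: '%s'",
                              worst))
  } else {
    lines <- c(lines, "verdict: all state constraints satisfied within tolerance")
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

# ---- main fitting interface -------------------------------------------------

#' Compute optimal doses (or dosing intervals) for a PK/PD problem
#'
#' The main fitting function: transforms the state-constrained optimal
#' dosing problem into box-constrained minimization of
#' `OFV(D) = CFV(D) + sum of PFV(D)` and solves it. With a `schedule`, a
#' penalty continuation is run (each stage warm-started from the previous
#' optimum) and the final stage is returned with the whole path attached in
#' `$path`; with a single `rho` one penalized solve is performed;
#' `method = "augmented_lagrangian"` runs the safeguarded multiplier loop.
#'
#' @param problem an [ocp_problem()], e.g. from [example_problem()] or
#'   [read_problem_config()].
#' @param D_init starting doses; feasible starts (penalty values of zero)
#'   are recommended. Defaults to the midpoint of the bounds.
#' @param rho penalty parameter for a single solve.
#' @param schedule optional increasing vector of penalty parameters for
#'   continuation.
#' @param method `"penalty"` (default; continuation when `schedule` is
#'   given) or `"augmented_lagrangian"`.
#' @param control solver/simulation controls, see [solve_penalized()].
#' @param ... passed to [augmented_lagrangian()] when selected.
#' @return An object of class `"optidose_fit"` with components `D_star`
#'   (optimal doses), `breakdown` (`CFV`, per-constraint `PFV`,
#'   `PFV_over_rho`, `OFV`), `margins`, `gradient_norm`, `feasible`,
#'   `converged`, `trace`, `trajectory`, and methods `print()`, `summary()`,
#'   `coef()`, `predict()`, `plot()`, `simulate()`.
#' @examples
#' \donttest{
#' toy <- make_toy_problem("point_constraint_1cpt")
#' fit <- optidose(toy$problem, D_init = toy$D_init, schedule = c(10, 1e3, 1e5))
#' coef(fit)        # close to toy$optimum
#' }
#' @export
optidose <- function(problem, D_init = NULL, rho = 1e4, schedule = NULL,
                     method = c("penalty", "augmented_lagrangian"),
                     control = list(), ...) {
  method <- match.arg(method)
  sc <- problem$scenario
  if (is.null(D_init)) D_init <- (sc$D_min + sc$D_max) / 2
  if (method == "augmented_lagrangian") {
    path <- augmented_lagrangian(problem, D_init, rho = rho,
                                 control = control, ...)
    fit <- path$fits[[path$completed]]
    fit$path <- path
    return(fit)
  }
  if (!is.null(schedule) && length(schedule) > 1) {
    path <- continuation(problem, schedule, D_init, control = control)
    if (!path$completed) stop("all continuation stages failed", call. = FALSE)
    fit <- path$fits[[path$completed]]
    fit$path <- path
    fit
  } else {
    if (!is.null(schedule)) rho <- schedule[1]
    solve_penalized(problem, penalty_config(rho = rho), D_init, control)
  }
}

#' @export
print.optidose_fit <- function(x, digits = 4, ...) {
  sc <- x$problem$scenario
  what <- if (sc$mode == "optimize_doses") "doses" else "interval parameters"
  cat(sprintf("Optimal dosing fit '%s' (%s)\n", x$problem$name, sc$mode))
  cat(sprintf("  optimal %s: %s\n", what,
              paste(sprintf("%s = %.*g", names(x$D_star), digits, x$D_star),
                    collapse = ", ")))
  cat(sprintf("  CFV = %.*g", digits, x$breakdown$CFV))
  if (length(x$breakdown$PFV)) {
    cat(sprintf(", sum PFV = %.*g", digits, sum(x$breakdown$PFV)))
  }
  cat(sprintf(", OFV = %.*g\n", digits, x$breakdown$OFV))
  cat(sprintf("  %s, %s; projected gradient norm %.3g; %d evaluations\n",
              x$status, if (x$feasible) "feasible" else "infeasible",
              x$gradient_norm, x$n_evaluations))
  invisible(x)
}

#' @export
summary.optidose_fit <- function(object, ...) {
  print(object)
  if (length(object$problem$constraints)) feasibility_report(object)
  invisible(object)
}

#' @export
coef.optidose_fit <- function(object, ...) object$D_star

#' Simulate the fitted (or alternative) dosing regimen
#'
#' @param object an `"optidose_fit"`.
#' @param doses dose vector to simulate (defaults to the optimum).
#' @param ... passed to [simulate_pkpd()].
#' @return A `"pkpd_trajectory"`.
#' @export
predict.optidose_fit <- function(object, doses = NULL, ...) {
  sc <- object$problem$scenario
  if (is.null(doses)) doses <- unname(object$D_star)
  ev <- if (sc$mode == "optimize_doses") expand_doses(doses, sc)
        else expand_intervals(doses, sc)
  simulate_pkpd(object$problem$model, ev, sc$t0, sc$tf,
                support_times = sc$support_times, ...)
}

#' @export
simulate.optidose_fit <- function(object, nsim = 1, seed = NULL, ...) {
  predict.optidose_fit(object, ...)
}

#' Plot the fitted trajectories against the constraint thresholds
#'
#' One panel per observable referenced by the cost or a constraint, with
#' horizontal threshold lines and shaded constraint windows.
#'
#' @param x an `"optidose_fit"`.
#' @param ... passed to [predict.optidose_fit()].
#' @export
plot.optidose_fit <- function(x, ...) {
  traj <- if (!is.null(x$trajectory)) x$trajectory else predict(x, ...)
  cons <- x$problem$constraints
  obs_names <- unique(c(x$problem$cost$observable,
                        vapply(cons, `[[`, "", "observable")))
  old <- graphics::par(mfrow = c(length(obs_names), 1),
                       mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (ob in obs_names) {
    graphics::plot(traj$times, traj$observables[, ob], type = "l",
                   xlab = sprintf("time [%s]", x$problem$scenario$time_unit),
                   ylab = ob, main = ob)
    for (con in cons) {
      if (con$observable == ob && con$kind %in% c("path", "point",
                                                  "mean_value")) {
        graphics::abline(h = con$threshold, col = 2, lty = 2)
      }
      if (con$observable == ob && con$kind == "duration") {
        graphics::abline(h = con$sub_threshold, col = 2, lty = 3)
      }
    }
  }
  invisible(x)
}
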