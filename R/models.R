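#' Define a PK/PD model
#'
#' A model is an ODE system `dy/dt = f(t, y, theta, u)` on a fixed horizon,
#' with a parameter set `theta` that stays fixed during optimization, an
#' initial-state function `y0(theta)`, and named scalar observables (e.g.
#' a concentration, a neutrophil count, a tumor weight) defined on every
#' state. Drug input enters two ways: boluses are instantaneous state jumps
#' applied by the simulator, and active infusions contribute a zero-order
#' rate through the per-compartment vector `u` passed to `rhs`.
#'
#' @param name model identifier.
#' @param n state dimension.
#' @param theta named numeric parameter set.
#' @param rhs function `(t, y, theta, u)` returning `dy/dt` of length `n`;
#'   `u` is the vector of currently active infusion rates per compartment.
#' @param y0 function `theta -> numeric(n)` giving the initial state.
#' @param observables named list of functions `(y, theta) -> scalar`.
#' @param dosing_compartments integer indices that accept administrations.
#' @param meta optional named list of metadata (units, targets such as a
#'   healthy biomarker level, baselines).
#' @return An object of class `"pkpd_model"`.
#' @export
pkpd_model <- function(name, n, theta, rhs, y0, observables,
                       dosing_compartments = 1L, meta = list()) {
  stopifnot(is.function(rhs), is.function(y0), length(observables) >= 1)
  y_init <- y0(theta)
  if (length(y_init) != n) stop("y0(theta) must have length n", call. = FALSE)
  dy <- rhs(0, y_init, theta, numeric(n))
  if (length(dy) != n || any(!is.finite(dy))) {
    stop("rhs must return a finite vector of length n at the initial state",
         call. = FALSE)
  }
  structure(list(name = name, n = as.integer(n), theta = theta, rhs = rhs,
                 y0 = y0, observables = observables,
                 dosing_compartments = as.integer(dosing_compartments),
                 meta = meta),
            class = "pkpd_model")
}

#' @export
print.pkpd_model <- function(x, ...) {
  cat(sprintf("PK/PD model '%s': %d states, observables: %s\n",
              x$name, x$n, paste(names(x$observables), collapse = ", ")))
  invisible(x)
}

#' Evaluate a model's observables on a matrix of states
#'
#' @param model a [pkpd_model()].
#' @param states numeric matrix, one row per time point, `n` columns.
#' @return Numeric matrix with one named column per observable.
#' @keywords internal
compute_observables <- function(model, states) {
  out <- vapply(model$observables, function(f) {
    apply(states, 1L, f, theta = model$theta)
  }, numeric(nrow(states)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(model$observables)))
  out
}

# ---- built-in models --------------------------------------------------------

#' Retrieve a bundled example model by name
#'
#' Available models: `"toy_1cpt"` (linear one-compartment model with
#' closed-form solution, used by the analytic test problems),
#' `"tumor_myelo"` (transit-compartment tumor-kill model coupled with the
#' Friberg myelosuppression model), `"biomarker_idr"` (turnover
#' indirect-response model with an elevated baseline returning to a healthy
#' target level), and `"antibiotic_ar"` (two-compartment PK driving
#' bacterial kill with adaptive resistance). The three disease models carry
#' synthetic parameterizations; see [example_problem()] and the package
#' vignette for what they emulate.
#'
#' @param name one of `"toy_1cpt"`, `"tumor_myelo"`, `"biomarker_idr"`,
#'   `"antibiotic_ar"`.
#' @param theta optional named list/vector of parameter overrides.
#' @return A [pkpd_model()].
#' @export
build_example_model <- function(name = c("toy_1cpt", "tumor_myelo",
                                         "biomarker_idr", "antibiotic_ar"),
                                theta = NULL) {
  name <- match.arg(name)
  m <- switch(name,
              toy_1cpt = model_toy_1cpt(),
              tumor_myelo = model_tumor_myelo(),
              biomarker_idr = model_biomarker_idr(),
              antibiotic_ar = model_antibiotic_ar())
  if (!is.null(theta)) {
    theta <- unlist(theta)
    unknown <- setdiff(names(theta), names(m$theta))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    m$theta[names(theta)] <- theta
  }
  m
}

# Linear one-compartment model: amount A eliminated first order, C = A/V.
# Closed form after a bolus D at time s: C(t) = D/V * exp(-ke (t - s)).
model_toy_1cpt <- function() {
  pkpd_model(
    name = "toy_1cpt", n = 1L,
    theta = c(ke = 0.1, V = 1),
    rhs = function(t, y, theta, u) {
      -theta[["ke"]] * y[1] + u[1]
    },
    y0 = function(theta) c(A = 0),
    observables = list(C = function(y, theta) y[1] / theta[["V"]]),
    dosing_compartments = 1L,
    meta = list(time_unit = "h")
  )
}

#' Simulate a model with no administrations
#'
#' A feasibility sanity check: runs the model drug-free on a time grid.
#' Models initialized at steady state (e.g. the neutrophil cascade) must
#' stay constant within solver tolerance; growth models evolve untreated.
#'
#' @param model a [pkpd_model()].
#' @param t_grid increasing numeric time grid (first and last element define
#'   the horizon).
#' @param ... passed to [simulate_pkpd()] (tolerances etc.).
#' @return A `"pkpd_trajectory"`, see [simulate_pkpd()].
#' @export
untreated_baseline <- function(model, t_grid, ...) {
  simulate_pkpd(model, events = NULL, t0 = t_grid[1],
                tf = t_grid[length(t_grid)],
                support_times = t_grid, ...)
}
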