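# Synthetic parameterizations of the three bundled disease models.
#
# The model STRUCTURES are the canonical published ones (transit-compartment
# tumor-kill coupled to the Friberg myelosuppression cascade; turnover
# indirect-response; two-compartment PK with adaptive-resistance bacterial
# kill). The PARAMETER VALUES are synthetic: they were chosen once to place
# each dosing task in a realistic regime (recommended starting doses are
# feasible, the dose-response of the constrained state is monotone, optima
# lie inside the dose box) and are NOT estimates for any particular drug.
# See the package vignette for the rationale behind each value.

# Tumor growth inhibition + Friberg myelosuppression, time in days.
# PK: IV bolus into a one-compartment model, C = A/V.
# Tumor: proliferating cells x1 with saturating growth and
# concentration-proportional kill; killed cells pass through three transit
# compartments before clearance; tumor weight W = x1 + x2 + x3 + x4.
# Neutrophils: proliferating pool P with feedback (Circ0/Circ)^gamma and
# linear drug effect E = slope * C; three maturation transits; circulating
# neutrophils N = Circ, baseline 7.
model_tumor_myelo <- function() {
  theta <- c(ke = 2, V = 10,                       # PK, /day and L
             lambda0 = 0.3, lambda1 = 0.25,        # tumor growth, /day, g/day
             k1 = 0.5, k2 = 0.06,                  # transit /day, kill L/mg/day
             w0 = 0.05,                            # initial tumor weight, g
             ktr = 0.8, gamma = 0.17, Circ0 = 7,   # Friberg cascade
             slope = 0.12)                         # drug effect on P, L/mg
  pkpd_model(
    name = "tumor_myelo", n = 10L, theta = theta,
    rhs = function(t, y, theta, u) {
      C <- y[1] / theta[["V"]]
      x1 <- y[2]
      E <- theta[["slope"]] * C
      fb <- (theta[["Circ0"]] / max(y[10], 1e-8))^theta[["gamma"]]
      ktr <- theta[["ktr"]]
      c(-theta[["ke"]] * y[1] + u[1],
        2 * theta[["lambda0"]] * theta[["lambda1"]] * x1 /
          (theta[["lambda1"]] + 2 * theta[["lambda0"]] * x1) -
          theta[["k2"]] * C * x1,
        theta[["k2"]] * C * x1 - theta[["k1"]] * y[3],
        theta[["k1"]] * (y[3] - y[4]),
        theta[["k1"]] * (y[4] - y[5]),
        ktr * y[6] * ((1 - E) * fb - 1),
        ktr * (y[6] - y[7]),
        ktr * (y[7] - y[8]),
        ktr * (y[8] - y[9]),
        ktr * (y[9] - y[10]))
    },
    y0 = function(theta) {
      c(A = 0, x1 = theta[["w0"]], x2 = 0, x3 = 0, x4 = 0,
        P = theta[["Circ0"]], T1 = theta[["Circ0"]], T2 = theta[["Circ0"]],
        T3 = theta[["Circ0"]], Circ = theta[["Circ0"]])
    },
    observables = list(
      C = function(y, theta) y[1] / theta[["V"]],
      W = function(y, theta) y[2] + y[3] + y[4] + y[5],
      N = function(y, theta) y[10]),
    dosing_compartments = 1L,
    meta = list(time_unit = "d", N_baseline = 7)
  )
}

# Indirect-response model for an elevated biomarker, time in days.
# PK: IV bolus one-compartment, C = A/V. Turnover: dB/dt = kin (1 - I(C))
# - kout B with inhibition I(C) = C/(IC50 + C); the untreated steady state
# is the elevated baseline B0 = kin/kout = 20, the healthy target level
# B_tar = 10 requires a sustained inhibition of one half.
model_biomarker_idr <- function() {
  theta <- c(ke = 1, V = 5, kin = 6, kout = 0.3, IC50 = 0.8)
  pkpd_model(
    name = "biomarker_idr", n = 2L, theta = theta,
    rhs = function(t, y, theta, u) {
      C <- y[1] / theta[["V"]]
      c(-theta[["ke"]] * y[1] + u[1],
        theta[["kin"]] * (1 - C / (theta[["IC50"]] + C)) -
          theta[["kout"]] * y[2])
    },
    y0 = function(theta) c(A = 0, B = theta[["kin"]] / theta[["kout"]]),
    observables = list(
      C = function(y, theta) y[1] / theta[["V"]],
      B = function(y, theta) y[2]),
    dosing_compartments = 1L,
    meta = list(time_unit = "d", B_tar = 10,
                B_baseline = 6 / 0.3)
  )
}

# Two-compartment PK with adaptive-resistance bacterial kill, time in hours.
# Drug enters the central compartment as a 1 h zero-order infusion.
# Bacteria S grow logistically and are killed at rate
# kmax C / (EC50 (1 + beta AR) + C); the adaptation state AR in [0, 1]
# rises under drug exposure and raises the effective EC50.
model_antibiotic_ar <- function() {
  theta <- c(V1 = 0.5, k10 = 0.3, k12 = 0.2, k21 = 0.15,   # PK, /h, L/kg
             kg = 0.8, Smax = 1e8, S0 = 1e4,               # bacterial growth
             kmax = 2, EC50 = 2,                           # kill, /h, mg/L
             beta = 5, kon = 0.05, koff = 0.05)            # adaptation
  pkpd_model(
    name = "antibiotic_ar", n = 4L, theta = theta,
    rhs = function(t, y, theta, u) {
      C <- y[1] / theta[["V1"]]
      S <- y[3]; AR <- y[4]
      kill <- theta[["kmax"]] * C / (theta[["EC50"]] * (1 + theta[["beta"]] * AR) + C)
      c(u[1] - (theta[["k10"]] + theta[["k12"]]) * y[1] + theta[["k21"]] * y[2],
        theta[["k12"]] * y[1] - theta[["k21"]] * y[2],
        theta[["kg"]] * S * (1 - S / theta[["Smax"]]) - kill * S,
        theta[["kon"]] * C * (1 - AR) - theta[["koff"]] * AR)
    },
    y0 = function(theta) c(A1 = 0, A2 = 0, S = theta[["S0"]], AR = 0),
    observables = list(
      C = function(y, theta) y[1] / theta[["V1"]],
      S = function(y, theta) y[3]),
    dosing_compartments = 1L,
    meta = list(time_unit = "h", S_threshold = 100)
  )
}

#' Bundled example optimal dosing problems
#'
#' Fully assembled state-constrained dosing tasks on the bundled synthetic
#' models, each returned together with a recommended feasible starting dose
#' and penalty schedule:
#' \describe{
#'   \item{`tumor_myelo`}{horizon 0--32 days; the tumor grows untreated
#'     until day 12, then 16 daily IV boluses (days 12--27) in four groups
#'     of four consecutive days, `m = 4`. Minimize the tumor-weight burden
#'     `integral of W over [12, 32]` subject to neutrophils `N >= 1` on
#'     `[12, 32]`.}
#'   \item{`tumor_myelo_final`}{as above plus the final-time constraint
#'     `N(32) >= 3`.}
#'   \item{`tumor_myelo_three`}{as `tumor_myelo_final` plus a duration
#'     constraint: neutrophils may spend at most 5 days below 1.5.}
#'   \item{`biomarker_idr`}{horizon 0--42 days, daily IV bolus with weekly
#'     dose changes (`m = 6`). Minimize the drug AUC subject to the
#'     elevated biomarker reaching and maintaining the healthy target,
#'     `B <= 10` on `[14, 42]`.}
#'   \item{`antibiotic_ar`}{horizon 0--24 h, the same dose (`m = 1`) as a
#'     1 h IV infusion at 0 h and 12 h. Minimize the drug AUC subject to
#'     the mean bacterial count over `[6, 24]` h staying `<= 100`.}
#'   \item{`antibiotic_interval`}{fixed 50 mg/kg infusions, the first at
#'     0 h; optimize the administration time of the second (`m = 1` gap
#'     parameter) under the same mean-bacterial-count constraint.}
#' }
#'
#' @param name one of the six problem names.
#' @return List with `problem` (an [ocp_problem()]), `D_init`,
#'   `rho_schedule`, and a one-line `description`.
#' @export
example_problem <- function(name = c("tumor_myelo", "tumor_myelo_final",
                                     "tumor_myelo_three", "biomarker_idr",
                                     "antibiotic_ar", "antibiotic_interval")) {
  name <- match.arg(name)
  if (startsWith(name, "tumor")) {
    model <- model_tumor_myelo()
    rec <- do.call(rbind, lapply(0:15, function(i) {
      dose_record(time = 12 + i, group = 1L + i %/% 4L)
    }))
    sc <- dosing_scenario(rec, 0, 32, mode = "optimize_doses", m = 4L,
                          D_min = 0, D_max = 300, time_unit = "d")
    cons <- list(state_constraint("path", "N", "lower", threshold = 1,
                                  window = c(12, 32), name = "N_path"))
    if (name %in% c("tumor_myelo_final", "tumor_myelo_three")) {
      cons <- c(cons, list(state_constraint("point", "N", "lower",
                                            threshold = 3, window = 32,
                                            name = "N_final")))
    }
    if (name == "tumor_myelo_three") {
      cons <- c(cons, list(state_constraint("duration", "N",
                                            sub_threshold = 1.5,
                                            max_duration = 5,
                                            name = "N_duration")))
    }
    prob <- ocp_problem(model, sc, cost_functional("W", c(12, 32)), cons,
                        name = name)
    return(list(problem = prob, D_init = rep(10, 4),
                rho_schedule = c(10, 100, 1000, 1e4),
                description = "minimize tumor burden, avoid neutropenia"))
  }
  if (name == "biomarker_idr") {
    model <- model_biomarker_idr()
    rec <- do.call(rbind, lapply(0:41, function(i) {
      dose_record(time = i, group = 1L + i %/% 7L)
    }))
    sc <- dosing_scenario(rec, 0, 42, mode = "optimize_doses", m = 6L,
                          D_min = 0, D_max = 20, time_unit = "d")
    prob <- ocp_problem(model, sc, cost_functional("C", c(0, 42)),
                        state_constraint("path", "B", "upper",
                                         threshold = model$meta$B_tar,
                                         window = c(14, 42), name = "B_path"),
                        name = name)
    return(list(problem = prob, D_init = rep(6, 6),
                rho_schedule = c(1, 100, 1e4, 1e6),
                description = "return biomarker to healthy level with minimal drug AUC"))
  }
  model <- model_antibiotic_ar()
  if (name == "antibiotic_ar") {
    rec <- rbind(dose_record(0, kind = "infusion", duration = 1, group = 1L),
                 dose_record(12, kind = "infusion", duration = 1, group = 1L))
    sc <- dosing_scenario(rec, 0, 24, mode = "optimize_doses", m = 1L,
                          D_min = 5, D_max = 150, time_unit = "h")
  } else {
    rec <- rbind(dose_record(0, amount = 50, kind = "infusion", duration = 1,
                             group = 1L),
                 dose_record(0, amount = 50, kind = "infusion", duration = 1,
                             group = 2L))
    sc <- dosing_scenario(rec, 0, 24, mode = "optimize_intervals", m = 1L,
                          D_min = 6, D_max = 23, time_unit = "h")
  }
  prob <- ocp_problem(model, sc, cost_functional("C", c(0, 24)),
                      state_constraint("mean_value", "S", "upper",
                                       threshold = 100, window = c(6, 24),
                                       name = "S_mean"),
                      name = name)
  list(problem = prob,
       D_init = if (name == "antibiotic_ar") 80 else 10,
       rho_schedule = c(100, 1e4, 1e6),
       description = "eradicate bacteria with minimal drug AUC")
}
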