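#' Create a single administration record
#'
#' A dose record describes one planned administration: when it happens, into
#' which compartment, whether it is a bolus or a fixed-duration infusion, and
#' which entry of the optimized dose vector it draws its amount from.
#'
#' @param time administration time in model time units (days or hours,
#'   per problem).
#' @param amount nonnegative amount; in dose-optimization mode this is a
#'   placeholder (the optimized dose replaces it), in interval-optimization
#'   mode it is the fixed dose.
#' @param compartment positive integer index of the receiving compartment.
#' @param kind `"bolus"` (instantaneous jump) or `"infusion"` (zero-order
#'   input of rate `amount / duration`).
#' @param duration infusion duration; required iff `kind = "infusion"`.
#' @param lag nonnegative administration lag added to `time`.
#' @param group positive integer index into the optimized dose vector
#'   (the `DOSE_NR` of NONMEM-style data files).
#' @param bioavailability scale factor applied to the administered amount.
#' @return A one-row `data.frame` with the record fields.
#' @seealso [dosing_scenario()], [expand_doses()], [expand_intervals()]
#' @export
dose_record <- function(time, amount = 1, compartment = 1L,
                        kind = c("bolus", "infusion"), duration = NA_real_,
                        lag = 0, group = 1L, bioavailability = 1) {
  kind <- match.arg(kind)
  if (kind == "infusion" && (is.na(duration) || duration <= 0)) {
    stop("infusion records require a positive 'duration'", call. = FALSE)
  }
  if (amount < 0) stop("'amount' must be nonnegative", call. = FALSE)
  data.frame(time = as.numeric(time), amount = as.numeric(amount),
             compartment = as.integer(compartment), kind = kind,
             duration = as.numeric(duration), lag = as.numeric(lag),
             group = as.integer(group),
             bioavailability = as.numeric(bioavailability),
             stringsAsFactors = FALSE)
}

#' Define a dosing scenario
#'
#' A scenario fixes the administration plan: the ordered dose records, the
#' observation interval `[t0, tf]`, optional support times at which the
#' simulator must place grid points, the optimization mode, the number of
#' optimized parameters `m` and their box bounds.
#'
#' Two modes are supported. In `"optimize_doses"` the amounts of the records
#' are optimized: record group `g` receives `bioavailability * D[g]`. In
#' `"optimize_intervals"` the amounts are fixed and a single gap parameter
#' `theta` places the record of group `g` at time `theta * (g - 1)` — the
#' lag-time construction used for dosing-interval optimization.
#'
#' @param records a `data.frame` of stacked [dose_record()] rows.
#' @param t0,tf observation interval endpoints, `t0 < tf`.
#' @param support_times numeric vector of additional times the simulation
#'   grid must contain (reporting/constraint support points).
#' @param mode `"optimize_doses"` or `"optimize_intervals"`.
#' @param m number of optimized parameters (doses, or gap parameters).
#' @param D_min,D_max numeric bounds of length `m` (recycled if scalar).
#' @param time_unit free-text unit label carried as metadata only.
#' @return An object of class `"dosing_scenario"`.
#' @export
dosing_scenario <- function(records, t0, tf, support_times = numeric(),
                            mode = c("optimize_doses", "optimize_intervals"),
                            m, D_min, D_max, time_unit = "time") {
  mode <- match.arg(mode)
  sc <- structure(list(records = records, t0 = as.numeric(t0),
                       tf = as.numeric(tf),
                       support_times = as.numeric(support_times),
                       mode = mode, m = as.integer(m),
                       D_min = rep_len(as.numeric(D_min), m),
                       D_max = rep_len(as.numeric(D_max), m),
                       time_unit = time_unit),
                  class = "dosing_scenario")
  diags <- validate_scenario(sc)
  if (length(diags)) {
    stop("invalid dosing scenario:\n  ", paste(diags, collapse = "\n  "),
         call. = FALSE)
  }
  sc
}

#' Validate a dosing scenario
#'
#' Checks the scenario invariants and returns human-readable diagnostics
#' instead of failing, so that configurations can be vetted before a solve.
#'
#' @param scenario a [dosing_scenario()] (or a bare list with its fields).
#' @return A character vector of violations; `character(0)` if all
#'   invariants hold.
#' @export
validate_scenario <- function(scenario) {
  out <- character()
  r <- scenario$records
  if (!is.null(scenario$t0) && !is.null(scenario$tf) &&
      scenario$t0 >= scenario$tf) {
    out <- c(out, sprintf("t0 (%g) must be < tf (%g)",
                          scenario$t0, scenario$tf))
  }
  if (any(scenario$D_min > scenario$D_max)) {
    bad <- which(scenario$D_min > scenario$D_max)
    out <- c(out, sprintf("D_min > D_max in coordinate(s) %s",
                          paste(bad, collapse = ", ")))
  }
  if (nrow(r)) {
    if (any(r$amount < 0)) out <- c(out, "negative record amount")
    if (any(r$lag < 0)) out <- c(out, "negative record lag")
    bad_inf <- r$kind == "infusion" & (is.na(r$duration) | r$duration <= 0)
    if (any(bad_inf)) {
      out <- c(out, sprintf("infusion record(s) %s lack a positive duration",
                            paste(which(bad_inf), collapse = ", ")))
    }
    if (scenario$mode == "optimize_doses") {
      tt <- r$time + r$lag
      if (any(tt < scenario$t0 | tt > scenario$tf)) {
        out <- c(out, sprintf("record time(s) %s outside [t0, tf]",
                              paste(which(tt < scenario$t0 | tt > scenario$tf),
                                    collapse = ", ")))
      }
      if (any(r$group < 1L | r$group > scenario$m)) {
        out <- c(out, "record group index outside 1..m")
      } else if (!all(seq_len(scenario$m) %in% r$group)) {
        miss <- setdiff(seq_len(scenario$m), r$group)
        out <- c(out, sprintf("dose group(s) %s not used by any record",
                              paste(miss, collapse = ", ")))
      }
    } else {
      if (any(r$time != 0)) {
        out <- c(out, "interval mode requires all records at time 0")
      }
    }
  }
  out
}

#' Expand an optimized dose vector into administration events
#'
#' Resolves a scenario in dose-optimization mode against a concrete dose
#' vector `D`: each record contributes exactly one event whose amount is
#' `bioavailability * D[group]`; times (including any lag) are unchanged.
#' Bounds are *not* clipped here — the optimizer owns the box; out-of-bounds
#' input is an error upstream, not silently repaired.
#'
#' @param D numeric vector of length `scenario$m`.
#' @param scenario a [dosing_scenario()] with `mode = "optimize_doses"`.
#' @return A `data.frame` of events with columns `time`, `amount`,
#'   `compartment`, `kind`, `duration`.
#' @export
expand_doses <- function(D, scenario) {
  if (scenario$mode != "optimize_doses") {
    stop("expand_doses() requires mode 'optimize_doses'", call. = FALSE)
  }
  D <- as.numeric(D)
  if (length(D) != scenario$m) {
    stop(sprintf("length(D) = %d but scenario has m = %d",
                 length(D), scenario$m), call. = FALSE)
  }
  if (any(!is.finite(D))) stop("non-finite dose vector", call. = FALSE)
  r <- scenario$records
  if (any(r$group > length(D))) {
    stop("record group index exceeds length of dose vector", call. = FALSE)
  }
  data.frame(time = r$time + r$lag,
             amount = r$bioavailability * D[r$group],
             compartment = r$compartment, kind = r$kind,
             duration = r$duration, stringsAsFactors = FALSE)
}

#' Expand interval parameters into administration events
#'
#' Resolves a scenario in interval-optimization mode: amounts are taken from
#' the records (fixed), and the record of group `g` is administered at
#' `theta[1] * (g - 1)` — a single gap parameter, mirroring a lag time
#' proportional to the dose number. With `per_dose_gaps = TRUE`, `theta`
#' holds one gap per inter-dose interval and group `g` is placed at
#' `sum(theta[1:(g-1)])`.
#'
#' @param theta numeric gap parameter(s), in the scenario's time unit.
#' @param scenario a [dosing_scenario()] with `mode = "optimize_intervals"`.
#' @param per_dose_gaps logical; default `FALSE` (single shared gap).
#' @return A `data.frame` of events (as [expand_doses()]), with an attribute
#'   `"degenerate"` set to `TRUE` when two events coincide in time.
#' @export
expand_intervals <- function(theta, scenario, per_dose_gaps = FALSE) {
  if (scenario$mode != "optimize_intervals") {
    stop("expand_intervals() requires mode 'optimize_intervals'",
         call. = FALSE)
  }
  theta <- as.numeric(theta)
  r <- scenario$records
  g <- r$group
  if (per_dose_gaps) {
    offs <- c(0, cumsum(theta))
    if (max(g) > length(offs)) {
      stop("per-dose gaps: need one gap per inter-dose interval",
           call. = FALSE)
    }
    times <- offs[g]
  } else {
    times <- theta[1] * (g - 1)
  }
  end <- times + ifelse(r$kind == "infusion", r$duration, 0)
  if (any(end > scenario$tf + 1e-12)) {
    stop("infeasible scenario: administration extends beyond tf",
         call. = FALSE)
  }
  ev <- data.frame(time = times, amount = r$bioavailability * r$amount,
                   compartment = r$compartment, kind = r$kind,
                   duration = r$duration, stringsAsFactors = FALSE)
  attr(ev, "degenerate") <- anyDuplicated(times) > 0
  ev
}
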