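#' Read a dosing-record CSV
#'
#' Parses the NONMEM-flavoured dosing dialect: a comma-separated file with
#' mandatory header `ID, TIME, AMT, RATE, EVID, DV, CMT, DOSE_NR` ('.'
#' decimal separator; extra columns are ignored with a warning). Row
#' semantics: `EVID = 1` is an administration (`AMT`, `CMT`, `DOSE_NR`
#' taken from the row; `RATE = -2` marks a fixed-duration infusion whose
#' duration comes from `infusion_durations[CMT]`), `EVID = 0` is an
#' observation record — the one with the largest `TIME` defines the final
#' time `tf` (the customary dummy `DV = 0` row) — and `EVID = 2` rows are
#' support points added to the simulation grid.
#'
#' @param path CSV file path.
#' @param infusion_durations named or positional numeric vector of infusion
#'   durations per compartment (the control-stream `D1` analogue); required
#'   when the file contains `RATE = -2` rows.
#' @return List with `records` (a [dose_record()] data frame), `tf`,
#'   `support_times`.
#' @export
read_dose_records <- function(path, infusion_durations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  header <- gsub('"', "", trimws(header), fixed = TRUE)
  if (anyDuplicated(header)) {
    stop("duplicate column(s) in header: ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  }
  req <- c("ID", "TIME", "AMT", "RATE", "EVID", "DV", "CMT", "DOSE_NR")
  miss <- setdiff(req, header)
  if (length(miss)) {
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(header, req)
  if (length(extra)) {
    warning("ignoring extra column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  df <- utils::read.csv(path, header = TRUE, na.strings = c("NA", "."))
  for (cc in req) {
    if (!is.numeric(df[[cc]])) {
      num <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(num) & !is.na(df[[cc]]))
      if (length(bad)) {   # '.' (missing) is tolerated, words are not
        stop(sprintf("non-numeric value in column %s, data row %d", cc,
                     bad[1]), call. = FALSE)
      }
      df[[cc]] <- num
    }
  }
  if (any(df$ID != df$ID[1])) {
    stop("multi-subject files (ID > 1 values) are not supported",
         call. = FALSE)
  }
  obs <- df[df$EVID == 0, , drop = FALSE]
  if (!nrow(obs)) {
    stop("no EVID = 0 observation record: final time tf is undefined",
         call. = FALSE)
  }
  tf <- max(obs$TIME)
  support <- df$TIME[df$EVID == 2]
  dosing <- df[df$EVID == 1, , drop = FALSE]
  records <- if (nrow(dosing)) {
    do.call(rbind, lapply(seq_len(nrow(dosing)), function(i) {
      r <- dosing[i, ]
      is_inf <- r$RATE == -2
      dur <- NA_real_
      if (is_inf) {
        if (is.null(infusion_durations)) {
          stop(sprintf("row %d: RATE = -2 requires 'infusion_durations'", i),
               call. = FALSE)
        }
        dur <- if (!is.null(names(infusion_durations))) {
          infusion_durations[[as.character(r$CMT)]]
        } else infusion_durations[[r$CMT]]
      }
      dose_record(time = r$TIME, amount = r$AMT, compartment = r$CMT,
                  kind = if (is_inf) "infusion" else "bolus",
                  duration = dur, group = max(1L, as.integer(r$DOSE_NR)))
    }))
  } else {
    dose_record(0, amount = 0)[0, ]
  }
  list(records = records, tf = tf, support_times = support)
}

#' Write a dosing scenario back to the record CSV dialect
#'
#' @param scenario a [dosing_scenario()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dose_records <- function(scenario, path) {
  r <- scenario$records
  rows <- data.frame(ID = 1, TIME = r$time, AMT = r$amount,
                     RATE = ifelse(r$kind == "infusion", -2, 0),
                     EVID = 1, DV = NA_real_, CMT = r$compartment,
                     DOSE_NR = r$group)
  if (length(scenario$support_times)) {
    rows <- rbind(rows, data.frame(ID = 1, TIME = scenario$support_times,
                                   AMT = 0, RATE = 0, EVID = 2,
                                   DV = NA_real_, CMT = 1, DOSE_NR = 0))
  }
  rows <- rbind(rows, data.frame(ID = 1, TIME = scenario$tf, AMT = 0,
                                 RATE = 0, EVID = 0, DV = 0, CMT = 1,
                                 DOSE_NR = 0))
  utils::write.csv(rows, path, row.names = FALSE, na = ".")
  invisible(path)
}

#' Read a YAML problem configuration
#'
#' Loads a complete optimal dosing problem from a YAML file: model name
#' (plus optional parameter overrides), dosing-record CSV (path resolved
#' relative to the config file), optimization mode, bounds, cost spec,
#' constraint specs, penalty schedule and optimizer settings.
#'
#' @param path YAML file path.
#' @return List with `problem` (an [ocp_problem()]), `D_init`,
#'   `rho_schedule`, `control`, `seed`.
#' @export
read_problem_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  model <- build_example_model(cfg$model$name, theta = cfg$model$theta)
  rec_path <- cfg$records
  if (!file.exists(rec_path)) {
    rec_path <- file.path(dirname(path), cfg$records)
  }
  dur <- cfg$infusion_durations
  if (!is.null(dur)) dur <- unlist(dur)
  rec <- read_dose_records(rec_path, infusion_durations = dur)
  mode <- if (is.null(cfg$mode)) "optimize_doses" else cfg$mode
  sc <- dosing_scenario(rec$records,
                        t0 = if (is.null(cfg$t0)) 0 else cfg$t0,
                        tf = rec$tf, support_times = rec$support_times,
                        mode = mode, m = cfg$m,
                        D_min = unlist(cfg$bounds$lower),
                        D_max = unlist(cfg$bounds$upper),
                        time_unit = if (is.null(cfg$time_unit)) "time"
                                    else cfg$time_unit)
  cost <- cost_functional(cfg$cost$observable, unlist(cfg$cost$window),
                          type = if (is.null(cfg$cost$type)) "integral"
                                 else cfg$cost$type)
  cons <- lapply(cfg$constraints, function(cc) {
    state_constraint(kind = cc$kind, observable = cc$observable,
                     direction = if (is.null(cc$direction)) "lower"
                                 else cc$direction,
                     threshold = if (is.null(cc$threshold)) NA_real_
                                 else cc$threshold,
                     window = if (is.null(cc$window)) NULL
                              else unlist(cc$window),
                     max_duration = cc$max_duration,
                     sub_threshold = cc$sub_threshold,
                     name = cc$name)
  })
  prob <- ocp_problem(model, sc, cost, cons,
                      name = if (is.null(cfg$name)) cfg$model$name
                             else cfg$name)
  ctl <- if (is.null(cfg$optimizer$control)) list() else cfg$optimizer$control
  list(problem = prob,
       D_init = unlist(cfg$optimizer$D_init),
       rho_schedule = unlist(cfg$penalty$schedule),
       control = ctl,
       seed = cfg$optimizer$seed)
}

#' Write a solution JSON
#'
#' Serializes the fit: optimal doses, CFV, per-constraint PFV and PFV/rho,
#' constraint margins, convergence and feasibility flags. All numbers are
#' written in full precision.
#'
#' @param fit an `"optidose_fit"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_solution <- function(fit, path) {
  sol <- list(problem = fit$problem$name,
              D_star = as.list(fit$D_star),
              CFV = fit$breakdown$CFV,
              OFV = fit$breakdown$OFV,
              gradient_norm = fit$gradient_norm,
              n_evaluations = fit$n_evaluations,
              converged = fit$converged, feasible = fit$feasible)
  if (length(fit$breakdown$PFV)) {
    sol$PFV <- as.list(fit$breakdown$PFV)
    sol$PFV_over_rho <- as.list(fit$breakdown$PFV_over_rho)
    sol$margins <- as.list(fit$margins)
  }
  jsonlite::write_json(sol, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a solution JSON back
#'
#' @param path file written by [write_solution()].
#' @return Named list mirroring the written structure.
#' @export
read_solution <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write the optimizer evaluation trace as CSV
#'
#' One row per objective evaluation: evaluation counter, parameter vector,
#' CFV, each PFV and the OFV.
#'
#' @param fit an `"optidose_fit"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(fit, path) {
  utils::write.csv(fit$trace, path, row.names = FALSE)
  invisible(path)
}
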