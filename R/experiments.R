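# Simulation campaigns: phase compensation, arrest/escape, robustness scans,
# rescue experiments and brute-force bifurcation sweeps.

applyPerturbation <- function(model, params) {
  if (is.null(params) || !length(params)) return(model)
  do.call(setParameters, c(list(model), as.list(params)))
}

runAndClassify <- function(model, settings, ...) {
  traj <- tryCatch(integrateModel(model, settings), error = function(e) NULL)
  defs <- eventDefinitions(model)
  if (is.null(traj))
    return(structure(list(code = 0L,
                          detail = data.frame(event = defs$event,
                                              status = "integration-failure"),
                          cycles = numeric(0), period = NA_real_,
                          events = NULL, amplitude = NA_real_,
                          window = c(NA_real_, NA_real_)),
                     class = "cyclephase_runclass"))
  classifyRun(traj, defs, ...)
}

#' Phase-compensation experiment
#'
#' Runs the model under a list of parameter perturbations and reports mean
#' G1S and G2M phase lengths and fractions per condition, mirroring the
#' compensation behaviour in which a lengthened G1/S is offset by a
#' shortened G2/M (and vice versa) so that the total cycle length is
#' approximately preserved.
#'
#' @param model A `cyclephase_model` whose default run oscillates with
#'   periodic events.
#' @param perturbations Named list of conditions; each element is a named
#'   vector/list of parameter overrides (e.g.
#'   `list("High Dap" = c(s_Dap = 1.05))`). The unperturbed row is always
#'   included first.
#' @param settings Solver settings.
#' @return A data frame: `condition`, `code`, `g1s`, `g2m`, `total`,
#'   `frac_g1s`, `frac_g2m`, `cycles` (number of analyzed cycles).
#' @export
phaseCompensation <- function(model, perturbations = list(),
                              settings = solverSettings()) {
  conds <- c(list("Default parameters" = NULL), perturbations)
  rows <- lapply(seq_along(conds), function(i) {
    m <- applyPerturbation(model, conds[[i]])
    run <- analyzeRun(m, settings)
    ph <- run$phases
    data.frame(condition = names(conds)[i], code = run$class$code,
               g1s = if (is.null(ph)) NA_real_ else mean(ph$g1s),
               g2m = if (is.null(ph)) NA_real_ else mean(ph$g2m),
               total = if (is.null(ph)) NA_real_ else mean(ph$total),
               frac_g1s = if (is.null(ph)) NA_real_ else mean(ph$frac_g1s),
               frac_g2m = if (is.null(ph)) NA_real_ else mean(ph$frac_g2m),
               cycles = if (is.null(ph)) 0L else nrow(ph),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

standardArrestGrid <- function() {
  data.frame(
    d_Stga = c(NA, NA, NA, 0.3, 0.3, 0.3, 0.3, 0.5, 0.5, 0.5, 0.5),
    s_Dap  = c(1.17, NA, NA, NA, 0.0, NA, NA, NA, 1.1, NA, NA),
    s_Rux  = c(NA, 2.7, NA, NA, NA, 0.0, NA, NA, NA, 2.0, NA),
    s_E2F2 = c(NA, NA, 1.2, NA, NA, NA, 0.0, NA, NA, NA, 1.1))
}

#' Cell cycle arrest / escape-of-arrest grid
#'
#' Evaluates combinations of active-String decay and inhibitor synthesis
#' rates. A single perturbation is scored `Arrested` (no oscillation) or
#' `Not arrested`; a second perturbation added to an arrested base is scored
#' `Escaped` when cycling resumes and `Not escaped` otherwise.
#'
#' @param model A `cyclephase_model`.
#' @param grid Data frame with columns `d_Stga`, `s_Dap`, `s_Rux`, `s_E2F2`
#'   (NA = default value); defaults to the standard 11-row grid.
#' @param settings Solver settings.
#' @return The grid with `code` (run class of the combined perturbation) and
#'   `outcome` columns added.
#' @export
arrestEscapeGrid <- function(model, grid = standardArrestGrid(),
                             settings = solverSettings()) {
  base_cache <- new.env(parent = emptyenv())
  base_code <- function(d_stga) {
    key <- format(d_stga)
    if (!is.null(base_cache[[key]])) return(base_cache[[key]])
    code <- runAndClassify(setParameters(model, d_Stga = d_stga), settings)$code
    base_cache[[key]] <- code
    code
  }
  codes <- integer(nrow(grid)); outcome <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    ps <- as.list(row)[!is.na(unlist(row))]
    cls <- runAndClassify(applyPerturbation(model, ps), settings)
    codes[i] <- cls$code
    second <- setdiff(names(ps), "d_Stga")
    if (!is.na(row$d_Stga) && length(second) &&
        base_code(row$d_Stga) == 0L) {
      outcome[i] <- if (cls$code >= 1L) "Escaped" else "Not escaped"
    } else {
      outcome[i] <- if (cls$code == 0L) "Arrested" else "Not arrested"
    }
  }
  cbind(grid, data.frame(code = codes, outcome = outcome,
                         stringsAsFactors = FALSE))
}

#' Robustness scan over Hill half-max parameters
#'
#' Increases and decreases every half-maximal coefficient governing a
#' defined signaling event by a fixed fraction and classifies each run.
#' The failure count is the number of class-0 outcomes.
#'
#' @param model A `cyclephase_model`.
#' @param factor Scan fraction (default 0.666, i.e. +/-66.6%).
#' @param extra Optional additional perturbation applied to every run (e.g.
#'   `c(s_Dap = 0)` to remove Dacapo).
#' @param mode `"plusminus"`: up = p*(1+factor), down = p*(1-factor);
#'   `"ratio"`: up = p*(1+factor), down = p/(1+factor).
#' @param settings Solver settings.
#' @param progress Print one line per run.
#' @return A `cyclephase_scan`: list with `outcomes` (data frame `link`,
#'   `event`, `param`, `direction`, `code`), `failures` (count of code-0
#'   runs) and `pairs` (per-event up/down code pairs).
#' @export
robustnessScan <- function(model, factor = 0.666, extra = NULL,
                           mode = c("plusminus", "ratio"),
                           settings = solverSettings(), progress = FALSE) {
  mode <- match.arg(mode)
  base <- applyPerturbation(model, extra)
  defs <- eventDefinitions(model)
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    p <- defs$param[i]
    p0 <- base$config$parameters[[p]]
    for (direction in c("up", "down")) {
      fac <- switch(mode,
                    plusminus = if (direction == "up") 1 + factor else 1 - factor,
                    ratio = if (direction == "up") 1 + factor else 1 / (1 + factor))
      m <- if (fac == 1) base else scaleParameter(base, p, fac)
      code <- runAndClassify(m, settings)$code
      if (progress)
        message(sprintf("%-22s %-4s %s -> %g: code %d", defs$event[i],
                        direction, p, p0 * fac, code))
      rows[[length(rows) + 1]] <- data.frame(
        link = defs$link[i], event = defs$event[i], param = p,
        direction = direction, factor = factor, code = code,
        stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, rows)
  up <- outcomes[outcomes$direction == "up", ]
  down <- outcomes[outcomes$direction == "down", ]
  pairs <- data.frame(link = up$link, event = up$event, param = up$param,
                      up = up$code, down = down$code[match(up$event, down$event)],
                      stringsAsFactors = FALSE)
  structure(list(outcomes = outcomes, failures = sum(outcomes$code == 0L),
                 pairs = pairs, factor = factor, mode = mode,
                 extra = extra),
            class = "cyclephase_scan")
}

#' @export
print.cyclephase_scan <- function(x, ...) {
  cat("Robustness scan: +/-", x$factor * 100, "% over",
      nrow(x$pairs), "event parameters\n")
  if (!is.null(x$extra))
    cat("Extra perturbation:",
        paste(names(x$extra), unlist(x$extra), sep = " = ", collapse = ", "),
        "\n")
  cat("Failures (code 0):", x$failures, "of", nrow(x$outcomes), "runs\n")
  invisible(x)
}

#' Rescue experiment
#'
#' Classifies the model after a cycle-breaking perturbation, then again with
#' an additional rescuing perturbation.
#'
#' @param model A `cyclephase_model`.
#' @param break_params Named parameter overrides that break the cycle.
#' @param rescue_params Named overrides applied on top of `break_params`.
#' @param settings Solver settings.
#' @return List with integer codes `before` and `after`, plus the full
#'   `cyclephase_runclass` objects.
#' @export
rescueExperiment <- function(model, break_params, rescue_params,
                             settings = solverSettings()) {
  broken <- applyPerturbation(model, break_params)
  before <- runAndClassify(broken, settings)
  after <- runAndClassify(applyPerturbation(broken, rescue_params), settings)
  list(before = before$code, after = after$code,
       before_class = before, after_class = after)
}

#' Brute-force one-parameter bifurcation sweep
#'
#' Classifies the model over a grid of values of one parameter and reports
#' period and amplitude of the mitotic marker for oscillating runs.
#'
#' @param model A `cyclephase_model`.
#' @param param Parameter name.
#' @param values Numeric grid (all >= 0).
#' @param marker Species for period/amplitude summaries.
#' @param settings Solver settings.
#' @return Data frame `value`, `code`, `period`, `amplitude`.
#' @export
bifurcationSweep <- function(model, param, values, marker = "CDKBa",
                             settings = solverSettings()) {
  stopifnot(length(values) >= 1, all(is.finite(values)), all(values >= 0))
  rows <- lapply(values, function(v) {
    args <- list(model); args[[param]] <- v
    cls <- runAndClassify(do.call(setParameters, args), settings)
    data.frame(value = v, code = cls$code,
               period = if (cls$code >= 1) cls$period else NA_real_,
               amplitude = if (cls$code >= 1) cls$amplitude else NA_real_)
  })
  do.call(rbind, rows)
}

#' Integrate with mid-run parameter switches
#'
#' Supports continuation-style experiments in which parameters change while
#' the trajectory is captured continuously: the state at each switch time is
#' carried over as the initial condition of the next segment.
#'
#' @param model A `cyclephase_model`.
#' @param schedule List of `list(time = t, params = c(name = value))`
#'   entries with strictly increasing times (> 0).
#' @param settings Solver settings (`t_end` is the total horizon).
#' @return A `cyclephase_trajectory` spanning the full horizon.
#' @export
simulateSchedule <- function(model, schedule, settings = solverSettings()) {
  times <- vapply(schedule, `[[`, 0, "time")
  stopifnot(!is.unsorted(times, strictly = TRUE), all(times > 0),
            all(times < settings$t_end))
  bounds <- c(0, times, settings$t_end)
  y <- initialState(model)
  m <- model
  all_t <- numeric(0); all_s <- NULL; acc <- 0; rej <- 0
  for (i in seq_len(length(bounds) - 1)) {
    if (i > 1) m <- applyPerturbation(m, schedule[[i - 1]]$params)
    seg <- settings; seg$t_end <- bounds[i + 1] - bounds[i]
    tr <- integrateModel(m, seg, y0 = y, t0 = bounds[i])
    keep <- if (i == 1) seq_along(tr$times) else -1L
    all_t <- c(all_t, tr$times[keep])
    all_s <- rbind(all_s, tr$states[keep, , drop = FALSE])
    acc <- acc + tr$accepted; rej <- rej + tr$rejected
    y <- tr$states[nrow(tr$states), ]
  }
  newTrajectory(all_t, all_s, acc, rej, colnames(all_s))
}
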