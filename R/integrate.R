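#' Solver settings for the adaptive second-order Runge-Kutta integrator
#'
#' Error control follows a per-component mixed criterion: a step is accepted
#' when the step-doubling error estimate satisfies
#' `err_i <= relerr * |y_i| + abserr` for every component; otherwise the step
#' is halved. After two consecutive acceptances the step is doubled, up to
#' `h_max`. `h_max` also bounds the output resolution, which matters for
#' threshold-crossing event detection (keep it well below 1% of the cycle
#' period for event runs).
#'
#' @param relerr Relative error tolerance (> 0).
#' @param abserr Absolute error tolerance (> 0).
#' @param h0 Initial step size.
#' @param h_min Smallest admissible step; persistent rejection below this
#'   aborts with a stiffness error.
#' @param h_max Largest admissible step.
#' @param t_end Integration horizon (from t = 0).
#' @param max_steps Safety cap on total attempted steps.
#' @return A `cyclephase_settings` list.
#' @export
solverSettings <- function(relerr = 1e-5, abserr = 1e-5, h0 = 0.01,
                           h_min = 1e-10, h_max = 0.05, t_end = 250,
                           max_steps = 5e6) {
  if (relerr <= 0 || abserr <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (!(h_min <= h0 && h0 <= h_max))
    stop("step bounds must satisfy h_min <= h0 <= h_max", call. = FALSE)
  if (t_end <= 0) stop("t_end must be positive", call. = FALSE)
  structure(list(relerr = relerr, abserr = abserr, h0 = h0, h_min = h_min,
                 h_max = h_max, t_end = t_end, max_steps = max_steps),
            class = "cyclephase_settings")
}

newTrajectory <- function(times, states, accepted, rejected, species) {
  colnames(states) <- species
  structure(list(times = times, states = states,
                 accepted = accepted, rejected = rejected),
            class = "cyclephase_trajectory")
}

#' Integrate the cell cycle model
#'
#' Solves the model ODEs with the adaptive second-order Runge-Kutta scheme
#' (explicit midpoint with step-doubling error estimation).
#'
#' @param model A `cyclephase_model`.
#' @param settings A [solverSettings()] object.
#' @param y0 Initial state; defaults to the model's configured initial
#'   conditions.
#' @param t0 Start time.
#' @return A `cyclephase_trajectory`: adaptively spaced `times`, a
#'   step-by-species `states` matrix, and `accepted`/`rejected` step counts.
#' @export
integrateModel <- function(model, settings = solverSettings(),
                           y0 = initialState(model), t0 = 0) {
  cm <- compileModel(model)
  if (length(y0) != cm$n_state)
    stop("initial state must have length ", cm$n_state, call. = FALSE)
  res <- tryCatch(
    integrate_model_cpp(cm, as.numeric(y0), t0, t0 + settings$t_end,
                        settings$relerr, settings$abserr, settings$h0,
                        settings$h_min, settings$h_max, settings$max_steps),
    error = function(e) {
      msg <- conditionMessage(e)
      m <- regmatches(msg, regexec("component ([0-9]+)", msg))[[1]]
      if (length(m) == 2) {
        sp <- cm$state_names[as.integer(m[2])]
        stop("integration failed (species ", sp, "): ", msg, call. = FALSE)
      }
      stop("integration failed: ", msg, call. = FALSE)
    })
  newTrajectory(res$times, res$states, res$accepted, res$rejected,
                cm$state_names)
}

#' Integrate an arbitrary ODE system with the package's adaptive RK2 scheme
#'
#' Same stepper and error control as [integrateModel()], for a user-supplied
#' derivative function. Used for analytic test fixtures (exponential decay,
#' harmonic oscillator) whose closed forms validate the error control.
#'
#' @param rhs Function `f(t, y)` returning the derivative vector.
#' @param y0 Initial state (optionally named).
#' @param settings A [solverSettings()] object.
#' @param t0 Start time.
#' @return A `cyclephase_trajectory`.
#' @export
integrateODE <- function(rhs, y0, settings = solverSettings(), t0 = 0) {
  f <- function(t, y) as.numeric(rhs(t, y))
  res <- integrate_fun_cpp(f, as.numeric(y0), t0, t0 + settings$t_end,
                           settings$relerr, settings$abserr, settings$h0,
                           settings$h_min, settings$h_max, settings$max_steps)
  nm <- if (!is.null(names(y0))) names(y0) else paste0("y", seq_along(y0))
  newTrajectory(res$times, res$states, res$accepted, res$rejected, nm)
}

#' @export
print.cyclephase_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "accepted points over t = [",
      format(x$times[1]), ",", format(x$times[length(x$times)]), "],",
      ncol(x$states), "species\n")
  cat("Steps accepted:", x$accepted, " rejected:", x$rejected, "\n")
  invisible(x)
}

#' @export
as.data.frame.cyclephase_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$states, check.names = FALSE)
}

#' Trajectory in tidy (long) form
#' @param traj A `cyclephase_trajectory`.
#' @return A data frame with columns `time`, `species`, `value`.
#' @export
tidyTrajectory <- function(traj) {
  sp <- colnames(traj$states)
  data.frame(time = rep(traj$times, times = length(sp)),
             species = rep(sp, each = length(traj$times)),
             value = as.vector(traj$states))
}

#' Write a trajectory to CSV
#' @param traj A `cyclephase_trajectory`.
#' @param path Output path.
#' @param tidy If TRUE write long format (time, species, value), else wide.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(traj, path, tidy = FALSE) {
  df <- if (tidy) tidyTrajectory(traj) else as.data.frame(traj)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Interpolate a trajectory at given times
#'
#' Linear interpolation between accepted steps (the integrator's dense
#' output convention).
#'
#' @param traj A `cyclephase_trajectory`.
#' @param times Times at which to evaluate.
#' @param species Optional species subset (names or indices).
#' @return Matrix of interpolated values, one row per requested time.
#' @export
interpolateTrajectory <- function(traj, times, species = NULL) {
  cols <- if (is.null(species)) seq_len(ncol(traj$states)) else species
  out <- vapply(cols, function(cc)
    approx(traj$times, traj$states[, cc], xout = times, rule = 2)$y,
    numeric(length(times)))
  out <- matrix(out, nrow = length(times))
  colnames(out) <- colnames(traj$states[, cols, drop = FALSE])
  out
}
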