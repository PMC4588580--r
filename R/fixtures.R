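# Deterministic analytic fixtures for oracle tests: trajectories and event
# traces with closed-form properties carried in metadata.

#' Build a deterministic test fixture
#'
#' Three fixture families:
#' * `"sine"` - one species `x(t) = offset + amplitude * sin(2*pi*t/period)`
#'   sampled on a uniform grid; for a given `threshold`, the closed-form
#'   crossing times are attached as metadata (`attr(, "crossings")`).
#' * `"square"` - a square-wave event trace: active on
#'   `[k*period, k*period + duty*period)`; exact edges in metadata.
#' * `"hill_ring"` - a three-species Hill-repression ring
#'   (`dx_i/dt = s * Hr(x_{i-1}, r, n) - d * x_i`), integrated with the
#'   package solver; sustains a limit cycle at the default parameters.
#'
#' @param kind Fixture family.
#' @param t_end Horizon.
#' @param dt Sample spacing for the analytic families.
#' @param amplitude,offset,period,duty,threshold Shape parameters.
#' @param s,d,r,n Hill-ring kinetics.
#' @param settings Solver settings for `"hill_ring"`.
#' @return A `cyclephase_trajectory` (with metadata attributes) for `"sine"`
#'   and `"hill_ring"`; a data frame of event records for `"square"`.
#' @export
makeFixture <- function(kind = c("sine", "square", "hill_ring"),
                        t_end = 50, dt = 0.01,
                        amplitude = 0.5, offset = 0.5, period = 2 * pi,
                        duty = 0.3, threshold = 0.75,
                        s = 1, d = 1, r = 0.3, n = 6,
                        settings = solverSettings(t_end = t_end)) {
  kind <- match.arg(kind)
  if (kind == "sine") {
    t <- seq(0, t_end, by = dt)
    x <- offset + amplitude * sin(2 * pi * t / period)
    traj <- newTrajectory(t, matrix(x, ncol = 1), length(t) - 1, 0, "x")
    # closed-form threshold crossings of offset + A sin(w t) = threshold
    u <- (threshold - offset) / amplitude
    if (abs(u) < 1) {
      phi <- asin(u)
      k <- 0:ceiling(t_end / period)
      up <- (phi / (2 * pi) + k) * period
      down <- ((pi - phi) / (2 * pi) + k) * period
      attr(traj, "crossings") <- list(up = up[up <= t_end],
                                      down = down[down <= t_end])
    }
    attr(traj, "period") <- period
    return(traj)
  }
  if (kind == "square") {
    k <- 0:(floor(t_end / period) - 1)
    rec <- data.frame(event = "fixture_event", link = 1L,
                      start = k * period, stop = (k + duty) * period,
                      open_start = FALSE, open_stop = FALSE)
    attr(rec, "period") <- period
    return(rec)
  }
  # hill_ring: three-species repression ring
  rhs <- function(t, y) {
    c(s * hillRepression(y[3], r, n) - d * y[1],
      s * hillRepression(y[1], r, n) - d * y[2],
      s * hillRepression(y[2], r, n) - d * y[3])
  }
  traj <- integrateODE(rhs, c(x1 = 0.9, x2 = 0.1, x3 = 0.2), settings)
  attr(traj, "parameters") <- c(s = s, d = d, r = r, n = n)
  traj
}
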