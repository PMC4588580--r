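# Signaling-event extraction and classification.
#
# An event Source_Verb_Target is active exactly while the source protein's
# concentration exceeds the half-maximal coefficient of the Hill term through
# which it acts on the target. Crossing times are located by linear
# interpolation between accepted integration steps.

#' Capture signaling events from a trajectory
#'
#' @param traj A `cyclephase_trajectory`.
#' @param defs Event definitions as returned by [eventDefinitions()]: a data
#'   frame with columns `event`, `watched`, `threshold` and (optionally)
#'   `link`.
#' @param min_duration Chatter filter: closed activations shorter than this
#'   (in time units) are discarded. Callers analysing periodic runs typically
#'   pass 0.1% of the cycle period.
#' @return A data frame of event records: `event`, `link`, `start`, `stop`,
#'   `open_start`, `open_stop`. Records still active at either end of the
#'   trajectory carry the boundary time with the corresponding `open_*` flag
#'   set.
#' @export
captureEvents <- function(traj, defs, min_duration = 0) {
  stopifnot(is.data.frame(defs), all(c("event", "watched", "threshold") %in%
                                       names(defs)))
  bad <- setdiff(defs$watched, colnames(traj$states))
  if (length(bad))
    stop("event definitions watch unknown species: ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  t <- traj$times
  n <- length(t)
  out <- vector("list", nrow(defs))
  for (i in seq_len(nrow(defs))) {
    x <- traj$states[, defs$watched[i]]
    thr <- defs$threshold[i]
    act <- x > thr
    flips <- which(act[-1] != act[-n])
    # interpolated crossing times
    tc <- t[flips] + (thr - x[flips]) * (t[flips + 1] - t[flips]) /
      (x[flips + 1] - x[flips])
    starts <- tc[!act[flips]]   # inactive -> active
    stops <- tc[act[flips]]     # active -> inactive
    open_start <- open_stop <- logical(0)
    if (act[1]) { starts <- c(t[1], starts); open_start <- TRUE }
    open_start <- c(open_start, rep(FALSE, length(starts) - length(open_start)))
    if (act[n]) { stops <- c(stops, t[n]); open_stop <- c(rep(FALSE, length(stops) - 1), TRUE) }
    else open_stop <- rep(FALSE, length(stops))
    if (length(starts) == 0) next
    stopifnot(length(starts) == length(stops))
    keep <- open_start | open_stop | (stops - starts >= min_duration)
    if (!any(keep)) next
    out[[i]] <- data.frame(
      event = defs$event[i],
      link = if ("link" %in% names(defs)) defs$link[i] else NA_integer_,
      start = starts[keep], stop = stops[keep],
      open_start = open_start[keep], open_stop = open_stop[keep],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(event = character(0), link = integer(0),
                      start = numeric(0), stop = numeric(0),
                      open_start = logical(0), open_stop = logical(0))
  rownames(res) <- NULL
  res
}

# Upward crossings of the mid-range line of one species, used both for the
# period estimate and to delimit classification cycles.
midlineCrossings <- function(traj, species, from = -Inf, to = Inf) {
  sel <- traj$times >= from & traj$times <= to
  t <- traj$times[sel]
  x <- traj$states[sel, species]
  if (length(t) < 3) return(numeric(0))
  mid <- (min(x) + max(x)) / 2
  up <- which(x[-length(x)] <= mid & x[-1] > mid)
  t[up] + (mid - x[up]) * (t[up + 1] - t[up]) / (x[up + 1] - x[up])
}

#' Estimate the oscillation period of one species
#'
#' @param traj A `cyclephase_trajectory`.
#' @param species Species name (default the mitotic marker CDKBa).
#' @param from,to Analysis window.
#' @param method `"crossing"` (mean spacing of upward mid-range crossings) or
#'   `"autocorrelation"` (lag of the first autocorrelation peak on a uniform
#'   resampling).
#' @return Period estimate, or `NA` if fewer than two full cycles are found.
#' @export
estimatePeriod <- function(traj, species = "CDKBa", from = -Inf, to = Inf,
                           method = c("crossing", "autocorrelation")) {
  method <- match.arg(method)
  if (method == "crossing") {
    cr <- midlineCrossings(traj, species, from, to)
    if (length(cr) < 3) return(NA_real_)
    return(mean(diff(cr)))
  }
  sel <- traj$times >= from & traj$times <= to
  t <- traj$times[sel]
  if (length(t) < 8) return(NA_real_)
  grid <- seq(t[1], t[length(t)], length.out = 4096)
  x <- approx(traj$times, traj$states[, species], xout = grid)$y
  x <- x - mean(x)
  r <- as.numeric(stats::acf(x, lag.max = length(grid) %/% 2,
                             plot = FALSE)$acf)
  neg <- which(r < 0)
  if (!length(neg)) return(NA_real_)
  after <- seq(neg[1], length(r))
  lag <- after[which.max(r[after])] - 1
  lag * (grid[2] - grid[1])
}

# Analysis window: discard the first `cycles` full cycles of the marker
# species, or the first `frac` of the horizon when no cycles are detectable.
analysisWindow <- function(traj, species = "CDKBa", cycles = 3, frac = 0.25) {
  t_end <- traj$times[length(traj$times)]
  cr <- midlineCrossings(traj, species)
  start <- if (length(cr) >= cycles + 1) cr[cycles + 1] else frac * t_end
  if (start > 0.5 * t_end) start <- frac * t_end
  c(start, t_end)
}

#' Classify a run as 0 / 1 / 2
#'
#' After discarding the initial transient, a run is classified as:
#' * `0` - no sustained oscillation (peak-to-trough amplitude of the marker
#'   species below `min_amplitude`, or fewer than two complete cycles),
#' * `1` - oscillating, but at least one defined event is absent in some
#'   analyzed cycle, active across an entire cycle (persistent), or occurs
#'   more than once per cycle,
#' * `2` - oscillating with every defined event occurring exactly once per
#'   analyzed cycle with both start and stop.
#'
#' @param traj A `cyclephase_trajectory`.
#' @param defs Event definitions ([eventDefinitions()]).
#' @param marker Species whose oscillation defines cycles (default CDKBa).
#' @param min_amplitude Oscillation threshold on the 0-1 concentration scale.
#' @param discard_cycles,discard_frac Transient discard (first cycles, or
#'   first fraction of the horizon when cycles cannot be delimited).
#' @param chatter Fraction of the period below which activations are
#'   discarded as interpolation chatter.
#' @return A `cyclephase_runclass`: list with `code` (0/1/2), `detail` (per
#'   event status), `cycles` (boundaries used), `period`, `events` (records).
#' @export
classifyRun <- function(traj, defs, marker = "CDKBa", min_amplitude = 0.05,
                        discard_cycles = 3, discard_frac = 0.25,
                        chatter = 0.001) {
  win <- analysisWindow(traj, marker, discard_cycles, discard_frac)
  sel <- traj$times >= win[1]
  x <- traj$states[sel, marker]
  amp <- if (length(x)) max(x) - min(x) else 0
  bounds <- midlineCrossings(traj, marker, win[1], win[2])
  result <- function(code, detail, period = NA_real_, events = NULL)
    structure(list(code = code, detail = detail, cycles = bounds,
                   period = period, events = events,
                   amplitude = amp, window = win),
              class = "cyclephase_runclass")
  if (amp < min_amplitude || length(bounds) < 3)
    return(result(0L, data.frame(event = defs$event,
                                 status = "no-oscillation")))
  period <- mean(diff(bounds))
  recs <- captureEvents(traj, defs, min_duration = chatter * period)
  status <- character(nrow(defs))
  for (i in seq_len(nrow(defs))) {
    r <- recs[recs$event == defs$event[i], , drop = FALSE]
    st <- "periodic"
    for (ci in seq_len(length(bounds) - 1)) {
      lo <- bounds[ci]; hi <- bounds[ci + 1]
      n_start <- sum(r$start >= lo & r$start < hi & !r$open_start)
      n_stop <- sum(r$stop >= lo & r$stop < hi & !r$open_stop)
      spanning <- any(r$start <= lo & r$stop >= hi)
      if (spanning) { st <- "persistent"; break }
      if (n_start == 0 && n_stop == 0) { st <- "absent"; break }
      if (n_start > 1 || n_stop > 1) { st <- "irregular"; break }
    }
    status[i] <- st
  }
  detail <- data.frame(event = defs$event, status = status,
                       stringsAsFactors = FALSE)
  code <- if (all(status == "periodic")) 2L else 1L
  result(code, detail, period, recs)
}

#' @export
print.cyclephase_runclass <- function(x, ...) {
  lab <- c("0 (no oscillation)", "1 (oscillating, aberrant events)",
           "2 (all events periodic)")[x$code + 1]
  cat("Run class:", lab, "\n")
  if (x$code == 1) {
    bad <- x$detail[x$detail$status != "periodic", ]
    cat("Aberrant events:",
        paste(sprintf("%s [%s]", bad$event, bad$status), collapse = ", "),
        "\n")
  }
  if (!is.na(x$period)) cat("Period:", format(x$period, digits = 4), "\n")
  invisible(x)
}

# first edge time of a given kind for one event inside a window
edgeIn <- function(recs, event, edge, lo, hi) {
  r <- recs[recs$event == event, , drop = FALSE]
  v <- if (edge == "start") r$start[!r$open_start] else r$stop[!r$open_stop]
  v <- v[v >= lo & v < hi]
  if (length(v)) v[1] else NA_real_
}

#' Mark G1/S/G2/M phase boundaries from event records
#'
#' Phase starts follow the event-edge convention: G1 starts at the stop of
#' `CDKBa_Ubi_E2F1`; S at the stop of `DapE2F2_Rep_CycA` together with the
#' start of `E2F1_Act_CycA` (the later of the two); G2 at the start of
#' `Stga_Rep_CDKBi`; M at the start of `APCFzy_Ubi_CDKBi` /
#' `APCFzy_Ubi_CDKBa` (the earlier). The reported aggregates are G1S (G1
#' start to G2 start) and G2M (G2 start to the next G1 start).
#'
#' @param events Event records from [captureEvents()].
#' @param from Ignore cycles starting before this time (transient discard).
#' @return A `cyclephase_phases` data frame: one row per complete cycle with
#'   boundary times, `g1s`, `g2m`, `total`, `frac_g1s`, `frac_g2m`. Cycles
#'   with missing or mis-ordered markers are excluded; their count is in
#'   `attr(, "excluded")`.
#' @export
markPhases <- function(events, from = -Inf) {
  g1 <- events[events$event == "CDKBa_Ubi_E2F1" & !events$open_stop, "stop"]
  g1 <- sort(g1[g1 >= from])
  if (length(g1) < 3)
    stop("insufficient data: fewer than 2 complete cycles with G1 markers",
         call. = FALSE)
  rows <- list(); excluded <- 0L
  for (i in seq_len(length(g1) - 1)) {
    lo <- g1[i]; hi <- g1[i + 1]
    s1 <- edgeIn(events, "DapE2F2_Rep_CycA", "stop", lo, hi)
    s2 <- edgeIn(events, "E2F1_Act_CycA", "start", lo, hi)
    s <- suppressWarnings(max(s1, s2))
    g2 <- edgeIn(events, "Stga_Rep_CDKBi", "start", lo, hi)
    m1 <- edgeIn(events, "APCFzy_Ubi_CDKBi", "start", lo, hi)
    m2 <- edgeIn(events, "APCFzy_Ubi_CDKBa", "start", lo, hi)
    m <- suppressWarnings(min(m1, m2, na.rm = TRUE))
    if (!is.finite(m)) m <- NA_real_
    if (anyNA(c(s, g2, m)) || !(lo < s && s < g2 && g2 < m && m < hi)) {
      excluded <- excluded + 1L
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      cycle = i, g1_start = lo, s_start = s, g2_start = g2, m_start = m,
      g1s = g2 - lo, g2m = hi - g2, total = hi - lo,
      frac_g1s = (g2 - lo) / (hi - lo), frac_g2m = (hi - g2) / (hi - lo))
  }
  if (!length(rows))
    stop("insufficient data: no cycle carries all four phase markers",
         call. = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("cyclephase_phases", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

#' Ordered sequence of event edges within one cycle
#'
#' Reconstructs the order of signaling-event starts and stops in a cycle
#' window; ties are broken by ascending link id.
#'
#' @param events Event records from [captureEvents()].
#' @param from,to Cycle window (e.g. consecutive G1 starts).
#' @return A data frame `event`, `link`, `edge` (start/stop), `time`, in
#'   temporal order.
#' @export
eventOrder <- function(events, from, to) {
  st <- events[events$start >= from & events$start < to & !events$open_start,
               c("event", "link", "start")]
  sp <- events[events$stop >= from & events$stop < to & !events$open_stop,
               c("event", "link", "stop")]
  df <- rbind(
    if (nrow(st)) data.frame(event = st$event, link = st$link, edge = "start",
                             time = st$start) else NULL,
    if (nrow(sp)) data.frame(event = sp$event, link = sp$link, edge = "stop",
                             time = sp$stop) else NULL)
  if (is.null(df))
    return(data.frame(event = character(0), link = integer(0),
                      edge = character(0), time = numeric(0)))
  df <- df[order(df$time, df$link), ]
  rownames(df) <- NULL
  df
}

#' Simulate, capture events, segment phases and classify in one call
#'
#' @param model A `cyclephase_model`.
#' @param settings Solver settings.
#' @param ... Passed to [classifyRun()].
#' @return A `cyclephase_run`: list with `trajectory`, `events` (records over
#'   the full run), `class` (a `cyclephase_runclass`), `phases` (or NULL when
#'   markers are missing), `period`, `defs`.
#' @export
analyzeRun <- function(model, settings = solverSettings(), ...) {
  traj <- integrateModel(model, settings)
  defs <- eventDefinitions(model)
  cls <- classifyRun(traj, defs, ...)
  period <- cls$period
  recs <- if (!is.null(cls$events)) cls$events
          else captureEvents(traj, defs)
  phases <- NULL
  if (cls$code >= 1) {
    phases <- tryCatch(markPhases(recs, from = cls$window[1]),
                       error = function(e) NULL)
  }
  structure(list(trajectory = traj, events = recs, class = cls,
                 phases = phases, period = period, defs = defs),
            class = "cyclephase_run")
}

#' @export
print.cyclephase_run <- function(x, ...) {
  print(x$class)
  if (!is.null(x$phases)) {
    cat(sprintf("Mean phase lengths over %d cycles: G1S = %.3f, G2M = %.3f (%.2f%% / %.2f%%)\n",
                nrow(x$phases), mean(x$phases$g1s), mean(x$phases$g2m),
                100 * mean(x$phases$frac_g1s), 100 * mean(x$phases$frac_g2m)))
  }
  invisible(x)
}

#' Export event records as JSON lines
#' @param events Event records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEventsJSONL <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events)))
    writeLines(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE), con)
  invisible(path)
}
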