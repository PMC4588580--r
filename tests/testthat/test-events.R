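sineDefs <- function(threshold = 0.75) {
  data.frame(event = "x_cross", watched = "x", threshold = threshold,
             link = 1L, stringsAsFactors = FALSE)
}

test_that("threshold crossings of a sine are located at the analytic times", {
  fx <- makeFixture("sine", t_end = 4 * pi, dt = 0.01, threshold = 0.75)
  recs <- captureEvents(fx, sineDefs())
  cr <- attr(fx, "crossings")
  ups <- sort(cr$up)[seq_len(nrow(recs))]
  downs <- sort(cr$down)[seq_len(nrow(recs))]
  expect_equal(nrow(recs), 2)  # two full periods
  expect_true(all(abs(recs$start - ups) < 0.01))
  expect_true(all(abs(recs$stop - downs) < 0.01))
})

test_that("a series that never reaches the threshold yields no records", {
  fx <- makeFixture("sine", t_end = 10, amplitude = 0.1, offset = 0.3)
  recs <- captureEvents(fx, sineDefs(0.75))
  expect_equal(nrow(recs), 0)
})

test_that("the chatter filter drops activations shorter than the cutoff", {
  t <- seq(0, 10, by = 0.01)
  x <- rep(0.1, length(t))
  x[t > 2 & t < 2.02] <- 0.9    # 0.02-long blip
  x[t > 5 & t < 6] <- 0.9       # genuine 1.0-long activation
  traj <- structure(list(times = t,
                         states = matrix(x, ncol = 1,
                                         dimnames = list(NULL, "x")),
                         accepted = length(t), rejected = 0),
                    class = "cyclephase_trajectory")
  all_recs <- captureEvents(traj, sineDefs(0.5))
  expect_equal(nrow(all_recs), 2)
  filtered <- captureEvents(traj, sineDefs(0.5), min_duration = 0.1)
  expect_equal(nrow(filtered), 1)
  expect_true(filtered$start > 4)
  expect_error(captureEvents(traj, data.frame(event = "e", watched = "nope",
                                              threshold = 1)),
               "unknown species")
})

test_that("event ordering is by time with ties broken by link id", {
  recs <- data.frame(event = c("A", "B", "C"), link = c(2L, 3L, 1L),
                     start = c(1, 2, 1), stop = c(3, 4, 5),
                     open_start = FALSE, open_stop = FALSE)
  ord <- eventOrder(recs, 0, 6)
  expect_equal(ord$event, c("C", "A", "B", "A", "B", "C"))
  expect_equal(ord$edge, c("start", "start", "start", "stop", "stop", "stop"))
  # C and A start simultaneously; C (link 1) precedes A (link 2)
  expect_equal(ord$link[1:2], c(1L, 2L))
  expect_equal(nrow(eventOrder(recs, 10, 20)), 0)
})

test_that("phase arithmetic on a fabricated marker log", {
  mk <- function(event, start, stop) {
    data.frame(event = event, link = 1L, start = start, stop = stop,
               open_start = FALSE, open_stop = FALSE)
  }
  # two cycles: G1 at 0 and 11 and 22; S at 8, G2 at 9, M at 10 (+11)
  ev <- rbind(
    mk("CDKBa_Ubi_E2F1", c(-1, 10.2, 21.2), c(0, 11, 22)),
    mk("DapE2F2_Rep_CycA", c(5, 16), c(8, 19)),
    mk("E2F1_Act_CycA", c(7.5, 18.5), c(8.5, 19.5)),
    mk("Stga_Rep_CDKBi", c(9, 20), c(10.5, 21.5)),
    mk("APCFzy_Ubi_CDKBi", c(10, 21), c(10.8, 21.8)),
    mk("APCFzy_Ubi_CDKBa", c(10.4, 21.4), c(10.9, 21.9)))
  ph <- markPhases(ev)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$g1s, c(9, 9))
  expect_equal(ph$g2m, c(2, 2))
  expect_equal(ph$total, c(11, 11))
  expect_equal(ph$frac_g1s + ph$frac_g2m, c(1, 1))
  expect_equal(ph$s_start, c(8, 19))   # later of the two S markers
  expect_equal(ph$m_start, c(10, 21))  # earlier of the two M markers
  # fewer than two complete cycles is an error
  expect_error(markPhases(ev[ev$start < 11, ]), "insufficient")
})

test_that("a flat trajectory classifies as 0 and the default run as 2", {
  flat <- makeFixture("sine", t_end = 60, amplitude = 0, offset = 0.4)
  cls0 <- classifyRun(flat, sineDefs(0.3), marker = "x")
  expect_equal(cls0$code, 0L)
  run <- cachedRun()
  expect_equal(run$class$code, 2L)
  expect_true(all(run$class$detail$status == "periodic"))
})

test_that("Skp2 ubiquitination of CycE occurs exactly once per cycle", {
  run <- cachedRun()
  bounds <- run$class$cycles
  starts <- run$events$start[run$events$event == "Skp2_Ubi_CycE"]
  per_cycle <- vapply(seq_len(length(bounds) - 1), function(i)
    sum(starts >= bounds[i] & starts < bounds[i + 1]), 0L)
  expect_true(all(per_cycle == 1))
})

test_that("raising an event's half-max threshold delays or abolishes its start", {
  run <- cachedRun()
  traj <- run$trajectory
  from <- run$class$window[1]
  for (ev in c("Plx_Act_APCFzy", "E2F1_Act_CycA", "Stga_Rep_CDKBi",
               "CDKE_Ubi_Rux")) {
    d0 <- run$defs[run$defs$event == ev, ]
    first_start <- function(thr) {
      d <- d0; d$threshold <- thr
      r <- captureEvents(traj, d)
      s <- r$start[r$start > from & !r$open_start]
      if (length(s)) s[1] else Inf
    }
    t_lo <- first_start(d0$threshold)
    t_hi <- first_start(d0$threshold * 1.25)
    expect_true(t_hi > t_lo)
  }
})

test_that("marker-derived period matches the autocorrelation period within 5%", {
  run <- cachedRun()
  traj <- run$trajectory
  from <- run$class$window[1]
  p_cross <- mean(run$phases$total)
  p_acf <- estimatePeriod(traj, "CDKBa", from = from,
                          method = "autocorrelation")
  expect_lt(abs(p_cross - p_acf) / p_cross, 0.05)
})

test_that("event records export as JSON lines", {
  recs <- data.frame(event = c("A", "B"), link = 1:2, start = c(1, 2),
                     stop = c(3, 4), open_start = FALSE, open_stop = FALSE)
  path <- tempfile(fileext = ".jsonl")
  writeEventsJSONL(recs, path)
  lines <- readLines(path)
  expect_length(lines, 2)
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$event, "A")
  expect_equal(parsed$stop, 3)
})
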