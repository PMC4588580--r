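test_that("a no-op perturbation reproduces the default compensation row exactly", {
  m <- cachedModel()
  st <- shortSettings()
  tab <- phaseCompensation(m, list("no-op" = NULL), settings = st)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$g1s[1], tab$g1s[2])
  expect_identical(tab$g2m[1], tab$g2m[2])
  expect_equal(tab$code, c(2L, 2L))
})

test_that("a zero-factor scan reproduces the unperturbed classification everywhere", {
  m <- cachedModel()
  sc <- robustnessScan(m, factor = 0, settings = solverSettings(t_end = 120))
  expect_equal(nrow(sc$outcomes), 76)
  expect_true(all(sc$outcomes$code == 2L))
  expect_equal(sc$failures, 0)
  expect_true(all(pairRank(sc$pairs$up, sc$pairs$down) == 6L))
})

test_that("a no-op rescue experiment reports (2, 2)", {
  m <- cachedModel()
  res <- rescueExperiment(m, break_params = NULL, rescue_params = NULL,
                          settings = shortSettings())
  expect_equal(res$before, 2L)
  expect_equal(res$after, 2L)
})

test_that("a single-point sweep at the defaults reports class 2 with a period", {
  m <- cachedModel()
  sw <- bifurcationSweep(m, "GF", 1.0, settings = shortSettings())
  expect_equal(sw$code, 2L)
  expect_gt(sw$period, 5)
  expect_gt(sw$amplitude, 0.05)
})

test_that("growth-factor onset is monotone: quiescent below, cycling above", {
  m <- cachedModel()
  sw <- bifurcationSweep(m, "GF", c(0.05, 0.1, 0.6, 1.0),
                         settings = shortSettings())
  expect_equal(sw$code[1:2], c(0L, 0L))
  expect_true(all(sw$code[3:4] >= 1L))
})

test_that("mid-run parameter switching carries state across segments", {
  m <- cachedModel()
  st <- solverSettings(t_end = 60)
  tr <- simulateSchedule(m, list(list(time = 30, params = c(s_Dap = 0))), st)
  expect_equal(tr$times[length(tr$times)], 60)
  expect_true(!is.unsorted(tr$times, strictly = TRUE))
  # Dap synthesis off after the switch: Dap must collapse
  before <- tr$states[max(which(tr$times <= 29.9)), "Dap"]
  after <- tr$states[length(tr$times), "Dap"]
  expect_gt(before, 0.1)
  expect_lt(after, 0.05)
  # the un-switched segment matches a plain run
  plain <- integrateModel(m, solverSettings(t_end = 30))
  expect_equal(tr$states[length(plain$times), ],
               plain$states[nrow(plain$states), ], tolerance = 1e-10)
})

test_that("compensation direction: more Dap favors G1/S, more Wee favors G2/M", {
  m <- cachedModel()
  st <- solverSettings(t_end = 250)
  tab <- phaseCompensation(m, list("High Dap" = c(s_Dap = 1.05),
                                   "High Wee" = c(s_Wee = 1.8)),
                           settings = st)
  expect_true(all(tab$code == 2L))
  expect_gt(tab$frac_g1s[2], tab$frac_g1s[1])
  expect_gt(tab$frac_g2m[3], tab$frac_g2m[1])
})

test_that("GF shows a hysteresis band: history selects the E2F1 attractor", {
  m <- cachedModel()
  tr <- integrateModel(m, solverSettings(t_end = 60))
  on_state <- tr$states[which.max(tr$states[, "E2F1"]), ]
  st <- solverSettings(t_end = 150)
  separated <- vapply(c(0.3, 0.35, 0.4), function(gf) {
    mg <- setParameters(m, GF = gf)
    e_rest <- mean(tail(integrateModel(mg, st)$states[, "E2F1"], 200))
    e_on <- mean(tail(integrateModel(mg, st, y0 = on_state)$states[, "E2F1"],
                      200))
    abs(e_rest - e_on) > 0.2
  }, logical(1))
  expect_true(any(separated))
})

test_that("the proteolysis block keeps a strict order across Dap and Wee overexpression", {
  st <- solverSettings(t_end = 250)
  protStarts <- function(m) {
    run <- analyzeRun(m, st)
    ph <- run$phases
    ord <- eventOrder(run$events, ph$g1_start[3], ph$g1_start[4])
    keep <- ord$edge == "start" &
      sub("_.*", "", ord$event) %in% c("Skp2", "APCFzy", "APCFzr")
    ord$event[keep]
  }
  m <- cachedModel()
  o_def <- protStarts(m)
  o_dap <- protStarts(setParameters(m, s_Dap = 1.05))
  o_wee <- protStarts(setParameters(m, s_Wee = 1.8))
  expect_equal(length(o_def), 14)  # links 9-11, 37-41, 42-47
  expect_identical(o_def, o_dap)
  expect_identical(o_def, o_wee)
})
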