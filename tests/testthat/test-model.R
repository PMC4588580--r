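test_that("shipped default declares 25 species, 47 links and 38 events", {
  m <- cachedModel()
  sp <- speciesNames(m)
  expect_length(sp, 25)
  expect_false(anyDuplicated(sp) > 0)
  links <- interactionTable(m)
  expect_equal(sort(links$link), 1:47)
  defs <- eventDefinitions(m)
  expect_equal(nrow(defs), 38)
  expect_false(anyDuplicated(defs$event) > 0)
  expect_true(all(grepl("^[A-Za-z0-9]+_(Act|Rep|Ubi)_[A-Za-z0-9]+$",
                        defs$event)))
  expect_true(all(initialState(m) >= 0))
})

test_that("Hill-mode links carry half-max parameters, mass-action links do not", {
  links <- interactionTable(cachedModel())
  hill <- links$mode %in% c("activate", "repress", "ubiquitinate",
                            "phosphorylate")
  expect_true(all(!is.na(links$half_max_param[hill])))
  expect_true(all(is.na(links$half_max_param[!hill])))
  pars <- modelParameters(cachedModel())
  expect_true(all(links$rate_param %in% names(pars)))
  expect_true(all(pars > 0 | names(pars) %in% c("GF")))
})

test_that("all-zero state derivative reduces to synthesis plus the Rb return flux", {
  m <- cachedModel()
  p <- modelParameters(m)
  rhs <- buildRhs(m)
  dy <- rhs(0, stats::setNames(rep(0, 25), speciesNames(m)))
  # with every concentration at zero all mass-action and substrate-linear
  # terms vanish; what remains is constant synthesis (repressive gates open,
  # activating gates shut) plus Rb dephosphorylation fed by the Rbp
  # remainder (Rb_tot at the zero state)
  expected <- stats::setNames(rep(0, 25), speciesNames(m))
  expected["CycE"] <- p["s_CycEb"] * p["GF"]
  expected["E2F1"] <- p["s_E2F1b"]
  expected["E2F2"] <- p["s_E2F2"]
  expected["Dap"] <- p["s_Dap"]
  expected["Rux"] <- p["s_Rux"]
  expected["Skp2"] <- p["s_Skp2"]
  expected["CycB"] <- p["s_CycB"]
  expected["Wee"] <- p["s_Wee"]
  expected["APCFzr"] <- p["s_Fzr"]
  rbp <- p["Rb_tot"]
  expected["Rb"] <- p["p_Rb"] * rbp / (p["a_RbRb"] + rbp) * rbp
  expect_equal(dy, expected, tolerance = 1e-12)
})

test_that("raising a_PlxFzy weakens APCFzy production at a fixed state", {
  m <- cachedModel()
  y <- initialState(m)
  y["Plx"] <- 0.4
  d1 <- buildRhs(m)(0, y)["APCFzy"]
  d2 <- buildRhs(setParameters(m, a_PlxFzy = 0.6))(0, y)["APCFzy"]
  d3 <- buildRhs(setParameters(m, a_PlxFzy = 1.2))(0, y)["APCFzy"]
  expect_true(d1 > d2)
  expect_true(d2 > d3)
})

test_that("Cdk bookkeeping cancels exactly at random states", {
  m <- cachedModel()
  rhs <- buildRhs(m)
  sp <- speciesNames(m)
  cdk1_pool <- c("Cdk1", "CDKA", "CDKARux", "CDKBi", "CDKBa")
  cdk2_pool <- c("Cdk2", "CDKE", "CDKEDap")
  set.seed(42)
  for (i in 1:20) {
    y <- stats::setNames(runif(25, 0, 1), sp)
    dy <- rhs(0, y)
    expect_equal(sum(dy[cdk1_pool]), 0, tolerance = 1e-12)
    expect_equal(sum(dy[cdk2_pool]), 0, tolerance = 1e-12)
  }
})

test_that("shared-kinase competition: more CycB-like load lowers the CycA-like complex", {
  lowY <- loadConfigList(competitionConfig(s_Y = 0.1))
  highY <- loadConfigList(competitionConfig(s_Y = 0.8))
  st <- solverSettings(t_end = 60, h_max = 0.1)
  cx_low <- tail(integrateModel(lowY, st)$states[, "CX"], 1)
  cx_high <- tail(integrateModel(highY, st)$states[, "CX"], 1)
  expect_true(cx_high < cx_low)
  # the shared pool is conserved in both
  tr <- integrateModel(highY, st)
  tot <- rowSums(tr$states[, c("K", "CX", "CY")])
  expect_lt(max(abs(tot - 1)), 1e-9)
})

test_that("configuration errors are descriptive", {
  m <- cachedModel()
  cfg <- m$config

  # empty / schema-less file
  empty <- tempfile(fileext = ".yaml")
  writeLines("", empty)
  expect_error(loadModelConfig(empty), "schema")

  # event naming an absent parameter is reported by name
  broken <- cfg
  broken$events[[1]]$param <- "a_NoSuchParam"
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(broken, path)
  expect_error(loadModelConfig(path), "a_NoSuchParam")

  # dangling species in a flux
  broken2 <- cfg
  broken2$fluxes[[1]]$produces <- list("Ghost")
  yaml::write_yaml(broken2, path)
  expect_error(loadModelConfig(path), "Ghost")

  # unknown parameter updates are rejected
  expect_error(setParameters(m, not_a_param = 1), "not_a_param")
  expect_error(setParameters(m, s_Dap = -1), ">= 0")
})

test_that("model configurations round-trip through save and load", {
  m <- cachedModel()
  path <- tempfile(fileext = ".yaml")
  saveModelConfig(m, path)
  m2 <- loadModelConfig(path)
  expect_equal(m2$config$parameters, m$config$parameters)
  expect_equal(speciesNames(m2), speciesNames(m))
  expect_equal(interactionTable(m2), interactionTable(m))
  expect_equal(eventDefinitions(m2), eventDefinitions(m))
  # and a second round trip is canonical
  path2 <- tempfile(fileext = ".yaml")
  saveModelConfig(m2, path2)
  expect_equal(yaml::read_yaml(path2), yaml::read_yaml(path))
})
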