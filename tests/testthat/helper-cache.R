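# Shared, lazily computed objects reused across test files. The default run
# is deterministic, so caching does not couple tests.
.cache <- new.env(parent = emptyenv())

cachedModel <- function() {
  if (is.null(.cache$model)) .cache$model <- defaultModel()
  .cache$model
}

cachedRun <- function() {
  if (is.null(.cache$run))
    .cache$run <- analyzeRun(cachedModel(), solverSettings(t_end = 250))
  .cache$run
}

shortSettings <- function(t_end = 150) solverSettings(t_end = t_end)

# Minimal two-cyclin / one-kinase competition fixture: X and Y bind a shared
# conserved kinase pool K into complexes CX and CY. Raising Y synthesis must
# lower the steady level of CX at fixed X synthesis.
competitionConfig <- function(s_Y = 0.3) {
  list(
    schema = "cyclephase-model/1",
    hill = list(n = 6, n_rb_dephos = 1),
    species = list(
      list(name = "X", init = 0), list(name = "Y", init = 0),
      list(name = "K", init = 1),
      list(name = "CX", init = 0), list(name = "CY", init = 0)),
    derived = list(),
    parameters = list(s_X = 0.3, s_Y = s_Y, d_X = 0.2, d_Y = 0.2,
                      k_X = 10, k_Y = 10, kk_X = 0.2, kk_Y = 0.2,
                      d_CX = 0.3, d_CY = 0.3),
    links = list(
      list(link = 1, source = "X", target = "CX", mode = "bind",
           rate_param = "k_X"),
      list(link = 2, source = "Y", target = "CY", mode = "bind",
           rate_param = "k_Y")),
    fluxes = list(
      list(rate = "s_X", produces = list("X")),
      list(rate = "s_Y", produces = list("Y")),
      list(rate = "d_X", consumes = list("X")),
      list(rate = "d_Y", consumes = list("Y")),
      list(rate = "k_X", consumes = list("X", "K"), produces = list("CX"),
           links = list(1L)),
      list(rate = "kk_X", consumes = list("CX"), produces = list("X", "K"),
           links = list(1L)),
      list(rate = "k_Y", consumes = list("Y", "K"), produces = list("CY"),
           links = list(2L)),
      list(rate = "kk_Y", consumes = list("CY"), produces = list("Y", "K"),
           links = list(2L)),
      list(rate = "d_CX", consumes = list("CX"), produces = list("K")),
      list(rate = "d_CY", consumes = list("CY"), produces = list("K"))),
    events = list(
      list(name = "X_Bind_K", watched = "X", param = "k_X", link = 1)),
    markers = NULL)
}

loadConfigList <- function(cfg) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  loadModelConfig(path)
}
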