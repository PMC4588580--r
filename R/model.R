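#' Load a cell cycle model from a plain-text configuration file
#'
#' Reads a YAML model definition (species with initial values, conserved
#' totals, parameters, the numbered interaction links, the flux list built
#' from them, signaling-event definitions, and phase-marker conventions) and
#' returns a validated `cyclephase_model` object.
#'
#' @param path Path to a model configuration file. The package default
#'   (25 species, 47 links, 38 events) ships at
#'   `system.file("extdata", "default_model.yaml", package = "cyclephase")`.
#' @return A `cyclephase_model` object.
#' @seealso [defaultModel()], [buildRhs()], [integrateModel()]
#' @export
loadModelConfig <- function(path) {
  if (!file.exists(path))
    stop("model configuration file not found: ", path, call. = FALSE)
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop("cannot parse model configuration '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  if (!is.list(cfg) || is.null(cfg$schema) ||
      !identical(cfg$schema, "cyclephase-model/1"))
    stop("not a cyclephase model configuration (missing or unknown 'schema')",
         call. = FALSE)
  required <- c("species", "parameters", "fluxes", "events", "links", "hill")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("model configuration lacks section(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  model <- structure(list(config = cfg, path = path),
                     class = "cyclephase_model")
  validateModel(model)
  model
}

#' The shipped default cell cycle model
#'
#' Convenience loader for the default configuration: 25 species, the 47
#' numbered interaction links, and 38 signaling events, with the package's
#' calibrated parameter set.
#'
#' @return A `cyclephase_model` object.
#' @export
defaultModel <- function() {
  loadModelConfig(system.file("extdata", "default_model.yaml",
                              package = "cyclephase"))
}

#' @export
print.cyclephase_model <- function(x, ...) {
  cfg <- x$config
  cat("Cell cycle model:", length(cfg$species), "species,",
      length(cfg$links), "links,", length(cfg$fluxes), "fluxes,",
      length(cfg$events), "signaling events\n")
  cat("Hill exponent:", cfg$hill[["n"]],
      "(Rb auto-dephosphorylation:", paste0(cfg$hill$n_rb_dephos, ")"), "\n")
  cat("Parameters:", length(cfg$parameters), "\n")
  invisible(x)
}

#' Species names of a model
#' @param model A `cyclephase_model`.
#' @return Character vector of the species names, in state-vector order.
#' @export
speciesNames <- function(model) {
  vapply(model$config$species, `[[`, "", "name")
}

#' Initial state of a model
#' @param model A `cyclephase_model`.
#' @return Named numeric vector of initial concentrations.
#' @export
initialState <- function(model) {
  init <- vapply(model$config$species, function(s) as.numeric(s$init), 0)
  names(init) <- speciesNames(model)
  init
}

#' Model parameters
#' @param model A `cyclephase_model`.
#' @return Named numeric vector of all parameter values.
#' @export
modelParameters <- function(model) {
  unlist(model$config$parameters)
}

#' The numbered interaction network as a table
#'
#' @param model A `cyclephase_model`.
#' @return A data frame with one row per numbered link: `link`, `source`,
#'   `target`, `mode`, `rate_param`, `half_max_param` (NA for mass-action
#'   binding/unbinding), and `event` (NA where the link defines no event).
#' @export
interactionTable <- function(model) {
  rows <- lapply(model$config$links, function(l) {
    data.frame(link = as.integer(l$link), source = l$source,
               target = l$target, mode = l$mode, rate_param = l$rate_param,
               half_max_param = if (is.null(l$half_max_param)) NA_character_
                                else l$half_max_param,
               event = if (is.null(l$event)) NA_character_ else l$event,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Signaling-event definitions of a model
#'
#' @param model A `cyclephase_model`.
#' @return A data frame with one row per defined event: `event`, `watched`
#'   (the species whose concentration is compared against the threshold),
#'   `param` (the governing half-max coefficient), `threshold` (its current
#'   value), and `link`.
#' @export
eventDefinitions <- function(model) {
  pars <- modelParameters(model)
  rows <- lapply(model$config$events, function(e) {
    data.frame(event = e$name, watched = e$watched, param = e$param,
               threshold = unname(pars[[e$param]]),
               link = as.integer(e$link), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Modify model parameters
#'
#' Returns a copy of the model with the named parameters set to new values.
#' Used to express perturbation experiments, e.g.
#' `setParameters(model, s_Dap = 1.05)`.
#'
#' @param model A `cyclephase_model`.
#' @param ... Named parameter values, or a single named list/vector.
#' @return The modified `cyclephase_model`.
#' @export
setParameters <- function(model, ...) {
  upd <- list(...)
  if (!length(upd)) return(model)
  if (length(upd) == 1L && is.null(names(upd)))
    upd <- as.list(upd[[1]])
  if (is.null(names(upd)) || any(!nzchar(names(upd))))
    stop("parameter updates must be named", call. = FALSE)
  unknown <- setdiff(names(upd), names(model$config$parameters))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- vapply(upd, as.numeric, 0)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("parameter values must be finite and >= 0", call. = FALSE)
  for (nm in names(upd)) model$config$parameters[[nm]] <- unname(vals[[nm]])
  model$compiled <- NULL
  model
}

#' Scale model parameters by a factor
#'
#' @param model A `cyclephase_model`.
#' @param param Parameter name.
#' @param factor Multiplier applied to the current value.
#' @return The modified model.
#' @export
scaleParameter <- function(model, param, factor) {
  cur <- model$config$parameters[[param]]
  if (is.null(cur)) stop("unknown parameter: ", param, call. = FALSE)
  args <- list(model)
  args[[param]] <- cur * factor
  do.call(setParameters, args)
}

#' Write a model configuration back to YAML
#'
#' Canonical round-trip partner of [loadModelConfig()]: writing a loaded
#' model and re-loading it yields an identical configuration.
#'
#' @param model A `cyclephase_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
saveModelConfig <- function(model, path) {
  yaml::write_yaml(model$config, path)
  invisible(path)
}

# --- validation ------------------------------------------------------------

validateModel <- function(model) {
  cfg <- model$config
  sp <- vapply(cfg$species, function(s) as.character(s$name), "")
  if (anyDuplicated(sp))
    stop("duplicate species names: ",
         paste(unique(sp[duplicated(sp)]), collapse = ", "), call. = FALSE)
  init <- vapply(cfg$species, function(s) as.numeric(s$init), 0)
  if (any(!is.finite(init)) || any(init < 0))
    stop("initial values must be finite and >= 0", call. = FALSE)
  pars <- cfg$parameters
  pv <- unlist(pars)
  if (any(!is.finite(pv)) || any(pv < 0))
    stop("parameter values must be finite and >= 0", call. = FALSE)
  if (is.null(cfg$hill[["n"]]) || is.null(cfg$hill[["n_rb_dephos"]]))
    stop("hill section must define 'n' and 'n_rb_dephos'", call. = FALSE)
  if (cfg$hill[["n"]] < 1 || cfg$hill[["n_rb_dephos"]] < 1)
    stop("Hill exponents must be >= 1", call. = FALSE)

  derived <- character(0)
  for (d in cfg$derived) {
    if (is.null(pars[[d$total_param]]))
      stop("derived species '", d$name, "' references missing total parameter '",
           d$total_param, "'", call. = FALSE)
    bad <- setdiff(unlist(d$members), sp)
    if (length(bad))
      stop("derived species '", d$name, "' references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    derived <- c(derived, d$name)
  }
  known <- c(sp, derived)

  link_ids <- vapply(cfg$links, function(l) as.integer(l$link), 0L)
  if (anyDuplicated(link_ids))
    stop("duplicate link ids", call. = FALSE)
  for (l in cfg$links) {
    hill_mode <- l$mode %in% c("activate", "repress", "ubiquitinate",
                               "phosphorylate")
    if (hill_mode && is.null(l$half_max_param))
      stop("link ", l$link, " (mode ", l$mode,
           ") must carry a half-max parameter", call. = FALSE)
    if (!hill_mode && !is.null(l$half_max_param))
      stop("link ", l$link, " (mode ", l$mode,
           ") must not carry a half-max parameter", call. = FALSE)
    for (p in c(l$rate_param, l$half_max_param))
      if (is.null(pars[[p]]))
        stop("link ", l$link, " references missing parameter '", p, "'",
             call. = FALSE)
    for (s in c(l$source, l$target))
      if (!s %in% known)
        stop("link ", l$link, " references unknown species '", s, "'",
             call. = FALSE)
  }

  cited <- integer(0)
  for (i in seq_along(cfg$fluxes)) {
    f <- cfg$fluxes[[i]]
    for (p in unlist(f$rate))
      if (is.null(pars[[p]]))
        stop("flux ", i, " references missing parameter '", p, "'",
             call. = FALSE)
    for (g in f$gates) {
      if (is.null(pars[[g$param]]))
        stop("flux ", i, " gate references missing parameter '", g$param, "'",
             call. = FALSE)
      if (!g$species %in% known)
        stop("flux ", i, " gate references unknown species '", g$species, "'",
             call. = FALSE)
      if (!g$type %in% c("act", "rep"))
        stop("flux ", i, " gate has unknown type '", g$type, "'",
             call. = FALSE)
    }
    bad <- setdiff(c(unlist(f$consumes), unlist(f$produces)), sp)
    if (length(bad))
      stop("flux ", i, " references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    bad <- setdiff(unlist(f$linear), known)
    if (length(bad))
      stop("flux ", i, " linear factor references unknown species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    cited <- c(cited, unlist(f$links))
  }
  uncovered <- setdiff(link_ids, cited)
  if (length(uncovered))
    stop("link(s) not implemented by any flux: ",
         paste(uncovered, collapse = ", "), call. = FALSE)

  ev <- vapply(cfg$events, function(e) as.character(e$name), "")
  if (anyDuplicated(ev)) stop("duplicate event names", call. = FALSE)
  for (e in cfg$events) {
    if (is.null(pars[[e$param]]))
      stop("event '", e$name, "' references missing threshold parameter '",
           e$param, "'", call. = FALSE)
    if (!e$watched %in% known)
      stop("event '", e$name, "' watches unknown species '", e$watched, "'",
           call. = FALSE)
  }
  invisible(TRUE)
}

# --- compilation -----------------------------------------------------------

# Resolve the flux list against current parameter values into the flat
# integer/double arrays consumed by the C++ evaluator. Species indices:
# 1..n_state for states, n_state+1.. for derived remainders.
compileModel <- function(model) {
  if (!is.null(model$compiled)) return(model$compiled)
  cfg <- model$config
  sp <- speciesNames(model)
  n <- length(sp)
  pars <- cfg$parameters
  dnames <- vapply(cfg$derived, function(d) as.character(d$name), "")
  idx <- stats::setNames(seq_len(n + length(dnames)), c(sp, dnames))

  der_total <- vapply(cfg$derived, function(d) as.numeric(pars[[d$total_param]]), 0)
  der_members <- lapply(cfg$derived, function(d) unname(idx[unlist(d$members)]))

  nf <- length(cfg$fluxes)
  f_rate <- numeric(nf)
  g_flux <- g_species <- g_type <- integer(0)
  g_half <- g_n <- numeric(0)
  l_flux <- l_species <- integer(0)
  s_flux <- s_species <- integer(0)
  s_coef <- numeric(0)
  n_default <- as.numeric(cfg$hill[["n"]])

  for (i in seq_len(nf)) {
    f <- cfg$fluxes[[i]]
    f_rate[i] <- prod(vapply(unlist(f$rate), function(p) as.numeric(pars[[p]]), 0))
    for (g in f$gates) {
      g_flux <- c(g_flux, i)
      g_species <- c(g_species, unname(idx[[g$species]]))
      g_half <- c(g_half, as.numeric(pars[[g$param]]))
      gn <- if (!is.null(g$n_param)) as.numeric(cfg$hill[[g$n_param]]) else n_default
      g_n <- c(g_n, gn)
      g_type <- c(g_type, if (g$type == "act") 0L else 1L)
    }
    lin <- if (!is.null(f$linear)) unlist(f$linear) else unlist(f$consumes)
    for (s in lin) {
      l_flux <- c(l_flux, i)
      l_species <- c(l_species, unname(idx[[s]]))
    }
    for (s in unlist(f$consumes)) {
      s_flux <- c(s_flux, i); s_species <- c(s_species, unname(idx[[s]]))
      s_coef <- c(s_coef, -1)
    }
    for (s in unlist(f$produces)) {
      s_flux <- c(s_flux, i); s_species <- c(s_species, unname(idx[[s]]))
      s_coef <- c(s_coef, 1)
    }
  }
  list(n_state = n, state_names = sp,
       der_total = as.numeric(der_total), der_members = der_members,
       f_rate = f_rate,
       g_flux = as.integer(g_flux), g_species = as.integer(g_species),
       g_type = as.integer(g_type), g_half = g_half, g_n = g_n,
       l_flux = as.integer(l_flux), l_species = as.integer(l_species),
       s_flux = as.integer(s_flux), s_species = as.integer(s_species),
       s_coef = s_coef)
}

#' Build the derivative function of a model
#'
#' Assembles the right-hand side of the 25 coupled ODEs term-by-term from
#' the model's flux list: constant synthesis for constitutively expressed
#' proteins, first-order decay, Hill-gated modification and ubiquitination
#' rates of the form `rate * Hill(modifier) * substrate`, and mass-action
#' binding/unbinding. Active/inactive protein forms are two discrete states
#' connected by switch-like Hill-gated conversion.
#'
#' @param model A `cyclephase_model`.
#' @return A function `f(t, y)` returning the named derivative vector; in a
#'   form directly usable as a `deSolve`-style function via
#'   `function(t, y, parms) list(f(t, y))`.
#' @export
buildRhs <- function(model) {
  cm <- compileModel(model)
  nm <- cm$state_names
  function(t, y) {
    dy <- rhs_eval_cpp(cm, as.numeric(y))
    names(dy) <- nm
    dy
  }
}
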