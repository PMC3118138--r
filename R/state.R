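# Fermentation state and simulation configuration.

#' Construct a fermentation state
#'
#' Snapshot of the broth at one time point: time, temperature, viable
#' biomass and the extracellular concentration vector.  Sugars and carbon
#' metabolites are in g/L; nitrogen compounds in mg N/L.
#'
#' @param time h.
#' @param temperature degC.
#' @param biomass viable biomass X_V, gDW/L.
#' @param conc named numeric vector/list of extracellular concentrations,
#'   keyed by metabolite id (e.g. `GLC_e`).
#' @param yan0 initial assimilable nitrogen (mg N/L); defaults to the sum of
#'   `nitrogen_species` entries in `conc`.
#' @param sugars0 initial total sugar (g/L); defaults to the sum of
#'   `sugar_species` entries.
#' @param sugar_species,nitrogen_species ids of the sugar and nitrogen
#'   entries of `conc`.
#' @return object of class `fermentation_state`.
#' @export
fermentation_state <- function(time = 0, temperature = 28, biomass = 0.1,
                               conc = c(GLC_e = 116.5, FRU_e = 116.5,
                                        NH3_e = 120, AAN_e = 180,
                                        ETH_e = 0, GLYC_e = 0, ACE_e = 0, CO2_e = 0),
                               yan0 = NULL, sugars0 = NULL,
                               sugar_species = c("GLC_e", "FRU_e"),
                               nitrogen_species = c("NH3_e", "AAN_e")) {
  conc <- as.list(conc)
  if (any(unlist(conc) < 0))
    stop_dynafba("dynafba_state_error", "negative concentration in state")
  if (biomass < 0) stop_dynafba("dynafba_state_error", "negative biomass")
  sugar_species <- intersect(sugar_species, names(conc))
  nitrogen_species <- intersect(nitrogen_species, names(conc))
  sug <- sum(unlist(conc[sugar_species]))
  s0 <- sugars0 %||% sug
  st <- list(time = time, temperature = temperature, biomass = biomass,
             conc = conc,
             sugar_species = sugar_species, nitrogen_species = nitrogen_species,
             sugars0 = s0,
             yan0 = yan0 %||% sum(unlist(conc[nitrogen_species])),
             f_consumed = if (s0 > 0) min(1, max(0, 1 - sug / s0)) else 1)
  structure(st, class = "fermentation_state")
}

total_sugar <- function(state) sum(unlist(state$conc[state$sugar_species]))
total_yan <- function(state) sum(unlist(state$conc[state$nitrogen_species]))

#' @export
print.fermentation_state <- function(x, ...) {
  cat(sprintf("fermentation_state t=%.2f h, %.1f degC, X=%.3f gDW/L\n",
              x$time, x$temperature, x$biomass))
  print(round(unlist(x$conc), 3))
  invisible(x)
}

#' Simulation configuration
#'
#' @param step_h LP/integration interval (h); production and consumption
#'   rates are held constant within each interval.
#' @param temperature either a single value (degC, isothermal) or a
#'   data.frame `(time_h, temp_C)` interpreted as a piecewise-linear profile
#'   with constant extrapolation.
#' @param sugar_threshold_g_l stop when total sugars fall to this level.
#' @param n_exhaust_mg_l YAN level at/below which the objective switches
#'   from growth maximisation to maintenance-ATP minimisation (boundary
#'   inclusive on the minimisation side).
#' @param max_time_h safety stop.
#' @param kinetics a [kinetic_parameters()] object.
#' @param composition a [biomass_composition()] object.
#' @param maintenance_mode `"equation"` (empirical function), `"zero"`
#'   (flux fixed to 0), `"unbounded"` (no lower bound) or `"constant"`
#'   (`maintenance_constant` mmol/gDW/h) - the ablation variants.
#' @param maintenance_constant value used by `"constant"` mode.
#' @param biomass_mode `"dynamic"` (time-medium-specific equation) or
#'   `"fixed"` (base composition throughout).
#' @param bilevel_tol relative slack when fixing the primary optimum in the
#'   lexicographic solve.
#' @param secondary `"parsimony"` (minimise total absolute flux; the default
#'   tie-break that makes trajectories solver-reproducible) or a list
#'   `list(sense =, reaction =)` for engineering objectives.
#' @param big_bound numeric stand-in for an unbounded flux in the LP.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(step_h = 0.5, temperature = 28,
                              sugar_threshold_g_l = 2, n_exhaust_mg_l = 1,
                              max_time_h = 1000,
                              kinetics = kinetic_parameters(),
                              composition = biomass_composition(),
                              maintenance_mode = c("equation", "zero",
                                                   "unbounded", "constant"),
                              maintenance_constant = 1,
                              biomass_mode = c("dynamic", "fixed"),
                              bilevel_tol = 1e-6,
                              secondary = "parsimony",
                              big_bound = BIG_BOUND) {
  if (step_h <= 0) stop_dynafba("dynafba_config_error", "step_h must be > 0")
  if (sugar_threshold_g_l < 0 || n_exhaust_mg_l < 0)
    stop_dynafba("dynafba_config_error", "thresholds must be >= 0")
  structure(list(step_h = step_h, temperature = temperature,
                 sugar_threshold_g_l = sugar_threshold_g_l,
                 n_exhaust_mg_l = n_exhaust_mg_l, max_time_h = max_time_h,
                 kinetics = kinetics, composition = composition,
                 maintenance_mode = match.arg(maintenance_mode),
                 maintenance_constant = maintenance_constant,
                 biomass_mode = match.arg(biomass_mode),
                 bilevel_tol = bilevel_tol, secondary = secondary,
                 big_bound = big_bound),
            class = "simulation_config")
}

#' Read a simulation configuration from YAML
#'
#' Top-level keys mirror the arguments of [simulation_config()]; the
#' `kinetics` block holds [kinetic_parameters()] group overrides and
#' `initial` describes the starting [fermentation_state()]
#' (`temperature`, `biomass`, and a `concentrations` mapping).
#'
#' @param path YAML file.
#' @return list with elements `config` and `state`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- setdiff(names(formals(simulation_config)), c("kinetics", "composition"))
  bad <- setdiff(names(y), c(known, "kinetics", "initial", "composition"))
  if (length(bad))
    stop_dynafba("dynafba_config_error", "unknown config key(s): ", paste(bad, collapse = ", "))
  args <- y[intersect(names(y), known)]
  if (!is.null(y$temperature) && is.list(y$temperature))
    args$temperature <- data.frame(time_h = vapply(y$temperature, `[[`, numeric(1), "time_h"),
                                   temp_C = vapply(y$temperature, `[[`, numeric(1), "temp_C"))
  if (!is.null(y$kinetics)) args$kinetics <- do.call(kinetic_parameters, y$kinetics)
  cfg <- do.call(simulation_config, args)
  st <- NULL
  if (!is.null(y$initial)) {
    ini <- y$initial
    st <- fermentation_state(
      temperature = ini$temperature %||%
        (if (is.data.frame(cfg$temperature)) cfg$temperature$temp_C[1] else cfg$temperature),
      biomass = ini$biomass %||% 0.1,
      conc = unlist(ini$concentrations),
      sugar_species = unlist(ini$sugar_species %||% c("GLC_e", "FRU_e")),
      nitrogen_species = unlist(ini$nitrogen_species %||% c("NH3_e", "AAN_e")))
  }
  list(config = cfg, state = st)
}
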