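# Dynamic simulation: derive bounds from the state, solve the LP, integrate
# the bioreactor mass balances over fixed intervals, iterate until the sugar
# is consumed or the LP becomes infeasible.

#' Temperature at a time point
#'
#' @param profile either a single temperature (degC) or a data.frame
#'   `(time_h, temp_C)`; interpolation is piecewise linear with constant
#'   extrapolation beyond the endpoints.
#' @param t time (h).
#' @return temperature in degC.
#' @export
temperature_at <- function(profile, t) {
  if (is.numeric(profile) && length(profile) == 1L) return(profile)
  if (!is.data.frame(profile) || !all(c("time_h", "temp_C") %in% names(profile)) ||
      nrow(profile) == 0L)
    stop_dynafba("dynafba_config_error",
                 "temperature profile must be a scalar or a (time_h, temp_C) data.frame")
  if (is.unsorted(profile$time_h, strictly = TRUE) && nrow(profile) > 1L)
    if (any(diff(profile$time_h) <= 0))
      stop_dynafba("dynafba_config_error", "temperature profile times must be increasing")
  if (nrow(profile) == 1L) return(profile$temp_C[1])
  approx(profile$time_h, profile$temp_C, xout = t, rule = 2)$y
}

# species -> exchange reaction id, NA when absent
exchange_of <- function(model, species) {
  model$exchange_map$reaction[match(species, model$exchange_map$species)]
}

met_field <- function(model, species, field) {
  model$metabolites[[field]][match(species, model$metabolites$id)]
}

nitrogen_compounds <- function(model, state) {
  sp <- intersect(state$nitrogen_species, model$exchange_map$species)
  data.frame(species = sp, n_content = met_field(model, sp, "n_content"),
             stringsAsFactors = FALSE)
}

# carbon content (g C per gDW) of a biomass composition, from the precursor
# formulas declared in the model
composition_carbon <- function(model, composition, fractions) {
  pre <- composition$precursors[names(fractions)]
  nc <- vapply(met_field(model, pre, "formula"), element_count, numeric(1), element = "C")
  sum(fractions * 12 * nc / (1000 * composition$mw[names(fractions)]))
}

#' Dynamic bounds for the current state
#'
#' Combines the kinetic constraints into one patch: hexose uptake bounds
#' (applied, with the uptake-negative sign convention, to the lower bounds
#' of the sugar exchanges), nitrogen-compound uptake bounds, the maintenance
#' ATP lower bound, and the current time-medium-specific biomass equation
#' (attached as a stoichiometry replacement for the biomass column).  Any
#' tracked species whose concentration has reached zero gets its uptake
#' closed.
#'
#' @param state a [fermentation_state()].
#' @param model a `metabolic_model`.
#' @param config a [simulation_config()].
#' @return a `constraint_patch` (provenance `"dynamic"`) with attributes
#'   `biomass_stoich`, `maintenance_lb` and `carbon_per_gdw`.
#' @export
build_dynamic_bounds <- function(state, model, config = simulation_config()) {
  p <- config$kinetics
  rxn <- character(0); lb <- numeric(0); ub <- numeric(0)
  add <- function(r, l, u) {
    if (is.na(r)) return()
    rxn <<- c(rxn, r); lb <<- c(lb, l); ub <<- c(ub, u)
  }

  sug <- sugar_uptake_bounds(state, p)
  add(exchange_of(model, p$sugar$glucose), -sug[["glc"]], 0)
  add(exchange_of(model, p$sugar$fructose), -sug[["fru"]], 0)

  cmp <- nitrogen_compounds(model, state)
  if (nrow(cmp)) {
    nb <- nitrogen_uptake_bounds(state, p, cmp)
    for (i in seq_len(nrow(cmp)))
      add(exchange_of(model, cmp$species[i]), -nb[[cmp$species[i]]], 0)
  }

  # no uptake of tracked species that are exhausted (or absent)
  others <- setdiff(names(state$conc),
                    c(p$sugar$glucose, p$sugar$fructose, cmp$species))
  for (s in others) {
    r <- exchange_of(model, s)
    if (is.na(r)) next
    mlb <- model$reactions$lb[match(r, model$reactions$id)]
    if (state$conc[[s]] <= 0 && mlb < 0) add(r, 0, NA)
  }

  m_lb <- switch(config$maintenance_mode,
                 equation = maintenance_lower_bound(state, p),
                 constant = config$maintenance_constant,
                 zero = 0, unbounded = 0)
  atpm <- reactions_with_tag(model, "maintenance_atp")
  if (length(atpm)) {
    if (config$maintenance_mode == "zero") add(atpm, 0, 0) else add(atpm, m_lb, NA)
  }

  patch <- constraint_patch(rxn, lb, ub, provenance = "dynamic")
  beq <- biomass_equation(state, config$composition, p,
                          legacy = config$biomass_mode == "fixed")
  attr(patch, "biomass_stoich") <- beq$stoichiometry
  attr(patch, "maintenance_lb") <- m_lb
  attr(patch, "carb_fraction") <- unname(beq$fractions["carbohydrate"])
  attr(patch, "carbon_per_gdw") <- composition_carbon(model, config$composition,
                                                      beq$fractions)
  patch
}

#' Integrate one interval of the bioreactor mass balances
#'
#' With the specific rates held constant over the interval the balances
#' `dX/dt = mu X`, `dM_i/dt = q_i X` have the exact solution
#' `X(t+dt) = X e^(mu dt)` and `M_i(t+dt) = M_i + q_i X (e^(mu dt)-1)/mu`
#' (with the obvious `mu -> 0` limit), which is used directly instead of a
#' numerical integrator.  If a concentration would cross zero the interval
#' is cut at the earliest crossing and the state returned carries the
#' attributes `dt_used` and `event_species` so the caller can re-solve the
#' remainder.
#'
#' @param state a [fermentation_state()].
#' @param fluxes a `flux_distribution`.
#' @param model a `metabolic_model`.
#' @param dt interval length (h).
#' @return the new `fermentation_state` (attributes `dt_used`,
#'   `event_species`).
#' @export
integrate_interval <- function(state, fluxes, model, dt) {
  stopifnot(dt > 0)
  biomass_rxn <- reactions_with_tag(model, "biomass")
  mu <- if (length(biomass_rxn)) unname(fluxes$fluxes[[biomass_rxn]]) else 0
  if (is.na(mu)) mu <- 0

  species <- names(state$conc)
  q <- vapply(species, function(s) {
    r <- exchange_of(model, s)
    if (is.na(r)) return(0)
    v <- unname(fluxes$fluxes[[r]])
    if (is.na(v)) return(0)
    if (s %in% state$nitrogen_species) v * met_field(model, s, "n_content")
    else v * met_field(model, s, "mw")
  }, numeric(1))

  growth_integral <- function(dt) {
    if (abs(mu) < 1e-12) dt else expm1(mu * dt) / mu
  }

  # earliest zero crossing among consumed species
  dt_used <- dt; event <- NA_character_
  X <- state$biomass
  for (s in species) {
    if (q[[s]] >= 0 || X <= 0) next
    M <- state$conc[[s]]
    if (M <= 0) next
    need <- -M * mu / (q[[s]] * X)        # = expm1(mu dt*) at crossing
    dt_s <- if (abs(mu) < 1e-12) -M / (q[[s]] * X) else
      if (need > -1) log1p(need) / mu else Inf
    if (!is.finite(dt_s) || dt_s <= 0) next
    if (dt_s < dt_used - 1e-15) { dt_used <- dt_s; event <- s }
  }

  g <- growth_integral(dt_used)
  conc <- state$conc
  for (s in species) conc[[s]] <- max(0, conc[[s]] + q[[s]] * X * g)
  if (!is.na(event)) conc[[event]] <- 0

  out <- fermentation_state(
    time = state$time + dt_used, temperature = state$temperature,
    biomass = X * exp(mu * dt_used), conc = conc,
    yan0 = state$yan0, sugars0 = state$sugars0,
    sugar_species = state$sugar_species,
    nitrogen_species = state$nitrogen_species)
  attr(out, "dt_used") <- dt_used
  attr(out, "event_species") <- event
  out
}

#' Simulate a batch fermentation
#'
#' The outer loop of the dynamic flux balance model: at each interval the
#' broth temperature is read from the profile, the dynamic bounds are built
#' from the state, the objective is selected (growth maximisation while
#' nitrogen lasts, maintenance-ATP minimisation with growth clamped to zero
#' afterwards), the LP is solved lexicographically with a parsimonious
#' tie-break, and the exchange rates are integrated forward.  The loop ends
#' when total sugars fall to the configured threshold, when the LP is
#' infeasible (after one retry with the maintenance bound relaxed by 50 %,
#' which separates numerical edge cases from true metabolic infeasibility),
#' or at the safety time limit.
#'
#' @param model a `metabolic_model` (with tags declared; see
#'   [make_toy_network()]).
#' @param initial a [fermentation_state()].
#' @param config a [simulation_config()].
#' @param patches fixed/genetic constraint patches, e.g. from
#'   [anaerobic_constraints()] and [genetic_modifications()].
#' @return object of class `trajectory`: `states` (one row per accepted
#'   step), `fluxes` (matrix, steps x reactions), `termination` (one of
#'   `sugar_exhausted`, `infeasible`, `max_time`) and `metadata`.
#' @export
simulate_fermentation <- function(model, initial, config = simulation_config(),
                                  patches = list()) {
  if (inherits(patches, "constraint_patch")) patches <- list(patches)
  state <- track_carbon_species(model, initial)
  rows <- list(); flux_rows <- list(); termination <- NULL

  record <- function(state, fluxes, extras) {
    rows[[length(rows) + 1L]] <<- c(
      list(time_h = state$time, temperature_C = state$temperature,
           biomass_gDW_L = state$biomass, f_consumed = state$f_consumed),
      state$conc, extras)
    flux_rows[[length(flux_rows) + 1L]] <<-
      if (is.null(fluxes)) rep(NA_real_, nrow(model$reactions)) else fluxes$fluxes
  }

  state$temperature <- temperature_at(config$temperature, state$time)
  dyn0 <- build_dynamic_bounds(state, model, config)
  record(state, NULL, list(phase = "initial", mu = 0,
                           maintenance_lb = attr(dyn0, "maintenance_lb"),
                           carb_fraction = attr(dyn0, "carb_fraction"),
                           carbon_per_gdw = attr(dyn0, "carbon_per_gdw")))

  repeat {
    state$temperature <- temperature_at(config$temperature, state$time)
    if (total_sugar(state) <= config$sugar_threshold_g_l) { termination <- "sugar_exhausted"; break }
    if (state$time >= config$max_time_h - 1e-9) { termination <- "max_time"; break }

    dyn <- build_dynamic_bounds(state, model, config)
    obj <- select_objective(state, config, model)
    step_patches <- c(patches, list(dyn))
    if (isTRUE(attr(obj, "clamp_growth"))) {
      step_patches <- c(step_patches,
                        list(constraint_patch(reactions_with_tag(model, "biomass"),
                                              lb = 0, ub = 0, provenance = "dynamic")))
    }
    sol <- solve_bilevel(model, step_patches, primary = obj,
                         secondary = config$secondary, tol = config$bilevel_tol,
                         big = config$big_bound)
    relaxed <- FALSE
    if (sol$status != "optimal" && obj$sense == "min") {
      # infeasibility fallback: halve the maintenance requirement once
      atpm <- obj$reaction
      m_lb <- attr(dyn, "maintenance_lb")
      relax <- constraint_patch(atpm, lb = m_lb * 0.5, ub = NA, provenance = "dynamic")
      sol <- solve_bilevel(model, c(step_patches, list(relax)), primary = obj,
                           secondary = config$secondary, tol = config$bilevel_tol,
                           big = config$big_bound)
      relaxed <- TRUE
    }
    if (sol$status != "optimal") { termination <- "infeasible"; break }

    dt <- min(config$step_h, config$max_time_h - state$time)
    new_state <- integrate_interval(state, sol, model, dt)
    biomass_rxn <- reactions_with_tag(model, "biomass")
    record(new_state, sol, list(
      phase = if (isTRUE(attr(obj, "clamp_growth"))) "stationary" else "growth",
      mu = unname(sol$fluxes[[biomass_rxn]]),
      maintenance_lb = attr(dyn, "maintenance_lb") * (if (relaxed) 0.5 else 1),
      carb_fraction = attr(dyn, "carb_fraction"),
      carbon_per_gdw = attr(dyn, "carbon_per_gdw")))
    state <- new_state
  }

  states <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  fluxes <- do.call(rbind, flux_rows)
  colnames(fluxes) <- model$reactions$id
  structure(list(states = states, fluxes = fluxes, termination = termination,
                 initial = initial,
                 metadata = list(config = config, solver = "revised-simplex",
                                 package_version = as.character(utils::packageVersion("dynafba")))),
            class = "trajectory")
}

# extend the tracked concentration vector with every carbon-carrying
# exchange species so that secreted by-products stay in the carbon audit;
# species drawn from reservoirs treated as unlimited (sterols) stay out
track_carbon_species <- function(model, state) {
  sterol <- model$exchange_map$species[
    model$exchange_map$reaction %in% reactions_with_tag(model, "sterol_uptake")]
  candidates <- setdiff(model$exchange_map$species, c(names(state$conc), sterol))
  nc <- vapply(met_field(model, candidates, "formula"), element_count,
               numeric(1), element = "C")
  extra <- candidates[nc > 0]
  if (length(extra)) for (s in extra) state$conc[[s]] <- 0
  state
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$states)
  cat(sprintf("trajectory: %d steps, %.1f h, termination: %s\n",
              n, x$states$time_h[n], x$termination))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) x$states

#' Final state of a trajectory
#' @param traj a `trajectory`.
#' @return the last row of the state table.
#' @export
final_state <- function(traj) traj$states[nrow(traj$states), , drop = FALSE]

#' Carbon balance audit of a trajectory
#'
#' Tracks total elemental carbon in medium + biomass + evolved CO2 over the
#' run; with an elementally balanced model and exact interval integration
#' this is conserved up to the (small) within-interval drift of the biomass
#' composition and the sterol carbon drawn from the unlimited reservoir.
#'
#' @param traj a `trajectory` from [simulate_fermentation()].
#' @param model the model it was run with.
#' @return list with `relative_drift` (max |C(t) - C(0)| / C(0)) and the
#'   per-step totals (g C/L).
#' @export
carbon_balance <- function(traj, model) {
  st <- traj$states
  species <- intersect(model$exchange_map$species, names(st))
  nC <- vapply(met_field(model, species, "formula"), element_count,
               numeric(1), element = "C")
  mw <- met_field(model, species, "mw")
  ncontent <- met_field(model, species, "n_content")
  nitro <- species %in% traj$initial$nitrogen_species
  # g C per unit of the tracked concentration
  fac <- ifelse(nitro, 12 * nC / (1000 * ncontent), 12 * nC / (1000 * mw))
  medium <- as.matrix(st[, species, drop = FALSE]) %*% fac

  x <- st$biomass_gDW_L
  cpg <- st$carbon_per_gdw
  bio <- numeric(length(x))
  bio[1] <- x[1] * cpg[1]
  if (length(x) > 1) for (i in 2:length(x))
    bio[i] <- bio[i - 1] + (x[i] - x[i - 1]) * cpg[i - 1]

  total <- as.numeric(medium) + bio
  list(relative_drift = max(abs(total - total[1])) / total[1], total_gC_L = total)
}
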