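# Kinetic constraints: the state-dependent bounds fed to the LP each
# interval.  Units: fluxes mmol/gDW/h; sugars and products g/L; nitrogen
# mg N/L; temperature degrees C.

R_GAS <- 8.314  # J/mol/K

#' Default kinetic parameter set
#'
#' Parameters of the dynamic constraint equations.  The defaults are a
#' documented reference set calibrated once so that the bundled toy network,
#' fermented at 28 degC with 300 mg N/L and 233 g/L of sugars, finishes in
#' roughly 100-150 h with qualitatively correct metabolite profiles; real
#' calibration against fermentation data is a user task and every value can
#' be overridden here or from the YAML config.
#'
#' * `sugar`: shared hexose-transporter kinetics. `vmax_ref_*` (mmol/gDW/h)
#'   at `t_ref` (degC); `kg`, `kf` Michaelis constants (g/L); `kig_f`,
#'   `kif_g` competitive-inhibition constants of the other sugar (g/L);
#'   `ki_eth` non-competitive ethanol inhibition constant (g/L); `ea`
#'   activation energy (J/mol) of the Arrhenius temperature factor.
#' * `nitrogen`: `vmax_n` (mg N/gDW/h) and `k_n` (mg N/L) of total
#'   assimilable-nitrogen uptake; compounds share it in proportion to their
#'   current concentration (competition for common transporters).
#' * `maintenance`: base cost `m0` (mmol ATP/gDW/h) plus hinge terms for
#'   ethanol above `e_thr` (g/L; 4 % v/v), temperature above `t_thr` (degC)
#'   and a flat surcharge when the culture started nitrogen-deficient
#'   (initial YAN below `n_sluggish`, mg N/L).
#' * `carbohydrate`: storage-carbohydrate mass fraction of biomass rises
#'   from `c_min` to `c_max` (g/gDW) with the fraction of sugar consumed,
#'   with shape exponent `k_c`.
#'
#' @param ... named overrides, e.g. `sugar = list(ki_eth = 80)` (partial
#'   lists are merged into the defaults).
#' @return object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(...) {
  p <- list(
    sugar = list(vmax_ref_glc = 25, vmax_ref_fru = 25, kg = 5, kf = 5,
                 kig_f = 5, kif_g = 5, ki_eth = 150, ea = 55000, t_ref = 28,
                 glucose = "GLC_e", fructose = "FRU_e", ethanol = "ETH_e"),
    nitrogen = list(vmax_n = 12, k_n = 25),
    maintenance = list(m0 = 3.5, a_eth = 0.07, e_thr = 31.6, a_t = 0.12,
                       t_thr = 30, a_sluggish = 0.8, n_sluggish = 140),
    carbohydrate = list(c_min = 0.22, c_max = 0.48, k_c = 2))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(p))
      stop_dynafba("dynafba_config_error", "unknown kinetic parameter group: ", nm)
    p[[nm]] <- modifyList(p[[nm]], ov[[nm]])
  }
  num <- unlist(p[c("nitrogen", "maintenance", "carbohydrate")])
  num <- c(num, unlist(p$sugar[!vapply(p$sugar, is.character, logical(1))]))
  if (any(num < 0)) stop_dynafba("dynafba_config_error", "kinetic constants must be non-negative")
  cb <- p$carbohydrate
  if (!(cb$c_min < cb$c_max && cb$c_max < 1))
    stop_dynafba("dynafba_config_error", "need c_min < c_max < 1")
  structure(p, class = "kinetic_parameters")
}

#' Hexose uptake bounds
#'
#' Maximum specific glucose and fructose uptake rates for the current broth
#' state.  Each sugar follows Michaelis-Menten kinetics with competitive
#' inhibition by the other sugar, non-competitive inhibition by ethanol, and
#' an Arrhenius temperature factor on the maximal rate:
#' `ub_glc = vmax_glc(T) * G / (Kg (1 + F/Kig) + G) * Ki / (Ki + E)`.
#'
#' @param state a [fermentation_state()].
#' @param p a [kinetic_parameters()] object.
#' @return named vector `c(glc = , fru = )` in mmol/gDW/h.
#' @export
sugar_uptake_bounds <- function(state, p = kinetic_parameters()) {
  s <- p$sugar
  G <- state$conc[[s$glucose]] %||% 0
  F_ <- state$conc[[s$fructose]] %||% 0
  E <- state$conc[[s$ethanol]] %||% 0
  if (any(c(G, F_, E) < 0))
    stop_dynafba("dynafba_state_error", "negative concentration in state")
  TC <- state$temperature
  if (TC < 0 || TC > 50)
    stop_dynafba("dynafba_state_error", "temperature outside 0-50 degC: ", TC)
  arr <- exp(-s$ea / R_GAS * (1 / (TC + 273.15) - 1 / (s$t_ref + 273.15)))
  eth <- s$ki_eth / (s$ki_eth + E)
  ubg <- if (G <= 0) 0 else s$vmax_ref_glc * arr * G / (s$kg * (1 + F_ / s$kig_f) + G) * eth
  ubf <- if (F_ <= 0) 0 else s$vmax_ref_fru * arr * F_ / (s$kf * (1 + G / s$kif_g) + F_) * eth
  c(glc = ubg, fru = ubf)
}

#' Nitrogen-compound uptake bounds
#'
#' Total assimilable-nitrogen uptake saturates with the YAN concentration,
#' `v_N = vmax_n * YAN / (k_n + YAN)` (mg N/gDW/h); the compounds share it
#' in proportion to their share of the current YAN (competition for a
#' limited transporter pool) and each share is converted to mmol/gDW/h by
#' the compound's nitrogen content.
#'
#' @param state a [fermentation_state()].
#' @param p a [kinetic_parameters()] object.
#' @param compounds data.frame(species, n_content) with nitrogen contents in
#'   mg N/mmol; concentrations are read from `state` in mg N/L.
#' @return named vector of per-compound bounds (mmol/gDW/h).
#' @export
nitrogen_uptake_bounds <- function(state, p = kinetic_parameters(), compounds) {
  if (any(compounds$n_content <= 0))
    stop_dynafba("dynafba_model_error", "nitrogen compound with zero declared N content: ",
                 paste(compounds$species[compounds$n_content <= 0], collapse = ", "))
  conc <- vapply(compounds$species, function(s) max(0, state$conc[[s]] %||% 0), numeric(1))
  yan <- sum(conc)
  if (yan <= 0) return(setNames(rep(0, nrow(compounds)), compounds$species))
  v_n <- p$nitrogen$vmax_n * yan / (p$nitrogen$k_n + yan)
  setNames(v_n * (conc / yan) / compounds$n_content, compounds$species)
}

#' Maintenance ATP lower bound
#'
#' Empirical non-growth ATP cost: a base rate plus linear surcharges above
#' an ethanol threshold (stress above ~4 % v/v) and a temperature threshold,
#' plus a flat surcharge for cultures that started nitrogen-deficient
#' (sluggish fermentations).  The sluggish trigger uses the culture's
#' initial YAN, not the instantaneous value, so the cost does not jump when
#' nitrogen is consumed normally.
#'
#' @param state a [fermentation_state()].
#' @param p a [kinetic_parameters()] object.
#' @param legacy if `TRUE`, return the constant 1 mmol/gDW/h typical of
#'   earlier genome-scale models instead of the empirical function.
#' @return lower bound on the maintenance ATP flux (mmol ATP/gDW/h).
#' @export
maintenance_lower_bound <- function(state, p = kinetic_parameters(), legacy = FALSE) {
  if (legacy) return(1)
  m <- p$maintenance
  E <- state$conc[[p$sugar$ethanol]] %||% 0
  m$m0 + m$a_eth * max(0, E - m$e_thr) +
    m$a_t * max(0, state$temperature - m$t_thr) +
    m$a_sluggish * (state$yan0 < m$n_sluggish)
}

#' Storage-carbohydrate fraction of biomass
#'
#' Smooth monotone interpolation between the carbohydrate content of young,
#' actively growing cells and of cells late in the fermentation:
#' `c(f) = c_min + (c_max - c_min) * f^k_c`, with `f` the fraction of the
#' initial sugar already consumed.
#'
#' @param fraction_sugar_consumed value in `[0, 1]`.
#' @param p a [kinetic_parameters()] object.
#' @return carbohydrate mass fraction (g/gDW).
#' @export
carbohydrate_fraction <- function(fraction_sugar_consumed, p = kinetic_parameters()) {
  f <- fraction_sugar_consumed
  if (any(f < 0 | f > 1))
    stop_dynafba("dynafba_state_error", "fraction of sugar consumed must be in [0, 1]")
  cb <- p$carbohydrate
  cb$c_min + (cb$c_max - cb$c_min) * f^cb$k_c
}

#' Base biomass composition
#'
#' Macromolecular composition used to build the biomass equation: mass
#' fractions (g/gDW) of the precursor pools together with the metabolite
#' each pool drains and its residue weight (g/mmol), plus the ATP cost of
#' polymerisation (growth-associated maintenance, mmol ATP/gDW).  The
#' defaults describe the bundled toy network's four macromolecule pools and
#' a small sterol requirement; fractions must sum to 1.
#'
#' @param fractions named numeric vector of mass fractions; must contain
#'   `carbohydrate`.
#' @param precursors named character vector mapping components to metabolite
#'   ids.
#' @param mw named numeric vector of precursor residue weights (g/mmol).
#' @param atp_cost polymerisation ATP (mmol/gDW).
#' @param energy_species ids of the ATP hydrolysis quartet used to charge
#'   the ATP cost.
#' @return object of class `biomass_composition`.
#' @export
biomass_composition <- function(
    fractions = c(protein = 0.455, carbohydrate = 0.33, lipid = 0.07,
                  nucleic = 0.14, sterol = 0.005),
    precursors = c(protein = "PROT_c", carbohydrate = "CARB_c", lipid = "LIP_c",
                   nucleic = "NUC_c", sterol = "ERG_c"),
    mw = c(protein = 0.129, carbohydrate = 0.162, lipid = 0.144,
           nucleic = 0.146, sterol = 0.396),
    atp_cost = 70,
    energy_species = c(atp = "ATP_c", adp = "ADP_c", pi = "PI_c", h2o = "H2O_c")) {
  if (abs(sum(fractions) - 1) > 1e-6)
    stop_dynafba("dynafba_config_error", "biomass mass fractions must sum to 1 (got ",
                 format(sum(fractions)), ")")
  if (!"carbohydrate" %in% names(fractions))
    stop_dynafba("dynafba_config_error", "composition needs a carbohydrate component")
  stopifnot(setequal(names(fractions), names(precursors)),
            setequal(names(fractions), names(mw)))
  structure(list(fractions = fractions, precursors = precursors, mw = mw,
                 atp_cost = atp_cost, energy_species = energy_species),
            class = "biomass_composition")
}

#' Time- and medium-specific biomass equation
#'
#' Rebuilds the biomass reaction for the current fermentation state: the
#' carbohydrate mass fraction is replaced by
#' [carbohydrate_fraction()]`(f_consumed)` and the remaining fractions are
#' rescaled proportionally so the composition still sums to 1.  Precursor
#' coefficients are `fraction / mw` (mmol per gDW); the polymerisation ATP
#' cost cycles ATP + H2O to ADP + Pi.  With `legacy = TRUE` the base
#' composition is used unchanged (a time-invariant biomass equation).
#'
#' @param state a [fermentation_state()].
#' @param composition a [biomass_composition()].
#' @param p a [kinetic_parameters()] object.
#' @param legacy use the fixed base composition.
#' @return list with `stoichiometry` (named coefficient vector for the
#'   biomass reaction) and `fractions` (the composition used).
#' @export
biomass_equation <- function(state, composition = biomass_composition(),
                             p = kinetic_parameters(), legacy = FALSE) {
  if (p$carbohydrate$c_max >= 1)
    stop_dynafba("dynafba_config_error", "carbohydrate c_max must be < 1")
  fr <- composition$fractions
  if (!legacy) {
    cf <- carbohydrate_fraction(state$f_consumed, p)
    others <- setdiff(names(fr), "carbohydrate")
    fr[others] <- fr[others] * (1 - cf) / sum(fr[others])
    fr["carbohydrate"] <- cf
  }
  coef <- fr / composition$mw[names(fr)]   # mmol precursor per gDW
  sto <- setNames(-as.numeric(coef), composition$precursors[names(coef)])
  es <- composition$energy_species
  gam <- composition$atp_cost
  add <- setNames(c(-gam, -gam, gam, gam), c(es[["atp"]], es[["h2o"]], es[["adp"]], es[["pi"]]))
  for (m in names(add)) sto[m] <- (if (m %in% names(sto)) sto[[m]] else 0) + add[[m]]
  list(stoichiometry = sto, fractions = fr)
}
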