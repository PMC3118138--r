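# Toy fermentation network: a ~55-reaction anaerobic yeast caricature with
# exact elemental bookkeeping (integer atomic masses), built so that the
# redox couplings the genome-scale constraints act on are present:
# fermentation is redox-neutral (glucose -> 2 ethanol + 2 CO2, +2 ATP),
# biomass synthesis produces surplus cytosolic NADH, and under anaerobiosis
# (quinones off, TCA split) the glycerol branch is the only NADH sink, so
# anaerobic growth REQUIRES glycerol production.  Cofactor pairs carry their
# redox hydrogens explicitly (NADH = NAD + H2) so every non-exchange,
# non-biomass reaction balances C, H, N, O, P and S exactly.

#' Toy network specification
#'
#' @param glycerol_branch,acetate,tca,quinone,respiration,sterols,flavor
#'   subsystem switches; glycolysis, the ethanol branch, nitrogen
#'   assimilation, maintenance and biomass are always present.
#' @param gam growth-associated ATP cost (mmol ATP/gDW) written into the
#'   base biomass reaction.
#' @param resp_atp_per_nadh P/O-like ATP yield of respiratory NADH
#'   reoxidation.
#' @return object of class `toy_network_spec`.
#' @export
toy_network_spec <- function(glycerol_branch = TRUE, acetate = TRUE, tca = TRUE,
                             quinone = TRUE, respiration = TRUE, sterols = TRUE,
                             flavor = TRUE, gam = 70, resp_atp_per_nadh = 2) {
  structure(list(glycerol_branch = glycerol_branch, acetate = acetate,
                 tca = tca, quinone = quinone, respiration = respiration,
                 sterols = sterols, flavor = flavor, gam = gam,
                 resp_atp_per_nadh = resp_atp_per_nadh),
            class = "toy_network_spec")
}

#' Build the toy fermentation network
#'
#' Constructs the bundled metabolic model: lumped glycolysis with explicit
#' ATP/NADH stoichiometry, the glycerol branch (the anaerobic NADH sink),
#' ethanol and acetate branches, the TCA cycle as oxidative and reductive
#' halves joined by the succinate-dehydrogenase / alpha-ketoglutarate-
#' dehydrogenase steps (tagged `tca_oxidative_break`), a quinone-style NADH
#' oxidation (tagged `quinone`), respiration, sterol uptake, acetoin and
#' butanediol sinks, nitrogen assimilation from ammonium and an amino-acid
#' pool, maintenance ATP hydrolysis and a four-macromolecule biomass
#' equation with a small sterol requirement.  All exchanged species carry
#' molecular weights; all reactions except exchanges and biomass are
#' elementally exact.
#'
#' @param spec a [toy_network_spec()].
#' @return a `metabolic_model`.
#' @export
make_toy_network <- function(spec = toy_network_spec()) {
  M <- function(id, name, comp, formula) {
    mw <- formula_weight(formula)
    data.frame(id = id, name = name, compartment = comp, formula = formula,
               mw = mw, is_extracellular = comp == "e", stringsAsFactors = FALSE)
  }
  mets <- rbind(
    M("GLC_e", "D-glucose", "e", "C6H12O6"),
    M("FRU_e", "D-fructose", "e", "C6H12O6"),
    M("NH3_e", "ammonium", "e", "NH3"),
    M("AAN_e", "amino-acid nitrogen pool", "e", "C5H9NO4"),
    M("ETH_e", "ethanol", "e", "C2H6O"),
    M("GLYC_e", "glycerol", "e", "C3H8O3"),
    M("ACE_e", "acetate", "e", "C2H4O2"),
    M("CO2_e", "carbon dioxide (evolved)", "e", "CO2"),
    M("O2_e", "oxygen", "e", "O2"),
    M("ERG_e", "ergosterol", "e", "C28H44O"),
    M("PI_e", "phosphate", "e", "H3PO4"),
    M("SO4_e", "sulphate", "e", "H2SO4"),
    M("H2_e", "reducing equivalents (evolved)", "e", "H2"),
    M("ACT_e", "acetoin", "e", "C4H8O2"),
    M("BTD_e", "2,3-butanediol", "e", "C4H10O2"),
    M("H2O_e", "water", "e", "H2O"),
    M("GLC_c", "glucose", "c", "C6H12O6"),
    M("FRU_c", "fructose", "c", "C6H12O6"),
    M("G6P_c", "hexose 6-phosphate", "c", "C6H13O9P"),
    M("T3P_c", "triose 3-phosphate", "c", "C3H7O6P"),
    M("G3P_c", "glycerol 3-phosphate", "c", "C3H9O6P"),
    M("PYR_c", "pyruvate", "c", "C3H4O3"),
    M("ACAL_c", "acetaldehyde", "c", "C2H4O"),
    M("ETH_c", "ethanol", "c", "C2H6O"),
    M("GLYC_c", "glycerol", "c", "C3H8O3"),
    M("ACE_c", "acetate", "c", "C2H4O2"),
    M("CO2_c", "carbon dioxide", "c", "CO2"),
    M("O2_c", "oxygen", "c", "O2"),
    M("NH3_c", "ammonium", "c", "NH3"),
    M("GLU_c", "glutamate (amino-acid pool)", "c", "C5H9NO4"),
    M("OAA_c", "oxaloacetate", "c", "C4H4O5"),
    M("AKG_c", "2-oxoglutarate", "c", "C5H6O5"),
    M("SUC_c", "succinate", "c", "C4H6O4"),
    M("MAL_c", "malate", "c", "C4H6O5"),
    M("FUM_c", "fumarate", "c", "C4H4O4"),
    M("COA_c", "coenzyme A", "c", "C21H36N7O16P3S"),
    M("ACCOA_c", "acetyl-CoA", "c", "C23H38N7O17P3S"),
    M("NAD_c", "NAD (oxidised)", "c", "C21H26N7O14P2"),
    M("NADH_c", "NADH (carries H2)", "c", "C21H28N7O14P2"),
    M("ATP_c", "ATP", "c", "C10H16N5O13P3"),
    M("ADP_c", "ADP", "c", "C10H15N5O10P2"),
    M("PI_c", "phosphate", "c", "H3PO4"),
    M("H2O_c", "water", "c", "H2O"),
    M("ERG_c", "ergosterol", "c", "C28H44O"),
    M("H2_c", "reducing equivalents", "c", "H2"),
    M("ACT_c", "acetoin", "c", "C4H8O2"),
    M("BTD_c", "2,3-butanediol", "c", "C4H10O2"),
    M("PROT_c", "protein residue equivalent", "c", "C5H7NO3"),
    M("CARB_c", "storage carbohydrate residue", "c", "C6H10O5"),
    M("LIP_c", "lipid equivalent", "c", "C8H16O2"),
    M("NUC_c", "nucleic-acid equivalent", "c", "C5H10N2O3"))

  rx <- list()  # id, name, equation, lb, ub, genes, tags
  R <- function(id, name, eq, lb = 0, ub = Inf, genes = "", tags = "") {
    rx[[length(rx) + 1L]] <<- data.frame(reaction_id = id, name = name,
                                         equation = eq, lb = lb, ub = ub,
                                         genes = genes, tags = tags,
                                         stringsAsFactors = FALSE)
  }
  on <- function(flag) isTRUE(spec[[flag]])

  # exchanges (uptake negative, secretion positive)
  R("EX_GLC", "glucose exchange", "GLC_e ->", -Inf, 0, tags = "hexose_uptake")
  R("EX_FRU", "fructose exchange", "FRU_e ->", -Inf, 0, tags = "hexose_uptake")
  R("EX_NH3", "ammonium exchange", "NH3_e ->", -Inf, 0, tags = "nitrogen_uptake")
  R("EX_AAN", "amino-acid exchange", "AAN_e ->", -Inf, 0, tags = "nitrogen_uptake")
  R("EX_ETH", "ethanol exchange", "ETH_e ->", 0, Inf)
  R("EX_ACE", "acetate exchange", "ACE_e ->", -Inf, Inf)
  R("EX_CO2", "CO2 exchange", "CO2_e ->", 0, Inf)
  R("EX_PI", "phosphate exchange", "PI_e ->", -Inf, Inf)
  R("EX_SO4", "sulphate exchange", "SO4_e ->", -Inf, Inf)
  R("EX_H2O", "water exchange", "H2O_e ->", -Inf, Inf)

  # transports / core carbon metabolism
  R("GLCt", "hexose transporter (glc)", "GLC_e -> GLC_c", genes = "HXT1 or HXT2")
  R("FRUt", "hexose transporter (fru)", "FRU_e -> FRU_c", genes = "HXT1 or HXT2")
  R("HXK", "hexokinase", "GLC_c + ATP_c -> G6P_c + ADP_c", genes = "HXK2")
  R("HXKF", "fructokinase (lumped PGI)", "FRU_c + ATP_c -> G6P_c + ADP_c", genes = "HXK2")
  R("PFK", "upper glycolysis (PFK+aldolase)", "G6P_c + ATP_c -> 2 T3P_c + ADP_c",
    genes = "PFK1 and PFK2")
  R("GAPD", "lower glycolysis (GAPDH..PYK)",
    "T3P_c + PI_c + 2 ADP_c + NAD_c -> PYR_c + 2 ATP_c + NADH_c + H2O_c",
    genes = "TDH1 or TDH2 or TDH3")
  R("PDC", "pyruvate decarboxylase", "PYR_c -> ACAL_c + CO2_c", genes = "PDC1 or PDC5")
  R("ADH", "alcohol dehydrogenase", "ACAL_c + NADH_c -> ETH_c + NAD_c", genes = "ADH1")
  R("ETHt", "ethanol export", "ETH_c -> ETH_e")
  R("CO2t", "CO2 diffusion", "CO2_c <-> CO2_e", -Inf, Inf)
  R("PIt", "phosphate transport", "PI_e <-> PI_c", -Inf, Inf)
  R("H2Ot", "water diffusion", "H2O_e <-> H2O_c", -Inf, Inf)
  R("NH3t", "ammonium transport", "NH3_e -> NH3_c", genes = "MEP1 or MEP2")
  R("AANt", "amino-acid uptake (glutamate pool)", "AAN_e -> GLU_c", genes = "GAP1")
  R("GDH", "glutamate dehydrogenase",
    "AKG_c + NH3_c + NADH_c -> GLU_c + NAD_c + H2O_c", genes = "GDH1")
  R("PDH", "pyruvate dehydrogenase (lumped bypass)",
    "PYR_c + COA_c + NAD_c -> ACCOA_c + CO2_c + NADH_c")
  R("PYC", "pyruvate carboxylase",
    "PYR_c + CO2_c + ATP_c + H2O_c -> OAA_c + ADP_c + PI_c", genes = "PYC1 or PYC2")
  R("CSAKG", "oxidative TCA branch (CS..IDH)",
    "ACCOA_c + OAA_c + H2O_c + NAD_c -> AKG_c + CO2_c + NADH_c + COA_c")

  if (on("glycerol_branch")) {
    R("GPD", "glycerol-3-phosphate dehydrogenase",
      "T3P_c + NADH_c -> G3P_c + NAD_c", genes = "GPD1 or GPD2")
    R("GPP", "glycerol-3-phosphatase", "G3P_c + H2O_c -> GLYC_c + PI_c",
      genes = "GPP1 or GPP2")
    R("GLYCt", "glycerol export", "GLYC_c -> GLYC_e", genes = "FPS1")
    R("EX_GLYC", "glycerol exchange", "GLYC_e ->", 0, Inf)
  }
  if (on("acetate")) {
    R("ALD", "acetaldehyde dehydrogenase",
      "ACAL_c + NAD_c + H2O_c -> ACE_c + NADH_c", genes = "ALD6")
    R("ACEt", "acetate transport", "ACE_e <-> ACE_c", -Inf, Inf)
  }
  if (on("tca")) {
    R("KGD", "oxidative branch break (KGDH+SCS)",
      "AKG_c + NAD_c + H2O_c <-> SUC_c + CO2_c + NADH_c", -Inf, Inf,
      genes = "KGD1 and LSC1", tags = "tca_oxidative_break")
    R("SDH", "succinate dehydrogenase (NAD-lumped)",
      "SUC_c + NAD_c <-> FUM_c + NADH_c", -Inf, Inf,
      genes = "SDH1 and SDH2", tags = "tca_oxidative_break")
    R("FUMS", "fumarase", "FUM_c + H2O_c <-> MAL_c", -Inf, Inf, genes = "FUM1")
    R("MDH", "malate dehydrogenase", "MAL_c + NAD_c <-> OAA_c + NADH_c", -Inf, Inf,
      genes = "MDH1")
  }
  if (on("quinone")) {
    R("QNO", "quinone-mediated NADH oxidation",
      "NADH_c -> NAD_c + H2_c", genes = "NDE1 or NDE2", tags = "quinone")
    R("H2t", "reducing-equivalent evolution", "H2_c -> H2_e")
    R("EX_H2", "reducing-equivalent exchange", "H2_e ->", 0, Inf)
  }
  if (on("respiration")) {
    R("O2t", "oxygen diffusion", "O2_e -> O2_c")
    R("EX_O2", "oxygen exchange", "O2_e ->", -Inf, 0, tags = "oxygen_uptake")
    atp <- spec$resp_atp_per_nadh
    R("RESP", "respiratory NADH oxidation",
      sprintf("NADH_c + 0.5 O2_c + %d ADP_c + %d PI_c -> NAD_c + %d ATP_c + %d H2O_c",
              atp, atp, atp, atp + 1))
  }
  if (on("sterols")) {
    R("ERGt", "sterol uptake", "ERG_e -> ERG_c", genes = "AUS1")
    R("EX_ERG", "ergosterol exchange", "ERG_e ->", 0, 0, tags = "sterol_uptake")
  }
  if (on("flavor")) {
    R("ACTS", "acetoin synthase (lumped)", "2 ACAL_c -> ACT_c", genes = "BDH2")
    R("BTDS", "butanediol dehydrogenase", "ACT_c + NADH_c -> BTD_c + NAD_c",
      genes = "BDH1")
    R("ACTt", "acetoin export", "ACT_c -> ACT_e")
    R("BTDt", "butanediol export", "BTD_c -> BTD_e")
    R("EX_ACT", "acetoin exchange", "ACT_e ->", 0, Inf)
    R("EX_BTD", "butanediol exchange", "BTD_e ->", 0, Inf)
  }

  # macromolecule synthesis, maintenance, biomass
  R("PROTS", "protein synthesis (lumped)",
    "GLU_c + 2 ATP_c + H2O_c -> PROT_c + 2 ADP_c + 2 PI_c")
  R("CARBS", "storage carbohydrate synthesis",
    "G6P_c + ATP_c + H2O_c -> CARB_c + ADP_c + 2 PI_c")
  R("LIPS", "lipid synthesis (lumped)",
    "4 ACCOA_c + 6 NADH_c + 4 ATP_c + 2 H2O_c -> LIP_c + 4 COA_c + 6 NAD_c + 4 ADP_c + 4 PI_c")
  R("NUCS", "nucleic-equivalent synthesis",
    "GLU_c + NH3_c + ATP_c -> NUC_c + ADP_c + PI_c")
  R("ATPM", "maintenance ATP hydrolysis", "ATP_c + H2O_c -> ADP_c + PI_c",
    tags = "maintenance_atp")

  comp <- biomass_composition(atp_cost = spec$gam)
  fr <- comp$fractions
  if (!on("sterols")) {
    fr <- fr[names(fr) != "sterol"]; fr <- fr / sum(fr)
    comp <- biomass_composition(fractions = fr,
                                precursors = comp$precursors[names(fr)],
                                mw = comp$mw[names(fr)], atp_cost = spec$gam)
  }
  coef <- comp$fractions / comp$mw
  gam <- comp$atp_cost
  lhs <- paste(sprintf("%.10g %s", coef, comp$precursors[names(coef)]), collapse = " + ")
  R("BIOMASS", "biomass (base composition)",
    sprintf("%s + %.10g ATP_c + %.10g H2O_c -> %.10g ADP_c + %.10g PI_c",
            lhs, gam, gam, gam, gam),
    tags = "biomass")

  rxns <- do.call(rbind, rx)
  stoich <- lapply(rxns$equation, parse_equation)
  names(stoich) <- rxns$reaction_id
  model <- metabolic_model(
    data.frame(id = mets$id, name = mets$name, compartment = mets$compartment,
               formula = mets$formula, mw = mets$mw,
               is_extracellular = mets$is_extracellular, stringsAsFactors = FALSE),
    data.frame(id = rxns$reaction_id, name = rxns$name, lb = rxns$lb, ub = rxns$ub,
               genes = rxns$genes, tags = rxns$tags, stringsAsFactors = FALSE),
    stoich)

  # connectivity guard: fully relaxed aerobic bounds must admit growth
  relax <- constraint_patch(model$exchange_map$reaction,
                            lb = -Inf, ub = Inf, provenance = "fixed")
  g <- solve_fba(model, list(relax), fba_objective("max", "BIOMASS"))
  if (g$status != "optimal" || g$objective_value <= 1e-9)
    stop_dynafba("dynafba_disconnected",
                 "toy network spec does not admit growth under relaxed bounds")
  model
}

#' Acetylating acetaldehyde-dehydrogenase insertion
#'
#' A lumped heterologous route (E. coli mhpF-style acetylating acetaldehyde
#' dehydrogenase plus acetyl-CoA synthetase and alcohol dehydrogenase) that
#' converts acetate to ethanol while reoxidising two NADH.  Inserting it
#' restores an NADH sink to a glycerol-negative (gpd deletion) strain, which
#' can then grow anaerobically by consuming acetate.
#'
#' @return a [genetic_modification()] of kind `"insertion"`.
#' @export
acetate_rescue_insertion <- function() {
  genetic_modification("mhpF", "insertion", added_reaction = list(
    id = "AALD", name = "acetylating acetaldehyde dehydrogenase route (lumped)",
    stoichiometry = parse_equation(
      "ACE_c + 2 NADH_c + 2 ATP_c + H2O_c -> ETH_c + 2 NAD_c + 2 ADP_c + 2 PI_c"),
    lb = 0, ub = Inf, genes = "mhpF", tags = ""))
}
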