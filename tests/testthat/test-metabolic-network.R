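# Model container, TSV dialect, constraint patches, genetic modifications.

test_that("toy model TSV round-trips through write_model/load_model", {
  m <- toy_model()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_model(m, path)
  m2 <- load_model(path)
  expect_identical(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lb, m$reactions$lb)
  expect_equal(m2$reactions$ub, m$reactions$ub)
  for (r in m$reactions$id) {
    a <- m$stoich[[r]]; b <- m2$stoich[[r]]
    expect_equal(b[sort(names(b))], a[sort(names(a))], tolerance = 1e-12)
  }
  # and the shipped fixture is that same model
  fx <- load_model(system.file("extdata", "toy_model.tsv", package = "dynafba"))
  expect_identical(fx$reactions$id, m$reactions$id)
})

test_that("model validation raises distinct named errors", {
  mets <- data.frame(id = "A_c", name = "A", compartment = "c",
                     formula = "C2H4O2", mw = 0.06, is_extracellular = FALSE)
  rxns <- data.frame(id = "R1", name = "r", lb = 0, ub = 1, genes = "", tags = "")
  expect_error(metabolic_model(mets, rxns, list(R1 = c(B_c = 1))),
               class = "dynafba_unknown_metabolite")
  expect_error(metabolic_model(rbind(mets, mets), rxns, list(R1 = c(A_c = 1))),
               class = "dynafba_duplicate_id")
  expect_error(metabolic_model(mets, transform(rxns, lb = 2), list(R1 = c(A_c = 1))),
               class = "dynafba_bound_error")
  # TSV naming an undeclared metabolite
  txt <- c("# metabolites", "id\tname\tcompartment\tformula\tmw\textracellular",
           "A_c\tA\tc\tC2H4O2\t0.06\t0",
           "# reactions", "reaction_id\tname\tequation\tlb\tub\tgenes\ttags",
           "R1\tr\tA_c -> B_c\t0\t1\t\t")
  path <- withr::local_tempfile(lines = txt, fileext = ".tsv")
  expect_error(load_model(path), class = "dynafba_unknown_metabolite")
})

test_that("toy network is elementally exact and exchange-complete", {
  m <- toy_model()
  expect_identical(nrow(elemental_audit(m)), 0L)
  # every extracellular species has exactly one exchange reaction
  expect_identical(anyDuplicated(m$exchange_map$species), 0L)
  ext <- m$metabolites$id[m$metabolites$is_extracellular]
  expect_setequal(m$exchange_map$species, ext)
  # required tags present and unique where they must be
  expect_length(reactions_with_tag(m, "biomass"), 1L)
  expect_length(reactions_with_tag(m, "maintenance_atp"), 1L)
  expect_true(all(c("EX_GLC", "EX_FRU") %in% reactions_with_tag(m, "hexose_uptake")))
})

test_that("anaerobic constraint patch matches the tagged reaction groups", {
  m <- toy_model()
  p <- toy_anaerobic()
  pick <- function(r) p[p$reaction == r, ]
  # oxygen uptake closed
  expect_equal(unname(unlist(pick("EX_O2")[c("lb", "ub")])), c(0, 0))
  # TCA split: both break-point reactions zeroed
  for (r in reactions_with_tag(m, "tca_oxidative_break"))
    expect_equal(unname(unlist(pick(r)[c("lb", "ub")])), c(0, 0))
  # quinone reactions zeroed
  for (r in reactions_with_tag(m, "quinone"))
    expect_equal(unname(unlist(pick(r)[c("lb", "ub")])), c(0, 0))
  # sterol and inorganic exchanges relaxed
  expect_equal(pick("EX_ERG")$ub, Inf)
  expect_equal(pick("EX_ERG")$lb, -Inf)
  expect_true(all(c("EX_PI", "EX_SO4") %in% p$reaction))
  # idempotent: applying twice gives the same effective bounds
  b1 <- effective_bounds(m, list(p))
  b2 <- effective_bounds(m, list(p, p))
  expect_equal(b2, b1)
  # lb <= ub everywhere after application
  expect_true(all(b1$lb <= b1$ub))
})

test_that("a model without tagged reactions yields an empty patch plus a warning", {
  m <- chain_model()
  expect_warning(p <- anaerobic_constraints(m), "oxygen_uptake")
  expect_identical(nrow(p), 0L)
})

test_that("zeroing a reaction with a positive lower bound is refused", {
  m <- toy_model()
  m$reactions$lb[m$reactions$id == "EX_O2"] <- 0.5
  m$reactions$ub[m$reactions$id == "EX_O2"] <- 1
  expect_error(anaerobic_constraints(m), class = "dynafba_bound_error")
})

test_that("genetic modifications: identity, deletions via gene rules, errors", {
  m <- toy_model()
  # empty list: empty patch, model unchanged
  gm0 <- genetic_modifications(m, list())
  expect_identical(nrow(gm0$patch), 0L)
  expect_identical(gm0$model$reactions$id, m$reactions$id)
  # single-isoform deletion does not kill an 'or' rule ...
  gm1 <- genetic_modifications(m, list(genetic_modification("GPD1", "deletion")))
  expect_false("GPD" %in% gm1$patch$reaction)
  # ... but deleting both isoforms zeroes the reaction
  gm2 <- genetic_modifications(m, list(genetic_modification("GPD1", "deletion"),
                                       genetic_modification("GPD2", "deletion")))
  expect_true("GPD" %in% gm2$patch$reaction)
  expect_equal(gm2$patch$lb[gm2$patch$reaction == "GPD"], 0)
  expect_equal(gm2$patch$ub[gm2$patch$reaction == "GPD"], 0)
  # an 'and' rule dies with one subunit
  gm3 <- genetic_modifications(m, list(genetic_modification("SDH1", "deletion")))
  expect_true("SDH" %in% gm3$patch$reaction)
  # reaction-id target works directly
  gm4 <- genetic_modifications(m, list(genetic_modification("PDC", "deletion")))
  expect_true("PDC" %in% gm4$patch$reaction)
  # unresolvable target and biomass deletion are named errors
  expect_error(genetic_modifications(m, list(genetic_modification("NOPE1", "deletion"))),
               class = "dynafba_unknown_target")
  expect_error(genetic_modifications(m, list(genetic_modification("BIOMASS", "deletion"))),
               class = "dynafba_mod_error")
})

test_that("overexpression and downregulation scale bounds by the factor", {
  m <- toy_model()
  ov <- genetic_modifications(m, list(genetic_modification("ADH1", "overexpression", factor = 5)))
  i <- ov$patch$reaction == "ADH"
  expect_true(any(i))
  expect_equal(ov$patch$ub[i], 5 * m$reactions$ub[m$reactions$id == "ADH"])
  dn <- genetic_modifications(m, list(genetic_modification("FPS1", "downregulation", factor = 0.2)))
  expect_equal(dn$patch$ub[dn$patch$reaction == "GLYCt"],
               0.2 * m$reactions$ub[m$reactions$id == "GLYCt"])
  expect_error(genetic_modification("ADH1", "overexpression", factor = 0.5),
               class = "dynafba_mod_error")
  expect_error(genetic_modification("ADH1", "downregulation", factor = 2),
               class = "dynafba_mod_error")
})

test_that("insertion extends the model and stays stoichiometrically valid", {
  m <- toy_model()
  gm <- genetic_modifications(m, list(acetate_rescue_insertion()))
  expect_identical(nrow(gm$model$reactions), nrow(m$reactions) + 1L)
  expect_true("AALD" %in% gm$model$reactions$id)
  expect_identical(nrow(elemental_audit(gm$model)), 0L)
})

test_that("genetic zero-bounds are never relaxed by later dynamic patches", {
  m <- toy_model()
  gen <- constraint_patch("GPD", 0, 0, provenance = "genetic")
  dyn <- constraint_patch("GPD", -5, 5, provenance = "dynamic")
  b <- effective_bounds(m, list(gen, dyn))
  expect_equal(b$lb[b$reaction == "GPD"], 0)
  expect_equal(b$ub[b$reaction == "GPD"], 0)
})

test_that("modifications round-trip through the JSON interface", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"target": "GPD1", "kind": "deletion"},
               {"target": "ADH1", "kind": "overexpression", "factor": 4},
               {"target": "mhpF", "kind": "insertion",
                "added_reaction": {"id": "AALD",
                  "equation": "ACE_c + 2 NADH_c + 2 ATP_c + H2O_c -> ETH_c + 2 NAD_c + 2 ADP_c + 2 PI_c",
                  "lb": 0, "ub": "Inf"}}]', path)
  mods <- read_modifications(path)
  expect_length(mods, 3L)
  expect_identical(mods[[1]]$kind, "deletion")
  expect_equal(mods[[2]]$factor, 4)
  expect_identical(names(mods[[3]]$added_reaction$stoichiometry)[1], "ACE_c")
})

test_that("the SBML reader imports species, stoichiometry and fbc bounds", {
  sbml <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">',
    '<model id="mini">',
    '<listOfParameters>',
    '<parameter id="lb0" value="0"/><parameter id="ub10" value="10"/>',
    '<parameter id="lbm10" value="-10"/>',
    '</listOfParameters>',
    '<listOfSpecies>',
    '<species id="A_e" compartment="e" boundaryCondition="false" chemicalFormula="C2H4O2"/>',
    '<species id="A_c" compartment="c" boundaryCondition="false" chemicalFormula="C2H4O2"/>',
    '<species id="B_b" compartment="b" boundaryCondition="true"/>',
    '</listOfSpecies>',
    '<listOfReactions>',
    '<reaction id="EX_A" reversible="true" lowerFluxBound="lbm10" upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="B_b" stoichiometry="1"/></listOfProducts>',
    '</reaction>',
    '<reaction id="TA" reversible="false" lowerFluxBound="lb0" upperFluxBound="ub10">',
    '<listOfReactants><speciesReference species="A_e" stoichiometry="1"/></listOfReactants>',
    '<listOfProducts><speciesReference species="A_c" stoichiometry="2"/></listOfProducts>',
    '</reaction>',
    '</listOfReactions>',
    '</model></sbml>')
  path <- withr::local_tempfile(lines = sbml, fileext = ".xml")
  m <- load_model(path)
  expect_identical(sort(m$reactions$id), c("EX_A", "TA"))
  expect_equal(m$stoich$TA, c(A_e = -1, A_c = 2))
  expect_equal(m$reactions$lb[m$reactions$id == "EX_A"], -10)
  # boundary species dropped, so EX_A is a single-metabolite exchange
  expect_identical(m$exchange_map$reaction, "EX_A")
})
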