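# Kinetic constraint equations.

state_with <- function(G = 0, F_ = 0, E = 0, N1 = 0, N2 = 0, temp = 28, f = 0) {
  st <- fermentation_state(temperature = temp,
                           conc = c(GLC_e = G, FRU_e = F_, ETH_e = E,
                                    NH3_e = N1, AAN_e = N2, GLYC_e = 0,
                                    ACE_e = 0, CO2_e = 0))
  st$f_consumed <- f
  st
}

test_that("sugar uptake bounds follow the transporter kinetics", {
  p <- kinetic_parameters()
  # zero substrate -> zero bound
  expect_equal(unname(sugar_uptake_bounds(state_with(G = 0, F_ = 50), p)["glc"]), 0)
  # saturating ethanol abolishes uptake (non-competitive limit)
  b <- sugar_uptake_bounds(state_with(G = 100, F_ = 100, E = 1e7), p)
  expect_lt(max(b), 1e-3)
  # direct evaluation of the stated rate law at reference temperature
  b0 <- sugar_uptake_bounds(state_with(G = 100, F_ = 100), p)
  s <- p$sugar
  expected <- s$vmax_ref_glc * 100 / (s$kg * (1 + 100 / s$kig_f) + 100)
  expect_equal(unname(b0["glc"]), expected, tolerance = 1e-12)
  expect_equal(unname(b0["fru"]),
               s$vmax_ref_fru * 100 / (s$kf * (1 + 100 / s$kif_g) + 100),
               tolerance = 1e-12)
  # negative concentration is a named error
  st_bad <- state_with(G = 1); st_bad$conc$GLC_e <- -1
  expect_error(sugar_uptake_bounds(st_bad, p), class = "dynafba_state_error")
})

test_that("sugar uptake bounds are monotone in their drivers", {
  p <- kinetic_parameters()
  grid <- seq(0, 200, length.out = 40)
  own <- vapply(grid, function(g) sugar_uptake_bounds(state_with(G = g, F_ = 50), p)["glc"], numeric(1))
  expect_true(all(diff(own) >= -1e-12))          # non-decreasing in own sugar
  comp <- vapply(grid, function(f) sugar_uptake_bounds(state_with(G = 50, F_ = f), p)["glc"], numeric(1))
  expect_true(all(diff(comp) <= 1e-12))          # non-increasing in competitor
  eth <- vapply(grid, function(e) sugar_uptake_bounds(state_with(G = 50, F_ = 50, E = e), p)["glc"], numeric(1))
  expect_true(all(diff(eth) <= 1e-12))           # non-increasing in ethanol
  # Arrhenius factor: warmer than t_ref is faster
  expect_gt(sugar_uptake_bounds(state_with(G = 50, temp = 34), p)["glc"],
            sugar_uptake_bounds(state_with(G = 50, temp = 28), p)["glc"])
})

test_that("nitrogen uptake saturates and allocation conserves total N flux", {
  p <- kinetic_parameters()
  cmp <- data.frame(species = c("NH3_e", "AAN_e"), n_content = c(14, 14))
  # exhausted nitrogen -> all bounds zero
  expect_true(all(nitrogen_uptake_bounds(state_with(), p, cmp) == 0))
  # single compound: bound equals total uptake converted by N content
  one <- data.frame(species = "NH3_e", n_content = 14)
  st <- state_with(N1 = 100)
  vn <- p$nitrogen$vmax_n * 100 / (p$nitrogen$k_n + 100)
  expect_equal(unname(nitrogen_uptake_bounds(st, p, one)), vn / 14, tolerance = 1e-12)
  # equal concentrations -> equal N-flux shares; exact conservation
  st2 <- state_with(N1 = 80, N2 = 80)
  b <- nitrogen_uptake_bounds(st2, p, cmp)
  expect_equal(unname(b["NH3_e"] * 14), unname(b["AAN_e"] * 14), tolerance = 1e-12)
  yan <- 160
  vn2 <- p$nitrogen$vmax_n * yan / (p$nitrogen$k_n + yan)
  expect_equal(sum(b * cmp$n_content), vn2, tolerance = 1e-12)
  # uneven split stays conservative and proportional
  st3 <- state_with(N1 = 30, N2 = 120)
  b3 <- nitrogen_uptake_bounds(st3, p, cmp)
  expect_equal(sum(b3 * cmp$n_content),
               p$nitrogen$vmax_n * 150 / (p$nitrogen$k_n + 150), tolerance = 1e-12)
  expect_equal(unname(b3["AAN_e"] / b3["NH3_e"]), 4, tolerance = 1e-12)
  # zero declared N content is a named error
  expect_error(nitrogen_uptake_bounds(st2, p,
                 data.frame(species = "NH3_e", n_content = 0)),
               class = "dynafba_model_error")
})

test_that("maintenance bound: base case, stress monotonicity, legacy constant", {
  p <- kinetic_parameters()
  benign <- state_with(G = 100, N1 = 150, N2 = 150)  # initial YAN 300, no ethanol
  expect_equal(maintenance_lower_bound(benign, p), p$maintenance$m0)
  # more ethanol never lowers the cost
  e80 <- state_with(G = 100, E = 80, N1 = 150, N2 = 150)
  e0 <- state_with(G = 100, E = 0, N1 = 150, N2 = 150)
  expect_gt(maintenance_lower_bound(e80, p), maintenance_lower_bound(e0, p))
  # temperature hinge
  hot <- state_with(G = 100, N1 = 150, N2 = 150, temp = 34)
  expect_gt(maintenance_lower_bound(hot, p), maintenance_lower_bound(benign, p))
  # sluggish surcharge keys on the culture's initial YAN
  lean <- state_with(G = 100, N1 = 25, N2 = 25)
  expect_equal(maintenance_lower_bound(lean, p),
               p$maintenance$m0 + p$maintenance$a_sluggish)
  # a culture that started rich does not become "sluggish" as N is consumed
  rich_then_empty <- state_with(G = 100)
  rich_then_empty$yan0 <- 300
  expect_equal(maintenance_lower_bound(rich_then_empty, p), p$maintenance$m0)
  # legacy constant used by earlier genome-scale models
  expect_equal(maintenance_lower_bound(e80, p, legacy = TRUE), 1)
})

test_that("carbohydrate fraction interpolates monotonically between c_min and c_max", {
  p <- kinetic_parameters()
  expect_equal(carbohydrate_fraction(0, p), p$carbohydrate$c_min)
  expect_equal(carbohydrate_fraction(1, p), p$carbohydrate$c_max)
  grid <- seq(0, 1, length.out = 100)
  v <- carbohydrate_fraction(grid, p)
  expect_true(all(diff(v) >= 0))
  expect_true(all(v >= p$carbohydrate$c_min & v <= p$carbohydrate$c_max))
  expect_error(carbohydrate_fraction(1.2, p), class = "dynafba_state_error")
})

test_that("biomass equation renormalises, shifts with progress, and closes mass", {
  p <- kinetic_parameters()
  comp <- biomass_composition()
  for (f in c(0, 0.3, 1)) {
    beq <- biomass_equation(state_with(G = 100, f = f), comp, p)
    expect_equal(sum(beq$fractions), 1, tolerance = 1e-9)
    # mass closure: precursor coefficients times residue weights give 1 gDW
    pre <- comp$precursors
    coefs <- -beq$stoichiometry[pre]
    expect_equal(sum(coefs * comp$mw), 1, tolerance = 1e-6)
  }
  early <- biomass_equation(state_with(G = 100, f = 0), comp, p)$stoichiometry
  late <- biomass_equation(state_with(G = 100, f = 1), comp, p)$stoichiometry
  # carbohydrate drain rises with progress, protein drain falls
  expect_gt(-late[["CARB_c"]], -early[["CARB_c"]])
  expect_lt(-late[["PROT_c"]], -early[["PROT_c"]])
  # legacy composition is progress-invariant
  l0 <- biomass_equation(state_with(G = 100, f = 0), comp, p, legacy = TRUE)
  l1 <- biomass_equation(state_with(G = 100, f = 1), comp, p, legacy = TRUE)
  expect_equal(l0$stoichiometry, l1$stoichiometry)
  expect_equal(unname(l0$fractions), unname(comp$fractions))
})

test_that("dynamic bounds are finite, non-negative in magnitude, and respect exhaustion", {
  m <- toy_model()
  cfg <- simulation_config()
  # glucose-free state: no glucose uptake allowed
  st <- state_with(F_ = 50, N1 = 100, N2 = 100)
  patch <- build_dynamic_bounds(st, m, cfg)
  expect_equal(patch$lb[patch$reaction == "EX_GLC"], 0)
  expect_lt(patch$lb[patch$reaction == "EX_FRU"], 0)
  # high ethanol raises the maintenance bound above its base value
  st80 <- state_with(G = 50, F_ = 50, E = 80, N1 = 150, N2 = 150)
  p80 <- build_dynamic_bounds(st80, m, cfg)
  expect_gt(attr(p80, "maintenance_lb"), cfg$kinetics$maintenance$m0)
  expect_equal(p80$lb[p80$reaction == "ATPM"], attr(p80, "maintenance_lb"))
  # all bounds finite
  expect_true(all(is.finite(p80$lb[!is.na(p80$lb)])))
  expect_true(all(is.finite(p80$ub[!is.na(p80$ub)])))
})
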