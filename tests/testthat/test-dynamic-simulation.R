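# Outer simulation loop: integration exactness, event handling, temperature
# profiles, termination, and whole-trajectory physiology.

fake_fluxes <- function(model, values) {
  v <- setNames(rep(0, nrow(model$reactions)), model$reactions$id)
  v[names(values)] <- unlist(values)
  structure(list(fluxes = v, objective_value = NA_real_, status = "optimal"),
            class = "flux_distribution")
}

test_that("temperature profiles interpolate linearly and clamp at the ends", {
  expect_equal(temperature_at(25, 123), 25)
  prof <- data.frame(time_h = c(0, 10), temp_C = c(20, 30))
  expect_equal(temperature_at(prof, 5), 25)
  expect_equal(temperature_at(prof, 0), 20)
  expect_equal(temperature_at(prof, 50), 30)   # constant extrapolation
  expect_equal(temperature_at(prof, -5), 20)
  bad <- data.frame(time_h = c(10, 0), temp_C = c(20, 30))
  expect_error(temperature_at(bad, 5), class = "dynafba_config_error")
})

test_that("interval integration matches the closed-form exponential", {
  m <- toy_model()
  st <- fermentation_state(biomass = 1,
                           conc = c(GLC_e = 50, FRU_e = 50, NH3_e = 100, AAN_e = 100,
                                    ETH_e = 0, GLYC_e = 0, ACE_e = 0, CO2_e = 0))
  # all fluxes zero: nothing changes but time
  s0 <- integrate_interval(st, fake_fluxes(m, list()), m, 0.5)
  expect_equal(s0$time, 0.5)
  expect_equal(s0$biomass, 1)
  expect_equal(unlist(s0$conc), unlist(st$conc))
  # constant growth: X' = X e^(mu dt) exactly
  fl <- fake_fluxes(m, list(BIOMASS = 0.1))
  s1 <- integrate_interval(st, fl, m, 0.5)
  expect_equal(s1$biomass, exp(0.05), tolerance = 1e-12)
  # consumed species follow the exact linear-ODE solution
  fl2 <- fake_fluxes(m, list(BIOMASS = 0.1, EX_GLC = -2))
  s2 <- integrate_interval(st, fl2, m, 0.5)
  expect_equal(s2$conc$GLC_e, 50 - 2 * 0.18 * 1 * expm1(0.05) / 0.1,
               tolerance = 1e-12)
  # nitrogen species use their mg N/mmol content
  fl3 <- fake_fluxes(m, list(EX_NH3 = -1))
  s3 <- integrate_interval(st, fl3, m, 0.5)
  expect_equal(s3$conc$NH3_e, 100 - 1 * 14 * 1 * 0.5, tolerance = 1e-12)
})

test_that("event sub-stepping lands exactly on the zero crossing", {
  m <- toy_model()
  st <- fermentation_state(biomass = 2,
                           conc = c(GLC_e = 0.5, FRU_e = 10, NH3_e = 50, AAN_e = 50,
                                    ETH_e = 0, GLYC_e = 0, ACE_e = 0, CO2_e = 0))
  mu <- 0.2; q <- -3
  fl <- fake_fluxes(m, list(BIOMASS = mu, EX_GLC = q))
  out <- integrate_interval(st, fl, m, 0.5)
  expect_identical(attr(out, "event_species"), "GLC_e")
  expect_equal(out$conc$GLC_e, 0)
  # independent root: solve M + q*mw*X*(e^(mu t)-1)/mu = 0 numerically
  root <- uniroot(function(t) 0.5 + q * 0.18 * 2 * expm1(mu * t) / mu,
                  c(1e-9, 0.5), tol = 1e-13)$root
  expect_equal(attr(out, "dt_used"), root, tolerance = 1e-9)
  # crossing inside the interval, so time advanced by less than dt
  expect_lt(out$time, 0.5)
})

test_that("the reference fermentation runs to sugar exhaustion with closed carbon", {
  traj <- bench_traj()
  expect_identical(traj$termination, "sugar_exhausted")
  fs <- final_state(traj)
  expect_gt(fs$ETH_e, 0)
  expect_gt(fs$GLYC_e, 0)
  expect_lte(fs$GLC_e + fs$FRU_e, simulation_config()$sugar_threshold_g_l + 1e-9)
  expect_no_negative_conc(traj)
  expect_true(all(diff(traj$states$time_h) > 0))
  cb <- carbon_balance(traj, toy_model())
  expect_lt(cb$relative_drift, 0.005)
})

test_that("after nitrogen exhaustion growth stops while sugars keep falling", {
  traj <- bench_traj()
  st <- traj$states
  stat <- which(st$phase == "stationary")
  expect_gt(length(stat), 10)
  # biomass plateaus (non-increasing up to numerical noise)
  expect_true(all(diff(st$biomass_gDW_L[stat]) <= 1e-9))
  expect_true(all(abs(st$mu[stat]) < 1e-7))
  # sugars continue to decline (maintenance metabolism)
  sug <- st$GLC_e[stat] + st$FRU_e[stat]
  expect_true(all(diff(sug) < 0))
  # and the switch happened when YAN reached the threshold
  sw <- stat[1]
  expect_lte(st$NH3_e[sw - 1] + st$AAN_e[sw - 1], simulation_config()$n_exhaust_mg_l + 1)
})

test_that("sugar-free initial state terminates immediately with one state", {
  m <- toy_model()
  st <- fermentation_state(conc = c(GLC_e = 0, FRU_e = 0, NH3_e = 100, AAN_e = 100,
                                    ETH_e = 0, GLYC_e = 0, ACE_e = 0, CO2_e = 0))
  traj <- simulate_fermentation(m, st, simulation_config(), list(toy_anaerobic()))
  expect_identical(traj$termination, "sugar_exhausted")
  expect_identical(nrow(traj$states), 1L)
})

test_that("halving the interval barely changes the endpoint (step robustness)", {
  traj1 <- bench_traj()
  traj2 <- cached("bench_half", simulate_fermentation(
    toy_model(), bench_state(), simulation_config(step_h = 0.25), list(toy_anaerobic())))
  f1 <- final_state(traj1); f2 <- final_state(traj2)
  expect_lt(abs(f2$ETH_e - f1$ETH_e) / f1$ETH_e, 0.02)
  expect_lt(abs(f2$GLYC_e - f1$GLYC_e) / f1$GLYC_e, 0.02)
})

test_that("a gpd-null strain cannot grow anaerobically unless the acetate rescue is inserted", {
  m <- toy_model()
  pat <- toy_anaerobic()
  st <- fermentation_state(conc = c(GLC_e = 50, FRU_e = 50, NH3_e = 120, AAN_e = 180,
                                    ETH_e = 0, GLYC_e = 0, ACE_e = 3, CO2_e = 0))
  cfg <- simulation_config(max_time_h = 60)
  del <- list(genetic_modification("GPD1", "deletion"),
              genetic_modification("GPD2", "deletion"))
  gm1 <- genetic_modifications(m, del)
  t1 <- simulate_fermentation(gm1$model, st, cfg, list(pat, gm1$patch))
  # no NADH sink: no growth at all
  expect_lt(final_state(t1)$biomass_gDW_L, st$biomass * 1.01)
  gm2 <- genetic_modifications(m, c(del, list(acetate_rescue_insertion())))
  t2 <- simulate_fermentation(gm2$model, st, cfg, list(pat, gm2$patch))
  f2 <- final_state(t2)
  expect_gt(f2$biomass_gDW_L, st$biomass * 2)   # growth restored
  expect_equal(f2$GLYC_e, 0)                    # no glycerol made
  expect_lt(f2$ACE_e, 3)                        # acetate consumed, not produced
})

test_that("an anisothermal profile modulates uptake through the Arrhenius factor", {
  m <- toy_model()
  st <- fermentation_state(conc = c(GLC_e = 60, FRU_e = 60, NH3_e = 120, AAN_e = 180,
                                    ETH_e = 0, GLYC_e = 0, ACE_e = 0, CO2_e = 0))
  prof <- data.frame(time_h = c(0, 10, 30), temp_C = c(16, 16, 30))
  cfg <- simulation_config(temperature = prof, max_time_h = 40)
  traj <- simulate_fermentation(m, st, cfg, list(toy_anaerobic()))
  expect_equal(traj$states$temperature_C[1], 16)
  late <- nrow(traj$states)
  expect_gt(traj$states$temperature_C[late], 25)
  # colder start consumes sugar more slowly than the isothermal 28 degC run
  iso <- simulate_fermentation(m, st, simulation_config(max_time_h = 40),
                               list(toy_anaerobic()))
  t10 <- function(tr) {
    s <- tr$states; approx(s$time_h, s$GLC_e + s$FRU_e, xout = 10, rule = 2)$y
  }
  expect_gt(t10(traj), t10(iso))
})

test_that("trajectory CSV and manifest round-trip through the command layer", {
  dir <- withr::local_tempdir()
  model_path <- file.path(dir, "toy.tsv")
  write_model(toy_model(), model_path)
  cfg_path <- system.file("config", "defaults.yaml", package = "dynafba")
  # trim the run so the test stays quick: small sugar load
  yml <- yaml::read_yaml(cfg_path)
  yml$initial$concentrations$GLC_e <- 25
  yml$initial$concentrations$FRU_e <- 25
  cfg2 <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(yml, cfg2)
  out <- file.path(dir, "run")
  code <- cmd_run(model_path, cfg2, out_prefix = out, quiet = TRUE)
  expect_identical(code, 0L)
  states <- read_trajectory_csv(paste0(out, ".csv"))
  expect_true(all(diff(states$GLC_e) <= 1e-9))  # monotone non-increasing sugar
  man <- jsonlite::fromJSON(paste0(out, "_manifest.json"))
  expect_identical(man$termination, "sugar_exhausted")
  expect_identical(unname(man$model_md5), unname(tools::md5sum(model_path)))
  # determinism: same inputs, byte-identical trajectory
  out2 <- file.path(dir, "run2")
  cmd_run(model_path, cfg2, out_prefix = out2, quiet = TRUE)
  expect_identical(readLines(paste0(out, ".csv")), readLines(paste0(out2, ".csv")))
  # deleting the biomass reaction through mods is a clean error
  mods <- file.path(dir, "mods.json")
  writeLines('[{"target": "BIOMASS", "kind": "deletion"}]', mods)
  expect_error(cmd_run(model_path, cfg2, mods, out_prefix = out, quiet = TRUE),
               class = "dynafba_mod_error")
})
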