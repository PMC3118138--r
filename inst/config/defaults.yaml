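# Default simulation configuration (documented in ?simulation_config and
# ?kinetic_parameters).  All values can be overridden; units in comments.
step_h: 0.5                # LP / integration interval (h)
temperature: 28            # degC; or a list of {time_h, temp_C} pairs
sugar_threshold_g_l: 2     # stop when total sugars reach this level (g/L)
n_exhaust_mg_l: 1          # YAN level switching the objective (mg N/L)
max_time_h: 1000           # safety stop (h)
maintenance_mode: equation # equation | zero | unbounded | constant
maintenance_constant: 1    # mmol ATP/gDW/h, used by "constant" mode
biomass_mode: dynamic      # dynamic | fixed
kinetics:
  sugar:
    vmax_ref_glc: 25       # mmol/gDW/h at t_ref
    vmax_ref_fru: 25
    kg: 5                  # g/L
    kf: 5
    kig_f: 5               # competitive inhibition by fructose (g/L)
    kif_g: 5
    ki_eth: 150            # non-competitive ethanol inhibition (g/L)
    ea: 55000              # J/mol
    t_ref: 28              # degC
  nitrogen:
    vmax_n: 12             # mg N/gDW/h
    k_n: 25                # mg N/L
  maintenance:
    m0: 3.5                # mmol ATP/gDW/h
    a_eth: 0.07            # per g/L ethanol above e_thr
    e_thr: 31.6            # g/L (~4 % v/v)
    a_t: 0.12              # per degC above t_thr
    t_thr: 30              # degC
    a_sluggish: 0.8        # surcharge for nitrogen-deficient cultures
    n_sluggish: 140        # initial-YAN threshold (mg N/L)
  carbohydrate:
    c_min: 0.22            # g/gDW
    c_max: 0.48
    k_c: 2
initial:
  temperature: 28
  biomass: 0.1             # gDW/L
  concentrations:
    GLC_e: 116.5           # g/L
    FRU_e: 116.5
    NH3_e: 120             # mg N/L
    AAN_e: 180
    ETH_e: 0
    GLYC_e: 0
    ACE_e: 0
    CO2_e: 0
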