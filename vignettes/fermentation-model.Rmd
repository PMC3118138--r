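---
title: "Dynamic flux balance simulation of anaerobic batch fermentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic flux balance simulation of anaerobic batch fermentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynafba)
```

## The model

`dynafba` simulates batch alcoholic fermentations of *Saccharomyces
cerevisiae* by coupling a stoichiometric flux balance model to the bioreactor
mass balances.  The procedure alternates four blocks:

1. **Fixed constraints** describe what does not change during the run: the
   anaerobic constraint set, the genetic background (deletions, insertions,
   over/under-expression), and non-limiting nutrient assumptions.
2. **Dynamic constraints** are rebuilt from the broth state every interval:
   hexose transport kinetics, nitrogen uptake, the maintenance-ATP lower
   bound, and the current biomass equation.
3. A **linear program** over the steady-state constraint $S\,v = 0$ with
   those bounds returns the specific consumption and production rates.
4. An **integrator** propagates the bioreactor balances
   $\dot X_V = \mu X_V$, $\dot M_i = q_i X_V$ over the interval with the
   rates held constant, after which the loop repeats until the sugar is
   consumed or the LP becomes infeasible.

Fluxes are in mmol/gDW/h; broth concentrations in g/L, except nitrogen
compounds which are tracked as mg N/L.  Exchange fluxes are negative for
uptake and positive for secretion, so a kinetic cap on uptake is applied to
the *lower* bound of the exchange reaction.  This convention is set once in
the bound-building code and used everywhere.

### Objective switching

While assimilable nitrogen (YAN) remains above an exhaustion threshold
(default 1 mg N/L, boundary inclusive on the exhausted side) the LP maximises
growth, mimicking exponential phase.  Once nitrogen is exhausted the growth
flux is clamped to zero and the LP minimises the maintenance-ATP flux: sugar
consumption then continues at the pace needed to cover maintenance, which is
what produces the long stationary phase characteristic of wine fermentations.

### Degeneracy and the parsimonious tie-break

FBA problems routinely have many optimal flux distributions.  Every
production solve in the dynamic loop is therefore lexicographic: the primary
objective is solved, its optimum is fixed (to within a relative slack of
$10^{-6}$), and the total absolute flux $\sum_i |v_i|$ is minimised on the
optimal face.  This makes trajectories reproducible run-to-run and
independent of solver vertex selection.  It is worth being explicit about
the consequence: quantities that in a degenerate LP are solver-dependent
(for example how much glycerol a *stationary-phase* solution makes when
several routes can supply maintenance ATP) are resolved here toward the
minimal-flux answer.  Published trajectories obtained with other solvers and
no tie-break can differ in exactly those regions, and ablation variants that
remove the maintenance bound altogether simply stall under this objective
rather than redistributing carbon.

### The LP backend

The package ships a dense bounded-variable revised simplex (RcppArmadillo)
behind a single `solve(c, A, b, l, u)` contract, so another backend can be
plugged in without touching the model code.  Numerical choices: feasibility
and reduced-cost tolerances $10^{-9}$; Dantzig pricing with a Bland-rule
fallback after $4(n+m)$ iterations to guarantee termination under
degeneracy; the basis inverse is maintained by product-form updates and
refactorised every 100 pivots.  Unbounded model bounds are represented in
the LP by $\pm 1000$ mmol/gDW/h, a solver-safe stand-in documented as the
numeric meaning of "non-limiting".  Optimal solutions satisfy
$\lVert S v\rVert_\infty \le 10^{-7}$ (asserted in the tests).

### Integration and event handling

Within an interval the balances are linear with constant specific rates, so
the exact solution is used instead of a numerical integrator:
$X_V(t{+}\Delta t) = X_V e^{\mu\Delta t}$ and
$M_i(t{+}\Delta t) = M_i + q_i X_V\,(e^{\mu\Delta t}-1)/\mu$ (with the
$\mu \to 0$ limit).  If a concentration would cross zero inside the
interval, the step is cut exactly at the earliest crossing (closed form, not
a root search), the species is set to zero, and the remainder of the
interval is re-solved with fresh bounds.  Concentrations therefore never go
negative.  The default interval is 0.5 h; halving it changes the bundled
benchmark's ethanol and glycerol endpoints by well under 2 % (asserted in
the tests), so the constant-rate assumption is not limiting at this
resolution.

If the LP is infeasible under the maintenance-minimisation objective the
step is retried once with the maintenance bound halved; this separates
numerical edge cases near sugar exhaustion from genuine metabolic
infeasibility, which terminates the run with reason `infeasible`.

## Dynamic constraint equations

The supplementary kinetic fits behind the original lookup-table constraints
are not part of this package; the dependencies they encode (what rises with
what) are implemented as closed forms that are monotone by construction and
fully overridable.

**Hexose transport.**  Each sugar follows Michaelis-Menten kinetics with
competitive inhibition by the other hexose, non-competitive inhibition by
ethanol, and an Arrhenius factor on the maximal rate:
$$
v^{ub}_{glc} \;=\; v_{max}(T)\,
\frac{G}{K_g\!\left(1 + F/K_{ig}\right) + G}\,
\frac{K_{i,eth}}{K_{i,eth} + E},
\qquad
v_{max}(T) = v_{max}^{ref}\,
e^{-\frac{E_a}{R}\left(\frac{1}{T}-\frac{1}{T_{ref}}\right)} .
$$

**Nitrogen uptake.**  Total YAN uptake saturates,
$v_N = v_{max,N}\, \mathrm{YAN}/(K_N + \mathrm{YAN})$ in mg N/gDW/h, and the
individual compounds (ammonium, amino-acid pool) share it in proportion to
their share of the current YAN - a competition for a common transporter
pool.  The allocation conserves total nitrogen flux exactly, which the tests
assert.  Sharing by concentration fraction is a design choice; a per-compound
affinity curve could replace it without touching the rest of the loop.

**Maintenance.**  The non-growth ATP demand is a lower bound on the
maintenance-hydrolysis flux,
$$
m_{ATP} = m_0 + a_{eth}\,(E - E_{thr})_+ + a_T\,(T - T_{thr})_+ +
a_{slug}\,[\mathrm{YAN}_0 < N_{slug}],
$$
with an ethanol stress threshold at about 4 % v/v (31.6 g/L).  The sluggish
surcharge keys on the *initial* YAN rather than the instantaneous value:
nitrogen deficiency is a property of the culture, and using the running YAN
would make every normal fermentation "sluggish" the moment nitrogen is
consumed.  A legacy flag returns the constant 1 mmol/gDW/h typical of
earlier genome-scale models.

**Biomass equation.**  Storage carbohydrate accumulates as fermentation
progresses; its mass fraction follows
$c(f) = c_{min} + (c_{max}-c_{min})\,f^{k_c}$ with $f$ the fraction of
initial sugar consumed, and the remaining macromolecule fractions are
rescaled proportionally so the composition always sums to 1 g/gDW.
Precursor coefficients are fraction over residue weight; a polymerisation
ATP cost (default 70 mmol/gDW) cycles ATP to ADP and phosphate.  The
biomass column of $S$ is replaced with this equation at every step; a
legacy flag freezes the base composition instead.

### Default parameters

Defaults live in `kinetic_parameters()` and `inst/config/defaults.yaml`,
with units documented there.  They are a reference set chosen once so that
the bundled toy network fermented at 28 degC with 300 mg N/L and 233 g/L of
sugars completes in roughly 100-150 h with qualitatively correct profiles
(ethanol accumulating to ~12 % v/v, glycerol produced during growth, a long
maintenance-paced stationary phase).  They are not a fit to any organism;
calibration against real fermentation data is the user's task and every
constant can be overridden from the YAML config.

## The toy network

Everything in the package is testable without external files because the
fixture network is built in code (`make_toy_network()`) and carries complete
elemental bookkeeping: every metabolite has a formula with integer atomic
masses, cofactor pairs carry their redox hydrogens explicitly
(NADH = NAD + H2), and every reaction except exchanges and the biomass drain
balances C, H, N, O, P and S exactly.  That exactness is what makes the
carbon-closure audit meaningful: over a full simulated fermentation,
elemental carbon in medium + biomass + evolved CO2 is conserved to well
under 0.5 % (the residual drift comes from the within-interval change of
biomass composition and the small sterol influx treated as an unlimited
reservoir).

The network is a caricature with the right couplings rather than a small
genome-scale model:

* fermentation is redox-neutral and yields 2 ATP per hexose
  (glucose to 2 ethanol + 2 CO2);
* biomass synthesis produces surplus cytosolic NADH, so anaerobic growth
  *requires* glycerol formation - closing the glycerol exchange drives the
  maximal anaerobic growth rate to zero;
* the TCA cycle is present as oxidative and reductive halves joined by the
  reactions tagged `tca_oxidative_break` (the succinate-dehydrogenase /
  alpha-ketoglutarate-dehydrogenase level); splitting it, as the anaerobic
  constraint set does, leaves the oxidative branch ending at 2-oxoglutarate
  for nitrogen assimilation and the reductive branch dead-ended at fumarate;
* quinone-tagged NADH oxidation evolves reducing equivalents without an
  oxygen requirement - exactly the shortcut that must be switched *off*
  anaerobically, because leaving it on displaces glycerol and inflates
  ethanol;
* sterol uptake is closed by default and relaxed by the anaerobic patch,
  so a "sterols limiting" ablation abolishes anaerobic growth;
* acetoin/butanediol sinks, an acetate branch, and respiration complete the
  subsystems the constraint set acts on.

Constraint targeting is tag-driven (`oxygen_uptake`, `tca_oxidative_break`,
`quinone`, `sterol_uptake`, ...) rather than hard-coded to gene lists, so the
same constraint logic applies to any model file that declares the tags.

What the toy deliberately does **not** emulate: genome-scale redundancy and
futile cycles (so degenerate-optimum behaviour is much milder than in a real
reconstruction), compartmentation, proton and phosphate balancing beyond
stoichiometric bookkeeping, regulation, lag phase, cell death, CO2
stripping and volume changes.  Passing tests on the toy therefore show that
the *machinery* - bounds, LP, integration, event handling, scoring - is
correct, not that the default parameters describe a particular strain.

## Genetic modifications

Deletions zero all reactions whose boolean gene rule evaluates false with
the deleted genes removed; all deletions in a modification list are
evaluated jointly, so isoenzyme pairs (`GPD1 or GPD2`) survive single
deletions and die with double ones.  Insertions append a new reaction and
re-validate the model.  Published overexpression levels are rarely
quantified, so over/under-expression scales the flux upper bound (and the
magnitude of a negative lower bound) by a factor, default 10 for
overexpression.  Genetic bounds are applied with their own provenance and
re-asserted after every dynamic patch: a knockout can never be re-opened by
a kinetic bound.

The bundled `acetate_rescue_insertion()` adds a lumped acetylating
acetaldehyde-dehydrogenase route (acetate + 2 NADH + 2 ATP to ethanol).  A
`GPD1`/`GPD2` double deletion leaves the anaerobic network without an NADH
sink and growth stalls; with the insertion and acetate in the medium, growth
resumes, glycerol stays at zero and acetate is consumed - the canonical
redox-engineering scenario the simulator is meant to explore.

## Validation scoring

Endpoint predictions for engineered strains are scored with the
relative-change statistic
$R = \lvert (D_{M,GM}-D_{M,WT})/D_{M,WT} - (D_{E,GM}-D_{E,WT})/D_{E,WT} \rvert$,
zero meaning the model reproduced the experimentally observed relative
change exactly.  The exact algebra behind the published score is not
recoverable from the available text, so this difference-of-relative-changes
form is implemented in a single function (`r_score()`) flagged as the place
to change should a different convention be preferred.  Wild-type
concentrations must be positive; table scoring reports undefined rows
instead of failing.

Profile agreement is the Pearson correlation (in percent; Spearman by flag)
between the experimental series and the simulation linearly interpolated at
the experimental times, per species, requiring at least three matched
points.  The published profile-agreement statistic is not defined precisely
enough to identify; Pearson on interpolated matched points is the documented
choice here.  `make_synthetic_experiment()` emulates triplicate measurements
with a given CV (multiplicative Gaussian noise, clamped at zero,
deterministic per seed) for self-contained testing of the scoring path.

## Problem sizes and run times

The bundled benchmark (toy network, 0.5 h intervals, ~285 steps with two
lexicographic LP solves per step) runs in a few seconds; the test suite
simulates about ten full fermentations, including ablation variants and a
half-interval sensitivity run.  These sizes were chosen as the package's
reference configuration; larger models plug in through the same interfaces,
with LP cost growing with the cube of the basis size per refactorisation.

## Known limitations

* Viable biomass is treated as total biomass: there is no death model, so
  late-phase biomass declines seen experimentally are not reproduced.
* Acetate is qualitatively right in engineering scenarios (consumed by the
  rescue route) but not quantitatively predictive; its synthesis is highly
  sensitive to conditions and regulation that constraint-based models do
  not carry.
* CO2 is tracked as cumulative evolved mass, not dissolved concentration;
  stripping and volume dynamics are out of scope.
* The maintenance, nitrogen and carbohydrate closed forms are monotone
  stand-ins for empirically fitted curves; their defaults are a documented
  reference set, not a calibration.
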