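---
title: "Modeling nitrogen-oxide fluxes during closed-vial nitrification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nitrogen-oxide fluxes during closed-vial nitrification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system

Nitrification converts ammonium to nitrate in two steps carried out by two
bacterial guilds: ammonia-oxidizing bacteria (here *Nitrosomonas europaea*,
"Ne") oxidize NH~3~ to nitrite via hydroxylamine, and nitrite-oxidizing
bacteria (*Nitrobacter winogradskyi*, "Nw") oxidize nitrite to nitrate.
Along the way both guilds, and plain aqueous/gas-phase chemistry, produce
and consume the nitrogen oxide gases NO, NO~2~ (together "NO~x~", as a
chemiluminescence analyzer reports them) and the greenhouse gas N~2~O.

`nitrox` models this system in the configuration in which it is typically
assayed: 5 ml of mineral medium in a crimp-sealed 160-ml serum vial at
30&nbsp;°C, shaken at 200 rpm, starting from 5 mM NH~4~^+^ and/or 5 mM
NO~2~^-^ and washed-cell inocula at OD~600~ 0.2 (Ne), 0.05 (Nw) or both
(coculture), incubated 10 h with hourly sampling.  The model couples three
layers:

1. **Reduced stoichiometric energy models** of each organism, solved by
   linear programming at every time step (flux balance analysis, FBA).
2. **Monod uptake kinetics and calibrated enzyme-activity bounds** that tie
   the LP to the state of the vial (dynamic FBA).
3. **Abiotic chemistry and two-film gas–liquid mass transfer** for the
   sealed vial: aqueous NO autoxidation
   (4NO + O~2~ + 2H~2~O → 4NO~2~^-^ + 4H^+^, extent rate
   $r = k\,[\mathrm{NO}]^2[\mathrm{O_2}]$), gas-phase oxidation
   (2NO + O~2~ → 2NO~2~), NO~2~ absorption with instantaneous hydrolysis to
   nitrite + nitrate, and Henry-law transfer
   $N_x = K_{L}a_x\,(H_x p_x - c_x)$ for O~2~, NO, N~2~O and CO~2~.

The pH is fixed at 7.4; protons are dropped from the state.  The
Henderson–Hasselbalch fraction of nitrite present as HONO at this pH is
below 10^-4^ (`hono_fraction()`), which is why nitrous acid volatilization
is treated as a diagnostic only.

## The energy cores

The genome-scale reconstructions that inspired this package have hundreds
of reactions; every quantity this package reports depends only on their
energy accounting, which a ~20-reaction core preserves:

* **Ne**: AMO (NH~3~ + O~2~ + 2e^-^ → NH~2~OH + H~2~O), HAO
  (NH~2~OH + H~2~O → NO~2~^-^ + 4e^-^, or the alternative three-electron
  mode yielding NO), nitrifier denitrification NIR (NO~2~^-^ + e^-^ → NO)
  and NOR (2NO + 2e^-^ → N~2~O), cytochrome P460 oxidizing *extracellular*
  hydroxylamine to N~2~O, a lumped oxidase/ATP-synthase chain, maintenance
  (NGAM 52.82 mmol ATP gDCW^-1^ h^-1^) and a biomass equation carrying the
  growth-associated maintenance (GAM 1060 mmol ATP gDCW^-1^).
* **Nw**: NXR (NO~2~^-^ + H~2~O → NO~3~^-^ + 2e^-^), a periplasmic NIR (its
  only NO source; the genome encodes no NOR, so the model cannot produce
  N~2~O), and the oxidase/synthase chain at 4 H^+^ per 2 e^-^ and 6 H^+^
  per ATP, which yields **0.667 mmol ATP per mmol NO~2~^-^**.  The POUGHON
  variant adds a lumped nitrite self-cycling loop (periplasmic reduction to
  NO, cytoplasmic re-oxidation) that nets 5.18 extra translocated protons
  per nitrite, raising the yield to **1.53**.  The energy variant and its
  maintenance (8 → 18.52 mmol ATP gDCW^-1^ h^-1^) switch at t = 3 h,
  reflecting the low initial nitrite-oxidation rates of batch cultures.

The proton-translocation stoichiometries are not independently observable
here; for Nw they are fixed by the two printed ATP yields, and for Ne the
lumped yield (3.5 ATP per electron pair respired, `atp_per_pair`) is set so
that the printed NGAM is payable at the measured uptake rates — with a
lower yield the culture could not even maintain itself at the observed
NH~3~ oxidation rate, which is the constraint that identifies it.

`audit_elements()` verifies that every interior reaction balances N and O
exactly (water is tracked; electrons/protons/ATP are currency metabolites).
Models round-trip through SBML Level 3 + FBC (`write_sbml()`/`read_sbml()`)
bit-exactly, which is also the hook for substituting full reconstructions.

## The dynamic engine

At every right-hand-side evaluation the engine computes Monod bounds from
the current concentrations and solves one LP per organism.  Three design
choices matter:

* **Uptake follows measured kinetics.**  The LP is driven to realize the
  Monod uptake rate (classic static-optimization dynamic FBA), implemented
  as the top level of a weighted objective hierarchy: uptake ≫ calibrated
  denitrification activity ≫ the scheduled objective (biomass, or nitrite
  production in candidate model 2).  The weights (10^4^, 10^2^, 1) exceed
  any feasible trade-off ratio, so the hierarchy is equivalent to
  lexicographic optimization here while needing a single solve.  A pure
  "maximize growth, uptake free" policy was rejected because it is
  inconsistent with the observed behavior of washed, starved cells, which
  oxidize ammonia at full rate from the first minutes.
* **Nitrifier denitrification is kinetically forced.**  NIR, NOR and P460
  carry calibrated capacity bounds modulated by substrate Monod terms and,
  for NIR/NOR, an O~2~-inhibition factor $K_I/(K_I + [\mathrm{O_2}])$
  (K~I~ = 25 µM): NO production switches on as dissolved O~2~ falls, which
  is the observed behavior.  A growth-greedy LP would never route electrons
  to these reactions (they yield no ATP), so they must be forced — this
  mirrors placing calibrated "constraints on NIR and NOR activity".
* **Hydroxylamine spill is an overflow, not an optimum.**  Extracellular
  NH~2~OH accumulates when the AMO influx exceeds the HAO throughput bound
  (`hao_cap`): freshly inoculated, starvation-recovering cells take up
  ammonia faster (elevated first-segment V~max~, 0–1 h) than they oxidize
  hydroxylamine, and the excess is excreted.  After the first segment the
  spill stops and the pool is consumed by periplasmic P460 (producing
  N~2~O) and by re-oxidation through spare HAO capacity.  An LP would never
  *choose* to excrete hydroxylamine — excretion always loses electrons —
  so a purely objective-driven account (e.g. a transient internal reductant
  pool discharged through AMO) cannot produce a peak at 1 h under a
  biomass-first objective; the overflow formulation can, and its single
  capacity parameter is calibrated directly against the measured NH~2~OH
  peak (`fit_hao_cap()`).
* Candidate objective schedules: the **final** model maximizes NH~3~ uptake
  for the first 15 min before biomass-first; **model1** is biomass-first
  throughout; **model2** maximizes nitrite production for the first 2 h,
  during which the HAO throughput bound is released (calibrating for
  maximal NO~2~^-^ output means nothing is diverted), which is why model2
  predicts essentially no extracellular hydroxylamine while model1 and the
  final model predict a transient peak.

If maintenance ATP cannot be paid (substrate exhausted), the step is
re-solved with growth blocked and the NGAM bound released: cells keep
catalyzing at kinetic rates but do not grow, reproducing the
post-exhaustion plateaus without a death model.

The LPs are solved by an internal dense bounded-variable simplex with
Bland's rule.  Between consecutive evaluations only the bounds change, and
the optimality of a simplex basis depends on the bound *status* pattern,
not the bound values, so the previous optimal basis is re-validated with a
single linear solve (~0.2 ms); a full re-solve happens only when the active
set actually changes.  This keeps a 10-h adaptive stiff integration
(`deSolve::lsoda`, rtol 10^-6^, atol 10^-12^, reporting grid 0.05 h) at a
few seconds.  Integration restarts at every structural switch time
(objective switch at 0.25 h, uptake-segment boundaries, the Nw energy
switch at 3 h) so discontinuities never sit inside an integrator step.

## Calibration

`calibrate_scenario()` reproduces the study's procedure from a measured
series:

1. **V~max~ per segment** from the least-squares slopes of the consumption
   curves (`vmax_from_segments()`), with the breakpoint chosen by
   piecewise-linear fit quality (`detect_segments()`, 2 segments max).
2. **K~m~** values default to literature constants (flagged in the
   parameter provenance); optionally `fit_km()` matches the simulated final
   concentration to the measured one by bisection on log K~m~, using the
   monotone relationship between K~m~ and residual substrate.
3. **HAO throughput** from the NH~2~OH peak (`fit_hao_cap()`, bisection;
   the peak height is monotone in the spill margin).
4. **NIR/NOR bounds** by bounded coordinate descent from a fixed coarse
   grid (`fit_gas_constraints()`), minimizing the squared relative mismatch
   of peak NO~x~, peak N~2~O and final NO~x~ (the final value, a single
   noisy sample, enters with weight 0.25).  Peaks of noisy series are taken
   as the maximum of a centered 3-point running mean, except the sharp 1-h
   NH~2~OH peak, which is a single sample.

On noise-free synthetic data this pipeline recovers the generating V~max~
within a few percent and the activity bounds within ~15%; at the
experimental noise level the slope-derived V~max~ stays within 15% across
seeds (both properties are exercised in the test suite).

## Synthetic data

`make_fixture_scenarios()` returns the four vial experiments with their
printed initial conditions; `generate_timeseries()` samples a simulation
hourly and adds per-replicate Gaussian noise (n = 4, clamped at zero) with
per-scenario SDs matching each experiment's error bars (e.g. NO~x~
±5.7 ppm in the Ne culture but ±0.12 ppm in the Nw culture).  The
generator emulates the *structure* of the experiments — magnitudes, error
levels, sampling — from the package's own forward model; it does not
emulate instrument drift, NO~x~-converter cross-sensitivity,
sampling-induced headspace loss, or any biology missing from the forward
model itself, so round-trip tests demonstrate internal consistency of the
pipeline, not correctness against independent laboratory data.

Default parameter values (uptake segments, activity bounds, spill
capacity) were chosen once so that the simulated cultures show the
characteristic published behavior of this vial system — ammonium consumed
in ~3.5 h with a steeper first hour, tens of ppm of NO~x~ and N~2~O in the
Ne culture and coculture but ~1.5 ppm NO~x~ in the Nw culture, a
transient extracellular NH~2~OH peak at 1 h that is gone by 4 h, a
microaerobic dip in dissolved O~2~, and a coculture that out-emits the
summed single cultures — and they are not revisited thereafter.  Each
experiment is calibrated separately (as in the study), so the coculture
defaults differ from the single-culture defaults: more electron flux
through NIR under the deeper O~2~ drawdown, and a smaller hydroxylamine
spill.

## Numerical choices and degenerate inputs

* Bland's rule makes the LP vertex deterministic; `fba_solve()`
  additionally breaks objective ties by minimizing total absolute flux
  (exact, via auxiliary variables).  The engine skips that stage for speed.
* Negative concentrations are clamped to zero inside the RHS; the state is
  clamped on output.  All-zero states give all-zero derivatives.
* Redundant stoichiometric rows are tolerated (phase-1 artificials stay
  basic at zero).
* Abiotic total-N conservation is exact by construction (every reaction
  conserves N; transfer terms are converted mole-consistently between
  phases), and simulations are required to keep total N (including
  biomass-incorporated N at 10 mmol N gDCW^-1^) within 0.1% over 10 h.
* The 0.25-h objective switch, segment boundaries and the 3-h energy
  switch are integrator restart points.
* The LP warm-start cache is keyed per organism and maintenance mode; a
  basis is reused only after re-verifying primal feasibility and reduced
  costs, so caching never changes results.

## Known limitations

* The per-species overall transfer coefficients are *effective* values for
  this vial format.  Film theory would put the NO coefficient within a
  factor ~2 of the O~2~ one; here the trace-gas coefficients (3 h^-1^ vs
  15 h^-1^ for O~2~) are empirical calibration constants of the closed
  system, absorbing everything the two-film picture misses (septum
  adsorption, analyzer sampling, surface renewal differences).
* With the literature aqueous autoxidation constant, the abiotic NO sink
  is strong at the micromolar dissolved NO of an active Ne culture but
  negligible at the nanomolar NO corresponding to a ~1.5-ppm headspace;
  consequently the NO source strength required to sustain small headspace
  peaks in a cell-free vial (`required_no_production()`) is of order
  1 nmol h^-1^, orders of magnitude below estimates derived from stronger
  assumed abiotic sinks.
* Biotic N~2~O by Nw, dynamic pH, quorum-sensing regulation of NO
  production, spatial gradients and death/lysis are out of scope.
* NO~x~ in simulations peaks at the end of NH~3~ oxidation (production is
  O~2~-gated and stops when uptake stops); observed coculture NO~x~ can
  peak somewhat earlier, suggesting regulation beyond the O~2~ gate.
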