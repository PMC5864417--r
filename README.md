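# nitrox

Dynamic flux balance modeling of nitrogen-oxide fluxes during complete
nitrification in sealed batch vials.

## What this package is for

Nitrifying bacteria emit the air pollutants NO/NO₂ (NOₓ) and the greenhouse
gas N₂O while converting ammonium to nitrate.  Disentangling *which*
processes produce and consume these gases — ammonia-oxidizer enzymes (NIR,
NOR, cytochrome P460, HAO), nitrite-oxidizer NIR, or plain abiotic
chemistry — requires a model that couples the organisms' energy metabolism
to the chemistry and gas transfer of the culture vessel.  `nitrox` is such a
model for the classic two-organism system *Nitrosomonas europaea* (ammonia
oxidizer) + *Nitrobacter winogradskyi* (nitrite oxidizer) in crimp-sealed
160-ml serum vials (5 ml medium, 30 °C, 10 h), for microbiologists and
modelers studying nitrifier N-oxide emissions.

At its core:

* reduced stoichiometric **energy models** of both organisms solved by
  linear programming at every time step (dynamic FBA, dFBA).  For the
  nitrite oxidizer the maximum ATP yield is 0.667 mmol ATP per mmol NO₂⁻
  with periplasmic nitrite reduction only, rising to 1.53 with the
  nitrite self-cycling (Poughon) energy variant that switches on at 3 h;
* **Monod uptake kinetics** (`Vmax·S/(Km+S)`) with per-segment Vmax
  calibrated from measured consumption-curve slopes, and calibrated
  NIR/NOR/P460 activity bounds gated by dissolved O₂;
* **abiotic chemistry**: third-order aqueous NO autoxidation
  (r = k[NO]²[O₂], 4NO + O₂ + 2H₂O → 4NO₂⁻ + 4H⁺), gas-phase
  2NO + O₂ → 2NO₂, NO₂ hydrolysis, fixed-pH speciation, and two-film
  gas–liquid transfer Nₓ = K_L aₓ (Hₓ pₓ − cₓ) for O₂, NO, N₂O, CO₂.

The package ships fixture scenarios for the four benchmark experiments
(ammonia-oxidizer single culture, nitrite-oxidizer single culture,
coculture, abiotic control), a synthetic-data generator that emulates their
hourly sampling and error bars, the calibration pipeline, and Fig-style NO
source/sink decomposition.

## Worked example

```r
library(nitrox)

scs <- make_fixture_scenarios()      # the four vial experiments
tr  <- simulate_scenario(scs$ne_single)
tr
#> <nox_trajectory> ne_single: 10.0 h, 201 points
#>   peak NOx   30.19 ppm at 4.35 h
#>   peak N2O   42.86 ppm at 10.00 h
#>   peak NH2OH  83.4 uM  at 1.00 h
```

The ammonia-oxidizer culture consumes its 5 mM NH₄⁺ in ~3.5 h; headspace
NOₓ climbs to ~30 ppm while oxidation is active and declines afterwards
(redissolved NO is oxidized abiotically to nitrite), N₂O accumulates to
~43 ppm and stays (it has no sink), and extracellular hydroxylamine spikes
to ~83 µM at 1 h — the overflow of ammonia uptake over hydroxylamine
oxidation capacity in starvation-recovering cells — before cytochrome P460
and re-oxidation clear it by 4 h.

```r
atp_yield_per_no2(build_nw_model("SIMPLE"))    # 0.6666667
atp_yield_per_no2(build_nw_model("POUGHON"))   # 1.53

dec <- no_source_sink_decomposition(tr)        # umol NO / h, whole vial
max(dec$ne_nir)                                # 0.353: NIR is the main NO source
```

Calibration against (synthetic or real) measured series:

```r
ser   <- generate_timeseries(scs$ne_single, seed = 1)  # hourly, n = 4, noisy
calib <- calibrate_scenario(scs$ne_single, ser)        # slopes, NH2OH peak, gas peaks
tr2   <- simulate_scenario(scs$ne_single, calib)
```

A thin command-line wrapper lives at `inst/cli/nitrox`
(`nitrox simulate|calibrate|synth|report --config cfg.yaml`).

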