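# mepflux

Kinetic flux profiling of the plastidial methylerythritol 4-phosphate
(MEP) pathway from whole-plant ¹³CO₂ labeling experiments.

## What it does, and for whom

When a plant's atmosphere is switched to ¹³CO₂, newly fixed carbon labels
the MEP pathway intermediates — DXP, MEcDP, and the C5 end products
IDP + DMADP — and the volatile product isoprene, whose isotopologues
(m/z 69–74 on a PTR-MS) read out the labeling state of the IDP + DMADP
pool on-line. `mepflux` is for plant physiologists and metabolic
biochemists who run such experiments (e.g. on drought-stressed conifers)
and want to turn the raw channel intensities, pool measurements and pot
weights into a pathway flux with honest diagnostics.

The core is the closed-form step response of a three-pool series cascade
at metabolic steady state. With plastidial pool sizes *A* (DXP), *B*
(MEcDP), *C* (IDP + DMADP), pathway flux *J* and plateau labeling *m*,
the fractional labeling of isoprene is

```
f(t) = m [ 1 − A²/((A−B)(A−C)) e^(−Jt/A)
             − B²/((B−A)(B−C)) e^(−Jt/B)
             − C²/((C−A)(C−B)) e^(−Jt/C) ]
```

`fit_flux()` estimates (J, m) by bounded Levenberg–Marquardt least
squares with the pools entered as known constants, flags curves with too
little incorporation ("not detectable") and fits whose labeling window is
too short to separate m from J. An independent ODE oracle
(`cascade_fraction_ode()`, via deSolve) guards the closed form, including
at confluent pool sizes.

Around the model sit the supporting steps: isotopologue enrichment
fractions, exact natural-¹³C-abundance correction, standard-addition and
external-standard quantification, PTR-MS ncps normalization and emission
rates, plastidial pool partitioning from final enrichments, FTSW/RTR
drought staging from daily pot weights, and per-variable group statistics
(one-way ANOVA, Tukey HSD, compact significance letters, Shapiro–Wilk).
A synthetic-experiment generator (`simulate_experiment()`) produces full
input bundles with known ground truth.

## Worked example

Simulate a drought experiment (control / moderate / severe, five trees
each, 50-min labeling window) and run the whole pipeline:

```r
library(mepflux)
ex  <- simulate_experiment(scenario_config(seed = 20))
res <- run_pipeline(ex)
res
#> MEP-pathway pipeline result
#>   enrich: 60 spectra corrected (p13C = 0.0107)
#>   pools: plastidial partition for 15 replicates
#>   fit: 15 replicates, 5 not detectable
#>   stage: 315 tree-days staged
#>   report: 3 variables

res$fits[, c("replicate_id", "treatment", "J_hat", "m_hat", "detectable")]
#>    replicate_id treatment J_hat  m_hat detectable
#>  1 control_1    control   0.198 0.858  TRUE
#>  6 moderate_1   moderate  0.125 0.605  TRUE
#> 11 severe_1     severe    0     0.0308 FALSE
#>    ... (15 rows)

res$report[res$report$variable_id == "mep_flux",
           c("group", "mean", "se", "pct_change", "letters")]
#>   group     mean       se pct_change letters
#> 1 control  0.199 0.000763        0   a
#> 2 moderate 0.123 0.000656       38.0 b
```

Read: control trees carry a flux of ≈0.2 nmol g⁻¹ DW min⁻¹ with isoprene
labeling saturating near 85%; moderate drought reduces the flux by ≈38%
(significant, distinct letters); under severe drought the labeling never
exceeds 5% within the window, so no flux can be calculated — the fits are
flagged not detectable rather than reported.

Individual steps are available directly:

```r
p <- cascade_params(2, 1, 0.5, flux = 0.2, plateau = 0.85)
cascade_fraction(c(10, 25, 50), p)      # model curve
plastidial_pool(10, 0.75, 0.87)         # 8.62 nmol/gDW plastidial DXP
classify_stage(rtr(150, 300))           # "moderate" (RTR 50%)
```

A thin shell wrapper for the simulate/run pair ships in
`inst/scripts/mepflux`.

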