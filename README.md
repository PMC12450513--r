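# afcea

Cost-effectiveness modelling of a clinical decision support (CDS) system
for anticoagulation in atrial fibrillation (AF).

Oral anticoagulation prevents most AF-related strokes, yet a substantial
fraction of eligible patients never receive it. A CDS embedded in the
electronic health record can raise adherence to guideline-recommended
anticoagulation by a small absolute amount (an adherence gain of 0.016 in
the trial this model is built around). `afcea` answers the health-economic
question that follows: is that gain worth paying for?

The package is aimed at health economists and HTA analysts. Its core is a
discrete-time Markov cohort model with yearly cycles: patients start in AF
(untreated / warfarin / NOAC by arm-specific adherence, the whole CDS
increment assumed NOAC-treated), face competing risks of ischaemic stroke
(IS), intracranial haemorrhage (ICH), systemic embolism (SE), myocardial
infarction (MI) and recurrent major bleeding (MB) converted from annual
rates by `p = 1 − exp(−r)` and scaled by treatment-specific relative
risks, pass through one-cycle acute states with case fatality, and accrue
half-cycle-corrected, discounted (3%/yr) costs and QALYs until the life
table closes at age 110. Results are reported as

```
ICER = (C_CDS − C_SoC) / (Q_CDS − Q_SoC)   [€ per QALY]
```

judged against a willingness-to-pay threshold λ = €50 000/QALY, with
probabilistic (10 000-draw), one-way (tornado), time-horizon,
treatment-effect, implementation-cost, threshold-price and risk-profile
sensitivity analyses.

## Worked example

All analyses run from a single validated parameter object. The bundled
synthetic generator produces a complete, internally consistent set
(literature-plausible rates, a Gompertz life table, Swedish-magnitude
costs) so the full pipeline runs with no external data:

```r
library(afcea)

params <- generate_synthetic_parameters(seed = 1)
res <- run_cea(params)
res
#> <afcea_cea> CDS vs standard of care
#>   undiscounted events/cohort patients (SoC -> CDS):
#>     IS    211.84 ->   208.40 (-3.44)
#>     ICH    22.80 ->    22.87 (+0.07)
#>     SE     31.32 ->    30.81 (-0.52)
#>     MI    140.60 ->   140.94 (+0.34)
#>     MB    154.32 ->   155.20 (+0.88)
#>   total cost:  SoC    13494731.01  CDS    13559589.43  (delta +64858.41)
#>   total QALYs: SoC         6578.1  CDS         6587.0  (delta +8.925)
#>   ICER: 7267.45 per QALY (tradeoff_icer)
```

Reading: per 1000 patients over a lifetime, the CDS strategy prevents
about 3.4 ischaemic strokes but causes ~0.9 extra major bleedings; it
costs €64 858 more (the €2996 CDS fee plus extra anticoagulation, partly
offset by avoided event costs) and gains 8.9 QALYs, i.e. ~€7267 per QALY
gained — far below the €50 000 threshold. Uncertainty and scenarios:

```r
psa <- run_psa(params, n_draws = 10000, seed = 1)   # probabilistic analysis
one_way_analysis(params)                            # tornado table
max_cds_cost(params)                                # highest cost-effective CDS price
risk_profile_scenario(params, "scenario1_low_risk") # CHA2DS2-VASc ~1 cohort
```

Parameter sets round-trip through a documented YAML schema
(`write_parameters()` / `load_parameters()`), and a command-line interface
(`inst/cli/afcea`, a thin wrapper over `cmd_base_case()`, `cmd_psa()` and
`cmd_sensitivity()`) writes diff-stable CSV/JSON tables, per-cycle traces
and a run manifest for every analysis:

```sh
Rscript inst/cli/afcea base-case --config params.yaml --out results/
Rscript inst/cli/afcea psa --config params.yaml --n-draws 10000 --seed 1 --out results/
Rscript inst/cli/afcea sensitivity --mode tornado --config params.yaml --out results/
```

See `vignettes/model-methods.Rmd` for the model's assumptions, the
synthetic defaults and their rationale, and known limitations.

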