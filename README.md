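# kneecua

Cost-utility analysis of the three surgical strategies for medial
compartment knee osteoarthritis in young patients — total knee arthroplasty
(TKA), unicompartmental knee arthroplasty (UKA), and medial opening wedge
high tibial osteotomy (HTO) — from a Canadian public-payer perspective.

The package is aimed at health-economics and outcomes researchers who want
a fully inspectable, testable implementation of this decision problem: a
discrete-time Markov cohort model (one-month cycles, age 45 to 90) whose
distinctive feature is mode-specific failure pathways. Failures with
postoperative joint instability are revised with an expensive varus-valgus
constrained (VVC) prosthesis and leave patients at lower utility; failures
without instability get a standard first revision, and any later failure is
revised with a VVC implant, after which no further surgery is modelled. HTO
failures convert to TKA (with hardware removal) and then follow the TKA
pathway.

## The model in brief

For each strategy the cohort occupancy vector `x_t` over health states
evolves as `x_{t+1} = x_t P(a_t)`, where the transition matrix at age `a_t`
applies background mortality first and scales event probabilities by the
survival complement. Discounted effectiveness in quality-adjusted life
months (QALMs) uses the trapezoidal within-cycle correction,

    E = Σ_t ½ (x_t + x_{t+1}) · u · (1 + r)^-(t + ½)/12,

while one-time surgery costs are event-dated: each arrival into a revision
state at cycle `t` is charged that state's cost at discount `(1+r)^-t/12`.
Strategies are compared by league table (absolute dominance, ICER = ΔC/ΔE
between successive undominated strategies) and net monetary benefit
`NMB = E·WTP − C` at WTP = $4,166.67 CAD/QALM ($50,000/QALY). Uncertainty
is explored by a 3,000-iteration probabilistic sensitivity analysis (beta
utilities/probabilities, gamma costs, method-of-moments), acceptability
curves, tornado/threshold/two-way deterministic sensitivity analysis, and
sex-specific mortality scenarios. A 200,000-patient microsimulation of the
identical process validates the cohort engine. Because national life
tables cannot be shipped, the package generates Gompertz–Makeham life
tables calibrated to Canadian remaining life expectancy at 45 (37.8 years
general, 36.0 male, 39.6 female); see the methods vignette for what that
stand-in does and does not certify.

## Worked example

```r
library(kneecua)

params <- base_case_parameters()                    # bundled table1.yaml
lt     <- read_life_table(synthetic_life_table_path("general"))

runs <- lapply(c("TKA", "UKA", "HTO"), function(s)
  run_cohort(build_strategy_model(s, params), lt, params))
league_table(runs, wtp = params$wtp_per_qalm)
#> League table (WTP 4,166.67 CAD/QALM)
#>  strategy    cost incr_cost  effect incr_effect icer     nmb            dominance
#>       UKA 13133.5        NA 280.851          NA   NA 1157080          undominated
#>       TKA 18882.8        NA 265.181          NA   NA 1086041 absolutely_dominated
#>       HTO 19087.7        NA 267.192          NA   NA 1094213 absolutely_dominated
```

UKA delivers the most QALMs (280.9 vs 265.2 for TKA and 267.2 for HTO) and
— once the revision burden implied by the monthly failure probabilities is
accrued — also the lowest lifetime cost, so at this willingness to pay it
has the highest NMB and absolutely dominates both alternatives. (The
published analysis this model follows reported lifetime costs equal to the
index surgery costs, making UKA the *most* expensive arm with an ICER of
$19.46/QALM over TKA; the methods vignette discusses why those published
costs cannot be reconciled with the published failure probabilities, and
the acceptance checks report the discrepancy rather than hiding the
accrual.)

```r
res <- run_psa(params, lt, n = 1000, seed = 42)
round(optimal_probabilities(res, params$wtp_per_qalm), 3)
#>   TKA   UKA   HTO
#> 0.200 0.582 0.218

threshold_find(params, lt, "u_well_UKA", c(0.60, 0.87))
#> [1] 0.8089727
```

UKA is the most cost-effective option in about 58% of PSA iterations at
the base willingness to pay, and loses its advantage over TKA only if the
utility of the well-after-UKA state falls below about 0.809.

Pipeline wrappers (`cua_run`, `cua_psa`, `cua_ceac`, `cua_tornado`,
`cua_twoway`, `cua_scenario`) write CSV artifacts plus a JSON manifest, and
`inst/cli/cua.R` exposes them as a command line:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/cua.R", package="kneecua"))')" \
  run --out results/
```

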