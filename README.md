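# persistkit

Treatment persistence and medical costs of injectable biologic therapies,
inferred from health-insurance claims.

Administrative claims data record dated drug claims, diagnoses and billed
amounts — never "the patient stopped therapy". For biologics in psoriasis
(adalimumab **ADL**, infliximab **IFX**, secukinumab **SCK**, ustekinumab
**UST**), persistence must be reconstructed from the spacing of refill
claims, and the economic consequences of discontinuation from costs summed
in windows around the initiation date. persistkit implements that full
chain as a tested R pipeline:

* **Cohort construction** from a four-table claims bundle (enrollment,
  diagnoses, drug claims, costs): ICD-10 prefix inclusion (psoriasis,
  L40) plus a biologic claim; exclusion of competing biologic
  indications (RA, IBD, ankylosing spondylitis, juvenile arthritis); one
  analysis unit per patient × biologic, indexed at that drug's first
  claim; biologic-naive classification over a 365-day look-back.
* **Refill-gap treatment episodes.** Per drug, the *non-refill period* =
  treatment interval + medication gap (base case 30 + 60 days for
  ADL/IFX/SCK, 90 + 60 for UST). An episode ends at the first of: a
  claim-free span exceeding the non-refill period (*gap*, dated at last
  claim + treatment interval — the end of supplied therapy), a claim of
  a different biologic (*switch*, dated at that claim), or censoring at
  the end of observation.
* **Survival machinery, from scratch**: Kaplan-Meier product-limit
  estimate S(t) = prod (1 − d_i/n_i) with Greenwood variance
  S² · sum d_i/(n_i(n_i−d_i)), symmetric 95% bands (flagged unavailable
  when a risk set is exhausted), log-rank and Gehan-Breslow Wilcoxon
  two-sample tests, pairwise against a reference drug.
* **Cost windows**: inpatient / outpatient / non-biologic-drug / total
  amounts over the 12 months before and after index (the index day is
  post), and persistent-vs-non-persistent contrasts of cost increases.
* **A seeded synthetic claims generator** with known ground truth
  (per-30-day-cycle geometric discontinuation, scheduled dosing,
  switching, gamma-distributed costs, decoy patients), calibrated to the
  published Japanese psoriasis biologics cohort it emulates, so every
  stage is testable without proprietary data.

## Worked example

```r
library(persistkit)

sim <- generate_cohort(simulation_config(n_patients = 500, seed = 42))
sim$bundle
#> <claims_bundle>
#>   enrollment     500 rows
#>   diagnoses     1078 rows
#>   drug_claims   6422 rows
#>   costs        79471 rows

pts   <- apply_exclusions(select_psoriasis_bt_patients(sim$bundle), sim$bundle)
attr(pts, "cascade")
#>                   stage count
#> 1   inclusion_dx_claims   466
#> 2 inclusion_dx_patients   466
#> 3             bt_claims  6422
#> 4           bt_patients   444
#> 5    dx_and_bt_patients   417
#> 6        excluded_by_dx   229
#> 7      after_exclusions   188

units    <- classify_naive(build_patient_units(pts, sim$bundle), sim$bundle)
episodes <- build_episodes(units, sim$bundle$drug_claims)
subset(persistence_table(units, episodes),
       population == "naive" & horizon_days == 365)
#>  drug  n rate_pct ci_halfwidth_pct ci_available logrank_p
#>   ADL 41     41.5            15.08         TRUE  1.06e-07
#>   IFX 37     62.2            15.63         TRUE  8.16e-02
#>   SCK 26     46.2            19.16         TRUE  5.67e-03
#>   UST 73     75.3             9.89         TRUE        NA
```

Each row is the Kaplan-Meier persistence rate at 12 months with its
Greenwood 95% half-width and the unadjusted log-rank p-value versus the
reference drug (UST, hence its own p is NA): under the calibrated default
hazards, UST keeps about three quarters of naive patients on therapy at
one year while ADL keeps well under half, and the UST–ADL contrast is
overwhelming. The cost side, in thousand JPY per patient
(`post = pre + increase`):

```r
cu <- select_cost_population(units[units$naive, ])
s  <- window_costs(cu, sim$bundle$costs)
reconstruct_post_costs(cost_summary_by_drug(cu, s))  # thousand JPY, naive
#>      drug   n pre_total inc_total post_total
#>       ADL  41       645      1731       2377
#>       IFX  37       634      2501       3134
#>       SCK  26       604      1776       2380
#>       UST  73       642      2534       3176
#>  subtotal 177       635      2230       2865
```

Total yearly medical costs rise from roughly 0.6M JPY before initiation
to around 3M JPY after — the biologic itself, billed in the outpatient or
inpatient setting, dominates the increase.

`run_pipeline(pipeline_config(...))` runs everything above from one
config (synthetic or CSV-file input) and writes the cascade, the
demographics/comorbidity/persistence/cost tables, the gap-sensitivity
grid, Kaplan-Meier plots and a seeded run log. A thin command-line
wrapper lives in `inst/cli/persistkit.R`
(`simulate` / `run` / `sensitivity`, YAML-configured; see
`inst/extdata/example_config.yaml`).

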