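---
title: "Methods: refill-gap persistence and cost windows from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: refill-gap persistence and cost windows from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(persistkit)
```

## The problem

Persistence — how long a patient stays on a therapy after starting it — is
a standard real-world outcome for injectable biologics in psoriasis
(adalimumab ADL, infliximab IFX, secukinumab SCK, ustekinumab UST).
Administrative claims data never record "the patient stopped"; they record
dated drug claims, and discontinuation must be *inferred* from the spacing
of those claims. persistkit implements the full inference chain — cohort
selection, refill-gap episode construction, product-limit estimation,
two-sample testing and 12-month pre/post cost accounting — over a
four-table claims bundle (enrollment, diagnoses, drug claims, costs), and
ships a seeded synthetic generator shaped like a Japanese employer-based
claims database so every stage can be validated against known ground
truth.

## Data model and cohort rules

All dates are integer day offsets from a common origin; claims databases
carry day-level dates, and integer arithmetic keeps every window exact.
On disk ([write_bundle()] / [read_bundle()]) dates are ISO-8601. "12
months" is always 365 days and "24 months" 730 days.

Cohort selection mirrors the usual flow-diagram cascade:

1. keep patients with at least one inclusion diagnosis (ICD-10 prefix
   `L40`, psoriasis) *and* at least one biologic claim;
2. remove patients with any diagnosis of rheumatoid arthritis (M05–M06),
   inflammatory bowel disease (K50–K51), ankylosing spondylitis (M45) or
   juvenile arthritis (M08) — diseases that are themselves biologic
   indications and would contaminate exposure. These prefixes are
   conventional defaults and fully overridable through [code_policy()],
   since code lists vary between studies;
3. split each patient into **patient-units**, one per biologic class
   received, indexed at that class's first claim. Multiple biologic
   cycles in one patient are deliberately counted as separate analysis
   units and never deduplicated;
4. a unit is **biologic-naive** when no claim of any biologic falls in
   the closed window `[index − 365, index − 1]`. We additionally require
   365 days of pre-index enrollment to *assert* naivety: an index too
   close to the start of observation cannot be proven naive and is
   labelled experienced by default (`unknown_as = "naive"` flips this).
   ICD-10 matching is by code prefix on normalised codes, so `L40`
   matches `L40.5`.

The cost population keeps units with 12 months of enrollment on both
sides of index (`obs_start ≤ index − 365`, `obs_end ≥ index + 365`).

## Episode construction

The core quantity per drug is the **non-refill period** = treatment
interval + medication gap. The treatment interval is the scheduled days
between administrations (30 for ADL/IFX/SCK, 90 for UST, per approved
regimens); the medication gap is the tolerated extra refill delay (60
days base case for all four). The base non-refill periods are therefore
90/90/90/150 days.

Scanning the index drug's claims forward from index, the episode ends at
the first of:

* **gap** — the span from one index-drug claim to the next (or to the
  end of observation) exceeds the non-refill period;
* **switch** — a claim of a *different* biologic occurs before that gap
  completes.

Three conventions deserve emphasis, because the published description of
this class of algorithm is silent on them:

* **Event time for a gap.** We date the discontinuation at
  *last qualifying claim + treatment interval* — the end of supplied
  therapy. Alternatives (last claim date; end of the non-refill window)
  either undercount supplied therapy or make the event date move with
  the gap parameter, which would contaminate the gap-sensitivity
  analysis. With our convention, enlarging the gap can only *delay or
  remove* events, never re-date them, which is what makes the
  sensitivity grid provably monotone.
* **Ties.** A switch claim on the same day as an index-drug claim, or on
  the last day before a gap completes, counts as a switch
  (`switch_on_tie = TRUE`; configurable). A claim arriving on day
  `last + non-refill + 1` is too late: the claim-free period has already
  completed.
* **Censoring.** When the window after the last claim is shorter than
  the non-refill period, no gap is provable and the episode is censored
  at the end of observation — standard refill-gap censoring.

"Other treatment(s)" in the switch rule means other *biologics*: only
biologic claims are classified in the data model, and the code set is
configurable for broader definitions. Binary 12-month persistence (no
event before day 365) is only defined for units with a full year of
post-index observation; [classify_12m_persistence()] enforces that
precondition. The gap-sensitivity grid defaults to gaps of 30 and 60 and
90 days for every drug; published gap lists for sensitivity analyses are
study-specific, so the grid is a parameter, not a constant.

An independent day-by-day coverage oracle (walk every observed day,
track the last claim, stop when the claim-free run exceeds the gap) is
kept in the test suite and must agree exactly with the vectorised scan
on thousands of randomised claim sequences.

## Survival estimation and tests

[km_estimate()] implements the product-limit estimator
$S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ with Greenwood variance
$S(t)^2 \sum d_i / (n_i(n_i - d_i))$. The 95% band is symmetric,
$S \pm 1.96\,\mathrm{SE}$, clipped to $[0,1]$, because persistence
tables in this literature print symmetric "rate ± CI" values; a
complementary log-log band is available behind `conf_type = "loglog"`.
Ties between events and censorings on the same day are resolved events
first. When events exhaust a risk set ($n_i = d_i$) the Greenwood term
is undefined; the curve keeps its point estimate and flags the interval
**unavailable** from that time on — small groups therefore report a
rate with an explicit "CI not available" marker rather than a fabricated
band, covering both an estimation failure and a reporting choice.

[two_sample_test()] computes the weighted observed-minus-expected sum
over pooled event times under the hypergeometric model, with weights 1
(log-rank) or the at-risk count $n_i$ (Gehan-Breslow). "Wilcoxon rank
sum" in a censored-persistence context is implemented as Gehan-Breslow —
the standard claims-survival reading — rather than Peto-Peto (which
weights by the survival estimate). Pairwise comparisons against a
reference drug (UST by default) are reported unadjusted, matching how
such tables are conventionally printed. The implementation is checked
three ways: a brute-force hypergeometric-sum oracle on random small
samples, agreement of the log-rank statistic with
`survival::survdiff()`, and empirical type-I error of ~5% over 500
equal-hazard synthetic replicates.

## Cost windows

[window_costs()] sums amounts over `[index − 365, index − 1]` (pre) and
`[index, index + 364]` (post); the index day belongs to the post window
because the first administration is a consequence of initiation.
Components are inpatient (IP), outpatient (OP) — both *including*
biologic drug costs billed in that setting — and RX, drugs other than
biologics, identified by the `is_bt_drug_cost` flag (a code-list adapter
can populate the flag for real data). `total = IP + OP + RX` exactly at
record precision; amounts are stored in JPY and rounded to thousand-JPY
integers only at report time, which is why printed components can miss
printed totals by one unit. Group means are unweighted arithmetic means
across units. [contrast_by_persistence()] stratifies by drug ×
population (naive / total) × 12-month persistence group and reports the
non-persistent-minus-persistent difference per component; empty strata
keep their row with `n = 0` and NA means.

The package also bundles published per-stratum cost aggregates and
persistence counts from a Japanese psoriasis biologics claims study
([reference_cost_summaries()] and friends) as plain-CSV fixtures. They
are used to verify the arithmetic relationships among printed figures —
post = pre + increase, group deltas, component additivity to within the
rounding unit — not as outputs of the pipeline, whose raw source data
are proprietary and not redistributable.

## What the synthetic generator emulates

[generate_cohort()] simulates, per patient: an enrollment window
(default 1460 days), an index biologic drawn from a drug mix, a
discontinuation sampled **per 30-day cycle** with per-drug hazard $h$
(geometric, so 12-month persistence is $(1-h)^{12}$), optional switching
(destination biologic claims start one dosing interval after the last
index-drug claim), monthly gamma-distributed background costs by
category with separate pre/post levels, per-administration biologic drug
costs, and diagnosis records (psoriasis, excluded diseases,
comorbidities) at configured prevalences. Decoy patients without
biologics or without the inclusion diagnosis exercise the selection
cascade.

The defaults are fixed once to the study conditions the generator
emulates: drug mix 42/52/21/90 over 205; per-cycle hazards
0.0613/0.0515/0.0480/0.0190 (the values implied by 12-month persistence
of 46.8/53.0/55.4/79.4%); 86.3% naive; 18.1% female; mean age 47;
comorbidity prevalences from the published comorbidity table; exclusion
prevalence 0.546; monthly cost levels scaled from the published yearly
naive-cohort components (≈0.64M JPY pre, ≈2.8M JPY post per year). The
switch probability (0.30), decoy fractions (5% without the inclusion
code, 10% without biologics) and per-administration biologic costs
(0.12–0.45M JPY) are not published quantities; they were chosen once as
field-plausible values and are configurable.

**Ground-truth convention.** The true discontinuation day is the first
day of the first 30-day cycle *not entered* ($30C$, $C$ geometric), and
claims are emitted strictly before it. Consequences: the fraction of
true discontinuations by day 360 is exactly $1-(1-h)^{12}$; a detected
gap-discontinuation lands exactly on the true day for drugs dosed on
the 30-day grid; and for UST (90-day dosing, coarser than the 30-day
hazard grid) the detected day is the true day rounded *up* to the
dosing grid — at the 12-month read-out the two coincide, so the
Kaplan-Meier estimate recovers $(1-h)^{12}$ for every drug.

Experienced patients carry a 300-day prior sequence of a different
biologic ending in a switch into the index drug. These prior episodes
are themselves (naive) patient-units, as they would be in real data
where one patient contributes several drug cycles; they shorten the
per-drug naive persistence rates relative to the pure $(1-h)^{12}$ of
the index units.

What the generator does **not** model — and what passing tests
therefore do not establish about real data: dose titration and
weight-based dosing, price/fee-schedule realism, seasonality,
persistence-dependent cost trajectories (post-index cost levels are
deliberately independent of discontinuation, which is what makes the
null cost-contrast check meaningful), informative censoring, and
enrollment churn (all patients share one observation span).

## Numerical and validation choices

* Degenerate inputs: `n_patients = 0` produces empty, schema-correct
  tables end to end; empty strata are reported, not dropped; a unit
  without a claim on its own index date is a hard error.
* Zero hazards are honoured exactly (no discontinuation ever), and zero
  cost means suppress cost records, which keeps null configurations
  fast.
* Determinism: identical config + seed gives byte-identical CSV output;
  generation restores the caller's RNG state.
* Validation problem sizes, chosen to give stable Monte-Carlo margins
  while keeping the default suite in the low minutes: 2,000 units for
  closed-form survival recovery (3 Greenwood-SE margin), 500 replicates
  of 200 patients for test-size calibration (3 binomial-SE margin at
  α = 0.05), 1,000 random claim sequences per drug for the episode
  oracle, 100 random samples for the no-censoring identity.

## Limitations

Episode construction is deliberately minimal: no stockpiling or
proportion-of-days-covered adjustment, no re-initiation episodes after a
qualifying discontinuation (a patient-unit ends once), and switch
detection is restricted to the biologic classes in the data model.
k-group omnibus survival tests are out of scope; comparisons are
pairwise against a reference. The bundled reference aggregates allow
arithmetic-consistency checks only — the underlying patient-level data
are proprietary, so published headline rates can be echoed qualitatively
by the calibrated generator but not reproduced exactly.
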