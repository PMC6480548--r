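---
title: "Methods: step-down allocation, resource allocation matrices and unit expenditure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step-down allocation, resource allocation matrices and unit expenditure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rems)
library(dplyr)
```

## The model

The quantity of interest is **unit expenditure**: money spent per unit of
service output in a calendar quarter, per facility and service line. It is
estimated by composing three mappings.

### 1. HIV isolation and step-down

Ledger records are `(account code a, controlling unit u, quarter q, funding
source, amount x)`. Account codes are opaque `/`-separated segment strings;
no arithmetic meaning is attached to the segments.

**HIV-share weights** map account-code *prefixes* (on segment boundaries) to
a fraction in `[0, 1]`. The most specific matching prefix wins; two equally
specific matches are an error rather than an arbitrary choice. Records with
share 0 (including unmatched records under the default) are dropped, so
non-programme spending never enters the cascade.

**Flow-down rules** are keyed by `(account pattern, source unit)`. A rule
splits money at a non-facility unit into a retained share `r` — classified as
an **above-facility expense** — and child shares `c_1..c_k` with
`r + sum(c_i) = 1` (validated to 1e-9). A child share may be left `NA` as a
fallback, in which case the remainder is split across those children in
proportion to their facility counts. The cascade applies rules recursively
until every Kwacha either reaches a facility or is retained, so for each
quarter and funding source

```
sum(facility inflows) + sum(above-facility) = sum(HIV-share ledger amounts)
```

holds to the configured tolerance (1e-6 currency units). `step_down()`
verifies this after every run; missing rules are reported *exhaustively*
before any money moves (`flow_rule_gaps()`), not one at a time.

### 2. The resource allocation matrix (RAM)

A facility's RAM is a weight per `(service, resource category)` cell, derived
from an ingredients-based annual operational budget: itemized resource
quantities times standard unit costs. Recurrent lines cost
`annual_quantity x standard_unit_cost`; capital lines (equipment, vehicles)
are annualized as `purchase cost / useful life`, with configurable default
lives (5 and 8 years). Lines dedicated to one service keep it; `SHARED` lines
are apportioned across the facility's services in proportion to
`sessions_per_week x relative_annual_volume` from the service schedule.

Weights are the cell's share of the facility's total annual cost, so each
facility's RAM sums to 1 (validated to 1e-9) and is invariant to rescaling
the budget by any positive constant. `allocate_ram()` multiplies each inflow
by the weights; it is exactly linear and conserving by construction.

### 3. Unit expenditure and aggregation

For each `(facility, service, quarter)`, allocated amounts are summed over
resource categories and divided by the same quarter's output volume.
Division is *never* performed for degenerate records; instead they carry a
status:

* `zero_volume` — volume reported as 0;
* `missing_volume` — no volume row at all (absence is not zero);
* `zero_expenditure` — volume present but no allocated money (a likely RAM
  or ledger omission).

Roll-ups to district or province recompute the group unit cost as
`sum(amount) / sum(volume)` over `ok` records — the volume-weighted ratio of
sums — because that is the only aggregate consistent with conservation: a
province roll-up of district roll-ups then equals the direct province
roll-up. The unweighted mean of facility unit costs is exposed only as a
`mean_unit` diagnostic column.

Outlier flags use a robust z-score, `(x - median) / (1.4826 * MAD)`, within
`service x quarter x district` (or province) comparison groups. Groups
smaller than `min_group` or with zero spread produce notes, not flags.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| conservation tolerance | 1e-6 currency units | far below the 0.01 money quantum; catches logic errors, ignores float noise |
| share-sum / RAM-sum tolerance | 1e-9 | validation of user-supplied fractions |
| default HIV share for unmatched accounts | 0 | unmatched spending is excluded, never guessed |
| negative ledger amounts | `net` (alternative: `reject`) | reversals are netted within the duplicate key; a net-negative key is always an error |
| equipment / vehicle useful life | 5 / 8 years | conventional straight-line annualization defaults, overridable per line |
| outlier threshold / min group / scope | 3 / 5 / district | conventional robust-z cutoff; below 5 observations the MAD is too unstable to flag peers |

## The synthetic generator

`rems_scenario()` + `generate_bundle()` produce a full input set with known
ground truth, built *truth-first*: true unit costs and volumes are fixed
before any accounting artifacts are synthesized, and the generator's defaults
describe the intended operating conditions rather than any test's needs.

Design choices worth recording:

* **Steady-state volumes.** One base volume per facility x service is drawn
  (negative binomial, floored at 1) and repeated across quarters. This keeps
  a single annual RAM and a single rule table legitimately valid for every
  quarter, which is exactly the regime the method assumes.
* **Where noise lives.** Multiplicative noise `x (1 + e)`, `e ~ N(0,
  noise_sd)` with default `noise_sd = 0.1`, is drawn per facility x quarter
  and carried by a facility-controlled ledger account (a top-up), while the
  national cascading account is noiseless and grossed up bottom-up so that
  after each level's retention it delivers exactly the cascaded share of each
  facility's true expenditure. Consequently a facility's total inflow is
  `true expenditure x (1 + e)` *exactly*: with `noise_sd = 0` the pipeline
  recovers every true unit cost exactly, and with noise the relative error
  per facility-quarter equals `e`, making recovery unbiased by construction
  rather than by tuning. Draws that would make a top-up negative abort as an
  infeasible scenario instead of being silently truncated (truncation would
  bias recovery).
* **Dedicated assessment lines only.** The generated facility assessment uses
  dedicated (non-`SHARED`) lines whose annualized costs reproduce the
  intended service x category mix exactly; shared-line apportionment is
  exercised separately by unit tests, keeping generated ground truth
  analytic.
* **A decoy account.** Each bundle includes a non-HIV account matching no
  weight pattern, so tests confirm exclusion rather than assuming it.
* **Fixed draw order.** Volumes, then noise, then decoys — adding features
  never perturbs earlier draws for a given seed.

`corrupt_bundle()` injects auditable faults (dropped or zeroed volume rows,
deleted assessments, inflated ledgers) with a manifest, for testing the
data-quality and outlier pathways against known answers.

## Numerical choices

* Money is serialized at 2 decimals with round-half-even; in-memory
  computation is full double precision throughout.
* Where written rows must sum to written totals (allocation tables), rounding
  uses a largest-remainder ("conserving") scheme within each inflow group.
* The CSV writer is deterministic: rows sorted by all non-money columns,
  every cell quoted, LF line endings — identical inputs give byte-identical
  outputs.
* Problem sizes in the test suite (hierarchies up to 2 provinces x 2
  districts x 8 facilities, 50 accounts, 1,000 random budgets) are this
  package's own verification choices, large enough to exercise every code
  path and oracle at sub-minute runtimes.

## Verification strategy

The unit suites pin hand-enumerated examples and properties (conservation,
linearity, scale invariance, prefix-match specificity, round-trip identity).
The cascade is additionally checked against an *independent* brute-force
oracle that enumerates every account-to-facility path and multiplies
fractions along it — structurally different from the engine's recursive
amount descent. End-to-end, `test-acceptance.R` holds one block per
guarantee, including exact noiseless parameter recovery and the unbiasedness
of noisy recovery across 200+ facility-quarters.
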