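---
title: "Identifying incident diabetes in claims: the case definition, its statistics, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying incident diabetes in claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmphenotype)
```

## The problem

Medication-associated type 2 diabetes in children and youth is rare enough
that administrative claims databases are often the only practical way to
study it. Claims, however, record billing events, not diagnoses: a single
ICD-9-CM 250.x code frequently marks a diagnostic work-up rather than
disease, an oral hypoglycemic fill may treat polycystic ovarian syndrome
(PCOS) rather than diabetes, and prevalent cases masquerade as incident ones
when the historical record is thin. `dmphenotype` implements a rule-based
computable phenotype that addresses each of these failure modes, together
with the statistics used to validate such a definition against chart review
and a synthetic claims generator that makes the whole pipeline testable
without access to protected data.

## The case definition

The engine scans each cohort member's follow-up for *diabetes-related
medical care encounters* and rests its verdict on the **first** one:

1. **Primary inpatient diagnosis** (restricted list: 250, 250.0--250.3,
   250.9, decimal-free matching). The definition is met immediately; a
   hospitalization primarily for diabetes is considered sufficient evidence
   on its own. The index date is the admission date, pulled back one day if
   an emergency or outpatient visit with a diabetes diagnosis fell on that
   prior day (the same clinical episode).
2. **Secondary inpatient diagnosis** -- a stay with a diabetes code in a
   secondary or admission position, or a professional claim with a primary
   diabetes diagnosis dated within the *hospital stay period* (day before
   admission through day after discharge).
3. **Outpatient diagnosis** -- a primary diabetes code at an outpatient or
   emergency visit outside every hospital stay period.
4. **Prescription** -- a fill of insulin, an insulin adjunct, or an oral
   hypoglycemic.

Encounters of types 2--4 pass through two additional gates:

* **PCOS exclusion.** Any PCOS diagnosis within ±120 days of the initial
  index date excludes the member (closed interval on both ends). For the
  prescription pathway the window is also applied at extraction, so a
  metformin fill flanked by a PCOS code never becomes an encounter at all.
* **Confirmation.** A later claim of a corroborating kind must appear,
  strictly after the encounter's calendar day (bundled same-day claims
  cannot self-confirm) and no later than the end of follow-up. Diagnoses are
  confirmed by prescriptions; prescriptions by diagnoses, or by a refill
  together with a diabetes-management procedure when no absent/irregular-
  menses diagnosis (a PCOS-adjacent indication) appears in the window. The
  one deliberate exception: the management procedure may share a date with
  the refill, since both are typically billed at the same visit.

Two variants are exposed. The **primary** variant is the strict matrix
above. The **secondary** variant, designed to catch diabetes managed without
medication, auto-confirms secondary inpatient diagnoses and lets a
glycosylated-hemoglobin (HbA1c) procedure alone confirm an outpatient
diagnosis. Because the secondary rules are a strict relaxation of the
primary's, every primary-positive member is secondary-positive; the test
suite asserts this superset property across seeded populations.

Met cases then get a **final index date** -- reset to the earliest
diabetes-related procedure in the 29 days before the initial encounter,
mirroring the clinical scenario in which a diagnosis follows a test result --
and a **subtype**: type 1 when an insulin fill occurs within 120 days after
the final index date with at most one oral-hypoglycemic fill in that
interval (a single oral agent is tolerated while confirmatory type 1 testing
is pending), else type 2.

### Design choices where the rules were genuinely open

* **First encounter only.** If the first encounter is excluded or
  unconfirmed the member is classified not-met; the engine does not fall
  through to later encounters. This is the strictest reading of "first
  encounter during follow-up" and keeps the index date attached to the
  earliest evidence. A `fall_through` flag in `phenotype_config()` exposes
  the alternative reading.
* **Confirmation window.** "Subsequent" is read as *any time up to the end
  of follow-up*; `confirmation_window_days` can cap it for sensitivity
  analyses.
* **Code matching.** Codes are normalized to decimal-free strings and
  matched by prefix at the three-digit family level or deeper. When a set
  enumerates fourth-digit subcategories (as the restricted inpatient list
  does), the bare three-digit pattern is treated as exact, so 250.41 --
  a chronic-complication code signalling established disease -- does not
  slip in through the "250" entry.
* **Tie-breaking.** Encounters sharing the earliest date rank
  inpatient-primary > inpatient-secondary > outpatient > prescription:
  stronger evidence first. This affects only which confirmation path is
  tried, not eventual case status under fall-through.
* **Index reset.** When several qualifying procedures precede the encounter,
  the *earliest* in the 29-day window wins -- the test that initiated the
  diagnostic episode.
* **Insulin adjuncts.** Pramlintide-class fills count as diabetes-related
  encounters and confirmations but not toward the type-1 insulin
  requirement (`adjunct_counts_as_insulin` reverses this).

## The cohort builder

The engine evaluates members of a new-user cohort of psychotropic
initiators. Eligibility on a candidate date requires: age 6--24 (inclusive;
eligibility ends at the 25th birthday); a full year of prior enrollment,
tolerating coverage lapses of at most 7 days (gap = next start − previous
end − 1); at least one medical care claim in that year (the weakest reading
of "medical care utilization"); no diabetes diagnosis or diabetes-medication
fill at any earlier time; no active exclusion condition (life-threatening
illness, institutional residence, schizophrenia/psychosis, pregnancy, PCOS --
consumed as a pre-computed flag table, since deriving them from codes is a
site-specific exercise); and no hospital discharge in the preceding 30 days
(in-hospital medications are invisible to pharmacy claims).

A fill qualifies as an initiation when the preceding 365 days hold no
study-drug fill, or when all such fills cluster within the preceding 90 days
(a post-discharge start) and the cluster's earliest fill itself has a clean
washout. Follow-up runs from the day after the qualifying fill to the
earliest of study end, the day before the 25th birthday, disenrollment,
failure of an inclusion criterion, or 365 days after the last day of current
study-drug use. "Current use" is chained from fill dates plus days supplied;
the days-supplied column is optional with a default of 30 days per fill and
a zero-day grace period, all configurable, since claims extracts differ in
whether they carry supply fields.

## Validation statistics

With chart-review adjudication as the gold standard, the package computes:

* **PPV** per stratum (overall, engine type 1, engine type 2, and type 2
  with unspecified-type adjudications folded in), with **Wilson score
  intervals** (default z = 1.959964). The Wilson interval is used for its
  small-sample coverage; at the boundary counts 0 and n the implementation
  pins the bounds at the exact algebraic values 0 and 1.
* **Design-weighted sensitivity** `a/(a+c)`: found cases `a` are the flagged
  catchment count scaled by the adjudicated PPV; missed cases `c` are the
  non-flagged encounter count scaled by the true-case fraction of its
  adjudicated subsample. With full adjudication this reduces exactly to the
  realized true-positive fraction, which the tests exploit.
* **Specificity** `d/(b+d)` from the same cells plus a user-supplied
  non-case denominator. The denominator is an input, not derived: the
  catchment's non-case count depends on the source population and is not
  recoverable from the validation sample itself.
* **Contingency reports** crossing engine verdicts with adjudication
  categories, percentages printed half-up to one decimal in the style of
  clinical tables.

The package ships a person-level reconstruction of the reference validation
sample for this definition (64 flagged persons, 46 adjudicated; 187
non-flagged, 113 sampled, 30 adjudicated) as plain-CSV fixtures; the rows
are synthetic stubs that carry the published cell counts, nothing more.
`reference_validation_report()` recomputes every statistic from them. One
figure deliberately does not match its source: applying the sensitivity
estimator as stated to the published counts gives 64.7% (a = 64·41/46 =
57.04, c = 187·5/30 = 31.17), while the source reports 64.8%. The
supplementary arithmetic behind the published figure evidently differs in a
rounding or denominator detail; this implementation follows the stated
formula and documents the 0.1-point divergence rather than patching it. No
confidence interval is attached to the sensitivity estimate, as its
two-stage sampling design does not admit the binomial formula.

## The synthetic test bed

`generate_claims()` plants one scenario per person, chosen from a
configurable mix that mirrors the misclassification taxonomy observed when
definitions of this kind are validated:

| scenario | stream | engine outcome (noise off) |
|---|---|---|
| `canonical_t1d` | inpatient or outpatient diagnosis, then insulin fills | met, type 1 |
| `canonical_t2d_rx` | outpatient diagnosis, metformin fills + HbA1c | met, type 2 |
| `t2d_lifestyle_only` | diagnosis + HbA1c, no fills | secondary variant only |
| `prevalent_diabetes` | diabetes care before time zero | screened out (or leaks as a false positive when records are withheld) |
| `pcos_metformin` | metformin + PCOS diagnosis within ±120 d | never flagged |
| `rule_out_single_dx` | one diagnosis, nothing after | not met |
| `subthreshold_hyperglycemia_dx` | diagnosis + glucose test, no chain | not met |
| `miscoded_dx` | isolated secondary inpatient code | secondary-variant false positive |
| `healthy` | routine care only | not flagged |

Defaults: ages uniform over 6--24 at time zero, 77% female (echoing the
predominance of young women in psychotropic-initiator populations), study
window 1996--2007, visit-gap jitter geometric with mean 14 days,
confirmation-drop probability 0. Every person receives an enrollment history
and baseline utilization that satisfy eligibility by construction, and the
cohort builder independently reproduces the generator's planted follow-up
windows -- a cross-check in the test suite.

Randomness flows from a single seed through fixed-width per-person draw
rows, so one person's claims never depend on another's scenario and the same
configuration is byte-reproducible. The generator emulates the *structure*
of claims streams, not their content realism: no laboratory values, billing
amounts, provider networks, comorbidity burden, or code-entry noise beyond
the planted miscoding scenario. Passing tests therefore demonstrate that the
engine implements its rules exactly and that the estimators recover planted
parameters -- not that the definition would achieve any particular PPV on
real claims, which depends on coding practice in the source population.

## Numerical and scale choices

Dates are whole calendar days; all intervals are closed. Degenerate inputs
are handled explicitly: empty tables classify to an empty case list,
zero-denominator estimators raise errors rather than returning NaN, and
malformed claim rows are quarantined in a rejects report rather than
dropped. The test suite exercises the engine at populations of 500--1,000
persons and 100--200 replicates, sizes at which Monte-Carlo standard errors
of recovered parameters are a few tenths of a percentage point; the
acceptance statistics themselves are deterministic functions of the
packaged reference counts.

## Limitations

* ICD-9-CM only; translating the code sets to ICD-10-CM is a configuration
  exercise left to the user (all sets are YAML-overridable).
* Drug classification relies on an explicit `drug_class` column; mapping
  NDC codes to classes is site-specific and out of scope.
* The procedure code lists ("diabetes management", index-reset procedures)
  are explicit, configurable defaults: the clinical sources name the tests
  but not the codes.
* Exclusion conditions are consumed as flags, not derived from codes.
* The engine classifies; it does not adjudicate. Laboratory-threshold
  criteria belong to chart review and appear here only as the generator's
  ground-truth labels.
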