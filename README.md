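# udise

Scoring and classification crosswalks for drug-induced sedation endoscopy
(DISE) findings.

DISE is the endoscopic evaluation of the upper airway during sedated sleep,
used to locate the sites of obstruction in obstructive sleep apnea before
surgery. Many incompatible grading schemes are in clinical use, so the same
examination can be recorded — and treated — differently depending on which
scheme the examiner prefers. This package implements the **uDISE model**, a
unified recording scheme, together with a rule-based crosswalk that converts
findings between uDISE and four established classification systems:
Pringle/Croft grading, VOTE, NOHL and P-T-L-Tb-E. It is aimed at sleep
surgeons, clinical informaticians and methodologists who need to pool or
compare DISE assessments recorded in different systems.

## The model

A uDISE examination records one finding per anatomical site, over seven
sites in fixed order — nose (N), velum (V), tonsils (Ts), lateral pharyngeal
wall/oropharynx (O), tongue base (Tb), epiglottis (E) and larynx (L). Each
finding carries

* a **degree of obstruction** *d* ∈ {0, 1, 2}: none (airway narrowing
  < 50%), partial (50–75%), complete (> 75%);
* where the site admits one, a **configuration of collapse**:
  anteroposterior (AP), lateral (L) or concentric (C). The nose and larynx
  carry none, the tonsils collapse only laterally, and the epiglottis folds
  AP or laterally.

An exam serializes to a compact score string such as `N0V0Ts2LO0Tb2APE0L0`
(complete lateral tonsillar plus complete anteroposterior tongue-base
obstruction). The **severity index** is the sum of the seven degrees,

&nbsp;&nbsp;&nbsp;&nbsp;S = Σᵢ dᵢ ∈ [0, 14].

The crosswalk is a declarative rule base of direction-specific, set-valued
mapping rules (shipped as JSON under `inst/extdata/`). Conversions track

* **ambiguity** — a one-to-many rule yields a candidate *set* (e.g. a
  complete lateral oropharyngeal VOTE finding means "oropharynx **or**
  tonsils" in uDISE);
* **lossiness** — grid marker `X` where the target system does not consider
  a site anatomically, `-` where it considers the site but not that
  degree/configuration;
* **provenance** — the ids of the rules that fired.

For foreign-to-uDISE conversions, `severityRange()` reports the minimum and
maximum severity index over all uDISE profiles consistent with the
candidate sets.

## Worked example

```r
library(udise)

p <- parseUdise("N0V0Ts2LO0Tb2APE0L0")
p
#> UdiseProfile: N0V0Ts2LO0Tb2APE0L0 (severity index 4)
severityIndex(p)
#> [1] 4

rb <- defaultRuleBase()
fromUdise(p, "VOTE", rb)
#> ConversionResult VOTE [udise_to_foreign]
#>   N -> X [site_excluded]
#>   V -> Vk0AP, Vk0C, Vk0L [ambiguous]
#>   Ts -> Ok2L [exact]
#>   O -> Ok0L [exact]
#>   Tb -> Tk2AP [exact]
#>   E -> Ek0AP, Ek0L [ambiguous]
#>   L -> X [site_excluded]
#>   rules: U2.VOTE.V.AP.0, U2.VOTE.V.L.0, U2.VOTE.V.C.0, U2.VOTE.Ts.2, ...
```

The severity index of 4 is the sum of the two complete (degree-2) findings.
Converting to VOTE, the tonsillar and tongue-base findings map exactly
(`Ok2L`, `Tk2AP`); the nose and larynx are not representable in VOTE
(`X`); and degree-0 findings without a configuration widen to every
configuration variant, hence the ambiguous candidate sets at V and E.

In the other direction, a Pringle/Croft grade constrains several sites at
once and only up to a set:

```r
res <- toUdise(parseForeign("PRINGLE", "G2"), rb)
res
#> ConversionResult PRINGLE [foreign_to_udise]
#>   V: {2AP, 2L, 2C} [ambiguous]
#>   Ts: {2L} [exact]
#>   unconstrained: N, O, Tb, E, L
#>   severity range: 4..14
severityRange(res)
#> min max
#>   4  14
```

Grade 2 (single-level palatal obstruction) pins the velum and tonsils to
complete obstruction — at least severity 4 — while leaving the five other
sites unconstrained, so any severity up to 14 remains consistent.

Other entry points: `generateReferenceTable(rb)` regenerates the full
42-row reference crosswalk grid from the rule base;
`simulateCohort()`/`cohortSummary()` produce and summarise seeded synthetic
cohorts; `udiseCli()` (wrapped by `inst/cli/udise.R`) exposes `validate`,
`severity`, `convert`, `table`, `cohort` and `simulate` subcommands for
shell pipelines.

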