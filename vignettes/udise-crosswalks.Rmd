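---
title: "The uDISE model and its classification crosswalks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The uDISE model and its classification crosswalks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(udise)
```

## The model

Drug-induced sedation endoscopy (DISE) examines the upper airway during
sedated sleep to locate obstruction in obstructive sleep apnea. The uDISE
model records one finding per anatomical site over seven sites in a fixed
canonical order — nose (N), velum (V), tonsils (Ts), lateral pharyngeal
wall/oropharynx (O), tongue base (Tb), epiglottis (E), larynx (L) — each
finding being a degree of obstruction (0 none, `<`50% narrowing; 1 partial,
50–75%; 2 complete, `>`75%) and, where the site admits one, a collapse
configuration (anteroposterior AP, lateral L, concentric C). The admissible
configurations per site are fixed: the velum, oropharynx and tongue base
admit all three, the tonsils only lateral collapse, the epiglottis AP or
lateral folding, and the nose and larynx none (nasal obstruction is static;
laryngeal obstruction is recorded by degree alone). The severity index of an
examination is the sum of the seven degrees, ranging 0–14. The percent
bands attached to the degrees are descriptive labels only; the package
never computes a numeric narrowing, because the model defines none.

Three modelling choices were genuinely open and are resolved as follows.
The larynx shares the letter `L` with the lateral configuration; rather
than renaming the site internally, structure codes and configuration codes
are kept in disjoint vocabularies, and the only place the clash can bite —
the score-string parser — resolves it by canonical-order lookahead (below).
Whether the larynx admits configurations is nowhere stated; since the
reference grid lists bare `L0/L1/L2` cells, none are allowed. Mapping
equations alternate between `T` and `Tb` for the tongue base; the model
uses `Tb` throughout and reads `T` in equations as the same symbol.

## Score-string notation

An exam serializes to a compact string such as `N0V1APTs0O0Tb0E0L0`. The
parser also accepts the separated typography (underscores, spaces or
hyphens between tokens) and produces identical profiles. Sites are
*required* in canonical order; permuted input is an error, not silently
reordered — without a fixed order, a string such as `...E2LL0` would be
genuinely ambiguous between a lateral epiglottic fold and a larynx token.
With the order fixed, the parser greedily tries an optional configuration
after each degree and backtracks when the next expected site code cannot
then be matched, which resolves every such case deterministically. Errors
cite the character offset in the original input.

Configuration is mandatory at degree ≥ 1 (for sites that admit one),
optional at degree 0, and canonical serialization omits it at degree 0.
Degree-0 configurations are still *accepted* and retained internally
because the crosswalk distinguishes, say, `V0 AP` from `V0 C` cells (they
map to different foreign grades); a finding carrying no configuration at
degree 0 simply matches every configuration variant ("degree-0 widening").
The one-line token grammar for foreign systems (`G3`, `Vk2AP`, `Ot4`,
`HAP3`, `LP`, `Tb2`) is a package convenience — the published notation uses
subscripts — and the structured record form is authoritative in files.

## The crosswalk rule base

Every published mapping equation between uDISE and the four systems
(Pringle/Croft grading, VOTE, NOHL, P-T-L-Tb-E) is encoded as a
declarative, *direction-specific* rule in `inst/extdata/crosswalk-rules.json`
(147 rules; a JSON schema ships alongside). Each rule records a source
pattern, a target (a conjunction of uDISE site constraints, or a set of
candidate foreign tokens), a `lossy` flag, the mapping equation in field
notation, and, where the encoding is deliberately surprising, a note.
Ranges are expanded to explicit cell sets at load time, and loading fails
loudly on unknown codes, out-of-range grades or duplicate ids, so an
invalid rule base cannot be half-used.

Design decisions embedded in the rule base:

* **Conjunction across tokens, union within a token.** A DISE exam yields
  one finding per site, so constraints from different tokens touching the
  same site are intersected, and an empty intersection raises a
  contradiction error naming the site and rules. Alternative
  interpretations of a *single* token (e.g. a NOHL negative larynx, which
  may mean an AP or a lateral epiglottic reading) are unioned.
* **The VOTE oropharynx disjunction.** A lateral oropharyngeal VOTE finding
  means obstruction at the uDISE oropharynx *or* tonsils, not necessarily
  both. The rule is flagged as a disjunction and kept as a group in the
  result, so downstream consumers (and `severityRange()`) treat it as
  "at least one of these sites", not as two independent constraints.
* **Directional asymmetries are preserved verbatim.** The uDISE velum maps
  forward to the NOHL oropharynx at palatal level (`V1 AP → Ov AP 3`), but
  NOHL oropharynx AP findings have no published uDISE mapping, so the round
  trip through NOHL does not return to the velum; `roundTripContainment()`
  reports exactly this. Similarly, concentric hypopharyngeal NOHL findings
  map to the *lateral* tongue base as published (rule ids `NOHL.Hc.*`
  carry a note), while the reverse direction keeps tongue-base concentric
  cells on `Hv C` grades, mirroring the reference grid.
* **Pringle grades are whole-exam labels.** G1/G2 constrain velum and
  tonsils jointly; G3 and G4 both map to a complete oropharyngeal
  obstruction (their inspiration/expiration distinction is dropped, as the
  model itself drops respiratory phase), so the reverse direction returns
  the candidate set {G3, G4}, lossy. Sites a grade is silent about are left
  unconstrained rather than forced to zero, since a whole-exam grade
  carries no evidence about them.
* **Unmapped grades constrain nothing.** NOHL tonsil grades 1–2 have no
  published mapping; they are flagged `unmapped_grade` rather than given an
  invented degree.
* **Velum rows vs oropharynx rows.** Where the published grid's
  typesetting and the displayed equations disagree, the equations win: the
  velum's AP cells map to `Ov AP` grades, its lateral cells to the
  transversal `Ov t`, and consequently uDISE oropharynx *AP* cells have no
  NOHL counterpart and carry the `-` marker.

Coverage is derived from the udise-to-foreign rules alone: a cell is
`covered` when a rule matches it, `site_excluded` (grid marker `X`) when
the system has no rule touching the structure at all, and
`config_excluded` (marker `-`) otherwise. The 42-row reference grid is a
pure function of the rule base; the packaged fixture
(`inst/extdata/reference-grid.csv`) was hand-typed independently of the
rule generator precisely so that the cell-by-cell equality test is a dual
encoding, not a tautology. Row order follows the grid's published
enumeration: site in canonical order, then configuration (AP, L, C), then
degree. Within a cell, candidate tokens are rendered in sorted order for
byte-identical output across runs.

## Severity ranges

For a foreign-to-uDISE result, `severityRange()` reports the minimum and
maximum severity index over all profiles consistent with the candidates:
per-site minima/maxima of the hard candidate degrees, unconstrained sites
contributing 0–2, and disjunction groups enumerated over which alternative
site satisfies them (the non-satisfying sites stay free). The test suite
checks this analytic computation against an independent brute-force oracle
that enumerates the full canonical profile space — 46,305 assignments —
and takes the attained min/max, over every single-token conversion of all
four systems (74 tokens).

## Synthetic cohorts

`simulateCohort()` draws per-site degrees independently from configurable
probability triples (validated to sum to 1 within 1e-9) and, at degree ≥ 1,
a configuration from the site's probability vector (uniform over the
admissible set by default). The default degree triple (0.5, 0.3, 0.2) at
every site describes a mixed clinical population in which half the sites
are unobstructed, and gives a closed-form expected severity of
7 × (0.3 + 2 × 0.2) = 4.9; the suite checks a 10,000-profile cohort against
this expectation within three standard errors. Identical configurations
(seed included) reproduce identical cohorts.

The simulator emulates the *format* and marginal composition of a cohort,
not its epidemiology: real DISE findings are correlated across sites
(multilevel obstruction clusters), configuration frequencies differ by
phenotype, and no attempt is made to match real obstructive sleep apnea
prevalence. Passing tests therefore demonstrate structural correctness of
scoring, conversion and summarisation — not clinical validity of the model,
which requires prospective study.

## Numerical and degenerate-input choices

All computation is exact integer/set arithmetic; the only tolerance in the
package is the 1e-9 probability-sum check. Ties never arise: candidate
sets are sets, and rendering sorts tokens lexicographically. Degenerate
inputs are rejected early with named errors — empty cohorts, missing or
duplicated sites, mixed-system token lists, contradictory tokens, and rule
files that violate the vocabulary all fail loudly rather than degrade.

## Limitations

* Only four foreign systems are mapped; rules for the many other published
  DISE classification schemes would be additions to the rule file, not code.
* Respiratory phase (inspiration/expiration) and sedation depth are not
  modelled; the Pringle G3/G4 distinction is therefore unrecoverable.
* Larynx sub-sites (supraglottis vs glottis) are collapsed into one site.
* Set-valued conversion results are not probabilistic: the crosswalk
  defines candidate sets, not distributions, and the package deliberately
  assigns no weights.
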