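---
title: "Scoring and reliability methods for route audit data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and reliability methods for route audit data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factsaudit)
```

## The instrument and its scoring model

The FACTS tool audits the microscale built environment of promoted "safe
routes" to primary schools. A route is walked as a sequence of *segments*
(sections alongside a road or through a greenway) and *crossings* (points
where the route crosses a road at street level or by underpass, overpass
or bridge). The instrument has 45 items: 23 segment items (S1–S23) and 22
crossing items (C1–C13, C14a, C14b, C15–C21), each assigned to one of
four domains — Subjective Safety, Quality, Traffic Safety, Physical
Disorder — except S17, which is informational and outside the scoring
protocol.

Every scored item maps its responses onto $[0, 1]$ with larger values
more supportive of active school travel: binary yes/no items score 0/1,
and ordinal items use equally spaced maps. Two spacing conventions
exist for $m$ ordered categories and `ordinal_score_map()` offers both:
*without-zero*, $j/m$ for $j = 1,\dots,m$ (three categories give
$1/3, 2/3, 1$, displayed 0.33 / 0.66 / 1.00), and *with-zero*,
$j/(m-1)$ for $j = 0,\dots,m-1$. The canonical schema stores an explicit
per-item map, so the convention is item semantics fixed at authoring
time, not a runtime inference. Display uses two-decimal truncation
(`format_score()`): $2/3$ prints as 0.66, matching the band boundary
constants below; full precision is kept internally.

Scores aggregate through five tiers. A *domain score* is the unweighted
mean of the unit's applicable item scores in that domain; a *unit score*
is the mean of its domain scores; a *route score* is the mean of unit
scores (all units pooled — a `stratified` switch instead averages the
segment-mean and crossing-mean); a *school score* is the mean of its
route scores (a `pooled` switch averages all the school's units
directly). Pooling all units is the default because it is the simplest
reading of a hierarchy of plain means and keeps school overall exactly
equal to the mean of route overalls; neither reading is asserted to be
the only defensible one, which is why both are exposed. Band labels use
the printed constants: $\le 0.33$ poor, $(0.33, 0.66]$ moderate,
$> 0.66$ good. Note the deliberate mismatch with the exact fractions: a
bare "a little" response ($1/3 = 0.333\ldots$) falls just above the poor
cutoff.

### Applicability gates

C1 classifies the crossing; C2–C12 (the underpass/overpass/bridge
structure items) apply only when C1 reports a grade-separated crossing,
following C1's literal wording, so a bridge opens them too. C14b applies
only when C14a reports no signals/supervised crossing. Gated-off items
are excluded from the domain-mean denominator — the absence of an
underpass is not evidence of disorder — so a street-level crossing has
no Physical Disorder node at all (C3–C6 are all gated), which the score
table flags by the node's absence rather than imputing a value.

### The schema fixture

The shipped schema (`facts_schema()`) encodes item wordings, the
45/23/22 composition, the 8 + 15 and 12 + 10 split between unweighted-
and weighted-kappa items, S17's unscored status, the domain sizes
(segment 1/8/6/7, crossing 2/8/8/4) and the two gates. The per-item
response labels and score maps are a synthetic transcription: they are
authored to satisfy every published structural constraint and to be
field-plausible, but the instrument's own supplementary response sheets
are not bundled, so label wordings (e.g. the width cutpoints) should be
re-verified against the source instrument before any field deployment.

## Reliability statistics

### Percentage agreement, kappa, weighted kappa

Item-by-item agreement between two raters (inter) or two passes (intra)
is computed from the $k \times k$ contingency table of paired responses,
in schema label order. Percentage agreement is $100\,\mathrm{tr}(N)/n$,
flagged high when strictly above 70%. Cohen's kappa is
$\kappa = (p_o - p_e)/(1 - p_e)$; ordinal items use linear agreement
weights $w_{ij} = 1 - |i-j|/(k-1)$ (categories assumed equally spaced),
with $p_o = \sum w_{ij} p_{ij}$ and $p_e = \sum w_{ij} p_{i\cdot}
p_{\cdot j}$. For $k = 2$ the weighted statistic reduces exactly to the
unweighted one.

Published audit-instrument tables report kappa with a 95% CI and a
p-value but rarely state the variance formula; this package uses the
Fleiss–Cohen–Everitt large-sample variance (the common default of
statistical packages) for both statistics, a Wald interval truncated to
$[-1, 1]$, and a one-sided p-value for $\kappa = 0$ computed from the
null-hypothesis variance. Published tables of this kind sometimes print
untruncated Wald limits above 1; machine-readable output here keeps the
truncated interval and full-precision estimates.

When one side's ratings are constant the kappa denominator degenerates;
the result carries `status = "undefined_constant_one_side"` (or
`..._both_sides`) with an `NA` estimate, and percentage agreement is
still reported — the behaviour behind the "could not be computed due to
constant values" footnotes in published item tables. Degeneracy is a
typed status, never an exception, so 45-row reports always have 45 rows.

### Intraclass correlation

Score-level reliability uses the single-rater two-way random-effects
ICC from the ANOVA mean squares of the units × sides score matrix
($MS_R$ rows, $MS_C$ columns, $MS_E$ residual):

- consistency: $(MS_R - MS_E) / (MS_R + (c-1) MS_E)$, which ignores a
  systematic offset between sides;
- absolute agreement: $(MS_R - MS_E) / (MS_R + (c-1) MS_E +
  \tfrac{c}{n}(MS_C - MS_E))$, which penalises it.

"Consistency-agreement" phrasing in field-audit reports conflates the
two McGraw–Wong definitions; the package defaults to consistency and
exposes `definition = "agreement"`. Confidence intervals are the exact
F interval (consistency) and the Satterthwaite interval (absolute
agreement); the p-value is the one-sided F test of $MS_R/MS_E$. Rows
with missing scores are dropped listwise and counted. ICC rows at the
route and school tiers rest on few entities (12 routes, 6–8 schools at
the default design), so their intervals are expected to be wide; they
are reported regardless.

Both kappa-family statistics and ICCs are interpreted on the
Landis–Koch scale (< 0.00 poor, 0.00–0.20 slight, 0.21–0.40 fair,
0.41–0.60 moderate, 0.61–0.80 substantial, 0.81–1.00 almost perfect).
The printed band edges are two-decimal and exhaustive only after
rounding, so values are rounded to two decimals before banding: 0.205
bands as slight.

### Pairing rules

`build_pairs()` aligns the two sides unit by unit. A pair for an item is
retained only when the item was applicable and answered on both sides. A
unit where the sides disagree about a gate (one auditor logs an
underpass, the other street level) keeps its pair for the gate item
itself and is excluded, with a count, for all items downstream of that
gate; how the original analysis handled such units beyond footnoting the
segment-type filter is not published, so this rule is a documented
package choice. A missing applicable response invalidates a record for
*scoring* (complete-case, loud error) but merely drops that unit from
the affected item's pairs for *reliability* — reliability estimation
stays robust to sparse field data while score tables never silently
average over holes.

## The synthetic study generator

`generate_study()` emulates paired audits without field data. Each
(unit, item) draws a latent true category from per-item marginals;
each side (rater or pass) reports the truth with probability
$\theta$ (*fidelity*) and otherwise errs by kernel: `uniform_other`
spreads error mass evenly over the other categories (nominal items),
`adjacent` puts it on the one or two neighbouring categories, split
equally (ordinal items; near-miss misgradings are what makes the
weighted kappa's distance weighting visible). Gate items are emitted
first, so each side's reported item set is coherent with its own gate
responses, and gate divergence arises naturally from gate-item errors.
Intra designs reuse the same latent truths across passes — the
streetscape is assumed static over a revisit gap of a few days — with
an optional `drift` probability that redraws truths for temporally
variable items (litter, temporary obstructions) between passes.

The exact joint response distribution under this model is
$J = \sum_t \pi_t\, e_t \otimes e_t$, which `expected_kappa()` and
`expected_weighted_kappa()` evaluate analytically; they are the
oracles against which simulated estimates are tested for recovery.
Expected kappa is nondecreasing in $\theta$ only where errors are a
minority ($\theta \ge 0.5$ in the tested configurations): below chance
level both raters share the same structured error distribution and
re-correlate (in the binary case $\theta \to 0$ drives $\kappa \to 1$),
so the monotonicity property is only asserted on the realistic regime.

Defaults are chosen once as a realistic field study and not tuned: 6
schools × 2 routes × (10 segments + 6 crossings) for the inter design —
120 segment and 72 crossing pairs, mirroring the scale of a published
six-school audit campaign — and 8 schools for intra designs. Latent
marginals tilt supportive (category $j$ of $k$ gets mass
$\propto 2^{j-1}$; binary items 1/3 vs 2/3), emulating promoted routes
that are mostly in good condition; the two classification items use
study-like mixes (crossings 50% street-level / 35% underpass / 10%
overpass / 5% bridge; segments 35% street / 65% greenway). Default
fidelity is 0.85, which lands most items in the substantial band —
typical of trained auditors.

What the generator does *not* emulate, and what passing tests therefore
do not establish about real data: spatial correlation along a route
(each unit is drawn independently), correlated errors across items of a
unit, auditor learning or fatigue, genuinely skewed rare-feature
marginals that produce the constant-value footnotes of real campaigns
(these are exercised by explicit degenerate configurations instead),
and GPS/photo capture. Reliability of the *statistics* is what the
simulator certifies; reliability of the *instrument* can only come from
field data.

Reproducibility: one `set.seed(seed)` plus a fixed traversal order
(schools → routes → units → items → sides) makes generation
byte-identical for a given seed. A counter-based per-(unit, item, side)
stream would additionally make *subsets* reproducible in isolation, but
R has no cheap counter-based generator; the simpler contract is tested
(identical seeds give identical files) and is sufficient here.

## Numerical choices and degenerate inputs

- Kappa/weighted-kappa estimates are validated against brute-force
  evaluations of the defining sums to $10^{-12}$ over random tables;
  ICCs against explicit `aov()` mean squares to $10^{-10}$. SE and CI
  formulas were cross-checked against independent implementations of
  the same estimators during development, with reference values frozen
  into the test suite.
- Zero between-unit variance makes the ICC undefined (status, not
  error); an empty contingency table, zero pairs, or zero scorable
  children are errors, since they indicate malformed input rather than
  degenerate-but-valid data.
- Simulation scale in tests: recovery checks use 500 replicate items of
  200 pairs at $\theta \in \{0.7, 0.85, 0.95\}$, compared to the
  analytic expectation within three Monte-Carlo standard errors;
  convergence is additionally checked at 5 000 pairs. These sizes give
  Monte-Carlo noise well below the effects being tested while keeping
  the suite fast.

## Known limitations

- The canonical score maps are a structural reconstruction, not the
  instrument's official response sheets (see above).
- Only two raters/passes per design are supported — by design: the
  statistics implemented are the two-rater ones (no Fleiss' kappa,
  Krippendorff's alpha or multi-rater ICC beyond what the two-column
  ANOVA gives).
- Wald intervals for kappa are poor near the boundaries; for small
  campaigns with near-perfect agreement the interval is mostly a width
  indicator, as in the published tables this mirrors.
- Route and school ICCs from a handful of entities are unstable by
  nature; treat their point estimates with the printed intervals, not
  instead of them.
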