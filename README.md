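# factsaudit

Scoring and reliability assessment for the FACTS route audit instrument
(Field Audit for Children's Active Transport to School).

Safe Routes to School programs promote designated walking routes to
primary schools; the FACTS tool audits the microscale built environment
of those routes — path quality, crossing treatments, traffic calming,
disorder — as a sequence of *segments* and *crossings* nested in routes
nested in schools. This package is for program evaluators and
measurement researchers who need to (a) score such audits and (b)
quantify how reliable the instrument is between auditors and between
repeat visits.

It provides:

- a machine-readable schema of the 45-item instrument (23 segment items
  S1–S23, 22 crossing items C1–C21 with C14a/C14b), including response
  scales, supportive-direction score maps, domain assignments and
  applicability gates (C1 gates the underpass items C2–C12; C14b applies
  only without signals);
- the hierarchical 0–1 scoring protocol: item → domain (mean of
  applicable items) → segment/crossing (mean of domains) → route →
  school, with poor (≤ 0.33) / moderate (≤ 0.66) / good (> 0.66) bands;
- the full two-rater reliability suite: percentage agreement
  (100 · tr N / n, "high" above 70%), Cohen's κ = (p_o − p_e)/(1 − p_e)
  for nominal items, linearly weighted κ_w with weights
  w_ij = 1 − |i−j|/(k−1) for ordinal items (Fleiss–Cohen–Everitt SEs,
  Wald 95% CIs, one-sided p against the zero null), and the
  single-rater two-way random-effects ICC — consistency
  (MS_R − MS_E)/(MS_R + (c−1)MS_E) and absolute agreement — with
  F-based confidence intervals, all interpreted on the Landis–Koch
  scale;
- a latent-category paired-audit simulator with analytic
  expected-agreement oracles, so every statistic is testable without
  field data;
- publication-style item and score reliability reports, and a `facts`
  command-line tool (`exec/facts`) with `score`, `reliability`,
  `simulate` and `report` subcommands.

## Worked example

Simulate a six-school inter-rater study (two auditors, fidelity 0.85,
120 segment and 72 crossing pairs), then compute the item and score
reliability reports:

```r
library(factsaudit)

schema <- facts_schema()
schema
#> <instrument_schema> version 1.0: 45 items (23 segment, 22 crossing)

cfg <- sim_config(n_schools = 6, model = rater_model(0.85), seed = 42)
records <- generate_study(cfg, schema)

rep <- item_report(records, schema, design = "inter")
head(rep[, c("item_id", "statistic", "n_pairs", "percent_agreement",
             "estimate", "interpretation", "status")], 5)
#>   item_id      statistic n_pairs percent_agreement estimate interpretation status
#> 1      S1 weighted_kappa     120              61.7    0.627    substantial     ok
#> 2      S2 weighted_kappa     120              79.2    0.686    substantial     ok
#> 3      S3 weighted_kappa     120              73.3    0.610    substantial     ok
#> 4      S4          kappa     120              71.7    0.384           fair     ok
#> 5      S5          kappa     120              77.5    0.543       moderate     ok
```

One row per instrument item: ordinal items get linearly weighted kappa,
nominal items unweighted kappa; items whose kappa is undefined because
an auditor's ratings were constant keep their row with a typed `status`
and their percentage agreement. The score-level report has the shape of
a published domain/score reliability table:

```r
sc <- score_report(records, schema, design = "inter")
sc[9:12, c("row", "n", "mean", "icc", "ci_low", "ci_high", "interpretation")]
#>                row   n  mean   icc  ci_low ci_high interpretation
#> 9   segment_scores 120 0.722 0.464  0.3116   0.594       moderate
#> 10 crossing_scores  72 0.661 0.305  0.0798   0.500           fair
#> 11    route_scores  12 0.699 0.113 -0.4690   0.627         slight
#> 12   school_scores   6 0.699 0.107 -0.7044   0.797         slight
```

(Route/school ICCs are low *in simulation* because simulated routes are
exchangeable — there is almost no true between-route variance to
detect; field data, where routes genuinely differ, is what those rows
are for.)

The statistics are also directly usable:

```r
cohens_kappa(matrix(c(20, 10, 5, 15), 2))
#> <kappa> 0.400 (95% CI 0.151-0.649), p 0.002, n = 50 [fair]
icc(cbind(c(.9, .4, .7, .6, .8, .5), c(.85, .45, .7, .65, .75, .55)))
#> <icc> 0.956 (95% CI 0.725-0.994), p < 0.001, n = 6 [almost perfect]
classify_band(c(0.30, 0.50, 0.80))
#> [1] "poor"     "moderate" "good"
```

From a shell, the same pipeline:

```sh
exec/facts simulate --design inter --schools 6 --seed 42 --out sim/
exec/facts score --records sim/records.csv --out scores/
exec/facts reliability --records sim/records.csv --design inter --out rel/
```

See `vignettes/facts-reliability-methods.Rmd` for the scoring model,
the statistical formulas and every documented design choice.

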