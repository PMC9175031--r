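# rivalryr

Analysis of perceptual grouping during binocular rivalry from dual-button
response logs, with a synthetic-observer simulator for end-to-end testing.

## The problem

When each eye is shown a different grating at the same retinal location, the
percept alternates between the two images (binocular rivalry). Spatially
separated rivalry targets with a shared feature tend to *group*: they
dominate together, and the strongest grouping cue is the eye of origin.
Experiments probing this present two adjacent grating-disc pairs
dichoptically under four viewing conditions — matching orientations in the
same eye or different eyes, in the same hemifield or different hemifields
(MO SE/SH, MO SE/DH, MO DE/SH, MO DE/DH, each counterbalanced twice) plus a
central single-target control — while the observer holds buttons: left =
both discs horizontal, right = both vertical, both = one of each (ungrouped),
none = mixed/piecemeal. Such designs are used to compare clinical groups
(e.g. mild glaucoma, where rivalry dynamics slow down) against controls.

`rivalryr` turns the raw two-channel press logs of one 60-s trial into an
exhaustive labelled partition of trial time and the standard outcome
measures:

* **dominance times** — cumulative exclusive dominance of the grouped
  percept (`GROUPED_H` + `GROUPED_V`), the ungrouped percept (sustained
  both-press), and the mixed percept (no press);
* **rivalry rate** — perceptual switches per minute, a switch being each
  change in the sequence of exclusive-dominance labels;
* **mean dominance epoch** — exclusive grouped time divided by the switch
  count, with brief both-pressed overlaps at dominance changes (the motor
  signature of the travelling dominance wave) *excluded* from the epoch
  accounting: a both-press shorter than `tau_overlap` (default 0.4 s)
  flanked by the two different exclusive percepts is labelled `TRANSITION`;
* **epoch difference** — per participant,
  `d = epoch(MO SE/DH) − epoch(MO SE/SH)`, the between- minus
  within-hemifield contrast.

The statistical battery mirrors the field's standard reporting: mixed
factorial ANOVA (Type III, sum-to-zero contrasts for the unbalanced
between-subject factor), Greenhouse–Geisser correction with
ε = tr(D)²/((k−1)·tr(D²)) on the double-centred within-cell covariance D,
partial η² = F·df₁/(F·df₁ + df₂), Cohen's d = t·√(1/n₁ + 1/n₂),
Bonferroni/LSD pairwise comparisons, pooled-variance and paired t-tests,
exact/min-U Mann–Whitney tests, and Pearson correlations.

Because raw data of this kind are rarely deposited, the package ships a
**synthetic observer**: a coupled two-zone rivalry renewal process (Gamma
dominance durations; at each zone renewal the zone adopts the other zone's
dominant eye with probability `eye_coupling`, else the opposite, so
coupling 1 yields full eye-of-origin grouping and coupling 0.5 independent
zones) plus a motor layer (press latency, both-press overlap at dominance
changes, report lapses). `simulate_cohort()` generates a seeded 17 + 14
participant cohort, 9 trials each, whose analyzed output approximates the
published group-level pattern.

## Worked example

```r
library(rivalryr)

cohort <- simulate_cohort(cohort_config(seed = 42))
report <- run_pipeline(cohort$logs, cohort$metadata, run_config(seed = 42))
report$rate_summary
#>      group condition_id rate_mean rate_sd  n
#> 1 glaucoma     MO_SE_SH      1.62   0.781 17
#> 2  control     MO_SE_SH      1.86   0.795 14
#> 3 glaucoma     MO_SE_DH      1.53   1.179 17
#> 4  control     MO_SE_DH      1.54   0.887 14
#> 5 glaucoma      CENTRAL     14.06   3.112 17
#> 6  control      CENTRAL     16.86   2.905 14

report$stats$ttest_central_rate
#>       t    df      p     d mean_diff
#> 1  2.57    29 0.0157 0.926      2.80
```

The central-condition rivalry rate of the simulated glaucoma group
(14.1 switches/min) is lower than the control group's (16.9), and the
independent-samples t-test on that contrast gives t(29) = 2.57, p = 0.016,
Cohen's d = 0.93 — the glaucoma-vs-control rate deficit the simulator is
calibrated to emulate. Grouped dominance time is high in the same-eye
conditions (≈ 43–45 s of 60 s) and low in the different-eye conditions
(≈ 3–4 s), the eye-of-origin grouping signature. `tidy()` on any fitted
ANOVA returns the effect table (SS, df, F, p, GG-corrected df/p, partial
η², Mauchly p); `autoplot()` on timelines and reports draws the timing
diagram, dominance summary, and epoch-difference boxplots.

Low-level entry points: `validate_log()`, `resolve_timeline()`,
`trial_metrics()`, `analyze_logs()`, `aggregate_by_condition()`,
`mixed_anova()`, `mann_whitney_u()`, and friends. A thin command-line
wrapper lives at `inst/cli/rivalryr` (`simulate`, `analyze`, `report`,
`all`).

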