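---
title: "Analysing perceptual grouping during binocular rivalry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing perceptual grouping during binocular rivalry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivalryr)
library(dplyr)
```

## From button presses to percepts

A perceptual-grouping rivalry trial yields two channels of press intervals:
the left button means "both discs horizontal", the right "both vertical",
both together "one of each" (the ungrouped percept), and no press a mixed
or piecemeal percept. `resolve_timeline()` partitions the trial
`[0, duration]` exhaustively into `GROUPED_H`, `GROUPED_V`, `UNGROUPED`,
`UNREPORTED` and `TRANSITION` intervals. The only non-obvious rule is the
transition one: when dominance changes, observers typically press the new
button slightly before releasing the old one, so a brief both-press appears
at every switch. Counting that span as ungrouped-percept time would
contaminate both the ungrouped account and the epoch lengths, so a
both-press is read as a transition wave exactly when

* it is shorter than `tau_overlap`, **and**
* it is immediately flanked by the two *different* exclusive percepts.

The flanking requirement is what protects deliberate sustained both-presses
(the ungrouped percept in different-eye conditions) from being eaten: a
genuine ungrouped report borders mixed or same-percept intervals, or simply
lasts longer than any motor overlap. `tau_overlap` defaults to 0.4 s; the
overlap is a sub-second motor phenomenon, and the default sits comfortably
above typical overlap durations (we simulate 0.15 s) while staying below
plausible deliberate reports. It is configurable, and `tau_overlap = 0`
disables the rule entirely.

Transition time is booked in its own fourth bucket rather than added to the
ungrouped percept, because it belongs to neither percept; the raw
"both buttons pressed" total remains recoverable as
`t_ungrouped + t_transition` and is exported per trial (`t_both_total`) for
audit.

Switches are changes in the exclusive-label sequence after deleting all
non-exclusive intervals; a percept resuming after a mixed interlude is not
a switch. The length of an intervening unreported span is ignored by
default (`tau_gap = Inf`); a finite `tau_gap` is available as a strictness
knob for analysts who do not want a switch bridged across a long mixed
spell. The mean dominance epoch is grouped time divided by the *switch
count*, not by the per-minute rate — identical for 60-s trials, but well
defined for any duration. A trial without switches has an undefined epoch
(`NA`, never a sentinel). When the two counterbalanced trials of a
condition are averaged, the epoch is averaged over the trials where it is
defined; it is missing only if neither trial had a switch. A run of mixed
percept between two same-orientation dominance periods splits one epoch
into two — with epochs defined through the switch count this choice only
affects which trials have defined epochs, not their sum.

Numerical conventions: seconds throughout, closed–open intervals
`[t_on, t_off)`, trial clock starting at 0; partitions are exact (the
components of `dominance_times()` sum to the duration to well below 1 ns);
repairs applied while validating a log (clamping, merging overlapping
same-button intervals) are surfaced as warnings, never silent.

## The synthetic observer

No public dataset of such logs exists, so the package ships a generative
observer used for end-to-end testing and calibration. Its latent layer is a
coupled two-zone semi-Markov renewal process:

* each zone (one disc position) holds a dominant eye; dominance durations
  are Gamma(shape 3, mean `epoch_mean`) — the conventional
  dominance-duration family for rivalry, with shape 3 giving the familiar
  right-skewed, non-exponential durations;
* at each zone renewal the zone adopts the *other* zone's current dominant
  eye with probability `eye_coupling`, else the opposite eye. Coupling 1
  therefore forces eye-of-origin grouping (all trial time grouped in
  same-eye conditions, all ungrouped in different-eye conditions) and
  coupling 0.5 makes the zones exactly independent, giving chance grouping;
* a renewal passes through an exponential mixed interlude with probability
  `mixed_prob`;
* the central control condition degenerates to a single zone whose
  renewals simply flip the percept — an ordinary renewal process with cycle
  mean `epoch_mean + mixed_prob * mixed_mean`, which is what
  `expected_rivalry_rate()` evaluates (including the second-order
  finite-trial correction).

The motor layer shifts each report boundary by a truncated-normal press
latency, inserts a truncated-normal both-press overlap at each dominance
change (new button down before old button up — reproducing exactly the
transition signature the analyzer removes), and drops whole exclusive
reports with probability `lapse_prob`. With all motor parameters at zero
the rendered log reproduces the latent timeline bit for bit, which is the
basis of the round-trip tests.

### Calibration

Defaults emulate a 17-patient (mild glaucoma) vs 14-control study of this
design: 9 trials of 60 s per participant (4 grouping conditions × 2
counterbalanced variants + 1 central control), ages 61 ± 12 vs 53 ± 11.
The group difference is injected through `epoch_mean` alone (glaucoma
3.7 s, control 2.9 s, between-observer SD 0.6 s), the simplest
configuration consistent with similar dominance *times* but lower rivalry
*rates* in the clinical group. Those means were set from the central-cycle
formula against target central rates of ≈ 13 and ≈ 17 switches/min and then
adjusted once for the switch loss introduced by the motor layer (a lapse
deletes two switches when the same percept resumes). `eye_coupling = 0.92`
puts grouped time in same-eye conditions near 0.78 of the trial
(≈ 45 s/60 s); `mixed_prob = 0.2`, `mixed_mean = 1.5` s put mixed time near
5–12 s. Dispersion parameters are conventional choices, not inferred from
data, and are exposed as tunables.

### A known limitation

A single coupling parameter cannot simultaneously reproduce strong grouping
*and* fast joint alternation in the two-zone conditions: with coupling near
1 the grouped percept's orientation changes only through brief
disagreement excursions, so simulated same-eye-condition rates sit near
1–2 switches/min instead of the teens. The calibration therefore privileges
the dominance-time pattern and the central-condition rates; in the same-eye
conditions the *ordering* (control faster than glaucoma) is preserved, and
that ordinal pattern — not the rate magnitudes — is what the emulation
tests assert. Simulated epoch differences inherit the same caveat: they are
on a seconds scale rather than the tens-of-milliseconds scale real
observers produce. What passing tests show, then, is that the analysis
pipeline is correct and that the generator reproduces the qualitative
group-level structure; they are not a validation of the generator against
human data. The generator also idealises away eye movements, blinks,
reaction-time asymmetries between percepts, and any drift of parameters
over a session.

## The statistical battery

`mixed_anova()` fits the split-plot designs used in this literature: one
between-subject factor (group, unbalanced), one or two within-subject
factors, optionally an age covariate. Sums of squares are Type III with
sum-to-zero contrasts; within effects are tested against their
subject-interaction error terms (the fit is delegated to the
repeated-measures machinery of the `car` package; the test suite checks
every F against an independent projection-matrix computation).
Greenhouse–Geisser ε is reported for every within effect — exactly 1 at two
levels, and via ε = tr(D)²/((k−1)·tr(D²)) on the double-centred pooled
covariance otherwise — together with ε-scaled dfs, the corrected p, and
Mauchly's sphericity p as auxiliary output. Corrected and uncorrected
values are always reported side by side; nothing is silently switched on a
sphericity test. Partial η² = F·df₁/(F·df₁ + df₂) holds identically for
raw and corrected dfs and is attached to every row.

With a covariate, the covariate is centred and only the between-subject
test is adjusted (its error df drops by one, e.g. from 29 to 28 at
n = 31); within effects are reported from the unadjusted model. This keeps
the within-subject results invariant to a purely between-subject nuisance
variable while answering the question the covariate is there for — whether
the group difference survives age adjustment.

`mann_whitney_u()` reports the min-U convention with ties mid-ranked; the
p-value is exact (null Wilcoxon distribution) when the combined sample is
at most 20 without ties, else a tie-corrected normal approximation.
Degenerate inputs (zero variance, empty groups, constant paired
differences) are errors, not numbers.

## Pipeline and reproducibility

`run_pipeline()` chains validate → resolve → per-trial metrics →
per-condition aggregation → summaries → statistics, and embeds a
provenance block (configuration hash, seed, package version) in the report
and in every file `write_report()` writes. Reports carry no timestamps, so
identical inputs and configuration give byte-identical output. Summary
tables are audited at report time against recomputation from the emitted
per-participant table. Participants with undefined epochs in either
same-eye condition are excluded from the epoch-difference test and counted
explicitly.

Seeds are derived hierarchically (master → participant → trial), so any
subset of a cohort can be regenerated. All problem sizes used by the test
suite were chosen to make sampling error small relative to the asserted
tolerances while keeping the default run quick: 1000 fuzzed logs for the
grid-scan equivalence, 200–300 trials per point for rate/epoch recovery
(sampling error ≈ 1.5 % against 5 % tolerances), 1000 replicates for the
type-I-error check of the group test, and 100 replicate cohorts for the
qualitative-pattern check.

```{r example}
cohort <- simulate_cohort(cohort_config(n_glaucoma = 4, n_control = 4, seed = 7))
report <- run_pipeline(cohort$logs, cohort$metadata, run_config(seed = 7))
report$rate_summary
tidy(report$stats$anova_grouped)
```
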