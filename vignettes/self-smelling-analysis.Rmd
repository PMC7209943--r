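---
title: "Methods: ordinal self-report inference and sniff detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ordinal self-report inference and sniff detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sniffself)
```

`sniffself` implements the two computational halves of a study of human
olfactory self-sampling: (i) the analysis of an online questionnaire in
which respondents rated, on the ordinal scale *never < rarely <
occasionally < often*, how frequently they sniff themselves and their
close others; and (ii) a rule-based detector of sniff events in nasal
airflow recordings, used to ask whether hand-to-face contact is
accompanied by sniffing rather than being mere displacement behaviour.
This vignette is the package's account of its models, parameter choices
and limitations.

## The ordinal testing framework

### The statistic

Sex and age contrasts of ordinal ratings use the two-sample
Cramér–von Mises (CvM) criterion, which compares the entire empirical
cumulative distribution functions (ECDFs) of two samples and is
therefore appropriate for ordered categories, where means are not
meaningful and chi-squared tests ignore the ordering.  With samples of
sizes $n_a$ and $n_b$, pooled size $N$, the package computes the
classical (Anderson) two-sample form

$$T = \frac{n_a n_b}{N^2}\sum_{x \in \text{pooled}}\bigl(F_a(x) - F_b(x)\bigr)^2 ,$$

where the sum runs over all $N$ pooled observations; for 4-category
data this collapses to a sum over the categories weighted by their
pooled counts.  $T$ is symmetric, invariant under strictly monotone
recoding of the categories, and zero exactly when the two ECDFs
coincide at every category.  Published CvM values do not always state
their normalization, so the normalization is pluggable
(`variant = "anderson"` or `"pooled_sum"`); the Anderson form is the
default because it is the common convention and produces statistics on
the order of 0.1–2 at questionnaire sample sizes, the scale on which
such results are usually reported.

### The permutation null

The null distribution of $T$ is obtained by randomly re-assigning the
group labels to the pooled ratings and recomputing the statistic for
each assignment.  For categorical data the permuted statistic depends
only on the 2×K contingency table of labels by categories, and under
label permutation that table follows the multivariate hypergeometric
distribution with the pooled category counts as fixed margins.
`permutation_test()` therefore samples tables directly with sequential
`rhyper()` calls, which vectorizes: $10^6$ permutations of
cohort-sized groups run in a few seconds on one core.  The tests
verify that this route agrees with explicit label shuffling and, for
pooled $n \le 8$, with exhaustive enumeration of all label
assignments.

The p-value uses the add-one estimator
$p = (1 + \#\{T^{perm} \ge T^{obs}\})/(n_{perm}+1)$: the observed
assignment is counted among the permutations, so $p$ can never be an
impossible Monte-Carlo zero, and ties between permuted and observed
statistics count as extreme, which is conservative.  A degenerate
input in which every pooled rating is identical yields $T = 0$,
$p = 1$ with a warning.  The default is `n_perm = 10000`; set
`n_perm = 1e6` to match high-precision published p-values.  Simulation
at $n = 100$ per group (1000 zero-effect replicates) puts the
empirical type-I error at $\alpha = 0.05$ inside $[0.03, 0.07]$, and a
proportional-odds shift of 1.5 at $n = 200$ per group is detected in
essentially every replicate.

### Multiple testing

The questionnaire's ten self/other-sniffing questions form one declared
family: `sex_comparison_family()` corrects their permutation p-values
with the Benjamini–Hochberg step-up rule (`bh_fdr()`, delegating to
`stats::p.adjust`).  For the age analyses the package declares the six
pairwise quartile contrasts of each scope (overall, men, women) as one
family each, and the four per-quartile sex contrasts as another.
Published corrected values from this design's original use imply
family-size multipliers between ×6 and ×10 and do not pin the exact
family composition, so the families are configurable; no test leaks
across families.

### The direction test

`binomial_direction_test(k, n)` is the exact upper tail
$P(X \ge k)$ for $X \sim \mathrm{Binomial}(n, 1/2)$.  For the often
quoted count of 12 of 17 subjects increasing, the exact tail is
$9402/131072 = 0.0717$; a figure of 0.047 sometimes attached to that
count cannot be reproduced by the exact tail (nor by an obvious
two-sided or mid-p variant) and is left unreconciled — the package
reports the exact value.

## Questionnaire cleaning

Answers are coded 1–4 with sentinel codes for blank cells, explicit
"n.a." answers, multiple selections, and deleted cells.
`clean_survey()` applies, in order:

1. **answer-level deletion** — every multi-answer cell becomes the
   deleted sentinel (discarding that entry only, not the respondent);
2. **respondent screens** — respondents younger than `min_age`
   (default 18) and respondents with at least `max_uninformative`
   (default 5) uninformative answers (blank, "n.a." or deleted) are
   removed.

Deletion precedes the screens so the deletion tally and the exclusion
tally are independent counts; the order of the two respondent screens
only matters for respondents qualifying for both and is configurable
(`underage_first`).  Cleaning is idempotent, never alters an
informative answer, and passes demographics through unchanged.
Respondents with unreported sex are retained and only dropped inside
sex contrasts.  Prevalence denominators are per-question informative
counts, since respondents could skip any question, and "engaging" in a
behaviour is operationalized as any answer other than "never" — the
only reading consistent with engagement figures in the 90% range when
a substantial minority answers "rarely".  Reported percentages are
rounded half-up to 2 decimals.

Age quartiles are formed by ranking respondents on age and cutting
into four contiguous groups as equal as ties permit; all respondents
sharing an age value take the quartile of the lowest rank among them,
so equal ages are never split.  Quartile sizes can therefore differ by
up to one tie group at each boundary, and the realized age ranges are
reported alongside the labels.

## The sniff detector

### Breath segmentation

`segment_breaths()` smooths the flow with a 0.2 s moving average
(zero-padded: zero flow is the flat-expiration context) and delimits
inspirations as runs above a low threshold, by default 5% of the 95th
flow percentile.  Detection uses hysteresis: a run only counts as a
breath if its smoothed peak also clears `peak_threshold` (default five
times the low threshold), and sub-threshold gaps shorter than 0.5 s
are closed.  Without these two guards, noise excursions during the
flat expiratory phase are called tiny "breaths" whose near-zero
volumes then masquerade as large normalized decreases.  Volumes are
trapezoidal integrals of the raw flow over each run.  Positive flow is
inhalation; `invert_flow()` handles the opposite recording convention.

### The criterion

A baseline respiration window (configurable; by default the epochs
labelled `baseline`, or the first 60 s) is held out and must contain
at least three breaths.  Each breath outside it is scored on its
normalized volume $v = V/\bar V_{base}$:

* **volume branch** — $|v - 1| > 0.15$, i.e. a greater than 15% change
  in normalized sniff volume, in either direction (increase as after
  pleasant odours, decrease as after unpleasant ones);
* **s.d. branch** — the breath shifts the standard deviation of
  normalized volume over ongoing respiration above 0.35: with the
  default `sd_method = "rolling"`, the rolling s.d. of the trailing
  ten normalized volumes exceeds 0.35 with the breath included but not
  without it.

An alternative z-score reading of the s.d. branch — flag when
$(V - \bar V_{base})/s_{base} > 0.35$ — is available as
`sd_method = "zscore"` (disabled with a warning when the baseline has
zero variance).  It is not the default because a 0.35 s.d. threshold
sits well inside the null bulk: roughly a third of perfectly ordinary
breaths exceed it under any noise level, which would make the detector
unusable as an event caller.  Reading the criterion on the
normalized-volume scale keeps 0.35 a genuinely extreme excursion while
still letting sustained volume modulation fire the branch.  Both
branches record the breath's direction, its normalized change, and its
baseline z-score; baseline breaths are never self-flagged.  Detections
from the volume branch are invariant to rescaling the whole trace,
since normalization divides the scale out.

On the generator's operating conditions — events at ±30% volume and
noise at 5% of amplitude over 500 traces — the detector's recall and
precision are both above 0.95 (in the shipped suite, both are 1.0).

### Epoch comparison

`epoch_flow_comparison()` implements the hand-at-face versus baseline
flow contrast.  Epoch annotations mark intervals in which the hand
touches the face below the eyebrows and above the lower lip; they are
taken as given (no video processing).  Per subject, mean flow is
computed within each label; across subjects the package reports
condition means ± s.d., the paired t statistic with $n-1$ degrees of
freedom, the count of subjects increasing and its exact binomial
tail.  The summary is invariant to epoch ordering and subject order.

## The synthetic-data generators

The generators define the conditions under which every stage is
tested, with no external downloads.

**Survey.** Ordinal answers follow a proportional-odds model: both
sexes share baseline category probabilities (default
$(0.20, 0.30, 0.30, 0.20)$, a neutral spread over the four categories)
and group W's cumulative logits are offset by a per-question effect
size — the minimal alternative a CvM test on ECDFs should detect.
Ages are uniform over 19–74 (quartile logic needs only ranked ages),
missingness is completely at random (default 3%, split between blank
and "n.a."), and multiple selections are injected at 1%.  The
generator does not model country effects, the empirical age
distribution, or any question's real marginal frequencies; passing
tests therefore demonstrate the machinery's correctness and operating
characteristics, not agreement with any particular cohort's answers.
`simulate_cohort_emulator()` additionally pins the structural anatomy
of a 404-respondent cohort — 137 men, 260 women, 7 unreported, one
underage exclusion, four uninformative exclusions, 33 multi-answer
deletions, 182 parents of whom 70 (38.46%) notice a child
hand-sniffing phase peaking at ages 3–6 — while its answers remain
synthetic draws.

**Airflow.** Respiration is one half-wave rectified sinusoid per
breath (default period 4 s, peak 100 ml/s, 25 Hz sampling — typical
for nasal-cannula recordings) plus additive Gaussian noise; only the
integrated inspiratory volume matters to the criterion, so no richer
breath shape is modelled.  An event scales the volume of the breath
containing its onset by $1 + \text{relative change}$; events must be
at least one breath period apart.  Real nasal airflow has variable
breath periods, amplitude drift and movement artefacts that this
generator deliberately omits.

## Numerical and design notes

* All percentages for report matching use half-up rounding
  (`round_half_up()`), so 0.125 → 0.13, not banker's 0.12.
* Every stochastic routine takes a `seed` and restores the caller's
  RNG state; families derive per-member child seeds so a family is
  reproducible as a whole while members stay independently rerunnable.
* Permutation ties are counted with ≥ and a 1e-12 absolute guard, so
  an observed statistic of zero yields $p = 1$ exactly.
* The shipped test-suite problem sizes — 1000 null replicates at
  $n = 100$/group, 500 power replicates at $n = 200$/group, 500
  detector traces of 100 s, 20 000-permutation enumeration checks —
  were chosen to keep Monte-Carlo error well below the asserted
  margins while running in well under a minute.
* `run_pipeline()` writes no timestamps into its products, so
  identical config + seeds give byte-identical TSV/JSON outputs; the
  manifest records config, seeds, checksums and version, which is
  sufficient to determine a rerun.

## Known limitations

* The exact CvM normalization behind any given published value can
  only be confirmed against that study's raw data; the variant is
  therefore pluggable and the Anderson form documented as default.
* The 0.047 binomial figure discussed above is unreconciled.
* The detector's thresholds (15% volume, 0.35 s.d.) are the study's
  stated criterion, not quantities fitted here; their operating
  characteristics are established only under the generator's
  conditions.
* The survey generator's missingness is MCAR; informative missingness
  (e.g. taboo questions skipped selectively) would bias prevalences in
  ways the pipeline does not model.
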