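---
title: "Scoring and evaluating questionnaire-based IATs with qiatr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and evaluating questionnaire-based IATs with qiatr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qiatr)
```

## The measurement model

The Implicit Association Test (IAT) measures the strength of automatic
associations between concepts through a double-categorization reaction-time
task: the respondent sorts stimuli to a left or right response key as
quickly as possible, and the *difference in response latencies* between two
key-pairing conditions indexes how strongly the paired concepts are
associated in memory. The questionnaire-based IAT (qIAT) replaces single
word stimuli with full questionnaire statements. For the packaged
instrument, the LPFS-qIAT, these are the 12 statements of a brief
personality-functioning scale describing *impaired* functioning (e.g. "I
often do not know who I really am"), each mirrored by a meaning-reversed
*not impaired* counterpart, sorted alongside objectively *true* or *false*
self-statements ("I am looking at a computer screen" / "I am sunbathing at
the beach").

The task has seven blocks (trial counts 40, 20, 20, 40, 40, 20, 40; 220
trials in total): two single-task learning blocks, a combined practice and
a combined test block under one pairing, a reversed single-task practice
block, and a combined practice and test block under the reversed pairing.
In a *compatible* pairing the construct's positive pole (Impaired) shares a
key with True; in the *incompatible* pairing it shares a key with False.
Respondents for whom "impaired" statements are self-descriptive sort the
compatible pairing faster, and the standardized latency difference is the
D score, signed so that positive D means a stronger self–impairment
association.

Two counterbalancing factors — which physical key carries which labels, and
whether the reversed pairing comes first — give four administration
variants (`counterbalance_variants()`). Scoring is defined entirely in
terms of the pairing, so D is invariant to the physical key assignment;
the package tests this property explicitly.

### Trial sequencing

Published descriptions of the task do not pin down the within-block trial
order. `build_trial_sequence()` uses the convention standard for this task
family: in combined blocks, target-category and logical-category trials
strictly alternate (target first), and each category stream draws stimuli
by reshuffled cycling, so no stimulus repeats before its pool is exhausted.
This guarantees balanced exposure of the two streams and of every
statement. Sequences are reproducible from `(spec, variant, seed)`; a seed
is mandatory everywhere randomness occurs.

## The D-score pipeline

`score_session()` applies, in order:

1. **Slow-trial dropping.** Trials slower than 10 s (strictly) are
   discarded; the count is reported per participant.
2. **Fast-responder exclusion.** A participant with strictly more than
   10 % of combined-block responses faster than 300 ms (strictly) is
   excluded. The share is computed over the four combined-task blocks by
   default (`fast_share_blocks = "all"` widens the denominator); fast
   trials are counted for the rule but *kept* in scoring
   (`drop_fast_trials = TRUE` deletes them instead).
3. **Error handling.** Two schemes, matching the two ways task errors are
   handled in the field. Under `d600`, an error trial's scoring latency
   becomes the mean of its block's correct retained latencies plus 600 ms.
   Under `built_in_penalty` the recorded latency is used as-is, because the
   respondent had to self-correct before proceeding, so the recorded
   latency already contains the penalty.
4. **Pair-wise D.** For each scored block pair, `D = (mean incompatible −
   mean compatible) / SD`, where the SD is the *inclusive* sample (n−1)
   standard deviation over the retained scoring latencies of both blocks.
   The final D is the unweighted mean of the practice-pair D (combined
   practice blocks) and the test-pair D (combined test blocks).

Scoring both pairs is the improved-algorithm convention; because the
instrument's description emphasizes the critical test blocks, a
`scored_pairs = "test_only"` flag preserves that stricter reading. The
choice of sample rather than population SD follows the reference algorithm
family. These are the only places where the pipeline's definition was
genuinely open; both are surfaced as configuration rather than silently
fixed.

Useful consequences of the definition, all verified as properties in the
test suite: D is invariant to trial order, to adding a constant to every
latency, and to rescaling all latencies by a positive factor; shifting only
the incompatible blocks strictly increases D; and swapping the two
conditions negates it exactly.

## Reliability and validity statistics

**Parcel alpha.** Internal consistency of a latency-based score needs
item-like units. `parcel_d_scores()` deals the retained trials of each
scored block round-robin (by trial position) into K disjoint, exhaustive
parcels and D-scores each parcel on its own trials; `cronbach_alpha()` is
then the usual `K/(K−1) (1 − Σ var(parcel) / var(total))` over the
participant-by-parcel matrix. K = 2 is the default (each parcel then spans
half of every block); the parcel count is configurable because published
alpha variants for this task family differ in their parcel schemes, and no
single scheme can be asserted as canonical. `split_half_reliability()`
reports the two-parcel Pearson correlation with the Spearman–Brown
step-up `2r/(1+r)` alongside.

**Bootstrap correlation inference.** All validity and retest correlations
use `bootstrap_pearson_ci()`: participants are resampled in pairs with
replacement (5000 replicates by default), the 95 % interval is the 2.5/97.5
percentile of the resampled correlations, and an effect is significant at
p < .05 exactly when zero lies outside the interval. The percentile method
is the default of common implementations and the natural reading of a CI
rule stated this way; resamples in which a variable degenerates to a
constant are dropped as uninformative. The suite calibrates the machinery:
over 500 null datasets (n = 200) the CI-rule rejection rate must fall in
[3 %, 7 %], and coverage at ρ = 0.3 in [93 %, 97 %].

**Minimum detectable effect size.** `mdes_correlation(n)` answers the
sensitivity question "what is the smallest population correlation a
two-tailed test at α = .05 detects with power .80 at this n?". Power is
computed exactly from the sampling distribution of the Pearson r under a
bivariate normal population (Hotelling's density, integrated in atanh
space for stability), and the MDES is found by bisection to 1e−6. A
bias-corrected Fisher-z approximation (`method = "fisher"`) agrees to about
1e−4 over the sample sizes relevant here and documents the calculation's
pedigree. For n = 806, 209 and 236 the solver gives 0.098, 0.192 and 0.181
(three decimals).

`validity_report()` assembles the correlation table an analyst reports:
one row per external measure, pairwise-complete n per cell, bootstrap CI,
CI-rule significance, and the cell's MDES. No multiplicity correction is
applied, matching standard practice for these descriptive tables.

## The respondent simulator

Because trial-level human data for this instrument are not redistributable,
the package ships a generative model so every stage is testable end to end
against known ground truth.

A respondent's latency is `shift + Lognormal(mu_log, sigma_log)` ms, plus
`d_true × pairing_shift_ms` on incompatible-pairing combined trials, where
`d_true` is the latent association strength (population `Normal(0, 1)`).
Defaults — floor 300 ms, median lognormal component 450 ms (`mu_log =
log 450`), `sigma_log = 0.4`, pairing shift 150 ms per unit trait, error
rate 12 % — produce typical latencies around 650–900 ms, trial-level SDs
near 200 ms and error rates in the low teens, the regime reported for
online administrations of statement-based IATs. Classification errors are
i.i.d. per trial; under the built-in penalty an error's latency is
inflated by an independent lognormal correction time (median 300 ms). A
*fast contaminant* — the simulator's model of an inattentive online
respondent — answers half of their trials with uniform 100–299 ms
latencies; the default contamination rate of 0.25 mirrors the prevalence
such screenings report. Retest data redraw the trait as `d2 = s·d1 +
sqrt(1−s²)·e`, preserving the marginal distribution, with independent
session noise.

Deliberate simplifications: the lognormal stands in for the heavier
ex-Gaussian sometimes fitted to latencies (three parameters suffice for
the properties tested, and the module documents where to swap the law);
the pairing effect is additive in milliseconds, keeping D linear in the
trait for recovery tests; there are no practice, fatigue or
block-order effects, no item-level difficulty, and no correlation between
the trait and error rate or speed. One visible consequence of additivity:
a respondent with an extreme negative trait can produce genuinely fast
incompatible-block responses and be excluded by the 300 ms rule, which is
why simulated cohorts are analyzed over retained participants, exactly as
real ones are. Passing recovery tests therefore show the pipeline is
correct and well-calibrated under a plausible data-generating process —
not that the instrument itself is valid in any population.

`recovery_experiment()` closes the loop: simulate, score, join to truth,
and report the trait-recovery correlation plus the contaminant-detection
confusion matrix. At the default conditions (n = 500) the pipeline
recovers the latent trait at r ≈ 0.95 and detects contaminants with
specificity above 0.95 (clean respondents cannot fall below the 300 ms
floor, so false alarms require an extreme trait).

## Numerical and interface choices

* Latencies are integer milliseconds in the canonical CSV; I/O is
  lossless, and boundary rules are strict exactly as worded (a 10 000 ms
  trial is kept, a 300 ms response is not "faster than 300 ms", a fast
  share of exactly 10 % is retained).
* In the participant ledger, incompleteness takes precedence over fast
  responding, so each participant is counted once.
* Degenerate inputs fail loudly with named reasons rather than propagating
  NaN: zero inclusive SD, a D600 block with no correct trials, constant
  inputs to correlations, Spearman–Brown at r = −1.
* All randomness flows from user-supplied seeds through deterministic
  substreams; reruns are byte-identical, and library calls restore the
  caller's RNG state.
* Test problem sizes are chosen to make Monte-Carlo bounds meaningful at
  desk scale: 500 datasets for bootstrap calibration, cohorts of 100–500
  for recovery and retest properties, 50 random sessions for the
  brute-force scoring oracle.

## Known limitations

The packaged instrument is statement-based; classic word-stimulus IATs are
out of scope. The parcel-alpha variant is one member of a family and other
published parcel schemes will give somewhat different coefficients. The
simulator is a measurement model, not a cognitive-process model (no
diffusion dynamics), and its defaults are engineering choices, not
estimates of any study population. Empirical reliability and validity
coefficients obtained on real cohorts cannot be reproduced or judged by
this package; it reproduces the *machinery* by which such coefficients are
computed.
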