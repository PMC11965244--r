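---
title: "Design, simulation, and distributional analysis of flanker experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design, simulation, and distributional analysis of flanker experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## What this package computes

In the Eriksen flanker task, observers judge the direction of a central
target arrowhead surrounded by task-irrelevant flankers that either agree
(congruent) or disagree (incongruent) with it. The flanker congruency effect
(FCE) — incongruent minus congruent performance, in error rate (FCE~ER~) or
median correct response time (FCE~RT~) — indexes the efficiency of spatial
selection. `fcepipe` implements the full behavioral-analysis machinery for
three experimental manipulations of that selection process:

* **EXP1** — target–flanker stimulus onset asynchrony (SOA), nine levels from
  −400 ms (flankers first) to +200 ms (flankers last); 8 blocks × 108 trials.
* **EXP2A/2B** — a mid-trial stimulus contrast change at t~Δ~ ∈
  {33, 50, 67, 83} ms after onset, or no change (the constant control);
  12 blocks × 80 trials, stimulus at one of four diagonal locations.
* **EXP3** — stimulus location certainty: Fixed blocks (always at fixation)
  alternating with Variable blocks (one of four cardinal offsets per trial),
  three repetitions of an ABBA/BAAB counterbalance; 12 blocks × 80 trials.

The pipeline covers schedule construction, a synthetic response generator
with controllable ground truth, trial classification, condition summaries,
FCE computation with within-subject error bars, composite speed–accuracy
block scores, delta-plot time-course analysis with slope inference,
repeated-measures ANOVA with Greenhouse–Geisser adjustment, location
carry-over contrasts, and a priori power computation.

## The synthetic generator: a stated world

The generator (`gen_params()`, `simulate_experiment()`) emulates the
*statistical structure the analyses assume*, not a cognitive mechanism.

**Base RT.** Each subject's correct-congruent RT follows an ex-Gaussian
distribution — the standard parametric family for response times — with
subject parameters drawn from a population of mean µ = 400 ms (SD 30),
σ = 50 ms (SD 10), τ = 100 ms (SD 20). These defaults produce median RTs of
roughly 430–530 ms and right-skewed tails, typical of speeded two-choice
performance in practiced undergraduate samples. Draws are clipped at
µ ≥ 150, σ, τ ≥ 10 ms to keep parameters physical.

**Interference.** Incongruent RTs are *quantile-coupled* to their
counterfactual congruent value: with `u ~ Uniform(0, 1)` and Q the subject's
ex-Gaussian quantile function,

```
T_C = Q(u)
T_I = Q(u) + delta0 + delta1 * (u - 1/2)
```

so `delta0` is the FCE~RT~ at the median and `delta1` is the change in the
effect from the fastest to the slowest quantile — the delta-plot slope's sign
and magnitude are directly controllable. Quantile coupling is a simulation
device chosen over independent draws precisely because it makes that
gradient a parameter; it is not a claim about how interference arises within
a trial. Errors are Bernoulli per congruency cell (`e_congruent`,
`e_incongruent`); premature responses (landing before target onset) occur
with a configurable rate on flanker-first trials; responses beyond the
response deadline (1 s from stimulus offset in EXP1/EXP2, 1.25 s from onset
in EXP3) become missing. RTs are floored to integer milliseconds, matching
frame-quantized acquisition. The ex-Gaussian quantile function is inverted
numerically by bisection to a relative tolerance of 1e-9.

**Carry-over.** In EXP3 Variable blocks, trials whose location differs from
the immediately preceding trial receive `kappa_rt_ms` extra RT, and
incongruent such trials a further `kappa_fce_ms` — a congruency-specific
carry-over increment the analysis should recover as the
Variable-Diff-vs-Same contrast.

**Presets.** `preset_paper_like()` encodes, per experiment, offsets and
gradients that reproduce the published qualitative pattern: interference
maximal when flankers lead by 50–100 ms and null once they trail by ≥100 ms;
negative gradients at SOAs −200/−100 and positive at +30/+50/+100; EXP3
Fixed/Variable-Same/Variable-Diff FCE~RT~ of about 43/57/78 ms with a 21-ms
congruency-specific carry-over. One deliberate deviation: the preset's EXP1
gradient magnitudes (|delta1| = 50–70 ms, emergent slope effect sizes
|d| ≈ 0.8–1.2) exceed what the published standardized slopes for the
flanker-leading conditions imply (d ≈ −0.4). They were fixed a priori by a
power calculation so that the configured sign pattern is Benjamini–Hochberg
detectable at the study's n = 40 in ≥90% of runs, which the end-to-end check
demands; with d ≈ −0.4 the joint detection probability would be far below
that. The preset therefore trades exact effect-size matching for reliable
sign recovery.

**What the generator does not emulate** — and hence what a green test does
*not* establish: congruency sequence (Gratton) effects, post-error slowing,
practice and fatigue trends, between-subject variability in interference
parameters (all subjects share each condition's delta0/delta1), RT–accuracy
coupling within a trial (errors are drawn independently of the RT), and any
dependence of error RTs on correctness. Green acceptance tests establish
that the *analysis machinery* recovers known ground truth, not that the
generator is a model of human performance.

## Preprocessing rules

* RT is referenced to target onset (the target's onset varies with SOA).
* Responses faster than 200 ms are counted incorrect for all analyses; the
  threshold is configurable but defaults to 200 ms and is applied uniformly
  to all three experiments (the source procedures state the later
  experiments reuse the first one's analysis rules).
* Premature responses (RT < 0) and missing responses are incorrect.
* EXP3: the first trial of every block is excluded (12 blocks × 80 trials →
  474 retained trials per location condition); the exclusion is applied
  uniformly to ER and RT analyses. Carry-over labels compare each Variable
  trial's location with the immediately preceding trial *regardless of that
  trial's correctness* — the classification is about spatial attention, not
  response monitoring.

## Summaries, effects, error bars, scores

Condition summaries are the subject-level mean error rate and **median**
correct RT (the median is the primary statistic; a mean-RT alternative is
not the default anywhere). The FCE sign convention is incongruent −
congruent, so interference is positive. Within-subject error bars use
Cousineau subject-centering with Morey's `sqrt(k/(k-1))` bias correction.

The composite block score mirrors the task's feedback:
`speed = mean over all trials of (ln 3000 − ln(rt + 1000)) / (ln 3000 − ln 1300)`
(responded trials contribute their term, missing responses contribute 0 but
count in the denominator — the source formula does not restrict the RT set
to correct trials, so we include all responded trials), `accuracy`
is the proportion correct, and the unweighted score is
`(accuracy − 0.5)/0.5 × speed × 100`, clipped to [0, 100] because responses
faster than 300 ms would otherwise push it past 100. The later experiments
re-weight accuracy and speed (80/20 and 75/25); the exact re-weighting
formula was never published, so this package uses the convex combination
`100 × (w_acc (accuracy − 0.5)/0.5 + w_spd × speed)`, clipped the same way —
this is a documented design choice, not a published formula.

## Delta plots

Per subject and condition, correct RTs in each congruency level are reduced
to nine percentiles (10%…90%) using linear interpolation between order
statistics (R's type-7 estimator; the source procedure does not name an
estimator, so the common default is fixed and documented). Each bin
contributes x = (q~C~ + q~I~)/2 and y = q~I~ − q~C~; a per-subject OLS line
through the nine points gives the slope. Group inference is a two-sided
one-sample t per condition with Benjamini–Hochberg step-up correction across
the experiment's condition family (9, 5, or 3). Cells with fewer than 10
correct RTs (configurable) are excluded with a warning. Degenerate fits
(zero x-variance) are flagged rather than fabricated.

Post hoc linear/quadratic trend tests use orthogonal polynomial contrasts
over the **bin index** (1..9), not the bin RT: RT spacing differs across
subjects, while index contrasts stay orthogonal by construction. Contrast
scores are tested across subjects with df = n − 1; the published analogue
pools to a larger df by an undescribed scheme, so this package reports the
subject-level test and notes the difference rather than reverse-engineering
the pooling.

## Repeated-measures inference

`rm_anova_2way()` uses the classical univariate decomposition: each within
effect is tested against its own effect × subject interaction, giving the
familiar df patterns (e.g., F(1, n−1) for congruency). Greenhouse–Geisser
epsilon is computed per effect from the covariance of the effect's
orthonormal contrast scores (for a main effect this equals the Box formula
on the double-centered covariance of the collapsed scores); it is bounded in
[1/(k−1), 1], equals 1 for two-level effects, and scales both df before the
p value is taken. One numerical caveat the tests encode: "the adjustment is
conservative" (adjusted p ≥ raw p) is guaranteed only for F ≥ 1; for F < 1
shrinking both df can lower the tail probability.

EXP3's location factor enters as three levels (Fixed, Variable-Same,
Variable-Diff): trial counts per level are unbalanced by design, but the
ANOVA consumes balanced subject-level cell means. The carry-over contrast is
the per-subject (Diff − Same) median-RT difference per congruency, with a
paired t and 95% CI on the incongruent-minus-congruent difference of those
differences. Pairwise comparisons apply no multiplicity correction by
default (matching the source analyses, which correct only the delta-plot
family); Holm is available behind a switch.

`power_within()` implements the two effect-size readings used in the
original power statements: a paired t with noncentrality `d√n`, and the
one-df within-subject F contrast with `f² = η²/(1−η²)`, ncp `n·f²`, df (1,
n−1). The exact design behind the published statements is not described;
the one-df contrast reading is the conservative, robust interpretation for
a "power to detect the congruency effect" claim.

## Randomization and determinism

Every random step derives a private stream seed from a (master seed, stream
index) pair via a Lehmer-style mixing function kept below 2³¹; block
shuffles, per-trial location draws, and per-subject response streams are
independently seeded, so identical configs produce byte-identical results
and partial rebuilds (per block or subject) are stable. No global RNG state
leaks: user-level `.Random.seed` is saved and restored around every
internal draw.

## Degenerate inputs and numerical choices

* Empty summary cells (no usable RT) are flagged, carry NA medians, and are
  excluded downstream with warnings; missing congruency levels are errors.
* Zero slope variance with nonzero mean reports an infinite t with a flag.
* The location sampler in Variable blocks is iid-uniform over the four
  positions by default (about 118.5 Same trials per subject in expectation);
  the original pseudo-random constraint was unspecified and its reported
  Same-trial count (114) slightly lower. We do not tune the sampler toward
  that number; a balanced per-block mode (20 trials per location) is
  available behind a flag.
* The ex-Gaussian CDF uses a log-scale correction term to avoid overflow;
  quantile bisection runs to relative tolerance 1e-9 (RTs are floored to ms
  afterwards, so the tolerance is far below the quantization).

## Known limitations

The generator's homogeneity (shared condition effects across subjects)
makes between-subject effect-size calibration approximate; the composite
score's weighted variant is this package's own construction; polynomial
trend df differ from the published analogue as described above; and the
pipeline performs no outlier trimming beyond the stated rules (no SD-based
RT clipping), by design.
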