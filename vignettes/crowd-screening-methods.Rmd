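---
title: "Bias amplification in nominal groups: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias amplification in nominal groups: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdscreen)
```

## The problem

Crowdsolving platforms collect answers to intellective questions from many
independent online workers and aggregate them, typically by plurality
(relative-majority) vote within a "nominal group" — a set of workers whose
answers are pooled statistically, without interaction. The generalized
Condorcet Jury Theorem governs what happens as group size grows: when each
worker is more likely to choose the correct option than any particular wrong
one, plurality accuracy rises with group size; when a systematic cognitive
bias makes a single wrong option the pool's modal answer, the same mechanism
amplifies the error toward certainty. `crowdscreen` implements a complete
pipeline for studying this phenomenon and the mitigation studied alongside
it: screening workers with the Cognitive Reflection Test (CRT) before group
formation.

Two quantities sit at the core:

* the **simulated** accuracy of nominal groups of size $n$, estimated by
  repeatedly sampling groups without replacement from a worker pool and
  plurality-voting every item, and
* the **exact** probability that the correct option is the plurality winner,
  under iid voting (multinomial counts) or finite-pool sampling without
  replacement (multivariate hypergeometric counts), with an option tied
  among $t$ maxima receiving win credit $1/t$ — the same quantity a uniform
  random tie-break estimates.

The second serves as the analytic oracle for the first: the simulation and
the exact curves are estimates of the same estimand, and the test suite
holds them to Monte-Carlo error of one another.

## The synthetic worker pool

No raw worker responses ship with the package; a generative stand-in
produces pools whose statistical structure matches the study conditions the
pipeline is designed for. The generator is deliberately minimal — a single
latent reasoning trait plus a lure-or-uniform error split — because that is
the simplest structure reproducing the three facts that matter downstream:

1. **Heterogeneous item difficulty.** Worker $w$ has trait
   $\theta_w \sim N(0,1)$ and answers item $i$ correctly with probability
   $\mathrm{logit}^{-1}(a_i\theta_w + b_i)$.
2. **Cross-test correlation.** The shared trait induces positive rank
   correlations between subtest totals.
3. **Incorrect-modal ("lure-dominated") items.** An incorrect answer falls
   on the item's designated lure with probability $\lambda_i$, else
   uniformly on the other distractors; a large enough $\lambda_i$ relative
   to the item's accuracy makes the lure the pool's modal answer.

The battery mirrors a 30-question, four-subtest reasoning challenge: 4 CRT
items (open-numeric, represented as canonical correct/lure/other labels), 9
Raven's-matrices short-form items (8 options, no lure), 9
heuristics-and-biases (HBT) items keyed by construct (3–5 options each),
and 8 syllogistic validity judgements (SRT; two options, half congruent and
half incongruent with believability — the incongruent items index belief
bias). Item texts are construct-keyed stand-ins; only the response
*structure* is modelled.

### Calibration

`calibrate_difficulties()` sets each $b_i$ so that the trait-marginalized
accuracy $\int \mathrm{logit}^{-1}(a_i\theta + b_i)\,\phi(\theta)\,d\theta$
equals a target, using 61-node Gauss–Hermite quadrature inside
one-dimensional root finding (converged to $10^{-6}$; the quadrature error
itself is near machine precision for this smooth integrand). Per-item
targets are anchored to the study-scale subtest means — CRT $1.27/4$, RSPM
$4.76/9$, HBT $3.63/9$, SRT-incongruent $1.45/4$, SRT-congruent $3.66/4$ —
with the per-item spread a design choice:

* HBT item accuracies span $0.147$–$0.705$ (error rates 29.5%–85.3%), with
  lure weights chosen so that exactly three constructs are lure-modal in
  the full pool — *sample size accounting* (.25 correct vs .60 lure),
  *covariation detection* (.147 vs .725, the most pronounced bias) and,
  weakly, *methodological reasoning* (.30 vs .42). *Denominator neglect*
  gets an almost-even split slightly favouring the correct answer, and
  *regression to the mean* a low accuracy but dispersed errors — the two
  contrasting curve shapes the theorem predicts (slow vs steep
  improvement).
* All four incongruent SRT items are lure-modal (accuracies .33–.39; with
  two options the single wrong judgement is the lure, $\lambda \equiv 1$).
  The spread is deliberately tight: the compressed range keeps every item
  below one-half in the full pool while letting a 2/4 CRT screen flip all
  four above one-half, the configuration whose consequences the aggregation
  analysis studies.
* Discriminations default to $a_i = 1$; the incongruent SRT items use
  $a = 2.6$. The higher loading is the calibrated choice that brings the
  CRT–belief-bias rank correlation to its target (≈ .54 against the .563
  anchor at $N = 10{,}000$; $a = 1$ leaves it near .41) and gives the
  screened subpool decisive correct majorities on all four items. CRT lure
  weight is 0.8 (errors overwhelmingly land on the intuitive answer);
  RSPM items have no designated lure.

With these defaults and $N = 10{,}000$: subtest marginals within $\pm 0.02$
of their anchors, CRT–HBT rank correlation ≈ .50, CRT–SRT-incongruent
≈ .52–.54, and a CRT pass rate (≥ 2/4) of ≈ .37 against the study's 35/95.
Demographics (age $N(48.6, 15.4^2)$ truncated at 18, 47% female, 42%
tertiary-educated) are drawn independently of the trait: the study design
found little demographic signal once ability measures entered the
regressions, and independence is the neutral default for a stand-in.

### What the generator does not emulate

Real pools have multi-dimensional ability, item-specific error structure,
inattention, and response-order effects; none of these are modelled. Tests
passing on synthetic pools therefore establish the *pipeline's*
correctness and the *theorem-level* behaviour (amplification, mitigation,
screening effects), not quantitative claims about any particular platform's
workers. Real-data effect sizes are not reproducible from the generator and
are treated as directional anchors only.

## The aggregation procedure

For each group size $n$ (default 1..25) and replicate $b$ (default
$B = 1000$): draw $n$ workers uniformly without replacement, take each
item's plurality answer (uniform random tie-break), score the answer vector
1/0 against the key, and sum to the group's test score. One group answers
the whole test per replicate, so item accuracies and the overall-score
distribution derive from the same draws. The maximal effect of aggregation
is summarized as pooled-SD Cohen's d between the replicate score
distributions at the largest and smallest size, sign preserved (negative =
amplified bias).

Reproducibility: the master seed is mixed with stage counters
(`derive_seed`) into independent substreams — group draws keyed by
(seed, size), tie-breaks by (seed, size, item identity) — so curves are
bit-identical across runs and invariant to item iteration order. Ties are
broken with `max.col(ties.method = "random")` under the item's substream.

## Exact plurality probabilities

`plurality_prob_multinomial()` and `plurality_prob_hypergeometric()`
compute $P(\text{correct option wins})$ by conditioning on the focal
option's vote count $m$ and sweeping the remaining options with a dynamic
program over (votes used, number tied at $m$), constraining every other
count to $\le m$ — $O(k\,n^3)$ states, exact to floating point, with ties
credited $1/t$. The multinomial backend is guarded at $n \le 170$ (double
factorials); study-scale sizes are $n \le 25$ with occasional limit checks
at $n \approx 100$. Normalization (win probabilities over all options sum
to 1), label-permutation equivariance, and convergence of the finite-pool
backend to the iid limit are property-tested; small cases are verified
against labelled brute-force enumeration ($k^n$ outcomes) and subset
enumeration ($\binom{N}{n}$ draws).

## Scoring, screening and inference conventions

* Missing responses score 0 (denominators stay fixed) and are logged, not
  excluded.
* Open-numeric CRT matching: raw strings are trimmed, lowercased, stripped
  of currency/unit tokens and parsed numerically, then matched against an
  accepted-value set per canonical answer ("5", "5 cents", "$0.05" all
  resolve to the same label); unparseable strings fall back to literal
  matching and then to "other". Normalization lives at the IO layer; the
  scorer compares canonical labels only.
* Percent-correct ($100\,s/k$) is never rounded internally.
* The nonparametric correlation is Spearman's $\rho$ (average ranks on
  ties, large-sample t approximation for $p$); Pearson is available by
  flag.
* Welch's t uses the Satterthwaite df and a 95% CI for the mean
  difference; the summary-statistic and raw-sample paths share one
  formula.
* Per-item 2×2 χ² contrasts (passed/failed × correct/incorrect) use no
  continuity correction by default (selectable), df = 1, and flag
  zero-marginal tables as degenerate rather than guessing. No
  multiple-testing adjustment is applied across the 13 bias items by
  default, mirroring the descriptive use of these tests.
* Hierarchical regressions z-score all variables (standardized β), add
  blocks demographics → estimated IQ → CRT-passed indicator, and report
  adjusted $R^2$, $\Delta R^2$ and
  $\Delta F = \frac{\Delta R^2/\Delta k}{(1-R^2_{full})/(n-k_{full}-1)}$.
  Rank-deficient designs error with the collinear columns named.
* The RSPM→IQ mapping is declared a stand-in: $100 + 15\,z$ against the
  pool reference. Standardized regression results are invariant to this
  affine choice (tested), so nothing downstream depends on it.

## Numerical and degenerate-input choices

* Probability-vector inputs must sum to 1 within $10^{-9}$; distribution
  outputs sum to 1 within $10^{-12}$.
* Calibration targets must lie strictly inside (0, 1); root finding is
  bracketed on $b \in [-40, 40]$ and errors, naming the item, on
  non-convergence.
* Screened pools shrink: group sizes are capped at the pool size, and
  sampling beyond it errors explicitly (a stringent 3/4 screen can cap the
  largest investigable group well below 25).
* Cohen's d with zero pooled SD returns 0 for equal means and errors as
  degenerate otherwise.

## Problem sizes used by the tests and drivers

The shipped analyses use the study-scale pool ($N = 95$, $B = 1000$,
$n \le 25$); calibration checks use $N = 10{,}000$ pools; the
simulation-vs-oracle agreement check uses a 20-worker pool with
$B = 20{,}000$ replicates at $n \in \{1,3,5,7\}$, where exact enumeration
is comfortable. These sizes keep every check deterministic under its fixed
seed while leaving Monte-Carlo error well below the tolerances asserted.

## Known limitations

* Single-trait generative model: cross-test correlations are exchangeable
  by construction beyond what discriminations induce; it cannot represent
  bias that is *unrelated* to general reasoning ability.
* Exact per-item HBT option counts of the original instruments are not
  public; the 3–5 option defaults are plausible stand-ins, and conclusions
  about specific constructs should be read as structural, not
  psychometric.
* The effect of screening is studied cross-sectionally; the pipeline makes
  no causal claim about cognitive reflection, and none of its statistics
  adjust for worker self-selection.
* Replicate curves for different tests are independently seeded; whether a
  shared set of groups should answer both bias tests is a design choice
  with no observable consequence for the reported quantities beyond
  Monte-Carlo pairing.
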