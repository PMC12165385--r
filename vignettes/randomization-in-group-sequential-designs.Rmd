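---
title: "Randomization procedures and group sequential designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization procedures and group sequential designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gseqrand)
```

## The problem

A two-arm group sequential trial plans its interim boundaries for a 1:1
allocation: at analysis $k$ the planned information is $N_k/4$ for $N_k$
patients accrued. The randomization procedure, however, decides what
allocation is actually realised stage by stage. Unrestricted procedures can
leave an interim stage badly imbalanced — or even single-armed — and with
small stage sizes (8 patients per stage in the central configuration used
throughout this package) such deviations are common, not exotic. This
package quantifies the consequences: how much type I error is lost or
gained when planned boundaries are applied naively, and how much power each
design family retains under each randomization procedure.

## Model and test

Outcomes are normal with known common variance 1; the one-sided hypothesis
is $H_0: \mu_E \le \mu_C$ against $\mu_E > \mu_C$, tested at one-sided
$\alpha = 0.025$ by default. For cumulative per-arm counts $(N_{E,k},
N_{C,k})$ at analysis $k$, the information is
$I_k = (1/N_{E,k} + 1/N_{C,k})^{-1}$ and the cumulative z statistic has
mean $\delta\sqrt{I_k}$ under standardized effect
$\delta = \mu_E - \mu_C$, with $\mathrm{corr}(Z_j, Z_k) = \sqrt{I_j/I_k}$.
Everything the exact engine computes is a rectangle probability under this
multivariate normal law (or the analogous law for the combination test
below).

## Design families

* **Classic Pocock / O'Brien-Fleming** (`method = "classic"`): constant
  bounds $b_k = c$, respectively $b_k = c\sqrt{K/k}$, with $c$ solved so
  the overall null crossing probability is $\alpha$ under the equal-stage
  correlation $\sqrt{j/k}$. These designs assume equally sized stages.
* **Lan-DeMets spending** (`method = "ldm"`): a spending function
  $\alpha(t)$ fixes the cumulative type I error spent by information
  fraction $t$. The package implements the standard one-sided forms
  $\alpha(t) = 2\{1 - \Phi(z_{1-\alpha/2}/\sqrt{t})\}$ (OBF-like) and
  $\alpha(t) = \alpha\log\{1 + (e-1)t\}$ (Pocock-like). Stage bounds are
  solved sequentially so that each stage's null crossing probability equals
  its incremental spend.
* **Inverse normal combination test** (`method = "inct"`): stage-wise
  statistics $Z^*_k$ (computed from each stage's data alone) are combined
  as $C_k = \sum_{i \le k} w_i Z^*_i / (\sum_{i \le k} w_i^2)^{1/2}$ with
  pre-fixed weights. Because stage increments are independent standard
  normal under the null *whatever the realised allocation*, the pre-planned
  boundaries remain exact — the INCT's defining robustness property, paid
  for in power when the realised stage informations drift from the plan.

Weights default to equal, which for equal planned stages coincides with
weights proportional to planned stage sizes. For the four-stage, 16-patient
worked example the boundaries are classic OBF-shaped
(`classic_bounds = TRUE`); for the 24-patient tables they are
spending-based. Both conventions are exposed because both appear in
practice, and the two reproduce different published reference values.

## Conditional evaluation

The central quantity is the rejection probability *conditional on one
randomization sequence's stage allocations*:

* **naive mode** applies the planned boundaries although the observed
  allocation (hence information) differs — the type-I-error-inflation
  scenario;
* **adjusted mode** re-solves Lan-DeMets boundaries at the observed
  fractions $t_k = I_k/(n/4)$, spending all remaining alpha at the final
  look ($\alpha(t_K) := \alpha$, standard last-look practice). This makes
  the conditional type I error exactly $\alpha$ for every admissible
  sequence, which the test suite asserts sequence by sequence.

The planned maximum information $n/4$ stays in the denominator, so
imbalance strictly reduces every $t_k$. Sequences whose first stage (for
cumulative families) or any stage (for the INCT) is single-armed have no
defined statistic and are excluded, with counts reported; for the t-test
the threshold is two patients per arm, since a variance must be estimated.
Excluded sequences are dropped from the mean, not imputed.

## Futility

Interim futility bounds $a_k$ (the evaluated rule is $a_1 = a_2 = 0$:
stop on any negative trend) may be **binding** — the trial must stop, so
efficacy bounds are re-solved with continuation regions truncated to
$[a_k, b_k)$, which lowers them — or **non-binding** — efficacy bounds are
left at their no-futility values and the futility rule enters only the
evaluation of power. Non-binding futility therefore costs more power than
binding, and both cost power relative to no futility stopping.

## Group sequential t-test

For small samples a pooled-variance t-test is the realistic analysis. The
z-scale bounds are converted by quantile substitution: the stage-$k$ t
bound is $F^{-1}_{t,\nu_k}(\Phi(b_k))$ with cumulative pooled degrees of
freedom $\nu_k = N_{E,k} + N_{C,k} - 2$ for cumulative families and
stage-wise $\tilde n_{E,k} + \tilde n_{C,k} - 2$ for the INCT — matching
the data each family actually tests. For the INCT the stage t statistic is
mapped to the normal scale through its tail p-value (the inverse normal
transformation), so the planned z-scale boundaries apply without
substitution; this is the canonical combination-test construction.
Quantile substitution is known to leave a small type I error inflation for
cumulative designs at these sample sizes, which the simulation engine
reproduces; the INCT t-test remains conservative. The t-test has no
tractable joint law, so it is evaluated by patient-level trial simulation
(vectorised over trials per sequence).

## Randomization procedures

The generator implements the allocation law of each procedure as a
conditional probability that the next patient receives the experimental
arm, applied over the whole trial (never restarted per stage): complete
randomization (fair coin), random allocation rule (random permutation of a
balanced label vector), permuted blocks (random allocation rule within
each block of length $l$), randomized block lengths (drawn uniformly from
a set; the final block is truncated at $n$), Efron's biased coin
(probability $p$ for the lagging arm, fair coin at ties), big stick
(fair coin with a deterministic assignment once the imbalance reaches
$m$), and Chen's design (biased coin plus the big stick's hard cap). The
headline parameters are $p = 2/3$, $m = 3$, $l = 4$ — the values used in
the simulation study this package reproduces, with $l = 4$ also the most
common block size in published group sequential trials.

The same allocation law drives the exact path enumeration behind
`single_group_stage_probability()`, so closed forms (for CR, EBC, RAR) and
enumeration can be cross-checked to machine precision; the test suite
additionally re-derives the enumeration with an independent helper.

What the generator emulates is the allocation mechanism only: real trials
add dropout, overrunning at interim cutoffs, stratification and possible
selection bias, none of which are modelled. Passing tests therefore show
the designs' behaviour under ideal conduct of each procedure, not under
operational imperfections (an unequal `stage_plan` can emulate simple
over-/under-running).

## Numerical choices

Sequential crossing probabilities use deterministic Miwa quadrature
(`mvtnorm`), 512 grid steps up to dimension 3 and 128 beyond, accurate to
well below $10^{-6}$ and bit-for-bit reproducible — important because
boundary solving is root finding (safeguarded bracketing, tolerance
$10^{-9}$ on the z scale) on top of these probabilities. Infinite limits
are clamped at 35 standard deviations. A stage whose incremental spend is
below $10^{-13}$ receives an infinite bound. Infeasible configurations — a
binding futility bound so high that a later stage's spend cannot be
achieved — raise errors naming the stage. Conditional evaluations are
cached per distinct stage-allocation pattern (a few hundred patterns per
1000 sequences), which keeps exact sequence averaging at interactive
speed.

Problem sizes follow the study conditions: 1000 sequences for power
averaging, 2000 trials per sequence for the t-test engine; the validation
of the exact engine against trial simulation uses 50 sequence-effect
combinations at $10^5$ trials. Tests use smaller counts where only a
property (monotonicity, ordering, level control) is at stake.

## Known limitations

Two-sided testing, unequal planned allocation ratios, response-adaptive
and covariate-adaptive randomization, sample-size reassessment and exact
t-test boundary computation are out of scope. The selection framework
(`framework_summary()`) applies to equal stage sizes only, and implements
the inequalities $m < n/K$ (cumulative families) and $m < (n/K)/2$ (INCT)
for maximum-tolerated-imbalance procedures — once an imbalance of $m$ is
reached, up to $2m$ consecutive assignments can go to the lagging arm,
which a small stage cannot absorb.
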