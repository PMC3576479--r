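---
title: "Permutation inference for unplanned adaptations made before unblinding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation inference for unplanned adaptations made before unblinding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permadapt)
```

## The problem

Clinical trials occasionally need a change that nobody planned: the primary
endpoint turns out to be measured unreliably, lumped data reveal outliers that
undermine the planned t-test, or so few events occur that the planned test of
proportions cannot possibly reach significance. If such a change is made
*after* the treatment blind is broken, the type I error is compromised in a
way no analysis can repair. If it is made *before* unblinding, a permutation
(randomization) test of the modified analysis remains valid — and this package
implements that argument as working, testable code.

The reasoning is conditional. A permutation test conditions on the outcome
data $Y = y$; the only randomness left is the treatment assignment vector $Z$.
Every assignment $z$ consistent with the randomization scheme is equally
likely, and the p-value refers the observed statistic $t(y, z_{\text{obs}})$
to the set $\{t(y, z)\}$ over consistent $z$:

$$p = \frac{\#\{z : t(y,z) \text{ at least as extreme as } t(y,z_{\text{obs}})\}}{\#\{\text{consistent } z\}}.$$

Any decision taken before unblinding is a function of the lumped data $X$
(pooled outcomes without labels). Under the strong null hypothesis — treatment
affects nothing that was examined — $X$ is independent of $Z$, so the
conditional type I error rate given each possible adaptation (including "no
change") stays at or below $\alpha$, and therefore so does the unconditional
rate. The package's modules mirror the pieces of this argument: test
statistics, the permutation engine, the blinded-view contract with a rule
catalog, conditional-error computations, and a simulation laboratory.

## Test statistics and their orientation

Each statistic (`diff_means`, `diff_props`, `wilcoxon`, `signed_rank`)
carries its own one-sided orientation: `"smaller"` means smaller values favor
treatment (a blood-pressure drop, fewer events). The engine reads the
direction off the statistic rather than taking it per call, which prevents
sign errors when an adaptation rule swaps statistics mid-stream.

Missing values are handled available-case, per endpoint, and the number of
exclusions is attached to every evaluation: missingness counts are themselves
data a blinded decision may have looked at, so they are never silently
discarded. Ties receive mid-ranks (the standard Wilcoxon convention). The
paired signed-rank statistic excludes zero differences before ranking; if
*every* difference is zero the statistic is degenerate, which the engine
reports as $p = 1$ with a flag rather than an error — a trial in which most
paired differences vanish is answering its own question, and the flag makes
that visible instead of burying it.

## The permutation engine

**Exact mode** enumerates all consistent assignment vectors (the product over
strata of binomial coefficients) up to a cap of $10^6$ vectors, evaluates the
statistic on each, and reports the p-value together with the full grid of
attainable p-values. Beyond the cap the engine refuses and directs the caller
to Monte Carlo: the cap keeps exact guarantees explicit rather than silently
approximate.

**Monte-Carlo mode** samples `B` consistent vectors uniformly (independent
Fisher–Yates draws within each stratum) and uses the add-one estimator
$(1 + k)/(1 + B)$, which never reports 0 and keeps the randomized test valid
at any `B`.

**Ties at the observed statistic** count as extreme, compared with a relative
tolerance of $10^{-12}$ — conservative and reproducible for floating-point
statistics. The same tolerance guards every comparison of a p-value against
$\alpha$, so a p-value that equals $\alpha$ exactly (common in discrete
designs: $1/\binom{6}{3} = 0.05$) is a rejection.

**Attainable size.** `attainable_size()` computes the conditional size of the
level-$\alpha$ exact test given the outcomes: the fraction of consistent
vectors whose own p-value is $\le \alpha$. Because exact p-values are uniform
on their attainable grid, this can never exceed $\alpha$; the test suite
verifies the inequality exhaustively on all binary designs up to $n = 8$
across a grid of levels.

Two-sided analyses, where needed, are expressed as a separate direction-free
statistic (the absolute difference with `"larger"` orientation) rather than by
doubling a one-sided p-value; the designs studied here are one-sided
throughout, matching the worked binary example below.

## Blinded views and the rule catalog

`blinded_view()` is a contract, not a convention: the object physically
contains the pooled outcome matrix with arm labels removed, per-endpoint
missingness counts, the total and per-stratum sizes — and nothing else.
Per-arm counts never pass through it. Subject order is shuffled by a keyed
permutation whose key is a digest of the outcome values themselves, so
enrollment order cannot act as a side channel, and a trial and its
arm-relabeled copy produce bit-identical views. A property test drives every
shipped rule over a thousand random trials and their relabeled copies and
requires identical decisions.

Blinding hides labels, not values. A drug-level endpoint — positive in every
treated subject, zero in every control — passes untouched through the view,
which is precisely the leak the adversarial rules exploit.

The shipped rules, with their tunable parameters:

* `rule_min_variance(candidates)` — picks the candidate endpoint with the
  smallest lumped variance (available cases); ties go to the earlier
  candidate. Tie-breaks throughout the catalog are by configured candidate
  order: deterministic and auditable.
* `rule_outlier_switch(k = 5)` — switches the planned t-type analysis to the
  Wilcoxon rank sum if any lumped value sits more than `k` consistency-scaled
  median absolute deviations from the lumped median. With the scaling
  constant, `k` plays the role of a z-score cut, and `k = 5` triggers on
  fewer than 1% of clean Gaussian samples of 100 while catching any gross
  outlier. If the MAD degenerates to zero on non-constant data the criterion
  falls back to the interquartile range, and if that is zero too, any value
  off the median counts as an outlier (in that regime more than three
  quarters of the data sit exactly at the median, so a far value is an
  outlier by any reasonable standard). No unblinded criterion for "apparent
  outliers" exists in practice either; `k` is exposed as a parameter for
  exactly that reason.
* `rule_threshold_feasibility(fallback_threshold, scheme)` — for an endpoint
  "source $\ge$ threshold": the lumped event total $m$ determines the best
  one-sided Fisher p-value any split could attain (all $m$ events in the
  unfavorable arm, $p_{\min} = \binom{n_C}{m}/\binom{n}{m}$ for the
  fewer-events-on-treatment direction). If even $p_{\min} > \alpha$,
  significance is literally impossible and the endpoint is re-derived at the
  clinically acceptable fallback threshold; if the fallback is also
  infeasible the plan stands, with a warning. The per-arm sizes it needs are
  design constants, known without unblinding.
* `rule_drug_level_adversary(drug, candidates)` — reconstructs arm labels
  from the drug level, evaluates each clinical endpoint under the
  reconstructed labels, and picks the most favorable. Flagged adversarial;
  it exists so the simulation laboratory can measure the inflation it causes.
* `rule_correlation_leak(drug, candidates)` — reads only two lumped summary
  numbers, the correlations between drug level and each clinical endpoint,
  and picks the larger in absolute value. Through the point-biserial identity
  $r^2 = t^2/(t^2 + \mathrm{df})$ the absolute correlation orders endpoints
  by $|t|$, so two summary statistics suffice to find the endpoint with the
  stronger apparent effect — summary measures are no safeguard. (The signed
  one-sided preference of the row-level adversary is *not* recoverable from
  absolute correlations; the property test therefore checks agreement with
  the larger-$|t|$ endpoint, which is what this leak can and does deduce.)

`run_adaptive_analysis()` wires these together: rule on the view, chosen plan
into the engine (stratified automatically when the trial has more than one
stratum), $\alpha$ frozen at its design value — a rule that tries to modify
$\alpha$ is silently overruled, because changing the level would break the
conditional-error argument the whole construction rests on. The decision
record carries the rule's declared inputs: a significant result rejects only
"no effect on any data the rule examined", and the record makes that scope
explicit.

## Stratification: when per-arm counts are known

If the per-arm sample sizes at the adaptation time were known, complete
blinding is lost and the plain permutation test is no longer guaranteed
conditionally valid. The worked 6-subject binary example makes this concrete:
three control patients enrolled first, all with events, then three treatment
patients. The plain test gives $p = 1/\binom{6}{3} = 0.05$. But knowing the
interim counts (0 T, 3 C), the conditional probability that the original
design rejects is $(1 - p_T)^3$ — up to 1 as $p_T \to 0$, far above 0.05 —
while with one early event rejection is already impossible and the
conditional probability is 0, an invitation to expand the sample size and buy
the error back. The stratified permutation test conditions on the per-stage
per-arm counts and removes the leak: in the example it leaves a single
consistent assignment and $p = 1$.

`simulate_size_adversary()` implements the buying-back strategy concretely,
since its narrative form has no parameters: the adversary observes the
first-stage per-arm counts and the lumped event total, averages the
conditional rejection probability over the (hypergeometric) unknown split of
events across arms, and — only when that probability is exactly 0 — extends
the second stage by up to `extension_cap` (default 8) extra subjects, chosen
to maximize it. At the 3-vs-3 design with $p = 0.5$ and $\alpha = 0.05$ this
roughly doubles the plain test's rejection rate (about 0.030 at 10,000
replications) relative to the fixed design's exact size
$0.5^6 = 0.015625$. Two numerical facts about this design are worth stating
plainly, because both look surprising and both are exactly right:

* the adversary cannot push the plain test all the way above the *nominal*
  5% here: branches with positive conditional error contribute their
  original total of 0.0156, each zero branch can be pushed at most toward
  $\alpha$, and zero branches occur with probability about 0.65, bounding
  the total near $0.65 \times 0.05 + 0.0156 < 0.05$. The inflation — the
  thing the stratified test exists to prevent — is relative to the design's
  own size, and the suite asserts it that way;
* the stratified test's measured rate at this design is exactly 0, because
  its attainable p-values are bounded below by $1/9 > 0.05$ for every
  realizable interim split. Total conservatism is the price of conditioning
  in a six-subject design; the point of the design is the guarantee, and the
  guarantee holds.

## Conditional error computations

`conditional_rejection_probability()` enumerates the second stage of a
partially observed binary design exactly. Every second-stage outcome vector
in $\{0,1\}^{n_{T2}+n_{C2}}$ carries its Bernoulli probability; because the
final Fisher-equivalent test depends on outcomes only through per-arm event
counts, the vector sum is aggregated by counts with binomial-coefficient
weights — an identical reformulation, not an approximation, and the test
suite keeps a genuine per-vector enumeration oracle to prove it. Designs past
$2^{20}$ second-stage vectors fall back to seeded Monte Carlo with a reported
standard error. A law-of-total-probability test confirms that integrating the
conditional probability over first-stage data recovers the design's
unconditional size.

`switching_adversary()` formalizes the theoretical loophole when a
permutation test was *not* pre-planned: keep the original design when its
conditional error given the lumped data exceeds $\alpha$, switch to a
permutation test otherwise. The switch branch is always controlled; the
no-change branch can exceed $\alpha$ only when the original test is
approximate. The shipped miscalibrated original is the pooled
normal-approximation z-test of proportions (`prop_ztest`) — chosen because an
approximate nominal-level test is exactly what the exact permutation test is
being contrasted with — and the record exposes both branch error rates. For
large trials the distinction evaporates: the suite verifies that the
permutation p-value and the pooled-variance t-test p-value differ by less
than 0.01 at 100 subjects per arm, which is why "pretend the permutation test
was planned all along" is an honest large-sample argument.

## The synthetic trial generator

The generator is the package's study-condition registry, not a convenience:
its defaults are the conditions under which every reported operating
characteristic is measured.

* Continuous endpoints are Gaussian with arm-specific means and a shared
  exchangeable correlation (Gaussian copula) — the simplest joint structure
  that supports endpoint-selection scenarios. No published outcome
  distribution exists for the motivating feeding-trial narrative, so margins
  default to unit-variance Gaussians and scenario configs state means and
  SDs explicitly.
* Binary endpoints are independent Bernoulli; the worked designs use
  $p = 0.5$ in both arms under the strong null.
* The drug-level endpoint is log-normal in treated subjects and exactly zero
  in controls: the cleanest possible unblinding leak.
* Missingness is Bernoulli per endpoint per arm; arm-dependent rates are
  supported explicitly because differential missingness is the recognized
  failure mode — with it, the examined variables always number more than
  two, and inflation can no longer be ruled out. The suite *records* the
  rejection rate under an informative-missingness scenario rather than
  asserting a bound, since no quantitative claim is available to check.
* Two enrollment modes: fixed per-stratum arm counts, or complete
  randomization with a known interim (`split_after`), which is how the
  stratified design studies are generated.

What the generator does not emulate — longitudinal measurement, covariates,
dropout over time, real blood-pressure scales — bounds what passing
simulations show: they validate the inferential machinery under the stated
conditions, not the clinical realism of any particular trial.

Scale choices, made once: operating characteristics use 10,000 replications
(binomial SE $\approx 0.0022$ at a rate of 0.05, enough to separate 0.05 from
meaningful inflation); continuous selection scenarios use 5 subjects per arm
(252 consistent assignments, so the attainable 5% level is $12/252 = 0.0476$
and exact enumeration is instant); weak-null scenarios shift the affected
endpoint by one standard deviation, a conventionally "large" standardized
effect that makes the affected/unaffected distinction visible at these sizes.
Per-replication RNG streams are derived from (seed, replication index), so a
scenario's results do not depend on evaluation order.

## Limitations

* Validity rests on the strong null over everything examined; rejection
  never localizes the effect to the adapted endpoint. The decision record
  states this, but no software can restore the sharper conclusion.
* No treatment-effect estimate is adjusted: without a pre-specified
  adaptation space there is no bias correction to apply, and the package
  deliberately offers none.
* Survival and longitudinal outcomes, more than two arms, and
  covariate-adaptive randomization are out of scope; the stratified engine
  covers stratum-count-preserving schemes only.
* Exact conditional-error computations are limited to binary outcomes;
  continuous analogues would require distributional assumptions the
  methodology avoids.
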