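# permadapt

Permutation tests for unplanned adaptations made in a randomized trial
*before breaking the treatment blind* — and a laboratory for measuring when
the type I error is, and is not, controlled.

## Who this is for

Trial statisticians and methodologists facing (or studying) mid-trial
surprises: an endpoint that turns out to be measured unreliably, lumped data
with outliers that undermine a planned t-test, an event threshold so strict
that significance has become arithmetically impossible. If the remedy is
decided while everyone is still blinded, a permutation test of the modified
analysis remains valid; this package implements that machinery and the
adversarial counterexamples that mark its limits.

## The core idea

A permutation (randomization) test conditions on the outcomes $Y = y$; the
only randomness left is the assignment vector $Z$. With every consistent
assignment equally likely,

$$p \;=\; \frac{\#\{z : t(y,z)\ \text{at least as extreme as}\ t(y,z_{\mathrm{obs}})\}}{\#\{\text{consistent } z\}} .$$

Any adaptation made before unblinding is a function of the lumped, label-free
data $X$. Under the strong null (treatment affects nothing that was
examined), $X \perp Z$, so the conditional type I error rate given each
possible adaptation — including "no change" — is at most $\alpha$, and the
unconditional rate follows. Two refinements matter in practice:

* **Per-arm counts known at the interim** break complete blinding. The fix is
  the *stratified* permutation test, restricted to assignments preserving the
  per-arm counts both before and after the adaptation
  (`stratified_permutation_pvalue()`).
* **Rejection scope**: a significant adaptive analysis rejects "no effect on
  *any* data the rule examined" — the decision record produced by
  `run_adaptive_analysis()` lists exactly what that was.

On binary outcomes the exact test is Fisher's exact test
(`fisher_exact_one_sided()`, equality verified exhaustively in the test
suite); in large samples it is nearly the pooled-variance t-test.

## Worked example

The 6-subject binary design: three control patients enrolled first, all with
events, then three treatment patients, none with an event. One-sided test,
fewer events favoring treatment, $\alpha = 0.05$.

```r
library(permadapt)
y <- c(1, 1, 1, 0, 0, 0)
z <- c("C", "C", "C", "T", "T", "T")

permutation_pvalue(y, z, statistic = "diff_props")
#> exact permutation test (diff_props, smaller values favor treatment)
#>   observed statistic = -1 over 20 assignments
#>   p-value = 0.05
```

The plain test is significant: the observed split is the single most extreme
of the $\binom{6}{3} = 20$ consistent assignments. But if the 0-vs-3 interim
split was *known*, the assignment was not exchangeable across stages — the
stratified test conditions on the per-stage counts:

```r
stratified_permutation_pvalue(y, z, stratum = c(1, 1, 1, 2, 2, 2),
                              statistic = "diff_props")
#> Stratified exact permutation test (diff_props, smaller values favor treatment)
#>   observed statistic = -1 over 1 assignments
#>   p-value = 1
```

Only one assignment is consistent with both stage counts, so nothing was
random and nothing is significant. The danger of the unstratified analysis is
quantified by the conditional error of the original design given the interim:

```r
conditional_rejection_probability(interim_state(
  n_T1 = 0, n_C1 = 3, events_T1 = 0, events_C1 = 3,
  n_T2 = 3, n_C2 = 0, p_T = 0.5))
#> [1] 0.125
```

Given three early control events, the fixed design rejects with probability
$(1 - p_T)^3$ — 0.125 at $p_T = 0.5$, approaching 1 as $p_T \to 0$, far above
the nominal 5%. Conversely the exact permutation test can never overspend:

```r
attainable_size(y, "diff_props", randomization_scheme(3, 3), alpha = 0.05)
#> [1] 0.05
```

An adaptive analysis end to end — blinded endpoint selection by smallest
lumped variance under a strong null, from a shipped scenario file:

```r
sc <- read_scenario(system.file("extdata", "two_outcome_scenario.json",
                                package = "permadapt"))
simulate_rejection_rate(sc)
#> Scenario 'two-outcome-selection-strong-null' (strong null): rejection rate 0.0410 (MC SE 0.0044, 2000 reps)
#>   branches: dbp_change/diff_means 0.974; sbp_change/diff_means 0.026
```

The rule selects an endpoint in every replication, yet the rejection rate
stays at the attainable 5% level (here $12/252 \approx 0.048$): blinded
selection between two complete outcomes cannot inflate the error. The
adversarial rules (`rule_drug_level_adversary()`, `rule_correlation_leak()`)
and `simulate_size_adversary()` show the counterpoint — what goes wrong when
a "blinded" quantity leaks arm information, and how stratification repairs
the per-arm-counts leak.

A thin command-line front end over the same functions lives at
`inst/cli/permadapt.R` (subcommands `generate`, `permtest`, `adapt`,
`conderror`, `simulate`).

## Documentation

The methods vignette (`vignettes/blinded-adaptation.Rmd`) covers the model
and its assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, numerical choices
(tie tolerances, enumeration caps, add-one Monte-Carlo estimator), and known
limitations.
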