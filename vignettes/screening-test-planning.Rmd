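---
title: "Evaluating and planning binary screening tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and planning binary screening tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenplan)
library(dplyr)
```

## The problem

Internet-based listening experiments often require a specific playback
device — typically headphones rather than loudspeakers — but the
experimenter cannot verify the device directly. Short psychoacoustic
screening tests (binaural cues that only survive headphone playback,
phase-cancellation stimuli that only occur over loudspeakers) give a
noisy binary signal. screenplan treats such a test as a binary
classifier and provides the full evaluation and planning chain: test
characteristics with confidence intervals, prevalence-adjusted
predictive values, ROC/AUC, parallel combination of up to three tests,
and binomial sample-size planning for three field strategies.

Although the vocabulary here is headphones versus loudspeakers, nothing
in the package is specific to audio: any binary screening rule scored
against a known truth fits.

## The model

A screening test applied to a participant with known device yields the
standard confusion matrix, from which sensitivity ($Sen = TP/(TP+FN)$,
the hit rate given headphones) and specificity ($Spe = TN/(TN+FP)$, the
correct-rejection rate given loudspeakers) follow. These are properties
of the test alone. What an experimenter actually cares about — the
probability that a test-positive participant really used headphones —
additionally depends on the prevalence $\pi$ of headphone use in the
screened population:

$$PPV = \frac{Sen\,\pi}{Sen\,\pi + (1-Spe)(1-\pi)}.$$

The package's planning layer is built on one further observation: in a
sample of $n$ participants accepted by a screening rule, the number $H$
of true headphone users is $\mathrm{Binomial}(n, p)$ with $p$ the
rule's PPV (or the SCC success probability below). Everything else —
post-hoc data-quality bounds, a-priori sample sizes, certainty levels —
is exact binomial-tail arithmetic on that model.

### Tests as thresholded trial counts

Each test consists of $T$ trials (six in the packaged main-study table,
four in the pre-study table) and is declared positive when at least $t$
trials are answered correctly. Sensitivity and specificity are therefore
non-increasing in $t$, which is what makes the per-threshold ROC curve
meaningful. `accuracy_from_responses()` applies this rule to item-level
data; `halt_characteristics()` ships the published per-threshold tables
of the three headphone screening tests (A: interaural time differences,
B: Franssen effect, C: destructive interference), stored as the printed
one-decimal percentages with group sizes 80/131 (main study) and 80/80
(pre-study). On load the integer counts are reconstructed from
percentage × group size and verified to re-round to the printed value;
all downstream arithmetic uses the full-precision count ratios. This
count-reconstruction convention is what reproduces the published AUC
values to three decimals; integrating the rounded percentages directly
does not (it is off in the third decimal for one test).

### ROC curves

`roc_points()` plots each threshold at $(1-Spe, Sen)$ and always adds
the anchors $(0,0)$ and $(1,1)$; `auc_trapezoid()` integrates the
polyline. The anchors are a deliberate convention: a finite threshold
set never spans the unit square on its own, and only the anchored
curve reproduces the published areas. No convex-hull correction or
smooth (binormal) fit is applied — the curve is the raw empirical one.

```{r roc}
main <- halt_characteristics("mainstudy")
sapply(c("testA", "testB", "testC"),
       function(t) round(auc_trapezoid(roc_points(main, t)), 3))
```

## Combining tests: weighted voting rules

Up to three tests run in parallel are combined by a weighted vote: the
global result is positive when $\omega_A A + \omega_B B + \omega_C C
\ge 1$. Eighteen logically distinct rules exist (3 singles, AND and OR
per pair, and AND / OR / majority / (X∨Y)∧Z / (X∧Y)∨Z for the triple),
each catalogued under an integer evaluation key (EK) by `combiners()`.
The numbering fixes EK 11 as the majority vote, EK 12 as the three-way
AND and EK 13 as (A∨B)∧C, with singles at 1–3, pairwise ANDs at 4–6
and ORs at 7–9; since only those anchor points are externally fixed,
the remaining order (OR-triple at 10, the rotations at 13–18) is this
package's documented convention. Weights are stored as integer twelfths
so the vote threshold is exact integer arithmetic — no floating-point
tie can flip a vote. With six thresholds per test the procedure space
has $3\cdot6 + 6\cdot6^2 + 9\cdot6^3 = 2{,}178$ members
(`procedures(6)`).

Two routes give a combination's characteristics:

* `combine_independent()` multiplies per-test marginals within each
  device stratum and sums outcome-tuple probabilities over the vote's
  truth table. This is only valid under conditional independence of
  the tests given the true device, so when item-level data are passed
  alongside, every involved pair is first checked with
  `conditional_independence_test()` and the product rule refuses to
  run if independence is rejected.
* `combine_empirical()` treats the combination as a single test on
  item-level data and needs no independence assumption.

The independence check uses a chi-square test on the within-stratum
2×2 table, switching to an exact multinomial test (all four-cell
compositions enumerated under the margin-estimated null) whenever an
expected cell drops below 5. The default $\alpha = .10$ is
deliberately high: the *null* is what licenses the product rule, so
the test is tuned to protect against falsely retaining it. No
continuity correction is applied by default (`correct = FALSE`),
matching the uncorrected statistic's better calibration at these
stratum sizes; it is exposed as an option.

## Screening strategies and sample-size planning

Three field strategies are supported:

* **FWR** (Filter Without Request): screen everyone without revealing
  the required device; success probability of an accepted participant
  is the PPV at the raw prevalence.
* **FAR** (Filter After Request): request headphones first, then
  screen; the prevalence entering the PPV is the (estimated)
  post-request rate.
* **SCC** (Split–Convince–Compare): trust the unbiased self-report
  (group D1 enters unscreened), prompt the rest, and accept prompted
  participants only on a positive test (D0⁺). The success probability
  is

$$\tilde p = \frac{\hat\pi + (1-\hat\pi)\hat\varsigma\,Sen}
 {\hat\pi + (1-\hat\pi)\left(\hat\varsigma\,Sen +
 (1-\hat\varsigma)(1-Spe)\right)},$$

with $\hat\varsigma$ the switching prevalence — the probability that a
prompted non-headphone user actually switches.

Given a target of $k$ true users and a certainty $\vartheta$,
`required_n()` inverts the binomial tail. For $\vartheta > 0.5$ it uses
the de Moivre–Laplace normal approximation with continuity correction,

$$n = -\tfrac{a}{2} + \sqrt{(\tfrac{a}{2})^2 - b}, \quad
a = -\tfrac{1}{p}\bigl(2k - 1 + (1-p)\,\Phi^{-1}(1-\vartheta)^2\bigr),
\quad b = \tfrac{(k-0.5)^2}{p^2},$$

rounded *up* (the worked planning example, 73.74 → 74, fixes ceiling
as the convention) and floored at $k$. Outside that domain — $\vartheta
\le 0.5$, where the formula's derivation does not hold, or a negative
discriminant — the package silently switches to an exact bisection on
the binomial tail and records which path produced each value in the
`method` attribute. Across a grid $k \in \{5..200\}$, $\vartheta \in
\{0.6..0.95\}$, $p \in \{0.5..0.99\}$ the approximation stays within
±1 of the exact answer (this is asserted in the test suite).

`plan_screening()` applies this per candidate procedure and ranks by
smallest $n$ (equivalently, best data quality per accepted
participant) or by overall utility
$U = \pi Sen\,U_{TP} + \pi(1-Sen)U_{FN} + (1-\pi)Spe\,U_{TN} +
(1-\pi)(1-Spe)U_{FP}$, evaluated at $\hat\varsigma$ instead of
$\hat\pi$ for SCC because the screening only acts on the prompted
group. Default utilities are (1,0,1,0) — plain classification accuracy.
Ties break deterministically: fewer involved tests first, then the
lexicographic procedure spec. `posthoc_quality()` runs the same
binomial logic backwards after data collection; for SCC, D1 is counted
at quality 1 and only D0⁺ carries binomial uncertainty.

```{r plan}
cand <- tibble::tibble(spec = "EK6:B3,C5", ek = 6,
                       sen = 0.8625, spe = 0.8473)
plan <- plan_screening(cand, strategy = "SCC", k = 70, theta = 0.80,
                       pi_hat = halt_prevalence("B")$pi_hat,
                       sigma_hat = 0.55)
glance(plan)
```

## The synthetic-cohort generator

`simulate_cohort()` draws the population the framework assumes: device
$\sim$ Bernoulli($\pi$), truthful self-report (a misreport probability
exists but defaults to 0, matching the unbiased-self-report assumption
of SCC), post-request switching with probability $\varsigma$, and
per-trial correctness Bernoulli($q$) given the actual device. Defaults
are the published study conditions: $\pi = 0.1767$ (the
wide-population base rate), $\varsigma = 0.55$, six trials per test,
and per-trial probabilities solved so each test's threshold-5
characteristics match the main-study table.

Two things the generator deliberately does *not* emulate: participant
heterogeneity in ability (real per-threshold profiles are flatter than
a single-$q$ binomial — a binomial trial model cannot match a test's
printed sensitivity at every threshold simultaneously, which is why
defaults are calibrated at one threshold), and any psychoacoustics of
the stimuli. Passing recovery tests therefore validate the estimators
under the framework's own assumptions, not the field behaviour of a
particular stimulus.

Dependence between trials and between tests — observed empirically in
real data but with no published magnitude — is modelled minimally: one
shared uniform draw per participant generates comonotone latent
outcomes across tests, and each trial copies its test's latent outcome
with probability `dependence` (else an independent Bernoulli draw).
Marginals are untouched; `dependence = 0` restores full conditional
independence. This is exactly enough to exercise the
empirical-combination fallback: at `dependence = 0.8` the product rule
and the empirical combination separate by far more than sampling
error, and the independence test rejects.

`run_strategy_sim()` closes the loop: it streams simulated
participants through a strategy until the planned number of accepted
participants is reached and reports, per replicate, the empirical
success probability and whether $k$ true users were obtained. The test
suite uses it to confirm that planned sample sizes honour $\vartheta$
within Monte-Carlo error.

## Numerical conventions and problem sizes

* Confidence intervals are Wilson score intervals with the exact
  normal quantile $z = \Phi^{-1}(1-\alpha/2)$; at one-decimal rounding
  the printed reference intervals are equally consistent with
  $z = 1.96$, so the choice is cosmetic. Bounds are clamped to the
  unit interval and always contain the point estimate.
* Sensitivity or specificity of an *empty* truth group is an error,
  never 0: an empty group signals malformed input.
* Table output is computed at full precision; percentages are rounded
  to one decimal only for display.
* The suite's simulation sizes are chosen to make 3-standard-error
  assertions sharp at ordinary laptop runtimes: recovery cohorts of
  10,000 per device group, 1,000 replicates for the certainty check,
  400 replicates for the independence-test calibration.

## Known limitations

* The evaluation-key numbering beyond the anchored keys (6, 11, 12,
  13) is a package convention; tables indexed by other conventions
  must be remapped via the `ek` column.
* The planner takes candidate characteristics as given; uncertainty in
  $Sen$, $Spe$, $\hat\pi$, $\hat\varsigma$ is not propagated into $n$.
  Planning at a CI bound instead of the point estimate is the
  practical workaround.
* Only parallel combination is supported — no sequential (gated)
  testing, no cost model beyond unit-interval utilities.
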