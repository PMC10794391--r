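# screenplan

Evaluation and planning of binary screening tests, built for the common
situation in Internet-based listening experiments where the playback
device (headphones vs. loudspeakers) must be verified by a short
psychoacoustic test rather than by direct observation. The package is
general to any binary screening rule scored against a known truth; the
shipped reference tables come from published headphone-screening
studies.

## What it computes

For a single test (a series of T trials, positive when at least *t*
are correct):

- sensitivity and specificity with Wilson score confidence intervals,
- prevalence-adjusted predictive values
  `PPV = Sen·π / (Sen·π + (1−Spe)(1−π))` and the analogous NPV,
- utility-weighted evaluation
  `U = π·Sen·U_TP + π(1−Sen)·U_FN + (1−π)·Spe·U_TN + (1−π)(1−Spe)·U_FP`,
- anchored empirical ROC curves and trapezoidal AUC.

For combinations of up to three parallel tests, a catalogue of 18
weighted voting rules (`G = 1` iff `ω_A·A + ω_B·B + ω_C·C ≥ 1`), with
characteristics computed either by the product rule under conditional
independence (checked by chi-square / exact multinomial tests and
refused when rejected) or empirically from item-level data. With six
thresholds per test the procedure space has 2,178 members.

For study planning, the accepted sample is modelled as Binomial(n, p)
with p the PPV (or the Split–Convince–Compare success probability
p̃), and the package inverts the exact binomial tail — via the de
Moivre–Laplace normal approximation with continuity correction where
valid — to answer: how many accepted participants are needed so that,
with certainty ϑ, at least k of them truly use the target device?
Three field strategies are supported (Filter Without Request, Filter
After Request, Split–Convince–Compare), plus post-hoc data-quality
bounds and a seeded synthetic-cohort simulator for end-to-end
validation.

## Worked example

Plan a Split–Convince–Compare study that needs k = 70 verified
headphone users with certainty ϑ = 0.80, using the packaged
wide-population prevalence estimate and a switching prevalence of 55%:

```r
library(screenplan)

halt_prevalence("B")
#> # A tibble: 1 × 6
#>   label n_headphones n_total pi_hat lower upper
#>   <chr>        <int>   <int>  <dbl> <dbl> <dbl>
#> 1 B              211    1194  0.177 0.156 0.199

cand <- tibble::tibble(spec = "EK6:B3,C5", ek = 6,
                       sen = 0.8625, spe = 0.8473)
plan <- plan_screening(cand, strategy = "SCC", k = 70, theta = 0.80,
                       pi_hat = 0.1767, sigma_hat = 0.55)
plan
#> Screening plan (SCC strategy, criterion min_n)
#>   target k = 70 true users at certainty theta = 0.80
#>   prevalence estimate = 0.1767, switching prevalence = 0.5500
#>   selected: EK6:B3,C5  (success prob 0.9093, n = 79, utility 0.8557)
#>   1 candidate(s) ranked; tidy() for the full table
```

Reading: the candidate procedure is the pairwise AND of Test B
(threshold 3) and Test C (threshold 5) with its published empirical
combined characteristics. An accepted participant — someone who either
self-reported headphones or tested positive after being prompted — is
a true headphone user with probability 0.909, so 79 accepted
participants suffice for at least 70 true users with 80% certainty. A
procedure with success probability 0.9614 would need only 74
(`required_n(70, 0.80, 0.9614)`).
`tidy(plan)` returns the ranked candidate table, `glance(plan)` a
one-row summary, and `autoplot(plan)` plots required n against success
probability.

The evaluation side runs the other way — from data to
characteristics:

```r
main <- halt_characteristics("mainstudy")       # published table, counts reconstructed
auc_trapezoid(roc_points(main, "testA"))
#> [1] 0.7682729

coh <- simulate_cohort(cohort_spec(n = 2000), seed = 1)
accuracy_table(coh) |> dplyr::filter(threshold == 5)
combine_empirical(coh, ek = 11, thr_a = 5, thr_b = 5, thr_c = 6)
```

A thin command-line front end for shell use lives at
`inst/cli/screenplan.R` (subcommands `eval`, `roc`, `combine`, `plan`,
`posthoc`, `simulate`).

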