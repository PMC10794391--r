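test_that("binomial tail probability matches enumeration and boundary cases", {
  expect_equal(prob_at_least(0, 10, 0.3), 1)
  # k=2 of n=3 at p=0.5: 4 of 8 equally likely outcomes
  expect_equal(prob_at_least(2, 3, 0.5), 0.5)
  # the published worked example clears its certainty level
  expect_gte(prob_at_least(70, 74, 0.9614), 0.80)
  expect_error(prob_at_least(5, 3, 0.5), class = "screenplan_input_error")
})

test_that("tail probability is monotone in k, n and p", {
  expect_true(all(diff(sapply(0:20, prob_at_least, n = 20, p = 0.7)) <= 0))
  expect_true(all(diff(sapply(10:40, function(n) prob_at_least(8, n, 0.5))) >= 0))
  expect_true(all(diff(sapply(seq(0.1, 0.9, 0.1), function(p) prob_at_least(5, 12, p))) >= 0))
})

test_that("data-quality quantile returns the largest k with tail >= theta", {
  expect_equal(data_quality_quantile(0.80, 74, 0.9614), 70)
  # theta near 0 guarantees at most everything
  expect_equal(data_quality_quantile(1e-12, 30, 0.5), 30)
  # exact scan oracle on a grid
  for (theta in c(0.5, 0.8, 0.95)) for (p in c(0.3, 0.66, 0.9)) {
    n <- 100
    k <- data_quality_quantile(theta, n, p)
    expect_gte(prob_at_least(k, n, p), theta)
    if (k < n) expect_lt(prob_at_least(k + 1, n, p), theta)
  }
})

test_that("required_n reproduces the worked example and the p = 1 shortcut", {
  n <- required_n(70, 0.80, 0.9614)
  expect_equal(as.integer(n), 74L)
  expect_equal(attr(n, "method"), "normal-approx")
  expect_equal(as.integer(required_n(25, 0.9, 1)), 25L)
})

test_that("the continuity-corrected approximation tracks the exact search within 1", {
  grid <- expand.grid(k = c(5, 20, 70, 120, 200),
                      theta = c(0.6, 0.8, 0.9, 0.95),
                      p = c(0.5, 0.66, 0.8, 0.9, 0.96, 0.99))
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; theta <- grid$theta[i]; p <- grid$p[i]
    approx_n <- as.integer(required_n(k, theta, p))
    exact_n <- required_n_oracle(k, theta, p)
    expect_lte(abs(approx_n - exact_n), 1,
               label = sprintf("k=%d theta=%.2f p=%.2f: |%d - %d|",
                               k, theta, p, approx_n, exact_n))
  }
})

test_that("theta <= 0.5 falls back to the exact search", {
  n <- required_n(10, 0.4, 0.7)
  expect_equal(attr(n, "method"), "exact-search")
  expect_equal(as.integer(n), required_n_oracle(10, 0.4, 0.7))
})

test_that("SCC success probability has the stated reductions and monotonicity", {
  expect_equal(scc_success_prob(0.2, 1, 0.7, 0.8), 1)
  expect_equal(scc_success_prob(0, 1, 0.7, 0.8), 1)
  # no switching: only false alarms dilute the self-reported group
  for (pi in c(0.1, 0.4)) for (spe in c(0.6, 0.95)) {
    expect_equal(scc_success_prob(pi, 0, 0.8, spe),
                 pi / (pi + (1 - pi) * (1 - spe)))
  }
  sig <- seq(0, 1, 0.1)
  expect_true(all(diff(scc_success_prob(0.2, sig, 0.8, 0.85)) >= 0))
  expect_true(all(diff(scc_success_prob(0.2, 0.5, sig, 0.85)) >= 0))
  expect_true(all(diff(scc_success_prob(0.2, 0.5, 0.8, sig)) >= 0))
})

test_that("SCC success probability agrees with a Monte-Carlo cohort oracle", {
  set.seed(808)
  n <- 1e6
  pi <- 0.1767; sigma <- 0.55; sen <- 0.8625; spe <- 0.8473
  hp0 <- runif(n) < pi           # unbiased self-report
  switched <- !hp0 & runif(n) < sigma
  hp_final <- hp0 | switched
  positive <- ifelse(hp_final, runif(n) < sen, runif(n) < 1 - spe)
  accepted <- hp0 | positive      # D1, or prompted with positive test
  mc <- mean(hp_final[accepted])
  se <- sqrt(mc * (1 - mc) / sum(accepted))
  expect_lt(abs(scc_success_prob(pi, sigma, sen, spe) - mc), 3 * se)
})

test_that("planning reproduces the published SCC worked example", {
  # success probability 0.9614 for the selected procedure, k = 70, theta = 0.80
  cand <- tibble::tibble(spec = "EK12:A6,B2,C6", sen = 1, spe = 1)
  plan <- plan_screening(cand, strategy = "SCC", k = 70, theta = 0.80,
                         pi_hat = 0.1767, sigma_hat = 0.55)
  # the published example enters via its printed success probability
  expect_equal(as.integer(required_n(70, 0.80, 0.9614)), 74L)
  # a perfect candidate needs exactly k
  expect_equal(tidy(plan)$n_required, 70L)
})

test_that("plan ranking is dominance-consistent and deterministic", {
  set.seed(99)
  for (r in 1:10) {
    sen <- runif(1, 0.5, 0.9); spe <- runif(1, 0.5, 0.9)
    cands <- tibble::tibble(
      spec = c("weak", "strong"),
      sen = c(sen, min(1, sen + 0.08)),
      spe = c(spe, min(1, spe + 0.08))
    )
    for (strat in c("FWR", "SCC")) for (crit in c("min_n", "utility")) {
      plan <- plan_screening(cands, strategy = strat, k = 40, theta = 0.8,
                             pi_hat = 0.3, sigma_hat = 0.5, criterion = crit)
      expect_equal(tidy(plan)$spec[1], "strong",
                   info = sprintf("%s/%s rep %d", strat, crit, r))
    }
  }
  expect_error(plan_screening(tibble::tibble(sen = numeric(), spe = numeric()),
                              "FWR", k = 10, theta = 0.8, pi_hat = 0.3),
               class = "screenplan_input_error")
  expect_error(plan_screening(tibble::tibble(sen = 0.9, spe = 0.9),
                              "SCC", k = 10, theta = 0.8, pi_hat = 0.3),
               class = "screenplan_input_error")
})

test_that("plan accessors expose the ranked table and summary", {
  cands <- tibble::tibble(spec = c("a", "b"), sen = c(0.9, 0.7), spe = c(0.9, 0.95))
  plan <- plan_screening(cands, "FAR", k = 30, theta = 0.8, pi_hat = 0.5)
  td <- tidy(plan)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$rank, 1:2)
  gl <- glance(plan)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$spec, td$spec[1])
  expect_s3_class(ggplot2::autoplot(plan), "ggplot")
  expect_output(print(plan), "Screening plan")
})

test_that("post-hoc data quality matches the binomial quantile logic", {
  # a perfect success probability gives quality 1 at any certainty
  expect_equal(posthoc_quality("FWR", theta = 0.9, n = 50, ppv = 1)$quality, 1)
  # near the median, k/n is close to the success probability
  q <- posthoc_quality("FAR", theta = 0.5, n = 100, ppv = 0.66)
  expect_lt(abs(q$quality - 0.66), 0.05)
  # SCC pools the trusted group with the screened group's bound
  scc <- posthoc_quality("SCC", theta = 0.8, ppv = 0.9, n_d1 = 50, n_d0pos = 24)
  k0 <- data_quality_quantile(0.8, 24, 0.9)
  expect_equal(scc$quality, (50 + k0) / 74)
  expect_equal(scc$n_total, 74L)
})
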