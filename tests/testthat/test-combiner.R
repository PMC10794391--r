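test_that("the catalogue holds exactly 18 combiners with the anchored keys", {
  tb <- combiners()
  expect_equal(nrow(tb), 18)
  expect_equal(sum(tb$n_tests == 1), 3)
  expect_equal(sum(tb$n_tests == 2), 6)
  expect_equal(sum(tb$n_tests == 3), 9)
  ek11 <- tb[tb$ek == 11, ]
  expect_equal(c(ek11$w_a, ek11$w_b, ek11$w_c), c(0.5, 0.5, 0.5))
  expect_match(ek11$label, "two")
  ek13 <- tb[tb$ek == 13, ]
  expect_equal(c(ek13$w_a, ek13$w_b, ek13$w_c), c(0.25, 0.25, 0.75))
  ek12 <- tb[tb$ek == 12, ]
  expect_equal(c(ek12$w_a, ek12$w_b, ek12$w_c), c(1, 1, 1) / 3)
})

test_that("every combiner's vote matches its logical rule over the full tuple space", {
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  for (ek in 1:18) {
    expected <- as.integer(mapply(
      function(a, b, c) ek_logic[[ek]](a == 1, b == 1, c == 1), g$a, g$b, g$c))
    expect_equal(vote(ek, g$a, g$b, g$c), expected,
                 info = sprintf("EK %d truth table", ek))
  }
  expect_equal(vote(11, 1, 1, 0), 1L)
  expect_equal(vote(11, 1, 0, 0), 0L)
  expect_error(vote(11, 2, 0, 0), class = "screenplan_input_error")
  expect_error(vote(42, 1, 1, 1), class = "screenplan_input_error")
})

test_that("procedure enumeration counts follow 3T + 6T^2 + 9T^3", {
  expect_equal(nrow(procedures(6)), 2178)
  expect_equal(nrow(procedures(1)), 18)
  expect_equal(nrow(procedures(2)), 102)
  p6 <- procedures(6)
  expect_equal(anyDuplicated(p6$spec), 0)
  # thresholds only for involved slots
  tb <- combiners()
  merged <- dplyr::left_join(p6, tb[, c("ek", "wa12")], by = "ek")
  expect_true(all(is.na(merged$thr_a) == (merged$wa12 == 0)))
  expect_error(procedures(0), class = "screenplan_input_error")
})

test_that("product-rule combination equals the exhaustive tuple oracle for all combiners", {
  chars <- tibble::tibble(
    test = c("testA", "testB", "testC"), threshold = 1L,
    sen = c(0.83, 0.71, 0.94), spe = c(0.64, 0.88, 0.55)
  )
  for (ek in 1:18) {
    row <- combiners()[combiners()$ek == ek, ]
    inv <- c(row$wa12, row$wb12, row$wc12) > 0
    got <- combine_independent(
      chars, ek,
      thr_a = if (inv[1]) 1 else NA, thr_b = if (inv[2]) 1 else NA,
      thr_c = if (inv[3]) 1 else NA
    )
    want <- combine_oracle(ek,
                           sen = ifelse(inv, chars$sen, NA),
                           spe = ifelse(inv, chars$spe, NA))
    expect_equal(got$sen, want$sen, tolerance = 1e-12, info = sprintf("EK %d sen", ek))
    expect_equal(got$spe, want$spe, tolerance = 1e-12, info = sprintf("EK %d spe", ek))
    probs <- got$outcome_probs[[1]]
    expect_equal(sum(probs$p_headphones), 1, tolerance = 1e-12)
    expect_equal(sum(probs$p_loudspeakers), 1, tolerance = 1e-12)
  }
})

test_that("pairwise AND and OR reduce to the product formulas and respect bounds", {
  set.seed(77)
  for (i in 1:25) {
    sens <- runif(2); spes <- runif(2)
    chars <- tibble::tibble(test = c("testA", "testB"), threshold = 1L,
                            sen = sens, spe = spes)
    and <- combine_independent(chars, ek = 4, thr_a = 1, thr_b = 1)
    or <- combine_independent(chars, ek = 7, thr_a = 1, thr_b = 1)
    expect_equal(and$sen, sens[1] * sens[2])
    expect_equal(and$spe, 1 - (1 - spes[1]) * (1 - spes[2]))
    expect_equal(or$sen, 1 - (1 - sens[1]) * (1 - sens[2]))
    expect_equal(or$spe, spes[1] * spes[2])
    expect_lte(and$sen, min(sens) + 1e-12)
    expect_gte(and$spe, max(spes) - 1e-12)
    expect_gte(or$sen, max(sens) - 1e-12)
    expect_lte(or$spe, min(spes) + 1e-12)
  }
})

test_that("empirical combination of a single-test procedure equals the plain accuracy", {
  coh <- simulate_cohort(cohort_spec(n = 600, pi = 0.4), seed = 9)
  emp <- combine_empirical(coh, ek = 2, thr_b = 4)
  acc <- accuracy_from_responses(coh, "testB", 4)
  expect_equal(emp$sen, acc$sen)
  expect_equal(emp$spe, acc$spe)
  # perfect agreement cohort
  perfect <- cohort_from_counts(
    list(testA = rep(6, 5), testB = rep(6, 5), testC = rep(6, 5)),
    list(testA = rep(0, 5), testB = rep(0, 5), testC = rep(0, 5))
  )
  all3 <- combine_empirical(perfect, ek = 12, thr_a = 6, thr_b = 6, thr_c = 6)
  expect_equal(all3$sen, 1)
  expect_equal(all3$spe, 1)
})

test_that("empirical combination converges to the product rule for independent cohorts", {
  spec <- cohort_spec(n = 20000, pi = 0.5, dependence = 0)
  coh <- simulate_cohort(spec, seed = 101)
  thr <- c(A = 5, B = 5, C = 6)
  theo <- tibble::tibble(
    test = spec$tests$test, threshold = thr,
    sen = theoretical_accuracy(spec$tests$q_pos, 6, thr),
    spe = 1 - theoretical_accuracy(spec$tests$q_neg, 6, thr)
  )
  prod_rule <- combine_independent(theo, ek = 11, thr_a = 5, thr_b = 5, thr_c = 6)
  emp <- combine_empirical(coh, ek = 11, thr_a = 5, thr_b = 5, thr_c = 6)
  n_grp <- 10000
  se_sen <- sqrt(prod_rule$sen * (1 - prod_rule$sen) / n_grp)
  se_spe <- sqrt(prod_rule$spe * (1 - prod_rule$spe) / n_grp)
  expect_lt(abs(emp$sen - prod_rule$sen), 3 * se_sen + 0.01)
  expect_lt(abs(emp$spe - prod_rule$spe), 3 * se_spe + 0.01)
})

test_that("a shared-error cohort breaks the product rule beyond sampling error", {
  spec <- cohort_spec(n = 20000, pi = 0.5, dependence = 0.8)
  coh <- simulate_cohort(spec, seed = 2024)
  # product rule fed the cohort's own per-test marginals, so any gap is
  # purely the cross-test dependence the product rule wrongly ignores
  marg <- accuracy_table(coh)
  prod_rule <- combine_independent(marg, ek = 12, thr_a = 4, thr_b = 4, thr_c = 5)
  emp <- combine_empirical(coh, ek = 12, thr_a = 4, thr_b = 4, thr_c = 5)
  se <- sqrt(prod_rule$sen * (1 - prod_rule$sen) / 10000)
  expect_gt(abs(emp$sen - prod_rule$sen), 3 * se)
  # and the product-rule path refuses when handed the dependent item data
  expect_error(
    combine_independent(marg, ek = 12, thr_a = 4, thr_b = 4, thr_c = 5,
                        responses = coh),
    class = "screenplan_input_error"
  )
})
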