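#' The catalogue of voting combiners for up to three parallel tests
#'
#' A parallel combination of screening tests is a weighted voting rule: the
#' global result is positive ("headphones") when
#' \eqn{\omega_A A + \omega_B B + \omega_C C \ge 1}, with \eqn{A, B, C \in
#' \{0, 1\}} the individual test results. Eighteen logically distinct rules
#' are catalogued, each under an integer *evaluation key* (EK):
#'
#' * EK 1-3: the three individual tests (weight 1 on one slot);
#' * EK 4-6: pairwise AND rules (weights 1/2, 1/2) for A&B, A&C, B&C;
#' * EK 7-9: pairwise OR rules (weights 1, 1);
#' * EK 10: three-way OR (1, 1, 1);
#' * EK 11: majority vote, "at least two positive" (1/2 each);
#' * EK 12: three-way AND, "all positive" (1/3 each);
#' * EK 13-15: (X OR Y) AND Z rules (1/4, 1/4, 3/4);
#' * EK 16-18: (X AND Y) OR Z rules (1/2, 1/2, 1).
#'
#' Weights are stored as integer twelfths (`wa12`, `wb12`, `wc12`; every
#' catalogue weight is a multiple of 1/12), so the vote threshold
#' \eqn{\ge 1} is the exact integer comparison \eqn{\ge 12} and never
#' suffers a floating-point tie.
#'
#' @return A tibble with one row per combiner: `ek`, `label`, `tests`
#'   (slots involved, e.g. `"BC"`), `w_a`, `w_b`, `w_c` (numeric weights),
#'   `wa12`, `wb12`, `wc12` (exact twelfths), `n_tests`.
#' @examples
#' combiners()
#' @export
combiners <- function() {
  w <- function(a, b, c) c(a, b, c) # twelfths
  rows <- list(
    list(1L,  "Test A",                      w(12, 0, 0)),
    list(2L,  "Test B",                      w(0, 12, 0)),
    list(3L,  "Test C",                      w(0, 0, 12)),
    list(4L,  "Test A AND Test B",           w(6, 6, 0)),
    list(5L,  "Test A AND Test C",           w(6, 0, 6)),
    list(6L,  "Test B AND Test C",           w(0, 6, 6)),
    list(7L,  "Test A OR Test B",            w(12, 12, 0)),
    list(8L,  "Test A OR Test C",            w(12, 0, 12)),
    list(9L,  "Test B OR Test C",            w(0, 12, 12)),
    list(10L, "Test A OR Test B OR Test C",  w(12, 12, 12)),
    list(11L, "at least two positive",       w(6, 6, 6)),
    list(12L, "Test A AND Test B AND Test C", w(4, 4, 4)),
    list(13L, "(Test A OR Test B) AND Test C", w(3, 3, 9)),
    list(14L, "(Test A OR Test C) AND Test B", w(3, 9, 3)),
    list(15L, "(Test B OR Test C) AND Test A", w(9, 3, 3)),
    list(16L, "(Test A AND Test B) OR Test C", w(6, 6, 12)),
    list(17L, "(Test A AND Test C) OR Test B", w(6, 12, 6)),
    list(18L, "(Test B AND Test C) OR Test A", w(12, 6, 6))
  )
  tb <- purrr::map(rows, function(r) {
    tw <- r[[3]]
    tibble(
      ek = r[[1]], label = r[[2]],
      tests = paste(c("A", "B", "C")[tw > 0], collapse = ""),
      w_a = tw[1] / 12, w_b = tw[2] / 12, w_c = tw[3] / 12,
      wa12 = as.integer(tw[1]), wb12 = as.integer(tw[2]),
      wc12 = as.integer(tw[3]),
      n_tests = sum(tw > 0)
    )
  }) |> bind_rows()
  tb
}

combiner_row <- function(ek) {
  tb <- combiners()
  row <- tb[tb$ek == ek, ]
  if (nrow(row) != 1) stop_input(sprintf("unknown evaluation key %s.", ek))
  row
}

#' Apply a voting combiner to binary test outcomes
#'
#' Computes the global result \eqn{G(A, B, C)} of the combiner `ek`:
#' 1 when the integer weighted sum reaches the vote threshold, else 0.
#' Outcomes for uninvolved slots are ignored.
#'
#' @param ek Evaluation key, 1-18 (see [combiners()]).
#' @param a,b,c Binary (0/1) outcome vectors for the three test slots.
#' @return An integer vector of 0/1 global results.
#' @examples
#' vote(11, a = 1, b = 1, c = 0) # majority: positive
#' vote(13, a = 1, b = 0, c = 0) # (A|B)&C: negative without C
#' @export
vote <- function(ek, a, b = 0L, c = 0L) {
  row <- combiner_row(ek)
  ab <- cbind(a, b, c)
  if (!all(ab %in% c(0, 1))) stop_input("test outcomes must be 0/1.")
  as.integer(ab[, 1] * row$wa12 + ab[, 2] * row$wb12 + ab[, 3] * row$wc12 >= 12L)
}

# truth table of a combiner over the full outcome-tuple space of its slots
combiner_truth_table <- function(ek) {
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  g$vote <- vote(ek, g$a, g$b, g$c)
  as_tibble(g)
}

#' Enumerate all screening procedures
#'
#' A *procedure* is a combiner together with a threshold (1..T) for every
#' involved test. With T thresholds per test there are
#' \eqn{3T + 6T^2 + 9T^3} procedures; T = 6 gives 2,178.
#'
#' @param max_threshold T, the number of trials per test (default 6).
#' @return A tibble with columns `ek`, `label`, `thr_a`, `thr_b`, `thr_c`
#'   (NA for uninvolved slots) and `spec` (e.g. `"EK11:A5,B5,C6"`).
#' @examples
#' nrow(procedures(6)) # 2178
#' @export
procedures <- function(max_threshold = 6) {
  if (max_threshold < 1 || max_threshold != round(max_threshold)) {
    stop_input("`max_threshold` must be a positive integer.")
  }
  th <- seq_len(max_threshold)
  purrr::map(seq_len(18L), function(ek) {
    row <- combiner_row(ek)
    grid <- expand.grid(
      thr_a = if (row$wa12 > 0) th else NA_integer_,
      thr_b = if (row$wb12 > 0) th else NA_integer_,
      thr_c = if (row$wc12 > 0) th else NA_integer_
    )
    tibble(ek = ek, label = row$label, as_tibble(grid))
  }) |>
    bind_rows() |>
    mutate(spec = format_procedure(.data$ek, .data$thr_a, .data$thr_b, .data$thr_c))
}

# validate thresholds against a combiner; returns named logical of involved slots
involved_slots <- function(row, thr_a, thr_b, thr_c) {
  inv <- c(A = row$wa12 > 0, B = row$wb12 > 0, C = row$wc12 > 0)
  thr <- c(A = thr_a, B = thr_b, C = thr_c)
  if (any(inv & is.na(thr))) {
    stop_input("a threshold is required for every involved test slot.")
  }
  inv
}

#' Combine test characteristics under conditional independence
#'
#' Computes the sensitivity and specificity of a voting combination by the
#' product rule: within each true-device stratum the probability of every
#' outcome tuple is the product of the per-test marginals (`sen` or
#' `1 - sen` given the target device, `1 - spe` or `spe` otherwise), and
#' the combined sensitivity (specificity) is the total probability of
#' tuples the combiner votes positive (negative). Valid only when the
#' involved tests are conditionally independent given the true device; if
#' item-level `responses` are supplied, every involved pair is checked in
#' both strata first and the combination is refused when independence is
#' rejected.
#'
#' @param chars Characteristics table with columns `test`, `threshold`,
#'   `sen`, `spe` (e.g. [halt_characteristics()] or [accuracy_table()]).
#' @param ek Evaluation key, 1-18.
#' @param thr_a,thr_b,thr_c Thresholds for the involved slots (NA
#'   otherwise). Slots A, B, C map to the tests named in `tests`.
#' @param tests Length-3 character vector mapping slots to `test` ids in
#'   `chars`.
#' @param responses Optional item-level data for the independence check.
#' @param alpha Significance level of the independence check (default .10).
#' @return A one-row tibble `ek`, `label`, `spec`, `sen`, `spe`,
#'   `method = "independent-product"`, with the per-stratum outcome-tuple
#'   probabilities in the list-column `outcome_probs`.
#' @examples
#' tab <- halt_characteristics("mainstudy")
#' combine_independent(tab, ek = 11, thr_a = 5, thr_b = 5, thr_c = 6)
#' @export
combine_independent <- function(chars, ek, thr_a = NA, thr_b = NA, thr_c = NA,
                                tests = c("testA", "testB", "testC"),
                                responses = NULL, alpha = 0.10) {
  row <- combiner_row(ek)
  inv <- involved_slots(row, thr_a, thr_b, thr_c)
  thr <- c(A = thr_a, B = thr_b, C = thr_c)

  if (!is.null(responses)) {
    slots <- names(inv)[inv]
    if (length(slots) > 1) {
      pairs <- utils::combn(slots, 2, simplify = FALSE)
      for (pr in pairs) for (dev in c("headphones", "loudspeakers")) {
        res <- conditional_independence_test(
          responses,
          test_x = tests[match(pr[1], c("A", "B", "C"))],
          test_y = tests[match(pr[2], c("A", "B", "C"))],
          threshold_x = thr[[pr[1]]], threshold_y = thr[[pr[2]]],
          device = dev, alpha = alpha
        )
        if (isTRUE(res$reject)) {
          stop_input(sprintf(
            "conditional independence rejected for %s vs %s given %s (p = %.4f); use combine_empirical().",
            pr[1], pr[2], dev, res$p_value))
        }
      }
    }
  }

  # marginal positive-result probabilities per stratum for each slot
  p_pos_hp <- p_pos_ls <- c(A = NA_real_, B = NA_real_, C = NA_real_)
  for (slot in c("A", "B", "C")[inv]) {
    tid <- tests[match(slot, c("A", "B", "C"))]
    hit <- chars[chars$test == tid & chars$threshold == thr[[slot]], ]
    if (nrow(hit) != 1) {
      stop_input(sprintf("no characteristics row for %s at threshold %s.",
                         tid, thr[[slot]]))
    }
    p_pos_hp[slot] <- hit$sen
    p_pos_ls[slot] <- 1 - hit$spe
  }

  tuples <- combiner_truth_table(ek)
  tuple_prob <- function(p_pos) {
    pr <- rep(1, nrow(tuples))
    for (slot in c("A", "B", "C")[inv]) {
      x <- tuples[[tolower(slot)]]
      pr <- pr * ifelse(x == 1, p_pos[[slot]], 1 - p_pos[[slot]])
    }
    # collapse uninvolved slots: keep tuples where they are 0
    for (slot in c("A", "B", "C")[!inv]) pr[tuples[[tolower(slot)]] == 1] <- 0
    pr
  }
  p_hp <- tuple_prob(p_pos_hp)
  p_ls <- tuple_prob(p_pos_ls)

  out_probs <- mutate(tuples, p_headphones = p_hp, p_loudspeakers = p_ls)
  tibble(
    ek = row$ek, label = row$label,
    spec = format_procedure(ek, thr_a, thr_b, thr_c),
    sen = sum(p_hp[tuples$vote == 1]),
    spe = sum(p_ls[tuples$vote == 0]),
    method = "independent-product",
    outcome_probs = list(out_probs)
  )
}

#' Combine tests empirically from item-level responses
#'
#' Treats the voting combination as a single screening test: each involved
#' test is dichotomised at its threshold, the vote rule is applied per
#' participant, and sensitivity and specificity are computed from the
#' resulting classification against the true device, with Wilson score
#' intervals. This is the fallback when conditional independence does not
#' hold, and requires no independence assumption.
#'
#' @inheritParams combine_independent
#' @inheritParams accuracy_from_responses
#' @return A one-row tibble `ek`, `label`, `spec`, `sen`, `sen_lower`,
#'   `sen_upper`, `spe`, `spe_lower`, `spe_upper`, `n_pos`, `n_neg`,
#'   `method = "empirical"`.
#' @export
combine_empirical <- function(responses, ek, thr_a = NA, thr_b = NA, thr_c = NA,
                              tests = c("testA", "testB", "testC"),
                              level = 0.95) {
  row <- combiner_row(ek)
  inv <- involved_slots(row, thr_a, thr_b, thr_c)
  thr <- c(A = thr_a, B = thr_b, C = thr_c)

  outcome <- function(slot) {
    if (!inv[[slot]]) return(rep(0L, nrow(responses)))
    tid <- tests[match(slot, c("A", "B", "C"))]
    as.integer(trial_correct_counts(responses, tid) >= thr[[slot]])
  }
  g <- vote(ek, outcome("A"), outcome("B"), outcome("C"))
  is_pos <- responses$device == "headphones"
  if (!any(is_pos) || !any(!is_pos)) stop_input("both device groups must be non-empty.")
  counts <- confusion_counts(
    tp = sum(g == 1 & is_pos), fn = sum(g == 0 & is_pos),
    tn = sum(g == 0 & !is_pos), fp = sum(g == 1 & !is_pos)
  )
  sen_ci <- score_ci(counts$tp, counts$tp + counts$fn, level)
  spe_ci <- score_ci(counts$tn, counts$tn + counts$fp, level)
  tibble(
    ek = row$ek, label = row$label,
    spec = format_procedure(ek, thr_a, thr_b, thr_c),
    sen = sen_ci$estimate, sen_lower = sen_ci$lower, sen_upper = sen_ci$upper,
    spe = spe_ci$estimate, spe_lower = spe_ci$lower, spe_upper = spe_ci$upper,
    n_pos = counts$tp + counts$fn, n_neg = counts$tn + counts$fp,
    method = "empirical"
  )
}
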