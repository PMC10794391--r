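#' Confusion counts for a binary screening decision
#'
#' Bundles the four cells of the confusion matrix of a screening rule
#' against the true playback device: hits (`tp`), misses (`fn`), correct
#' rejections (`tn`) and false alarms (`fp`). All arguments are vectorised,
#' so a table of rules can be built in one call.
#'
#' @param tp,fn,tn,fp Non-negative integer counts of true positives, false
#'   negatives, true negatives and false positives.
#' @return A tibble with columns `tp`, `fn`, `tn`, `fp`.
#' @examples
#' confusion_counts(tp = 74, fn = 6, tn = 76, fp = 55)
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  cells <- list(tp = tp, fn = fn, tn = tn, fp = fp)
  for (nm in names(cells)) {
    x <- cells[[nm]]
    if (any(!is.finite(x) | x < 0 | x != round(x))) {
      stop_input(sprintf("`%s` must be a non-negative integer count.", nm))
    }
  }
  tibble(tp = as.integer(tp), fn = as.integer(fn),
         tn = as.integer(tn), fp = as.integer(fp))
}

#' Sensitivity and specificity of a screening rule
#'
#' `sensitivity()` is the hit rate, the probability of a positive test given
#' the target device (TP / (TP + FN)); `specificity()` is the correct
#' rejection rate, the probability of a negative test given the non-target
#' device (TN / (TN + FP)). An empty truth group signals malformed input and
#' raises an error rather than returning 0.
#'
#' @param counts A data frame of confusion counts with columns `tp`, `fn`,
#'   `tn`, `fp` (see [confusion_counts()]); rows are vectorised over.
#' @return A numeric vector of proportions in \[0, 1\].
#' @examples
#' sensitivity(confusion_counts(74, 6, 76, 55)) # 0.925
#' specificity(confusion_counts(74, 6, 76, 55)) # 76/131
#' @export
sensitivity <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$tp + counts$fn == 0)) {
    stop_undefined("sensitivity is undefined: no true positives-group members (tp + fn = 0).")
  }
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  counts <- as_tibble(counts)
  if (any(counts$tn + counts$fp == 0)) {
    stop_undefined("specificity is undefined: no true negatives-group members (tn + fp = 0).")
  }
  counts$tn / (counts$tn + counts$fp)
}

#' Prevalence-adjusted predictive values
#'
#' The positive predictive value is the probability that the target device
#' was truly used given a positive test; the negative predictive value is
#' the probability that it was not used given a negative test. Unlike
#' sensitivity and specificity these depend on the prevalence `pi` of the
#' target device in the screened population:
#' \deqn{PPV = \frac{Sen \cdot \pi}{Sen \cdot \pi + (1 - Spe)(1 - \pi)}}
#' \deqn{NPV = \frac{Spe (1 - \pi)}{(1 - Sen)\pi + Spe (1 - \pi)}}
#'
#' @param sen,spe Sensitivity and specificity of the test, in \[0, 1\].
#' @param pi Prevalence (base rate) of the target device, in \[0, 1\].
#' @return A numeric vector of probabilities. A zero denominator (the test
#'   result in question has probability zero) raises an error.
#' @examples
#' ppv(0.90, 0.90, 0.18) # about 0.66
#' ppv(0.90, 0.90, 0.25) # exactly 0.75
#' @export
ppv <- function(sen, spe, pi) {
  check_prob(sen, "sen"); check_prob(spe, "spe"); check_prob(pi, "pi")
  den <- sen * pi + (1 - spe) * (1 - pi)
  if (any(den <= 0)) {
    stop_undefined("PPV is undefined: a positive test result has probability 0.")
  }
  sen * pi / den
}

#' @rdname ppv
#' @export
npv <- function(sen, spe, pi) {
  check_prob(sen, "sen"); check_prob(spe, "spe"); check_prob(pi, "pi")
  den <- (1 - sen) * pi + spe * (1 - pi)
  if (any(den <= 0)) {
    stop_undefined("NPV is undefined: a negative test result has probability 0.")
  }
  spe * (1 - pi) / den
}

#' Utility weights for the four classification outcomes
#'
#' Desirabilities in \[0, 1\] placed on true positives, false negatives,
#' true negatives and false positives. The default (1, 0, 1, 0) scores
#' correct classifications only, so the overall utility reduces to
#' classification accuracy.
#'
#' @param u_tp,u_fn,u_tn,u_fp Utilities in \[0, 1\].
#' @return A named numeric vector of class `utility_weights`.
#' @export
utility_weights <- function(u_tp = 1, u_fn = 0, u_tn = 1, u_fp = 0) {
  w <- c(u_tp = u_tp, u_fn = u_fn, u_tn = u_tn, u_fp = u_fp)
  check_prob(w, "utility weights")
  structure(w, class = "utility_weights")
}

#' Overall utility of a screening test at a given prevalence
#'
#' The utilities-weighted sum of the probabilities of the four
#' classification outcomes:
#' \deqn{U = \pi Sen\, U_{TP} + \pi (1-Sen)\, U_{FN} +
#'   (1-\pi) Spe\, U_{TN} + (1-\pi)(1-Spe)\, U_{FP}}
#' With the default weights (1, 0, 1, 0) this is the expected proportion of
#' correct classifications, \eqn{\pi Sen + (1-\pi) Spe}.
#'
#' @inheritParams ppv
#' @param weights A [utility_weights()] vector.
#' @return A numeric vector.
#' @examples
#' overall_utility(0.8, 0.7, 0.4) # 0.74
#' @export
overall_utility <- function(sen, spe, pi, weights = utility_weights()) {
  check_prob(sen, "sen"); check_prob(spe, "spe"); check_prob(pi, "pi")
  pi * sen * weights[["u_tp"]] + pi * (1 - sen) * weights[["u_fn"]] +
    (1 - pi) * spe * weights[["u_tn"]] + (1 - pi) * (1 - spe) * weights[["u_fp"]]
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval recommended by Agresti and Coull for a binomial
#' proportion, using the exact normal quantile
#' \eqn{z = \Phi^{-1}(1 - \alpha/2)}. Bounds are clamped to \[0, 1\] and
#' always contain the point estimate.
#'
#' @param successes,total Vectors of success counts and trial counts.
#' @param level Confidence level in (0, 1); default 0.95.
#' @return A tibble with columns `estimate`, `lower`, `upper`.
#' @examples
#' score_ci(80, 211)   # prevalence 37.9%, CI [31.6%, 44.6%]
#' score_ci(74, 80)    # sensitivity 92.5%, CI [84.6%, 96.5%]
#' @export
score_ci <- function(successes, total, level = 0.95) {
  if (any(!is.finite(successes) | !is.finite(total) | total <= 0 |
            successes < 0 | successes > total)) {
    stop_input("need 0 <= successes <= total with total > 0.")
  }
  if (any(level <= 0 | level >= 1)) stop_input("`level` must be in (0, 1).")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / total
  centre <- (p + z^2 / (2 * total)) / (1 + z^2 / total)
  half <- z * sqrt((p * (1 - p) + z^2 / (4 * total)) / total) / (1 + z^2 / total)
  # the interval provably contains p; pmin/pmax also absorb float rounding
  # at the boundaries
  tibble(
    estimate = p,
    lower = pmin(pmax(0, centre - half), p),
    upper = pmax(pmin(1, centre + half), p)
  )
}

#' Sensitivity and specificity from item-level responses at a threshold
#'
#' Classifies every participant positive when their number of correct trial
#' responses on `test` reaches `threshold` ("at least t of T correct"), then
#' scores the classification against the true device column. Wilson score
#' confidence intervals are attached to both characteristics.
#'
#' @param responses A data frame of item-level responses: one row per
#'   participant with a `device` column (`"headphones"` or
#'   `"loudspeakers"`) and 0/1 trial outcome columns named
#'   `<test>_1 .. <test>_T` (see [read_responses()] for the CSV schema).
#' @param test Test identifier, e.g. `"testA"`; trial columns are
#'   `paste0(test, "_", 1:T)`.
#' @param threshold Minimum number of correct responses for a positive
#'   result, between 1 and the number of trials.
#' @param level Confidence level for the score intervals.
#' @return A one-row tibble: `test`, `threshold`, `sen`, `sen_lower`,
#'   `sen_upper`, `spe`, `spe_lower`, `spe_upper`, `n_pos`, `n_neg`.
#' @export
accuracy_from_responses <- function(responses, test, threshold, level = 0.95) {
  correct <- trial_correct_counts(responses, test)
  trials <- attr(correct, "trials")
  if (threshold < 1 || threshold > trials || threshold != round(threshold)) {
    stop_input(sprintf("`threshold` must be an integer in 1..%d.", trials))
  }
  positive <- correct >= threshold
  is_pos <- responses$device == "headphones"
  if (!any(is_pos) || !any(!is_pos)) {
    stop_input("both device groups must be non-empty.")
  }
  counts <- confusion_counts(
    tp = sum(positive & is_pos), fn = sum(!positive & is_pos),
    tn = sum(!positive & !is_pos), fp = sum(positive & !is_pos)
  )
  sen_ci <- score_ci(counts$tp, counts$tp + counts$fn, level)
  spe_ci <- score_ci(counts$tn, counts$tn + counts$fp, level)
  tibble(
    test = test, threshold = as.integer(threshold),
    sen = sen_ci$estimate, sen_lower = sen_ci$lower, sen_upper = sen_ci$upper,
    spe = spe_ci$estimate, spe_lower = spe_ci$lower, spe_upper = spe_ci$upper,
    n_pos = counts$tp + counts$fn, n_neg = counts$tn + counts$fp
  )
}

#' Full per-threshold characteristics table from item-level responses
#'
#' Applies [accuracy_from_responses()] at every threshold of every
#' requested test, yielding a characteristics table suitable for
#' [roc_points()] and [combine_independent()].
#'
#' @inheritParams accuracy_from_responses
#' @param tests Character vector of test identifiers; defaults to every
#'   test with trial columns present in `responses`.
#' @return A tibble with one row per test and threshold.
#' @export
accuracy_table <- function(responses, tests = NULL, level = 0.95) {
  if (is.null(tests)) tests <- detect_tests(responses)
  if (length(tests) == 0) stop_input("no trial columns found in `responses`.")
  purrr::map(tests, function(tt) {
    trials <- attr(trial_correct_counts(responses, tt), "trials")
    purrr::map(seq_len(trials), function(th) {
      accuracy_from_responses(responses, tt, th, level)
    }) |> bind_rows()
  }) |> bind_rows()
}

# per-participant correct-response counts for one test; errors on missing
# or incomplete trial columns
trial_correct_counts <- function(responses, test) {
  cols <- grep(paste0("^", test, "_[0-9]+$"), names(responses), value = TRUE)
  if (length(cols) == 0) {
    stop_input(sprintf("no trial columns found for test `%s`.", test))
  }
  idx <- as.integer(sub(paste0("^", test, "_"), "", cols))
  cols <- cols[order(idx)]
  mat <- as.matrix(responses[cols])
  if (anyNA(mat) || !all(mat %in% c(0, 1))) {
    stop_input(sprintf("trial columns for `%s` must be complete 0/1 outcomes.", test))
  }
  structure(rowSums(mat), trials = length(cols))
}

detect_tests <- function(responses) {
  hits <- grep("^(.*)_[0-9]+$", names(responses), value = TRUE)
  unique(sub("_[0-9]+$", "", hits))
}
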