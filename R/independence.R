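#' Test conditional independence of two screening tests within a stratum
#'
#' Two tests may only be combined by the product rule if their dichotomised
#' outcomes are statistically independent conditional on the true playback
#' device. This dichotomises both tests at their thresholds within one
#' device stratum, forms the 2x2 contingency table, and tests independence
#' with a chi-square test; when any expected cell count falls below 5 the
#' chi-square approximation is unreliable and an exact multinomial test is
#' used instead (cell probabilities estimated from the margins, p-value the
#' total probability of tables no more likely than the observed one). A
#' comparatively high default alpha of .10 protects against falsely
#' retaining the independence hypothesis, since the null is what the
#' product rule relies on.
#'
#' @inheritParams accuracy_from_responses
#' @param test_x,test_y Test identifiers (trial-column prefixes).
#' @param threshold_x,threshold_y Dichotomisation thresholds.
#' @param device Stratum: `"headphones"` or `"loudspeakers"`.
#' @param alpha Significance level for the `reject` flag (default .10).
#' @param correct Apply Yates continuity correction in the chi-square test
#'   (default FALSE).
#' @return A one-row tibble: `test_x`, `test_y`, `device`, `p_value`,
#'   `method` (`"chi-square"`, `"exact-multinomial"` or `"degenerate"`),
#'   `reject`, `degenerate`. A table with a zero margin cannot reject
#'   independence; it is flagged degenerate with `p_value = NA`.
#' @export
conditional_independence_test <- function(responses, test_x, test_y,
                                          threshold_x, threshold_y,
                                          device = c("headphones", "loudspeakers"),
                                          alpha = 0.10, correct = FALSE) {
  device <- match.arg(device)
  sub <- responses[responses$device == device, , drop = FALSE]
  if (nrow(sub) == 0) stop_input(sprintf("device group `%s` is empty.", device))
  x <- as.integer(trial_correct_counts(sub, test_x) >= threshold_x)
  y <- as.integer(trial_correct_counts(sub, test_y) >= threshold_y)
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))

  base <- tibble(test_x = test_x, test_y = test_y, device = device)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(mutate(base, p_value = NA_real_, method = "degenerate",
                  reject = FALSE, degenerate = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- exact_multinomial_p(tab)
    method <- "exact-multinomial"
  } else {
    p <- suppressWarnings(chisq.test(tab, correct = correct)$p.value)
    method <- "chi-square"
  }
  mutate(base, p_value = p, method = method, reject = p < alpha,
         degenerate = FALSE)
}

# exact multinomial test of independence on a 2x2 table: under H0 the cell
# probabilities are the products of the margin proportions; the p-value sums
# the multinomial probability of every table of the same total that is no
# more probable than the observed one (with a small relative tolerance for
# ties). Enumerates all compositions of N into four cells.
exact_multinomial_p <- function(tab) {
  n <- sum(tab)
  p0 <- as.vector(outer(rowSums(tab), colSums(tab))) / n^2 # n11 n21 n12 n22
  obs <- as.vector(tab)
  log_p0 <- log(p0)
  lfac <- lgamma(seq_len(n + 1)) # lgamma(k+1) at index k+1
  tab_logprob <- function(n11, n12, n21, n22) {
    lgamma(n + 1) - lfac[n11 + 1] - lfac[n12 + 1] - lfac[n21 + 1] - lfac[n22 + 1] +
      n11 * log_p0[1] + n21 * log_p0[2] + n12 * log_p0[3] + n22 * log_p0[4]
  }
  lp_obs <- tab_logprob(obs[1], obs[3], obs[2], obs[4])
  total <- 0
  for (n11 in 0:n) {
    rest <- n - n11
    grid <- expand.grid(n12 = 0:rest, n21 = 0:rest)
    grid <- grid[grid$n12 + grid$n21 <= rest, , drop = FALSE]
    n22 <- rest - grid$n12 - grid$n21
    lp <- tab_logprob(n11, grid$n12, grid$n21, n22)
    total <- total + sum(exp(lp[lp <= lp_obs + 1e-07]))
  }
  min(1, total)
}
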