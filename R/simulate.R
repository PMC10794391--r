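#' Specification of a synthetic screening cohort
#'
#' Describes the population the planning framework assumes: participants
#' use the target device ("headphones") with prevalence `pi`; when
#' prompted, non-target users switch with probability `sigma`; each test is
#' a series of `trials` Bernoulli trials whose per-trial correctness
#' probability depends only on the actual device (`q_pos` given
#' headphones, `q_neg` given loudspeakers). A shared-error mixing
#' parameter `dependence` injects within-participant correlation (with
#' probability `dependence` a trial copies a latent outcome driven by one
#' shared participant-level quantile draw instead of being independent),
#' correlating both the trials within a test and the outcomes of different
#' tests while leaving every per-trial marginal at `q`. Defaults mirror the main-study conditions:
#' prevalence 0.1767 (the wide-population base rate), switching prevalence
#' 0.55, six trials per test, and per-trial probabilities calibrated so
#' each test's threshold-5 sensitivity and specificity match the
#' main-study characteristics table.
#'
#' @param n Number of participants per simulated cohort.
#' @param pi Target-device prevalence in \[0, 1\].
#' @param sigma Switching probability in \[0, 1\].
#' @param tests Tibble with columns `test`, `q_pos`, `q_neg`.
#' @param trials Trials per test (default 6).
#' @param dependence Shared-error mixing weight in \[0, 1\] (default 0:
#'   conditionally independent trials and tests).
#' @param misreport Probability that the pre-request self-report is wrong
#'   (default 0: unbiased self-report).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1000,
                        pi = 0.1767,
                        sigma = 0.55,
                        tests = default_test_probs(),
                        trials = 6,
                        dependence = 0,
                        misreport = 0) {
  check_prob(pi, "pi"); check_prob(sigma, "sigma")
  check_prob(dependence, "dependence"); check_prob(misreport, "misreport")
  check_prob(tests$q_pos, "q_pos"); check_prob(tests$q_neg, "q_neg")
  if (trials < 1 || trials != round(trials)) {
    stop_input("`trials` must be a positive integer.")
  }
  structure(
    list(n = as.integer(n), pi = pi, sigma = sigma, tests = as_tibble(tests),
         trials = as.integer(trials), dependence = dependence,
         misreport = misreport),
    class = "cohort_spec"
  )
}

#' @rdname cohort_spec
#' @export
default_test_probs <- function() {
  solve_q <- function(target, trials = 6, threshold = 5) {
    uniroot(function(q) pbinom(threshold - 1, trials, q, lower.tail = FALSE) - target,
            c(1e-6, 1 - 1e-6), tol = 1e-10)$root
  }
  tibble(
    test = c("testA", "testB", "testC"),
    q_pos = c(solve_q(0.800), solve_q(0.800), solve_q(0.925)),
    q_neg = c(solve_q(1 - 0.687), solve_q(1 - 0.832), solve_q(1 - 0.580))
  )
}

#' Simulate an item-level screening cohort
#'
#' Draws a cohort according to a [cohort_spec()]: a true initial device per
#' participant, a (by default truthful) self-report, optionally the
#' post-request switch of non-target users, and 0/1 trial outcomes for
#' every test given the actual device used during testing. The output uses
#' the item-level response schema of [accuracy_from_responses()] /
#' [read_responses()], so all evaluation functions apply directly. A given
#' seed fully determines the cohort.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @param request If TRUE, non-target users switch to the target device
#'   with probability `spec$sigma` before testing (the FAR request, or the
#'   SCC prompt applied to the self-reported non-target group — target
#'   users are unaffected either way).
#' @return A tibble: `participant_id`, `device_initial`, `self_report`,
#'   `switched`, `device` (device during testing), and trial columns
#'   `<test>_1 .. <test>_T`.
#' @examples
#' head(simulate_cohort(cohort_spec(n = 100), seed = 1))
#' @export
simulate_cohort <- function(spec, seed, request = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  out <- simulate_cohort_stream(spec, request)
  out$participant_id <- seq_len(nrow(out))
  select(out, "participant_id", dplyr::everything())
}

# draws one cohort using the current RNG state (no reseeding), so a
# caller that set the seed once can draw successive chunks deterministically
simulate_cohort_stream <- function(spec, request = FALSE) {
  n <- spec$n
  device_initial <- ifelse(runif(n) < spec$pi, "headphones", "loudspeakers")
  self_report <- ifelse(runif(n) < spec$misreport,
                        ifelse(device_initial == "headphones",
                               "loudspeakers", "headphones"),
                        device_initial)
  switched <- rep(FALSE, n)
  device <- device_initial
  if (request) {
    sw <- device_initial != "headphones" & runif(n) < spec$sigma
    switched <- sw
    device[sw] <- "headphones"
  }
  out <- tibble(device_initial = device_initial, self_report = self_report,
                switched = switched, device = device)
  is_hp <- device == "headphones"
  # shared participant-level quantile: one draw per participant couples the
  # latent outcomes of all tests (and the trials within each test) while
  # leaving every per-trial marginal at its q
  u <- runif(n)
  for (i in seq_len(nrow(spec$tests))) {
    tt <- spec$tests$test[i]
    q <- ifelse(is_hp, spec$tests$q_pos[i], spec$tests$q_neg[i])
    latent <- u < q
    for (j in seq_len(spec$trials)) {
      use_latent <- runif(n) < spec$dependence
      indep <- runif(n) < q
      out[[paste0(tt, "_", j)]] <- as.integer(ifelse(use_latent, latent, indep))
    }
  }
  out
}

#' Theoretical test accuracy under the binomial trial model
#'
#' For independent trials with per-trial correctness probability `q`, the
#' probability of a positive result under the rule "at least `threshold`
#' of `trials` correct" is the exact binomial upper tail
#' \eqn{P(\mathrm{Bin}(trials, q) \ge threshold)}. Evaluated at `q_pos`
#' this is the test's sensitivity; at `q_neg` it is the false-alarm rate
#' (1 - specificity).
#'
#' @param q Per-trial correctness probability.
#' @param trials Number of trials.
#' @param threshold Positivity threshold in 1..trials.
#' @return A probability.
#' @export
theoretical_accuracy <- function(q, trials, threshold) {
  check_prob(q, "q")
  if (any(threshold < 1 | threshold > trials)) {
    stop_input("`threshold` must be in 1..trials.")
  }
  pbinom(threshold - 1, trials, q, lower.tail = FALSE)
}

#' Simulate a screening strategy end to end
#'
#' Repeatedly simulates participants streaming into a study run under one
#' of the three screening strategies and a chosen procedure, accepting
#' participants until the planned sample size `n_accept` is reached:
#'
#' * FWR: no request; a participant is accepted when the procedure votes
#'   positive.
#' * FAR: headphones are requested first (non-target users switch with
#'   probability `sigma`), then acceptance by positive vote.
#' * SCC: participants self-reporting the target device (D1) are accepted
#'   outright; the rest are prompted (switch with probability `sigma`) and
#'   accepted only on a positive vote (D0+).
#'
#' Each replicate reports how many of the accepted participants truly used
#' the target device, the empirical success probability, and whether the
#' target `k` was met.
#'
#' @param spec A [cohort_spec()]; `spec$n` is the simulation chunk size.
#' @param strategy `"FWR"`, `"FAR"` or `"SCC"`.
#' @param ek,thr_a,thr_b,thr_c The screening procedure (see [vote()]).
#' @param tests Slot-to-test mapping as in [combine_empirical()].
#' @param n_accept Accepted-sample size to collect per replicate
#'   (e.g. from [required_n()]).
#' @param k Target count of true users a replicate should contain.
#' @param replicates Number of simulated studies.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return A tibble with one row per replicate: `replicate`, `n_accepted`,
#'   `n_true_users`, `success_prob`, `met_k`.
#' @export
run_strategy_sim <- function(spec, strategy = c("FWR", "FAR", "SCC"),
                             ek, thr_a = NA, thr_b = NA, thr_c = NA,
                             tests = c("testA", "testB", "testC"),
                             n_accept, k, replicates = 100, seed = 1) {
  strategy <- match.arg(strategy)
  row <- combiner_row(ek)
  inv <- involved_slots(row, thr_a, thr_b, thr_c)
  thr <- c(A = thr_a, B = thr_b, C = thr_c)

  vote_on <- function(chunk) {
    outcome <- function(slot) {
      if (!inv[[slot]]) return(rep(0L, nrow(chunk)))
      tid <- tests[match(slot, c("A", "B", "C"))]
      as.integer(trial_correct_counts(chunk, tid) >= thr[[slot]])
    }
    vote(ek, outcome("A"), outcome("B"), outcome("C"))
  }

  purrr::map(seq_len(replicates), function(r) {
    set.seed(as.integer(seed) + r)
    accepted_true <- integer(0)
    guard <- 0
    while (length(accepted_true) < n_accept && guard < 1000) {
      guard <- guard + 1
      chunk <- switch(strategy,
        FWR = simulate_cohort_stream(spec, request = FALSE),
        FAR = simulate_cohort_stream(spec, request = TRUE),
        SCC = simulate_cohort_stream(spec, request = TRUE)
      )
      keep <- switch(strategy,
        FWR = vote_on(chunk) == 1L,
        FAR = vote_on(chunk) == 1L,
        # SCC: self-reported target users enter unscreened; only the
        # prompted group is screened (prompting target users is a no-op,
        # so the request-applied chunk serves both groups)
        SCC = chunk$self_report == "headphones" |
          (chunk$self_report != "headphones" & vote_on(chunk) == 1L)
      )
      accepted_true <- c(accepted_true,
                         as.integer(chunk$device[keep] == "headphones"))
    }
    n_acc <- min(length(accepted_true), n_accept)
    truth <- accepted_true[seq_len(n_acc)]
    tibble(replicate = r, n_accepted = n_acc,
           n_true_users = sum(truth),
           success_prob = mean(truth),
           met_k = sum(truth) >= k)
  }) |> bind_rows()
}
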