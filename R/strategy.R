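#' Probability that a screened sample contains at least k true users
#'
#' In a sample of `n` participants accepted by a screening procedure, the
#' number H of true target-device users is binomial with size `n` and
#' success probability `p` (the PPV of the procedure at the relevant
#' prevalence, or the SCC success probability). This returns the exact
#' upper tail \eqn{P(H \ge k)}.
#'
#' @param k Target count of true users (0 <= k <= n).
#' @param n Accepted sample size.
#' @param p Per-participant success probability in \[0, 1\].
#' @return \eqn{P(H \ge k)}.
#' @examples
#' prob_at_least(70, 74, 0.9614) # > 0.80
#' @export
prob_at_least <- function(k, n, p) {
  if (any(k < 0 | k != round(k) | n < 0 | n != round(n))) {
    stop_input("`k` and `n` must be non-negative integers.")
  }
  if (any(k > n)) stop_input("`k` must not exceed `n`.")
  check_prob(p, "p")
  pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Data-quality quantile: largest k guaranteed with certainty theta
#'
#' Given an accepted sample of size `n` with per-participant success
#' probability `p`, returns the largest `k` such that
#' \eqn{P(H \ge k) \ge \vartheta}. The post-hoc data-quality lower bound of
#' the sample is then `k / n`: with probability at least `theta` the sample
#' contains at least `k` true users.
#'
#' @param theta Certainty level in (0, 1).
#' @param n Accepted sample size.
#' @param p Success probability (PPV or SCC success probability).
#' @return The integer k.
#' @examples
#' data_quality_quantile(0.80, 74, 0.9614) # 70
#' @export
data_quality_quantile <- function(theta, n, p) {
  if (any(theta <= 0 | theta >= 1)) stop_input("`theta` must be in (0, 1).")
  check_prob(p, "p")
  # P(H >= k) is non-increasing in k and equals 1 at k = 0
  ks <- 0:n
  tail <- pbinom(ks - 1, n, p, lower.tail = FALSE)
  max(ks[tail >= theta])
}

#' Required accepted-sample size for k true users at certainty theta
#'
#' Smallest `n` such that a binomial sample of size `n` with success
#' probability `p` contains at least `k` successes with probability at
#' least `theta`. For `theta` > 0.5 the normal approximation with
#' continuity correction is used:
#' \deqn{n = -a/2 + \sqrt{(a/2)^2 - b}}
#' with \eqn{a = -p^{-1}(2k - 1 + (1-p)\,\Phi^{-1}(1-\vartheta)^2)} and
#' \eqn{b = p^{-2}(k - 0.5)^2}, rounded up to the next integer and floored
#' at `k`. Outside that domain (theta <= 0.5, or a degenerate
#' discriminant) an exact search over the binomial tail is used instead;
#' the `method` attribute records which path produced each value.
#'
#' @param k Target count of true users (k >= 1).
#' @param theta Certainty in (0, 1).
#' @param p Success probability in (0, 1\].
#' @return Integer sample size(s), with attribute `method`
#'   (`"normal-approx"` or `"exact-search"`).
#' @examples
#' required_n(70, 0.80, 0.9614) # 74
#' @export
required_n <- function(k, theta, p) {
  if (any(k < 1 | k != round(k))) stop_input("`k` must be a positive integer.")
  if (any(theta <= 0 | theta >= 1)) stop_input("`theta` must be in (0, 1).")
  if (any(p <= 0 | p > 1)) stop_input("`p` must be in (0, 1].")
  out <- mapply(function(k, theta, p) {
    if (p == 1) return(c(n = k, approx = 0))
    if (theta > 0.5) {
      z <- qnorm(1 - theta)
      a <- -(2 * k - 1 + (1 - p) * z^2) / p
      disc <- (a / 2)^2 - (k - 0.5)^2 / p^2
      if (disc >= 0) {
        n <- max(k, ceiling(-a / 2 + sqrt(disc)))
        return(c(n = n, approx = 1))
      }
    }
    c(n = required_n_exact(k, theta, p), approx = 0)
  }, k, theta, p)
  structure(as.integer(out["n", ]),
            method = unname(ifelse(out["approx", ] == 1,
                                   "normal-approx", "exact-search")))
}

# exact search: smallest n >= k with P(H >= k | n, p) >= theta
required_n_exact <- function(k, theta, p) {
  n <- k
  while (pbinom(k - 1, n, p, lower.tail = FALSE) < theta) {
    n <- n + max(1L, ceiling(0.02 * n))
  }
  # back off to the boundary
  lo <- k; hi <- n
  while (lo < hi) {
    mid <- (lo + hi) %/% 2
    if (pbinom(k - 1, mid, p, lower.tail = FALSE) >= theta) hi <- mid else lo <- mid + 1
  }
  lo
}

#' Success probability under the Split-Convince-Compare strategy
#'
#' Under SCC, participants self-reporting the target device (group D1) are
#' accepted outright; the rest are prompted to switch (a proportion
#' `switching` actually does) and only test-positives among them (D0+) are
#' accepted. Assuming unbiased self-report, the probability that an
#' accepted participant truly uses the target device is
#' \deqn{\tilde p = \frac{\hat\pi + (1-\hat\pi)\,\hat\varsigma\, Sen}
#'  {\hat\pi + (1-\hat\pi)(\hat\varsigma\, Sen + (1-\hat\varsigma)(1-Spe))}}
#'
#' @param pi_hat Prevalence estimate of the target device.
#' @param sigma_hat Switching-prevalence estimate (probability a prompted
#'   non-target user switches).
#' @param sen,spe Characteristics of the screening procedure applied to the
#'   prompted group.
#' @return The success probability \eqn{\tilde p}.
#' @export
scc_success_prob <- function(pi_hat, sigma_hat, sen, spe) {
  check_prob(pi_hat, "pi_hat"); check_prob(sigma_hat, "sigma_hat")
  check_prob(sen, "sen"); check_prob(spe, "spe")
  num <- pi_hat + (1 - pi_hat) * sigma_hat * sen
  den <- pi_hat + (1 - pi_hat) * (sigma_hat * sen + (1 - sigma_hat) * (1 - spe))
  if (any(den <= 0)) {
    stop_undefined("SCC success probability undefined: acceptance has probability 0.")
  }
  num / den
}

#' Plan a screening study: rank candidate procedures for a strategy
#'
#' For each candidate procedure (with known combined sensitivity and
#' specificity) computes the per-participant success probability — the PPV
#' at the prevalence estimate for the Filter-Without-Request (FWR) and
#' Filter-After-Request (FAR) strategies, or the SCC success probability
#' from [scc_success_prob()] — and the accepted-sample size required to
#' contain at least `k` true users with certainty `theta`. Candidates are
#' ranked by smallest required n (criterion `"min_n"`, maximising data
#' quality) or by largest overall utility (criterion `"utility"`; for SCC
#' the utility is evaluated at the switching prevalence, since the
#' screening only acts on the prompted group). Ties break towards fewer
#' involved tests, then lexicographically by procedure spec.
#'
#' @param candidates Data frame of candidate procedures with columns `sen`
#'   and `spe`; optional `spec` (procedure label) and `ek`.
#' @param strategy `"FWR"`, `"FAR"` or `"SCC"`.
#' @param k Target number of true target-device users.
#' @param theta Certainty in (0, 1).
#' @param pi_hat Prevalence estimate (for FAR this is the post-request
#'   prevalence).
#' @param sigma_hat Switching-prevalence estimate; required for SCC.
#' @param criterion `"min_n"` or `"utility"`.
#' @param weights [utility_weights()] used by the utility criterion.
#' @return An object of class `screening_plan`: use [tidy()] for the
#'   ranked candidate table and [glance()] for a one-row summary of the
#'   selected procedure.
#' @examples
#' cand <- tibble::tibble(spec = "EK12:A6,B2,C6", sen = 0.9, spe = 0.995)
#' plan_screening(cand, strategy = "SCC", k = 70, theta = 0.80,
#'                pi_hat = 0.1767, sigma_hat = 0.55)
#' @export
plan_screening <- function(candidates, strategy = c("FWR", "FAR", "SCC"),
                           k, theta, pi_hat, sigma_hat = NULL,
                           criterion = c("min_n", "utility"),
                           weights = utility_weights()) {
  strategy <- match.arg(strategy)
  criterion <- match.arg(criterion)
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) stop_input("`candidates` must be non-empty.")
  if (!all(c("sen", "spe") %in% names(candidates))) {
    stop_input("`candidates` needs `sen` and `spe` columns.")
  }
  if (strategy == "SCC" && is.null(sigma_hat)) {
    stop_input("`sigma_hat` is required for the SCC strategy.")
  }
  check_prob(pi_hat, "pi_hat")

  if (!"spec" %in% names(candidates)) {
    candidates$spec <- sprintf("candidate-%d", seq_len(nrow(candidates)))
  }
  n_tests <- if ("ek" %in% names(candidates)) {
    combiners()$n_tests[match(candidates$ek, combiners()$ek)]
  } else {
    rep(1L, nrow(candidates))
  }

  success <- if (strategy == "SCC") {
    scc_success_prob(pi_hat, sigma_hat, candidates$sen, candidates$spe)
  } else {
    ppv(candidates$sen, candidates$spe, pi_hat)
  }
  n_req <- required_n(rep(as.integer(k), nrow(candidates)),
                      rep(theta, nrow(candidates)), success)
  util_pi <- if (strategy == "SCC") sigma_hat else pi_hat
  util <- overall_utility(candidates$sen, candidates$spe, util_pi, weights)

  ranked <- candidates |>
    mutate(success_prob = success, n_required = as.integer(n_req),
           n_method = attr(n_req, "method"), utility = util,
           n_tests = n_tests)
  ranked <- if (criterion == "min_n") {
    arrange(ranked, .data$n_required, .data$n_tests, .data$spec)
  } else {
    arrange(ranked, desc(.data$utility), .data$n_tests, .data$spec)
  }
  ranked <- mutate(ranked, rank = row_number())

  structure(
    list(
      candidates = ranked, strategy = strategy, criterion = criterion,
      k = as.integer(k), theta = theta, pi_hat = pi_hat,
      sigma_hat = sigma_hat, weights = weights
    ),
    class = "screening_plan"
  )
}

#' @export
print.screening_plan <- function(x, ...) {
  cat(sprintf("Screening plan (%s strategy, criterion %s)\n",
              x$strategy, x$criterion))
  cat(sprintf("  target k = %d true users at certainty theta = %.2f\n",
              x$k, x$theta))
  cat(sprintf("  prevalence estimate = %.4f%s\n", x$pi_hat,
              if (!is.null(x$sigma_hat))
                sprintf(", switching prevalence = %.4f", x$sigma_hat) else ""))
  best <- x$candidates[1, ]
  cat(sprintf("  selected: %s  (success prob %.4f, n = %d, utility %.4f)\n",
              best$spec, best$success_prob, best$n_required, best$utility))
  cat(sprintf("  %d candidate(s) ranked; tidy() for the full table\n",
              nrow(x$candidates)))
  invisible(x)
}

#' @rdname plan_screening
#' @param x A `screening_plan`.
#' @param ... Unused.
#' @export
tidy.screening_plan <- function(x, ...) {
  select(x$candidates, "rank", "spec", dplyr::any_of("ek"), "sen", "spe",
         "success_prob", "n_required", "n_method", "utility")
}

#' @rdname plan_screening
#' @export
glance.screening_plan <- function(x, ...) {
  best <- x$candidates[1, ]
  tibble(
    strategy = x$strategy, criterion = x$criterion, k = x$k, theta = x$theta,
    pi_hat = x$pi_hat, sigma_hat = x$sigma_hat %||% NA_real_,
    spec = best$spec, success_prob = best$success_prob,
    n_required = best$n_required, utility = best$utility,
    n_candidates = nrow(x$candidates)
  )
}

#' @rdname plan_screening
#' @param object A `screening_plan`.
#' @export
autoplot.screening_plan <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$success_prob, y = .data$n_required)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rank == 1), show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "red")) +
    ggplot2::labs(x = "Per-participant success probability",
                  y = sprintf("Required n for k = %d at theta = %.2f",
                              object$k, object$theta)) +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Post-hoc data-quality lower bound of a completed screening study
#'
#' After data collection, estimates a lower bound on the proportion of
#' true target-device users in the accepted sample, holding with
#' probability `theta`. For FWR/FAR the accepted sample of size `n` is
#' binomial with success probability the procedure's PPV, and the bound is
#' `k / n` with `k` from [data_quality_quantile()]. For SCC the
#' self-reported group D1 counts as quality 1, the prompted-positive group
#' D0+ is binomial at the PPV evaluated at the switching prevalence, and
#' the pooled bound is `(|D1| + k_{D0+}) / (|D1| + |D0+|)`.
#'
#' @param strategy `"FWR"`, `"FAR"` or `"SCC"`.
#' @param theta Certainty in (0, 1).
#' @param n Accepted sample size (FWR/FAR).
#' @param ppv Success probability of an accepted participant (FWR/FAR: the
#'   PPV at the study prevalence; SCC: the PPV at the switching
#'   prevalence, applying to D0+).
#' @param n_d1,n_d0pos Group sizes |D1| and |D0+| (SCC).
#' @return A one-row tibble: `strategy`, `quality` (the lower bound),
#'   `k_bound` (guaranteed true-user count), `n_total`, `theta`.
#' @examples
#' posthoc_quality("FAR", theta = 0.5, n = 100, ppv = 0.66)
#' @export
posthoc_quality <- function(strategy = c("FWR", "FAR", "SCC"), theta,
                            n = NULL, ppv = NULL,
                            n_d1 = NULL, n_d0pos = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "SCC") {
    if (is.null(n_d1) || is.null(n_d0pos) || is.null(ppv)) {
      stop_input("SCC needs `n_d1`, `n_d0pos` and `ppv` (at the switching prevalence).")
    }
    k0 <- if (n_d0pos > 0) data_quality_quantile(theta, n_d0pos, ppv) else 0L
    tibble(strategy = strategy,
           quality = (n_d1 + k0) / (n_d1 + n_d0pos),
           k_bound = as.integer(n_d1 + k0),
           n_total = as.integer(n_d1 + n_d0pos), theta = theta)
  } else {
    if (is.null(n) || is.null(ppv)) stop_input("FWR/FAR need `n` and `ppv`.")
    k <- data_quality_quantile(theta, n, ppv)
    tibble(strategy = strategy, quality = k / n, k_bound = as.integer(k),
           n_total = as.integer(n), theta = theta)
  }
}
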