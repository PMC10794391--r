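#' Packaged characteristics tables from the HALT headphone-screening studies
#'
#' Per-test, per-threshold sensitivity and specificity (with 95% Wilson
#' score intervals) for the three headphone screening tests, as published:
#' the laboratory pre-study (Tests A and B, four trials each, 80
#' observations per device group) and the Internet main study (Tests A, B
#' and C, six trials each, 80 headphone and 131 loudspeaker users). The
#' tables ship as one-decimal percentages; on load, the underlying integer
#' counts are reconstructed from percentage x group size and verified to
#' re-round to the printed value, and the returned proportions are the
#' full-precision count ratios.
#'
#' @param study `"mainstudy"` or `"prestudy"`.
#' @return A tibble with columns `test`, `threshold`, `sen`, `sen_lower`,
#'   `sen_upper`, `spe`, `spe_lower`, `spe_upper`, `n_pos`, `n_neg`,
#'   `n_sen`, `n_spe` (reconstructed success counts).
#' @examples
#' halt_characteristics("mainstudy")
#' @export
halt_characteristics <- function(study = c("mainstudy", "prestudy")) {
  study <- match.arg(study)
  path <- system.file("extdata", paste0("halt_characteristics_", study, ".csv"),
                      package = "screenplan", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  reconstruct <- function(pct, n, what) {
    count <- round(pct / 100 * n)
    if (any(abs(count / n * 100 - pct) > 0.05 + 1e-9)) {
      stop_input(sprintf("fixture %s: reconstructed %s count does not re-round to the printed percentage.",
                         study, what))
    }
    count
  }
  n_sen <- reconstruct(raw$sen_pct, raw$n_pos, "sensitivity")
  n_spe <- reconstruct(raw$spe_pct, raw$n_neg, "specificity")
  tibble(
    test = raw$test, threshold = as.integer(raw$threshold),
    sen = n_sen / raw$n_pos,
    sen_lower = raw$sen_lower_pct / 100, sen_upper = raw$sen_upper_pct / 100,
    spe = n_spe / raw$n_neg,
    spe_lower = raw$spe_lower_pct / 100, spe_upper = raw$spe_upper_pct / 100,
    n_pos = as.integer(raw$n_pos), n_neg = as.integer(raw$n_neg),
    n_sen = as.integer(n_sen), n_spe = as.integer(n_spe)
  )
}

#' Packaged headphone-prevalence estimates
#'
#' The two published self-report base rates of headphone use among online
#' participants: estimate A (80 of 211 valid cases after device exclusions)
#' and estimate B (211 of 1,194 participants reaching the device filter,
#' smartphones/tablets/TVs still included). Wilson score intervals are
#' recomputed from the counts.
#'
#' @param which `"A"` or `"B"`.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `label`, `n_headphones`, `n_total`, `pi_hat`,
#'   `lower`, `upper`.
#' @examples
#' halt_prevalence("B") # 211/1194, about 17.7%
#' @export
halt_prevalence <- function(which = c("A", "B"), level = 0.95) {
  which <- match.arg(which)
  path <- system.file("extdata", "halt_prevalence.csv",
                      package = "screenplan", mustWork = TRUE)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  row <- raw[raw$label == which, ]
  ci <- score_ci(row$n_headphones, row$n_total, level)
  tibble(label = row$label,
         n_headphones = as.integer(row$n_headphones),
         n_total = as.integer(row$n_total),
         pi_hat = ci$estimate, lower = ci$lower, upper = ci$upper)
}
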