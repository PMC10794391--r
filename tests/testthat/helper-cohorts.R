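# Builders and independent oracles shared across the suite.

# item-level cohort with exact per-participant correct counts: `pos_counts`
# and `neg_counts` give, for each test, the correct-response count of every
# headphone / loudspeaker participant (list named by test id)
cohort_from_counts <- function(pos_counts, neg_counts, trials = 6) {
  n_pos <- length(pos_counts[[1]])
  n_neg <- length(neg_counts[[1]])
  out <- tibble::tibble(
    participant_id = seq_len(n_pos + n_neg),
    device = c(rep("headphones", n_pos), rep("loudspeakers", n_neg)),
    self_report = c(rep("headphones", n_pos), rep("loudspeakers", n_neg))
  )
  for (tt in names(pos_counts)) {
    counts <- c(pos_counts[[tt]], neg_counts[[tt]])
    for (j in seq_len(trials)) {
      # first `count` trials correct: preserves the count, order irrelevant
      out[[paste0(tt, "_", j)]] <- as.integer(j <= counts)
    }
  }
  out
}

# cohort whose per-threshold confusion counts reproduce a characteristics
# table exactly: n_sen of n_pos headphone users reach each threshold etc.
# Works because "correct count >= t" is monotone: give participant i a
# correct count equal to the largest threshold they should pass.
cohort_from_characteristics <- function(chars, trials = max(chars$threshold)) {
  tests <- unique(chars$test)
  counts_for <- function(n_group, successes_by_threshold) {
    # successes_by_threshold[t] participants must have count >= t;
    # non-increasing in t, so participant i passes thresholds t with
    # successes_by_threshold[t] >= i
    sapply(seq_len(n_group), function(i) {
      passed <- which(successes_by_threshold >= i)
      if (length(passed) == 0) 0L else max(passed)
    })
  }
  pos <- neg <- list()
  for (tt in tests) {
    sub <- chars[chars$test == tt, ]
    sub <- sub[order(sub$threshold), ]
    stopifnot(all(sub$threshold == seq_len(nrow(sub))))
    pos[[tt]] <- counts_for(sub$n_pos[1], sub$n_sen)
    # spe counts are negatives below threshold; positives at threshold t
    # number n_neg - n_spe[t]
    neg[[tt]] <- counts_for(sub$n_neg[1], sub$n_neg[1] - sub$n_spe)
  }
  cohort_from_counts(pos, neg, trials = trials)
}

# hand-written logical rules for all 18 evaluation keys, independent of the
# package's weight representation
ek_logic <- list(
  function(a, b, c) a,
  function(a, b, c) b,
  function(a, b, c) c,
  function(a, b, c) a & b,
  function(a, b, c) a & c,
  function(a, b, c) b & c,
  function(a, b, c) a | b,
  function(a, b, c) a | c,
  function(a, b, c) b | c,
  function(a, b, c) a | b | c,
  function(a, b, c) (a + b + c) >= 2,
  function(a, b, c) a & b & c,
  function(a, b, c) (a | b) & c,
  function(a, b, c) (a | c) & b,
  function(a, b, c) (b | c) & a,
  function(a, b, c) (a & b) | c,
  function(a, b, c) (a & c) | b,
  function(a, b, c) (b & c) | a
)

# exhaustive outcome-tuple oracle for product-rule combination: sums the
# product probabilities of all 8 tuples through the hand-written logic
combine_oracle <- function(ek, sen, spe) {
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1)
  involved <- !is.na(sen)
  prob_given <- function(p_pos) {
    apply(g, 1, function(row) {
      pr <- 1
      for (s in 1:3) {
        if (!involved[s]) {
          if (row[s] == 1) return(0)
        } else {
          pr <- pr * if (row[s] == 1) p_pos[s] else 1 - p_pos[s]
        }
      }
      pr
    })
  }
  p_hp <- prob_given(sen)
  p_ls <- prob_given(1 - spe)
  gvote <- mapply(function(a, b, c) as.integer(ek_logic[[ek]](a == 1, b == 1, c == 1)),
                  g$a, g$b, g$c)
  list(sen = sum(p_hp[gvote == 1]), spe = sum(p_ls[gvote == 0]))
}

# smallest n with P(Binomial(n, p) >= k) >= theta, by upward scan
required_n_oracle <- function(k, theta, p) {
  n <- k
  while (pbinom(k - 1, n, p, lower.tail = FALSE) < theta) n <- n + 1
  n
}
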