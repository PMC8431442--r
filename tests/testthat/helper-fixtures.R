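# small in-code fixtures shared across test files

tiny_counts <- function() {
  m <- matrix(c(1L, 2L,
                0L, 5L,
                3L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m
}

# a small, fully valid cohort for fast integration tests
small_cohort <- function(seed = 1L, ...) {
  simulate_cohort(sim_config(n_pdac = 12L, n_cp = 10L, n_mirna = 60L,
                             seed = seed, ...))
}

# brute-force Mann-Whitney AUC by pair enumeration (independent oracle)
auc_pairs <- function(values, labels, case) {
  cs <- values[labels == case]
  ct <- values[labels != case]
  mean(outer(cs, ct, ">") + 0.5 * outer(cs, ct, "=="))
}

# hand-rolled BH step-up (independent of stats::p.adjust)
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# all permutations of a vector (recursive; used for small n only)
combinat_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(combinat_perms(v[-i]), function(p) c(v[i], p)))
  out
}

# two-group log-rank by explicit hypergeometric tables (independent oracle)
logrank_by_hand <- function(os_days, os_event, group) {
  g1 <- unique(group)[1]
  u <- 0; v <- 0
  for (t in sort(unique(os_days[os_event == 1]))) {
    at_risk <- os_days >= t
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(os_days == t & os_event == 1)
    d1j <- sum(os_days == t & os_event == 1 & group == g1)
    u <- u + d1j - dj * n1j / nj
    if (nj > 1)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  stat <- u^2 / v
  list(statistic = stat,
       p_value = stats::pchisq(stat, 1, lower.tail = FALSE))
}
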