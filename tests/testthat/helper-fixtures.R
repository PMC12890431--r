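# Shared in-code fixtures: small cohorts reused across test files.
# Built once per test run; all downstream randomness is seeded explicitly.

small_cohort <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      memo <<- simulate_cohort(cohort_config(n = 2500), seed = 101L)
    }
    memo
  }
})

# complete (no missingness) mid-size cohort for fitting tests
complete_cohort <- local({
  memo <- NULL
  function(n = 8000, seed = 202L, ...) {
    if (is.null(memo)) {
      cfg <- cohort_config(n = n, ...)
      cfg$missingness$rates[] <- 0
      memo <<- simulate_cohort(cfg, seed = seed)
    }
    memo
  }
})

with_seed_test <- function(seed, code) withr::with_seed(seed, code)

# brute-force O(n^2) Kendall tau-b oracle with tie correction
tau_b_oracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

# exhaustive pair-counting AUC oracle
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# step-up BH oracle: min over j >= i of p_(j) * m / j
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
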