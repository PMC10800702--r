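# Independent naive-loop oracles. Deliberately written with explicit
# element-wise loops and no shared code with the package internals, so
# agreement is a genuine cross-check.

oracle_ahp_weights <- function(a) {
  n <- nrow(a)
  w <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      csum <- 0
      for (k in seq_len(n)) csum <- csum + a[k, j]
      acc <- acc + a[i, j] / csum
    }
    w[i] <- acc / n
  }
  w
}

oracle_weighted_sum <- function(a, w) {
  n <- nrow(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)) s <- s + a[i, j] * w[j]
    out[i] <- s
  }
  out
}

# Full ARAS chain by loops: returns list(s = m+1 values, optimal last,
# k = m utility degrees, ranks).
oracle_aras <- function(scores, optimal, directions, w) {
  m <- nrow(scores); n <- ncol(scores)
  x <- rbind(scores, optimal)
  for (j in seq_len(n)) {
    if (directions[j] == "cost") {
      for (i in seq_len(m + 1)) x[i, j] <- 1 / x[i, j]
    }
  }
  shares <- x
  for (j in seq_len(n)) {
    csum <- 0
    for (i in seq_len(m + 1)) csum <- csum + x[i, j]
    for (i in seq_len(m + 1)) shares[i, j] <- x[i, j] / csum
  }
  s <- numeric(m + 1)
  for (i in seq_len(m + 1)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + shares[i, j] * w[j]
    s[i] <- acc
  }
  k <- numeric(m)
  for (i in seq_len(m)) k[i] <- s[i] / s[m + 1]
  ranks <- integer(m)
  for (i in seq_len(m)) {
    r <- 1L
    for (j in seq_len(m)) if (k[j] > k[i]) r <- r + 1L
    ranks[i] <- r
  }
  list(s = s, k = k, ranks = ranks)
}

# A random reciprocal matrix with discrete Saaty judgments: valid by
# construction, generally inconsistent.
random_saaty_matrix <- function(n, seed) {
  vals <- c(1 / (9:2), 1:9)
  withr::with_seed(seed, {
    a <- diag(n)
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        v <- sample(vals, 1)
        a[i, j] <- v
        a[j, i] <- 1 / v
      }
    }
    a
  })
}

random_weights <- function(n, seed) {
  withr::with_seed(seed, {
    w <- stats::rexp(n) + 0.05
    w / sum(w)
  })
}

# The worked health-monitoring example, loaded once per test file.
fixture_pairwise <- function() health_pairwise()
fixture_decision <- function() health_decision()
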