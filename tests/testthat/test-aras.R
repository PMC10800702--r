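# Decision-matrix construction and the ARAS ranking chain.

test_that("the optimal row is derived as column extrema by direction", {
  d <- fixture_decision()
  expect_equal(unname(attr(d, "optimal")), c(9, 8, 9, 7, 6, 8, 9, 9))
  expect_equal(unname(attr(decision_matrix(cbind(c(2, 5, 3))), "optimal")), 5)
  expect_equal(unname(attr(decision_matrix(cbind(c(2, 5, 3)),
                                           directions = "cost"), "optimal")), 2)
})

test_that("invalid scores and user optima are handled per contract", {
  expect_error(decision_matrix(rbind(c(1, 2), c(0, 3))), "positive")
  expect_error(decision_matrix(rbind(c(1, 2), c(1, 3)), optimal = c(5, 5, 5)),
               "one value per criterion")
  d <- decision_matrix(rbind(c(2, 4), c(6, 3)), optimal = c(4, 4))
  expect_identical(attr(d, "optimal_source"), "user")
  expect_match(attr(d, "warnings"), "beaten", all = TRUE)
  expect_length(attr(d, "warnings"), 1L) # only C1's optimum is beaten
})

test_that("share normalization sums to one and reproduces known shares", {
  d <- fixture_decision()
  nd <- normalize_decision(d)
  expect_equal(unname(colSums(nd)), rep(1, 8), tolerance = 1e-12)
  expect_equal(nd["OV", "C1"], 9 / 47, tolerance = 1e-15)
  expect_equal(nd["Ap1", "C3"], 9 / 49, tolerance = 1e-15)
  expect_true(all(nd > 0 & nd < 1))
  # uniform column: equal scores share 1/(m+1)
  u <- decision_matrix(cbind(rep(4, 4)))
  expect_equal(unname(normalize_decision(u)[, 1]), rep(0.2, 5))
})

test_that("shares are invariant to rescaling a raw criterion column", {
  d <- fixture_decision()
  x <- unclass(d)
  x[, 3] <- x[, 3] * 10
  d10 <- decision_matrix(x, directions = attr(d, "directions"))
  expect_equal(normalize_decision(d10), normalize_decision(d), tolerance = 1e-12)
})

test_that("a cost criterion behaves exactly like a benefit criterion on reciprocals", {
  scores <- withr::with_seed(11, matrix(sample(1:9, 12, TRUE), 4, 3))
  cost <- decision_matrix(scores, directions = c("benefit", "cost", "benefit"))
  recip <- scores
  recip[, 2] <- 1 / recip[, 2]
  ben <- decision_matrix(recip, directions = "benefit")
  expect_equal(unname(normalize_decision(cost)[, 2]),
               unname(normalize_decision(ben)[, 2]), tolerance = 1e-14)
})

test_that("weighting scales each column to its weight", {
  d <- fixture_decision()
  w <- coef(ahp(fixture_pairwise()))
  wd <- apply_weights(normalize_decision(d), w)
  expect_equal(unname(colSums(wd)), unname(w), tolerance = 1e-12)
  expect_equal(wd["OV", "C7"], (9 / 52) * w[["C7"]], tolerance = 1e-15)
  # equal weights reduce weighting to a global 1/n scaling
  nd <- normalize_decision(d)
  expect_equal(apply_weights(nd, rep(1 / 8, 8)), nd / 8, tolerance = 1e-15)
  expect_error(apply_weights(nd, rep(1 / 3, 3)), "criterion count")
})

test_that("optimality values conserve total mass and divide into utility degrees", {
  d <- fixture_decision()
  w <- coef(ahp(fixture_pairwise()))
  s <- optimality_values(apply_weights(normalize_decision(d), w))
  expect_equal(sum(s), 1, tolerance = 1e-12)
  k <- utility_degrees(s)
  expect_equal(length(k), 8L)
  expect_error(utility_degrees(unname(s)), "OV")
  # an alternative equal to the optimal row attains K = 1
  eq <- decision_matrix(rbind(c(5, 5), c(2, 3), c(5, 5)))
  fit <- aras(eq, c(0.5, 0.5))
  expect_equal(unname(fit$k[c(1, 3)]), c(1, 1), tolerance = 1e-14)
})

test_that("ranking is descending in K with competition ties", {
  expect_equal(unname(rank_alternatives(c(a = 0.9, b = 0.5, c = 0.7))),
               c(1L, 3L, 2L))
  expect_equal(unname(rank_alternatives(c(0.5, 0.5, 0.5))), c(1L, 1L, 1L))
  expect_equal(unname(rank_alternatives(c(0.8, 0.6, 0.6, 0.2))),
               c(1L, 2L, 2L, 4L))
  expect_equal(unname(rank_alternatives(seq(0.9, 0.1, length.out = 5))), 1:5)
  expect_error(rank_alternatives(numeric(0)), "no alternatives")
})

test_that("the full chain matches the naive-loop oracle on random instances", {
  for (seed in 1:40) {
    m <- 2 + (seed %% 6); n <- 2 + (seed %% 4)
    dirs <- withr::with_seed(seed + 500,
                             sample(c("benefit", "cost"), n, TRUE))
    d <- simulate_decision(m, n, seed = seed, directions = dirs)
    w <- random_weights(n, seed + 1000)
    fit <- aras(d, w)
    orc <- oracle_aras(unclass(d), attr(d, "optimal"), dirs, w)
    expect_equal(unname(fit$k), orc$k, tolerance = 1e-12)
    expect_equal(unname(fit$s), orc$s[seq_len(m)], tolerance = 1e-12)
    expect_equal(fit$s0, orc$s[m + 1], tolerance = 1e-12)
    expect_equal(unname(fit$ranks), orc$ranks)
  }
})

test_that("increasing a benefit score strictly improves the relative standing", {
  for (seed in 1:20) {
    d <- simulate_decision(5, 4, seed = seed)
    w <- random_weights(4, seed + 77)
    base <- aras(d, w)
    x <- unclass(d)
    x[2, 3] <- x[2, 3] + 2
    bumped <- aras(decision_matrix(x), w)
    for (j in seq_len(5)) {
      if (j == 2) next
      expect_gt(bumped$s[2] / bumped$s[j], base$s[2] / base$s[j])
    }
  }
})

test_that("permuting alternatives permutes S, K and ranks identically", {
  d <- fixture_decision()
  w <- coef(ahp(fixture_pairwise()))
  fit <- aras(d, w)
  perm <- withr::with_seed(3, sample(8))
  dp <- decision_matrix(unclass(d)[perm, ], alternatives = rownames(d)[perm])
  fitp <- aras(dp, w)
  expect_equal(unname(fitp$k), unname(fit$k)[perm], tolerance = 1e-14)
  expect_equal(unname(fitp$s), unname(fit$s)[perm], tolerance = 1e-14)
  expect_equal(unname(fitp$ranks), unname(fit$ranks)[perm])
})

test_that("weights are reconciled to the decision matrix by criterion id", {
  d <- fixture_decision()
  w <- coef(ahp(fixture_pairwise()))
  shuffled <- w[c(3, 1, 2, 8, 5, 4, 7, 6)]
  expect_equal(aras(d, shuffled)$k, aras(d, w)$k, tolerance = 1e-15)
  names(shuffled)[1] <- "C9"
  expect_error(aras(d, shuffled), "C9")
  expect_error(aras(d, rep(0.2, 5)), "sum to 1|criterion count")
})

test_that("a single alternative equal to its own optimum ranks first with K = 1", {
  d <- decision_matrix(matrix(c(3, 7), 1, 2))
  fit <- aras(d, c(0.4, 0.6))
  expect_equal(unname(fit$k), 1, tolerance = 1e-14)
  expect_equal(unname(fit$ranks), 1L)
})
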