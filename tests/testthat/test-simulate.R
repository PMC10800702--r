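# The scenario generator: reproducibility, exact consistency at zero
# jitter, Saaty snapping, and controlled inconsistency.

test_that("scenarios are reproducible and seed-sensitive", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  expect_identical(simulate_pairwise(w, seed = 5, inconsistency = 0.3),
                   simulate_pairwise(w, seed = 5, inconsistency = 0.3))
  expect_false(identical(simulate_pairwise(w, seed = 5, inconsistency = 0.3),
                         simulate_pairwise(w, seed = 6, inconsistency = 0.3)))
  expect_identical(simulate_decision(8, 8, seed = 9),
                   simulate_decision(8, 8, seed = 9))
  # and the global RNG stream is untouched
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_decision(4, 4, seed = 1)); after <- runif(1)
  expect_identical(before, after)
})

test_that("zero inconsistency without snapping gives an exactly consistent matrix", {
  m <- simulate_pairwise(c(0.5, 0.25, 0.25), seed = 1)
  expect_equal(m[1, 2], 2)
  expect_equal(m[1, 3], 2)
  expect_equal(m[2, 3], 1)
  fit <- ahp(m)
  expect_equal(fit$cr, 0, tolerance = 1e-9)
})

test_that("generated matrices validate cleanly at zero jitter", {
  for (seed in 1:20) {
    n <- 3 + (seed %% 6)
    w <- random_weights(n, seed)
    expect_no_warning({
      m <- simulate_pairwise(w, seed = seed)
      d <- simulate_decision(5, n, seed = seed)
    })
    expect_s3_class(m, "pairwise_matrix")
    expect_s3_class(d, "decision_matrix")
  }
})

test_that("snapping lands on exact Saaty values and still recovers the weights", {
  m <- simulate_pairwise(c(0.6, 0.3, 0.1), seed = 2, snap = TRUE)
  expect_equal(m[1, 3], 6) # the 0.6/0.1 ratio is already on the scale
  expect_equal(m[1, 2], 2)
  expect_equal(m[2, 3], 3)
  w <- coef(ahp(m))
  expect_lt(max(abs(w - c(0.6, 0.3, 0.1))), 0.02)
  # ratios beyond the scale are clamped with a warning
  expect_warning(simulate_pairwise(c(0.95, 0.05), seed = 3, snap = TRUE),
                 "clamped")
})

test_that("snapped recovery error stays below 0.06 for representable weights", {
  # uniform-simplex weights, conditioned on every pairwise ratio being
  # representable on the Saaty scale
  worst <- 0
  for (seed in 1:200) {
    n <- 3 + (seed %% 6)
    w <- withr::with_seed(seed + 2000, { w <- stats::rexp(n); w / sum(w) })
    if (max(outer(w, w, "/")) > 9) next
    m <- simulate_pairwise(w, seed = seed, snap = TRUE)
    worst <- max(worst, max(abs(coef(ahp(m)) - w)))
  }
  expect_lt(worst, 0.06)
})

test_that("mean consistency ratio grows with the inconsistency level", {
  mean_cr <- function(level) {
    crs <- vapply(1:200, function(seed) {
      w <- random_weights(6, seed + 4000)
      ahp(simulate_pairwise(w, seed = seed, inconsistency = level))$cr
    }, numeric(1))
    mean(crs)
  }
  expect_gt(mean_cr(0.3), mean_cr(0.1))
})

test_that("decision scenarios honour the score range and reject an empty one", {
  d <- simulate_decision(6, 3, seed = 4, score_range = c(5, 5))
  expect_true(all(unclass(d) == 5))
  fit <- aras(d, rep(1 / 3, 3))
  expect_equal(unname(fit$k), rep(1, 6), tolerance = 1e-14)
  expect_equal(unname(fit$ranks), rep(1L, 6))
  expect_error(simulate_decision(3, 3, seed = 1, score_range = c(7, 2)),
               "empty score range")
})

test_that("the top-ranked alternative tends to score above the population mean", {
  hits <- 0
  for (seed in 1:200) {
    d <- simulate_decision(8, 8, seed = seed)
    fit <- aras(d, rep(1 / 8, 8))
    best <- which(fit$ranks == 1L)[1L]
    if (mean(unclass(d)[best, ]) >= mean(unclass(d))) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.95)
})

test_that("perturbation at zero noise is the identity and re-derives the optimum", {
  d <- decision_matrix(unclass(fixture_decision())) # derived optimum
  expect_equal(perturb_decision(d, 0, seed = 1), d)
  p <- perturb_decision(d, 2, seed = 1)
  expect_true(all(unclass(p) >= 1))
  expect_true(all(unclass(p) == round(unclass(p)))) # integer scale preserved
  derived <- vapply(seq_len(ncol(p)), function(j) max(unclass(p)[, j]), 0)
  expect_equal(unname(attr(p, "optimal")), derived)
})

test_that("rank stability degrades monotonically with score noise", {
  d <- fixture_decision()
  w <- coef(ahp(fixture_pairwise()))
  retained <- function(noise_sd) {
    keep <- vapply(1:150, function(seed) {
      fit <- aras(perturb_decision(d, noise_sd, seed = seed), w)
      fit$ranks[["Ap2"]] == 1L
    }, logical(1))
    mean(keep)
  }
  lo <- retained(0.1); hi <- retained(5)
  expect_true(lo >= 0 && lo <= 1)
  expect_lte(hi, lo)
})
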