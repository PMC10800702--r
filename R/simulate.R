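# Scenario generator: synthetic judgment and score matrices with known
# ground truth, for parameter-recovery and robustness studies.

saaty_values <- function() c(1 / (9:2), 1:9)

#' Simulate a pairwise-comparison matrix from known weights
#'
#' Builds a reciprocal judgment matrix around a ground-truth weight vector
#' `w`, so that recovery of the weights by [ahp()] can be studied under
#' controlled inconsistency. Each upper-triangle entry is
#' `(w[i]/w[j]) * eps` with log-normal jitter `eps` (standard deviation
#' `inconsistency` on the log scale); the lower triangle mirrors exact
#' reciprocals, so reciprocity survives any perturbation. At
#' `inconsistency = 0` without snapping the matrix is exactly consistent
#' and [ahp()] recovers `w` to machine precision.
#'
#' With `snap = TRUE` each upper-triangle entry is moved to the nearest
#' Saaty value (nearest in log space, over `{1/9..1/2, 1..9}`), emulating
#' an expert forced onto the discrete 1-9 scale; ratios outside the scale
#' are clamped to 9 or 1/9 with a warning.
#'
#' @param weights Positive ground-truth weights; normalized to sum to 1.
#' @param seed Integer seed; the generator never touches the global RNG
#'   state.
#' @param inconsistency Log-scale spread of the multiplicative jitter
#'   (0 = perfectly consistent).
#' @param snap Snap judgments to the discrete Saaty scale?
#' @return A `"pairwise_matrix"`.
#' @examples
#' m <- simulate_pairwise(c(0.5, 0.25, 0.25), seed = 1)
#' m[1, 2] # exactly 2
#' @export
simulate_pairwise <- function(weights, seed, inconsistency = 0, snap = FALSE) {
  w <- as.numeric(weights)
  if (any(w <= 0)) stop("ground-truth weights must be strictly positive", call. = FALSE)
  if (inconsistency < 0) stop("inconsistency level must be >= 0", call. = FALSE)
  w <- w / sum(w)
  n <- length(w)
  if (n < 2L) stop("need at least 2 criteria", call. = FALSE)
  nm <- names(weights)
  if (is.null(nm)) nm <- paste0("C", seq_len(n))

  a <- withr::with_seed(seed, {
    a <- diag(n)
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        eps <- if (inconsistency > 0) exp(stats::rnorm(1, 0, inconsistency)) else 1
        v <- (w[i] / w[j]) * eps
        if (snap) {
          if (v > 9 || v < 1 / 9) {
            warning("weight ratio ", format(signif(v, 3)),
                    " outside the Saaty scale; clamped", call. = FALSE)
            v <- min(max(v, 1 / 9), 9)
          }
          sv <- saaty_values()
          v <- sv[which.min(abs(log(sv) - log(v)))]
        }
        a[i, j] <- v
        a[j, i] <- 1 / v
      }
    }
    a
  })
  pairwise_matrix(a, criteria = nm, scale_action = "none")
}

#' Simulate a decision matrix of integer expert scores
#'
#' Draws uniform integer performance scores (default on the 1-9 rating
#' scale) for `m` alternatives on `n` criteria and derives the optimal
#' row, emulating the score matrices produced by an expert panel.
#'
#' @param m Number of alternatives.
#' @param n Number of criteria.
#' @param seed Integer seed; the global RNG state is untouched.
#' @param directions Per-criterion `"benefit"`/`"cost"` (recycled).
#' @param score_range Integer bounds `c(lo, hi)` of the score scale.
#' @return A [decision_matrix()].
#' @export
simulate_decision <- function(m, n, seed, directions = "benefit",
                              score_range = c(1L, 9L)) {
  lo <- as.integer(score_range[1L]); hi <- as.integer(score_range[2L])
  if (is.na(lo) || is.na(hi) || lo > hi) {
    stop("empty score range: ", score_range[1L], "..", score_range[2L],
         call. = FALSE)
  }
  if (lo < 1L) stop("scores must be strictly positive", call. = FALSE)
  vals <- seq.int(lo, hi)
  scores <- withr::with_seed(seed, {
    matrix(vals[sample.int(length(vals), m * n, replace = TRUE)], m, n)
  })
  decision_matrix(scores, directions = directions)
}

#' Perturb a decision matrix with score noise
#'
#' Adds Gaussian noise to every raw score, truncated so scores stay
#' strictly positive; when the input scores are all integers the noisy
#' scores are rounded back to integers (floored at 1), mirroring a rating
#' scale. The optimal row is re-derived. Used to measure how stable a
#' ranking is against measurement error in the expert scores.
#'
#' @param d A [decision_matrix()].
#' @param noise_sd Standard deviation of the additive noise (0 returns the
#'   input unchanged).
#' @param seed Integer seed; the global RNG state is untouched.
#' @return A [decision_matrix()] of the same shape and directions.
#' @export
perturb_decision <- function(d, noise_sd, seed) {
  if (!inherits(d, "decision_matrix")) stop("`d` must be a decision_matrix", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  x <- unclass(d)
  integer_scale <- all(x == round(x))
  y <- withr::with_seed(seed, x + stats::rnorm(length(x), 0, noise_sd))
  y <- if (integer_scale) pmax(round(y), 1) else pmax(y, min(x) * 1e-6)
  decision_matrix(y, alternatives = rownames(d), criteria = colnames(d),
                  directions = attr(d, "directions"))
}
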