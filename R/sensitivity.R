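# Rank-stability diagnostics: weight perturbation and criterion knockout.

get_ranking_inputs <- function(x) {
  if (inherits(x, "hybrid_mcda")) x <- x$aras
  if (!inherits(x, "aras")) {
    stop("`x` must be an aras or hybrid_mcda fit", call. = FALSE)
  }
  x
}

#' Rank stability under weight perturbation
#'
#' Measures how robust a ranking is to uncertainty in the criterion
#' weights. Each replicate multiplies every weight by an independent
#' uniform factor in `[1 - epsilon, 1 + epsilon]` (perturbation is
#' relative, because MCDA weights commonly span an order of magnitude),
#' renormalizes to the simplex, re-runs ARAS, and records whether each
#' alternative keeps its original rank. The result is the per-alternative
#' frequency of rank retention over the replicates.
#'
#' @param x An [aras()] or [hybrid_mcda()] fit.
#' @param epsilon Relative perturbation half-width (>= 0).
#' @param samples Number of Monte-Carlo replicates (>= 1).
#' @param seed Integer seed; the global RNG state is untouched.
#' @return An object of class `"rank_stability"`: a list with `stability`
#'   (named frequencies in [0, 1]), `original_ranks`, `epsilon`, `samples`
#'   and `seed`.
#' @examples
#' fit <- hybrid_mcda(health_pairwise(), health_decision())
#' rank_stability(fit, epsilon = 0.05, samples = 100, seed = 1)
#' @export
rank_stability <- function(x, epsilon, samples, seed) {
  r <- get_ranking_inputs(x)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (samples < 1L) stop("need at least one replicate", call. = FALSE)
  w <- r$weights
  d <- r$decision
  original <- r$ranks
  kept <- withr::with_seed(seed, {
    kept <- matrix(FALSE, samples, length(original))
    for (b in seq_len(samples)) {
      wp <- w * (1 + stats::runif(length(w), -epsilon, epsilon))
      wp <- wp / sum(wp)
      kept[b, ] <- aras(d, wp)$ranks == original
    }
    kept
  })
  freq <- colMeans(kept)
  names(freq) <- names(original)
  structure(list(stability = freq, original_ranks = original,
                 epsilon = epsilon, samples = samples, seed = seed),
            class = "rank_stability")
}

#' @export
print.rank_stability <- function(x, digits = 3, ...) {
  cat("Rank stability under relative weight perturbation (epsilon = ",
      x$epsilon, ", ", x$samples, " replicates)\n\n", sep = "")
  tab <- data.frame(rank = x$original_ranks,
                    retained = round(x$stability, digits),
                    row.names = names(x$stability))
  print(tab[order(tab$rank), ])
  invisible(x)
}

#' Criterion-knockout rankings
#'
#' Re-ranks the alternatives with each criterion removed in turn: column
#' `j` is dropped from the decision matrix, the remaining weights are
#' renormalized to sum to 1, and ARAS is re-run. A ranking that survives
#' every knockout does not hinge on any single criterion; knocking out a
#' zero-weight criterion leaves the ranking unchanged.
#'
#' @param x An [aras()] or [hybrid_mcda()] fit with at least 2 criteria.
#' @return An object of class `"criterion_knockout"`: a list with
#'   `rankings` (criteria x alternatives matrix of ranks; row `j` is the
#'   ranking without criterion `j`), `weights` (list of renormalized
#'   weight vectors), `k` (matrix of utility degrees) and
#'   `original_ranks`.
#' @export
criterion_knockout <- function(x) {
  r <- get_ranking_inputs(x)
  d <- r$decision
  w <- r$weights
  n <- length(w)
  if (n < 2L) stop("knockout needs at least 2 criteria", call. = FALSE)
  crit <- colnames(d)
  rankings <- matrix(NA_integer_, n, nrow(d), dimnames = list(crit, rownames(d)))
  kmat <- matrix(NA_real_, n, nrow(d), dimnames = list(crit, rownames(d)))
  wlist <- vector("list", n)
  names(wlist) <- crit
  user_opt <- attr(d, "optimal_source") == "user"
  for (j in seq_len(n)) {
    wj <- w[-j]
    if (sum(wj) <= 0) {
      stop("all remaining weight mass is on criterion ", crit[j],
           "; cannot renormalize after knocking it out", call. = FALSE)
    }
    wj <- wj / sum(wj)
    dj <- decision_matrix(
      unclass(d)[, -j, drop = FALSE],
      alternatives = rownames(d),
      criteria = crit[-j],
      directions = attr(d, "directions")[-j],
      optimal = if (user_opt) attr(d, "optimal")[-j] else NULL
    )
    fit <- aras(dj, wj)
    rankings[j, ] <- fit$ranks
    kmat[j, ] <- fit$k
    wlist[[j]] <- wj
  }
  structure(list(rankings = rankings, weights = wlist, k = kmat,
                 original_ranks = r$ranks),
            class = "criterion_knockout")
}

#' @export
print.criterion_knockout <- function(x, ...) {
  cat("Rankings with each criterion knocked out (rows = removed criterion)\n\n")
  print(x$rankings)
  cat("\nOriginal ranking:\n")
  print(x$original_ranks)
  invisible(x)
}
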