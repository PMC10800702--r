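# Validated pairwise-comparison matrices on the Saaty 1-9 scale.

#' Saaty random index
#'
#' Average consistency index of random reciprocal matrices of order `n`,
#' used as the denominator of the consistency ratio. The built-in table
#' covers n = 1..15 (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
#' 1.51, 1.48, 1.56, 1.57, 1.59); RI is 0 for n <= 2 because a 2x2
#' reciprocal matrix is always consistent.
#'
#' @param n Matrix order (number of criteria).
#' @param ri_table Optional replacement table, a numeric vector indexed by
#'   `n`. Supply this to use a random index beyond order 15 or from a
#'   different calibration.
#' @return The random index, a single non-negative number.
#' @examples
#' saaty_random_index(8) # 1.41
#' @export
saaty_random_index <- function(n, ri_table = NULL) {
  if (is.null(ri_table)) {
    ri_table <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
                  1.51, 1.48, 1.56, 1.57, 1.59)
  }
  n <- as.integer(n)
  if (n < 1L || n > length(ri_table)) {
    stop("no random index available for n = ", n,
         "; supply `ri_table` covering this order", call. = FALSE)
  }
  ri_table[n]
}

#' Construct a validated pairwise-comparison matrix
#'
#' Checks a square grid of expert judgments against the contract of an AHP
#' comparison matrix: strictly positive entries, unit diagonal, reciprocity
#' (`a[j,i] * a[i,j] = 1`) within a relative tolerance, and entries on the
#' Saaty scale `[1/9, 9]`. The reciprocity tolerance is deliberately loose
#' by default (0.05) so that matrices transcribed with two-decimal
#' roundings of reciprocals (0.33 for 1/3, 0.13 for 1/8, 0.11 for 1/9)
#' validate cleanly.
#'
#' @param x Square numeric matrix of judgments; cell `[i, j]` is how
#'   strongly criterion `i` is preferred over criterion `j`.
#' @param criteria Character vector of criterion ids. Defaults to the
#'   dimnames of `x`, or `C1..Cn` when absent.
#' @param reciprocity_tol Relative tolerance for `|a_ij * a_ji - 1|`; also
#'   used for the unit-diagonal check.
#' @param scale_action What to do with entries outside `[1/9, 9]` (after
#'   widening by `reciprocity_tol`): `"warn"` (default), `"error"`, or
#'   `"none"`.
#' @return A matrix of class `"pairwise_matrix"` with criterion ids as
#'   dimnames.
#' @examples
#' m <- pairwise_matrix(rbind(c(1, 3), c(1 / 3, 1)), criteria = c("C1", "C2"))
#' @export
pairwise_matrix <- function(x, criteria = NULL, reciprocity_tol = 0.05,
                            scale_action = c("warn", "error", "none")) {
  scale_action <- match.arg(scale_action)
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    stop("pairwise matrix must be square; got ", nrow(x), " x ", ncol(x),
         call. = FALSE)
  }
  n <- nrow(x)
  if (n < 2L) stop("pairwise matrix needs at least 2 criteria", call. = FALSE)
  if (!is.numeric(x) || anyNA(x)) {
    stop("pairwise matrix entries must be numeric and non-missing",
         call. = FALSE)
  }
  if (is.null(criteria)) {
    criteria <- rownames(x)
    if (is.null(criteria)) criteria <- paste0("C", seq_len(n))
  }
  if (length(criteria) != n) {
    stop("length(criteria) must equal the matrix order", call. = FALSE)
  }
  if (anyDuplicated(criteria)) {
    stop("criterion ids must be unique", call. = FALSE)
  }
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1L, ]
    stop("judgment at (", criteria[bad[1L]], ", ", criteria[bad[2L]],
         ") is not strictly positive", call. = FALSE)
  }
  if (any(abs(diag(x) - 1) > reciprocity_tol)) {
    bad <- which(abs(diag(x) - 1) > reciprocity_tol)[1L]
    stop("diagonal entry for ", criteria[bad], " is ", diag(x)[bad],
         "; self-comparisons must equal 1", call. = FALSE)
  }
  prod_dev <- abs(x * t(x) - 1)
  if (any(prod_dev > reciprocity_tol)) {
    bad <- which(prod_dev > reciprocity_tol, arr.ind = TRUE)
    bad <- bad[bad[, 1L] < bad[, 2L], , drop = FALSE]
    if (nrow(bad) == 0L) bad <- which(prod_dev > reciprocity_tol, arr.ind = TRUE)
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop("reciprocity violated for (", criteria[i], ", ", criteria[j],
         "): ", format(x[i, j]), " * ", format(x[j, i]), " = ",
         format(x[i, j] * x[j, i]), " differs from 1 by more than ",
         reciprocity_tol, call. = FALSE)
  }
  lo <- (1 / 9) * (1 - reciprocity_tol)
  hi <- 9 * (1 + reciprocity_tol)
  if (scale_action != "none" && any(x < lo | x > hi)) {
    bad <- which(x < lo | x > hi, arr.ind = TRUE)[1L, ]
    msg <- paste0("judgment at (", criteria[bad[1L]], ", ", criteria[bad[2L]],
                  ") lies outside the Saaty scale [1/9, 9]")
    if (scale_action == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  dimnames(x) <- list(criteria, criteria)
  structure(x, class = c("pairwise_matrix", "matrix", "array"))
}

#' @export
print.pairwise_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise comparison matrix (", nrow(x), " criteria, Saaty scale)\n",
      sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Column-normalize a pairwise matrix
#'
#' Divides every judgment by its column total, so that each column of the
#' result sums to 1. This is the first step of the column-mean (approximate
#' eigenvector) weight derivation.
#'
#' @param m A [pairwise_matrix()] (a raw square matrix is validated first).
#' @return An n x n numeric matrix with unit column sums.
#' @export
normalize_pairwise <- function(m) {
  if (!inherits(m, "pairwise_matrix")) m <- pairwise_matrix(m)
  sweep(unclass(m), 2L, colSums(m), "/")
}

#' Derive criterion weights from a normalized pairwise matrix
#'
#' Averages each row of the column-normalized matrix over the `n` criteria.
#' The resulting weights are non-negative and sum to one.
#'
#' @param normalized Column-normalized matrix, as from [normalize_pairwise()].
#' @return Named numeric vector of weights summing to 1.
#' @export
derive_weights <- function(normalized) {
  cs <- colSums(normalized)
  if (any(abs(cs - 1) > 1e-8)) {
    stop("input columns must each sum to 1; did you call normalize_pairwise()?",
         call. = FALSE)
  }
  rowMeans(normalized)
}

#' Weighted sum values of a pairwise matrix
#'
#' Multiplies the (unnormalized) judgment matrix by the weight vector:
#' `value_i = sum_j a[i,j] * w[j]`. For a perfectly consistent matrix this
#' equals `n * w`. Computed at full precision, never from rounded weights.
#'
#' @param m A [pairwise_matrix()].
#' @param w Weight vector of matching length.
#' @return Named numeric vector, one value per criterion.
#' @export
weighted_sum_values <- function(m, w) {
  if (length(w) != nrow(m)) {
    stop("weight vector length ", length(w), " does not match matrix order ",
         nrow(m), call. = FALSE)
  }
  drop(unclass(m) %*% as.numeric(w))
}

#' Principal-eigenvalue estimate of a pairwise matrix
#'
#' The mean over criteria of the ratio (weighted sum value / weight). For a
#' reciprocal matrix this estimates the principal eigenvalue and is bounded
#' below by the matrix order `n`, with equality exactly at consistency.
#'
#' @param wsv Weighted sum values from [weighted_sum_values()].
#' @param w Weight vector (all entries strictly positive).
#' @return A single number, `lambda_max >= n`.
#' @export
lambda_max <- function(wsv, w) {
  if (length(wsv) != length(w)) {
    stop("weighted sum values and weights differ in length", call. = FALSE)
  }
  if (any(w <= 0)) {
    bad <- if (is.null(names(w))) which(w <= 0)[1L] else names(w)[which(w <= 0)[1L]]
    stop("weight for criterion ", bad, " is not strictly positive; ",
         "cannot form the ratio", call. = FALSE)
  }
  mean(wsv / w)
}

#' Consistency index
#'
#' `CI = (lambda_max - n) / (n - 1)`; zero for perfectly consistent
#' judgments, growing with contradiction among the pairwise comparisons.
#'
#' @param lmax Principal-eigenvalue estimate from [lambda_max()].
#' @param n Matrix order; must be at least 2.
#' @return A single number.
#' @export
consistency_index <- function(lmax, n) {
  if (n < 2L) stop("consistency index requires n >= 2", call. = FALSE)
  (lmax - n) / (n - 1)
}

#' Consistency ratio
#'
#' `CR = CI / RI(n)` against the Saaty random-index table. A ratio above
#' the threshold (conventionally 0.10) marks the judgments as inconsistent
#' but is reported as a warning status, never a hard failure: analysts
#' routinely proceed with mildly inconsistent panels, and the decision of
#' whether to re-elicit belongs to them. For n <= 2 the random index is 0
#' and CR is defined as 0 (such matrices are always consistent).
#'
#' @param ci Consistency index.
#' @param n Matrix order.
#' @param threshold CR cutoff separating `"consistent"` from `"warning"`.
#' @param ri_table Optional random-index table passed to
#'   [saaty_random_index()].
#' @return A list with components `cr`, `ri`, `threshold` and `status`
#'   (`"consistent"` or `"warning"`).
#' @export
consistency_ratio <- function(ci, n, threshold = 0.10, ri_table = NULL) {
  ri <- saaty_random_index(n, ri_table)
  cr <- if (ri > 0) ci / ri else 0
  list(cr = cr, ri = ri, threshold = threshold,
       status = if (cr <= threshold) "consistent" else "warning")
}
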