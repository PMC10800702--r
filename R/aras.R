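# Additive ratio assessment: share normalization, weighting, optimality
# values and utility degrees.

#' Share-normalize a decision matrix
#'
#' Converts raw scores to shares. For a benefit criterion each cell is
#' divided by its column total, with the optimal row included in the
#' denominator. For a cost criterion every score (optimal row included) is
#' first replaced by its reciprocal and the same share normalization is
#' applied, so that smaller raw scores earn larger shares. Every column of
#' the result sums to 1.
#'
#' @param d A [decision_matrix()].
#' @return An (m+1) x n numeric matrix whose last row, labelled `"OV"`, is
#'   the normalized optimal row.
#' @export
normalize_decision <- function(d) {
  if (!inherits(d, "decision_matrix")) {
    stop("`d` must be a decision_matrix", call. = FALSE)
  }
  x <- rbind(unclass(d), OV = attr(d, "optimal"))
  dirs <- attr(d, "directions")
  cost <- which(dirs == "cost")
  x[, cost] <- 1 / x[, cost]
  sweep(x, 2L, colSums(x), "/")
}

#' Weight a normalized decision matrix
#'
#' Multiplies each criterion's column of shares by that criterion's weight.
#' Column `j` of the result sums to `w[j]`.
#'
#' @param nd Normalized matrix from [normalize_decision()].
#' @param w Weight vector (full precision), one entry per criterion.
#' @return Weighted normalized matrix of the same shape as `nd`.
#' @export
apply_weights <- function(nd, w) {
  w <- as.numeric(if (inherits(w, "ahp")) coef(w) else w)
  if (length(w) != ncol(nd)) {
    stop("weight vector length ", length(w),
         " does not match the criterion count ", ncol(nd), call. = FALSE)
  }
  sweep(nd, 2L, w, "*")
}

#' Optimality function values
#'
#' Sums each row of the weighted normalized matrix, yielding the
#' optimality value `S_i` of every alternative and `S_0` of the optimal
#' row. Because every weighted column sums to its weight and the weights
#' sum to 1, the `S` values over all rows sum to 1.
#'
#' @param wd Weighted normalized matrix from [apply_weights()].
#' @return Named numeric vector of row sums, the `"OV"` element last.
#' @export
optimality_values <- function(wd) {
  rowSums(wd)
}

#' Utility degrees
#'
#' Divides each alternative's optimality value by that of the optimal row:
#' `K_i = S_i / S_0`. With a derived optimal row every `K_i` lies in
#' (0, 1]; an alternative matching the optimum on every criterion attains
#' exactly 1.
#'
#' @param s Named optimality values from [optimality_values()], including
#'   the `"OV"` element.
#' @return Named numeric vector of utility degrees, one per alternative
#'   (the optimal row excluded).
#' @export
utility_degrees <- function(s) {
  if (!"OV" %in% names(s)) {
    stop("`s` must contain the optimal row's value, named \"OV\"", call. = FALSE)
  }
  s0 <- s[["OV"]]
  if (!is.finite(s0) || s0 <= 0) {
    stop("optimality value of the optimal row must be strictly positive",
         call. = FALSE)
  }
  s[setdiff(names(s), "OV")] / s0
}

#' Rank alternatives by utility degree
#'
#' Rank 1 goes to the largest utility degree. Ties share the minimum
#' (competition) rank; within a tie the report order follows the input
#' order, so the result is deterministic.
#'
#' @param k Utility degrees.
#' @return Integer vector of ranks, named like `k`.
#' @export
rank_alternatives <- function(k) {
  if (length(k) == 0L) stop("no alternatives to rank", call. = FALSE)
  r <- as.integer(rank(-as.numeric(k), ties.method = "min"))
  names(r) <- names(k)
  r
}

#' Rank alternatives by additive ratio assessment
#'
#' Runs the full ARAS pipeline against a fixed criterion weighting:
#' share-normalize the decision matrix (optimal row included in every
#' column denominator), weight each column, sum rows into optimality
#' values `S_i`, divide by the optimal row's `S_0` to obtain utility
#' degrees `K_i`, and rank by descending `K`. All intermediates are
#' retained in the fit for reporting and audit.
#'
#' @param decision A [decision_matrix()].
#' @param weights Criterion weights: a numeric vector summing to 1, or an
#'   [ahp()] fit whose coefficients are used at full precision. When both
#'   the weights and the decision matrix carry criterion ids they must
#'   match; named weights are reordered to the decision matrix's column
#'   order.
#' @return An object of class `"aras"`: a list with components `decision`,
#'   `weights`, `normalized`, `weighted`, `s` (per-alternative optimality
#'   values), `s0`, `k` (utility degrees), `ranks` and `warnings`.
#' @seealso [hybrid_mcda()] to derive the weights and rank in one call.
#' @examples
#' d <- health_decision()
#' w <- coef(ahp(health_pairwise()))
#' fit <- aras(d, w)
#' fit$k      # utility degrees
#' fit$ranks  # 1 = best
#' @export
aras <- function(decision, weights) {
  if (!inherits(decision, "decision_matrix")) {
    decision <- decision_matrix(decision)
  }
  w <- if (inherits(weights, "ahp")) coef(weights) else weights
  w <- reconcile_weights(w, colnames(decision))
  if (abs(sum(w) - 1) > 1e-6) {
    stop("weights must sum to 1 (got ", format(sum(w)), ")", call. = FALSE)
  }
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)

  nd <- normalize_decision(decision)
  wd <- apply_weights(nd, w)
  s <- optimality_values(wd)
  k <- utility_degrees(s)
  ranks <- rank_alternatives(k)

  structure(list(
    decision = decision,
    weights = w,
    normalized = nd,
    weighted = wd,
    s = s[setdiff(names(s), "OV")],
    s0 = s[["OV"]],
    k = k,
    ranks = ranks,
    warnings = attr(decision, "warnings")
  ), class = "aras")
}

# Match a weight vector to the decision matrix's criterion order by id,
# erroring on any mismatch; unnamed weights are taken positionally.
reconcile_weights <- function(w, criteria) {
  nm <- names(w)
  wv <- as.numeric(w)
  if (!is.null(nm)) {
    missing_ids <- setdiff(criteria, nm)
    extra_ids <- setdiff(nm, criteria)
    if (length(missing_ids) || length(extra_ids)) {
      stop("criterion ids do not reconcile between weights and decision ",
           "matrix; missing: ", paste(missing_ids, collapse = ", "),
           "; unmatched: ", paste(extra_ids, collapse = ", "), call. = FALSE)
    }
    wv <- wv[match(criteria, nm)]
  } else if (length(wv) != length(criteria)) {
    stop("weight vector length ", length(wv),
         " does not match the criterion count ", length(criteria), call. = FALSE)
  }
  names(wv) <- criteria
  wv
}

#' @export
coef.aras <- function(object, ...) object$k

#' @export
print.aras <- function(x, digits = 3, ...) {
  cat("ARAS ranking (", length(x$k), " alternatives, ",
      length(x$weights), " criteria)\n\n", sep = "")
  tab <- data.frame(S = round(x$s, digits), K = round(x$k, digits),
                    rank = x$ranks, row.names = names(x$k))
  print(tab[order(tab$rank), ])
  cat("\nS0 (optimal row) = ", format(round(x$s0, digits)), "\n", sep = "")
  for (w in x$warnings) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}

#' @export
summary.aras <- function(object, digits = 3, ...) {
  structure(list(fit = object, digits = digits), class = "summary.aras")
}

#' @export
print.summary.aras <- function(x, ...) {
  f <- x$fit; d <- x$digits
  print(f, digits = d)
  cat("\nWeighted normalized matrix (optimal row last):\n")
  print(round(f$weighted, d))
  invisible(x)
}

#' @export
plot.aras <- function(x, ...) {
  k <- sort(x$k, decreasing = TRUE)
  graphics::barplot(k, ylab = "utility degree K", ylim = c(0, 1), las = 2, ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
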