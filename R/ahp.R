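# AHP weight derivation with consistency diagnostics.

#' Fit an analytic hierarchy process weighting
#'
#' Derives criterion weights from a pairwise-comparison matrix and
#' quantifies how self-consistent the underlying judgments are. The default
#' derivation is the column-mean method: normalize each column to unit sum,
#' then average each row over the criteria. `method = "eigenvector"`
#' instead uses the principal eigenvector of the raw matrix (Saaty's
#' original proposal); the two coincide exactly on consistent matrices and
#' closely for mildly inconsistent ones. Whatever the method, the principal
#' eigenvector is also computed as a cross-check and the maximum absolute
#' difference between the two weightings is retained in the fit.
#'
#' All chained quantities (weighted sum values, lambda-max, CI, CR) are
#' computed at full precision; rounding is applied only by the print and
#' summary methods.
#'
#' @param x A [pairwise_matrix()], or a raw square judgment matrix which is
#'   validated first.
#' @param method Weight derivation: `"colmean"` (column normalization and
#'   row averaging, the default) or `"eigenvector"`.
#' @param cr_threshold Consistency-ratio cutoff; above it the fit carries
#'   status `"warning"`. Default 0.10.
#' @param reciprocity_tol Passed to [pairwise_matrix()] when `x` is raw.
#' @param ri_table Optional custom random-index table (see
#'   [saaty_random_index()]).
#' @return An object of class `"ahp"`: a list with components
#'   \describe{
#'     \item{weights}{named weight vector summing to 1,}
#'     \item{normalized}{the column-normalized matrix,}
#'     \item{wsv}{weighted sum values `A %*% w`,}
#'     \item{row_ratios}{per-criterion `wsv / w`, whose mean is lambda-max,}
#'     \item{lambda_max, ci, ri, cr, status}{the consistency chain,}
#'     \item{eigen_weights, eigen_diff}{principal-eigenvector weights and
#'       their maximum absolute deviation from `weights`.}
#'   }
#' @seealso [aras()] for ranking alternatives against the fitted weights,
#'   [hybrid_mcda()] for the combined pipeline.
#' @examples
#' m <- health_pairwise()
#' fit <- ahp(m)
#' coef(fit)     # criterion weights
#' summary(fit)  # weights plus the consistency table
#' @export
ahp <- function(x, method = c("colmean", "eigenvector"), cr_threshold = 0.10,
                reciprocity_tol = 0.05, ri_table = NULL) {
  method <- match.arg(method)
  m <- if (inherits(x, "pairwise_matrix")) x else
    pairwise_matrix(x, reciprocity_tol = reciprocity_tol)
  n <- nrow(m)
  normalized <- normalize_pairwise(m)
  w_colmean <- derive_weights(normalized)

  ev <- eigen(unclass(m))
  k <- which.max(Re(ev$values))
  ew <- Re(ev$vectors[, k])
  ew <- ew / sum(ew)
  names(ew) <- rownames(m)

  w <- if (method == "colmean") w_colmean else ew
  wsv <- weighted_sum_values(m, w)
  ratios <- wsv / w
  lmax <- mean(ratios)
  ci <- consistency_index(lmax, n)
  crf <- consistency_ratio(ci, n, threshold = cr_threshold, ri_table = ri_table)

  structure(list(
    pairwise = m,
    method = method,
    normalized = normalized,
    weights = w,
    wsv = wsv,
    row_ratios = ratios,
    lambda_max = lmax,
    ci = ci,
    ri = crf$ri,
    cr = crf$cr,
    cr_threshold = cr_threshold,
    status = crf$status,
    eigen_weights = ew,
    eigen_lambda = Re(ev$values[k]),
    eigen_diff = max(abs(w - ew))
  ), class = "ahp")
}

#' @export
coef.ahp <- function(object, ...) object$weights

#' @export
print.ahp <- function(x, digits = 2, ...) {
  cat("AHP weighting (", length(x$weights), " criteria, ",
      if (x$method == "colmean") "column-mean" else "principal-eigenvector",
      " method)\n\n", sep = "")
  print(round(x$weights, digits))
  cat("\nlambda_max = ", format(round(x$lambda_max, 2)),
      ", CI = ", format(round(x$ci, 2)),
      ", RI = ", format(x$ri),
      ", CR = ", format(round(x$cr, 3)), "\n", sep = "")
  if (x$status == "warning") {
    cat("Judgments exceed the CR threshold of ", x$cr_threshold,
        " -- interpret the weights with caution.\n", sep = "")
  } else {
    cat("Judgments are consistent (CR <= ", x$cr_threshold, ").\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.ahp <- function(object, digits = 2, ...) {
  tab <- data.frame(
    weight = round(object$weights, digits),
    weighted_sum = round(object$wsv, digits),
    ratio = round(object$row_ratios, digits),
    row.names = names(object$weights)
  )
  out <- list(table = tab, lambda_max = object$lambda_max, ci = object$ci,
              ri = object$ri, cr = object$cr, status = object$status,
              eigen_diff = object$eigen_diff, digits = digits)
  class(out) <- "summary.ahp"
  out
}

#' @export
print.summary.ahp <- function(x, ...) {
  cat("Criterion weights and consistency diagnostics\n\n")
  print(x$table)
  cat("\nlambda_max = ", format(round(x$lambda_max, x$digits)),
      "  CI = ", format(round(x$ci, x$digits)),
      "  RI = ", format(x$ri),
      "  CR = ", format(round(x$cr, 3)),
      "  [", x$status, "]\n", sep = "")
  cat("Max |column-mean - eigenvector| weight difference: ",
      format(signif(x$eigen_diff, 3)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.ahp <- function(x, ...) {
  graphics::barplot(sort(x$weights, decreasing = TRUE),
                    ylab = "criterion weight", las = 2, ...)
  invisible(x)
}
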