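# Decision matrices: alternatives x criteria scores plus the optimal row.

#' Construct a decision matrix with its optimal-value row
#'
#' Assembles the alternatives-by-criteria grid of raw performance scores
#' used by ARAS, together with the optimal-value (OV) row that plays the
#' role of an ideal alternative. When not supplied, the optimal value for a
#' benefit criterion is the column maximum over the alternatives, and for a
#' cost criterion the column minimum. A user-supplied optimal row is
#' accepted but flagged with a warning attribute when it is beaten by an
#' actual alternative (a benefit optimum below the column maximum, or a
#' cost optimum above the column minimum), since utility degrees may then
#' exceed 1.
#'
#' @param scores Numeric matrix (alternatives in rows, criteria in
#'   columns), all entries strictly positive.
#' @param alternatives Row labels; default taken from `scores` or `Ap1..Apm`.
#' @param criteria Column labels; default taken from `scores` or `C1..Cn`.
#' @param directions Character vector, one of `"benefit"` or `"cost"` per
#'   criterion; a single value is recycled. Default all-benefit.
#' @param optimal Optional numeric vector of per-criterion optimal values.
#' @return A matrix of class `"decision_matrix"` carrying attributes
#'   `directions`, `optimal` (named numeric), `optimal_source` (`"derived"`
#'   or `"user"`) and `warnings` (character vector, possibly empty).
#' @examples
#' d <- decision_matrix(rbind(c(2, 1), c(5, 4), c(3, 9)))
#' attr(d, "optimal") # 5, 9: column maxima of the benefit criteria
#' @export
decision_matrix <- function(scores, alternatives = NULL, criteria = NULL,
                            directions = "benefit", optimal = NULL) {
  scores <- as.matrix(scores)
  m <- nrow(scores); n <- ncol(scores)
  if (m < 1L || n < 1L) stop("decision matrix must be non-empty", call. = FALSE)
  if (!is.numeric(scores) || anyNA(scores)) {
    stop("scores must be numeric and non-missing", call. = FALSE)
  }
  if (is.null(alternatives)) {
    alternatives <- rownames(scores)
    if (is.null(alternatives)) alternatives <- paste0("Ap", seq_len(m))
  }
  if (is.null(criteria)) {
    criteria <- colnames(scores)
    if (is.null(criteria)) criteria <- paste0("C", seq_len(n))
  }
  if (length(alternatives) != m || length(criteria) != n) {
    stop("label lengths do not match the score grid (", m, " x ", n, ")",
         call. = FALSE)
  }
  if (anyDuplicated(alternatives)) stop("alternative ids must be unique", call. = FALSE)
  if (anyDuplicated(criteria)) stop("criterion ids must be unique", call. = FALSE)
  directions <- rep_len(match.arg(directions, c("benefit", "cost"),
                                  several.ok = TRUE), n)
  if (any(scores <= 0)) {
    bad <- which(scores <= 0, arr.ind = TRUE)[1L, ]
    stop("score at (", alternatives[bad[1L]], ", ", criteria[bad[2L]],
         ") is not strictly positive", call. = FALSE)
  }

  derived <- vapply(seq_len(n), function(j) {
    if (directions[j] == "benefit") max(scores[, j]) else min(scores[, j])
  }, numeric(1))
  warnings <- character(0)
  if (is.null(optimal)) {
    optimal <- derived
    source <- "derived"
  } else {
    optimal <- as.numeric(optimal)
    if (length(optimal) != n) {
      stop("optimal row must have one value per criterion", call. = FALSE)
    }
    if (any(optimal <= 0)) stop("optimal values must be strictly positive", call. = FALSE)
    source <- "user"
    beaten <- (directions == "benefit" & optimal < derived) |
              (directions == "cost" & optimal > derived)
    if (any(beaten)) {
      warnings <- paste0("user optimal value for ", criteria[beaten],
                         " is beaten by an alternative; utility degrees may exceed 1")
    }
  }
  names(optimal) <- criteria
  names(directions) <- criteria
  dimnames(scores) <- list(alternatives, criteria)
  structure(scores, directions = directions, optimal = optimal,
            optimal_source = source, warnings = warnings,
            class = c("decision_matrix", "matrix", "array"))
}

#' @export
print.decision_matrix <- function(x, ...) {
  dirs <- attr(x, "directions")
  cat("Decision matrix: ", nrow(x), " alternatives x ", ncol(x),
      " criteria (", sum(dirs == "benefit"), " benefit, ",
      sum(dirs == "cost"), " cost)\n", sep = "")
  shown <- rbind(unclass(x), OV = attr(x, "optimal"))
  print(shown, ...)
  cat("optimal row: ", attr(x, "optimal_source"), "\n", sep = "")
  for (w in attr(x, "warnings")) cat("warning: ", w, "\n", sep = "")
  invisible(x)
}
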