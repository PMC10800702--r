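# Labelled-CSV readers and writers, plus the shipped worked example.

# Parse a labelled numeric CSV strictly: comma-delimited, dot decimal,
# first row = criterion ids, first column = row ids. Ragged rows and
# non-numeric cells are reported with coordinates.
read_labelled_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  fields <- utils::count.fields(path, sep = ",", quote = "\"")
  if (length(fields) < 2L) {
    stop("file has no data rows: ", path, call. = FALSE)
  }
  if (any(fields != fields[1L])) {
    bad <- which(fields != fields[1L])[1L]
    stop("ragged row at line ", bad, " of ", path, ": expected ",
         fields[1L], " fields, found ", fields[bad], call. = FALSE)
  }
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("no data columns in ", path, call. = FALSE)
  labels <- df[[1L]]
  if (anyDuplicated(labels)) stop("duplicate row labels in ", path, call. = FALSE)
  cols <- names(df)[-1L]
  grid <- matrix(NA_real_, nrow(df), length(cols),
                 dimnames = list(labels, cols))
  for (j in seq_along(cols)) {
    raw <- trimws(df[[j + 1L]])
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      i <- which(is.na(val))[1L]
      stop("non-numeric cell at row \"", labels[i], "\", column \"",
           cols[j], "\" of ", path, ": \"", raw[i], "\"", call. = FALSE)
    }
    grid[, j] <- val
  }
  grid
}

#' Read a pairwise-comparison matrix from labelled CSV
#'
#' Expects a comma-delimited, dot-decimal, UTF-8 file whose first row and
#' first column are criterion ids and whose cell (i, j) is the judgment of
#' the row criterion over the column criterion. The grid is validated with
#' [pairwise_matrix()].
#'
#' @param path Path to the CSV file.
#' @inheritParams pairwise_matrix
#' @return A `"pairwise_matrix"`.
#' @export
read_pairwise_csv <- function(path, reciprocity_tol = 0.05,
                              scale_action = c("warn", "error", "none")) {
  grid <- read_labelled_csv(path)
  if (!identical(rownames(grid), colnames(grid))) {
    stop("row and column criterion ids differ in ", path, call. = FALSE)
  }
  pairwise_matrix(grid, reciprocity_tol = reciprocity_tol,
                  scale_action = match.arg(scale_action))
}

#' Read a decision matrix from labelled CSV
#'
#' Expects alternative ids in the first column and criterion ids in the
#' header. A row labelled `OV` (any case) is recognized as a user-supplied
#' optimal-value row; set `ov = "ignore"` to drop it and derive the
#' optimum from the alternatives instead.
#'
#' @param path Path to the CSV file.
#' @param directions Per-criterion `"benefit"`/`"cost"` vector (recycled);
#'   default all-benefit.
#' @param ov Whether to `"use"` an OV row found in the file or `"ignore"` it.
#' @return A [decision_matrix()].
#' @export
read_decision_csv <- function(path, directions = "benefit",
                              ov = c("use", "ignore")) {
  ov <- match.arg(ov)
  grid <- read_labelled_csv(path)
  is_ov <- toupper(rownames(grid)) == "OV"
  optimal <- NULL
  if (any(is_ov)) {
    if (sum(is_ov) > 1L) stop("multiple OV rows in ", path, call. = FALSE)
    if (ov == "use") optimal <- grid[is_ov, ]
    grid <- grid[!is_ov, , drop = FALSE]
  }
  decision_matrix(grid, directions = directions, optimal = optimal)
}

#' Write a matrix to labelled CSV
#'
#' Writes a pairwise or decision matrix in the same labelled dialect the
#' readers expect (comma-delimited, dot decimal, UTF-8), so that a
#' write-then-read round trip reproduces the values exactly. For a
#' [decision_matrix()] the optimal row is appended as `OV`.
#'
#' @param x A `"pairwise_matrix"`, `"decision_matrix"`, or plain labelled
#'   numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(x, path) {
  if (inherits(x, "decision_matrix")) {
    grid <- rbind(unclass(x), OV = attr(x, "optimal"))
    corner <- "Alternatives"
  } else {
    grid <- unclass(x)
    corner <- "Criteria"
  }
  df <- data.frame(rownames(grid), format(grid, digits = 17, trim = TRUE,
                                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(corner, colnames(grid))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path, or a character vector of file names.
#' @export
ahparas_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ahparas")))
  }
  path <- system.file("extdata", file, package = "ahparas")
  if (path == "") stop("no packaged example file \"", file, "\"", call. = FALSE)
  path
}

#' Worked example: evaluating health-monitoring applications
#'
#' The packaged case study: eight computer-based health-monitoring
#' applications (Ap1..Ap8) evaluated on eight benefit criteria -- real-time
#' ability (C1), dynamic nature (C2), surgical services (C3), data
#' security (C4), telecommunication (C5), disease monitoring (C6),
#' usability (C7) and convenience (C8). `health_pairwise()` returns the
#' expert panel's 8 x 8 Saaty-scale comparison matrix of the criteria;
#' `health_decision()` returns the 8 x 8 matrix of integer 1-9 performance
#' scores with its optimal-value row.
#'
#' @return A `"pairwise_matrix"` or `"decision_matrix"` respectively.
#' @examples
#' hybrid_mcda(health_pairwise(), health_decision())
#' @export
health_pairwise <- function() {
  read_pairwise_csv(ahparas_example("health_pairwise.csv"))
}

#' @rdname health_pairwise
#' @export
health_decision <- function() {
  read_decision_csv(ahparas_example("health_decision.csv"))
}
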