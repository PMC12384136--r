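#' Construct a two-rater ratings matrix
#'
#' The unit of analysis throughout the package: `n` subjects each rated once
#' by the same two raters. Rows are subjects, columns are raters, entries are
#' continuous ratings in arbitrary (but common) units.
#'
#' @param x Either an `n x 2` numeric matrix / data frame, or a numeric
#'   vector of first-rater scores (in which case `y` must be supplied).
#' @param y Optional numeric vector of second-rater scores, same length as
#'   `x`.
#'
#' @return A numeric matrix of class `"ratings_matrix"` with columns
#'   `rater1`, `rater2`.
#'
#' @details At least 3 subjects are required (the two-way mean squares and
#'   the moment-based studentizer are degenerate below that), exactly two
#'   raters are supported, and every entry must be finite.
#'
#' @examples
#' r <- ratings_matrix(c(1, 2, 3, 4), c(1.1, 2.3, 2.9, 4.2))
#' icc21(r)
#' @export
ratings_matrix <- function(x, y = NULL) {
  if (!is.null(y)) {
    if (!is.numeric(x) || !is.numeric(y)) {
      stop("'x' and 'y' must be numeric vectors when both are given",
           call. = FALSE)
    }
    if (length(x) != length(y)) {
      stop("'x' and 'y' must have the same length", call. = FALSE)
    }
    m <- cbind(as.double(x), as.double(y))
  } else {
    if (is.data.frame(x)) x <- as.matrix(x)
    if (!is.matrix(x) || !is.numeric(x)) {
      stop("'x' must be a numeric matrix, data frame, or a pair of vectors",
           call. = FALSE)
    }
    m <- matrix(as.double(x), nrow = nrow(x))
  }
  if (ncol(m) != 2L) {
    stop("a ratings matrix must have exactly 2 columns (two raters), got ",
         ncol(m), call. = FALSE)
  }
  if (nrow(m) < 3L) {
    stop("at least 3 subjects are required, got ", nrow(m), call. = FALSE)
  }
  if (!all(is.finite(m))) {
    bad <- which(!apply(is.finite(m), 1L, all))
    stop("non-finite ratings in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  dimnames(m) <- list(NULL, c("rater1", "rater2"))
  class(m) <- c("ratings_matrix", class(m))
  m
}

#' Coerce to a ratings matrix
#'
#' @param x Object to coerce (matrix, data frame, or `ratings_matrix`).
#' @return A validated [ratings_matrix()].
#' @export
as_ratings <- function(x) {
  if (inherits(x, "ratings_matrix")) return(x)
  ratings_matrix(x)
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat("Two-rater ratings matrix:", nrow(x), "subjects x 2 raters\n")
  print(unclass(x), ...)
  invisible(x)
}
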