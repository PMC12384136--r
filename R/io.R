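#' Read a two-column ratings file
#'
#' Reads delimited text with one subject per row and the two raters' scores
#' in two columns. The delimiter (comma, semicolon, tab, or whitespace) is
#' sniffed from the first data line; a header line is auto-detected unless
#' `header` is given explicitly. Rows with missing or non-numeric cells are
#' rejected with their 1-based file line numbers.
#'
#' @param path Path to the file.
#' @param header `TRUE`/`FALSE`, or `NA` (default) to auto-detect: the
#'   first line is treated as a header when any of its fields fails to
#'   parse as a number.
#' @return A [ratings_matrix()] in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("rater1,rater2", "1,2", "2,2", "3,4"), f)
#' read_ratings(f)
#' @export
read_ratings <- function(path, header = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0L) stop("empty ratings file: ", path, call. = FALSE)
  delim <- sniff_delim(lines[[1L]])
  split_line <- function(l) {
    f <- strsplit(trimws(l), delim)[[1L]]
    trimws(f[f != ""])
  }
  fields <- lapply(lines, split_line)
  first_num <- suppressWarnings(as.numeric(fields[[1L]]))
  if (is.na(header)) header <- anyNA(first_num)
  offset <- if (header) 1L else 0L
  if (header) fields <- fields[-1L]
  if (length(fields) < 3L) {
    stop("need at least 3 data rows, got ", length(fields), call. = FALSE)
  }
  ncols <- lengths(fields)
  if (any(ncols != 2L)) {
    bad <- which(ncols != 2L) + offset
    stop("expected exactly 2 columns; wrong field count in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    t(vapply(fields, function(f) as.numeric(f), numeric(2L))))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 1L, any)) + offset
    stop("non-numeric or missing cell(s) in row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  ratings_matrix(vals)
}

sniff_delim <- function(line) {
  for (d in c(",", ";", "\t")) {
    if (grepl(d, line, fixed = TRUE)) {
      return(if (d == "\t") "\t" else d)
    }
  }
  "[[:space:]]+"
}

#' Write a ratings matrix to CSV
#'
#' Values are written with 17 significant digits so that a write/read
#' round trip reproduces the doubles exactly.
#'
#' @param ratings A [ratings_matrix()].
#' @param path Output path; a `rater1,rater2` header is written.
#' @return Invisibly, `path`.
#' @export
write_ratings <- function(ratings, path) {
  r <- as_ratings(ratings)
  lines <- c("rater1,rater2",
             sprintf("%.17g,%.17g", r[, 1L], r[, 2L]))
  writeLines(lines, path)
  invisible(path)
}
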