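# Delimited-text input and BED-style segmentation output. Plain text only:
# tab- or comma-separated matrices with a header row, single- or three-column
# signals, 0-based half-open BED intervals.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a design matrix and response from delimited text
#'
#' Expects a header row and a numeric body (tab or comma separated,
#' autodetected). Rows containing any missing value are dropped with a
#' warning stating the count: the adaptive ridge solvers need complete data.
#'
#' @param path File path.
#' @param response Name (or 1-based index) of the response column.
#' @return A list `X` (matrix of the remaining columns), `y`, `names`.
#' @export
read_matrix <- function(path, response) {
  if (!file.exists(path)) stop("input file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                         check.names = FALSE)
  nonnum <- names(d)[!vapply(d, is.numeric, logical(1))]
  if (length(nonnum))
    stop("non-numeric column(s): ", paste(nonnum, collapse = ", "))
  if (is.numeric(response)) response <- names(d)[response]
  if (!response %in% names(d))
    stop("response column not found: ", response)
  miss <- !stats::complete.cases(d)
  if (any(miss)) {
    warning(sprintf("dropped %d row(s) with missing values", sum(miss)))
    d <- d[!miss, , drop = FALSE]
  }
  y <- d[[response]]
  X <- as.matrix(d[setdiff(names(d), response)])
  list(X = X, y = y, names = colnames(X))
}

#' Read an ordered signal from text
#'
#' Accepts either a single column of values (no header needed) or a
#' three-column tab-separated `chrom pos value` layout.
#'
#' @param path File path.
#' @return A list `y`, `positions` (NULL for single-column input), `chrom`.
#' @export
read_signal <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), "[\t,]")[[1]]
  if (length(first) >= 3L) {
    d <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("chrom", "pos", "value"))
    if (any(diff(d$pos) <= 0)) stop("positions must be strictly increasing")
    list(y = d$value, positions = d$pos, chrom = d$chrom[1])
  } else {
    list(y = scan(path, quiet = TRUE), positions = NULL, chrom = NULL)
  }
}

#' Write a segmentation as a BED file
#'
#' Emits 0-based half-open intervals whose 4th column is the refit segment
#' mean; adjacent intervals tile the input exactly. With `positions`
#' supplied, interval bounds are `positions[start] - 1` and
#' `positions[end]`; otherwise indices are used.
#'
#' @param fit An `"ar_segmentation"` or `"dp_segmentation"` object.
#' @param path Output file.
#' @param chrom Chromosome/sequence label for column 1.
#' @param positions Optional 1-based coordinates of the measurements.
#' @return The path, invisibly.
#' @export
write_segments <- function(fit, path, chrom = "seg", positions = NULL) {
  n <- length(fit$y)
  if (is.null(positions)) positions <- seq_len(n)
  stopifnot(length(positions) == n, all(diff(positions) > 0))
  starts <- c(1L, fit$breakpoints + 1L)
  ends <- c(fit$breakpoints, n)
  bed <- data.frame(chrom = chrom,
                    start = positions[starts] - 1L,
                    end = positions[ends],
                    mean = fit$segment_means)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED segmentation back
#'
#' @param path BED file written by [write_segments()].
#' @return A data.frame `chrom`, `start`, `end`, `mean`.
#' @export
read_segments <- function(path) {
  utils::read.table(path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "start", "end", "mean"))
}

#' Serialize a regularization path as a tab-separated table
#'
#' One row per penalty: `lambda`, support size, a 0/1 support bitmask
#' string, and the refit coefficients.
#'
#' @param path_obj An `"ar_path"`.
#' @param file Output file.
#' @return The file path, invisibly.
#' @export
write_path <- function(path_obj, file) {
  stopifnot(inherits(path_obj, "ar_path"))
  rows <- lapply(seq_along(path_obj$lambdas), function(i) {
    f <- path_obj$fits[[i]]
    data.frame(lambda = path_obj$lambdas[i], size = sum(f$support),
               support = paste(as.integer(f$support), collapse = ""),
               t(f$beta_refit))
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
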