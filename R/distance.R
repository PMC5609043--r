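#' Validate a labelled distance matrix
#'
#' Distance matrices throughout the package are square numeric matrices with
#' matching row/column labels, symmetric to 1e-12, non-negative, and exactly
#' zero on the diagonal. Entries may be `NA` where a pairwise value is
#' undefined (e.g. no co-called variants).
#'
#' @param m square numeric matrix with dimnames.
#' @return the validated matrix (diagonal forced to exactly 0).
#' @export
distance_matrix <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (is.null(rownames(m))) {
    dimnames(m) <- list(paste0("L", seq_len(nrow(m))),
                        paste0("L", seq_len(nrow(m))))
  }
  if (!identical(rownames(m), colnames(m))) {
    stopf("row and column labels differ")
  }
  asym <- max(abs(m - t(m)), na.rm = TRUE)
  if (is.finite(asym) && asym > 1e-12) {
    stopf("matrix not symmetric (max asymmetry %.3g)", asym)
  }
  if (any(m < 0, na.rm = TRUE)) stopf("negative distances present")
  diag(m) <- 0
  m
}

#' Read/write a distance matrix as square TSV
#'
#' The layout is a header row of labels and a leading label column, so the
#' file round-trips label order exactly.
#'
#' @param m distance matrix; `path` file path.
#' @export
write_distance_matrix <- function(m, path) {
  m <- distance_matrix(m)
  df <- data.frame(label = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  distance_matrix(m)
}
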