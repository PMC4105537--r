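#' Write an expression matrix and sample sheet as tab-delimited text
#'
#' @param mat genes x libraries RPKM matrix.
#' @param sheet sample sheet (library, tissue, animal, state).
#' @param matrix_path,sheet_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(mat, sheet, matrix_path, sheet_path) {
  validate_matrix(mat)
  validate_sheet(sheet, colnames(mat))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write_tsv(df, matrix_path)
  write_tsv(sheet, sheet_path)
  invisible(c(matrix_path, sheet_path))
}

#' Read an expression matrix and sample sheet
#'
#' Cross-validates the two files: every matrix library must appear exactly
#' once in the sheet and vice versa; values must be numeric, finite and
#' nonnegative. The sheet is reordered to the matrix's column order.
#'
#' @param matrix_path tab-delimited matrix (header = library ids, first
#'   column = gene ids).
#' @param sheet_path tab-delimited sheet with columns library, tissue,
#'   animal, state.
#' @return list with `matrix` and `sheet`.
#' @export
read_expression <- function(matrix_path, sheet_path) {
  if (!file.exists(matrix_path)) stop2("no such file: ", matrix_path)
  if (!file.exists(sheet_path)) stop2("no such file: ", sheet_path)
  df <- read_tsv(matrix_path, colClasses = "character")
  if (ncol(df) < 1L) stop2("matrix file has no columns")
  genes <- df[[1L]]
  if (anyDuplicated(genes)) stop2("duplicate gene ids in ", matrix_path)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num) | num < 0, arr.ind = TRUE)
  if (nrow(vals) > 0 && length(bad)) {
    stop2(sprintf(
      "invalid expression value '%s' at row %d (gene %s), column %d (%s)",
      vals[bad[1, 1], bad[1, 2]], bad[1, 1], genes[bad[1, 1]],
      bad[1, 2], colnames(vals)[bad[1, 2]]))
  }
  dimnames(num) <- list(genes, colnames(vals))
  sheet <- read_tsv(sheet_path, colClasses = "character")
  validate_matrix(num)
  sheet <- align_sheet(sheet, num)
  list(matrix = num, sheet = sheet)
}

#' Expressed-gene filter
#'
#' A gene is considered expressed when its mean RPKM within at least one
#' (tissue, state) cell reaches the detection threshold, mirroring an
#' "expressed in at least one tissue and physiological state" rule.
#'
#' @param mat RPKM matrix.
#' @param sheet sample sheet aligned to `mat`.
#' @param threshold detection threshold on the RPKM scale (default 0.2).
#' @return character vector of retained gene ids (subset of rownames).
#' @export
filter_expressed <- function(mat, sheet, threshold = 0.2) {
  assert_scalar_number(threshold, "threshold")
  if (threshold <= 0) stop2("threshold must be > 0")
  validate_matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) return(character(0))
  sheet <- align_sheet(sheet, mat)
  cell <- interaction(sheet$tissue, sheet$state, drop = TRUE)
  # per-gene mean within each (tissue, state) cell
  sums <- t(rowsum(t(mat), group = cell))
  counts <- as.vector(table(cell)[colnames(sums)])
  means <- sweep(sums, 2L, counts, "/")
  rownames(mat)[apply(means >= threshold, 1L, any)]
}

#' Floored base-2 log transform
#'
#' Maps each RPKM value x to log2(max(x, floor)). Flooring at the
#' detection threshold keeps unexpressed entries at a finite value
#' (log2(0.2) ~ -2.32) instead of -Inf, which keeps the downstream linear
#' model well defined without inventing pseudo-counts.
#'
#' @param mat RPKM matrix.
#' @param floor positive flooring constant (default 0.2).
#' @return matrix of log2 values, same dimnames.
#' @export
log_transform <- function(mat, floor = 0.2) {
  assert_scalar_number(floor, "floor")
  if (floor <= 0) stop2("floor must be > 0")
  validate_matrix(mat)
  log2(pmax(mat, floor))
}
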