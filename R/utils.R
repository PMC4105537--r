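#' @keywords internal
"_PACKAGE"

# Canonical tissue abbreviations for the eight-tissue design:
# hypothalamus, pituitary, liver, longissimus dorsi muscle, adipose,
# uterus, endometrium, ovary.
DEFAULT_TISSUES <- c("HYP", "PIT", "LIV", "LDM", "FAT", "UTE", "END", "OVA")

STATES <- c("PRE", "POST")

TRAITS <- c("ACL", "FSC", "HPG")

stop2 <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical unordered edge keys
#'
#' Builds an order-independent key "a|b" for an unordered gene pair, so
#' edge sets from different runs or node orderings compare equal.
#'
#' @param a,b character vectors of node ids (recycled pairwise).
#' @return character vector of keys.
#' @keywords internal
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    stop2(sprintf("'%s' must be a single finite number in [%s, %s]",
                  name, format(min), format(max)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x)) {
    stop2(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

# Validate an expression matrix: numeric, finite, nonnegative, uniquely
# named rows (genes) and columns (libraries).
validate_matrix <- function(mat) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop2("expression matrix must be a numeric matrix")
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop2("expression matrix must have gene row names and library column names")
  }
  if (anyDuplicated(rownames(mat))) stop2("duplicate gene ids in matrix")
  if (anyDuplicated(colnames(mat))) stop2("duplicate library ids in matrix")
  if (nrow(mat) > 0L && ncol(mat) > 0L) {
    if (any(!is.finite(mat))) stop2("expression matrix has non-finite values")
    if (any(mat < 0)) stop2("expression matrix has negative values")
  }
  invisible(mat)
}

# Validate a sample sheet against a matrix's library columns.
validate_sheet <- function(sheet, lib_ids = NULL) {
  need <- c("library", "tissue", "animal", "state")
  if (!is.data.frame(sheet) || !all(need %in% names(sheet))) {
    stop2("sample sheet needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(sheet$library)) stop2("duplicate libraries in sample sheet")
  bad <- setdiff(unique(sheet$state), STATES)
  if (length(bad)) stop2("unknown state labels: ", paste(bad, collapse = ", "))
  if (!is.null(lib_ids)) {
    miss_sheet <- setdiff(lib_ids, sheet$library)
    miss_mat <- setdiff(sheet$library, lib_ids)
    if (length(miss_sheet) || length(miss_mat)) {
      stop2("matrix/sheet library mismatch; missing from sheet: [",
            paste(miss_sheet, collapse = ", "), "]; missing from matrix: [",
            paste(miss_mat, collapse = ", "), "]")
    }
  }
  invisible(sheet)
}

# Harmonize sheet row order to the matrix column order.
align_sheet <- function(sheet, mat) {
  validate_sheet(sheet, colnames(mat))
  sheet <- sheet[match(colnames(mat), sheet$library), , drop = FALSE]
  rownames(sheet) <- NULL
  sheet
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
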