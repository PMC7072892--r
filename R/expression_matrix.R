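#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix with unique, non-empty row
#' names (features: mature miRNAs or precursors) and column names (samples).
#' All cells must be finite; negative values are allowed at this level (some
#' normalization pipelines can produce slightly negative log intensities) and
#' are policed where the scoring math requires non-negativity.
#'
#' @param x numeric matrix with row and column names.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix must have feature (row) and sample (column) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(x))) {
    dup <- unique(rownames(x)[duplicated(rownames(x))])
    stop("duplicate feature identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(colnames(x))) {
    dup <- unique(colnames(x)[duplicated(colnames(x))])
    stop("duplicate sample identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(rownames(x) == "") || any(colnames(x) == "")) {
    stop("empty feature or sample identifier", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("expression matrix contains non-finite or missing values",
         call. = FALSE)
  }
  invisible(x)
}

#' Read a delimited expression table
#'
#' Reads a TSV/CSV expression table with one header row and a leading
#' identifier column into a features-by-samples numeric matrix. Orientation is
#' normalized so that rows are always features on return.
#'
#' @param path path to a delimited text file. The delimiter is taken from the
#'   file extension (`.csv` means comma, anything else tab) unless `sep` is
#'   given.
#' @param orientation `"rows-are-features"` (default) or `"rows-are-samples"`.
#' @param sep field separator override.
#' @param missing_tokens cell values treated as missing.
#' @param on_missing `"error"` (default) rejects tables with missing cells;
#'   `"drop"` removes features that contain any missing cell.
#' @return a validated numeric matrix (features x samples).
#' @export
read_expression_table <- function(path,
                                  orientation = c("rows-are-features",
                                                  "rows-are-samples"),
                                  sep = NULL,
                                  missing_tokens = c("", "NA", "NaN"),
                                  on_missing = c("error", "drop")) {
  orientation <- match.arg(orientation)
  on_missing <- match.arg(on_missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           colClasses = "character", fill = FALSE,
                           na.strings = character(0),
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression table needs an identifier column and ",
                          "at least one data column", call. = FALSE)
  ids <- raw[[1]]
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  is_missing <- matrix(cells %in% missing_tokens, nrow = nrow(cells))
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- !is_missing & is.na(num)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop("non-numeric cell '", cells[bad][1], "' at row '", ids[idx[1]],
         "', column '", colnames(cells)[idx[2]], "'", call. = FALSE)
  }
  num[is_missing] <- NA_real_
  dimnames(num) <- list(ids, colnames(cells))
  if (anyNA(num)) {
    if (on_missing == "error") {
      stop("missing values in expression table ", path,
           " (use on_missing = \"drop\" to remove affected features)",
           call. = FALSE)
    }
    keep <- rowSums(is.na(num)) == 0
    message("dropping ", sum(!keep), " feature(s) with missing cells")
    num <- num[keep, , drop = FALSE]
  }
  if (orientation == "rows-are-samples") num <- t(num)
  validate_expression_matrix(num)
  num
}

#' Write an expression matrix as TSV
#'
#' @param x validated expression matrix (features x samples).
#' @param path output path.
#' @param id_column header name of the identifier column.
#' @export
write_expression_table <- function(x, path, id_column = "feature") {
  validate_expression_matrix(x)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
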