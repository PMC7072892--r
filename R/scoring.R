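#' Construct scoring weights
#'
#' The reliability score is the weighted combination `w_A*A + w_B*B + w_C*C`
#' of the three scaled components: median expression (A), MIMAT recency (B),
#' and precursor correlation (C). The defaults 0.5/0.3/0.2 maximize the
#' specificity ratio on paired array/sequencing data; see
#' [optimize_weights()] for re-deriving weights on your own data. Weights are
#' renormalized to sum to one.
#'
#' @param w_a,w_b,w_c non-negative weights for components A, B, C.
#' @return named numeric vector `c(w_a, w_b, w_c)` of class `score_weights`,
#'   summing to 1.
#' @export
score_weights <- function(w_a = 0.5, w_b = 0.3, w_c = 0.2) {
  w <- c(w_a = w_a, w_b = w_b, w_c = w_c)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1)) {
    stop("weights must lie in [0, 1]", call. = FALSE)
  }
  s <- sum(w)
  if (s <= 0) stop("at least one weight must be positive", call. = FALSE)
  structure(w / s, class = "score_weights")
}

#' Median expression of a feature across samples
#'
#' Even sample counts use the arithmetic mean of the two central order
#' statistics (the [stats::median()] convention).
#'
#' @param matrix expression matrix (features x samples).
#' @param feature feature identifier(s); default all features.
#' @return named numeric vector of medians.
#' @export
median_expression <- function(matrix, feature = rownames(matrix)) {
  validate_expression_matrix(matrix)
  missing <- setdiff(feature, rownames(matrix))
  if (length(missing)) {
    stop("unknown feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  apply(matrix[feature, , drop = FALSE], 1, stats::median)
}

#' Spearman correlation between a miRNA and its precursor(s)
#'
#' Rank correlation with average ranks for ties. When the mature miRNA
#' derives from several genomic loci, correlation with any one precursor is
#' evidence of genuine biogenesis, so the maximum over precursors is
#' returned. Below `min_samples` samples the correlation is unreliable and
#' `NA` is returned (the score then falls back to a neutral or
#' weight-dropping policy, see [score_all()]).
#'
#' @param mirna_row numeric vector of the mature miRNA's expression.
#' @param precursor_rows numeric vector or matrix (precursors x samples) with
#'   the same sample ordering as `mirna_row`; `NULL` yields `NA`.
#' @param min_samples minimum number of samples (default 5).
#' @return Spearman correlation in \[-1, 1\], or `NA` when unavailable.
#' @export
precursor_correlation <- function(mirna_row, precursor_rows,
                                  min_samples = 5L) {
  if (is.null(precursor_rows) || length(precursor_rows) == 0) {
    return(NA_real_)
  }
  if (is.vector(precursor_rows)) {
    precursor_rows <- matrix(precursor_rows, nrow = 1)
  }
  if (ncol(precursor_rows) != length(mirna_row)) {
    stop("sample count mismatch between miRNA (", length(mirna_row),
         ") and precursor (", ncol(precursor_rows), ") vectors",
         call. = FALSE)
  }
  if (length(mirna_row) < min_samples) return(NA_real_)
  cors <- apply(precursor_rows, 1, function(p) {
    suppressWarnings(stats::cor(mirna_row, p, method = "spearman"))
  })
  cors <- cors[!is.na(cors)]
  if (length(cors) == 0) return(NA_real_)
  max(cors)
}

#' Scale raw score inputs to the unit interval
#'
#' Computes the three components `A = m / m_max`, `B = 1 - N / n_max`
#' (clipped at 0 when `N` exceeds `n_max`), and `C = (c + 1) / 2`, with an
#' absent correlation mapped to the neutral value 0.5. All maxima are taken
#' across the analyzed miRNA set.
#'
#' @param m non-negative median expression (vectorized).
#' @param m_max positive maximum median over the set.
#' @param N positive integer MIMAT number (vectorized).
#' @param n_max positive maximum MIMAT number over the set.
#' @param c Spearman correlation in \[-1, 1\] or `NA` (vectorized).
#' @param clip clip `A` at 1 when `m > m_max` instead of erroring.
#' @return data.frame with columns `A`, `B`, `C`, all in \[0, 1\].
#' @export
scale_components <- function(m, m_max, N, n_max, c = NA_real_, clip = FALSE) {
  if (!is.finite(m_max) || m_max <= 0) stop("m_max must be positive",
                                            call. = FALSE)
  if (!is.finite(n_max) || n_max <= 0) stop("n_max must be positive",
                                            call. = FALSE)
  if (any(m < 0)) stop("median expression must be non-negative ",
                       "(rescale or shift the input first)", call. = FALSE)
  if (any(N < 1)) stop("MIMAT numbers must be >= 1", call. = FALSE)
  if (any(m > m_max) && !clip) {
    stop("m exceeds m_max (set clip = TRUE to clip A at 1)", call. = FALSE)
  }
  ok_c <- is.na(c) | (c >= -1 & c <= 1)
  if (!all(ok_c)) stop("correlation outside [-1, 1]", call. = FALSE)
  A <- pmin(m / m_max, 1)
  B <- pmax(0, 1 - N / n_max)
  C <- ifelse(is.na(c), 0.5, (c + 1) / 2)
  data.frame(A = A, B = B, C = C)
}

#' Combine scaled components into a reliability score
#'
#' @param A,B,C component values in \[0, 1\] (vectorized).
#' @param weights a [score_weights()] object.
#' @return numeric score(s) in \[0, 1\].
#' @export
compute_score <- function(A, B, C, weights = score_weights()) {
  if (!inherits(weights, "score_weights")) {
    weights <- do.call(score_weights, as.list(weights))
  }
  for (comp in list(A, B, C)) {
    if (any(comp < -1e-12 | comp > 1 + 1e-12)) {
      stop("score components must lie in [0, 1]", call. = FALSE)
    }
  }
  unname(weights[1] * A + weights[2] * B + weights[3] * C)
}

#' Score every annotated miRNA in an expression matrix
#'
#' For each mature miRNA present in both the expression matrix and the
#' annotation set, computes the median expression `m`, looks up the MIMAT
#' number `N`, correlates the miRNA with its precursor expression profile(s)
#' (Spearman, maximum over precursors), scales the three values to \[0, 1\]
#' and combines them with the weights. `m_max` is taken over the scored set;
#' `n_max` comes from the annotation set (or an override). Rows are ordered by
#' descending score with ties broken by ascending MIMAT number. miRNAs in the
#' matrix but missing from the annotation are reported via the `unannotated`
#' attribute, never silently dropped.
#'
#' @param mirna_matrix mature miRNA expression matrix (features x samples).
#' @param precursor_matrix optional precursor expression matrix over the same
#'   sample set; `NULL` makes every correlation absent.
#' @param annotation a `mirna_annotation` object.
#' @param weights a [score_weights()] object (default 0.5/0.3/0.2).
#' @param min_samples minimum samples for the Spearman correlation.
#' @param absent_corr policy for absent correlations: `"neutral"` maps them to
#'   C = 0.5; `"drop_weight"` zeroes `w_C` and renormalizes the remaining
#'   weights for the affected miRNAs (the recommended fallback when sample
#'   counts are too low for rank correlations).
#' @param n_max optional override of the maximum MIMAT number (e.g. the
#'   whole-miRBase maximum); must be at least the annotation set's own.
#' @param min_shift if the matrix contains negative values, shift all medians
#'   by the minimum instead of erroring.
#' @return data.frame of class `mirna_score_table` with columns `name`,
#'   `median`, `mimat`, `correlation`, `A`, `B`, `C`, `score`; attributes
#'   `weights`, `m_max`, `n_max`, `unannotated`.
#' @export
score_all <- function(mirna_matrix, precursor_matrix = NULL, annotation,
                      weights = score_weights(), min_samples = 5L,
                      absent_corr = c("neutral", "drop_weight"),
                      n_max = NULL, min_shift = FALSE) {
  absent_corr <- match.arg(absent_corr)
  validate_expression_matrix(mirna_matrix)
  stopifnot(inherits(annotation, "mirna_annotation"))
  if (!inherits(weights, "score_weights")) {
    weights <- do.call(score_weights, as.list(weights))
  }
  if (!is.null(precursor_matrix)) {
    validate_expression_matrix(precursor_matrix)
    if (!setequal(colnames(mirna_matrix), colnames(precursor_matrix))) {
      stop("miRNA and precursor matrices cover different sample sets",
           call. = FALSE)
    }
    precursor_matrix <- precursor_matrix[, colnames(mirna_matrix),
                                         drop = FALSE]
  }
  rec <- annotation$records
  scored <- intersect(rownames(mirna_matrix), rec$mature_name)
  unannotated <- setdiff(rownames(mirna_matrix), rec$mature_name)
  if (length(scored) == 0) {
    stop("no overlap between expression features and annotation",
         call. = FALSE)
  }
  if (length(unannotated)) {
    message(length(unannotated),
            " expression feature(s) missing from the annotation; ",
            "reported in attr(, \"unannotated\")")
  }
  m <- median_expression(mirna_matrix, scored)
  if (any(m < 0)) {
    if (!min_shift) {
      stop("negative median expression encountered; the input should be on ",
           "a non-negative scale (set min_shift = TRUE to shift)",
           call. = FALSE)
    }
    m <- m - min(m)
  }
  m_max <- max(m)
  if (m_max <= 0) stop("all median expressions are zero", call. = FALSE)
  n_max_eff <- if (is.null(n_max)) annotation$n_max else n_max
  if (n_max_eff < annotation$n_max) {
    stop("n_max override is smaller than the annotation set's maximum",
         call. = FALSE)
  }
  N <- rec[scored, "mimat"]
  corr <- vapply(scored, function(nm) {
    if (is.null(precursor_matrix)) return(NA_real_)
    prec <- intersect(rec[nm, "precursors"][[1]], rownames(precursor_matrix))
    if (length(prec) == 0) return(NA_real_)
    precursor_correlation(mirna_matrix[nm, ],
                          precursor_matrix[prec, , drop = FALSE],
                          min_samples = min_samples)
  }, numeric(1))
  comps <- scale_components(m, m_max, N, n_max_eff, corr)
  score <- compute_score(comps$A, comps$B, comps$C, weights)
  if (absent_corr == "drop_weight") {
    miss <- is.na(corr)
    if (any(miss)) {
      w_ab <- weights[1] + weights[2]
      if (w_ab <= 0) {
        stop("cannot drop the correlation weight: w_A + w_B is zero",
             call. = FALSE)
      }
      score[miss] <- (weights[1] * comps$A[miss] +
                        weights[2] * comps$B[miss]) / w_ab
    }
  }
  tab <- data.frame(
    name = scored,
    median = unname(m),
    mimat = N,
    correlation = unname(corr),
    A = comps$A, B = comps$B, C = comps$C,
    score = score,
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$score, tab$mimat), ]
  rownames(tab) <- NULL
  structure(tab,
            class = c("mirna_score_table", "data.frame"),
            weights = weights, m_max = m_max, n_max = n_max_eff,
            unannotated = unannotated)
}

#' @export
print.mirna_score_table <- function(x, ...) {
  cat("miRNA score table:", nrow(x), "miRNAs (m_max =",
      format(attr(x, "m_max"), digits = 4), ", n_max =", attr(x, "n_max"),
      ")\n")
  print.data.frame(utils::head(x, 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Write a score table as TSV
#'
#' Columns `name`, `median`, `mimat`, `correlation`, `A`, `B`, `C`, `score`;
#' rows sorted by descending score, ties broken by ascending MIMAT number.
#'
#' @param table a `mirna_score_table` (or compatible data.frame).
#' @param path output path.
#' @export
write_score_table <- function(table, path) {
  cols <- c("name", "median", "mimat", "correlation", "A", "B", "C", "score")
  stopifnot(all(cols %in% names(table)))
  out <- as.data.frame(table)[, cols]
  out <- out[order(-out$score, out$mimat), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path TSV path.
#' @return a `mirna_score_table` data.frame.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE)
  cols <- c("name", "median", "mimat", "correlation", "A", "B", "C", "score")
  if (!all(cols %in% names(tab))) {
    stop("not a score table: missing column(s) ",
         paste(setdiff(cols, names(tab)), collapse = ", "), call. = FALSE)
  }
  structure(tab[, cols], class = c("mirna_score_table", "data.frame"))
}
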