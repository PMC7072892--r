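#' Read a sequencing reference expression profile
#'
#' Two-column TSV (name, median RPM) as produced by sequencing quantifiers.
#'
#' @param path TSV path; a header line is detected when the second field is
#'   non-numeric.
#' @return named numeric vector of median RPM values (finite, >= 0).
#' @export
read_reference_profile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("reference profile needs two columns",
                          call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(raw[1, 2])))) {
    raw <- raw[-1, , drop = FALSE]
  }
  rpm <- as.numeric(raw[[2]])
  if (anyNA(rpm) || any(!is.finite(rpm)) || any(rpm < 0)) {
    stop("reference RPM values must be finite and non-negative",
         call. = FALSE)
  }
  if (anyDuplicated(raw[[1]])) stop("duplicate names in reference profile",
                                    call. = FALSE)
  stats::setNames(rpm, raw[[1]])
}

#' Write a reference profile as TSV
#'
#' @param reference named numeric vector of median RPM values.
#' @param path output path.
#' @export
write_reference_profile <- function(reference, path) {
  utils::write.table(
    data.frame(name = names(reference), median_rpm = unname(reference)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cumulative expression coverage of the top-n miRNAs
#'
#' Sorts a reference profile by decreasing RPM and reports, for every n, the
#' percentage of total expression mass covered by the first n miRNAs. In
#' sequencing data a few dozen miRNAs typically cover well over 90 percent of
#' the mass; the curve makes that concentration visible.
#'
#' @param reference named numeric vector of median RPM values, at least one
#'   positive.
#' @return numeric vector of percentages (non-decreasing, last element 100),
#'   named by miRNA in coverage order.
#' @export
cumulative_coverage <- function(reference) {
  if (length(reference) == 0 || sum(reference) <= 0) {
    stop("reference profile must contain at least one positive RPM value",
         call. = FALSE)
  }
  sorted <- sort(reference, decreasing = TRUE)
  100 * cumsum(sorted) / sum(sorted)
}

#' Concordance between score-selected miRNAs and a sequencing reference
#'
#' Selects the miRNAs whose score strictly exceeds `score_threshold` and
#' counts how many are confirmed by the sequencing reference (median RPM
#' strictly above `rpm_threshold`; miRNAs absent from the reference count as
#' RPM 0). The baseline selects the same number of miRNAs by raw median
#' expression instead (ties broken by ascending MIMAT number); the ratio
#' baseline_discordant / n_discordant is the specificity gain of scoring over
#' raw expression and is the objective maximized by [optimize_weights()].
#'
#' @param score_table a `mirna_score_table`.
#' @param reference named numeric vector of median RPM values.
#' @param score_threshold strict score cutoff (default 0.75).
#' @param rpm_threshold strict RPM cutoff for "expressed" (default 10).
#' @return list of class `concordance_report`: `n_selected`, `n_concordant`,
#'   `n_discordant`, `baseline_discordant`, `ratio` (`NA` when
#'   `n_discordant` is 0 — reported as undefined), plus the thresholds.
#' @export
concordance <- function(score_table, reference, score_threshold = 0.75,
                        rpm_threshold = 10) {
  stopifnot(is.data.frame(score_table),
            all(c("name", "median", "mimat", "score") %in%
                  names(score_table)))
  if (length(intersect(score_table$name, names(reference))) == 0) {
    stop("score table and reference profile share no miRNA names",
         call. = FALSE)
  }
  rpm <- reference[score_table$name]
  absent <- is.na(rpm)
  if (any(absent)) {
    message(sum(absent), " scored miRNA(s) absent from the reference; ",
            "counted as RPM 0")
    rpm[absent] <- 0
  }
  selected <- score_table$score > score_threshold
  n_selected <- sum(selected)
  n_concordant <- sum(selected & rpm > rpm_threshold)
  n_discordant <- n_selected - n_concordant
  baseline_idx <- order(-score_table$median, score_table$mimat)[
    seq_len(n_selected)]
  baseline_discordant <- sum(rpm[baseline_idx] <= rpm_threshold)
  ratio <- if (n_discordant == 0) NA_real_ else
    baseline_discordant / n_discordant
  structure(list(n_selected = n_selected, n_concordant = n_concordant,
                 n_discordant = n_discordant,
                 baseline_discordant = baseline_discordant,
                 ratio = ratio, score_threshold = score_threshold,
                 rpm_threshold = rpm_threshold),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance with sequencing reference\n")
  cat("  score > ", x$score_threshold, ": ", x$n_selected,
      " miRNAs selected\n", sep = "")
  cat("  of these, RPM > ", x$rpm_threshold, ": ", x$n_concordant,
      " (discordant: ", x$n_discordant, ")\n", sep = "")
  cat("  raw-expression baseline discordant: ", x$baseline_discordant, "\n",
      sep = "")
  cat("  specificity ratio (baseline/score discordant): ",
      if (is.na(x$ratio)) "undefined (no discordant selections)"
      else format(x$ratio, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Rank separation between two score groups
#'
#' Two-sided Mann-Whitney U test (tie-corrected) comparing the scores of two
#' groups of miRNAs — typically those confirmed by sequencing (RPM above
#' threshold) against the rest — plus each group's mean and sample (n-1)
#' standard deviation.
#'
#' @param scores_group1,scores_group2 non-empty numeric vectors.
#' @return list with `U`, `p.value`, `mean1`, `sd1`, `mean2`, `sd2`, and the
#'   p-value method.
#' @export
rank_separation <- function(scores_group1, scores_group2) {
  res <- mann_whitney_u(scores_group1, scores_group2,
                        alternative = "two.sided")
  list(U = res$U, p.value = res$p.value,
       mean1 = mean(scores_group1), sd1 = stats::sd(scores_group1),
       mean2 = mean(scores_group2), sd2 = stats::sd(scores_group2),
       method = res$method)
}

# All weight triples (i, j, k) * step with i + j + k = 1 / step.
weight_grid <- function(grid_step) {
  k <- 1 / grid_step
  if (abs(k - round(k)) > 1e-9) {
    stop("grid_step must divide 1 evenly", call. = FALSE)
  }
  k <- as.integer(round(k))
  grid <- expand.grid(i = 0:k, j = 0:k)
  grid <- grid[grid$i + grid$j <= k, ]
  data.frame(w_a = grid$i / k, w_b = grid$j / k,
             w_c = (k - grid$i - grid$j) / k)
}

#' Select scoring weights by maximizing the specificity ratio
#'
#' Exhaustively evaluates every weight triple on the simplex lattice with the
#' given step, scoring all miRNAs with each triple and computing the
#' concordance report against the sequencing reference. The objective is the
#' specificity ratio (baseline discordant / score discordant), with zero
#' score-discordant selections treated as +Inf; ties are broken toward larger
#' `n_concordant`, then lexicographically by descending (w_A, w_B, w_C).
#'
#' @param mirna_matrix,precursor_matrix,annotation inputs to [score_all()].
#' @param reference named numeric vector of median RPM values.
#' @param grid_step simplex lattice step; must divide 1 evenly (default 0.05).
#' @param score_threshold,rpm_threshold thresholds passed to [concordance()].
#' @param ... further arguments passed to [score_all()].
#' @return list with `weights` (a [score_weights()] object), `objective`,
#'   and `grid` (data.frame of every evaluated triple with its objective and
#'   counts).
#' @export
optimize_weights <- function(mirna_matrix, precursor_matrix = NULL,
                             annotation, reference, grid_step = 0.05,
                             score_threshold = 0.75, rpm_threshold = 10,
                             ...) {
  grid <- weight_grid(grid_step)
  grid$objective <- NA_real_
  grid$n_selected <- NA_integer_
  grid$n_concordant <- NA_integer_
  grid$n_discordant <- NA_integer_
  for (r in seq_len(nrow(grid))) {
    w <- score_weights(grid$w_a[r], grid$w_b[r], grid$w_c[r])
    tab <- suppressMessages(
      score_all(mirna_matrix, precursor_matrix, annotation, weights = w, ...))
    rep_ <- suppressMessages(
      concordance(tab, reference, score_threshold, rpm_threshold))
    grid$objective[r] <- if (rep_$n_discordant == 0) Inf else rep_$ratio
    grid$n_selected[r] <- rep_$n_selected
    grid$n_concordant[r] <- rep_$n_concordant
    grid$n_discordant[r] <- rep_$n_discordant
  }
  ord <- order(-grid$objective, -grid$n_concordant,
               -grid$w_a, -grid$w_b, -grid$w_c)
  best <- grid[ord[1], ]
  list(weights = score_weights(best$w_a, best$w_b, best$w_c),
       objective = best$objective, grid = grid)
}
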