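# In-code fixture builders shared across test files.

make_matrix <- function(values, features, samples) {
  matrix(values, nrow = length(features), byrow = TRUE,
         dimnames = list(features, samples))
}

# Write a tiny expression TSV and return its path.
write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A small annotation built through the file-reading path (aliases + mapping).
read_annotation_fixture <- function(aliases_lines, mapping_lines,
                                    fasta_lines = NULL, ...) {
  ap <- write_tsv_fixture(aliases_lines, ".txt")
  mp <- write_tsv_fixture(mapping_lines)
  fp <- if (is.null(fasta_lines)) NULL else write_tsv_fixture(fasta_lines,
                                                              ".fa")
  read_annotation(ap, mp, fasta_path = fp, ...)
}

# Independent straight-line recomputation of the scoring model: medians,
# max-over-precursors Spearman, component scaling and the weighted sum, with
# no shared code with score_all() beyond base R.
oracle_scores <- function(mirna, prec, ann, weights, n_max = ann$n_max,
                          min_samples = 5L) {
  names_ <- intersect(rownames(mirna), ann$records$mature_name)
  m <- vapply(names_, function(nm) median(mirna[nm, ]), numeric(1))
  m_max <- max(m)
  out <- numeric(0)
  for (nm in names_) {
    A <- m[nm] / m_max
    B <- max(0, 1 - ann$records[nm, "mimat"] / n_max)
    cc <- NA_real_
    if (!is.null(prec) && ncol(mirna) >= min_samples) {
      pn <- intersect(ann$records[nm, "precursors"][[1]], rownames(prec))
      if (length(pn)) {
        cc <- max(vapply(pn, function(p) {
          cor(mirna[nm, ], prec[p, colnames(mirna)], method = "spearman")
        }, numeric(1)))
      }
    }
    C <- if (is.na(cc)) 0.5 else (cc + 1) / 2
    out[nm] <- weights[1] * A + weights[2] * B + weights[3] * C
  }
  out
}

# Brute-force Mann-Whitney U for the first group: all cross pairs, half
# credit for ties.
brute_force_u <- function(x, y) {
  sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Enumeration oracle for approximate occurrence counting: all substitution
# neighbors of the pattern at Hamming distance <= k (ACGT alphabet), counted
# as exact window matches; both strands.
oracle_occurrences <- function(pattern, genome, k, both_strands = TRUE) {
  alphabet <- c("A", "C", "G", "T")
  neighbors <- function(p) {
    chars <- strsplit(p, "")[[1]]
    L <- length(chars)
    out <- p
    if (k >= 1) {
      for (i in seq_len(L)) {
        for (b in setdiff(alphabet, chars[i])) {
          v <- chars; v[i] <- b
          out <- c(out, paste(v, collapse = ""))
        }
      }
    }
    if (k >= 2 && L >= 2) {
      pos <- combn(L, 2)
      for (j in seq_len(ncol(pos))) {
        i1 <- pos[1, j]; i2 <- pos[2, j]
        for (b1 in setdiff(alphabet, chars[i1])) {
          for (b2 in setdiff(alphabet, chars[i2])) {
            v <- chars; v[i1] <- b1; v[i2] <- b2
            out <- c(out, paste(v, collapse = ""))
          }
        }
      }
    }
    out
  }
  count_one <- function(p, text) {
    L <- nchar(p)
    G <- nchar(text)
    if (L > G) return(0L)
    windows <- substring(text, 1:(G - L + 1), L:G)
    sum(windows %in% neighbors(p))
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  total <- 0L
  for (text in genome) {
    total <- total + count_one(pattern, text)
    if (both_strands) total <- total + count_one(rc(pattern), text)
  }
  total
}

random_acgt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
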