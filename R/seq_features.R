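#' Read nucleotide sequences from FASTA
#'
#' Sequences are uppercased and U (RNA) is normalized to T on load; the
#' alphabet is restricted to A, C, G, T, N.
#'
#' @param path FASTA file (mature miRNAs, probes, or genome records).
#' @return named character vector of sequences.
#' @export
read_sequences_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  normalize_sequence(seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector over the A/C/G/T/U/N alphabet.
#' @param path output path.
#' @export
write_sequences_fasta <- function(seqs, path) {
  seqs <- normalize_sequence(seqs)
  if (is.null(names(seqs))) stop("sequences must be named", call. = FALSE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 70L)
  invisible(path)
}

#' Normalize a nucleotide sequence
#'
#' Uppercases, converts U to T, and rejects characters outside A/C/G/T/N.
#'
#' @param seq character vector of sequences.
#' @return normalized character vector (names preserved).
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq) || length(seq) == 0) {
    stop("sequence must be a character vector", call. = FALSE)
  }
  out <- chartr("u", "T", toupper(seq))
  out <- chartr("U", "T", out)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    stop("invalid nucleotide alphabet in sequence(s): ",
         paste(utils::head(names(out)[bad], 3), collapse = ", "),
         if (is.null(names(out))) paste(utils::head(out[bad], 3),
                                        collapse = ", ") else "",
         call. = FALSE)
  }
  out
}

#' Reverse complement
#'
#' @param seq character vector over A/C/G/T/N (U accepted, normalized first).
#' @return reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_sequence(seq)
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC-content of nucleotide sequences
#'
#' Fraction of G and C bases among non-N bases. Microarray probe sequences for
#' miRNA arrays coincide with the mature miRNA sequence, so this doubles as
#' probe GC-content.
#'
#' @param seq character vector of sequences (U accepted).
#' @return numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(seq) {
  seq <- normalize_sequence(seq)
  chars <- strsplit(seq, "", fixed = TRUE)
  out <- vapply(chars, function(ch) {
    n_informative <- sum(ch != "N")
    if (n_informative == 0) {
      stop("GC-content undefined for empty or all-N sequence", call. = FALSE)
    }
    sum(ch %in% c("G", "C")) / n_informative
  }, numeric(1))
  names(out) <- names(seq)
  out
}

# Count windows of `text` within Hamming distance <= k of `pattern`.
# Substitutions only; N mismatches everything, including another N.
# Vectorized over window start positions using raw bytes.
hamming_window_count <- function(pattern, text, k) {
  lp <- nchar(pattern)
  lt <- nchar(text)
  if (lp > lt) return(0L)
  pr <- charToRaw(pattern)
  tr <- charToRaw(text)
  n_win <- lt - lp + 1L
  raw_n <- charToRaw("N")
  mism <- integer(n_win)
  for (j in seq_len(lp)) {
    tj <- tr[j:(j + n_win - 1L)]
    mism <- mism + as.integer(tj != pr[j] | tj == raw_n | pr[j] == raw_n)
    # windows already past the budget can never recover; no early exit needed
    # at these scales, the vectorized pass is cheap
  }
  sum(mism <= k)
}

#' Count approximate occurrences of a sequence in a genome
#'
#' Slides the pattern along every genome record and counts alignment
#' positions whose Hamming distance (substitutions only, no gaps) to the
#' genome window is at most `max_mismatches` — the search bowtie performs in
#' `-v` mode. Both strands are searched by default (the reverse complement of
#' the pattern is scanned against the forward genome text). Overlapping sites
#' each count; `N` in pattern or genome counts as a mismatch.
#'
#' @param pattern a single sequence (character; U accepted).
#' @param genome character vector of genome records (multi-FASTA contents).
#' @param max_mismatches maximum allowed substitutions (default 2).
#' @param both_strands search the reverse complement too (default TRUE).
#' @return non-negative integer count, summed over records and strands. A
#'   pattern longer than every genome record yields 0 with a warning.
#' @export
count_genomic_occurrences <- function(pattern, genome, max_mismatches = 2,
                                      both_strands = TRUE) {
  stopifnot(length(pattern) == 1)
  pattern <- normalize_sequence(pattern)
  genome <- normalize_sequence(genome)
  if (max_mismatches < 0) stop("max_mismatches must be >= 0", call. = FALSE)
  if (all(nchar(genome) < nchar(pattern))) {
    warning("pattern is longer than every genome record; count is 0",
            call. = FALSE)
    return(0L)
  }
  pats <- pattern
  if (both_strands) pats <- c(pats, reverse_complement(pattern))
  total <- 0L
  for (rec in genome) {
    for (p in pats) {
      total <- total + hamming_window_count(p, rec, max_mismatches)
    }
  }
  total
}

#' Identify false-positive miRNAs from paired array and sequencing data
#'
#' A miRNA is called a false positive when it is highly expressed on the array
#' (median at or above the empirical `top_quantile` cutoff of all array
#' medians) yet shows no expression in the sequencing reference (median RPM at
#' or below `expressed_cutoff`; miRNAs absent from the reference count as RPM
#' 0). The quantile uses linear interpolation (R type 7) and the cutoff is
#' boundary-inclusive.
#'
#' @param array_medians named numeric vector of per-miRNA array medians.
#' @param reference named numeric vector of median RPM values (see
#'   [read_reference_profile()]).
#' @param top_quantile array-median quantile defining "highly expressed"
#'   (default 0.90, i.e. the top 10 percent).
#' @param expressed_cutoff RPM at or below which a miRNA counts as not
#'   expressed (default 0, exact zero).
#' @return data.frame with columns `name`, `array_median`, `seq_rpm`,
#'   `is_false_positive`, one row per entry of `array_medians`; the cutoff is
#'   attached as attribute `cutoff`.
#' @export
identify_false_positives <- function(array_medians, reference,
                                     top_quantile = 0.90,
                                     expressed_cutoff = 0) {
  if (length(array_medians) == 0 || is.null(names(array_medians))) {
    stop("array_medians must be a non-empty named numeric vector",
         call. = FALSE)
  }
  if (top_quantile <= 0 || top_quantile >= 1) {
    stop("top_quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  if (expressed_cutoff < 0) stop("expressed_cutoff must be >= 0",
                                 call. = FALSE)
  cutoff <- stats::quantile(array_medians, top_quantile, names = FALSE,
                            type = 7)
  rpm <- reference[names(array_medians)]
  rpm[is.na(rpm)] <- 0
  calls <- data.frame(
    name = names(array_medians),
    array_median = unname(array_medians),
    seq_rpm = unname(rpm),
    is_false_positive = unname(array_medians >= cutoff &
                                 rpm <= expressed_cutoff),
    stringsAsFactors = FALSE
  )
  attr(calls, "cutoff") <- cutoff
  calls
}

#' Compare a sequence feature between false positives and the remainder
#'
#' One-sided Mann-Whitney U test of whether the false-positive group's feature
#' values (GC-content, genomic occurrence count, ...) are stochastically
#' greater than the remaining miRNAs', with tie correction.
#'
#' @param calls data.frame from [identify_false_positives()].
#' @param feature_values named numeric vector of the feature, joined on name.
#' @return list with `U` (false-positive group statistic), `p.value`
#'   (one-sided, alternative: false positives greater), `direction` (which
#'   group has the larger values), and group sizes.
#' @export
compare_feature <- function(calls, feature_values) {
  stopifnot(is.data.frame(calls),
            all(c("name", "is_false_positive") %in% names(calls)))
  joined <- calls[calls$name %in% names(feature_values), ]
  fp <- feature_values[joined$name[joined$is_false_positive]]
  other <- feature_values[joined$name[!joined$is_false_positive]]
  if (length(fp) == 0 || length(other) == 0) {
    stop("both the false-positive group and the remainder must be non-empty ",
         "after joining on names", call. = FALSE)
  }
  res <- mann_whitney_u(fp, other, alternative = "greater")
  half <- length(fp) * length(other) / 2
  direction <- if (res$U > half) {
    "false-positives greater"
  } else if (res$U < half) {
    "false-positives smaller"
  } else {
    "tied"
  }
  list(U = res$U, p.value = res$p.value, direction = direction,
       n_false_positive = length(fp), n_other = length(other),
       method = res$method)
}
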