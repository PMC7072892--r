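#' Parse a MIMAT accession into its chronological number
#'
#' miRBase assigns mature miRNAs accessions of the form `MIMAT` followed by a
#' zero-padded decimal number; the number is chronological, so small values
#' mark early-discovered (and generally better-validated) miRNAs. Precursor
#' accessions (`MI0...`) are rejected.
#'
#' @param accession character vector of accessions.
#' @return integer vector of MIMAT numbers (leading zeros stripped).
#' @examples
#' parse_mimat_number("MIMAT0000062")  # 62
#' @export
parse_mimat_number <- function(accession) {
  if (!is.character(accession) || length(accession) == 0) {
    stop("accession must be a non-empty character vector", call. = FALSE)
  }
  ok <- grepl("^MIMAT[0-9]+$", accession)
  if (!all(ok)) {
    stop("malformed MIMAT accession(s): ",
         paste(accession[!ok], collapse = ", "), call. = FALSE)
  }
  n <- as.integer(sub("^MIMAT", "", accession))
  if (any(n < 1L)) {
    stop("MIMAT number must be >= 1, got: ",
         paste(accession[n < 1L], collapse = ", "), call. = FALSE)
  }
  n
}

#' Format a MIMAT number as a zero-padded accession
#'
#' Inverse of [parse_mimat_number()].
#'
#' @param n positive integer vector.
#' @return character vector of `MIMAT`-prefixed accessions (7-digit padding).
#' @export
format_mimat_accession <- function(n) {
  stopifnot(is.numeric(n), all(n >= 1))
  sprintf("MIMAT%07d", as.integer(n))
}

# Internal constructor/validator for annotation sets. `records` is a
# data.frame with columns mature_name (character), mimat (integer),
# precursors (list of character vectors), sequence (character or NA).
annotation_set <- function(records, n_max = NULL) {
  stopifnot(is.data.frame(records),
            all(c("mature_name", "mimat", "precursors", "sequence") %in%
                  names(records)))
  if (nrow(records) == 0) stop("annotation set is empty", call. = FALSE)
  if (anyDuplicated(records$mature_name)) {
    stop("duplicate mature names in annotation set", call. = FALSE)
  }
  if (any(records$mimat < 1L)) stop("MIMAT numbers must be >= 1",
                                    call. = FALSE)
  if (any(lengths(records$precursors) == 0)) {
    stop("every annotation record needs at least one precursor name",
         call. = FALSE)
  }
  has_seq <- !is.na(records$sequence)
  if (any(nchar(records$sequence[has_seq]) < 16)) {
    stop("mature sequences must be at least 16 nt", call. = FALSE)
  }
  observed_max <- max(records$mimat)
  if (is.null(n_max)) {
    n_max <- observed_max
  } else if (n_max < observed_max) {
    stop("n_max override (", n_max, ") is smaller than the largest MIMAT ",
         "number in the set (", observed_max, ")", call. = FALSE)
  }
  rownames(records) <- records$mature_name
  structure(list(records = records, n_max = as.integer(n_max)),
            class = "mirna_annotation")
}

#' @export
print.mirna_annotation <- function(x, ...) {
  cat("miRNA annotation set:", nrow(x$records), "mature records, n_max =",
      x$n_max, "\n")
  invisible(x)
}

#' Construct an annotation set programmatically
#'
#' In-memory alternative to [read_annotation()] for workflows that already
#' hold the mature/precursor relationships in R.
#'
#' @param mature_name character vector of unique mature miRNA names.
#' @param mimat integer vector of MIMAT numbers (same length).
#' @param precursors list of character vectors (one non-empty vector per
#'   mature), or a single character vector with one precursor per mature.
#' @param sequence optional character vector of mature sequences (NA where
#'   unknown; at least 16 nt otherwise).
#' @param n_max optional override of the maximum MIMAT number.
#' @return a `mirna_annotation` object.
#' @export
make_annotation <- function(mature_name, mimat, precursors,
                            sequence = NA_character_, n_max = NULL) {
  if (is.character(precursors)) precursors <- as.list(precursors)
  records <- data.frame(mature_name = mature_name,
                        mimat = as.integer(mimat),
                        stringsAsFactors = FALSE)
  records$precursors <- precursors
  records$sequence <- rep_len(sequence, length(mature_name))
  annotation_set(records, n_max = n_max)
}

#' Read miRNA annotation from aliases + precursor mapping files
#'
#' The aliases file follows the miRBase `aliases.txt` dialect: one accession
#' per line, a tab, then a semicolon-separated list of names. Only `MIMAT`
#' (mature) accessions are used. The mapping file is two-column delimited text
#' pairing a precursor name with a mature name; a mature produced from several
#' genomic loci gets all its precursors merged into one record. Mature names
#' lacking a MIMAT accession or lacking any precursor are skipped with a
#' warning.
#'
#' @param aliases_path miRBase-style aliases file.
#' @param mapping_path two-column precursor-to-mature mapping (TSV; a header
#'   line is detected and skipped if its first field is `precursor`).
#' @param fasta_path optional FASTA of mature sequences (U is normalized to T).
#' @param n_max optional override for the maximum MIMAT number; must not be
#'   smaller than the maximum observed in the set.
#' @return an object of class `mirna_annotation` with elements `records`
#'   (data.frame: mature_name, mimat, precursors, sequence) and `n_max`.
#' @export
read_annotation <- function(aliases_path, mapping_path, fasta_path = NULL,
                            n_max = NULL) {
  for (p in c(aliases_path, mapping_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  lines <- readLines(aliases_path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  name2mimat <- new.env(parent = emptyenv())
  for (p in parts) {
    if (length(p) < 2 || !grepl("^MIMAT[0-9]+$", p[1])) next
    num <- parse_mimat_number(p[1])
    for (nm in strsplit(p[2], ";", fixed = TRUE)[[1]]) {
      nm <- trimws(nm)
      if (!nzchar(nm)) next
      if (!is.null(name2mimat[[nm]]) && name2mimat[[nm]] != num) {
        warning("mature name '", nm, "' maps to multiple MIMAT accessions; ",
                "keeping the first", call. = FALSE)
      } else {
        name2mimat[[nm]] <- num
      }
    }
  }
  map_raw <- utils::read.table(mapping_path, header = FALSE, sep = "\t",
                               quote = "", comment.char = "",
                               colClasses = "character",
                               stringsAsFactors = FALSE)
  if (ncol(map_raw) < 2) stop("mapping file needs two columns", call. = FALSE)
  if (tolower(map_raw[1, 1]) %in% c("precursor", "precursor_name")) {
    map_raw <- map_raw[-1, , drop = FALSE]
  }
  precursors <- split(map_raw[[1]], map_raw[[2]])
  precursors <- lapply(precursors, function(v) unique(v))

  matures <- ls(name2mimat)
  skipped_no_prec <- setdiff(matures, names(precursors))
  skipped_no_mimat <- setdiff(names(precursors), matures)
  if (length(skipped_no_mimat)) {
    warning(length(skipped_no_mimat),
            " mature name(s) in mapping have no MIMAT accession; skipped: ",
            paste(utils::head(skipped_no_mimat, 5), collapse = ", "),
            call. = FALSE)
  }
  if (length(skipped_no_prec)) {
    warning(length(skipped_no_prec),
            " mature name(s) have no precursor mapping; skipped",
            call. = FALSE)
  }
  keep <- intersect(matures, names(precursors))
  if (length(keep) == 0) {
    stop("no mature records with both a MIMAT accession and a precursor",
         call. = FALSE)
  }
  seqs <- rep(NA_character_, length(keep))
  names(seqs) <- keep
  if (!is.null(fasta_path)) {
    fa <- read_sequences_fasta(fasta_path)
    hit <- intersect(keep, names(fa))
    seqs[hit] <- unname(fa[hit])
  }
  records <- data.frame(
    mature_name = keep,
    mimat = vapply(keep, function(nm) name2mimat[[nm]], integer(1)),
    stringsAsFactors = FALSE
  )
  records$precursors <- unname(precursors[keep])
  records$sequence <- unname(seqs)
  annotation_set(records, n_max = n_max)
}

#' Read miRNA annotation from a miRBase-style GFF3 file
#'
#' Convenience reader extracting the same fields as [read_annotation()] from a
#' GFF3 file in the miRBase dialect: `miRNA_primary_transcript` features name
#' the precursors; `miRNA` features carry `Alias=MIMAT...` and
#' `Derives_from=` attributes linking each mature to its precursor.
#'
#' @param path GFF3 file.
#' @param fasta_path optional FASTA of mature sequences.
#' @param n_max optional override for the maximum MIMAT number.
#' @return a `mirna_annotation` object.
#' @export
read_annotation_gff3 <- function(path, fasta_path = NULL, n_max = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  attr_of <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0("(^|;)", key, "=[^;]+"), attrs))
    if (length(m) == 0) return(NA_character_)
    sub(paste0("^;?", key, "="), "", m)
  }
  prec_id2name <- character(0)
  mat <- list()
  for (f in fields) {
    if (length(f) < 9) next
    attrs <- f[9]
    if (f[3] == "miRNA_primary_transcript") {
      id <- attr_of(attrs, "ID")
      nm <- attr_of(attrs, "Name")
      if (!is.na(id) && !is.na(nm)) prec_id2name[id] <- nm
    } else if (f[3] == "miRNA") {
      nm <- attr_of(attrs, "Name")
      alias <- attr_of(attrs, "Alias")
      from <- attr_of(attrs, "Derives_from")
      if (is.na(nm) || is.na(from)) next
      alias <- strsplit(alias, ",", fixed = TRUE)[[1]]
      alias <- alias[grepl("^MIMAT[0-9]+$", alias)]
      if (length(alias) == 0) {
        warning("mature '", nm, "' has no MIMAT alias; skipped",
                call. = FALSE)
        next
      }
      mat[[length(mat) + 1]] <- list(name = nm, mimat = alias[1],
                                     from = from)
    }
  }
  if (length(mat) == 0) stop("no mature miRNA records in ", path,
                             call. = FALSE)
  names_ <- vapply(mat, `[[`, character(1), "name")
  mimat <- parse_mimat_number(vapply(mat, `[[`, character(1), "mimat"))
  prec <- vapply(mat, function(r) {
    nm <- prec_id2name[r$from]
    if (is.na(nm)) r$from else unname(nm)
  }, character(1))
  agg <- split(seq_along(names_), names_)
  keep <- names(agg)
  records <- data.frame(mature_name = keep, stringsAsFactors = FALSE)
  records$mimat <- vapply(agg, function(i) mimat[i][1], integer(1))
  records$precursors <- lapply(agg, function(i) unique(prec[i]))
  seqs <- rep(NA_character_, length(keep))
  names(seqs) <- keep
  if (!is.null(fasta_path)) {
    fa <- read_sequences_fasta(fasta_path)
    hit <- intersect(keep, names(fa))
    seqs[hit] <- unname(fa[hit])
  }
  records$sequence <- unname(seqs)
  annotation_set(records, n_max = n_max)
}

#' Serialize an annotation set to aliases + mapping files
#'
#' Writes the two-file canonical form read by [read_annotation()], so that
#' reading the output back yields an equal annotation set.
#'
#' @param annotation a `mirna_annotation` object.
#' @param aliases_path,mapping_path output paths.
#' @param fasta_path optional output FASTA for records carrying sequences.
#' @export
write_annotation <- function(annotation, aliases_path, mapping_path,
                             fasta_path = NULL) {
  stopifnot(inherits(annotation, "mirna_annotation"))
  rec <- annotation$records
  writeLines(paste0(format_mimat_accession(rec$mimat), "\t",
                    rec$mature_name, ";"), aliases_path)
  pairs <- data.frame(
    precursor = unlist(rec$precursors),
    mature = rep(rec$mature_name, lengths(rec$precursors)),
    stringsAsFactors = FALSE
  )
  utils::write.table(pairs, mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(fasta_path)) {
    has <- !is.na(rec$sequence)
    write_sequences_fasta(stats::setNames(rec$sequence[has],
                                          rec$mature_name[has]),
                          fasta_path)
  }
  invisible(annotation)
}
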