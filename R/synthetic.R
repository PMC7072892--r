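#' Configuration for the synthetic paired array/sequencing generator
#'
#' The generator emulates the structure the scorer exploits in real data:
#' truly expressed miRNAs carry low (early) MIMAT numbers, rank-correlated
#' precursor profiles and positive sequencing RPM, while false positives
#' carry high MIMAT numbers, uncorrelated precursors, zero RPM, array medians
#' drawn from the same range as the true group (so raw expression cannot
#' separate the groups) and GC-rich mature sequences planted repeatedly in
#' the genome with up to two substitutions.
#'
#' @param n_true,n_false counts of truly expressed and false-positive miRNAs.
#' @param n_samples number of samples (default 30).
#' @param mimat_true_range,mimat_false_range disjoint integer intervals for
#'   MIMAT numbers (defaults \[1, 5000\] and \[5001, 35000\]).
#' @param corr_true,corr_false target miRNA-precursor Spearman levels
#'   (defaults 0.8 and 0).
#' @param gc_true_mean,gc_false_mean per-base GC probabilities for mature
#'   sequences (defaults 0.45 and 0.60).
#' @param noise_sd standard deviation of array noise on the log2-like scale
#'   (default 1).
#' @param seed integer RNG seed.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_true = 50L, n_false = 150L, n_samples = 30L,
                             mimat_true_range = c(1L, 5000L),
                             mimat_false_range = c(5001L, 35000L),
                             corr_true = 0.8, corr_false = 0,
                             gc_true_mean = 0.45, gc_false_mean = 0.60,
                             noise_sd = 1, seed = 1L) {
  cfg <- list(n_true = as.integer(n_true), n_false = as.integer(n_false),
              n_samples = as.integer(n_samples),
              mimat_true_range = as.integer(mimat_true_range),
              mimat_false_range = as.integer(mimat_false_range),
              corr_true = corr_true, corr_false = corr_false,
              gc_true_mean = gc_true_mean, gc_false_mean = gc_false_mean,
              noise_sd = noise_sd, seed = as.integer(seed))
  if (cfg$n_true < 1 || cfg$n_false < 1 || cfg$n_samples < 1) {
    stop("counts must be positive", call. = FALSE)
  }
  for (r in list(cfg$mimat_true_range, cfg$mimat_false_range)) {
    if (length(r) != 2 || r[1] < 1 || r[2] < r[1]) {
      stop("MIMAT ranges must be increasing positive intervals",
           call. = FALSE)
    }
  }
  if (cfg$mimat_true_range[2] >= cfg$mimat_false_range[1] &&
      cfg$mimat_false_range[2] >= cfg$mimat_true_range[1]) {
    stop("MIMAT ranges must be disjoint", call. = FALSE)
  }
  if (diff(cfg$mimat_true_range) + 1 < cfg$n_true ||
      diff(cfg$mimat_false_range) + 1 < cfg$n_false) {
    stop("MIMAT range too small for the requested count", call. = FALSE)
  }
  for (v in c(cfg$corr_true, cfg$corr_false)) {
    if (v < -1 || v > 1) stop("correlation targets must lie in [-1, 1]",
                              call. = FALSE)
  }
  for (v in c(cfg$gc_true_mean, cfg$gc_false_mean)) {
    if (v <= 0 || v >= 1) stop("GC means must lie strictly in (0, 1)",
                               call. = FALSE)
  }
  if (cfg$noise_sd <= 0) stop("noise_sd must be positive", call. = FALSE)
  structure(cfg, class = "synthetic_config")
}

# Expected sample Spearman coefficient of a bivariate normal with Pearson
# correlation rho at sample size n (Moran's finite-n formula).
expected_spearman <- function(rho, n) {
  6 / (pi * (n + 1)) * (asin(rho) + (n - 2) * asin(rho / 2))
}

# Pearson level of the latent bivariate normal whose sample Spearman has
# expectation `target` at sample size n. Inverts expected_spearman
# numerically; falls back to the asymptotic 2*sin(pi*target/6) when the
# target is outside the attainable finite-n range.
calibrate_latent_correlation <- function(target, n) {
  if (target == 0) return(0)
  bound <- expected_spearman(sign(target) * 1, n)
  if (abs(target) >= abs(bound)) return(2 * sin(pi * target / 6))
  stats::uniroot(function(r) expected_spearman(r, n) - target,
                 interval = sort(c(0, sign(target))),
                 tol = 1e-10)$root
}

# Random sequence with a given per-base GC probability.
random_sequence <- function(length, gc_prob) {
  gc <- stats::runif(length) < gc_prob
  strong <- ifelse(stats::runif(length) < 0.5, "G", "C")
  weak <- ifelse(stats::runif(length) < 0.5, "A", "T")
  paste(ifelse(gc, strong, weak), collapse = "")
}

# Apply n random substitutions (each to a different position, always changing
# the base) to a sequence.
mutate_sequence <- function(seq, n_sub) {
  if (n_sub == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic paired array/sequencing dataset with planted truth
#'
#' Array intensities sit on a log2-like scale (baselines uniform in 2-14 as
#' RMA output would be); sequencing RPM values are linear. Correlation between
#' a true miRNA and its precursor is induced by a shared latent factor: the
#' target Spearman level is converted to the Pearson correlation of the
#' underlying bivariate normal whose sample Spearman coefficient has exactly
#' that expectation at the configured sample size (Moran's finite-n formula,
#' inverted numerically; asymptotically 2*sin(pi*rho_s/6)), and both
#' profiles mix the latent factor with independent noise accordingly. Mature sequences are 22 nt, sampled base-by-base with the
#' group's GC probability. The genome plants every true sequence once and
#' every false sequence three times with 0-2 random substitutions per copy,
#' separated by random background spacers.
#'
#' @param config a [synthetic_config()] object.
#' @return list of class `synthetic_dataset` with elements `mirna_matrix`,
#'   `precursor_matrix`, `annotation` (a `mirna_annotation`), `reference`
#'   (named RPM vector), `truth` (named logical: truly expressed), `genome`
#'   (named character, one record), and `config`.
#' @export
generate_synthetic_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_true + config$n_false
  is_true <- c(rep(TRUE, config$n_true), rep(FALSE, config$n_false))
  names_ <- sprintf("sim-miR-%04d-5p", seq_len(n))
  prec_names <- sprintf("sim-mir-%04d", seq_len(n))
  samples <- sprintf("sample_%02d", seq_len(config$n_samples))

  mimat <- integer(n)
  mimat[is_true] <- sample(seq(config$mimat_true_range[1],
                               config$mimat_true_range[2]), config$n_true)
  mimat[!is_true] <- sample(seq(config$mimat_false_range[1],
                                config$mimat_false_range[2]), config$n_false)

  # Pearson level of the shared latent factor whose sample Spearman has the
  # configured expectation at this sample size (exact bivariate-normal
  # calibration; the asymptotic form is 2*sin(pi*rho_s/6))
  rho_true <- calibrate_latent_correlation(config$corr_true,
                                           config$n_samples)
  rho_false <- calibrate_latent_correlation(config$corr_false,
                                            config$n_samples)
  rho <- ifelse(is_true, rho_true, rho_false)
  mu_mirna <- stats::runif(n, 6, 13)
  mu_prec <- stats::runif(n, 5, 12)
  ns <- config$n_samples
  mirna_mat <- matrix(0, n, ns, dimnames = list(names_, samples))
  prec_mat <- matrix(0, n, ns, dimnames = list(prec_names, samples))
  for (i in seq_len(n)) {
    z <- stats::rnorm(ns)
    e1 <- stats::rnorm(ns)
    e2 <- stats::rnorm(ns)
    a <- sqrt(abs(rho[i]))
    s <- sign(rho[i])
    b <- sqrt(1 - abs(rho[i]))
    mirna_mat[i, ] <- mu_mirna[i] + config$noise_sd * (a * z + b * e1)
    prec_mat[i, ] <- mu_prec[i] + config$noise_sd * (s * a * z + b * e2)
  }
  mirna_mat <- pmax(mirna_mat, 0)
  prec_mat <- pmax(prec_mat, 0)

  reference <- stats::setNames(numeric(n), names_)
  reference[is_true] <- stats::rlnorm(config$n_true, log(200), 1.2)

  seqs <- vapply(seq_len(n), function(i) {
    random_sequence(22L, if (is_true[i]) config$gc_true_mean
                    else config$gc_false_mean)
  }, character(1))
  names(seqs) <- names_

  plant <- character(0)
  for (i in seq_len(n)) {
    copies <- if (is_true[i]) 1L else 3L
    for (k in seq_len(copies)) {
      plant <- c(plant, mutate_sequence(seqs[i], sample(0:2, 1)))
    }
  }
  plant <- plant[sample(length(plant))]
  spacers <- vapply(seq_len(length(plant) + 1),
                    function(i) random_sequence(30L, 0.41), character(1))
  genome <- paste0(paste0(spacers[seq_along(plant)], plant,
                          collapse = ""), spacers[length(spacers)])
  genome <- stats::setNames(genome, "sim_chr1")

  records <- data.frame(mature_name = names_, mimat = mimat,
                        stringsAsFactors = FALSE)
  records$precursors <- as.list(prec_names)
  records$sequence <- unname(seqs)
  annotation <- annotation_set(records)

  structure(list(mirna_matrix = mirna_mat, precursor_matrix = prec_mat,
                 annotation = annotation, reference = reference,
                 truth = stats::setNames(is_true, names_),
                 genome = genome, config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic dataset:", sum(x$truth), "true +", sum(!x$truth),
      "false miRNAs,", ncol(x$mirna_matrix), "samples, genome",
      nchar(x$genome), "nt\n")
  invisible(x)
}

#' Write a synthetic dataset as the fixture files the package reads
#'
#' Emits every dialect the I/O layer consumes, so an end-to-end run needs
#' only this directory: `mirna_expression.tsv`, `precursor_expression.tsv`,
#' `aliases.txt`, `precursor_to_mature.tsv`, `mature.fa`, `genome.fa`,
#' `reference_rpm.tsv`, `truth.tsv` (eight files).
#'
#' @param dataset a `synthetic_dataset`.
#' @param directory output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(directory, f)
  write_expression_table(dataset$mirna_matrix, p("mirna_expression.tsv"),
                         id_column = "mirna")
  write_expression_table(dataset$precursor_matrix,
                         p("precursor_expression.tsv"),
                         id_column = "precursor")
  write_annotation(dataset$annotation, p("aliases.txt"),
                   p("precursor_to_mature.tsv"), fasta_path = p("mature.fa"))
  write_sequences_fasta(dataset$genome, p("genome.fa"))
  write_reference_profile(dataset$reference, p("reference_rpm.tsv"))
  utils::write.table(
    data.frame(name = names(dataset$truth),
               truly_expressed = unname(dataset$truth)),
    p("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}
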