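test_that("median expression follows the even/odd order-statistic convention", {
  m <- make_matrix(c(1, 2, 3), "x", c("s1", "s2", "s3"))
  expect_equal(unname(median_expression(m, "x")), 2)
  m2 <- make_matrix(c(1, 3), "x", c("s1", "s2"))
  expect_equal(unname(median_expression(m2, "x")), 2)
  m1 <- make_matrix(7, "x", "s1")
  expect_equal(unname(median_expression(m1, "x")), 7)
  expect_error(median_expression(m, "y"), "unknown feature")
})

test_that("precursor correlation is rank-based with a max-over-precursors rule", {
  expect_equal(precursor_correlation(1:5, c(10, 20, 30, 40, 50)), 1)
  expect_equal(precursor_correlation(1:5, c(50, 40, 30, 20, 10)), -1)
  two <- rbind(c(2, 1, 4, 3, 5),    # moderate rank agreement
               c(10, 20, 30, 40, 50)) # perfect
  expect_equal(precursor_correlation(1:5, two), 1)
  # monotone transforms of either profile leave the value unchanged
  expect_equal(precursor_correlation(exp(1:6), (1:6)^3), 1)
  expect_error(precursor_correlation(1:5, 1:4), "mismatch")
  expect_true(is.na(precursor_correlation(1:4, 4:1)))  # below min_samples
  expect_true(is.na(precursor_correlation(1:5, NULL)))
})

test_that("component scaling hits the documented boundaries", {
  at_max <- scale_components(8, 8, 100, 1000, 0)
  expect_equal(at_max$A, 1)
  expect_equal(at_max$C, 0.5)
  expect_equal(scale_components(1, 8, 1000, 1000, 0)$B, 0)
  expect_equal(scale_components(1, 8, 100, 1000, 1)$C, 1)
  expect_equal(scale_components(1, 8, 100, 1000, -1)$C, 0)
  expect_equal(scale_components(1, 8, 100, 1000, NA)$C, 0.5)
  # B clips at 0 when N exceeds the override
  expect_equal(scale_components(1, 8, 2000, 1000, 0)$B, 0)
  expect_error(scale_components(1, 0, 100, 1000, 0), "m_max")
  expect_error(scale_components(1, 8, 100, -5, 0), "n_max")
  expect_error(scale_components(9, 8, 100, 1000, 0), "clip")
  expect_equal(scale_components(9, 8, 100, 1000, 0, clip = TRUE)$A, 1)
})

test_that("the weighted combination reproduces hand-evaluated scores", {
  w <- score_weights(0.5, 0.3, 0.2)
  expect_equal(compute_score(1, 1, 1, w), 1)
  expect_equal(compute_score(0, 0, 0, w), 0)
  expect_equal(compute_score(1, 0, 0.5, w), 0.6)
  expect_error(compute_score(1.2, 0, 0, w), "\\[0, 1\\]")
  expect_error(score_weights(-0.1, 0.5, 0.6), "\\[0, 1\\]")
  # constructor renormalizes
  expect_equal(sum(score_weights(1, 1, 1)), 1)
  expect_equal(unclass(score_weights(0.5, 0.3, 0.2)),
               c(w_a = 0.5, w_b = 0.3, w_c = 0.2))
})

test_that("a single-miRNA table is its own maximum", {
  m <- make_matrix(c(3, 4, 5, 6, 7), "hsa-miR-21-5p", paste0("s", 1:5))
  ann <- make_annotation("hsa-miR-21-5p", 76L, "hsa-mir-21")
  tab <- score_all(m, NULL, ann)
  expect_equal(tab$A, 1)
  expect_equal(tab$C, 0.5)
})

test_that("equal expression with a later MIMAT number scores strictly lower", {
  m <- make_matrix(rep(c(4, 5, 6, 7, 8), 2), c("early", "late"),
                   paste0("s", 1:5))
  ann <- make_annotation(c("early", "late"), c(100L, 30000L),
                         c("pre-early", "pre-late"))
  tab <- score_all(m, NULL, ann)
  expect_identical(tab$name[1], "early")
  expect_gt(tab$score[1], tab$score[2])
})

test_that("unannotated miRNAs are reported, never silently dropped", {
  m <- make_matrix(c(1:5, 5:1), c("known", "mystery"), paste0("s", 1:5))
  ann <- make_annotation("known", 10L, "pre-known")
  expect_message(tab <- score_all(m, NULL, ann), "unannotated")
  expect_identical(attr(tab, "unannotated"), "mystery")
  expect_identical(tab$name, "known")
  m_none <- make_matrix(1:5, "mystery", paste0("s", 1:5))
  expect_error(suppressMessages(score_all(m_none, NULL, ann)), "overlap")
})

test_that("scores agree with a straight-line recomputation on random tables", {
  set.seed(202)
  for (trial in 1:25) {
    n_mir <- sample(2:10, 1)
    n_samp <- sample(5:10, 1)
    mirna <- matrix(runif(n_mir * n_samp, 0, 14), n_mir,
                    dimnames = list(paste0("m", 1:n_mir),
                                    paste0("s", 1:n_samp)))
    prec <- matrix(runif(n_mir * n_samp, 0, 14), n_mir,
                   dimnames = list(paste0("p", 1:n_mir),
                                   paste0("s", 1:n_samp)))
    ann <- make_annotation(paste0("m", 1:n_mir),
                           sample(35000L, n_mir), paste0("p", 1:n_mir))
    w <- score_weights(runif(1), runif(1), runif(1))
    tab <- score_all(mirna, prec, ann, weights = w)
    expected <- oracle_scores(mirna, prec, ann, w)
    expect_equal(setNames(tab$score, tab$name), expected[tab$name],
                 tolerance = 1e-12)
  }
})

test_that("the score is monotone in each raw input, all else fixed", {
  set.seed(303)
  w <- score_weights()
  for (trial in 1:50) {
    m_max <- runif(1, 5, 20)
    n_max <- sample(2000:35000, 1)
    m <- sort(runif(2, 0, m_max))
    N <- sort(sample(n_max, 2))
    cc <- sort(runif(2, -1, 1))
    base <- function(m_, N_, c_) {
      s <- scale_components(m_, m_max, N_, n_max, c_)
      compute_score(s$A, s$B, s$C, w)
    }
    expect_gte(base(m[2], N[1], cc[1]), base(m[1], N[1], cc[1]))
    expect_lte(base(m[1], N[2], cc[1]), base(m[1], N[1], cc[1]))
    expect_gte(base(m[1], N[1], cc[2]), base(m[1], N[1], cc[1]))
  }
})

test_that("consistent sample permutations leave every score unchanged", {
  set.seed(404)
  ds <- generate_synthetic_dataset(synthetic_config(n_true = 10L,
                                                    n_false = 20L,
                                                    n_samples = 12L,
                                                    seed = 5L))
  tab <- score_all(ds$mirna_matrix, ds$precursor_matrix, ds$annotation)
  perm <- sample(ncol(ds$mirna_matrix))
  tab_p <- score_all(ds$mirna_matrix[, perm],
                     ds$precursor_matrix[, perm], ds$annotation)
  expect_equal(setNames(tab_p$score, tab_p$name),
               setNames(tab$score, tab$name)[tab_p$name])
})

test_that("degenerate weights reduce to the expected single-factor rankings", {
  ds <- generate_synthetic_dataset(synthetic_config(n_true = 15L,
                                                    n_false = 25L,
                                                    n_samples = 10L,
                                                    seed = 9L))
  # (1,0,0): ranking by median expression
  tab_a <- score_all(ds$mirna_matrix, ds$precursor_matrix, ds$annotation,
                     weights = score_weights(1, 0, 0))
  med <- median_expression(ds$mirna_matrix)
  expect_identical(tab_a$name,
                   names(sort(med, decreasing = TRUE)))
  # (0,0,1) without precursor data: constant neutral score 0.5
  tab_c <- score_all(ds$mirna_matrix, NULL, ds$annotation,
                     weights = score_weights(0, 0, 1))
  expect_equal(tab_c$score, rep(0.5, nrow(tab_c)))
})

test_that("zero correlation weight makes scores independent of precursors", {
  ds <- generate_synthetic_dataset(synthetic_config(n_true = 15L,
                                                    n_false = 25L,
                                                    n_samples = 10L,
                                                    seed = 13L))
  w <- score_weights(0.6, 0.4, 0)
  with_prec <- score_all(ds$mirna_matrix, ds$precursor_matrix,
                         ds$annotation, weights = w)
  shuffled <- ds$precursor_matrix[sample(nrow(ds$precursor_matrix)), ]
  rownames(shuffled) <- rownames(ds$precursor_matrix)
  with_other <- score_all(ds$mirna_matrix, shuffled, ds$annotation,
                          weights = w)
  without <- score_all(ds$mirna_matrix, NULL, ds$annotation, weights = w)
  expect_equal(with_prec$score, with_other$score)
  expect_equal(setNames(with_prec$score, with_prec$name),
               setNames(without$score, without$name)[with_prec$name])
})

test_that("the drop-weight fallback renormalizes for absent correlations", {
  m <- make_matrix(c(1:5, 5:1), c("a", "b"), paste0("s", 1:5))
  ann <- make_annotation(c("a", "b"), c(10L, 20L), c("pre-a", "pre-b"))
  # no precursor matrix: every correlation absent
  tab <- score_all(m, NULL, ann, absent_corr = "drop_weight")
  byname <- setNames(tab$score, tab$name)
  comps <- setNames(split(tab[, c("A", "B")], seq_len(nrow(tab))), tab$name)
  for (nm in tab$name) {
    expect_equal(byname[[nm]],
                 (0.5 * comps[[nm]]$A + 0.3 * comps[[nm]]$B) / 0.8)
  }
})
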