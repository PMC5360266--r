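test_that("p-distance counts mismatches over residue/residue positions", {
  expect_identical(p_distance("MKV", "MKV"), 0)
  expect_identical(p_distance("MKVL", "MK-L"), 0)     # 3 comparable, 0 diffs
  expect_identical(p_distance("MKVL", "AKVI"), 0.5)
  expect_error(p_distance("MKV", "MKVL"), "unequal")
  expect_warning(d <- p_distance("MK--", "--VL"), "no position")
  expect_identical(d, 0)
  # X never matches, including against X
  expect_identical(p_distance("MX", "MX"), 0.5)
})

test_that("modified p-distance treats gap as a 21st state", {
  expect_identical(modified_p_distance("MKVL", "MK-L"), 0.25)
  # exon-skipping pair: distance stays moderate instead of saturating
  expect_identical(modified_p_distance("MKVLDEAD", "MKVL----"), 0.5)
  expect_identical(modified_p_distance("M-KV", "M-KV"), 0)
  expect_error(modified_p_distance("---", "---"), "entirely gaps")
  # standard p-distance on the same exon-skip pair is blind to the event
  expect_identical(p_distance("MKVLDEAD", "MKVL----"), 0)
})

test_that("closed-form corrections evaluate exactly", {
  expect_identical(as.numeric(correct_distance(0, "poisson")), 0)
  expect_identical(as.numeric(correct_distance(0, "pam_kimura")), 0)
  expect_identical(as.numeric(correct_distance(0, "jtt_approx")), 0)
  expect_equal(as.numeric(correct_distance(0.5, "poisson")), -log(0.5),
               tolerance = 1e-12)
  expect_equal(round(as.numeric(correct_distance(0.5, "poisson")), 6), 0.693147)
  expect_equal(as.numeric(correct_distance(0.5, "pam_kimura")),
               -log(1 - 0.5 - 0.2 * 0.25), tolerance = 1e-12)
  a <- 2.4
  expect_equal(as.numeric(correct_distance(0.3, "jtt_approx")),
               a * ((1 - 0.3)^(-1 / a) - 1), tolerance = 1e-12)
})

test_that("saturation caps at the ceiling and is flagged", {
  d <- correct_distance(1, "poisson")
  expect_identical(as.numeric(d), 10)
  expect_true(attr(d, "saturated"))
  # kimura saturates where 1 - p - 0.2 p^2 <= 0 (p ~ 0.8541)
  d2 <- correct_distance(0.9, "pam_kimura")
  expect_true(attr(d2, "saturated"))
  d3 <- correct_distance(0.8, model_spec("pam_kimura", ceiling = 5))
  expect_false(attr(d3, "saturated"))
  # a finite correction beyond the ceiling is capped and flagged too
  d4 <- correct_distance(0.85, model_spec("pam_kimura", ceiling = 5))
  expect_identical(as.numeric(d4), 5)
  expect_true(attr(d4, "saturated"))
})

test_that("corrections are monotone in p and Gamma-Poisson converges to Poisson", {
  p <- seq(0, 0.8, by = 0.01)
  for (m in list("poisson", "pam_kimura", "jtt_approx",
                 model_spec("poisson", gamma_alpha = 0.7))) {
    d <- as.numeric(correct_distance(p, m))
    expect_true(all(diff(d) > 0))
  }
  big <- model_spec("poisson", gamma_alpha = 1e6)
  expect_lt(max(abs(as.numeric(correct_distance(p, big)) -
                    as.numeric(correct_distance(p, "poisson")))), 1e-4)
})

test_that("ML matrix distances recover simulated truth", {
  eg <- isopick:::rate_eigen("LG")
  Pt <- isopick:::.transition_prob(eg, 0.5)
  aa <- isopick:::AA20
  set.seed(17)
  est <- replicate(5, {
    x <- sample(aa, 10000, replace = TRUE, prob = eg$bf)
    y <- vapply(x, function(q) sample(aa, 1, prob = Pt[match(q, aa), ]), "")
    as.numeric(ml_matrix_distance(paste(x, collapse = ""),
                                  paste(y, collapse = ""), "lg_ml"))
  })
  expect_lt(mean(abs(est - 0.5)), 0.05)
})

test_that("ML distance degenerate cases behave", {
  d <- ml_matrix_distance(strrep("ARNDCW", 20), strrep("ARNDCW", 20), "lg_ml")
  expect_lt(as.numeric(d), 1e-4)
  expect_false(attr(d, "saturated"))
  # unrelated random sequences: likelihood plateaus, distance capped
  set.seed(41)
  aa <- isopick:::AA20
  d2 <- ml_matrix_distance(paste(sample(aa, 400, TRUE), collapse = ""),
                           paste(sample(aa, 400, TRUE), collapse = ""),
                           "lg_ml")
  expect_identical(as.numeric(d2), 10)
  expect_true(attr(d2, "saturated"))
  expect_error(ml_matrix_distance("---X", "X---", "lg_ml"), "comparable")
})

test_that("ML distances agree with an independent estimator", {
  # phangorn::dist.ml maximizes the same pairwise likelihood; compare on
  # sequences at a realistic divergence, well inside the estimable range
  set.seed(3)
  aa <- isopick:::AA20
  for (model in c("lg_ml", "wag_ml", "jtt_ml")) {
    eg <- isopick:::rate_eigen(isopick:::ML_MODELS[[model]])
    P <- isopick:::.transition_prob(eg, 0.4)
    anc <- sample(aa, 250, replace = TRUE, prob = eg$bf)
    x <- t(vapply(1:4, function(i) {
      vapply(anc, function(q) sample(aa, 1, prob = P[match(q, aa), ]), "")
    }, character(250)))
    rownames(x) <- paste0("s", 1:4)
    aln <- protein_alignment(rownames(x), apply(x, 1, paste, collapse = ""))
    mine <- distance_matrix(aln, model)
    ref <- as.matrix(phangorn::dist.ml(
      phangorn::as.phyDat(x, type = "AA"),
      model = isopick:::ML_MODELS[[model]]))
    expect_lt(max(abs(mine - ref[rownames(mine), colnames(mine)])), 1e-3)
  }
})

test_that("distance_matrix is symmetric, zero-diagonal, and matches hand counts", {
  a <- protein_alignment(c("x", "y", "z"), c("MKVL", "MK-L", "AKVI"))
  D <- distance_matrix(a, "pdist")
  expect_identical(unname(diag(D)), c(0, 0, 0))
  expect_identical(D, t(D))
  expect_identical(D["x", "y"], 0)
  expect_identical(D["x", "z"], 0.5)
  expect_identical(D["y", "z"], 2 / 3)   # M-A and L-I differ, K-K matches

  b <- protein_alignment(c("x", "y", "z"), rep("MKVL", 3))
  expect_true(all(distance_matrix(b, "jtt_approx") == 0))

  set.seed(9)
  for (rep in 1:5) {
    aln <- random_gapping(random_seqs(4, max_len = 20L, min_len = 10L))
    for (m in c("pdist", "modified_pdist", "poisson")) {
      D <- distance_matrix(aln, m)
      expect_identical(unname(D), unname(t(D)))
    }
  }
})

test_that("PHYLIP export writes a square matrix readable by ape", {
  a <- protein_alignment(c("x", "y", "z"), c("MKVL", "MK-L", "AKVI"))
  D <- distance_matrix(a, "pdist")
  f <- withr::local_tempfile(fileext = ".dist")
  write_phylip_dist(D, f)
  lines <- readLines(f)
  expect_identical(trimws(lines[1]), "3")
  expect_length(lines, 4L)
})
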