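# two tiny alignments of the same residues used for hand-verified cases:
# ref:   a MKVL    pert:  a MKVL-
#        b MK-L           b -MKL-  (b's residues shifted one column right)
#        c MKVL           c MKVL-
hand_ref <- function() protein_alignment(c("a", "b", "c"),
                                         c("MKVL", "MK-L", "MKVL"))

test_that("pair agreement is 1 on identical maps and 0 after a shift", {
  ref <- hand_ref()
  rm_ <- residue_column_map(ref)
  for (i in 1:3) {
    li <- length(rm_$cols[[i]])
    for (k in seq_len(li)) {
      for (j in setdiff(1:3, i)) {
        if (!is.na(rm_$ord[j, rm_$cols[[i]][k]]))
          expect_identical(pair_agreement(rm_, rm_, i, k, j), 1L)
      }
    }
  }
  # shift b one column right: its residues face different partners of a
  pert <- protein_alignment(c("a", "b", "c"), c("MKVL-", "-MK-L", "MKVL-"))
  pm <- residue_column_map(pert)
  # residue 1 of a faces residue 1 of b in ref (column 1); perturbed: b gapped
  expect_identical(pair_agreement(rm_, pm, "a", 1, "b"), 0L)
  # residue 2 of a faces residue 2 of b in ref; perturbed col 2 has b's residue 1
  expect_identical(pair_agreement(rm_, pm, "a", 2, "b"), 0L)
  # a vs c is unshifted
  expect_identical(pair_agreement(rm_, pm, "a", 2, "c"), 1L)
  # preconditions
  expect_error(pair_agreement(rm_, pm, "a", 99, "b"), "out of range")
  expect_error(pair_agreement(rm_, pm, "a", 1, "a"), "differ")
  expect_error(pair_agreement(rm_, pm, "b", 3, "x"), "unknown")
})

test_that("residue scores honour the m_k = 1 special cases", {
  # column 5 holds only d's residue: m = 4, m_k = 1, m_g = 3
  ref <- protein_alignment(c("a", "b", "c", "d"),
                           c("MKVL-", "MKVL-", "MKVL-", "MKVLW"))
  rm_ <- residue_column_map(ref)
  expect_identical(residue_score(rm_, rm_, "d", 5, gap_variant = FALSE), 1)
  expect_identical(residue_score(rm_, rm_, "d", 5, gap_variant = TRUE), -1 / 3)
  # fully populated column, identical maps
  expect_identical(residue_score(rm_, rm_, "a", 1), 1)
  # gap variant divides by m_g = 1 on gapless columns
  expect_identical(residue_score(rm_, rm_, "a", 1, gap_variant = TRUE), 1)
})

test_that("identity reduction: perturbed == reference", {
  set.seed(4)
  for (rep in 1:5) {
    aln <- random_gapping(random_seqs(4, max_len = 15L))
    st <- sp_scores(aln, list(aln, aln), "default")
    expect_true(all(st$scores == 1))
    st_short <- sp_scores(aln, list(aln), "short")
    li <- nchar(gsub("-", "", aln$rows))
    expect_equal(unname(st_short$scores), li / aln$length, tolerance = 1e-15)
  }
})

test_that("scores equal the brute-force oracle on random instances", {
  set.seed(12)
  for (rep in 1:40) {
    inst <- random_sp_instance()
    for (v in c("default", "gap", "short")) {
      mine <- sp_scores(inst$ref, inst$perturbed, v)$scores
      oracle <- sp_score_oracle(inst$ref, inst$perturbed, v)
      expect_lt(max(abs(mine - oracle)), 1e-12)
    }
  }
})

test_that("default scores stay in [0,1]; gap variant never exceeds default", {
  set.seed(6)
  for (rep in 1:20) {
    inst <- random_sp_instance()
    s_def <- sp_scores(inst$ref, inst$perturbed, "default")$scores
    s_gap <- sp_scores(inst$ref, inst$perturbed, "gap")$scores
    expect_true(all(s_def >= 0 & s_def <= 1))
    has_gap <- any(aln_matrix(inst$ref) == "-")
    if (has_gap) expect_true(all(s_gap <= s_def + 1e-12))
    else expect_equal(unname(s_gap), unname(s_def), tolerance = 1e-12)
  }
})

test_that("scores follow ids under sequence permutation", {
  set.seed(8)
  inst <- random_sp_instance(max_m = 5)
  perm <- sample(seq_along(inst$ref$ids))
  permute <- function(a) protein_alignment(a$ids[perm], a$rows[perm])
  s1 <- sp_scores(inst$ref, inst$perturbed, "default")$scores
  s2 <- sp_scores(permute(inst$ref), lapply(inst$perturbed, permute),
                  "default")$scores
  expect_equal(s2[names(s1)], s1, tolerance = 1e-15)
})

test_that("replicates must carry the same sequences as the reference", {
  ref <- hand_ref()
  other <- protein_alignment(c("a", "b", "z"), c("MKVL", "MK-L", "MKVL"))
  expect_error(sp_scores(ref, list(other)), "ids differ")
  mutated <- protein_alignment(c("a", "b", "c"), c("MKIL", "MK-L", "MKVL"))
  expect_error(sp_scores(ref, list(mutated)), "residues differ")
})

test_that("distance scores match hand arithmetic on a 5-sequence toy", {
  # loci: {x1,x2} gene gx, {y1,y2} gene gy, z singleton => omega = {z}
  aln <- protein_alignment(c("x1", "x2", "y1", "y2", "z"),
                           c("MKVLDEAD",
                             "MKVL----",
                             "MKILDEAD",
                             "MKILDE--",
                             "MKVLDEAH"))
  lm <- c(x1 = "gx", x2 = "gx", y1 = "gy", y2 = "gy")
  D <- distance_matrix(aln, "modified_pdist")
  st <- distance_scores(aln, lm, wot = FALSE)
  expect_identical(st$variant, "ds")
  # omega has one member: each score is just the distance to z
  expect_equal(unname(st$scores[c("x1", "x2", "y1", "y2")]),
               unname(D[c("x1", "x2", "y1", "y2"), "z"]), tolerance = 1e-15)
  expect_identical(unname(st$scores["z"]), 0)

  st_wot <- distance_scores(aln, lm, wot = TRUE)
  expect_identical(st_wot$variant, "ds_wot")
  hand <- vapply(rownames(D), function(i) mean(D[i, setdiff(rownames(D), i)]), 0)
  expect_equal(st_wot$scores, hand, tolerance = 1e-15)

  # identical sequence to the whole backbone scores 0
  aln2 <- protein_alignment(c("p", "q", "r"), c("MKVL", "MKVL", "MKVL"))
  st2 <- distance_scores(aln2, NULL, wot = TRUE)
  expect_true(all(st2$scores == 0))
})

test_that("empty single-isoform backbone demands the WOT mode", {
  aln <- protein_alignment(c("x1", "x2"), c("MKVL", "MK-L"))
  expect_error(distance_scores(aln, c(x1 = "g", x2 = "g"), wot = FALSE),
               "wot|WOT")
})

test_that("WOT equals the backbone mode when every gene is a singleton", {
  set.seed(10)
  aln <- random_gapping(random_seqs(5, max_len = 15L))
  s1 <- distance_scores(aln, NULL, wot = FALSE)$scores
  s2 <- distance_scores(aln, NULL, wot = TRUE)$scores
  expect_equal(s1, s2, tolerance = 1e-15)
})

test_that("per-locus selection keeps the best score and resolves ties", {
  st <- structure(list(scores = c(a1 = 0.91, a2 = 0.88, b1 = 0.5),
                       variant = "default", n = 1L), class = "score_table")
  lm <- c(a1 = "ga", a2 = "ga")
  sel <- select_per_locus(st, lm)
  expect_identical(sel[["ga"]], "a1")
  expect_identical(sel[["b1"]], "b1")   # singleton always kept

  st$variant <- "ds"
  st$scores <- c(a1 = 0.12, a2 = 0.30, b1 = 0.5)
  expect_identical(select_per_locus(st, lm)[["ga"]], "a1")

  st$variant <- "default"
  st$scores <- c(a2 = 0.9, a1 = 0.9, b1 = 0.5)
  expect_warning(sel <- select_per_locus(st, lm), "tie")
  expect_identical(sel[["ga"]], "a1")
})

test_that("per-residue dump has one row per residue", {
  ref <- hand_ref()
  st <- sp_scores(ref, list(ref), keep_residue_scores = TRUE)
  tab <- residue_scores_table(st)
  expect_identical(nrow(tab), sum(nchar(gsub("-", "", ref$rows))))
  expect_true(all(tab$R_ik == 1))
})
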