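# Random instances used across tests: a set of ungapped sequences plus
# independently re-gapped alignments of them (any gap placement is a valid
# alignment of the same residues, which is all the scoring contract needs).

AA13 <- strsplit("ARNDCQEGHIKLM", "")[[1]]

random_seqs <- function(m, max_len = 12L, min_len = 3L) {
  vapply(seq_len(m), function(i) {
    paste(sample(AA13, sample(min_len:max_len, 1L), replace = TRUE),
          collapse = "")
  }, "")
}

# spread the residues of each sequence over `target` columns at random
random_gapping <- function(seqs, ids = paste0("s", seq_along(seqs)),
                           extra_cols = 4L) {
  target <- max(nchar(seqs)) + sample(0:extra_cols, 1L)
  M <- t(vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    out <- rep("-", target)
    out[sort(sample(target, length(ch)))] <- ch
    out
  }, character(target)))
  keep <- colSums(M != "-") > 0L
  protein_alignment(ids, apply(M[, keep, drop = FALSE], 1L, paste, collapse = ""))
}

random_sp_instance <- function(max_m = 6L, max_len = 12L, max_n = 3L) {
  m <- sample(3:max_m, 1L)
  seqs <- random_seqs(m, max_len)
  list(ref = random_gapping(seqs),
       perturbed = lapply(seq_len(sample(seq_len(max_n), 1L)),
                          function(b) random_gapping(seqs)))
}

# additive distance matrix from a random tree, with sorted taxa
random_additive <- function(ntip = 8L, lo = 0.05, hi = 0.3) {
  tr <- ape::rtree(ntip, br = function(n) stats::runif(n, lo, hi))
  D <- stats::cophenetic(tr)
  list(tree = tr, D = D[order(rownames(D)), order(colnames(D))])
}
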