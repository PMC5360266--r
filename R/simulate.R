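## Synthetic gene families with known canonical isoforms, and independent
## brute-force oracles. Everything here is deliberately simple and separate
## from the production code paths: the simulator evolves a canonical protein
## along a random species tree under a uniform (Poisson) substitution process,
## then derives alternative isoforms by splicing-like events; the oracles are
## literal transcriptions of the scoring equations and of textbook
## neighbor-joining.

#' Simulate a gene family with alternative isoforms
#'
#' One gene per species. A random ancestral protein evolves along a random
#' species tree (uniform substitutions, expected `t` substitutions/site per
#' branch of length `t`). A fraction `isoform_rate` of genes then gains 1-2
#' alternative isoforms, each derived from the canonical protein by one
#' event: exon skipping (contiguous 10-40% deleted), intron retention
#' (10-40% of random residues inserted) or truncation (20-60% removed from
#' one end). The canonical isoform of each gene is recorded as the truth.
#'
#' @param n_species number of species (>= 4).
#' @param seq_length ancestral protein length (>= 60).
#' @param isoform_rate fraction of genes with alternative isoforms in
#'   `[0, 1]`.
#' @param event_mix named probabilities for `exon_skip`, `intron_retention`,
#'   `truncation`; the default mix leans on exon skipping, the most common
#'   splicing alteration.
#' @param seed integer; fully determines the family.
#' @return A `synthetic_family`: `seqs` (a `seq_set` with locus labels on
#'   alternative-isoform genes), `tree` (the species tree), `truth` (named
#'   character, gene -> canonical sequence id) and `events` (data.frame).
#' @export
simulate_family <- function(n_species = 8L, seq_length = 100L,
                            isoform_rate = 0.3,
                            event_mix = c(exon_skip = 0.5,
                                          intron_retention = 0.3,
                                          truncation = 0.2),
                            seed = 1L) {
  if (n_species < 4L) stop("n_species must be >= 4")
  if (seq_length < 60L) stop("seq_length must be >= 60")
  if (isoform_rate < 0 || isoform_rate > 1) stop("isoform_rate must be in [0, 1]")
  stopifnot(setequal(names(event_mix),
                     c("exon_skip", "intron_retention", "truncation")),
            all(event_mix >= 0), sum(event_mix) > 0)
  event_mix <- event_mix / sum(event_mix)

  with_seed(seed, {
    tree <- ape::rtree(n_species, tip.label = sprintf("sp%02d", seq_len(n_species)),
                       br = function(n) stats::runif(n, 0.03, 0.25))
    root_seq <- sample(AA20, seq_length, replace = TRUE)
    tips <- .evolve_poisson(tree, root_seq)

    ids <- character(0); seqs <- character(0); locus <- character(0)
    truth <- character(0)
    events <- data.frame(id = character(0), gene = character(0),
                         event = character(0))
    iso_genes <- stats::runif(n_species) < isoform_rate
    for (s in seq_len(n_species)) {
      sp <- sprintf("sp%02d", s)
      gene <- paste0("g_", sp)
      canonical <- paste0(sp, "_t1")
      ids <- c(ids, canonical)
      seqs <- c(seqs, paste(tips[[sp]], collapse = ""))
      locus <- c(locus, gene)
      truth[gene] <- canonical
      if (iso_genes[s]) {
        for (t in seq_len(sample(1:2, 1L))) {
          ev <- sample(names(event_mix), 1L, prob = event_mix)
          alt <- .apply_event(tips[[sp]], ev)
          id <- paste0(sp, "_t", t + 1L)
          ids <- c(ids, id)
          seqs <- c(seqs, paste(alt, collapse = ""))
          locus <- c(locus, gene)
          events <- rbind(events,
                          data.frame(id = id, gene = gene, event = ev))
        }
      }
    }
    structure(list(seqs = seq_set(ids, seqs, locus), tree = tree,
                   truth = truth, events = events, seed = seed),
              class = "synthetic_family")
  })
}

#' @export
print.synthetic_family <- function(x, ...) {
  cat("synthetic_family:", length(x$truth), "genes,",
      length(x$seqs$ids), "sequences,", nrow(x$events),
      "alternative isoforms (seed", x$seed, ")\n")
  invisible(x)
}

## evolve a residue vector along the tree: per branch of length t, the number
## of substitution events is Poisson(t * L), each hitting a uniform site and
## replacing its residue by a uniform different one
.evolve_poisson <- function(tree, root_seq) {
  ntip <- length(tree$tip.label)
  seq_at <- vector("list", ntip + tree$Nnode)
  seq_at[[ntip + 1L]] <- root_seq
  ## parents precede children in ape's edge matrix for rtree output? not
  ## guaranteed -> process edges in preorder explicitly
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; chi <- ord$edge[e, 2L]
    s <- seq_at[[par]]
    nev <- stats::rpois(1L, ord$edge.length[e] * length(s))
    if (nev > 0L) {
      for (pos in sample.int(length(s), nev, replace = TRUE)) {
        s[pos] <- sample(setdiff(AA20, s[pos]), 1L)
      }
    }
    seq_at[[chi]] <- s
  }
  stats::setNames(seq_at[seq_len(ntip)], tree$tip.label)
}

.apply_event <- function(res, event) {
  L <- length(res)
  switch(event,
    exon_skip = {
      len <- max(1L, round(stats::runif(1, 0.10, 0.40) * L))
      start <- sample.int(L - len + 1L, 1L)
      res[-(start:(start + len - 1L))]
    },
    intron_retention = {
      len <- max(1L, round(stats::runif(1, 0.10, 0.40) * L))
      at <- sample.int(L + 1L, 1L) - 1L
      append(res, sample(AA20, len, replace = TRUE), after = at)
    },
    truncation = {
      len <- max(1L, round(stats::runif(1, 0.20, 0.60) * L))
      if (stats::runif(1) < 0.5) res[-(1:len)] else res[seq_len(L - len)]
    },
    stop("unknown event: ", event))
}

#' Write a synthetic family as FASTA plus locus-tag file
#'
#' Produces exactly the input files the command-line interface consumes: an
#' unaligned FASTA and a two-column locus-tag table listing the
#' alternative-isoform sequences only.
#'
#' @param fam a `synthetic_family`.
#' @param prefix output path prefix.
#' @return Character vector `c(fasta, locus_tags)`, invisibly.
#' @export
write_family <- function(fam, prefix) {
  stopifnot(inherits(fam, "synthetic_family"))
  fa <- paste0(prefix, ".fasta")
  lt <- paste0(prefix, "_locus_tag.txt")
  write_fasta(fam$seqs, fa)
  multi <- names(which(table(fam$seqs$locus) > 1L))
  keep <- fam$seqs$locus %in% multi
  writeLines(sprintf(">%s %s", fam$seqs$ids[keep], fam$seqs$locus[keep]), lt)
  invisible(c(fa, lt))
}

#' Brute-force Sum-of-Pairs score oracle
#'
#' Literal triple-loop transcription of the residue pair score, its replicate
#' average and the sequence score, sharing no code with [sp_scores()]. Meant
#' for small instances only (O(m^2 l n)).
#'
#' @param ref reference `protein_alignment`.
#' @param perturbed list of perturbed `protein_alignment`s.
#' @param variant `"default"`, `"gap"` or `"short"`.
#' @return Named numeric vector of sequence scores.
#' @export
sp_score_oracle <- function(ref, perturbed,
                            variant = c("default", "gap", "short")) {
  variant <- match.arg(variant)
  Mref <- aln_matrix_chr(ref$rows)
  m <- nrow(Mref)
  ## ordinal lookup built independently: position of k-th residue of row i
  col_of <- function(M, i, k) which(M[i, ] != "-")[k]
  ord_at <- function(M, j, col) {
    if (M[j, col] == "-") return(NA_integer_)
    sum(M[j, seq_len(col)] != "-")
  }
  l_i <- vapply(seq_len(m), function(i) sum(Mref[i, ] != "-"), 0L)
  n <- length(perturbed)
  S <- numeric(m)
  for (i in seq_len(m)) {
    Rik <- numeric(l_i[i])
    for (k in seq_len(l_i[i])) {
      cref <- col_of(Mref, i, k)
      mk <- sum(Mref[, cref] != "-")
      mg <- max(1L, m - mk)
      acc <- 0
      for (b in seq_len(n)) {
        Mp <- aln_matrix_chr(perturbed[[b]]$rows)
        if (mk == 1L) {
          rikb <- if (variant == "gap") -1 / mg else 1
        } else {
          cp <- col_of(Mp, i, k)
          tot <- 0
          for (j in seq_len(m)) {
            if (j == i) next
            oref <- ord_at(Mref, j, cref)
            if (is.na(oref)) next
            op <- ord_at(Mp, j, cp)
            p <- as.numeric(!is.na(op) && op == oref)
            tot <- tot + if (variant == "gap") p / mg else p
          }
          rikb <- tot / (mk - 1L)
        }
        acc <- acc + rikb
      }
      Rik[k] <- acc / n
    }
    S[i] <- if (variant == "short") sum(Rik) / ncol(Mref) else mean(Rik)
  }
  stats::setNames(S, ref$ids)
}

#' Textbook neighbor-joining oracle
#'
#' Classical NJ (Saitou & Nei), coded independently of [bionj_tree()] for
#' property tests: same selection criterion and branch lengths, unweighted
#' matrix reduction.
#'
#' @param D symmetric distance matrix with dimnames.
#' @return Unrooted `phylo`.
#' @export
nj_oracle <- function(D) {
  stopifnot(is.matrix(D), nrow(D) >= 3L, !is.null(rownames(D)))
  lab <- rownames(D)
  frag <- vapply(lab, .nwk_label, "")
  d <- unname(D)
  while (length(frag) > 3L) {
    r <- length(frag)
    Tt <- rowSums(d)
    bq <- Inf; bi <- 1L; bj <- 2L
    for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
      q <- (r - 2) * d[i, j] - Tt[i] - Tt[j]
      if (q < bq - 1e-15) { bq <- q; bi <- i; bj <- j }
    }
    vi <- 0.5 * d[bi, bj] + (Tt[bi] - Tt[bj]) / (2 * (r - 2))
    vj <- d[bi, bj] - vi
    ks <- setdiff(seq_len(r), c(bi, bj))
    du <- (d[bi, ks] + d[bj, ks] - d[bi, bj]) / 2
    frag[bi] <- sprintf("(%s:%.15g,%s:%.15g)", frag[bi], vi, frag[bj], vj)
    d[bi, ks] <- d[ks, bi] <- du
    d <- d[-bj, -bj, drop = FALSE]
    frag <- frag[-bj]
  }
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], (d[1, 2] + d[1, 3] - d[2, 3]) / 2,
                 frag[2], (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
                 frag[3], (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  ape::read.tree(text = nwk)
}
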