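## Aligner adapters.
##
## The pipeline needs two alignment calls: an initial reference alignment and
## guide-tree-constrained realignments. External programs (mafft, clustalo,
## muscle) are driven through temporary files; a deterministic built-in
## progressive aligner ("mock") makes the whole pipeline runnable with no
## external binary. The built-in aligner is a test-grade progressive method
## (pairwise-distance guide tree, profile-profile merges with BLOSUM62 and
## affine gaps, open 10 / extend 1), not a competitive MSA program.

#' Specify a multiple-sequence aligner
#'
#' @param name `"mock"` (built-in progressive aligner), `"mafft"`,
#'   `"clustalo"` or `"muscle"`.
#' @param exec optional path to the executable (defaults to `name` on PATH).
#' @param opts character vector of extra options passed through verbatim.
#' @param keep_intermediates keep the run-scoped temporary directory.
#' @return An `aligner_spec`.
#' @export
aligner_spec <- function(name = c("mock", "mafft", "clustalo", "muscle"),
                         exec = NULL, opts = character(),
                         keep_intermediates = FALSE) {
  name <- match.arg(name)
  structure(list(name = name,
                 exec = if (is.null(exec)) name else exec,
                 opts = as.character(opts),
                 keep_intermediates = isTRUE(keep_intermediates)),
            class = "aligner_spec")
}

#' Check that an aligner can be invoked
#'
#' External programs are probed on PATH before a run starts; the built-in
#' aligner always passes.
#'
#' @param spec an `aligner_spec`.
#' @return `TRUE`, invisibly; error if the executable cannot be found.
#' @export
probe_aligner <- function(spec) {
  stopifnot(inherits(spec, "aligner_spec"))
  if (spec$name != "mock" && !nzchar(Sys.which(spec$exec)))
    stop("aligner executable not found on PATH: ", spec$exec)
  invisible(TRUE)
}

#' Align a set of protein sequences
#'
#' @param seqs a `seq_set` with at least 2 sequences.
#' @param spec an `aligner_spec`.
#' @return A `protein_alignment` whose rows degap to the input residues, in
#'   input order.
#' @export
align <- function(seqs, spec = aligner_spec("mock")) {
  stopifnot(inherits(seqs, "seq_set"))
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  probe_aligner(spec)
  aln <- if (spec$name == "mock") mock_align(seqs, tree = NULL)
         else .external_align(seqs, tree = NULL, spec)
  .check_aligned(seqs, aln)
}

#' Realign sequences under a guide tree
#'
#' The guide tree dictates the order of progressive merges (built-in aligner)
#' or is exported in the external tool's guide-tree dialect (newick for
#' clustalo/muscle, the merge-list format for mafft). Non-positive branch
#' lengths are clamped to 1e-8 on export.
#'
#' @param seqs a `seq_set`.
#' @param tree a `phylo` whose leaf set equals the sequence ids.
#' @param spec an `aligner_spec`.
#' @return A `protein_alignment` in input order.
#' @export
align_with_guide_tree <- function(seqs, tree, spec = aligner_spec("mock")) {
  stopifnot(inherits(seqs, "seq_set"), inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, seqs$ids) ||
      length(tree$tip.label) != length(seqs$ids))
    stop("guide-tree leaf set does not match the sequence ids")
  probe_aligner(spec)
  aln <- if (spec$name == "mock") mock_align(seqs, tree = tree)
         else .external_align(seqs, tree = tree, spec)
  .check_aligned(seqs, aln)
}

.check_aligned <- function(seqs, aln) {
  if (!identical(aln$ids, seqs$ids))
    stop("aligner returned different ids than the input")
  if (!identical(gsub("-", "", aln$rows, fixed = TRUE), seqs$seqs))
    stop("aligner altered residues: degapped output differs from input")
  aln
}

## ---- built-in progressive aligner --------------------------------------

.blosum_cache <- new.env(parent = emptyenv())
.blosum62 <- function() {
  if (is.null(.blosum_cache$S)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_cache$S <- e$BLOSUM62[AA20, AA20]
  }
  .blosum_cache$S
}

## 20 x L count profile of a set of aligned rows (gaps and X contribute 0)
.profile_counts <- function(rows) {
  M <- aln_matrix_chr(rows)
  P <- matrix(0, 20L, ncol(M))
  for (a in seq_along(AA20)) P[a, ] <- colSums(M == AA20[a])
  P
}

## merge two aligned groups with the affine DP; returns rows of A then B
.merge_profiles <- function(rowsA, rowsB) {
  PA <- .profile_counts(rowsA)
  PB <- .profile_counts(rowsB)
  S <- .blosum62()
  C <- crossprod(PA, S %*% PB) / (length(rowsA) * length(rowsB))
  res <- affine_align_path(C, gap_open = 10, gap_ext = 1)
  path <- res$path
  ## index vectors: position in merged alignment -> source column or gap
  idxA <- ifelse(path != 2L, cumsum(path != 2L), NA_integer_)
  idxB <- ifelse(path != 1L, cumsum(path != 1L), NA_integer_)
  expand <- function(row, idx) {
    ch <- strsplit(row, "")[[1]]
    out <- rep("-", length(idx))
    out[!is.na(idx)] <- ch[idx[!is.na(idx)]]
    paste(out, collapse = "")
  }
  c(vapply(rowsA, expand, "", idx = idxA, USE.NAMES = FALSE),
    vapply(rowsB, expand, "", idx = idxB, USE.NAMES = FALSE))
}

## pairwise distance for the default guide tree: modified p-distance on the
## pairwise affine alignment of the two ungapped sequences
.pairwise_guide_dist <- function(seqs) {
  m <- length(seqs$ids)
  D <- matrix(0, m, m, dimnames = list(seqs$ids, seqs$ids))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      mr <- .merge_profiles(seqs$seqs[i], seqs$seqs[j])
      D[i, j] <- D[j, i] <- modified_p_distance(mr[1], mr[2])
    }
  }
  D
}

## merge schedule from a phylo: list of (a, b) tip-index groups, produced by
## a post-order walk. The schedule is canonicalized so it is a pure function
## of the unrooted topology: the tree is rerooted on the first input
## sequence and children are folded in order of their smallest member, so
## BioNJ root rotations or agglomeration order cannot change the alignment.
.merge_schedule <- function(tree, ids) {
  if (length(tree$tip.label) > 2L) {
    tree <- tryCatch(
      ape::root(ape::unroot(tree), outgroup = ids[1L], resolve.root = TRUE),
      error = function(e) tree)
  }
  tip_of <- match(tree$tip.label, ids)
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  schedule <- list()
  group_of <- function(node) {
    if (node <= ntip) return(tip_of[node])
    groups <- lapply(kids[[as.character(node)]], group_of)
    groups <- groups[order(vapply(groups, min, 0L))]
    acc <- groups[[1L]]
    for (g in groups[-1L]) {
      schedule[[length(schedule) + 1L]] <<- list(a = acc, b = g)
      acc <- c(acc, g)
    }
    acc
  }
  group_of(ntip + 1L)
  schedule
}

## The built-in aligner: progressive profile merging in the post-order of the
## guide tree. Without a tree it runs two iterations, like standard
## progressive programs: a first pass guided by BioNJ on pairwise modified
## p-distances, then a realignment guided by BioNJ on the modified
## p-distances of the first-pass alignment (two sequences or degenerate
## matrices fall back to input-order merging). Pure function of
## (sequences, tree): bit-identical across runs.
mock_align <- function(seqs, tree = NULL) {
  m <- length(seqs$ids)
  if (m == 2L) {
    rows <- .merge_profiles(seqs$seqs[1], seqs$seqs[2])
    return(protein_alignment(seqs$ids, rows))
  }
  if (is.null(tree)) {
    D <- .pairwise_guide_dist(seqs)
    tree <- if (max(D) == 0) NULL else bionj_tree(D)
    if (!is.null(tree)) {
      aln1 <- .progressive_align(seqs, tree)
      D2 <- distance_matrix(aln1, "jtt_approx")
      if (max(D2) > 0) tree <- bionj_tree(D2)
    }
  }
  .progressive_align(seqs, tree)
}

.progressive_align <- function(seqs, tree) {
  m <- length(seqs$ids)
  schedule <- if (is.null(tree)) {
    lapply(seq_len(m - 1L), function(i) list(a = seq_len(i), b = i + 1L))
  } else {
    .merge_schedule(tree, seqs$ids)
  }
  ## gap-placement tie-breaks in the DP depend on operand order; normalize so
  ## the group holding the smallest input index is always the first operand,
  ## making each merge invariant to the order the guide tree proposes it
  schedule <- lapply(schedule, function(st) {
    if (min(st$b) < min(st$a)) list(a = st$b, b = st$a) else st
  })
  ## group id -> aligned rows, groups keyed by sorted member indices
  rows_env <- new.env(parent = emptyenv())
  key <- function(g) paste(sort(g), collapse = ",")
  for (i in seq_len(m)) assign(key(i), seqs$seqs[i], envir = rows_env)
  for (st in schedule) {
    ra <- get(key(st$a), envir = rows_env)
    rb <- get(key(st$b), envir = rows_env)
    assign(key(c(st$a, st$b)), .merge_profiles(ra, rb), envir = rows_env)
  }
  final_group <- c(schedule[[length(schedule)]]$a,
                   schedule[[length(schedule)]]$b)
  rows <- get(key(final_group), envir = rows_env)
  ## rows are in merge-concatenation order; map back to input order
  member_order <- .member_order(schedule, m)
  rows <- rows[match(seq_len(m), member_order)]
  aln <- protein_alignment(seqs$ids, rows)
  .strip_allgap_cols(aln)
}

## concatenation order of members produced by the schedule
.member_order <- function(schedule, m) {
  if (!length(schedule)) return(seq_len(m))
  last <- schedule[[length(schedule)]]
  ord_env <- new.env(parent = emptyenv())
  key <- function(g) paste(sort(g), collapse = ",")
  for (i in seq_len(m)) assign(key(i), i, envir = ord_env)
  for (st in schedule) {
    oa <- get(key(st$a), envir = ord_env)
    ob <- get(key(st$b), envir = ord_env)
    assign(key(c(st$a, st$b)), c(oa, ob), envir = ord_env)
  }
  get(key(c(last$a, last$b)), envir = ord_env)
}

## remove columns that became all-gap (possible after merging gapped groups)
.strip_allgap_cols <- function(aln) {
  M <- aln_matrix_chr(aln$rows)
  keep <- colSums(M != "-") > 0L
  if (all(keep)) return(aln)
  protein_alignment(aln$ids,
                    apply(M[, keep, drop = FALSE], 1L, paste, collapse = ""))
}

## ---- external tools ------------------------------------------------------

## newick with non-positive branch lengths clamped for tools that reject them
export_guide_tree <- function(tree, path, eps = 1e-8) {
  t2 <- tree
  if (!is.null(t2$edge.length)) t2$edge.length[t2$edge.length <= 0] <- eps
  writeLines(to_newick(t2, digits = 10L), path)
  invisible(path)
}

## mafft's --treein merge-list dialect: one line per merge, the two groups
## named by the 1-based input index of their smallest member, then the two
## branch lengths.
export_mafft_tree <- function(tree, ids, path, eps = 1e-8) {
  bl <- function(node) {
    e <- which(tree$edge[, 2L] == node)
    if (!length(e) || is.null(tree$edge.length)) return(eps)
    max(tree$edge.length[e], eps)
  }
  ntip <- length(tree$tip.label)
  tip_of <- match(tree$tip.label, ids)
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])
  lines <- character(0)
  walk <- function(node) {
    ## returns list(members, blen-of-node)
    if (node <= ntip) return(list(g = tip_of[node], b = bl(node)))
    ch <- lapply(kids[[as.character(node)]], walk)
    acc <- ch[[1L]]
    for (k in seq_along(ch)[-1L]) {
      x <- ch[[k]]
      g1 <- min(acc$g); g2 <- min(x$g)
      lines[length(lines) + 1L] <<-
        sprintf("%5d %5d %10.5f %10.5f",
                min(g1, g2), max(g1, g2),
                if (g1 < g2) acc$b else x$b,
                if (g1 < g2) x$b else acc$b)
      acc <- list(g = c(acc$g, x$g), b = if (k < length(ch)) eps else bl(node))
    }
    list(g = acc$g, b = bl(node))
  }
  walk(ntip + 1L)
  writeLines(lines, path)
  invisible(path)
}

.external_align <- function(seqs, tree, spec) {
  dir <- tempfile(paste0("isopick_", spec$name, "_"))
  dir.create(dir)
  if (!spec$keep_intermediates) on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  in_fa <- file.path(dir, "input.fasta")
  out_fa <- file.path(dir, "output.fasta")
  write_fasta(seqs, in_fa)

  args <- switch(spec$name,
    mafft = {
      a <- c("--quiet", "--anysymbol", spec$opts)
      if (!is.null(tree)) {
        tf <- file.path(dir, "guide.mafft")
        export_mafft_tree(tree, seqs$ids, tf)
        a <- c(a, "--treein", tf)
      }
      c(a, in_fa)
    },
    clustalo = {
      a <- c("-i", in_fa, "-o", out_fa, "--force", spec$opts)
      if (!is.null(tree)) {
        tf <- file.path(dir, "guide.nwk")
        export_guide_tree(tree, tf)
        a <- c(a, paste0("--guidetree-in=", tf))
      }
      a
    },
    muscle = {
      a <- c("-in", in_fa, "-out", out_fa, "-quiet", spec$opts)
      if (!is.null(tree)) {
        tf <- file.path(dir, "guide.nwk")
        export_guide_tree(tree, tf)
        a <- c(a, "-usetree_nowarn", tf)
      }
      a
    },
    stop("unknown external aligner: ", spec$name))

  if (spec$name == "mafft") {
    status <- system2(spec$exec, args, stdout = out_fa, stderr = FALSE)
  } else {
    status <- system2(spec$exec, args, stdout = FALSE, stderr = FALSE)
  }
  if (!identical(status, 0L))
    stop(spec$name, " exited with status ", status)
  out <- read_fasta(out_fa, aligned = TRUE)
  ord <- match(seqs$ids, out$ids)
  if (anyNA(ord)) stop(spec$name, " output ids do not match the input")
  protein_alignment(out$ids[ord], out$rows[ord])
}
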