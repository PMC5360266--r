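## Sum-of-Pairs agreement scoring between a reference alignment and a set of
## perturbed realignments, plus the distance-score variants.
##
## Residue identity is tracked by residue ordinal (the k-th residue of a
## sequence), never by column index, so alignments of different lengths are
## comparable. For residue k of sequence i, the pair score against sequence j
## is 1 exactly when j's residue facing (i,k) in the reference alignment is
## the same residue ordinal facing (i,k) in the perturbed alignment.

#' Residue/column bookkeeping for one alignment
#'
#' @param aln a `protein_alignment`.
#' @return A `residue_column_map` with components: `ord`, an m x l integer
#'   matrix giving the residue ordinal of each sequence at each column (NA at
#'   gaps); `cols`, a list mapping each sequence's residue ordinal k to its
#'   column; `mk`, residues per column; `mg`, gaps per column.
#' @export
residue_column_map <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  M <- aln_matrix_chr(aln$rows)
  res <- M != "-"
  ord <- t(apply(res, 1L, cumsum))
  ord[!res] <- NA_integer_
  mode(ord) <- "integer"
  cols <- lapply(seq_len(nrow(M)), function(i) which(res[i, ]))
  mk <- colSums(res)
  structure(list(ids = aln$ids, ord = ord, cols = cols,
                 mk = mk, mg = nrow(M) - mk, m = nrow(M), length = ncol(M)),
            class = "residue_column_map")
}

.seq_index <- function(map, i) {
  if (is.character(i)) {
    idx <- match(i, map$ids)
    if (is.na(idx)) stop("unknown sequence id: ", i)
    idx
  } else as.integer(i)
}

#' Pair agreement indicator p_ijk
#'
#' 1 when the residue of sequence `j` facing residue `k` of sequence `i` in
#' the reference alignment is the same residue (by ordinal) facing it in the
#' perturbed alignment, otherwise 0. Requires `j` to carry a residue in the
#' reference column of `(i, k)`.
#'
#' @param ref_map,pert_map `residue_column_map`s of the reference and a
#'   perturbed alignment (same sequences).
#' @param i,j sequence indices or ids, `i != j`.
#' @param k residue ordinal of sequence `i` (1-based).
#' @return 0 or 1.
#' @export
pair_agreement <- function(ref_map, pert_map, i, k, j) {
  i <- .seq_index(ref_map, i); j <- .seq_index(ref_map, j)
  if (i == j) stop("i and j must differ")
  if (k < 1L || k > length(ref_map$cols[[i]]))
    stop("residue ordinal k out of range")
  partner_ref <- ref_map$ord[j, ref_map$cols[[i]][k]]
  if (is.na(partner_ref))
    stop("sequence j has a gap in the reference column of (i, k)")
  partner_pert <- pert_map$ord[j, pert_map$cols[[i]][k]]
  as.integer(!is.na(partner_pert) && partner_pert == partner_ref)
}

#' Per-residue score R_ik(b) against one perturbed alignment
#'
#' Default variant: mean of the pair agreements over the `m_k - 1` sequences
#' carrying a residue in the reference column; 1 when `m_k = 1`. Gap variant:
#' each agreement divided by the number of gaps `m_g` in the reference column
#' (`m_g = 1` when the column has no gap); when `m_k = 1` the score is the
#' penalty `-1/m_g`.
#'
#' @inheritParams pair_agreement
#' @param gap_variant logical.
#' @return Numeric score.
#' @export
residue_score <- function(ref_map, pert_map, i, k, gap_variant = FALSE) {
  i <- .seq_index(ref_map, i)
  if (k < 1L || k > length(ref_map$cols[[i]]))
    stop("residue ordinal k out of range")
  col <- ref_map$cols[[i]][k]
  mk <- ref_map$mk[col]
  mg <- max(1L, ref_map$mg[col])
  if (mk == 1L) return(if (gap_variant) -1 / mg else 1)
  js <- which(!is.na(ref_map$ord[, col]))
  js <- js[js != i]
  p <- vapply(js, function(j) pair_agreement(ref_map, pert_map, i, k, j), 0L)
  if (gap_variant) sum(p / mg) / (mk - 1L) else mean(p)
}

## vectorized residue scores of sequence i against one perturbed map:
## returns numeric vector over k = 1..l_i
.residue_scores_seq <- function(ref_map, pert_map, i, gap_variant) {
  cols_ref <- ref_map$cols[[i]]
  cols_prt <- pert_map$cols[[i]]
  A <- ref_map$ord[, cols_ref, drop = FALSE]   # partner ordinals, reference
  B <- pert_map$ord[, cols_prt, drop = FALSE]  # partner ordinals, perturbed
  A[i, ] <- NA_integer_
  valid <- !is.na(A)
  agree <- valid & !is.na(B) & A == B
  num <- colSums(agree, na.rm = TRUE)
  den <- colSums(valid)                        # = m_k - 1
  mg <- pmax(1L, ref_map$mg[cols_ref])
  if (gap_variant) {
    r <- ifelse(den == 0L, -1 / mg, num / (mg * pmax(den, 1L)))
  } else {
    r <- ifelse(den == 0L, 1, num / pmax(den, 1L))
  }
  r
}

#' Sum-of-Pairs sequence scores over bootstrap-perturbed alignments
#'
#' Residue scores are averaged over replicates, then over residues. The
#' `short` variant divides the residue-score sum by the reference alignment
#' length instead of the sequence length, penalizing short isoforms.
#'
#' @param ref the reference `protein_alignment`.
#' @param perturbed list of perturbed `protein_alignment`s over the same
#'   sequences (ids and residues must match).
#' @param variant `"default"`, `"gap"` or `"short"`.
#' @param keep_residue_scores keep the per-residue means R_ik in the result.
#' @return A `score_table`: named numeric scores plus the variant and the
#'   replicate count.
#' @export
sp_scores <- function(ref, perturbed, variant = c("default", "gap", "short"),
                      keep_residue_scores = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(ref, "protein_alignment"), length(perturbed) >= 1L)
  ref_map <- residue_column_map(ref)
  m <- ref_map$m
  ref_res <- gsub("-", "", ref$rows, fixed = TRUE)
  pert_maps <- lapply(perturbed, function(p) {
    stopifnot(inherits(p, "protein_alignment"))
    if (!identical(p$ids, ref$ids))
      stop("perturbed alignment ids differ from the reference")
    if (!identical(gsub("-", "", p$rows, fixed = TRUE), ref_res))
      stop("perturbed alignment residues differ from the reference")
    residue_column_map(p)
  })
  n <- length(pert_maps)
  gap_variant <- variant == "gap"
  Rik <- vector("list", m)
  S <- numeric(m)
  for (i in seq_len(m)) {
    acc <- 0
    for (pm in pert_maps)
      acc <- acc + .residue_scores_seq(ref_map, pm, i, gap_variant)
    r <- acc / n
    li <- length(ref_map$cols[[i]])
    S[i] <- if (variant == "short") sum(r) / ref_map$length else sum(r) / li
    if (keep_residue_scores) Rik[[i]] <- r
  }
  structure(list(scores = stats::setNames(S, ref$ids), variant = variant,
                 n = n,
                 residue_scores = if (keep_residue_scores) Rik else NULL),
            class = "score_table")
}

#' Distance scores (no bootstrap)
#'
#' Approximates the Sum-of-Pairs score by the mean modified p-distance from
#' each sequence to a comparison backbone: the single-isoform sequences
#' (default) or every other sequence (`wot = TRUE`). Lower is better;
#' selection takes the minimum.
#'
#' @param ref the reference `protein_alignment`.
#' @param locus_map named character vector mapping sequence id to gene id
#'   (ids absent from it are singleton loci).
#' @param wot average over the entire dataset instead of the single-isoform
#'   subset ("with other transcripts").
#' @return A `score_table` with variant `"ds"` or `"ds_wot"`.
#' @export
distance_scores <- function(ref, locus_map = NULL, wot = FALSE) {
  stopifnot(inherits(ref, "protein_alignment"))
  gene <- effective_locus(ref$ids, locus_map)
  sizes <- table(gene)
  omega <- ref$ids[sizes[gene] == 1L]
  if (!wot && length(omega) == 0L)
    stop("every sequence belongs to a multi-isoform locus; ",
         "use the with-other-transcripts mode (wot = TRUE / -WOT)")
  D <- distance_matrix(ref, "modified_pdist")
  S <- vapply(ref$ids, function(id) {
    js <- if (wot) setdiff(ref$ids, id) else setdiff(omega, id)
    if (!length(js)) 0 else mean(D[id, js])
  }, 0.0)
  structure(list(scores = S, variant = if (wot) "ds_wot" else "ds",
                 n = 0L, residue_scores = NULL),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score_table (variant:", x$variant,
      if (x$n > 0) paste0(", n = ", x$n), ")\n")
  print(round(x$scores, 6))
  invisible(x)
}

#' Pick the best-scoring isoform of each locus
#'
#' Sum-of-Pairs variants keep the highest score per gene, distance-score
#' variants the lowest. Singleton genes are always selected. Exact ties go to
#' the lexicographically smallest id, with a warning.
#'
#' @param scores a `score_table`.
#' @param locus_map named character vector (see [read_locus_tags()]).
#' @return Named character vector: gene id -> selected sequence id.
#' @export
select_per_locus <- function(scores, locus_map = NULL) {
  stopifnot(inherits(scores, "score_table"))
  ids <- names(scores$scores)
  gene <- effective_locus(ids, locus_map)
  minimize <- scores$variant %in% c("ds", "ds_wot")
  groups <- split(ids, gene)
  sel <- vapply(groups, function(g) {
    s <- scores$scores[g]
    best <- if (minimize) s == min(s) else s == max(s)
    winners <- sort(g[best])
    if (length(winners) > 1L)
      warning("score tie at locus of '", winners[1L],
              "'; keeping the lexicographically smallest id", call. = FALSE)
    winners[1L]
  }, "")
  sel
}

#' Per-residue score dump
#'
#' @param scores a `score_table` produced with `keep_residue_scores = TRUE`.
#' @return data.frame with columns id, k and the replicate-averaged residue
#'   score.
#' @export
residue_scores_table <- function(scores) {
  stopifnot(inherits(scores, "score_table"))
  if (is.null(scores$residue_scores))
    stop("score_table was built without keep_residue_scores = TRUE")
  ids <- names(scores$scores)
  do.call(rbind, lapply(seq_along(ids), function(i) {
    r <- scores$residue_scores[[i]]
    data.frame(id = ids[i], k = seq_along(r), R_ik = r)
  }))
}
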