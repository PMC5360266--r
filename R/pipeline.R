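## Orchestration: reference alignment -> n guide-tree-perturbed realignments
## -> Sum-of-Pairs scores -> per-locus selection; the distance-score shortcut;
## the automatic variant chooser; and the tree-length utility used for
## self-evaluation on synthetic data.

## run `code` under a local RNG state fully determined by `seed`
with_seed <- function(seed, code) {
  ge <- globalenv()
  old <- if (exists(".Random.seed", envir = ge, inherits = FALSE))
    get(".Random.seed", envir = ge) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = ge, inherits = FALSE))
        rm(".Random.seed", envir = ge)
    } else assign(".Random.seed", old, envir = ge)
  })
  set.seed(seed)
  force(code)
}

## child seed for replicate b of a master seed; kept < 2^31
.child_seed <- function(seed, b) {
  (as.double(seed) * 1009 + b * 7919) %% 2147483647
}

#' Bootstrap resample of alignment columns
#'
#' Draws l columns uniformly with replacement from the alignment (l = its
#' length) using the current RNG state. Sampled columns are copies, so no
#' all-gap column can arise.
#'
#' @param aln a `protein_alignment`.
#' @return A `protein_alignment` of the same ids and length.
#' @export
bootstrap_replicate <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  l <- aln$length
  cols <- sample.int(l, l, replace = TRUE)
  M <- aln_matrix_chr(aln$rows)[, cols, drop = FALSE]
  protein_alignment(aln$ids, apply(M, 1L, paste, collapse = ""))
}

#' Choose a scoring variant from the reference alignment
#'
#' Gap-heavy alignments (strictly more than 35% of columns with strictly more
#' than 80% gaps) get the gap variant; very large inputs (more than 600
#' sequences or more than 10000 columns) get the distance-score variant;
#' everything else gets the default.
#'
#' @param aln the reference `protein_alignment`.
#' @return `"gap"`, `"ds"` or `"default"`.
#' @export
auto_mode <- function(aln) {
  stopifnot(inherits(aln, "protein_alignment"))
  m <- length(aln$ids)
  gap_frac <- 1 - residue_column_map(aln)$mk / m
  if (mean(gap_frac > 0.80) > 0.35) return("gap")
  if (m > 600L || aln$length > 10000L) return("ds")
  "default"
}

#' Sum of branch lengths of a tree
#'
#' Under the minimum-evolution rationale, the selection giving the shortest
#' tree is taken as the better one.
#'
#' @param tree a `phylo`.
#' @return Numeric tree length; 0 when the tree carries no branch lengths.
#' @export
tree_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) 0 else sum(tree$edge.length)
}

#' Pick the default aligner
#'
#' mafft when found on PATH, otherwise the built-in progressive aligner with
#' a loud warning.
#'
#' @return An `aligner_spec`.
#' @export
default_aligner <- function() {
  if (nzchar(Sys.which("mafft"))) return(aligner_spec("mafft"))
  warning("mafft not found on PATH; falling back to the built-in ",
          "progressive aligner, which is test-grade only", call. = FALSE)
  aligner_spec("mock")
}

#' Score sequences and select one isoform per locus
#'
#' The full procedure: (1) build a reference alignment of the input (or use a
#' supplied one); (2) for each of `n` replicates, resample the reference
#' alignment's columns, compute a distance matrix under `model`, infer a BioNJ
#' guide tree and realign the input under it; (3) score every sequence by its
#' Sum-of-Pairs agreement between reference and perturbed alignments, and keep
#' the best-scoring isoform of each locus. The distance-score variants replace
#' steps 2-3 by mean modified p-distances on the reference alignment alone.
#'
#' @param seqs a `seq_set` (at least 3 sequences).
#' @param locus_map named character vector mapping sequence ids to gene ids
#'   (see [read_locus_tags()]); `NULL` means every sequence is its own locus.
#' @param variant `"default"`, `"gap"`, `"short"`, `"ds"`, or `"auto"`.
#' @param wot with the `"ds"` variant, average distances over the whole
#'   dataset instead of the single-isoform subset.
#' @param n bootstrap replicate count (SP variants only; default 30).
#' @param model a `model_spec` or model name for the replicate distance
#'   matrices (default the closed-form Gamma-Poisson JTT approximation).
#' @param aligner an `aligner_spec`; default [default_aligner()].
#' @param seed integer; fully determines the column resampling.
#' @param threads replicate-level workers (forked; results are reduced in
#'   replicate order, so the value never changes results).
#' @param reference optional pre-computed reference `protein_alignment` whose
#'   rows degap to `seqs` (skips step 1).
#' @param keep_residue_scores keep per-residue scores (SP variants).
#' @return An `isoform_selection` object with components `scores` (named
#'   numeric), `selection` (gene -> kept sequence id), `reference`, `variant`,
#'   `score_table`, and the inputs needed by [write_outputs()].
#' @export
select_isoforms <- function(seqs, locus_map = NULL,
                            variant = c("default", "gap", "short", "ds", "auto"),
                            wot = FALSE, n = 30L, model = "jtt_approx",
                            aligner = NULL, seed = 1L, threads = 1L,
                            reference = NULL, keep_residue_scores = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(seqs, "seq_set"))
  if (length(seqs) < 3L) stop("need at least 3 sequences")
  if (wot && !variant %in% c("ds", "auto"))
    stop("wot = TRUE requires the distance-score variant")
  if (is.null(aligner)) aligner <- default_aligner()
  probe_aligner(aligner)
  model <- .as_model_spec(model)
  n <- as.integer(n)
  cl <- match.call()

  if (is.null(reference)) {
    reference <- align(seqs, aligner)
  } else {
    stopifnot(inherits(reference, "protein_alignment"))
    if (!identical(reference$ids, seqs$ids) ||
        !identical(gsub("-", "", reference$rows, fixed = TRUE), seqs$seqs))
      stop("supplied reference alignment does not match the input sequences")
  }

  requested <- variant
  if (variant == "auto") {
    variant <- auto_mode(reference)
    message("auto mode selected the '", variant, "' variant")
  }

  ## honour locus labels carried by the seq_set itself when no map is given
  had_locus_map <- !is.null(locus_map) || any(!is.na(seqs$locus))
  lm <- effective_locus(seqs, locus_map)

  if (variant == "ds") {
    st <- distance_scores(reference, lm, wot = wot)
  } else {
    if (n < 1L) stop("n must be >= 1 for Sum-of-Pairs variants")
    one_replicate <- function(b) {
      tryCatch({
        boot <- with_seed(.child_seed(seed, b), bootstrap_replicate(reference))
        D <- distance_matrix(boot, model)
        gt <- bionj_tree(D)
        align_with_guide_tree(seqs, gt, aligner)
      }, error = function(e) {
        stop("perturbed-alignment replicate ", b, " failed: ",
             conditionMessage(e), call. = FALSE)
      })
    }
    perturbed <- if (threads > 1L && .Platform$OS.type == "unix") {
      parallel::mclapply(seq_len(n), one_replicate, mc.cores = threads)
    } else {
      lapply(seq_len(n), one_replicate)
    }
    for (p in perturbed) if (inherits(p, "try-error") || !inherits(p, "protein_alignment"))
      stop("a perturbed-alignment replicate failed")
    st <- sp_scores(reference, perturbed, variant,
                    keep_residue_scores = keep_residue_scores)
  }

  sel <- select_per_locus(st, lm)
  structure(list(scores = st$scores, selection = sel, score_table = st,
                 reference = reference, variant = st$variant,
                 requested_variant = requested, n = if (st$n > 0) st$n else NA_integer_,
                 model = model, seed = seed, input = seqs,
                 locus_map = lm, had_locus_map = had_locus_map, call = cl),
            class = "isoform_selection")
}

#' @export
print.isoform_selection <- function(x, ...) {
  cat("Isoform selection (variant:", x$variant,
      if (!is.na(x$n)) paste0(", ", x$n, " replicates"), ")\n")
  cat("  ", length(x$input$ids), "sequences,",
      length(unique(x$locus_map)), "loci,",
      sum(table(x$locus_map) > 1L), "with alternative isoforms\n")
  cat("  kept", length(x$selection), "sequences (one per locus)\n")
  invisible(x)
}

#' @export
summary.isoform_selection <- function(object, ...) {
  gene <- object$locus_map
  groups <- split(names(object$scores), gene[names(object$scores)])
  multi <- groups[lengths(groups) > 1L]
  rows <- lapply(names(multi), function(g) {
    ids <- multi[[g]]
    data.frame(gene = g, id = ids, score = unname(object$scores[ids]),
               selected = ids == object$selection[[g]])
  })
  out <- list(variant = object$variant, n = object$n,
              m = length(object$input$ids),
              n_loci = length(unique(gene)),
              score_range = range(object$scores),
              isoform_table = if (length(rows)) do.call(rbind, rows) else NULL)
  class(out) <- "summary.isoform_selection"
  out
}

#' @export
print.summary.isoform_selection <- function(x, ...) {
  cat("Isoform selection summary\n")
  cat("  variant:", x$variant,
      if (!is.na(x$n)) paste0("(", x$n, " replicates)"), "\n")
  cat("  sequences:", x$m, " loci:", x$n_loci, "\n")
  cat(sprintf("  score range: %.6f - %.6f\n",
              x$score_range[1], x$score_range[2]))
  if (!is.null(x$isoform_table)) {
    cat("  multi-isoform loci:\n")
    print(x$isoform_table, row.names = FALSE)
  } else cat("  no multi-isoform locus\n")
  invisible(x)
}

#' @export
coef.isoform_selection <- function(object, ...) object$scores

#' @export
plot.isoform_selection <- function(x, ...) {
  gene <- x$locus_map[names(x$scores)]
  gi <- as.integer(factor(gene))
  sel <- names(x$scores) %in% unname(x$selection)
  graphics::plot(gi, x$scores, pch = ifelse(sel, 19, 1),
                 col = ifelse(sel, "firebrick", "grey40"),
                 xlab = "locus", ylab = paste0("score (", x$variant, ")"),
                 xaxt = "n", ...)
  graphics::axis(1, at = unique(gi), labels = unique(gene), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}
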