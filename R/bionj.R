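## BioNJ distance-tree inference (Gascuel 1997).
##
## Classical NJ agglomeration criterion and branch lengths, but the matrix
## reduction uses the variance-minimizing weight lambda computed from pair
## variances (initialized to the distances themselves). Returns an unrooted
## ape "phylo" with a trifurcating root node. Fully deterministic: ties on
## the selection criterion are broken by the lowest (row, column) index pair
## in current matrix order, and the merged cluster takes the row slot.

#' BioNJ tree from a distance matrix
#'
#' @param D symmetric numeric matrix with zero diagonal and dimnames giving
#'   the taxon labels; at least 3 taxa.
#' @return Unrooted `phylo` tree over all ids. Negative branch lengths that
#'   the NJ length formulas can produce are kept (guide-tree export clamps
#'   them).
#' @export
bionj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  m <- nrow(D)
  if (m < 3L) stop("BioNJ needs at least 3 taxa")
  if (is.null(rownames(D))) stop("D must carry taxon ids as dimnames")
  if (any(!is.finite(D))) stop("non-finite distances")
  if (max(abs(D - t(D))) > 1e-9) stop("D is not symmetric")
  if (any(diag(D) < 0) || max(abs(diag(D))) > 1e-12)
    stop("D must have a zero diagonal")

  lab <- vapply(rownames(D), .nwk_label, "")
  d <- unname(D)
  v <- d                      # pair variances, initialized proportional to d
  frag <- lab                 # newick fragment per active cluster

  while (length(frag) > 3L) {
    r <- length(frag)
    Tt <- rowSums(d)
    ## NJ selection criterion; scan i<j in order, strict improvement only,
    ## so ties resolve to the lowest (row, column) pair.
    best <- c(1L, 2L)
    bq <- Inf
    for (i in seq_len(r - 1L)) {
      for (j in (i + 1L):r) {
        q <- (r - 2) * d[i, j] - Tt[i] - Tt[j]
        if (q < bq - 1e-15) { bq <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- 0.5 * d[i, j] + (Tt[i] - Tt[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    ## variance-minimizing reduction weight
    ks <- setdiff(seq_len(r), c(i, j))
    lam <- if (v[i, j] <= 0) 0.5
           else 0.5 + sum(v[j, ks] - v[i, ks]) / (2 * (r - 2) * v[i, j])
    lam <- min(1, max(0, lam))

    du <- lam * (d[i, ks] - bi) + (1 - lam) * (d[j, ks] - bj)
    vu <- lam * v[i, ks] + (1 - lam) * v[j, ks] - lam * (1 - lam) * v[i, j]

    frag[i] <- sprintf("(%s:%.15g,%s:%.15g)", frag[i], bi, frag[j], bj)
    d[i, ks] <- d[ks, i] <- du
    v[i, ks] <- v[ks, i] <- vu
    d <- d[-j, -j, drop = FALSE]
    v <- v[-j, -j, drop = FALSE]
    frag <- frag[-j]
  }

  ## final three clusters: exact three-point branch lengths
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = nwk)
}

## quote a label for newick when it contains anything beyond [A-Za-z0-9_.-]
.nwk_label <- function(x) {
  if (grepl("^[A-Za-z0-9_.-]+$", x)) x
  else paste0("'", gsub("'", "''", x), "'")
}

#' Serialize a tree to newick
#'
#' Branch lengths are printed to 6 decimal places; labels containing newick
#' reserved characters are single-quoted.
#'
#' @param tree a `phylo`.
#' @param digits decimal places for branch lengths (default 6).
#' @return Newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 6L) {
  stopifnot(inherits(tree, "phylo"))
  fmt <- paste0("%s:%.", digits, "f")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  el <- tree$edge.length
  rec <- function(node, edge_idx) {
    s <- if (node <= ntip) {
      .nwk_label(tree$tip.label[node])
    } else {
      sub <- vapply(kids[[as.character(node)]],
                    function(e) rec(tree$edge[e, 2L], e), "")
      paste0("(", paste(sub, collapse = ","), ")")
    }
    if (is.na(edge_idx)) s
    else sprintf(fmt, s, if (is.null(el)) 0 else el[edge_idx])
  }
  paste0(rec(root, NA_integer_), ";")
}
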