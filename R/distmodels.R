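## Pairwise distances between aligned protein sequences.
##
## Identity-based distances (p-distance and the gap-as-21st-state modified
## p-distance) are computed directly. Model-corrected distances come either
## from closed-form corrections of p (Poisson, Gamma-Poisson, Kimura's PAM
## approximation, a Gamma-Poisson JTT approximation) or from pairwise maximum
## likelihood under an empirical exchangeability matrix (PAM/Dayhoff, JTT,
## WAG, LG, or a BLOSUM62-derived rate matrix), optionally with discrete-Gamma
## rate mixing. X is never treated as informative: it counts as a mismatch in
## identity-based distances and its columns are excluded from ML counts.

ML_MODELS <- c(pam_ml = "Dayhoff", jtt_ml = "JTT", wag_ml = "WAG",
               lg_ml = "LG", blosum62_ml = "Blosum62")
ALL_MODELS <- c("poisson", "pam_kimura", "jtt_approx", names(ML_MODELS),
                "pdist", "modified_pdist")

#' Specify a substitution model for distance computation
#'
#' @param model one of `"poisson"`, `"pam_kimura"`, `"jtt_approx"`,
#'   `"pam_ml"`, `"jtt_ml"`, `"wag_ml"`, `"lg_ml"`, `"blosum62_ml"`,
#'   `"pdist"`, `"modified_pdist"`.
#' @param gamma_alpha optional positive Gamma shape for among-site rate
#'   variation. Closed forms use the rescaling `alpha*((1-p)^(-1/alpha)-1)`;
#'   ML models mix a 4-category discrete Gamma into the transition
#'   probabilities.
#' @param jtt_shape shape constant of the Gamma-Poisson JTT approximation
#'   (default 2.4).
#' @param ceiling saturation ceiling in substitutions/site (default 10).
#' @return A `model_spec` list.
#' @export
model_spec <- function(model = "jtt_approx", gamma_alpha = NULL,
                       jtt_shape = 2.4, ceiling = 10.0) {
  model <- match.arg(model, ALL_MODELS)
  if (!is.null(gamma_alpha)) {
    stopifnot(is.numeric(gamma_alpha), length(gamma_alpha) == 1L)
    if (gamma_alpha <= 0) stop("gamma_alpha must be > 0")
  }
  stopifnot(jtt_shape > 0, ceiling > 0)
  structure(list(model = model, gamma_alpha = gamma_alpha,
                 jtt_shape = jtt_shape, ceiling = ceiling),
            class = "model_spec")
}

.as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

.row_chars <- function(x) {
  if (length(x) == 1L && nchar(x[1]) > 1L) strsplit(x, "")[[1]] else x
}

#' p-distance between two aligned rows
#'
#' Proportion of mismatching positions among positions where both rows carry a
#' residue. X never matches anything (including X). Returns 0 with a warning
#' when no comparable position exists.
#'
#' @param a,b aligned rows (strings of equal length).
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  ca <- .row_chars(a); cb <- .row_chars(b)
  if (length(ca) != length(cb)) stop("rows have unequal lengths")
  both <- ca != "-" & cb != "-"
  if (!any(both)) {
    warning("no position where both sequences carry a residue; p-distance set to 0")
    return(0)
  }
  diff <- (ca != cb) | ca == "X" | cb == "X"
  sum(diff & both) / sum(both)
}

#' Modified p-distance (gap as a 21st character state)
#'
#' A residue facing a gap counts as a difference; columns gapped in both rows
#' are excluded. The denominator is the number of columns where at least one
#' row has a residue, so isoforms differing by an exon-skipping event get a
#' moderate distance instead of one close to 1.
#'
#' @inheritParams p_distance
#' @return Proportion in `[0, 1]`.
#' @export
modified_p_distance <- function(a, b) {
  ca <- .row_chars(a); cb <- .row_chars(b)
  if (length(ca) != length(cb)) stop("rows have unequal lengths")
  any_res <- ca != "-" | cb != "-"
  if (!any(any_res)) stop("both rows are entirely gaps")
  diff <- (ca != cb) | (ca == "X" & cb != "-") | (cb == "X" & ca != "-")
  sum(diff & any_res) / sum(any_res)
}

#' Closed-form model correction of a p-distance
#'
#' * `poisson`: `-log(1-p)`; with `gamma_alpha` = a,
#'   `a*((1-p)^(-1/a) - 1)`.
#' * `pam_kimura`: `-log(1 - p - 0.2*p^2)` (Kimura's PAM approximation).
#' * `jtt_approx`: the Gamma-Poisson form with shape `jtt_shape`.
#'
#' Saturated inputs (argument of the log non-positive, or p >= 1) are capped
#' at the model ceiling and flagged in the `"saturated"` attribute.
#'
#' @param p numeric vector of proportions in `[0, 1]`.
#' @param model a `model_spec` (or model name) among the closed-form models.
#' @return Numeric vector of distances (substitutions/site) with a logical
#'   `"saturated"` attribute.
#' @export
correct_distance <- function(p, model = "poisson") {
  spec <- .as_model_spec(model)
  stopifnot(all(p >= 0), all(p <= 1))
  d <- switch(spec$model,
    pdist = ,
    modified_pdist = p,
    poisson = {
      if (is.null(spec$gamma_alpha)) -log(1 - p)
      else spec$gamma_alpha * ((1 - p)^(-1 / spec$gamma_alpha) - 1)
    },
    pam_kimura = {
      arg <- 1 - p - 0.2 * p^2
      ifelse(arg > 0, -log(arg), Inf)
    },
    jtt_approx = spec$jtt_shape * ((1 - p)^(-1 / spec$jtt_shape) - 1),
    stop("correct_distance has no closed form for model '", spec$model, "'")
  )
  sat <- !is.finite(d) | d > spec$ceiling
  d[sat] <- spec$ceiling
  attr(d, "saturated") <- sat
  d
}

## ---- empirical rate matrices -------------------------------------------

## phangorn carries the published exchangeabilities (lower triangle,
## column-major) and equilibrium frequencies for the standard models.
aa_model_data <- function(name) {
  obj <- utils::getFromNamespace(paste0(".", name), "phangorn")
  S <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  S[lower.tri(S)] <- obj$Q
  S <- S + t(S)
  bf <- as.numeric(obj$bf)
  names(bf) <- AA20
  list(S = S, bf = bf / sum(bf))
}

## Eigendecomposition of the normalized reversible rate matrix Q with
## Q_ij = S_ij * pi_j, mean rate 1. Decomposed via the symmetric
## B = diag(sqrt(pi)) Q diag(1/sqrt(pi)).
.rate_eigen_cache <- new.env(parent = emptyenv())

rate_eigen <- function(name) {
  if (!is.null(.rate_eigen_cache[[name]])) return(.rate_eigen_cache[[name]])
  md <- aa_model_data(name)
  Q <- md$S * rep(md$bf, each = 20)
  diag(Q) <- -rowSums(Q)
  rate <- -sum(md$bf * diag(Q))
  Q <- Q / rate
  sp <- sqrt(md$bf)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  res <- list(bf = md$bf, values = e$values,
              U = e$vectors / sp,         # diag(1/sqrt(pi)) V
              Vt = t(e$vectors * sp))     # t(V) diag(sqrt(pi))
  .rate_eigen_cache[[name]] <- res
  res
}

## P(t), optionally averaged over discrete-Gamma rate categories.
.transition_prob <- function(eg, t, gamma_alpha = NULL, k = 4L) {
  rates <- if (is.null(gamma_alpha)) 1
           else phangorn::discrete.gamma(gamma_alpha, k)
  P <- matrix(0, 20, 20)
  for (r in rates)
    P <- P + eg$U %*% (exp(eg$values * r * t) * eg$Vt)
  P <- P / length(rates)
  P[P < 1e-300] <- 1e-300
  P
}

#' Maximum-likelihood pairwise distance under an empirical matrix model
#'
#' Maximizes over t the log-likelihood of the observed residue pairs,
#' `sum N_xy * log(pi_x * P_xy(t))`, with transition probabilities from the
#' eigendecomposition of the model's reversible rate matrix (mean rate 1).
#' Columns containing a gap or X are excluded.
#'
#' @param a,b aligned rows.
#' @param model model name (`pam_ml`, `jtt_ml`, `wag_ml`, `lg_ml`,
#'   `blosum62_ml`) or a `model_spec` of one of those.
#' @return Distance in substitutions/site, with a logical `"saturated"`
#'   attribute (TRUE when the optimum hit the ceiling).
#' @export
ml_matrix_distance <- function(a, b, model = "lg_ml") {
  spec <- .as_model_spec(model)
  if (!spec$model %in% names(ML_MODELS))
    stop("not an ML matrix model: ", spec$model)
  ca <- .row_chars(a); cb <- .row_chars(b)
  if (length(ca) != length(cb)) stop("rows have unequal lengths")
  ok <- ca %in% AA20 & cb %in% AA20
  if (!any(ok)) stop("no comparable residue/residue column")
  N <- table(factor(ca[ok], AA20), factor(cb[ok], AA20))
  .ml_dist_from_counts(N, spec)
}

.ml_dist_from_counts <- function(N, spec) {
  eg <- rate_eigen(ML_MODELS[[spec$model]])
  nz <- which(N > 0, arr.ind = TRUE)
  cnt <- N[nz]
  lpi <- log(eg$bf)[nz[, 1]]
  negll <- function(t) {
    P <- .transition_prob(eg, t, spec$gamma_alpha)
    -sum(cnt * (lpi + log(P[nz])))
  }
  opt <- stats::optimize(negll, c(1e-6, spec$ceiling), tol = 1e-6)
  d <- opt$minimum
  ## saturated when the likelihood has no interior optimum: the objective at
  ## the ceiling matches the best value found (flat or still improving)
  sat <- d > spec$ceiling * 0.99 || negll(spec$ceiling) <= opt$objective + 1e-6
  if (sat) d <- spec$ceiling
  attr(d, "saturated") <- sat
  d
}

#' All-pairs distance matrix of an alignment
#'
#' @param aln a `protein_alignment`.
#' @param model a `model_spec` or model name.
#' @return Symmetric numeric matrix with zero diagonal, dimnames the sequence
#'   ids, and a logical `"saturated"` attribute matrix.
#' @export
distance_matrix <- function(aln, model = "pdist") {
  stopifnot(inherits(aln, "protein_alignment"))
  spec <- .as_model_spec(model)
  m <- length(aln$ids)
  if (m < 2L) stop("need at least 2 sequences")
  M <- aln_matrix(aln)
  D <- matrix(0, m, m, dimnames = list(aln$ids, aln$ids))
  SAT <- matrix(FALSE, m, m, dimnames = dimnames(D))
  is_ml <- spec$model %in% names(ML_MODELS)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if (is_ml) {
        d <- ml_matrix_distance(M[i, ], M[j, ], spec)
        sat <- attr(d, "saturated")
      } else if (spec$model == "modified_pdist") {
        d <- modified_p_distance(M[i, ], M[j, ]); sat <- FALSE
      } else if (spec$model == "pdist") {
        d <- p_distance(M[i, ], M[j, ]); sat <- FALSE
      } else {
        d <- correct_distance(p_distance(M[i, ], M[j, ]), spec)
        sat <- attr(d, "saturated")
      }
      D[i, j] <- D[j, i] <- as.numeric(d)
      SAT[i, j] <- SAT[j, i] <- isTRUE(sat)
    }
  }
  attr(D, "saturated") <- SAT
  D
}

#' Export a distance matrix in PHYLIP square format
#'
#' @param D symmetric matrix with dimnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phylip_dist <- function(D, path) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste0(formatC(rownames(D)[i], width = -10),
                      paste(sprintf("%.6f", D[i, ]), collapse = "  ")), con)
  }
  invisible(path)
}
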