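## Sequence containers and file I/O.
##
## Unaligned sequences are held in a `seq_set`; aligned ones in a
## `protein_alignment`. Residue alphabet: the 20 amino acids plus X (unknown);
## gap is '-' ('.' converted on read); everything upper-cased on read.

AA20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
AA_OK <- c(AA20, "X")

#' Construct a set of unaligned protein sequences
#'
#' @param ids character vector of unique, non-empty identifiers.
#' @param seqs character vector of residue strings (no gaps allowed).
#' @param locus optional character vector of gene identifiers; `NA` marks a
#'   sequence whose gene is unknown (treated as its own single-isoform locus).
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(ids, seqs, locus = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs lengths differ")
  if (any(!nzchar(ids))) stop("empty sequence identifier")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(grepl("-", seqs, fixed = TRUE)))
    stop("gap character '-' found in unaligned sequences")
  if (any(nchar(seqs) < 1L)) stop("zero-length sequence")
  .check_alphabet(seqs, allow_gap = FALSE)
  if (is.null(locus)) locus <- rep(NA_character_, length(ids))
  structure(list(ids = ids, seqs = seqs, locus = as.character(locus)),
            class = "seq_set")
}

#' @export
length.seq_set <- function(x) length(x$ids)

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set:", length(x$ids), "protein sequences, lengths",
      min(nchar(x$seqs)), "-", max(nchar(x$seqs)), "\n")
  ng <- length(unique(effective_locus(x)))
  cat("  loci:", ng, "(", sum(table(effective_locus(x)) > 1L),
      "with >1 isoform )\n")
  invisible(x)
}

#' Construct a protein multiple alignment
#'
#' Rows must be equal-length strings over the amino-acid alphabet plus gap.
#' No column may consist entirely of gaps.
#'
#' @param ids character vector of unique identifiers.
#' @param rows character vector of aligned rows (same length as `ids`).
#' @return An object of class `protein_alignment`.
#' @export
protein_alignment <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  if (length(ids) != length(rows)) stop("ids and rows lengths differ")
  if (anyDuplicated(ids)) stop("duplicate identifier in alignment")
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("alignment rows have unequal lengths")
  if (len == 0L) stop("alignment has zero columns")
  .check_alphabet(rows, allow_gap = TRUE)
  M <- aln_matrix_chr(rows)
  if (any(colSums(M != "-") == 0L)) stop("alignment contains an all-gap column")
  structure(list(ids = ids, rows = rows, length = len),
            class = "protein_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", length(x$ids), "sequences x", x$length, "columns\n")
  invisible(x)
}

.check_alphabet <- function(strings, allow_gap) {
  ok <- if (allow_gap) c(AA_OK, "-") else AA_OK
  bad <- setdiff(unique(strsplit(paste(strings, collapse = ""), "")[[1]]), ok)
  if (length(bad))
    stop("invalid residue character(s): ", paste(bad, collapse = " "))
  invisible(TRUE)
}

## rows (character vector) -> m x l character matrix
aln_matrix_chr <- function(rows) {
  matrix(unlist(strsplit(rows, ""), use.names = FALSE),
         nrow = length(rows), byrow = TRUE)
}

#' Alignment as a character matrix
#' @param aln a `protein_alignment`.
#' @return m x l character matrix with rownames set to the sequence ids.
#' @export
aln_matrix <- function(aln) {
  M <- aln_matrix_chr(aln$rows)
  rownames(M) <- aln$ids
  M
}

#' Remove gaps from alignment rows
#' @param aln a `protein_alignment`.
#' @return A `seq_set` holding the ungapped residues in the same order.
#' @export
degap <- function(aln) {
  seq_set(aln$ids, gsub("-", "", aln$rows, fixed = TRUE))
}

#' Read protein sequences from a FASTA file
#'
#' The identifier is the full header line up to the first whitespace (headers
#' may themselves contain '|'). Input order is preserved. '.' is converted to
#' '-' and residues are upper-cased.
#'
#' @param path FASTA file.
#' @param aligned if `TRUE` the records must be equal length and a
#'   `protein_alignment` is returned; otherwise gaps are an error and a
#'   `seq_set` is returned.
#' @return `seq_set` or `protein_alignment`.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  ## parsed line-wise rather than through Biostrings::readAAStringSet, which
  ## silently drops invalid residue codes this reader must reject
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("empty FASTA file (no '>' header): ", path)
  if (!hdr[match(TRUE, nzchar(trimws(lines)))])
    stop("malformed FASTA (sequence before first header): ", path)
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", headers)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), function(x)
    gsub("[ \t]", "", paste(x, collapse = "")), "")[as.character(seq_along(ids))]
  seqs[is.na(seqs)] <- ""
  if (any(!nzchar(seqs)))
    stop("record without sequence data in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs <- toupper(unname(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (anyDuplicated(ids))
    stop("duplicate identifier(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (aligned) {
    if (length(unique(nchar(seqs))) != 1L)
      stop("aligned input has ragged row lengths: ", path)
    protein_alignment(ids, seqs)
  } else {
    seq_set(ids, seqs)
  }
}

#' Write sequences or an alignment to FASTA
#'
#' @param x a `seq_set` or `protein_alignment`.
#' @param path output file.
#' @param width line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  seqs <- if (inherits(x, "protein_alignment")) x$rows else x$seqs
  ss <- Biostrings::AAStringSet(seqs)
  names(ss) <- x$ids
  Biostrings::writeXStringSet(ss, filepath = path, width = width)
  invisible(path)
}

#' Read a locus-tag table
#'
#' Two whitespace-separated columns: sequence id (a leading '>' is tolerated
#' and stripped), then gene id. Sequences absent from the table are treated as
#' single-isoform loci by downstream code.
#'
#' @param path text file; empty files give an empty mapping.
#' @param ids optional character vector of known sequence ids; table entries
#'   not in `ids` trigger a warning (not an error).
#' @return Named character vector: `names` are sequence ids, values gene ids.
#' @export
read_locus_tags <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(stats::setNames(character(0), character(0)))
  parts <- strsplit(lines, "\\s+")
  nf <- lengths(parts)
  if (any(nf < 2L))
    stop("locus-tag line with fewer than 2 fields: '", lines[which(nf < 2L)[1]], "'")
  sid <- sub("^>", "", vapply(parts, `[[`, "", 1L))
  gid <- vapply(parts, `[[`, "", 2L)
  dup <- duplicated(sid)
  if (any(dup)) {
    for (s in unique(sid[dup])) {
      if (length(unique(gid[sid == s])) > 1L)
        stop("sequence '", s, "' mapped to conflicting gene ids")
    }
    gid <- gid[!dup]
    sid <- sid[!dup]
  }
  if (!is.null(ids)) {
    missing <- setdiff(sid, ids)
    if (length(missing))
      warning("locus-tag entries absent from the FASTA: ",
              paste(missing, collapse = ", "))
  }
  stats::setNames(gid, sid)
}

## Effective gene id per sequence: mapped gene where given, else the sequence
## id itself (singleton locus). `x` is a seq_set or a character vector of ids.
effective_locus <- function(x, locus_map = NULL) {
  if (inherits(x, "seq_set")) {
    ids <- x$ids
    own <- x$locus
  } else {
    ids <- as.character(x)
    own <- rep(NA_character_, length(ids))
  }
  gene <- own
  if (!is.null(locus_map) && length(locus_map)) {
    hit <- match(ids, names(locus_map))
    gene[!is.na(hit)] <- unname(locus_map[hit[!is.na(hit)]])
  }
  gene[is.na(gene)] <- ids[is.na(gene)]
  stats::setNames(gene, ids)
}

#' Write scoring and selection output files
#'
#' Writes the reference alignment (`<prefix>.aln`, aligned FASTA), the score
#' table (`<prefix>.scores`, or `<prefix>.DistanceScore` for distance-score
#' variants; id and score separated by a tab, 6 decimal places), and — only
#' when a locus map was used — `<prefix>_filtered.fasta` holding exactly one
#' record per locus, in input order, with original ids.
#'
#' @param fit an `isoform_selection` (see [select_isoforms()]).
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(fit, prefix) {
  stopifnot(inherits(fit, "isoform_selection"))
  out <- character(0)
  aln_path <- paste0(prefix, ".aln")
  write_fasta(fit$reference, aln_path)
  out <- c(out, aln_path)

  sc_path <- paste0(prefix,
                    if (fit$variant %in% c("ds", "ds_wot")) ".DistanceScore" else ".scores")
  con <- file(sc_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("%s\t%.6f", names(fit$scores), fit$scores), con)
  out <- c(out, sc_path)

  if (isTRUE(fit$had_locus_map)) {
    keep <- fit$input$ids %in% unname(fit$selection)
    flt <- seq_set(fit$input$ids[keep], fit$input$seqs[keep])
    f_path <- paste0(prefix, "_filtered.fasta")
    write_fasta(flt, f_path)
    out <- c(out, f_path)
  }
  invisible(out)
}
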