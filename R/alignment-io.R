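# Multiple-sequence alignment input/output and reference-column filtering.
#
# Alignments are stored as a character matrix (sequences x columns) over the
# 20 amino acids plus '-'. One row is the designated reference (the sequence
# of the structure under study); coupling analysis operates on the columns
# that are ungapped in that reference.

#' Read a FASTA/A2M alignment
#'
#' A2M insert states are normalised on read: '.' becomes '-' and lowercase
#' letters are uppercased. All sequences must have equal length after
#' normalisation.
#'
#' @param source Path to a FASTA/A2M file, or a character scalar of FASTA
#'   text (detected by a newline).
#' @param ref_id Identifier of the reference sequence; default is the first
#'   sequence.
#' @return Object of class `alignment`: list with `seqs` (character matrix,
#'   n_seqs x n_cols), `ids`, `ref_row`, `n_seqs`, `n_cols`.
#' @export
read_alignment <- function(source, ref_id = NULL) {
  stopifnot(is.character(source), length(source) == 1L)
  path <- source
  if (grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".fasta")
    writeLines(source, path)
    on.exit(unlink(path))
  }
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty alignment")
  seqs <- toupper(gsub(".", "-", as.character(ss), fixed = TRUE))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "))
  }
  if (lens[1L] == 0L) stop("empty alignment")
  m <- do.call(rbind, strsplit(seqs, ""))
  ids <- names(ss)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(m)))
  new_alignment(m, ids = ids, ref_row = if (is.null(ref_id)) 1L else {
    r <- match(ref_id, ids)
    if (is.na(r)) stop("reference id '", ref_id, "' not found")
    r
  })
}

#' Construct an alignment object from a character matrix
#'
#' @param seqs Character matrix, sequences in rows, one residue/gap per cell.
#' @param ids Sequence identifiers (default seq1..seqN).
#' @param ref_row Row index of the reference sequence.
#' @return An `alignment` object.
#' @export
new_alignment <- function(seqs, ids = NULL, ref_row = 1L) {
  seqs <- as.matrix(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(seqs)))
  stopifnot(length(ids) == nrow(seqs),
            ref_row >= 1L, ref_row <= nrow(seqs))
  dimnames(seqs) <- NULL
  structure(list(seqs = seqs, ids = ids, ref_row = as.integer(ref_row),
                 n_seqs = nrow(seqs), n_cols = ncol(seqs)),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("alignment:", x$n_seqs, "sequences x", x$n_cols,
      "columns | reference row", x$ref_row, "\n")
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param aln An `alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  ss <- Biostrings::BStringSet(apply(aln$seqs, 1L, paste, collapse = ""))
  names(ss) <- aln$ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Drop alignment columns gapped in the reference sequence
#'
#' Retains exactly the columns where the reference row is not a gap; all
#' sequences are kept regardless of their own gap content. Idempotent.
#'
#' @param aln An `alignment`.
#' @return Filtered `alignment` whose column count equals the ungapped length
#'   of the reference.
#' @export
filter_to_reference <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  keep <- aln$seqs[aln$ref_row, ] != "-"
  if (!any(keep)) stop("reference sequence is entirely gapped")
  new_alignment(aln$seqs[, keep, drop = FALSE], aln$ids, aln$ref_row)
}
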