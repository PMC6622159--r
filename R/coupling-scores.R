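# Coupling-score matrices: a mutual-information scorer with average product
# correction (APC) and sequence reweighting, plus readers/writers for
# externally computed score matrices (plain L x L text, or i-j-score edge
# lists). The MI+APC scorer is a transparent local statistic, not a global
# inverse-model method; it provides the coupling-score interface for
# synthetic-data experiments and for any alignment a user supplies.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.NSTATE <- 21L # 20 amino acids + gap

#' Encode an alignment as integer states
#'
#' States 1..20 are the amino acids in alphabetical one-letter order; state
#' 21 is the gap. Ambiguity codes (B, Z, X) and any other unexpected symbol
#' are mapped to the gap state by default.
#'
#' @param aln An `alignment`.
#' @param ambiguous `"gap"` (default) maps B/Z/X and unknowns to the gap
#'   state; `"error"` stops on any symbol outside the 20 + gap alphabet.
#' @return Integer matrix n_seqs x n_cols with values in 1..21.
#' @export
encode_alignment <- function(aln, ambiguous = c("gap", "error")) {
  ambiguous <- match.arg(ambiguous)
  code <- match(aln$seqs, .AA20)
  unknown <- is.na(code) & aln$seqs != "-"
  if (any(unknown) && ambiguous == "error") {
    stop("unexpected symbol(s): ", paste(unique(aln$seqs[unknown]), collapse = ", "))
  }
  code[is.na(code)] <- .NSTATE
  matrix(code, nrow(aln$seqs), ncol(aln$seqs))
}

#' Sequence weights by local identity clustering
#'
#' The weight of a sequence is 1 / (number of sequences, itself included,
#' whose fractional identity to it is at least `identity_threshold`). The
#' sum of weights is the effective number of sequences.
#'
#' @param aln An `alignment` (typically already filtered to the reference).
#' @param identity_threshold Fractional identity at or above which two
#'   sequences count as neighbours (default 0.8).
#' @return Numeric vector of per-sequence weights, each in (0, 1].
#' @export
sequence_weights <- function(aln, identity_threshold = 0.8) {
  A <- encode_alignment(aln)
  N <- nrow(A)
  Lc <- ncol(A)
  X <- Matrix::sparseMatrix(
    i = rep(seq_len(N), Lc),
    j = as.vector((col(A) - 1L) * .NSTATE + A),
    x = 1,
    dims = c(N, Lc * .NSTATE)
  )
  thr <- identity_threshold * Lc
  nnb <- integer(N)
  block <- max(1L, floor(2e7 / N))
  for (s in seq(1L, N, by = block)) {
    e <- min(N, s + block - 1L)
    S <- as.matrix(Matrix::tcrossprod(X[s:e, , drop = FALSE], X))
    nnb[s:e] <- rowSums(S >= thr)
  }
  1 / nnb
}

#' Mutual-information coupling scores with average product correction
#'
#' Computes weighted single-site and pair frequencies over a 21-state
#' alphabet (20 amino acids + gap) with a pseudocount, the mutual information
#' `MI_ij = sum_ab f_ij(a,b) log( f_ij(a,b) / (f_i(a) f_j(b)) )` for every
#' column pair, and the APC-corrected score
#' `S_ij = MI_ij - mean_i(MI) * mean_j(MI) / mean(MI)` where the means run
#' over off-diagonal entries.
#'
#' The pair pseudocount is `pseudocount / 21` per cell so that pair and
#' single frequencies share the marginal normaliser. `pseudocount = 0` gives
#' the plug-in MI estimator (empty cells contribute zero).
#'
#' @param aln An `alignment`, already filtered to the reference columns.
#' @param pseudocount Pseudocount per state per column (default 0.5).
#' @param weights Optional per-sequence weights (e.g. from
#'   [sequence_weights()]); default is unit weights.
#' @param treat_gaps `"state"` (default) counts the gap as a 21st state;
#'   `"exclude"` drops, per column pair, the observations where either column
#'   is a gap (counts are renormalised per pair).
#' @param bias_correction If `TRUE`, applies the Miller-Madow correction
#'   `(m_ij - m_i - m_j + 1) / (2 N_eff)` to each pair's MI, where `m` counts
#'   the occupied cells of the pair table and the two marginals. Intended for
#'   comparing estimates against analytic MI values with `pseudocount = 0`;
#'   default `FALSE`.
#' @return Object of class `coupling_matrix`: list with `L`, `s` (APC-
#'   corrected symmetric score matrix, zero diagonal) and `mi` (raw MI
#'   matrix).
#' @export
mi_apc <- function(aln, pseudocount = 0.5, weights = NULL,
                   treat_gaps = c("state", "exclude"),
                   bias_correction = FALSE) {
  treat_gaps <- match.arg(treat_gaps)
  stopifnot(inherits(aln, "alignment"))
  if (aln$n_seqs < 2L) stop("alignment has fewer than 2 sequences")
  A <- encode_alignment(aln)
  N <- nrow(A)
  Lc <- ncol(A)
  if (is.null(weights)) weights <- rep(1, N)
  stopifnot(length(weights) == N, all(weights > 0))

  X <- Matrix::sparseMatrix(
    i = rep(seq_len(N), Lc),
    j = as.vector((col(A) - 1L) * .NSTATE + A),
    x = 1,
    dims = c(N, Lc * .NSTATE)
  )
  WX <- X * weights # row scaling (sparse, column-major recycling over rows)
  C <- as.matrix(Matrix::crossprod(X, WX)) # (Lc*21) x (Lc*21) weighted counts

  q <- .NSTATE
  lam <- pseudocount
  mi <- matrix(0, Lc, Lc)
  blocks <- lapply(seq_len(Lc), function(i) ((i - 1L) * q + 1L):(i * q))
  singles <- lapply(seq_len(Lc), function(i) diag(C[blocks[[i]], blocks[[i]]]))
  neff <- sum(weights)
  for (i in seq_len(Lc - 1L)) {
    bi <- blocks[[i]]
    for (j in (i + 1L):Lc) {
      cij <- C[bi, blocks[[j]]]
      ci <- singles[[i]]
      cj <- singles[[j]]
      nij <- neff
      if (treat_gaps == "exclude") {
        ci <- ci - cij[, q]
        cj <- cj - cij[q, ]
        cij <- cij[-q, -q, drop = FALSE]
        ci <- ci[-q]
        cj <- cj[-q]
        nij <- sum(cij)
        if (nij <= 0) next
      }
      qq <- length(ci)
      fij <- (cij + lam / qq) / (qq * lam + nij)
      fi <- (ci + lam) / (qq * lam + nij)
      fj <- (cj + lam) / (qq * lam + nij)
      pos <- fij > 0
      ratio <- fij / outer(fi, fj)
      m <- sum(fij[pos] * log(ratio[pos]))
      if (bias_correction) {
        m <- m - (sum(fij > 0) - sum(fi > 0) - sum(fj > 0) + 1) / (2 * nij)
      }
      mi[i, j] <- m
      mi[j, i] <- m
    }
  }
  s <- apc_correct(mi)
  structure(list(L = Lc, s = s, mi = mi), class = "coupling_matrix")
}

#' Average product correction of a symmetric score matrix
#'
#' Subtracts `mean_i * mean_j / grand_mean` from each off-diagonal entry,
#' where the means are over off-diagonal entries only.
#'
#' @param m Symmetric numeric matrix.
#' @return Corrected matrix, symmetric, zero diagonal.
#' @export
apc_correct <- function(m) {
  L <- nrow(m)
  diag(m) <- NA_real_
  rmean <- rowMeans(m, na.rm = TRUE)
  gmean <- mean(m[upper.tri(m)])
  s <- if (isTRUE(all.equal(gmean, 0))) {
    m
  } else {
    m - outer(rmean, rmean) / gmean
  }
  diag(s) <- 0
  s
}

#' Wrap a numeric matrix as a coupling matrix
#'
#' Asymmetric input is symmetrised by the elementwise maximum.
#'
#' @param s Square numeric matrix of scores.
#' @return A `coupling_matrix`.
#' @export
as_coupling_matrix <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) != ncol(s)) stop("non-square matrix (", nrow(s), " x ", ncol(s), ")")
  if (any(!is.finite(s[row(s) != col(s)]))) stop("non-finite off-diagonal scores")
  s <- pmax(s, t(s))
  dimnames(s) <- NULL
  structure(list(L = nrow(s), s = s, mi = NULL), class = "coupling_matrix")
}

#' Read a plain-text L x L coupling matrix
#'
#' Whitespace-separated floats, one matrix row per line (the output dialect
#' of common coupling inference tools). Asymmetric input is symmetrised by
#' the elementwise maximum.
#'
#' @param path Path to the matrix file.
#' @return A `coupling_matrix`.
#' @export
read_coupling_matrix <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  as_coupling_matrix(m)
}

#' Write a coupling matrix as plain L x L text
#'
#' @param cm A `coupling_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coupling_matrix <- function(cm, path) {
  write.table(format(cm$s, digits = 9, trim = TRUE, scientific = TRUE),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an i-j-score edge list as a coupling matrix
#'
#' Three whitespace-separated columns: residue indices (1-based) and a score.
#' Pairs absent from the file score 0.
#'
#' @param path Path to the edge-list file.
#' @param L Chain length.
#' @return A `coupling_matrix`.
#' @export
read_edge_list <- function(path, L) {
  e <- read.table(path, header = FALSE)
  if (ncol(e) < 3L) stop("edge list needs columns: i j score")
  if (any(e[[1]] < 1 | e[[1]] > L | e[[2]] < 1 | e[[2]] > L)) {
    stop("edge list indices outside 1..", L)
  }
  s <- matrix(0, L, L)
  s[cbind(e[[1]], e[[2]])] <- e[[3]]
  as_coupling_matrix(s)
}

#' @export
print.coupling_matrix <- function(x, ...) {
  cat("coupling_matrix:", x$L, "x", x$L,
      if (!is.null(x$mi)) "(MI + APC)" else "(external scores)", "\n")
  invisible(x)
}

#' Rank eligible residue pairs by coupling score
#'
#' Restricts to pairs with chain separation at least `min_sep` and sorts by
#' score descending; ties are broken deterministically by (i, j).
#'
#' @param cm A `coupling_matrix`.
#' @param min_sep Minimum chain separation (default 12).
#' @return Object of class `ranked_pairs`: data frame with columns `i`, `j`,
#'   `score`, plus attributes `L` and `min_sep`.
#' @export
rank_pairs <- function(cm, min_sep = 12) {
  stopifnot(inherits(cm, "coupling_matrix"), min_sep >= 1)
  ep <- eligible_pairs(cm$L, min_sep)
  sc <- cm$s[ep]
  ord <- order(-sc, ep[, 1L], ep[, 2L])
  out <- data.frame(i = ep[ord, 1L], j = ep[ord, 2L], score = sc[ord])
  attr(out, "L") <- cm$L
  attr(out, "min_sep") <- min_sep
  class(out) <- c("ranked_pairs", "data.frame")
  out
}
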