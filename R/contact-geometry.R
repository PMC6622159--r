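# Residue-residue distance matrices under five reference methods, and contact
# maps derived from them by fixed or count-matched cutoffs.
#
# Methods:
#   CA        - distance between CA atoms
#   CB        - distance between CB atoms (glycine: CA)
#   SC_CENTER - distance between side-chain geometric centers (unweighted mean
#               of non-backbone heavy atoms, CB included; glycine: CA)
#   MIN_ALL   - minimum distance over all heavy-atom pairs
#   MIN_SC    - minimum distance over side-chain heavy-atom pairs
#               (glycine contributes its CA)

.METHODS <- c("CA", "CB", "SC_CENTER", "MIN_ALL", "MIN_SC")

.check_method <- function(method) {
  if (!method %in% .METHODS) {
    stop("unknown reference method '", method, "'; expected one of ",
         paste(.METHODS, collapse = ", "))
  }
  method
}

#' Reference points of all residues under a point-based method
#'
#' @param s A `protein_structure`.
#' @param method `"CA"`, `"CB"` or `"SC_CENTER"`. Glycine always falls back
#'   to its CA atom.
#' @param missing_sidechain Policy for non-glycine residues lacking the
#'   required side-chain atoms; see [atom_subset()].
#' @return Numeric L x 3 matrix of coordinates (angstrom).
#' @export
reference_points <- function(s, method = c("CA", "CB", "SC_CENTER"),
                             missing_sidechain = c("error", "ca")) {
  method <- match.arg(method)
  missing_sidechain <- match.arg(missing_sidechain)
  at <- s$atoms
  P <- matrix(NA_real_, s$L, 3L)
  ca <- at[at$name == "CA", , drop = FALSE]
  P[ca$res, ] <- as.matrix(ca[, c("x", "y", "z")])
  if (method == "CA") return(P)
  gly <- strsplit(s$sequence, "")[[1]] == "G"
  if (method == "CB") {
    cb <- at[at$name == "CB", , drop = FALSE]
    Q <- matrix(NA_real_, s$L, 3L)
    Q[cb$res, ] <- as.matrix(cb[, c("x", "y", "z")])
    miss <- is.na(Q[, 1L]) & !gly
    if (any(miss)) {
      if (missing_sidechain == "error") {
        stop("residue(s) missing CB atom: ",
             paste(which(miss), collapse = ", "))
      }
      warning("residue(s) missing CB, using CA: ",
              paste(which(miss), collapse = ", "))
    }
    use_ca <- gly | miss
    Q[use_ca, ] <- P[use_ca, ]
    return(Q)
  }
  # SC_CENTER
  Q <- P # glycine (and any permitted fallback) stays at CA
  for (i in seq_len(s$L)) {
    if (gly[i]) next
    sc <- atom_subset(s, i, "side_chain", missing_sidechain)
    Q[i, ] <- colMeans(as.matrix(sc[, c("x", "y", "z")]))
  }
  Q
}

#' Reference point of a single residue
#'
#' @inheritParams reference_points
#' @param i Residue index.
#' @return Numeric 3-vector.
#' @export
reference_point <- function(s, i, method = c("CA", "CB", "SC_CENTER"),
                            missing_sidechain = c("error", "ca")) {
  reference_points(s, match.arg(method), missing_sidechain)[i, ]
}

#' Distance between two residues under a reference method
#'
#' @param s A `protein_structure`.
#' @param i,j Residue indices.
#' @param method One of `"CA"`, `"CB"`, `"SC_CENTER"`, `"MIN_ALL"`,
#'   `"MIN_SC"`.
#' @param missing_sidechain See [atom_subset()].
#' @return Distance in angstrom.
#' @export
pair_distance <- function(s, i, j, method,
                          missing_sidechain = c("error", "ca")) {
  .check_method(method)
  missing_sidechain <- match.arg(missing_sidechain)
  if (method %in% c("CA", "CB", "SC_CENTER")) {
    P <- reference_points(s, method, missing_sidechain)
    return(sqrt(sum((P[i, ] - P[j, ])^2)))
  }
  subset <- if (method == "MIN_ALL") "all_heavy" else "side_chain"
  A <- as.matrix(atom_subset(s, i, subset, missing_sidechain)[, c("x", "y", "z")])
  B <- as.matrix(atom_subset(s, j, subset, missing_sidechain)[, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Residue-residue distance matrix
#'
#' @inheritParams pair_distance
#' @return An object of class `distance_matrix`: list with `method`, `L` and
#'   `d`, a symmetric L x L matrix of distances in angstrom with zero
#'   diagonal.
#' @export
distance_matrix <- function(s, method, missing_sidechain = c("error", "ca")) {
  .check_method(method)
  missing_sidechain <- match.arg(missing_sidechain)
  L <- s$L
  if (method %in% c("CA", "CB", "SC_CENTER")) {
    P <- reference_points(s, method, missing_sidechain)
    d <- as.matrix(dist(P))
  } else {
    at <- s$atoms
    if (method == "MIN_SC") {
      keep <- logical(nrow(at))
      gly <- at$aa == "G"
      keep[!at$name %in% .BACKBONE] <- TRUE
      keep[gly & at$name == "CA"] <- TRUE
      # enforce missing-side-chain policy per residue
      have <- tapply(keep, at$res, any)
      if (any(!have)) {
        idx <- as.integer(names(have))[!have]
        if (missing_sidechain == "error") {
          stop("residue(s) with no side-chain heavy atoms: ",
               paste(idx, collapse = ", "))
        }
        warning("residue(s) with no side-chain atoms, using CA: ",
                paste(idx, collapse = ", "))
        keep[at$res %in% idx & at$name == "CA"] <- TRUE
      }
      at <- at[keep, , drop = FALSE]
    }
    A <- as.matrix(at[, c("x", "y", "z")])
    DA <- as.matrix(dist(A))
    idx <- split(seq_len(nrow(at)), at$res)
    d <- matrix(0, L, L)
    for (i in seq_len(L - 1L)) {
      ii <- idx[[as.character(i)]]
      for (j in (i + 1L):L) {
        jj <- idx[[as.character(j)]]
        m <- min(DA[ii, jj])
        d[i, j] <- m
        d[j, i] <- m
      }
    }
  }
  dimnames(d) <- NULL
  diag(d) <- 0
  structure(list(method = method, L = L, d = d), class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("distance_matrix:", x$method, "|", x$L, "residues\n")
  invisible(x)
}

#' All residue pairs at or beyond a minimum chain separation
#'
#' A pair (i, j), i < j, is eligible when j - i >= min_sep; with the default
#' of 12 the pair (1, 13) is the closest eligible pair.
#'
#' @param L Chain length.
#' @param min_sep Minimum chain separation in residues.
#' @return Two-column integer matrix (i, j), ordered by (i, j).
#' @export
eligible_pairs <- function(L, min_sep = 12) {
  stopifnot(min_sep >= 1)
  if (L <= min_sep) return(matrix(integer(0), 0L, 2L,
                                  dimnames = list(NULL, c("i", "j"))))
  i <- rep.int(seq_len(L - min_sep),
               times = L - min_sep - seq_len(L - min_sep) + 1L)
  j <- unlist(lapply(seq_len(L - min_sep), function(a) (a + min_sep):L))
  cbind(i = i, j = j)
}

.pair_key <- function(i, j, L) (i - 1) * L + j

.new_contact_map <- function(method, min_sep, cutoff, pairs, L) {
  structure(list(method = method, min_sep = min_sep, cutoff = cutoff,
                 pairs = pairs, L = L),
            class = "contact_map")
}

#' Contact map at a fixed distance cutoff
#'
#' A pair is a contact when its distance is at most `cutoff` (inclusive
#' boundary) and its chain separation is at least `min_sep`.
#'
#' @param dm A `distance_matrix`.
#' @param cutoff Distance cutoff in angstrom (default 8, the conventional
#'   CA-based definition).
#' @param min_sep Minimum chain separation (default 12).
#' @return An object of class `contact_map`: list with `method`, `min_sep`,
#'   `cutoff`, `L`, and `pairs`, a data frame with columns `i`, `j`, `d`
#'   (i < j, ordered by (i, j)).
#' @export
contacts_fixed <- function(dm, cutoff = 8, min_sep = 12) {
  stopifnot(inherits(dm, "distance_matrix"), cutoff > 0, min_sep >= 1)
  ep <- eligible_pairs(dm$L, min_sep)
  d <- dm$d[ep]
  keep <- d <= cutoff
  pairs <- data.frame(i = ep[keep, 1L], j = ep[keep, 2L], d = d[keep])
  .new_contact_map(dm$method, min_sep, cutoff, pairs, dm$L)
}

#' Contact map matched to a target contact count
#'
#' Selects exactly `n` eligible pairs with the shortest distances. The
#' effective cutoff is the n-th smallest eligible distance; ties at that
#' distance are broken deterministically by (distance, i, j) order.
#'
#' @param dm A `distance_matrix`.
#' @param n Number of contacts to select (typically the count from the
#'   CA-based 8-angstrom definition).
#' @param min_sep Minimum chain separation (default 12).
#' @return An object of class `matched_cutoff`: list with `contact_map`,
#'   `effective_cutoff` and `n`.
#' @export
contacts_matched <- function(dm, n, min_sep = 12) {
  stopifnot(inherits(dm, "distance_matrix"), min_sep >= 1)
  ep <- eligible_pairs(dm$L, min_sep)
  if (n > nrow(ep)) {
    stop("n = ", n, " exceeds the ", nrow(ep), " eligible pairs")
  }
  stopifnot(n >= 1)
  d <- dm$d[ep]
  ord <- order(d, ep[, 1L], ep[, 2L])
  take <- ord[seq_len(n)]
  pairs <- data.frame(i = ep[take, 1L], j = ep[take, 2L], d = d[take])
  cutoff <- pairs$d[n]
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    contact_map = .new_contact_map(dm$method, min_sep, cutoff, pairs, dm$L),
    effective_cutoff = cutoff,
    n = n
  ), class = "matched_cutoff")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", x$method, "|", nrow(x$pairs), "contacts | cutoff",
      format(x$cutoff, digits = 4), "A | min_sep", x$min_sep, "\n")
  invisible(x)
}

#' Fraction of contacts shared by two count-matched maps
#'
#' Both maps must hold the same number of contacts (the comparison is
#' count-matched by design) over the same chain and separation rule.
#'
#' @param a,b `contact_map` objects with equal contact counts.
#' @return Fraction in 0..1 of pairs present in both maps.
#' @export
overlap_fraction <- function(a, b) {
  stopifnot(inherits(a, "contact_map"), inherits(b, "contact_map"))
  if (a$L != b$L || a$min_sep != b$min_sep) {
    stop("contact maps differ in L or min_sep")
  }
  if (nrow(a$pairs) != nrow(b$pairs)) {
    stop("contact counts differ (", nrow(a$pairs), " vs ", nrow(b$pairs),
         "); overlap is defined for count-matched maps")
  }
  if (nrow(a$pairs) == 0L) stop("empty contact maps")
  ka <- .pair_key(a$pairs$i, a$pairs$j, a$L)
  kb <- .pair_key(b$pairs$i, b$pairs$j, b$L)
  sum(ka %in% kb) / length(ka)
}

#' Spearman correlation between two distance matrices
#'
#' Rank correlation over the vector of eligible-pair distances.
#'
#' @param a,b `distance_matrix` objects over the same chain.
#' @param min_sep Minimum chain separation (default 12).
#' @return Spearman's rho.
#' @export
distance_correlation <- function(a, b, min_sep = 12) {
  stopifnot(inherits(a, "distance_matrix"), inherits(b, "distance_matrix"))
  if (a$L != b$L) stop("distance matrices differ in L")
  ep <- eligible_pairs(a$L, min_sep)
  if (nrow(ep) < 3L) stop("fewer than 3 eligible pairs")
  cor(a$d[ep], b$d[ep], method = "spearman")
}

#' Write a contact map to a text file
#'
#' The flat format is one line per contact: `i j distance method` (1-based,
#' i < j). The CASP-RR-style format is `i j 0 cutoff confidence` with
#' confidence 1.
#'
#' @param cm A `contact_map`.
#' @param path Output path.
#' @param format `"flat"` or `"casprr"`.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path, format = c("flat", "casprr")) {
  format <- match.arg(format)
  p <- cm$pairs
  lines <- if (format == "flat") {
    sprintf("%d %d %.4f %s", p$i, p$j, p$d, cm$method)
  } else {
    sprintf("%d %d 0 %.2f %.2f", p$i, p$j, cm$cutoff, 1)
  }
  writeLines(lines, path)
  invisible(path)
}
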