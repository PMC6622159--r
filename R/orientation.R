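# Side-chain orientation of residue pairs.
#
# For a pair (a, b): draw the vector from CA_a to the side-chain center of a,
# and the vector from CA_a to CA_b. If the angle between them is strictly
# less than pi/2 (positive dot product), the side chain of a points toward b.
# Repeating with b as the reference classifies the pair as
#   both_toward : both side chains point toward the partner (type i)
#   mixed       : exactly one does (type ii)
#   both_away   : neither does (type iii)
#
# Glycine's side-chain center coincides with its CA, giving a zero-length
# side-chain vector with an undefined angle: its dot product is 0, which
# fails the strict test, so a glycine side is classified as not pointing
# toward its partner. Summaries can instead exclude glycine-containing pairs.

.ORIENT_LEVELS <- c("both_toward", "mixed", "both_away")

.orientation_geometry <- function(s) {
  ca <- reference_points(s, "CA")
  sc <- reference_points(s, "SC_CENTER")
  list(ca = ca, v = sc - ca)
}

#' Does the side chain of residue `a` point toward residue `b`?
#'
#' @param s A `protein_structure`.
#' @param a,b Distinct residue indices.
#' @return `TRUE` iff the angle between CA_a -> side-chain-center_a and
#'   CA_a -> CA_b is strictly less than pi/2.
#' @export
points_toward <- function(s, a, b) {
  stopifnot(a != b)
  g <- .orientation_geometry(s)
  sum(g$v[a, ] * (g$ca[b, ] - g$ca[a, ])) > 0
}

#' Classify the side-chain orientation of one residue pair
#'
#' @inheritParams points_toward
#' @return One of `"both_toward"`, `"mixed"`, `"both_away"`. Symmetric in
#'   (a, b).
#' @export
classify_pair <- function(s, a, b) {
  stopifnot(a != b)
  ab <- points_toward(s, a, b)
  ba <- points_toward(s, b, a)
  if (ab && ba) "both_toward" else if (!ab && !ba) "both_away" else "mixed"
}

#' Classify many residue pairs at once
#'
#' @param s A `protein_structure`.
#' @param pairs Two-column matrix or data frame of residue indices (i, j).
#' @return Factor with levels `both_toward`, `mixed`, `both_away`.
#' @export
classify_pairs <- function(s, pairs) {
  pairs <- as.matrix(pairs[, 1:2, drop = FALSE])
  g <- .orientation_geometry(s)
  a <- pairs[, 1L]
  b <- pairs[, 2L]
  u <- g$ca[b, , drop = FALSE] - g$ca[a, , drop = FALSE]
  ab <- rowSums(g$v[a, , drop = FALSE] * u) > 0
  ba <- rowSums(g$v[b, , drop = FALSE] * -u) > 0
  out <- ifelse(ab & ba, "both_toward", ifelse(!ab & !ba, "both_away", "mixed"))
  factor(out, levels = .ORIENT_LEVELS)
}

#' Orientation-type composition of a pair set
#'
#' Callers typically pass all eligible pairs, the pairs of a contact map, or
#' the top-ranked coupling pairs.
#'
#' @param s A `protein_structure`.
#' @param pairs Two-column matrix/data frame of residue pairs; a
#'   `contact_map` is also accepted.
#' @param exclude_glycine If `TRUE`, pairs containing a glycine are dropped
#'   before summarising (glycine orientation is a convention, not a
#'   measurement).
#' @return Object of class `orientation_summary`: list with `fractions`
#'   (named numeric over the three types, summing to 1) and `n_pairs`.
#' @export
orientation_summary <- function(s, pairs, exclude_glycine = FALSE) {
  if (inherits(pairs, "contact_map")) pairs <- pairs$pairs
  pairs <- as.matrix(pairs[, 1:2, drop = FALSE])
  if (nrow(pairs) == 0L) stop("empty pair set")
  if (exclude_glycine) {
    gly <- which(strsplit(s$sequence, "")[[1]] == "G")
    keep <- !(pairs[, 1L] %in% gly | pairs[, 2L] %in% gly)
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L) stop("no pairs left after excluding glycine")
  }
  cls <- classify_pairs(s, pairs)
  fr <- as.numeric(table(cls)) / length(cls)
  names(fr) <- .ORIENT_LEVELS
  structure(list(fractions = fr, n_pairs = length(cls)),
            class = "orientation_summary")
}

#' @export
print.orientation_summary <- function(x, ...) {
  cat("orientation_summary over", x$n_pairs, "pairs:\n")
  print(round(x$fractions, 3))
  invisible(x)
}
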