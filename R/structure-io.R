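# Reading, cleaning and representing single-chain protein structures.
#
# A cleaned structure holds only heavy atoms of the 20 standard amino acids,
# one alternate location per atom, residues renumbered 1..L. All downstream
# geometry (distance matrices, side-chain centers, orientations) assumes this
# representation.

#' @importFrom stats cor dist median wilcox.test
#' @importFrom utils read.table write.csv
NULL

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.AA1TO3 <- stats::setNames(names(.AA3TO1), unname(.AA3TO1))

# Backbone atom names; OXT is the C-terminal carboxyl oxygen and belongs to
# the backbone. CB is deliberately NOT here: it counts as side chain.
.BACKBONE <- c("N", "CA", "C", "O", "OXT")

.element_of <- function(name, elesy) {
  el <- toupper(trimws(elesy))
  miss <- is.na(el) | el == ""
  if (any(miss)) {
    # derive from the atom name: strip digits/primes, take the first letter
    nm <- gsub("[0-9']", "", toupper(name[miss]))
    el[miss] <- substr(nm, 1, 1)
  }
  el
}

#' Load and clean a single protein chain from a PDB file
#'
#' Reads ATOM records for one chain, drops HETATM records and hydrogens,
#' resolves alternate locations (highest occupancy wins, ties broken by
#' altloc identifier), verifies that every residue is one of the 20 standard
#' amino acids and carries a CA atom, and renumbers residues consecutively
#' from 1.
#'
#' @param pdb Path to a PDB file, or a character scalar containing PDB-format
#'   text (detected by the presence of a newline).
#' @param chain Chain identifier to extract. Default `NULL` selects the chain
#'   of the first ATOM record.
#' @param map_nonstandard If `TRUE`, selenomethionine (MSE) is mapped to MET
#'   and selenocysteine (SEC) to CYS before the standard-residue check. Any
#'   other non-standard residue is always a hard error.
#' @return An object of class `protein_structure`: a list with elements
#'   `chain_id`, `atoms` (data frame with columns `res`, `aa`, `name`,
#'   `element`, `x`, `y`, `z`), `sequence` (one-letter string of length `L`)
#'   and `L` (number of residues).
#' @examples
#' pdb <- system.file("extdata", "toy_dipeptide.pdb", package = "eccontacts")
#' s <- load_structure(pdb)
#' s$L
#' @export
load_structure <- function(pdb, chain = NULL, map_nonstandard = FALSE) {
  stopifnot(is.character(pdb), length(pdb) == 1L)
  path <- pdb
  if (grepl("\n", pdb, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    writeLines(pdb, path)
    on.exit(unlink(path))
  }
  p <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE, multi = FALSE)
  a <- p$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("no ATOM records found in input")

  if (is.null(chain)) chain <- a$chain[1L]
  a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0L) stop("chain '", chain, "' not found")

  a$element <- .element_of(a$elety, a$elesy)
  a <- a[!a$element %in% c("H", "D"), , drop = FALSE]
  if (nrow(a) == 0L) stop("chain '", chain, "' contains no heavy atoms")

  # residue key preserves file order and insertion codes
  ins <- ifelse(is.na(a$insert), "", a$insert)
  rkey <- paste(a$resno, ins, sep = "_")
  a$rid <- match(rkey, unique(rkey))

  # alternate locations: keep highest occupancy, ties by altloc order
  alt <- ifelse(is.na(a$alt), "", a$alt)
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(a$rid, a$elety, -occ, alt)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$rid, a$elety)), , drop = FALSE]
  a <- a[order(a$rid, a$eleno), , drop = FALSE]

  resid3 <- toupper(a$resid)
  if (map_nonstandard) {
    resid3[resid3 == "MSE"] <- "MET"
    resid3[resid3 == "SEC"] <- "CYS"
    a$elety[a$elety == "SE" & resid3 %in% c("MET", "CYS")] <-
      ifelse(resid3[a$elety == "SE" & resid3 %in% c("MET", "CYS")] == "MET",
             "SD", "SG")
  }
  bad <- !resid3 %in% names(.AA3TO1)
  if (any(bad)) {
    stop("non-standard residue(s): ",
         paste(unique(resid3[bad]), collapse = ", "),
         " (set map_nonstandard = TRUE to map MSE/SEC)")
  }

  atoms <- data.frame(
    res = a$rid,
    aa = unname(.AA3TO1[resid3]),
    name = a$elety,
    element = a$element,
    x = a$x, y = a$y, z = a$z,
    stringsAsFactors = FALSE
  )
  # per-residue amino-acid consistency and CA presence
  L <- max(atoms$res)
  aa_by_res <- vapply(split(atoms$aa, atoms$res), function(v) v[1L], "")
  has_ca <- vapply(split(atoms$name, atoms$res),
                   function(v) "CA" %in% v, NA)
  if (!all(has_ca)) {
    stop("residue(s) without a CA atom: ",
         paste(which(!has_ca), collapse = ", "))
  }
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in input")
  }

  out <- structure(list(
    chain_id = chain,
    atoms = atoms,
    sequence = paste(aa_by_res, collapse = ""),
    L = L
  ), class = "protein_structure")
  out
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("protein_structure: chain", x$chain_id, "|", x$L, "residues |",
      nrow(x$atoms), "heavy atoms\n")
  cat("sequence:", if (nchar(x$sequence) > 60)
    paste0(substr(x$sequence, 1, 60), "...") else x$sequence, "\n")
  invisible(x)
}

#' Extract an atom subset for one residue
#'
#' Partitions a residue's heavy atoms into backbone (N, CA, C, O, OXT) and
#' side chain (everything else, so CB is side chain). Glycine has no
#' side-chain heavy atoms; by convention its CA stands in as the side chain,
#' so for glycine `side_chain` returns the CA atom (which therefore appears
#' in both subsets).
#'
#' @param s A `protein_structure`.
#' @param i Residue index (1..L).
#' @param which One of `"all_heavy"`, `"backbone"`, `"side_chain"`.
#' @param missing_sidechain Policy when a non-glycine residue has no
#'   side-chain heavy atoms: `"error"` (default; the structure was not
#'   repaired) or `"ca"` (fall back to the CA atom, with a warning).
#' @return Data frame of atom rows (columns as in `s$atoms`).
#' @export
atom_subset <- function(s, i,
                        which = c("all_heavy", "backbone", "side_chain"),
                        missing_sidechain = c("error", "ca")) {
  which <- match.arg(which)
  missing_sidechain <- match.arg(missing_sidechain)
  at <- s$atoms[s$atoms$res == i, , drop = FALSE]
  if (nrow(at) == 0L) stop("no residue with index ", i)
  if (which == "all_heavy") return(at)
  bb <- at$name %in% .BACKBONE
  if (which == "backbone") return(at[bb, , drop = FALSE])
  sc <- at[!bb, , drop = FALSE]
  if (nrow(sc) == 0L) {
    if (at$aa[1L] == "G") {
      return(at[at$name == "CA", , drop = FALSE])
    }
    if (missing_sidechain == "ca") {
      warning("residue ", i, " (", at$aa[1L],
              ") has no side-chain atoms; falling back to CA")
      return(at[at$name == "CA", , drop = FALSE])
    }
    stop("residue ", i, " (", at$aa[1L], ") has no side-chain heavy atoms")
  }
  sc
}

#' Write a cleaned structure back to PDB format
#'
#' Emits standard ATOM lines with the structure's 1-based residue numbering.
#'
#' @param s A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  at <- s$atoms
  xyz <- as.vector(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path,
    xyz = xyz,
    resno = at$res,
    resid = unname(.AA1TO3[at$aa]),
    eleno = seq_len(nrow(at)),
    elety = at$name,
    chain = rep(s$chain_id, nrow(at)),
    o = rep(1, nrow(at)),
    b = rep(0, nrow(at)),
    elesy = at$element
  )
  invisible(path)
}
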