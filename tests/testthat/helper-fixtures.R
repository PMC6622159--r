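# Fixture builders shared across the test files. Everything is constructed
# in code; no binary data.

# one PDB ATOM line with correct fixed-width columns
pdb_line <- function(serial, name, resn, resi, x, y, z,
                     element = "C", altloc = " ", occ = 1, chain = "A") {
  nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, altloc, resn, chain, resi, x, y, z, occ, 0, element)
}

# minimal GLY + ALA dipeptide as PDB text
dipeptide_pdb <- function(extra_lines = character()) {
  lines <- c(
    pdb_line(1, "N",  "GLY", 1, 0.000, 0.000, 0.000, "N"),
    pdb_line(2, "CA", "GLY", 1, 1.458, 0.000, 0.000),
    pdb_line(3, "C",  "GLY", 1, 2.009, 1.420, 0.000),
    pdb_line(4, "O",  "GLY", 1, 1.251, 2.390, 0.000, "O"),
    pdb_line(5, "N",  "ALA", 2, 3.332, 1.536, 0.000, "N"),
    pdb_line(6, "CA", "ALA", 2, 3.988, 2.839, 0.000),
    pdb_line(7, "C",  "ALA", 2, 5.504, 2.693, 0.000),
    pdb_line(8, "O",  "ALA", 2, 6.030, 1.581, 0.000, "O"),
    pdb_line(9, "CB", "ALA", 2, 3.542, 3.659, 1.211),
    extra_lines,
    "END"
  )
  paste(lines, collapse = "\n")
}

# build a protein_structure directly: residues = list of
# list(aa = "A", atoms = data.frame(name, x, y, z[, element]))
make_structure <- function(residues, chain = "A") {
  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    r <- residues[[i]]
    a <- r$atoms
    if (is.null(a$element)) a$element <- "C"
    data.frame(res = i, aa = r$aa, name = a$name, element = a$element,
               x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
  }))
  structure(list(
    chain_id = chain,
    atoms = atoms,
    sequence = paste(vapply(residues, function(r) r$aa, ""), collapse = ""),
    L = length(residues)
  ), class = "protein_structure")
}

# a glycine residue (CA only) at a position
gly_at <- function(xyz) {
  list(aa = "G", atoms = data.frame(name = "CA",
                                    x = xyz[1], y = xyz[2], z = xyz[3]))
}

# an alanine-like residue with CA at `ca` and a single side-chain atom at `cb`
ala_at <- function(ca, cb) {
  list(aa = "A", atoms = data.frame(name = c("CA", "CB"),
                                    x = c(ca[1], cb[1]),
                                    y = c(ca[2], cb[2]),
                                    z = c(ca[3], cb[3])))
}

# chain of glycines spaced along the x axis (distance-based tests)
gly_chain <- function(xs) {
  make_structure(lapply(xs, function(x) gly_at(c(x, 0, 0))))
}

# wrap a raw symmetric matrix as a distance_matrix object
as_dm <- function(d, method = "CA") {
  structure(list(method = method, L = nrow(d), d = d),
            class = "distance_matrix")
}

# random residues with `k` side-chain atoms in a box, for brute-force checks
random_structure <- function(L, k = 3, seed = 1, spread = 20) {
  set.seed(seed)
  make_structure(lapply(seq_len(L), function(i) {
    ca <- runif(3, 0, spread)
    sc <- matrix(rep(ca, k), k, 3, byrow = TRUE) + matrix(rnorm(3 * k), k, 3)
    list(aa = "A", atoms = data.frame(
      name = c("CA", paste0("C", LETTERS[2:(k + 1)])),
      x = c(ca[1], sc[, 1]), y = c(ca[2], sc[, 2]), z = c(ca[3], sc[, 3])))
  }))
}

# independent brute-force MI (+ optional weights/pseudocount), 21-state
brute_mi_matrix <- function(A, lambda = 0.5, weights = NULL, q = 21) {
  N <- nrow(A); L <- ncol(A)
  if (is.null(weights)) weights <- rep(1, N)
  neff <- sum(weights)
  mi <- matrix(0, L, L)
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    cij <- matrix(0, q, q)
    for (s in seq_len(N)) {
      cij[A[s, i], A[s, j]] <- cij[A[s, i], A[s, j]] + weights[s]
    }
    fij <- (cij + lambda / q) / (q * lambda + neff)
    fi <- (rowSums(cij) + lambda) / (q * lambda + neff)
    fj <- (colSums(cij) + lambda) / (q * lambda + neff)
    v <- 0
    for (a in seq_len(q)) for (b in seq_len(q)) {
      if (fij[a, b] > 0) v <- v + fij[a, b] * log(fij[a, b] / (fi[a] * fj[b]))
    }
    mi[i, j] <- v; mi[j, i] <- v
  }
  mi
}

# random gapless alignment over the 20 amino acids
random_alignment <- function(N, L, seed = 1, gap_rate = 0) {
  set.seed(seed)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m <- matrix(sample(aa, N * L, replace = TRUE), N, L)
  if (gap_rate > 0) m[runif(N * L) < gap_rate] <- "-"
  new_alignment(m)
}

# exact two-sided signed-rank p-value by enumeration of all sign assignments
signed_rank_exact_p <- function(d) {
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  p_ge <- mean(v_all >= v_obs)
  p_le <- mean(v_all <= v_obs)
  min(1, 2 * min(p_ge, p_le))
}
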