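# Synthetic structures and alignments with planted pairwise covariation.
#
# The generator produces (i) a compact self-avoiding CA trace with pseudo
# side-chain atoms, and (ii) an alignment of i.i.d. sequences in which a
# chosen set of structural contact pairs carries planted covariation of
# strength c: with probability c the two sites of a planted pair are linked
# by a fixed random bijection of the 20 amino acids, otherwise both are drawn
# independently and uniformly. Each site belongs to at most one planted pair,
# so the joint distribution of any planted pair is known in closed form and
# its mutual information is `planted_mi(c, q)`. Sequences are independent
# (no phylogeny), mirroring simulation designs that deliberately remove
# phylogenetic confounding.

#' Parameters for the synthetic generator
#'
#' @param L Chain length (>= 30 so that pairs at separation >= 12 exist).
#' @param N Number of sequences.
#' @param c Pair correlation strength in 0..1.
#' @param q Alphabet size (20 amino acids; fixed).
#' @param planted_on Contact definition receiving the planted couplings:
#'   one of `"CA"`, `"CB"`, `"SC_CENTER"`, `"MIN_ALL"`, `"MIN_SC"`. Planted
#'   pairs are the CA 8-angstrom contacts when `"CA"`, otherwise the
#'   count-matched contacts of that method.
#' @param seed Random seed; all generator randomness derives from it.
#' @param compactness Confinement-radius scale: the CA trace is grown inside
#'   a sphere of radius `compactness * L^(1/3)` angstrom. The default 2.8
#'   packs the chain densely enough that essentially every site carries
#'   long-range side-chain contacts (a requirement of the one-pair-per-site
#'   planting scheme); the resulting long-range contact density is higher
#'   than in natural proteins.
#' @param sc_length_range Range (angstrom) over which pseudo side-chain atoms
#'   extend from the CA along the residue's side-chain direction.
#' @return Object of class `synth_params`.
#' @export
synth_params <- function(L = 100, N = 3000, c = 0.7, q = 20,
                         planted_on = "SC_CENTER", seed = 1,
                         compactness = 2.8, sc_length_range = c(1.5, 4)) {
  stopifnot(L >= 30, N >= 2, c >= 0, c <= 1, q == 20,
            compactness > 0, length(sc_length_range) == 2,
            sc_length_range[1] > 0, diff(sc_length_range) >= 0,
            seed == round(seed))
  .check_method(planted_on)
  structure(list(L = as.integer(L), N = as.integer(N), c = c, q = as.integer(q),
                 planted_on = planted_on, seed = as.integer(seed),
                 compactness = compactness, sc_length_range = sc_length_range),
            class = "synth_params")
}

.runif_sphere <- function(n = 1L) {
  v <- matrix(stats::rnorm(3L * n), n, 3L)
  v / sqrt(rowSums(v^2))
}

#' Generate a toy protein structure
#'
#' Grows a self-avoiding CA trace with 3.8-angstrom consecutive spacing
#' inside a confinement sphere (radius `compactness * L^(1/3)`), then adds,
#' for every non-glycine residue, a CB atom at 1.5 angstrom plus 1-3 further
#' pseudo side-chain atoms at increasing distances along an isotropically
#' drawn per-residue direction. Amino acids are drawn uniformly from the 20
#' standard types, so glycines occur at rate 1/20. The result passes all
#' `protein_structure` invariants; backbone content is the CA atom only.
#'
#' @param p A `synth_params` object.
#' @return A `protein_structure`.
#' @export
synth_structure <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  set.seed(p$seed)
  L <- p$L
  R0 <- p$compactness * L^(1 / 3)
  step <- 3.8
  clash <- 3.8
  max_restarts <- 60L
  for (restart in seq_len(max_restarts)) {
    # if the walk keeps jamming at the target density, relax the confinement
    # radius by 5% per block of ten failed restarts (bounded, deterministic)
    R <- R0 * 1.05^((restart - 1L) %/% 10L)
    pos <- matrix(NA_real_, L, 3L)
    pos[1L, ] <- c(0, 0, 0)
    ok <- TRUE
    i <- 2L
    while (i <= L) {
      placed <- FALSE
      for (try in seq_len(60L)) {
        dir <- .runif_sphere()[1L, ]
        # mild inward bias keeps the walk inside the confinement sphere
        pull <- -pos[i - 1L, ] / max(R, 1e-9)
        dir <- dir + 0.6 * pull
        dir <- dir / sqrt(sum(dir^2))
        cand <- pos[i - 1L, ] + step * dir
        if (sqrt(sum(cand^2)) > R) next
        if (i > 2L) {
          prior <- pos[seq_len(i - 2L), , drop = FALSE]
          d2 <- rowSums((prior - matrix(cand, nrow(prior), 3L, byrow = TRUE))^2)
          if (min(d2) < clash^2) next
        }
        pos[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        # backtrack a few steps and regrow
        i <- max(2L, i - 5L)
        pos[i:L, ] <- NA_real_
        if (stats::runif(1) < 0.05) { ok <- FALSE; break }
        next
      }
      i <- i + 1L
    }
    if (ok && !anyNA(pos)) break
    if (restart == max_restarts) {
      stop("failed to grow a self-avoiding chain (L = ", L,
           ", seed = ", p$seed, ")")
    }
  }

  aa <- sample(.AA20, L, replace = TRUE)
  rows <- vector("list", L)
  lo <- p$sc_length_range[1L]
  hi <- p$sc_length_range[2L]
  sc_names <- c("CB", "CG", "CD", "CE")
  for (i in seq_len(L)) {
    r <- data.frame(res = i, aa = aa[i], name = "CA", element = "C",
                    x = pos[i, 1L], y = pos[i, 2L], z = pos[i, 3L],
                    stringsAsFactors = FALSE)
    if (aa[i] != "G") {
      dir <- .runif_sphere()[1L, ]
      n_extra <- sample(1:3, 1L)
      dists <- c(1.5, lo + (hi - lo) * seq_len(n_extra) / 3)
      sc <- data.frame(
        res = i, aa = aa[i],
        name = sc_names[seq_len(n_extra + 1L)],
        element = "C",
        x = pos[i, 1L] + dists * dir[1L],
        y = pos[i, 2L] + dists * dir[2L],
        z = pos[i, 3L] + dists * dir[3L],
        stringsAsFactors = FALSE
      )
      r <- rbind(r, sc)
    }
    rows[[i]] <- r
  }
  structure(list(
    chain_id = "A",
    atoms = do.call(rbind, rows),
    sequence = paste(aa, collapse = ""),
    L = L
  ), class = "protein_structure")
}

#' Planted contact pairs of a structure
#'
#' The planted set starts from the contacts of the structure under
#' `p$planted_on` (CA 8-angstrom contacts for `"CA"`; otherwise the contacts
#' of that method count-matched to the CA definition) and is thinned to a
#' pairing in which each site belongs to at most one pair. The pairing is
#' built greedily -- always matching the free site with the fewest free
#' partners, ties broken by contact distance and index -- and then improved
#' by length-3 augmenting paths, so that the number of planted pairs comes
#' close to the maximum matching of the contact graph. All steps are
#' deterministic.
#'
#' @param s A `protein_structure`.
#' @param p A `synth_params`.
#' @param min_sep Minimum chain separation (default 12).
#' @return Two-column integer matrix of planted pairs (i < j).
#' @export
planted_pairs <- function(s, p, min_sep = 12) {
  dm_ca <- distance_matrix(s, "CA")
  ca_map <- contacts_fixed(dm_ca, 8, min_sep)
  n <- nrow(ca_map$pairs)
  if (n == 0L) stop("structure has no eligible CA contacts to plant on")
  pairs <- if (p$planted_on == "CA") {
    ca_map$pairs
  } else {
    contacts_matched(distance_matrix(s, p$planted_on), n, min_sep)$contact_map$pairs
  }
  pairs <- pairs[order(pairs$d, pairs$i, pairs$j), , drop = FALSE]
  L <- s$L

  # adjacency: for each site, partner sites in increasing contact distance
  adj <- vector("list", L)
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$i[r]; b <- pairs$j[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  mate <- integer(L)

  free_deg <- function(v) sum(mate[adj[[v]]] == 0L)
  # greedy: repeatedly match the free site with the fewest free partners
  repeat {
    free <- which(mate == 0L & lengths(adj) > 0L)
    if (length(free) == 0L) break
    fd <- vapply(free, free_deg, 0L)
    free <- free[fd > 0L]
    fd <- fd[fd > 0L]
    if (length(free) == 0L) break
    v <- free[order(fd, free)][1L]
    nb <- adj[[v]][mate[adj[[v]]] == 0L]
    nb_fd <- vapply(nb, free_deg, 0L)
    u <- nb[order(nb_fd, seq_along(nb))][1L] # adjacency is distance-ordered
    mate[v] <- u
    mate[u] <- v
  }
  # length-3 augmenting paths: free u - v, matched v - w, free w - z
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (u in seq_len(L)) {
      if (mate[u] != 0L || length(adj[[u]]) == 0L) next
      done <- FALSE
      for (v in adj[[u]]) {
        w <- mate[v]
        if (w == 0L) {
          mate[u] <- v; mate[v] <- u; done <- TRUE; break
        }
        for (z in adj[[w]]) {
          if (z != u && z != v && mate[z] == 0L) {
            mate[v] <- u; mate[u] <- v; mate[w] <- z; mate[z] <- w
            done <- TRUE; break
          }
        }
        if (done) break
      }
      if (done) improved <- TRUE
    }
  }

  v <- which(mate > seq_len(L))
  m <- cbind(i = v, j = mate[v])
  m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  dimnames(m) <- list(NULL, c("i", "j"))
  m
}

#' Generate an alignment with covariation planted at structural contacts
#'
#' Every site of every sequence is drawn uniformly from the 20 amino acids,
#' independently across sequences. For each planted pair (i, j), with
#' probability `c` the state at j is set to a fixed random bijection of the
#' state at i; otherwise the two sites stay independent. No gaps are
#' introduced. Row 1 is the reference sequence.
#'
#' @param s A `protein_structure` (from [synth_structure()]).
#' @param p A `synth_params`; alignment randomness is seeded with
#'   `p$seed + 1` so that structure and alignment draws do not overlap.
#' @param min_sep Minimum chain separation for the planted contacts.
#' @return An `alignment` with attribute `planted_pairs` (the pair matrix).
#' @export
synth_alignment <- function(s, p, min_sep = 12) {
  stopifnot(inherits(s, "protein_structure"), inherits(p, "synth_params"))
  pp <- planted_pairs(s, p, min_sep)
  if (nrow(pp) == 0L) stop("no plantable pairs")
  set.seed(p$seed + 1L)
  N <- p$N
  q <- p$q
  A <- matrix(sample.int(q, N * s$L, replace = TRUE), N, s$L)
  for (r in seq_len(nrow(pp))) {
    i <- pp[r, 1L]; j <- pp[r, 2L]
    bij <- sample.int(q) # fixed random bijection for this pair
    linked <- stats::runif(N) < p$c
    A[linked, j] <- bij[A[linked, i]]
  }
  seqs <- matrix(.AA20[A], N, s$L)
  aln <- new_alignment(seqs, ids = c("reference", paste0("synth", seq_len(N - 1L))),
                       ref_row = 1L)
  attr(aln, "planted_pairs") <- pp
  aln
}

#' Closed-form mutual information of a planted pair
#'
#' For the planted joint distribution (probability `c` of a bijective link,
#' otherwise independence, uniform marginals over `q` states):
#' `MI(c) = (c + (1-c)/q) log(cq + 1 - c) + (1-c)(1 - 1/q) log(1-c)`,
#' in nats. `MI(0) = 0`, `MI(1) = log(q)`.
#'
#' @param c Correlation strength in 0..1.
#' @param q Alphabet size (default 20).
#' @return Mutual information in nats.
#' @export
planted_mi <- function(c, q = 20) {
  stopifnot(c >= 0, c <= 1, q >= 2)
  if (c == 0) return(0)
  if (c == 1) return(log(q))
  (c + (1 - c) / q) * log(c * q + 1 - c) + (1 - c) * (1 - 1 / q) * log(1 - c)
}
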