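test_that("reference points follow the glycine and side-chain conventions", {
  s <- make_structure(list(
    gly_at(c(0, 0, 0)),
    ala_at(ca = c(5, 0, 0), cb = c(6, 1, 0)),
    list(aa = "S", atoms = data.frame(name = c("CA", "CB", "OG"),
                                      x = c(10, 10, 12), y = c(0, 0, 0),
                                      z = c(0, 0, 0)))
  ))
  # glycine: all three point methods collapse to CA
  for (m in c("CA", "CB", "SC_CENTER")) {
    expect_equal(reference_point(s, 1, m), c(0, 0, 0))
  }
  # alanine: SC_CENTER is the lone CB
  expect_equal(reference_point(s, 2, "SC_CENTER"), c(6, 1, 0))
  # two side-chain atoms at x = 10 and x = 12: center is the midpoint
  expect_equal(reference_point(s, 3, "SC_CENTER"), c(11, 0, 0))
})

test_that("single-atom residues give the same distance under every method", {
  s <- gly_chain(c(0, 5))
  for (m in c("CA", "CB", "SC_CENTER", "MIN_ALL", "MIN_SC")) {
    expect_equal(pair_distance(s, 1, 2, m), 5)
  }
})

test_that("minimum-distance methods match a brute-force scan and MIN_ALL <= MIN_SC", {
  for (seed in 1:5) {
    s <- random_structure(L = 6, k = 3, seed = seed)
    for (i in 1:5) for (j in (i + 1):6) {
      ai <- s$atoms[s$atoms$res == i, ]
      aj <- s$atoms[s$atoms$res == j, ]
      brute <- function(A, B) {
        best <- Inf
        for (r in seq_len(nrow(A))) for (t in seq_len(nrow(B))) {
          best <- min(best, sqrt(sum((unlist(A[r, c("x", "y", "z")]) -
                                      unlist(B[t, c("x", "y", "z")]))^2)))
        }
        best
      }
      d_all <- pair_distance(s, i, j, "MIN_ALL")
      d_sc <- pair_distance(s, i, j, "MIN_SC")
      expect_equal(d_all, brute(ai, aj))
      expect_equal(d_sc, brute(ai[ai$name != "CA", ], aj[aj$name != "CA", ]))
      expect_lte(d_all, d_sc)
    }
  }
})

test_that("distance matrices are symmetric with zero diagonal and match a naive loop", {
  s <- random_structure(L = 7, k = 2, seed = 3)
  for (m in c("CA", "SC_CENTER", "MIN_ALL", "MIN_SC")) {
    dm <- distance_matrix(s, m)
    expect_equal(dm$d, t(dm$d))
    expect_equal(diag(dm$d), rep(0, s$L))
    naive <- matrix(0, s$L, s$L)
    for (i in seq_len(s$L - 1)) for (j in (i + 1):s$L) {
      naive[i, j] <- naive[j, i] <- pair_distance(s, i, j, m)
    }
    expect_equal(dm$d, naive)
  }
})

test_that("all-glycine structures give identical CA, CB and SC_CENTER matrices", {
  s <- gly_chain(cumsum(runif(8, 3, 5)))
  d_ca <- distance_matrix(s, "CA")$d
  expect_equal(distance_matrix(s, "CB")$d, d_ca)
  expect_equal(distance_matrix(s, "SC_CENTER")$d, d_ca)
})

test_that("point-method distances obey the triangle inequality", {
  s <- random_structure(L = 8, k = 2, seed = 9)
  for (m in c("CA", "CB", "SC_CENTER")) {
    d <- distance_matrix(s, m)$d
    for (i in 1:8) for (j in 1:8) for (k in 1:8) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-9)
    }
  }
})

test_that("fixed-cutoff contacts respect separation, boundary and monotonicity", {
  L <- 20
  set.seed(4)
  d <- as.matrix(dist(matrix(runif(L * 3, 0, 15), L, 3)))
  dm <- as_dm(d)
  # cutoff below every eligible distance: empty
  expect_equal(nrow(contacts_fixed(dm, 1e-6)$pairs), 0L)
  # a pair at exactly the cutoff is included (<= boundary)
  ep <- eligible_pairs(L, 12)
  c0 <- d[ep[1, 1], ep[1, 2]]
  cm <- contacts_fixed(dm, c0)
  expect_true(any(cm$pairs$i == ep[1, 1] & cm$pairs$j == ep[1, 2]))
  # every contact respects the separation rule
  expect_true(all(cm$pairs$j - cm$pairs$i >= 12))
  # pair sets grow monotonically with the cutoff
  prev <- 0L
  for (cut in c(2, 5, 8, 12, 20)) {
    n <- nrow(contacts_fixed(dm, cut)$pairs)
    expect_gte(n, prev)
    prev <- n
  }
})

test_that("separation >= 12 means pair (1,13) is eligible and (1,12) is not", {
  ep <- eligible_pairs(30, 12)
  expect_true(any(ep[, 1] == 1 & ep[, 2] == 13))
  expect_false(any(ep[, 1] == 1 & ep[, 2] == 12))
  expect_equal(nrow(ep), sum(outer(1:30, 1:30, function(i, j) j - i >= 12)))
})

test_that("matched-count selection is exact for every n, even under ties", {
  L <- 18
  set.seed(5)
  # quantized distances force many ties
  d <- as.matrix(dist(matrix(round(runif(L * 3, 0, 10)), L, 3)))
  dm <- as_dm(d)
  n_el <- nrow(eligible_pairs(L, 12))
  for (n in seq_len(n_el)) {
    mc <- contacts_matched(dm, n)
    expect_equal(nrow(mc$contact_map$pairs), n)
    expect_equal(mc$effective_cutoff,
                 sort(d[eligible_pairs(L, 12)], partial = n)[n])
  }
  expect_error(contacts_matched(dm, n_el + 1), "exceeds")
})

test_that("matched selection at n = 1 finds the closest eligible pair", {
  s <- random_structure(L = 20, k = 2, seed = 11)
  dm <- distance_matrix(s, "SC_CENTER")
  ep <- eligible_pairs(20, 12)
  dv <- dm$d[ep]
  best <- ep[which.min(dv), ]
  mc <- contacts_matched(dm, 1)
  expect_equal(c(mc$contact_map$pairs$i, mc$contact_map$pairs$j),
               unname(best))
  expect_equal(mc$effective_cutoff, min(dv))
})

test_that("matched and fixed selections agree when counts line up without ties", {
  s <- random_structure(L = 25, k = 2, seed = 2)
  dm <- distance_matrix(s, "CA")
  cf <- contacts_fixed(dm, 9)
  n <- nrow(cf$pairs)
  mc <- contacts_matched(dm, n)
  expect_equal(mc$contact_map$pairs[, c("i", "j")], cf$pairs[, c("i", "j")])
})

test_that("overlap fraction handles identity, disjointness and count mismatch", {
  s <- random_structure(L = 30, k = 2, seed = 6)
  dm <- distance_matrix(s, "CA")
  a <- contacts_matched(dm, 10)$contact_map
  expect_equal(overlap_fraction(a, a), 1)
  # construct a disjoint map of the same size from the farthest pairs
  ep <- eligible_pairs(30, 12)
  dv <- dm$d[ep]
  far <- ep[order(-dv)[1:10], ]
  b <- a
  b$pairs <- data.frame(i = far[, 1], j = far[, 2], d = dv[order(-dv)[1:10]])
  expect_equal(overlap_fraction(a, b), 0)
  c3 <- contacts_matched(dm, 9)$contact_map
  expect_error(overlap_fraction(a, c3), "count")
})

test_that("distance correlation matches a direct rank computation", {
  s <- random_structure(L = 25, k = 2, seed = 8)
  da <- distance_matrix(s, "CA")
  db <- distance_matrix(s, "SC_CENTER")
  expect_equal(distance_correlation(da, da), 1)
  neg <- as_dm(-db$d)
  expect_equal(distance_correlation(db, neg), -1)
  # independent rank-then-pearson oracle
  ep <- eligible_pairs(25, 12)
  oracle <- cor(rank(da$d[ep]), rank(db$d[ep]))
  expect_equal(distance_correlation(da, db), oracle)
})

test_that("contact maps export in flat and CASP-RR-like formats", {
  s <- random_structure(L = 25, k = 2, seed = 8)
  cm <- contacts_fixed(distance_matrix(s, "CA"), 10)
  f1 <- tempfile(); f2 <- tempfile()
  write_contacts(cm, f1, "flat")
  write_contacts(cm, f2, "casprr")
  flat <- read.table(f1)
  expect_equal(flat$V1, cm$pairs$i)
  expect_equal(flat$V3, round(cm$pairs$d, 4))
  expect_equal(unique(as.character(flat$V4)), "CA")
  rr <- read.table(f2)
  expect_equal(ncol(rr), 5L)
  expect_true(all(rr$V3 == 0))
})
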