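test_that("sequence weights count identity neighbourhoods correctly", {
  # three mutually dissimilar sequences: all weights 1
  a <- new_alignment(rbind(strsplit("ACDEFGHIKL", "")[[1]],
                           strsplit("MNPQRSTVWY", "")[[1]],
                           strsplit("LKIHGFEDCA", "")[[1]]))
  expect_equal(sequence_weights(a), rep(1, 3))
  # k identical sequences: weight 1/k each
  b <- new_alignment(matrix("A", 4, 10))
  expect_equal(sequence_weights(b), rep(1 / 4, 4))
})

test_that("sequence weights match brute-force identity counting", {
  aln <- random_alignment(15, 8, seed = 5, gap_rate = 0.1)
  w <- sequence_weights(aln, identity_threshold = 0.5)
  n <- aln$n_seqs
  brute <- vapply(seq_len(n), function(s) {
    nb <- 0
    for (t in seq_len(n)) {
      ident <- mean(aln$seqs[s, ] == aln$seqs[t, ])
      if (ident >= 0.5) nb <- nb + 1
    }
    1 / nb
  }, 0)
  expect_equal(w, brute)
})

test_that("MI matrix matches an independent brute-force computation", {
  for (gap_rate in c(0, 0.15)) {
    aln <- random_alignment(40, 5, seed = 7, gap_rate = gap_rate)
    A <- encode_alignment(aln)
    w <- runif(40, 0.2, 1)
    got <- mi_apc(aln, pseudocount = 0.5, weights = w)
    want <- brute_mi_matrix(A, lambda = 0.5, weights = w)
    expect_equal(got$mi, want)
    expect_equal(got$s, apc_correct(want))
  }
})

test_that("duplicated columns attain the maximum MI, near log(state count)", {
  set.seed(8)
  states <- sample(c("A", "C", "D", "E", "F"), 2000, replace = TRUE)
  m <- cbind(states, states,
             matrix(sample(c("G", "H", "I", "K"), 2000 * 3, replace = TRUE),
                    2000, 3))
  aln <- new_alignment(m)
  cm <- mi_apc(aln, pseudocount = 0)
  off <- cm$mi[upper.tri(cm$mi)]
  expect_equal(which.max(cm$mi[1, ]), 2L)
  expect_equal(max(off), cm$mi[1, 2])
  expect_equal(cm$mi[1, 2], log(5), tolerance = 0.02)
})

test_that("independent uniform columns score near zero after APC", {
  aln <- random_alignment(5000, 10, seed = 9)
  cm <- mi_apc(aln)
  off <- cm$s[upper.tri(cm$s)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("MI is invariant to row order and consistent state relabeling", {
  aln <- random_alignment(60, 6, seed = 10)
  cm <- mi_apc(aln)
  perm <- sample(60)
  cm_rows <- mi_apc(new_alignment(aln$seqs[perm, , drop = FALSE]))
  expect_equal(cm_rows$mi, cm$mi)
  expect_equal(cm_rows$s, cm$s)
  # relabel amino acids by a fixed permutation applied everywhere
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  set.seed(1)
  relab <- setNames(sample(aa), aa)
  cm_lab <- mi_apc(new_alignment(matrix(relab[aln$seqs], nrow(aln$seqs))))
  expect_equal(cm_lab$mi, cm$mi)
})

test_that("weighting k-fold duplicated sequences by 1/k recovers the original MI", {
  aln <- random_alignment(30, 5, seed = 12)
  dup <- new_alignment(aln$seqs[rep(seq_len(30), each = 3), ])
  cm0 <- mi_apc(aln, pseudocount = 0.5)
  cm3 <- mi_apc(dup, pseudocount = 0.5, weights = rep(1 / 3, 90))
  expect_equal(cm3$mi, cm0$mi)
})

test_that("gap exclusion matches brute force on the non-gap subset", {
  aln <- random_alignment(200, 4, seed = 14, gap_rate = 0.2)
  got <- mi_apc(aln, pseudocount = 0, treat_gaps = "exclude")
  A <- encode_alignment(aln)
  for (i in 1:3) for (j in (i + 1):4) {
    keep <- A[, i] != 21 & A[, j] != 21
    tab <- table(factor(A[keep, i], levels = 1:20),
                 factor(A[keep, j], levels = 1:20))
    f <- tab / sum(tab)
    fi <- rowSums(f); fj <- colSums(f)
    pos <- f > 0
    want <- sum(f[pos] * log(f[pos] / outer(fi, fj)[pos]))
    expect_equal(got$mi[i, j], want)
  }
})

test_that("APC preserves symmetry and suppresses a rank-one score pattern", {
  set.seed(16)
  v <- runif(8, 0.5, 2)
  m <- outer(v, v)
  s <- apc_correct(m)
  expect_equal(s, t(s))
  expect_equal(diag(s), rep(0, 8))
  # product-form backgrounds are removed up to diagonal-exclusion effects
  expect_lt(max(abs(s[upper.tri(s)])),
            0.15 * max(m[upper.tri(m)]))
})

test_that("matrix and edge-list readers round trip and validate input", {
  s <- matrix(rnorm(25), 5, 5)
  s <- s + t(s)
  cm <- as_coupling_matrix(s)
  path <- tempfile()
  write_coupling_matrix(cm, path)
  cm2 <- read_coupling_matrix(path)
  expect_equal(cm2$s, cm$s, tolerance = 1e-7)
  expect_equal(cm2$L, 5L)

  # asymmetric input symmetrised by the elementwise maximum
  asym <- matrix(1:9, 3, 3)
  cma <- as_coupling_matrix(asym)
  expect_equal(cma$s, pmax(asym, t(asym)))

  writeLines(c("1 2 3", "4 5 6"), path)
  expect_error(read_coupling_matrix(path), "non-square")

  writeLines(c("1 3 2.5", "2 5 1.5"), path)
  el <- read_edge_list(path, L = 5)
  expect_equal(el$s[1, 3], 2.5)
  expect_equal(el$s[3, 1], 2.5)
  expect_equal(el$s[2, 4], 0)
  expect_error(read_edge_list(path, L = 4), "outside")
})

test_that("pair ranking is deterministic and matches a brute-force sort", {
  L <- 30
  set.seed(15)
  s <- matrix(rnorm(L * L), L, L)
  s <- pmax(s, t(s))
  cm <- as_coupling_matrix(s)
  rp <- rank_pairs(cm)
  expect_true(all(rp$j - rp$i >= 12))
  ep <- eligible_pairs(L, 12)
  ord <- order(-s[ep], ep[, 1], ep[, 2])
  expect_equal(rp$i, ep[ord, 1])
  expect_equal(rp$j, ep[ord, 2])
  expect_equal(rp$score, s[ep][ord])

  # all-equal scores fall back to lexicographic order
  cm_const <- as_coupling_matrix(matrix(1, L, L))
  rpc <- rank_pairs(cm_const)
  expect_equal(rpc$i, ep[, 1])
  expect_equal(rpc$j, ep[, 2])

  # one dominant score ranks first
  s2 <- matrix(0, L, L); s2[2, 20] <- s2[20, 2] <- 5
  rp2 <- rank_pairs(as_coupling_matrix(s2))
  expect_equal(c(rp2$i[1], rp2$j[1]), c(2, 20))
})
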