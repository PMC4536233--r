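test_that("pairwise differences exclude gaps and N, treat U as T", {
  expect_equal(pairwise_differences("ACGT", "ACGT"), 0L)
  expect_equal(pairwise_differences("ACGT", "ACGA"), 1L)
  expect_equal(pairwise_differences("AC-GT", "ACAGA"), 1L)
  expect_equal(pairwise_differences("ACGU", "ACGT"), 0L)
  expect_equal(pairwise_differences("ACGN", "ACGT"), 0L)
  expect_error(pairwise_differences("ACGT", "ACG"), "unequal")
})

test_that("pairwise differences form a metric on gap-free sequences", {
  set.seed(13)
  seqs <- replicate(6, random_sequence(40, sample.int(1e6, 1)))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    dij <- pairwise_differences(seqs[i], seqs[j])
    dik <- pairwise_differences(seqs[i], seqs[k])
    dkj <- pairwise_differences(seqs[k], seqs[j])
    expect_lte(dij, dik + dkj)
  }
})

test_that("Kimura distance matches the closed form over a (P, Q) grid", {
  for (P in c(0, 0.05, 0.1, 0.2)) for (Q in c(0, 0.05, 0.1)) {
    if (P + Q == 0) next
    L <- 200
    base <- random_sequence(L, seed = round(1000 * (P + 3 * Q)) + 7)
    pair <- mutate_sequence(base, round(P * L), round(Q * L), 0, seed = 3)
    d <- kimura_distance(pair$a, pair$b, gap_penalty = 0)
    Pr <- round(P * L) / L; Qr <- round(Q * L) / L
    expect_equal(as.numeric(d), -0.5 * log((1 - 2 * Pr - Qr) *
                                             sqrt(1 - 2 * Qr)),
                 tolerance = 1e-12)
    expect_equal(attr(d, "P"), Pr)
    expect_equal(attr(d, "Q"), Qr)
  }
  expect_equal(as.numeric(kimura_distance("ACGT", "ACGT")), 0)
})

test_that("one-sided gap columns add gap_penalty / L_comparable each", {
  base <- random_sequence(110, seed = 4)
  pair <- mutate_sequence(base, 0, 0, 10, seed = 5)
  d <- kimura_distance(pair$a, pair$b)  # default 12% gap penalty
  expect_equal(as.numeric(d), 0.12 * 10 / 100, tolerance = 1e-12)
  d0 <- kimura_distance(pair$a, pair$b, gap_penalty = 0)
  expect_equal(as.numeric(d0), 0)
})

test_that("saturated distances raise a named error", {
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(rep("G", 50), collapse = "")   # all transitions, P = 1
  expect_error(kimura_distance(a, b), "saturated")
})

test_that("neighbor joining: 3-taxon closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co[rownames(D), colnames(D)], D)
  el <- setNames(tr$edge.length,
                 tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 1)   # (d_AB + d_AC - d_BC) / 2
  expect_equal(el[["B"]], 2)
  expect_equal(el[["C"]], 3)
  expect_error(neighbor_joining(D[1:2, 1:2]), ">= 3")
})

test_that("neighbor joining recovers additive trees exactly", {
  set.seed(17)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 1)
    D <- ape::cophenetic.phylo(tr)
    nj <- neighbor_joining(D)
    co <- ape::cophenetic.phylo(nj)
    expect_lt(max(abs(D[rownames(co), colnames(co)] - co)), 1e-9)
    expect_equal(nrow(nj$edge), 2 * n - 3)
    expect_true(all(nj$edge.length >= 0))
  }
})

test_that("4-taxon oracle: NJ finds the least-squares-best topology", {
  # brute force over the 3 unrooted quartet topologies
  set.seed(23)
  for (i in 1:20) {
    tr <- ape::rtree(4, rooted = FALSE)
    tr$edge.length <- runif(5, 0.1, 1)
    D <- ape::cophenetic.phylo(tr)
    taxa <- rownames(D)
    quartets <- list(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 4, 2, 3))
    sse <- vapply(quartets, function(q) {
      nwk <- sprintf("((%s,%s),(%s,%s));", taxa[q[1]], taxa[q[2]],
                     taxa[q[3]], taxa[q[4]])
      t0 <- ape::read.tree(text = nwk)
      ph <- phangorn::nnls.tree(as.dist(D), t0, method = "unrooted")
      sum((ape::cophenetic.phylo(ph)[taxa, taxa] - D)^2)
    }, numeric(1))
    nj <- neighbor_joining(D)
    best <- quartets[[which.min(sse)]]
    expect_equal(phangorn::RF.dist(nj, ape::read.tree(text = sprintf(
      "((%s,%s),(%s,%s));", taxa[best[1]], taxa[best[2]],
      taxa[best[3]], taxa[best[4]]))), 0)
  }
})

test_that("ultrametric input: NJ and UPGMA topologies agree", {
  d <- matrix(c(0, .2, .6, .6,
                .2, 0, .6, .6,
                .6, .6, 0, .3,
                .6, .6, .3, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  nj <- neighbor_joining(d)
  up <- ape::as.phylo(upgma(1 - d))
  expect_equal(phangorn::RF.dist(ape::unroot(up), nj), 0)
})

test_that("distance matrix from an alignment is symmetric, zero-diagonal", {
  f <- withr::local_tempfile(fileext = ".fasta")
  base <- random_sequence(120, seed = 31)
  p1 <- mutate_sequence(base, 3, 1, 0, seed = 32)$b
  p2 <- mutate_sequence(base, 0, 2, 4, seed = 33)$b
  writeLines(c(">t1", base, ">t2", p1, ">t3", p2), f)
  aln <- read_alignment(f)
  D <- kimura_distance_matrix(aln)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3), ignore_attr = TRUE)
  expect_true(all(D >= 0))
})

test_that("compare_partitions reports monophyly and RF distance", {
  msS <- matrix(0.2, 6, 6); diag(msS) <- 1
  labs <- paste0("x", 1:6)
  # MS tree mixes classes; sequence tree keeps them monophyletic
  msS[1, 4] <- msS[4, 1] <- 0.9
  msS[2, 5] <- msS[5, 2] <- 0.85
  dimnames(msS) <- list(labs, labs)
  ms <- upgma(msS)
  seq_tree <- ape::read.tree(
    text = "(((x1:1,x2:1):1,x3:2):1,(x4:1,(x5:1,x6:1):1):1);")
  cls <- setNames(rep(c("A", "B"), each = 3), labs)
  rep_ <- compare_partitions(ms, seq_tree, cls)
  expect_true(all(rep_$per_class$monophyletic_seq))
  expect_false(all(rep_$per_class$monophyletic_ms))
  expect_gte(rep_$n_seq_only_monophyletic, 1L)
  # identical trees: RF 0 and identical monophyly columns
  rep0 <- compare_partitions(ape::as.phylo(ms), ape::as.phylo(ms) , cls)
  expect_equal(rep0$rf_distance, 0)
  expect_equal(rep0$per_class$monophyletic_ms,
               rep0$per_class$monophyletic_seq)
  # star vs resolved: RF = number of internal edges of the resolved tree
  star <- ape::read.tree(text = "(x1,x2,x3,x4,x5,x6);")
  star$edge.length <- rep(1, nrow(star$edge))
  repS <- compare_partitions(star, seq_tree, cls)
  expect_equal(repS$rf_distance, 3)
  expect_error(compare_partitions(ms, star, cls[1:3]), "cover")
})
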