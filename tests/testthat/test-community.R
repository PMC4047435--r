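# Community distance: presence matrices, binary Jaccard dissimilarity,
# neighbor joining and patristic distances.

test_that("presence matrix records cluster membership per sample", {
  clusters <- list(c("s1|a", "s2|b"), c("s1|c", "s1|d"), "s2|e")
  samples <- setNames(c("s1", "s2", "s1", "s1", "s2"),
                      c("s1|a", "s2|b", "s1|c", "s1|d", "s2|e"))
  p <- presence_matrix(clusters, samples)
  expect_equal(dim(p), c(3L, 2L))
  expect_equal(unname(p[1, ]), c(TRUE, TRUE))
  expect_equal(unname(p[2, ]), c(TRUE, FALSE))
  expect_equal(unname(colSums(p)), c(2, 2))
  expect_error(presence_matrix(clusters, samples[-1]), "sample tag")
})

test_that("Jaccard dissimilarity matches its set definition", {
  p <- matrix(FALSE, 4, 2, dimnames = list(sprintf("C%d", 1:4),
                                           c("A", "B")))
  p[1:3, "A"] <- TRUE
  p[2:4, "B"] <- TRUE
  expect_equal(jaccard_dissimilarity(p, "A", "B"), 0.5)  # 1 - 2/4
  p[, "B"] <- p[, "A"]
  expect_equal(jaccard_dissimilarity(p, "A", "B"), 0)
  p[, "B"] <- c(FALSE, FALSE, FALSE, TRUE)
  expect_equal(jaccard_dissimilarity(p, "A", "B"), 1)
  p[, "B"] <- FALSE
  expect_error(jaccard_dissimilarity(p, "A", "B"), "zero clusters")
})

test_that("the dissimilarity matrix is a proper Jaccard metric", {
  # degenerate corners
  ident <- matrix(TRUE, 3, 3, dimnames = list(sprintf("C%d", 1:3),
                                              c("A", "B", "C")))
  expect_equal(unname(dissimilarity_matrix(ident)), matrix(0, 3, 3))
  disjoint <- matrix(FALSE, 3, 3, dimnames = dimnames(ident))
  diag(disjoint) <- TRUE
  d <- dissimilarity_matrix(disjoint)
  expect_equal(unname(d[upper.tri(d)]), rep(1, 3))
  # symmetry, range and the triangle inequality on random fixtures
  for (seed in 1:20) {
    p <- random_presence(10, 4, p = 0.5, seed = seed)
    d <- dissimilarity_matrix(p)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    for (i in 1:4) for (j in 1:4) for (k in 1:4)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("dissimilarity matrix agrees with an independent binary Jaccard", {
  skip_if_not_installed("vegan")
  p <- random_presence(12, 5, p = 0.4, seed = 77)
  d <- dissimilarity_matrix(p)
  ref <- as.matrix(vegan::vegdist(t(p) * 1, method = "jaccard"))
  expect_equal(unname(d), unname(ref), tolerance = 1e-12)
})

test_that("neighbor joining recovers the 4-taxon additive fixture exactly", {
  # distances hand-computed from the tree with pendant branches
  # A:1, B:2, C:3, D:4 and internal branch 1
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- neighbor_joining(d)
  pat <- patristic_distances(tr)
  expect_equal(pat[LETTERS[1:4], LETTERS[1:4]], d, tolerance = 1e-9)
  # branch lengths themselves are the planted ones
  tip_edges <- tr$edge[, 2] <= 4
  lens <- sort(tr$edge.length[tip_edges])
  expect_equal(lens, c(1, 2, 3, 4), tolerance = 1e-9)
  expect_equal(sort(tr$edge.length)[2], 1, tolerance = 1e-9)  # internal
})

test_that("3-taxon trees use the closed-form star lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(d)
  la <- (3 + 5 - 6) / 2; lb <- (3 + 6 - 5) / 2; lc <- (5 + 6 - 3) / 2
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = la, B = lb, C = lc))
})

test_that("NJ is invariant to input label order", {
  fx <- random_additive(7, seed = 13)
  perm <- sample(rownames(fx$d))
  pat1 <- patristic_distances(neighbor_joining(fx$d))
  pat2 <- patristic_distances(neighbor_joining(fx$d[perm, perm]))
  lab <- rownames(fx$d)
  expect_equal(pat2[lab, lab], pat1[lab, lab], tolerance = 1e-9)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "symmetric")
})

test_that("NJ + patristic round-trips additive matrices to 1e-9", {
  for (seed in 1:10) {
    fx <- random_additive(sample(4:9, 1), seed = seed)
    lab <- rownames(fx$d)
    pat <- patristic_distances(neighbor_joining(fx$d))
    expect_equal(pat[lab, lab], fx$d, tolerance = 1e-9)
  }
})

test_that("our NJ matches the reference NJ implementation", {
  for (seed in c(3, 14, 25)) {
    p <- random_presence(40, 6, p = 0.45, seed = seed)
    d <- dissimilarity_matrix(p)
    lab <- rownames(d)
    ours <- patristic_distances(neighbor_joining(d))
    ref <- ape::cophenetic.phylo(ape::nj(d))
    expect_equal(ours[lab, lab], ref[lab, lab], tolerance = 1e-8)
  }
})

test_that("patristic distances sum branch lengths along leaf paths", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,C:3);")
  pat <- patristic_distances(tr)
  expect_equal(pat["A", "B"], 3)
  expect_equal(pat["A", "C"], 5)
  expect_equal(pat["B", "C"], 6)
  expect_equal(unname(diag(pat)), rep(0, 3))
})

test_that("negative NJ branches can be clamped with the deficit moved", {
  # a non-additive matrix known to produce a negative pendant branch
  d <- matrix(c(0, 1, 6, 6,
                1, 0, 6, 6,
                6, 6, 0, 1,
                6, 6, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 0.05
  d["A", "C"] <- d["C", "A"] <- 9
  tr <- neighbor_joining(d, negative = "clamp")
  expect_true(all(tr$edge.length >= 0))
  # the joined pair's path length is preserved by the transfer
  kept <- neighbor_joining(d, negative = "keep")
  pk <- patristic_distances(kept)
  pc <- patristic_distances(tr)
  expect_equal(pc["A", "B"], pk["A", "B"], tolerance = 1e-9)
})

test_that("the composite cluster-to-Newick map is deterministic", {
  p <- random_presence(30, 5, p = 0.4, seed = 9)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_newick(neighbor_joining(dissimilarity_matrix(p)), f1)
  write_newick(neighbor_joining(dissimilarity_matrix(p)), f2)
  expect_identical(readLines(f1), readLines(f2))
})
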