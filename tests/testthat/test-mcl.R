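# Markov clustering: stochastic matrix construction, expansion/inflation
# algebra, convergence and cluster readout.

test_that("to_stochastic adds max-incident self-loops and normalises", {
  g <- similarity_graph(data.frame(id = "a", sample_id = "s"),
                        data.frame(from = character(0), to = character(0),
                                   weight = numeric(0)))
  expect_equal(unname(as.matrix(to_stochastic(g))), matrix(1))
  g2 <- similarity_graph(data.frame(id = c("a", "b"), sample_id = "s"),
                         data.frame(from = "a", to = "b", weight = 3))
  m <- to_stochastic(g2)
  expect_equal(unname(m), matrix(0.5, 2, 2))
  set.seed(42)
  g3 <- modular_graph(3, 4, intra = 8, inter = 1, seed = 3)
  m3 <- to_stochastic(g3)
  expect_equal(unname(colSums(m3)), rep(1, 12), tolerance = 1e-9)
})

test_that("expansion equals a naive triple-loop matrix product", {
  set.seed(9)
  m <- matrix(runif(25), 5)
  m <- sweep(m, 2, colSums(m), "/")
  expect_equal(unname(mcl_expand(m)), naive_matmul(m, m), tolerance = 1e-12)
  # stochastic fixed points
  expect_equal(mcl_expand(diag(4)), diag(4))
  u <- matrix(0.5, 2, 2)
  expect_equal(mcl_expand(u), u)
})

test_that("inflation renormalises entry-wise powers", {
  m <- matrix(c(0.5, 0.5, 0.8, 0.2), 2)
  out <- mcl_inflate(m, 2)
  expect_equal(out[, 1], c(0.5, 0.5))
  expect_equal(out[, 2], c(0.64, 0.04) / 0.68)
  expect_error(mcl_inflate(m, 1), "> 1")
  # inflation raises the maximum of every non-uniform column
  set.seed(10)
  for (i in 1:20) {
    col <- runif(6)
    col <- col / sum(col)
    infl <- mcl_inflate(matrix(col), 1.5)
    if (max(col) - min(col) > 1e-8)
      expect_gt(max(infl), max(col))
  }
})

test_that("column stochasticity is preserved along the iteration", {
  g <- modular_graph(3, 5, intra = 10, inter = 0.5, seed = 4)
  m <- to_stochastic(g)
  for (i in 1:5) {
    m <- mcl_inflate(mcl_expand(m), 1.2)
    expect_equal(unname(colSums(m)), rep(1, ncol(m)), tolerance = 1e-9)
  }
})

test_that("mcl resolves cliques, bridges and disconnected components", {
  g <- clique_graph(list(c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  out <- mcl(g, inflation = 1.2)
  expect_equal(canon_partition(out$clusters),
               canon_partition(list(c("a1", "a2", "a3"),
                                    c("b1", "b2", "b3"))))
  # single 5-clique stays together
  g5 <- clique_graph(list(sprintf("n%d", 1:5)))
  expect_equal(length(mcl(g5, inflation = 1.2)$clusters), 1)
  # two 4-cliques joined by a weak bridge split at the bridge
  gb <- clique_graph(list(sprintf("a%d", 1:4), sprintf("b%d", 1:4)),
                     weight = 10,
                     bridges = data.frame(from = "a1", to = "b1",
                                          weight = 0.1))
  outb <- mcl(gb, inflation = 2.0)
  expect_equal(canon_partition(outb$clusters),
               canon_partition(list(sprintf("a%d", 1:4),
                                    sprintf("b%d", 1:4))))
})

test_that("clusters partition the node set and come out deterministically", {
  for (seed in 1:5) {
    g <- modular_graph(3, 4, intra = 10, inter = 1, p_inter = 0.4,
                       seed = seed)
    out <- mcl(g, inflation = 2.0)
    members <- unlist(out$clusters)
    expect_setequal(members, g$nodes$id)
    expect_equal(anyDuplicated(members), 0)
    # size-descending, then smallest member id
    sz <- lengths(out$clusters)
    expect_true(all(diff(sz) <= 0))
    out2 <- mcl(g, inflation = 2.0)
    expect_identical(out$clusters, out2$clusters)
  }
})

test_that("per-component iteration matches whole-matrix iteration", {
  g <- clique_graph(list(c("a1", "a2", "a3"), c("b1", "b2", "b3", "b4"),
                         c("c1", "c2")))
  a <- mcl(g, inflation = 1.4, by_component = TRUE)
  b <- mcl(g, inflation = 1.4, by_component = FALSE)
  expect_equal(canon_partition(a$clusters), canon_partition(b$clusters))
})

test_that("package MCL agrees with an independent minimal implementation", {
  for (seed in 1:10) {
    g <- modular_graph(k = 3, size = 4, intra = 10, inter = 1,
                       p_inter = 0.3, seed = seed)
    for (infl in c(1.2, 2.0)) {
      expect_equal(canon_partition(mcl(g, inflation = infl)$clusters),
                   canon_partition(naive_mcl(g, infl)),
                   label = sprintf("seed %d inflation %.1f", seed, infl))
    }
  }
})

test_that("planted modules are recovered exactly at inflation 1.2", {
  for (seed in 1:5) {
    k <- 4; size <- 5
    g <- modular_graph(k, size, intra = 10, inter = 0.2, p_inter = 0.2,
                       seed = 100 + seed)
    out <- mcl(g, inflation = 1.2)
    planted <- split(g$nodes$id, rep(seq_len(k), each = size))
    expect_equal(canon_partition(out$clusters),
                 canon_partition(unname(planted)))
  }
})

test_that("higher inflation never coarsens the clustering on average", {
  coarse <- fine <- numeric(0)
  for (seed in 1:20) {
    g <- modular_graph(3, 4, intra = 6, inter = 2, p_inter = 0.5,
                       seed = 200 + seed)
    coarse <- c(coarse, mean(lengths(mcl(g, inflation = 1.2)$clusters)))
    fine <- c(fine, mean(lengths(mcl(g, inflation = 5.0)$clusters)))
  }
  expect_lte(mean(fine), mean(coarse))
})

test_that("cluster files use the cluster-per-line dialect", {
  g <- clique_graph(list(c("a1", "a2", "a3"), c("b1", "b2")))
  out <- mcl(g, inflation = 1.5)
  f <- withr::local_tempfile()
  write_mcl_clusters(out, f)
  lines <- readLines(f)
  expect_equal(length(lines), 2)
  expect_equal(strsplit(lines[1], "\t")[[1]], c("a1", "a2", "a3"))
})
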