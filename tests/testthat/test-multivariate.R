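# Geochemical distances, correlation matrices, PCA and Mantel tests.

make_geochem <- function(values, sites = NULL, params = NULL) {
  if (is.null(sites)) sites <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(params)) params <- sprintf("P%d", seq_len(ncol(values)))
  dimnames(values) <- list(sites, params)
  geochem_table(values)
}

test_that("parameter distances are absolute differences", {
  g <- make_geochem(cbind(c(56.1, 74.0, 92.1), c(7, 7, 7)),
                    params = c("T", "pH"))
  d <- parameter_distance(g, "T")
  expect_equal(max(d), 36.0)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_equal(unname(parameter_distance(g, "pH")),
               matrix(0, 3, 3))
  # sites missing the parameter are dropped with a warning
  g2 <- make_geochem(cbind(c(1, 2, 3, NA), c(1, 1, 1, 1)))
  expect_warning(d2 <- parameter_distance(g2, "P1"), "dropping")
  expect_equal(dim(d2), c(3L, 3L))
  expect_error(suppressWarnings(
    parameter_distance(make_geochem(cbind(c(1, NA, NA, 2), 1:4)), "P1")),
    "fewer than 3")
})

test_that("correlation matrices are Pearson with pairwise completion", {
  g <- make_geochem(cbind(x = c(1, 2, 3), y = c(2, 4, 6), z = c(3, 2, 1)),
                    params = c("x", "y", "z"))
  r <- correlation_matrix(g)
  expect_equal(r["x", "y"], 1)
  expect_equal(r["x", "z"], -1)
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(r, t(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
  # positive semidefinite on complete data
  g2 <- make_geochem(matrix(rnorm(60), 10))
  ev <- eigen(correlation_matrix(g2), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gte(min(ev), -1e-10)
  # zero-variance column flagged NA with a warning
  g3 <- make_geochem(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_warning(r3 <- correlation_matrix(g3), "zero-variance")
  expect_true(all(is.na(r3["P2", ])))
  # extra diversity columns join the matrix
  extra <- cbind(genus = c(3, 2, 1))
  r4 <- correlation_matrix(g, extra, digits = 2)
  expect_equal(r4["x", "genus"], -1)
})

test_that("PCA satisfies the spectral identities", {
  set.seed(61)
  x <- matrix(rnorm(24), 6, 4)
  g <- make_geochem(x)
  p <- geochem_pca(g, scale = FALSE)
  # eigenvalues match an independent eigendecomposition of the covariance
  expect_equal(p$eigenvalues, sort(eigen(cov(x))$values, decreasing = TRUE),
               tolerance = 1e-9)
  expect_equal(sum(p$variance_fraction), 1)
  expect_true(all(diff(p$variance_fraction) <= 1e-12))
  # reconstruction from all components reproduces the centred data
  centred <- sweep(x, 2, colMeans(x))
  expect_equal(unname(p$scores %*% t(p$loadings)), unname(centred),
               tolerance = 1e-9)
  # scores are the projected data
  expect_equal(unname(p$scores), unname(centred %*% p$loadings),
               tolerance = 1e-9)
  # sign convention: largest-magnitude loading entry positive
  for (k in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
})

test_that("two perfectly correlated variables collapse onto one axis", {
  g <- make_geochem(cbind(c(1, 2, 3, 4), c(2, 4, 6, 8)))
  p <- geochem_pca(g, scale = TRUE)
  expect_equal(p$variance_fraction, c(1, 0), tolerance = 1e-12)
})

test_that("cor_pca matches geochem_pca eigenvalues on scaled data", {
  set.seed(62)
  x <- matrix(rnorm(50), 10, 5)
  g <- make_geochem(x)
  a <- geochem_pca(g, scale = TRUE)
  b <- cor_pca(cor(x))
  # sample-covariance eigenvalues differ by the (n-1)/n-free prcomp
  # convention only in scale handling; correlation input has no such
  # factor ambiguity
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-9)
  expect_equal(b$variance_fraction, b$eigenvalues / 5)
})

test_that("PC-space distances respect rotation invariance and truncation", {
  set.seed(63)
  x <- matrix(rnorm(40), 8, 5)
  g <- make_geochem(x)
  p <- geochem_pca(g, scale = FALSE)
  dall <- pc_space_distance(p, 5)
  raw <- as.matrix(dist(scale(x, center = TRUE, scale = FALSE)))
  expect_equal(unname(dall), unname(raw), tolerance = 1e-9)
  d1 <- pc_space_distance(p, 1)
  d3 <- pc_space_distance(p, 3)
  expect_true(all(d1 <= d3 + 1e-12))
  expect_error(pc_space_distance(p, 6), "exceeds")
  # identical sites sit at distance zero
  x2 <- rbind(x, x[1, ])
  g2 <- make_geochem(x2)
  p2 <- geochem_pca(g2, scale = FALSE)
  d2 <- pc_space_distance(p2, 3)
  expect_equal(d2["S1", "S9"], 0, tolerance = 1e-9)
})

test_that("mantel_test finds perfect relations and is label-invariant", {
  set.seed(64)
  m <- matrix(runif(36), 6); m <- (m + t(m)) / 2; diag(m) <- 0
  d1 <- dist_matrix(m)
  d2 <- dist_matrix(2 * m)
  res <- mantel_test(d1, d2, 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p_value, (0 + 1) / 100, tolerance = 0.05)
  # joint relabeling leaves r unchanged
  perm <- sample(rownames(d1))
  res2 <- mantel_test(dist_matrix(d1[perm, perm]),
                      dist_matrix(d2[perm, perm]), 99, seed = 1)
  expect_equal(res2$r, res$r)
  # reproducible under a fixed seed
  mm <- matrix(runif(36), 6); mm <- (mm + t(mm)) / 2; diag(mm) <- 0
  d3 <- dist_matrix(mm)
  expect_identical(mantel_test(d1, d3, 500, seed = 7),
                   mantel_test(d1, d3, 500, seed = 7))
  expect_error(mantel_test(d1, dist_matrix(d1[perm, perm])), "labels")
  expect_error(mantel_test(d1, dist_matrix(matrix(0, 6, 6),
                                           rownames(d1))), "constant")
})

test_that("mantel_test agrees with the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(65)
  a <- matrix(runif(49), 7); a <- (a + t(a)) / 2; diag(a) <- 0
  b <- a + matrix(rnorm(49, sd = 0.1), 7)
  b <- (b + t(b)) / 2; diag(b) <- 0; b <- abs(b)
  d1 <- dist_matrix(a); d2 <- dist_matrix(b)
  ours <- mantel_test(d1, d2, 999, seed = 3)
  ref <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  # permutation p-values from the two implementations agree closely
  expect_equal(ours$p_value, ref$signif, tolerance = 0.05)
})

test_that("mantel_table covers every parameter over shared sites", {
  set.seed(66)
  x <- matrix(rnorm(24), 6)
  g <- make_geochem(x)
  comm <- matrix(runif(36), 6); comm <- (comm + t(comm)) / 2; diag(comm) <- 0
  dimnames(comm) <- list(rownames(x <- g$values), rownames(g$values))
  tab <- mantel_table(dist_matrix(comm), g, 99, seed = 2)
  expect_equal(tab$parameter, colnames(g$values))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true(all(tab$n_sites == 6))
})
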