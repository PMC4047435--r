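# Independent oracles and fixture builders shared across the suite.
# These deliberately avoid the package's own code paths: naive loops and
# a bare-bones dense MCL, so agreement is a genuine two-route check.

# naive O(n^3) matrix product
naive_matmul <- function(a, b) {
  n <- nrow(a); p <- ncol(b)
  out <- matrix(0, n, p)
  for (i in seq_len(n)) for (j in seq_len(p))
    for (k in seq_len(ncol(a))) out[i, j] <- out[i, j] + a[i, k] * b[k, j]
  out
}

# bare-bones dense MCL: plain loops, no pruning shortcuts, no
# per-component decomposition; clusters read as connected components of
# the symmetrised nonzero pattern of the limit matrix
naive_mcl <- function(g, inflation, max_iter = 500, tol = 1e-8) {
  ids <- g$nodes$id
  n <- length(ids)
  a <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(g$edges)) {
    fi <- match(g$edges$from, ids); ti <- match(g$edges$to, ids)
    a[cbind(fi, ti)] <- g$edges$weight
    a[cbind(ti, fi)] <- g$edges$weight
  }
  for (i in seq_len(n)) {
    inc <- max(a[, i])
    a[i, i] <- if (inc > 0) inc else 1
  }
  m <- sweep(a, 2, colSums(a), "/")
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m
    m2 <- m2^inflation
    m2[m2 < 1e-6] <- 0
    m2 <- sweep(m2, 2, colSums(m2), "/")
    if (max(abs(m2 - m)) < tol) { m <- m2; break }
    m <- m2
  }
  adj <- (m + t(m)) > 0
  seen <- rep(FALSE, n)
  clusters <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    frontier <- i
    seen[i] <- TRUE
    while (length(frontier)) {
      nxt <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & !seen)
      seen[nxt] <- TRUE
      comp <- c(comp, nxt)
      frontier <- nxt
    }
    clusters <- c(clusters, list(sort(ids[comp])))
  }
  clusters
}

# canonical form of a partition for set-wise comparison
canon_partition <- function(clusters) {
  cl <- lapply(clusters, sort)
  cl[order(vapply(cl, `[`, "", 1L))]
}

# modular random graph: k planted modules, heavy intra-module edges and
# (optionally) light inter-module edges
modular_graph <- function(k = 3, size = 4, intra = 10, inter = 0,
                          p_inter = 0.3, seed = 1) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(k * size))
  module <- rep(seq_len(k), each = size)
  samples <- sprintf("s%d", rep_len(1:2, length(ids)))
  from <- to <- character(0); w <- numeric(0)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    if (module[i] == module[j]) {
      from <- c(from, ids[i]); to <- c(to, ids[j])
      w <- c(w, intra * runif(1, 0.8, 1.2))
    } else if (inter > 0 && runif(1) < p_inter) {
      from <- c(from, ids[i]); to <- c(to, ids[j])
      w <- c(w, inter * runif(1, 0.8, 1.2))
    }
  }
  similarity_graph(data.frame(id = ids, sample_id = samples),
                   data.frame(from = from, to = to, weight = w))
}

# clique graph helper: named list of cliques -> similarity_graph
clique_graph <- function(cliques, weight = 10, bridges = NULL) {
  ids <- unlist(cliques)
  from <- to <- character(0); w <- numeric(0)
  for (cl in cliques) {
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (i < j) { from <- c(from, cl[i]); to <- c(to, cl[j]); w <- c(w, weight) }
    }
  }
  if (!is.null(bridges)) {
    from <- c(from, bridges$from); to <- c(to, bridges$to)
    w <- c(w, bridges$weight)
  }
  similarity_graph(data.frame(id = ids, sample_id = "s1"),
                   data.frame(from = from, to = to, weight = w))
}

# random presence matrix guaranteeing every sample has >= 1 cluster
random_presence <- function(n_clusters = 8, n_samples = 4, p = 0.5,
                            seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(runif(n_clusters * n_samples) < p, n_clusters, n_samples,
                dimnames = list(sprintf("C%03d", seq_len(n_clusters)),
                                sprintf("S%d", seq_len(n_samples))))
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) >= 2 && all(colSums(m) > 0)) return(m)
  }
}

# random additive distance matrix from a random tree with known branch
# lengths; returns list(tree, d)
random_additive <- function(n_tips = 6, seed = 1) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, br = function(n) runif(n, 0.5, 2))
  tr <- ape::unroot(tr)
  d <- ape::cophenetic.phylo(tr)
  d <- d[sort(rownames(d)), sort(rownames(d))]
  list(tree = tr, d = d)
}

# the worked 3-sample toy fixture: cluster sets A = {1,2,3},
# B = {2,3,4}, C = {5,6}, hand-computed Jaccard entries
#   d(A,B) = 1 - 2/4 = 0.5,  d(A,C) = d(B,C) = 1,  diagonal 0
toy_presence <- function() {
  m <- matrix(FALSE, 6, 3,
              dimnames = list(sprintf("C%03d", 1:6), c("A", "B", "C")))
  m[c(1, 2, 3), "A"] <- TRUE
  m[c(2, 3, 4), "B"] <- TRUE
  m[c(5, 6), "C"] <- TRUE
  m
}

toy_jaccard_expected <- function() {
  matrix(c(0, 0.5, 1, 0.5, 0, 1, 1, 1, 0), 3, 3,
         dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
}

# sequence-level version of the same fixture: six random 180-residue
# families, samples carrying A = {f1,f2,f3}, B = {f2,f3,f4}, C = {f5,f6},
# identical copies within a family
toy_records <- function() {
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  set.seed(4242)
  fams <- vapply(1:6, function(i) paste(sample(aa, 180, TRUE), collapse = ""), "")
  protein_records(
    id = c("A|p1", "A|p2", "A|p3", "B|p1", "B|p2", "B|p3", "C|p1", "C|p2"),
    sample_id = c("A", "A", "A", "B", "B", "B", "C", "C"),
    sequence = fams[c(1, 2, 3, 2, 3, 4, 5, 6)])
}
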