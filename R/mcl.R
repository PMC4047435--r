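# Markov clustering (MCL) from scratch: expansion (matrix squaring) and
# inflation (entry-wise power + renormalisation) on a column-stochastic
# transition matrix, iterated to a fixed point whose nonzero pattern is
# read out as hard clusters.

MCL_PRUNE <- 1e-6

# simple union-find over 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

# connected components of a similarity graph; integer membership vector
graph_components <- function(g) {
  ids <- g$nodes$id
  parent <- uf_new(length(ids))
  if (nrow(g$edges)) {
    fi <- match(g$edges$from, ids)
    ti <- match(g$edges$to, ids)
    for (k in seq_along(fi)) parent <- uf_union(parent, fi[k], ti[k])
  }
  roots <- vapply(seq_along(ids), function(i) uf_find(parent, i), 1L)
  match(roots, unique(roots))
}

#' Column-stochastic transition matrix from a similarity graph
#'
#' Adds a self-loop to every node equal to its maximum incident edge
#' weight (1 for isolated nodes) -- the standard MCL recipe, which also
#' prevents period-2 oscillation -- then normalises each column to sum 1.
#'
#' @param g a [similarity_graph].
#' @param sparse use a sparse \pkg{Matrix} representation; defaults to
#'   dense below 2000 nodes.
#' @return A column-stochastic matrix with node ids as dimnames.
#' @export
to_stochastic <- function(g, sparse = nrow(g$nodes) > 2000) {
  stopifnot(inherits(g, "similarity_graph"))
  ids <- g$nodes$id
  n <- length(ids)
  if (n == 0L) stop("empty graph")
  fi <- match(g$edges$from, ids)
  ti <- match(g$edges$to, ids)
  w <- g$edges$weight
  loop <- rep(1, n)
  if (length(fi)) {
    mx <- tapply(c(w, w), c(fi, ti), max)
    loop[as.integer(names(mx))] <- mx
  }
  if (sparse) {
    m <- Matrix::sparseMatrix(i = c(fi, ti, seq_len(n)),
                              j = c(ti, fi, seq_len(n)),
                              x = c(w, w, loop), dims = c(n, n),
                              dimnames = list(ids, ids))
  } else {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    if (length(fi)) {
      m[cbind(fi, ti)] <- w
      m[cbind(ti, fi)] <- w
    }
    diag(m) <- loop
  }
  normalize_columns(m)
}

normalize_columns <- function(m) {
  cs <- Matrix::colSums(m)
  if (any(cs == 0)) stop("zero column in transition matrix")
  if (inherits(m, "sparseMatrix")) {
    m %*% Matrix::Diagonal(x = 1 / cs)
  } else {
    sweep(m, 2L, cs, "/")
  }
}

#' MCL expansion step
#'
#' Squares the column-stochastic matrix (two steps of the random walk).
#'
#' @param m column-stochastic matrix.
#' @return `m %*% m`, still column-stochastic.
#' @export
mcl_expand <- function(m) {
  dn <- dimnames(m)
  out <- m %*% m
  dimnames(out) <- dn
  out
}

#' MCL inflation step
#'
#' Entry-wise power `r` followed by column renormalisation; entries below
#' `prune` are zeroed before renormalising.  Inflation sharpens the walk:
#' it raises the largest entry of every non-uniform column.
#'
#' @param m column-stochastic matrix.
#' @param r inflation exponent, must exceed 1.
#' @param prune pruning threshold (default `1e-6`).
#' @return Column-stochastic matrix.
#' @export
mcl_inflate <- function(m, r, prune = MCL_PRUNE) {
  if (r <= 1) stop("inflation must be > 1")
  dn <- dimnames(m)
  if (inherits(m, "sparseMatrix")) {
    m <- m^r
    m <- Matrix::drop0(m, tol = prune)
  } else {
    m <- m^r
    m[m < prune] <- 0
  }
  out <- normalize_columns(m)
  dimnames(out) <- dn
  out
}

# iterate expansion/inflation on one stochastic matrix until the largest
# absolute entry change drops below tol
mcl_iterate <- function(m, inflation, max_iter, tol, prune) {
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    m2 <- mcl_inflate(mcl_expand(m), inflation, prune)
    delta <- max(abs(m2 - m))
    m <- m2
    iter <- iter + 1L
    if (delta < tol) { converged <- TRUE; break }
  }
  list(m = m, iterations = iter, converged = converged)
}

# read hard clusters off the limit matrix: attractors are nodes with
# nonzero diagonal; attractor systems are merged along nonzero entries;
# every other node follows its largest limit-matrix entry (ties to the
# system containing the smallest id).
interpret_limit <- function(m, ids) {
  m <- as.matrix(m)
  n <- length(ids)
  attract <- which(diag(m) > 0)
  if (length(attract) == 0L) attract <- seq_len(n)  # degenerate safeguard
  parent <- uf_new(length(attract))
  for (ai in seq_along(attract)) {
    for (bi in seq_along(attract)) {
      if (ai < bi) {
        a <- attract[ai]; b <- attract[bi]
        if (m[a, b] > 0 || m[b, a] > 0) parent <- uf_union(parent, ai, bi)
      }
    }
  }
  sys_of <- vapply(seq_along(attract), function(i) uf_find(parent, i), 1L)
  assign <- integer(n)
  assign[attract] <- sys_of
  for (j in setdiff(seq_len(n), attract)) {
    wt <- m[attract, j]
    if (all(wt == 0)) { assign[j] <- NA_integer_; next }
    best <- which(wt == max(wt))
    if (length(best) > 1L) {
      # tie: pick the system containing the smallest node id
      cand <- sys_of[best]
      minid <- vapply(cand, function(s) min(ids[attract[sys_of == s]]), "")
      best <- best[order(minid)][1L]
    }
    assign[j] <- sys_of[best]
  }
  out <- list()
  for (s in unique(assign[!is.na(assign)]))
    out <- c(out, list(sort(ids[which(assign == s)])))
  for (j in which(is.na(assign)))  # unreachable nodes become singletons
    out <- c(out, list(ids[j]))
  out
}

#' Markov clustering of a similarity graph
#'
#' Alternates expansion and inflation on the column-stochastic transition
#' matrix until the largest entry change falls below `tol`, then reads
#' hard clusters off the limit matrix (each node joins the attractor
#' system it flows to; ties go to the cluster containing the smallest
#' node id).  The graph is decomposed into connected components first and
#' iterated per block -- the transition matrix is block-diagonal, so the
#' result is identical to whole-matrix iteration (set
#' `by_component = FALSE` to force the latter).
#'
#' @param g a [similarity_graph].
#' @param inflation inflation exponent (> 1); default 1.2, the granularity
#'   used for whole-metagenome comparisons.
#' @param max_iter iteration cap per component (default 200); hitting it
#'   raises a warning and returns best-effort clusters.
#' @param tol convergence tolerance on the max entry change (default
#'   `1e-8`).
#' @param prune entry pruning threshold (default `1e-6`).
#' @param by_component iterate per connected component (default TRUE).
#' @return An object of class `mcl_clusters`: list of disjoint clusters
#'   (sorted by size, then smallest member id), plus `inflation`,
#'   `iterations_run` and `converged`.
#' @export
mcl <- function(g, inflation = 1.2, max_iter = 200L, tol = 1e-8,
                prune = MCL_PRUNE, by_component = TRUE) {
  stopifnot(inherits(g, "similarity_graph"))
  if (inflation <= 1) stop("inflation must be > 1")
  if (nrow(g$nodes) == 0L) stop("empty graph")
  ids <- g$nodes$id
  clusters <- list()
  iterations <- 0L
  converged <- TRUE
  if (by_component) {
    comp <- graph_components(g)
    for (ci in unique(comp)) {
      members <- ids[comp == ci]
      if (length(members) == 1L) {
        clusters <- c(clusters, list(members))
        next
      }
      keep <- g$edges$from %in% members  # edges never straddle components
      sub <- similarity_graph(g$nodes[g$nodes$id %in% members, , drop = FALSE],
                              g$edges[keep, , drop = FALSE])
      res <- mcl_iterate(to_stochastic(sub), inflation, max_iter, tol, prune)
      iterations <- max(iterations, res$iterations)
      converged <- converged && res$converged
      clusters <- c(clusters, interpret_limit(res$m, members))
    }
  } else {
    res <- mcl_iterate(to_stochastic(g), inflation, max_iter, tol, prune)
    iterations <- res$iterations
    converged <- res$converged
    clusters <- interpret_limit(res$m, ids)
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations; ",
            "returning best-effort clusters")
  sizes <- lengths(clusters)
  minid <- vapply(clusters, min, "")
  clusters <- clusters[order(-sizes, minid)]
  structure(list(clusters = clusters, inflation = inflation,
                 iterations_run = iterations, converged = converged,
                 n_nodes = length(ids)),
            class = "mcl_clusters")
}

#' @export
print.mcl_clusters <- function(x, ...) {
  cat("MCL clustering: ", length(x$clusters), " clusters over ",
      x$n_nodes, " proteins (inflation ", x$inflation, ", ",
      x$iterations_run, " iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  sz <- lengths(x$clusters)
  cat("cluster sizes: ", paste(utils::head(sz, 10L), collapse = " "),
      if (length(sz) > 10L) " ...", "\n", sep = "")
  invisible(x)
}

#' Write MCL clusters in the native cluster-per-line dialect
#'
#' One cluster per line, member ids tab-separated -- directly diffable
#' against the output of the reference MCL tool.
#'
#' @param x an `mcl_clusters` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mcl_clusters <- function(x, path) {
  stopifnot(inherits(x, "mcl_clusters"))
  writeLines(vapply(x$clusters, paste, "", collapse = "\t"), path)
  invisible(path)
}
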