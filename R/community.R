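# Community distance: cluster presence/absence per metagenome, binary
# Jaccard dissimilarity, neighbor-joining dendrograms and patristic
# (total branch length) distances between communities.

#' Cluster-by-sample presence matrix
#'
#' A cluster is present in a sample iff at least one member protein
#' originates from that sample.  Column sums are the per-sample Markov
#' cluster counts reused by the diversity metrics.
#'
#' @param clusters an `mcl_clusters` object (or plain list of character
#'   vectors of protein ids).
#' @param node_samples named character vector mapping protein id to
#'   sample id.
#' @return Logical matrix, clusters x samples; row names are cluster ids
#'   (`C0001`, ... in cluster order), column names sorted sample ids.
#' @export
presence_matrix <- function(clusters, node_samples) {
  cl <- if (inherits(clusters, "mcl_clusters")) clusters$clusters else clusters
  members <- unlist(cl, use.names = FALSE)
  unknown <- setdiff(members, names(node_samples))
  if (length(unknown))
    stop("protein id(s) without sample tag: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  samples <- sort(unique(unname(node_samples[members])))
  ids <- sprintf("C%0*d", max(4L, nchar(length(cl))), seq_along(cl))
  p <- matrix(FALSE, length(cl), length(samples),
              dimnames = list(ids, samples))
  for (i in seq_along(cl))
    p[i, unique(unname(node_samples[cl[[i]]]))] <- TRUE
  p
}

#' Binary Jaccard dissimilarity between two metagenomes
#'
#' `1 - |A intersect B| / |A union B|` where `A` and `B` are the Markov
#' cluster sets of the two samples: 0 when every cluster occurs in both
#' metagenomes, 1 when none is shared.
#'
#' @param p presence matrix from [presence_matrix()].
#' @param sample_a,sample_b column names in `p`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
jaccard_dissimilarity <- function(p, sample_a, sample_b) {
  if (!all(c(sample_a, sample_b) %in% colnames(p)))
    stop("unknown sample id")
  a <- p[, sample_a]
  b <- p[, sample_b]
  if (!any(a) || !any(b))
    stop("Jaccard dissimilarity undefined for a sample with zero clusters")
  1 - sum(a & b) / sum(a | b)
}

#' Pairwise Jaccard dissimilarity matrix
#'
#' @param p presence matrix from [presence_matrix()].
#' @return A symmetric zero-diagonal distance matrix over samples.
#' @export
dissimilarity_matrix <- function(p) {
  samples <- colnames(p)
  if (length(samples) < 2L) stop("need at least two samples")
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    d[i, j] <- d[j, i] <- jaccard_dissimilarity(p, samples[i], samples[j])
  dist_matrix(d)
}

#' Neighbor-joining dendrogram from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`, with branch
#' lengths from the standard NJ formulas.  Q ties are broken by the
#' lexicographically smallest label pair (merged nodes carry their
#' smallest leaf label), making the output deterministic.  Negative
#' branch lengths are kept as computed by default; `negative = "clamp"`
#' zeroes them and moves the deficit onto the sister branch so the joined
#' pair's path length is preserved.
#'
#' @param d symmetric distance matrix with >= 3 labelled taxa.
#' @param negative `"keep"` (default) or `"clamp"`.
#' @return An unrooted `phylo` tree with branch lengths; consistent on
#'   additive matrices (recovers the generating tree exactly).
#' @export
neighbor_joining <- function(d, negative = c("keep", "clamp")) {
  negative <- match.arg(negative)
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("input must be a symmetric distance matrix")
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must be labelled")
  n <- nrow(d)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  # active node state: newick fragment and smallest contained leaf label
  frag <- labels
  rep_label <- labels
  fix <- function(li, lj) {
    if (negative == "clamp") {
      if (li < 0) { lj <- lj + li; li <- 0 }
      if (lj < 0) { li <- max(li + lj, 0); lj <- 0 }
    }
    c(li, lj)
  }
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    if (nrow(best) > 1L) {
      key <- apply(best, 1L, function(ij) {
        pair <- sort(c(rep_label[ij[1L]], rep_label[ij[2L]]))
        paste(pair, collapse = "\r")
      })
      best <- best[order(key)[1L], , drop = FALSE]
    }
    i <- best[1L, 1L]; j <- best[1L, 2L]
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    lens <- fix(li, lj)
    new_frag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], lens[1L],
                        frag[j], lens[2L])
    new_rep <- min(rep_label[i], rep_label[j])
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_label <- c(rep_label[keep], new_rep)
    rownames(d) <- colnames(d) <- rep_label
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (negative == "clamp") { la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0) }
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 frag[1L], la, frag[2L], lb, frag[3L], lc)
  ape::read.tree(text = txt)
}

#' Canonical linear leaf order of a dendrogram
#'
#' An unrooted dendrogram determines a leaf sequence only up to rotations
#' at internal nodes, so "reading the leaves in tree order" needs a
#' canonical embedding.  This uses the tree's principal path: leaves are
#' ordered by patristic distance from one end of the tree diameter (the
#' leaf pair at maximal patristic distance; the end with the smaller
#' label is the origin).  For dendrograms built from gradient-structured
#' communities this recovers the gradient ordering.
#'
#' @param tree a `phylo` object with branch lengths.
#' @return Character vector of tip labels in canonical order.
#' @export
leaf_order <- function(tree) {
  pat <- patristic_distances(tree)
  ends <- which(pat == max(pat), arr.ind = TRUE)
  origin <- sort(rownames(pat)[ends[1, ]])[1L]
  rownames(pat)[order(pat[origin, ], rownames(pat))]
}

#' Patristic distances between the leaves of a tree
#'
#' Entry (a, b) is the total branch length along the unique path between
#' leaves a and b -- the "Markov cluster distance" between communities
#' when applied to the Jaccard NJ dendrogram.
#'
#' @param tree a `phylo` object with branch lengths on every edge.
#' @return A symmetric zero-diagonal matrix over the tip labels, in tip
#'   label order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths on all edges")
  m <- ape::cophenetic.phylo(tree)
  m <- m[tree$tip.label, tree$tip.label]
  dist_matrix(m, allow_negative = TRUE, tol = 1e-6)
}
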