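# Homology graph construction: exact local alignment scores, Karlin-Altschul
# E-values, and the thresholded all-vs-all similarity network that Markov
# clustering consumes.

# Ungapped BLOSUM62 Karlin-Altschul parameters; configurable everywhere.
KA_K <- 0.134
KA_LAMBDA <- 0.3176
WEIGHT_CAP <- 200

# BLOSUM62 with X made score-neutral (0 against everything), so unknown
# residues neither reward nor penalise an alignment.
blosum62_neutral_x <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      m["X", ] <- 0L
      m[, "X"] <- 0L
      cache <<- m
    }
    cache
  }
})

#' Optimal local alignment score
#'
#' Exact Smith-Waterman local alignment under affine gap penalties,
#' computed with \pkg{Biostrings}.  A gap of length L costs
#' `gap_open + L * gap_extend`.  The score of the empty alignment is 0, so
#' sequence pairs with no positively scoring residue pair score 0.
#' Residues outside the 20-letter alphabet are treated as score-neutral
#' `X`.
#'
#' @param a,b non-empty amino-acid strings.
#' @param substitution_matrix integer substitution matrix; default BLOSUM62
#'   with neutral `X`.
#' @param gap_open,gap_extend affine gap penalties (positive costs);
#'   defaults 11 and 1.
#' @return A list with `raw_score` and `bit_score` (under the default
#'   ungapped Karlin-Altschul parameters `K` = 0.134, `lambda` = 0.3176).
#' @export
local_align <- function(a, b, substitution_matrix = blosum62_neutral_x(),
                        gap_open = 11, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  a <- clean_aa(a)
  b <- clean_aa(b)
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
  s <- max(0, s)
  list(raw_score = s,
       bit_score = (KA_LAMBDA * s - log(KA_K)) / log(2))
}

# map residues outside the supported alphabet to X
clean_aa <- function(x) {
  gsub(sprintf("[^%s]", AA_ALPHABET), "X", toupper(x))
}

#' Karlin-Altschul expectation value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw alignment score `S` against
#' search-space sizes `m` (total query letters) and `n` (total database
#' letters).  Strictly decreasing in `S`.
#'
#' @param raw_score raw local alignment score(s).
#' @param m,n positive search-space sizes in residues.
#' @param K,lambda Karlin-Altschul parameters; defaults are the ungapped
#'   BLOSUM62 values 0.134 and 0.3176.
#' @return Expectation value(s), same length as `raw_score`.
#' @export
evalue <- function(raw_score, m, n, K = KA_K, lambda = KA_LAMBDA) {
  if (m <= 0 || n <= 0) stop("'m' and 'n' must be positive")
  if (K <= 0 || lambda <= 0) stop("'K' and 'lambda' must be positive")
  K * m * n * exp(-lambda * raw_score)
}

#' Similarity graph constructor
#'
#' Weighted undirected homology graph: nodes are proteins tagged with
#' their sample of origin, edges carry positive weights.  Self-edges are
#' rejected (MCL adds its own self-loops); reciprocal duplicates are
#' collapsed keeping the larger weight.
#'
#' @param nodes data frame with columns `id` and `sample_id`.
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @return An object of class `similarity_graph`.
#' @export
similarity_graph <- function(nodes, edges) {
  stopifnot(all(c("id", "sample_id") %in% names(nodes)),
            all(c("from", "to", "weight") %in% names(edges)))
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node id(s)")
  if (nrow(edges)) {
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (any(edges$from == edges$to)) stop("self-edges not allowed")
    if (any(edges$weight <= 0)) stop("edge weights must be positive")
    unknown <- setdiff(c(edges$from, edges$to), nodes$id)
    if (length(unknown))
      stop("edge endpoint(s) not in node set: ",
           paste(unknown, collapse = ", "))
    # canonical orientation, best weight per unordered pair
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, sep = "\r")
    ord <- order(key, -edges$weight)
    edges <- edges[ord[!duplicated(key[ord])], , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes[, c("id", "sample_id")],
                 edges = edges[, c("from", "to", "weight")]),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("Similarity graph: ", nrow(x$nodes), " proteins, ",
      nrow(x$edges), " edges, ",
      length(unique(x$nodes$sample_id)), " sample(s)\n", sep = "")
  invisible(x)
}

# -log10(E) edge weight, capped; E = 0 maps to the cap
edge_weight <- function(e, cap = WEIGHT_CAP) {
  w <- ifelse(e <= 0, cap, -log10(e))
  pmin(pmax(w, 0), cap)
}

#' All-vs-all similarity graph from protein sequences
#'
#' Aligns every protein pair (exact local alignment, BLOSUM62, affine
#' gaps), converts raw scores to Karlin-Altschul E-values with
#' `m = n =` total residue count, and keeps an edge wherever the E-value
#' is strictly better than (below) `e_threshold`.  Edge weight is
#' `min(-log10(E), weight_cap)`; an E-value of zero maps to the cap.
#' Within-sample and between-sample edges are both kept.
#'
#' @param records a [protein_records] data frame with >= 2 rows.
#' @param e_threshold strict E-value cutoff (default `1e-40`).
#' @param K,lambda Karlin-Altschul parameters.
#' @param weight_cap upper bound for edge weights (default 200).
#' @param gap_open,gap_extend affine gap penalties.
#' @return A [similarity_graph].
#' @export
all_vs_all <- function(records, e_threshold = 1e-40, K = KA_K,
                       lambda = KA_LAMBDA, weight_cap = WEIGHT_CAP,
                       gap_open = 11, gap_extend = 1) {
  if (nrow(records) < 2L) stop("need at least two records")
  if (e_threshold <= 0) stop("'e_threshold' must be positive")
  n_rec <- nrow(records)
  seqs <- Biostrings::AAStringSet(setNames(clean_aa(records$sequence),
                                           records$id))
  total <- sum(Biostrings::width(seqs))
  sub <- blosum62_neutral_x()
  from <- to <- character(0)
  ev <- numeric(0)
  for (i in seq_len(n_rec - 1L)) {
    js <- (i + 1L):n_rec
    scores <- Biostrings::pairwiseAlignment(
      seqs[js], seqs[[i]], type = "local", substitutionMatrix = sub,
      gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
    scores <- pmax(0, scores)
    e <- evalue(scores, m = total, n = total, K = K, lambda = lambda)
    hit <- e < e_threshold
    if (any(hit)) {
      from <- c(from, rep(records$id[i], sum(hit)))
      to <- c(to, records$id[js][hit])
      ev <- c(ev, e[hit])
    }
  }
  similarity_graph(records[, c("id", "sample_id")],
                   data.frame(from = from, to = to,
                              weight = edge_weight(ev, weight_cap),
                              stringsAsFactors = FALSE))
}

#' Similarity graph from imported tabular hits
#'
#' Builds the same thresholded graph as [all_vs_all()] but from externally
#' computed homology hits (see [read_tabular_hits()]).  For reciprocal
#' hits with different E-values the best (smallest) is kept, so the graph
#' is search-engine-agnostic.
#'
#' @param hits data frame as returned by [read_tabular_hits()].
#' @param nodes data frame with columns `id`, `sample_id` covering every
#'   protein (hits to unknown ids are an error).
#' @param e_threshold strict E-value cutoff (default `1e-40`).
#' @param weight_cap upper bound for edge weights.
#' @return A [similarity_graph].
#' @export
graph_from_hits <- function(hits, nodes, e_threshold = 1e-40,
                            weight_cap = WEIGHT_CAP) {
  if (e_threshold <= 0) stop("'e_threshold' must be positive")
  keep <- hits$query_id != hits$subject_id & hits$e_value < e_threshold
  h <- hits[keep, , drop = FALSE]
  similarity_graph(nodes,
                   data.frame(from = h$query_id, to = h$subject_id,
                              weight = edge_weight(h$e_value, weight_cap),
                              stringsAsFactors = FALSE))
}

#' Export a similarity graph as a tab-separated edge list
#'
#' One line per edge: `id1 TAB id2 TAB weight` -- the label-input dialect
#' common to graph clustering tools.
#'
#' @param g a [similarity_graph].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "similarity_graph"))
  writeLines(sprintf("%s\t%s\t%.6g", g$edges$from, g$edges$to,
                     g$edges$weight), path)
  invisible(path)
}
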