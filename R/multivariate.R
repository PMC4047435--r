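# Multivariate statistics: per-parameter geochemical distance matrices,
# Pearson correlation matrices, principal component ordination with
# PC-space distances, and Mantel permutation tests.

#' Per-parameter geochemical distance matrix
#'
#' Entry (i, j) is the absolute difference `|x_i - x_j|` of one
#' geochemical parameter between two sites.  Sites missing the parameter
#' are dropped with a warning.
#'
#' @param g a [geochem_table].
#' @param parameter parameter (column) name.
#' @return A symmetric zero-diagonal distance matrix over the retained
#'   sites.
#' @export
parameter_distance <- function(g, parameter) {
  stopifnot(inherits(g, "geochem_table"))
  if (!parameter %in% colnames(g$values))
    stop("unknown parameter: ", parameter)
  x <- g$values[, parameter]
  if (anyNA(x)) {
    warning("dropping ", sum(is.na(x)), " site(s) missing '", parameter, "'")
    x <- x[!is.na(x)]
  }
  if (length(x) < 3L)
    stop("fewer than 3 sites with '", parameter, "' measured")
  dist_matrix(abs(outer(x, x, "-")), names(x))
}

#' Pearson correlation matrix of geochemistry (plus diversity metrics)
#'
#' Pairwise-complete Pearson correlations between every pair of
#' geochemical parameters, optionally augmented with extra per-site
#' columns (e.g. the three diversity metrics).  Zero-variance variables
#' get `NA` rows/columns with a warning.
#'
#' @param g a [geochem_table].
#' @param extra_columns optional numeric matrix/data frame of additional
#'   per-site variables, rows matching the sites of `g`.
#' @param digits optional rounding applied to the returned matrix (the
#'   published-style tables use 2); `NULL` for full precision.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(g, extra_columns = NULL, digits = NULL) {
  stopifnot(inherits(g, "geochem_table"))
  x <- g$values
  if (!is.null(extra_columns)) {
    extra_columns <- as.matrix(extra_columns)
    if (nrow(extra_columns) != nrow(x))
      stop("'extra_columns' must have one row per site")
    x <- cbind(x, extra_columns)
  }
  sds <- apply(x, 2, sd, na.rm = TRUE)
  flat <- which(!is.na(sds) & sds == 0)
  if (length(flat))
    warning("zero-variance variable(s): ",
            paste(colnames(x)[flat], collapse = ", "))
  r <- suppressWarnings(cor(x, use = "pairwise.complete.obs",
                            method = "pearson"))
  diag(r) <- 1
  if (length(flat)) {
    r[flat, ] <- NA_real_
    r[, flat] <- NA_real_
  }
  if (!is.null(digits)) r <- round(r, digits)
  r
}

#' Principal component analysis of a geochemistry table
#'
#' Eigendecomposition of the covariance (`scale = FALSE`) or correlation
#' (`scale = TRUE`, the default, matching ordination with unit-variance
#' standardisation) matrix of the site-by-parameter data.  Sites with
#' missing values are dropped (listwise) with a message.  The sign of
#' each loading column is fixed so its largest-magnitude entry is
#' positive.
#'
#' @param g a [geochem_table] (or plain sites x parameters matrix).
#' @param scale standardise parameters to unit variance (default TRUE).
#' @return An object of class `geochem_pca` with `eigenvalues`,
#'   `variance_fraction`, `loadings` (parameters x components, unit-norm
#'   columns), `scores` (sites x components) and `scaled`.
#' @export
geochem_pca <- function(g, scale = TRUE) {
  x <- if (inherits(g, "geochem_table")) g$values else as.matrix(g)
  complete <- stats::complete.cases(x)
  if (!all(complete)) {
    message("dropping ", sum(!complete), " site(s) with missing values")
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 complete sites")
  if (scale) {
    flat <- apply(x, 2, sd) == 0
    if (any(flat)) {
      message("dropping zero-variance parameter(s): ",
              paste(colnames(x)[flat], collapse = ", "))
      x <- x[, !flat, drop = FALSE]
    }
  }
  p <- prcomp(x, center = TRUE, scale. = scale)
  loadings <- p$rotation
  scores <- p$x
  for (k in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0) {
      loadings[, k] <- -loadings[, k]
      scores[, k] <- -scores[, k]
    }
  }
  ev <- p$sdev^2
  structure(list(eigenvalues = ev,
                 variance_fraction = ev / sum(ev),
                 loadings = loadings, scores = scores,
                 scaled = scale, center = p$center,
                 sdev = p$sdev),
            class = "geochem_pca")
}

#' @export
print.geochem_pca <- function(x, ...) {
  cat("PCA of geochemistry (", if (x$scaled) "correlation" else "covariance",
      " based): ", nrow(x$scores), " sites, ", nrow(x$loadings),
      " parameters\n", sep = "")
  vf <- round(100 * x$variance_fraction, 1)
  cat("variance explained (%):", paste(utils::head(vf, 5L), collapse = " "),
      if (length(vf) > 5L) "...", "\n")
  invisible(x)
}

#' PCA of a correlation matrix
#'
#' Eigendecomposition of a pre-computed correlation matrix -- PCA of
#' standardised data when only the published correlation table (not the
#' raw measurements) is available.  No site scores are produced.
#'
#' @param r symmetric correlation matrix.
#' @return A `geochem_pca`-like object with `eigenvalues`,
#'   `variance_fraction` and `loadings` (no scores).
#' @export
cor_pca <- function(r) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r) || max(abs(r - t(r))) > 1e-8)
    stop("input must be a symmetric correlation matrix")
  e <- eigen(r, symmetric = TRUE)
  ev <- pmax(e$values, 0)  # tiny negatives from rounded published tables
  loadings <- e$vectors
  rownames(loadings) <- rownames(r)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  for (k in seq_len(ncol(loadings))) {
    if (loadings[which.max(abs(loadings[, k])), k] < 0)
      loadings[, k] <- -loadings[, k]
  }
  structure(list(eigenvalues = ev, variance_fraction = ev / sum(ev),
                 loadings = loadings, scores = NULL, scaled = TRUE),
            class = "geochem_pca")
}

#' Euclidean distance between sites in principal component space
#'
#' Distances between site score vectors truncated to the first `k`
#' components -- the "overall geochemical distance" between sites.
#'
#' @param p a `geochem_pca` with scores.
#' @param k number of leading components (default 3).
#' @return A symmetric distance matrix over sites.
#' @export
pc_space_distance <- function(p, k = 3L) {
  stopifnot(inherits(p, "geochem_pca"))
  if (is.null(p$scores)) stop("PCA result has no site scores")
  if (k > ncol(p$scores)) stop("'k' exceeds the number of components")
  s <- p$scores[, seq_len(k), drop = FALSE]
  dist_matrix(as.matrix(dist(s)), rownames(s))
}

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation over the `n(n-1)/2` off-diagonal pairs, with a
#' permutation null built by simultaneously permuting the rows and
#' columns of the second matrix.  One-sided (greater) p-value with the
#' +1 correction: `p = (#{r_perm >= r_obs} + 1) / (n_permutations + 1)`.
#'
#' @param d1,d2 distance matrices with identical labels in identical
#'   order.
#' @param n_permutations number of permutations (default 1000).
#' @param seed optional integer seed for reproducible permutations.
#' @return An object of class `mantel_result` with `r`, `p_value`,
#'   `n_permutations` and `method`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 1000L, seed = NULL) {
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (is.null(rownames(d1)) || is.null(rownames(d2)) ||
      !identical(rownames(d1), rownames(d2)))
    stop("distance matrices must share identical labels in identical order")
  n <- nrow(d1)
  if (n < 4L) stop("Mantel test needs at least 4 sites")
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  v2 <- d2[lt]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("Mantel r undefined for a constant distance matrix")
  r_obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  count <- 0L
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    r_perm <- cor(v1, d2[idx, idx][lt])
    if (r_perm >= r_obs) count <- count + 1L
  }
  structure(list(r = r_obs,
                 p_value = (count + 1L) / (n_permutations + 1L),
                 n_permutations = as.integer(n_permutations),
                 method = "pearson", n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel statistic (Pearson): r = %.4f, p = %.4g (%d sites, %d permutations)\n",
              x$r, x$p_value, x$n, x$n_permutations))
  invisible(x)
}

#' Mantel tests of community distance against every geochemical parameter
#'
#' One Mantel test per geochemical parameter, relating the per-parameter
#' absolute-difference matrix to the community distance matrix over the
#' shared sites.
#'
#' @param community distance matrix over samples (e.g. patristic).
#' @param g a [geochem_table] whose sites cover the samples.
#' @param n_permutations permutations per test (default 1000).
#' @param seed optional base seed; test `i` uses `seed + i`.
#' @return Data frame with columns `parameter`, `n_sites`, `mantel_r`,
#'   `p_value`.
#' @export
mantel_table <- function(community, g, n_permutations = 1000L, seed = NULL) {
  community <- as.matrix(community)
  params <- colnames(g$values)
  out <- data.frame(parameter = params, n_sites = NA_integer_,
                    mantel_r = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(params)) {
    res <- tryCatch({
      pd <- suppressWarnings(parameter_distance(g, params[i]))
      shared <- intersect(rownames(pd), rownames(community))
      if (length(shared) < 4L) stop("too few shared sites")
      mantel_test(dist_matrix(community[shared, shared],
                              allow_negative = TRUE),
                  dist_matrix(pd[shared, shared]),
                  n_permutations,
                  seed = if (is.null(seed)) NULL else seed + i)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      out$n_sites[i] <- res$n
      out$mantel_r[i] <- res$r
      out$p_value[i] <- res$p_value
    }
  }
  out
}
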