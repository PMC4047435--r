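# End-to-end orchestration: FASTA (or imported hits) + geochemistry in,
# clusters, distance matrices, dendrogram, Mantel tables, PCA exports and
# diversity metrics out.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run.  Defaults are the
#' settings used for whole-metagenome comparisons: strict E-value cutoff
#' `1e-40`, MCL inflation 1.2, 1000 Mantel permutations, scaled PCA with
#' distances in (PC1, PC2, PC3) space, genus retention at the 0.80
#' coverage level and a minimum of two hits per EC number.
#'
#' @param fasta character vector of per-sample FASTA paths (headers may
#'   use the `"sample|protein"` convention; otherwise the file stem
#'   names the sample).
#' @param geochem path to a geochemistry CSV, or a [geochem_table].
#' @param hits optional path to a 12-column tabular hit file to use
#'   instead of the internal aligner.
#' @param reference optional annotated reference FASTA path (genus/EC
#'   diversity metrics are skipped without it).
#' @param outdir output directory.
#' @param e_threshold strict E-value cutoff (default `1e-40`).
#' @param inflation MCL inflation (> 1; default 1.2).
#' @param n_permutations Mantel permutations (default 1000).
#' @param pca_scale correlation-based PCA (default TRUE).
#' @param pc_k components for PC-space distances (default 3).
#' @param percentile genus coverage retention level (default 0.80).
#' @param min_hits minimum hits per EC number (default 2).
#' @param seed integer seed making the whole run reproducible.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fasta, geochem, hits = NULL, reference = NULL,
                            outdir = ".", e_threshold = 1e-40,
                            inflation = 1.2, n_permutations = 1000L,
                            pca_scale = TRUE, pc_k = 3L,
                            percentile = 0.80, min_hits = 2L, seed = 1L) {
  if (e_threshold <= 0) stop("'e_threshold' must be positive")
  if (inflation <= 1) stop("'inflation' must be > 1")
  if (n_permutations < 1L) stop("'n_permutations' must be >= 1")
  if (pc_k < 1L) stop("'pc_k' must be >= 1")
  if (percentile <= 0 || percentile > 1) stop("'percentile' must be in (0,1]")
  if (min_hits < 1L) stop("'min_hits' must be >= 1")
  for (f in c(fasta, hits, reference))
    if (!file.exists(f)) stop("input does not exist: ", f)
  structure(list(fasta = fasta, geochem = geochem, hits = hits,
                 reference = reference, outdir = outdir,
                 e_threshold = e_threshold, inflation = inflation,
                 n_permutations = as.integer(n_permutations),
                 pca_scale = isTRUE(pca_scale), pc_k = as.integer(pc_k),
                 percentile = percentile, min_hits = as.integer(min_hits),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# minimal ASCII rendering of a phylo tree (indented outline, tips in
# plot order) so dendrograms are inspectable without graphics
ascii_tree <- function(tree, digits = 4) {
  n_tip <- length(tree$tip.label)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  lens <- tree$edge.length
  lab <- function(node) {
    if (node <= n_tip) tree$tip.label[node] else "+"
  }
  out <- character(0)
  recurse <- function(node, prefix, edge_idx) {
    len <- if (is.na(edge_idx)) "" else
      sprintf(":%s", format(lens[edge_idx], digits = digits))
    out <<- c(out, paste0(prefix, "+-- ", lab(node), len))
    kids <- children[[as.character(node)]]
    for (k in kids) recurse(tree$edge[k, 2L], paste0(prefix, "    "), k)
  }
  recurse(n_tip + 1L, "", NA)
  out
}

#' Run the whole comparative-metagenomics pipeline
#'
#' Executes, in order: input parsing, all-vs-all similarity graph (or
#' imported hits), Markov clustering, presence matrix and Jaccard
#' dissimilarity, neighbor-joining dendrogram, patristic distances,
#' per-parameter Mantel tests, PCA with PC-space distances and an
#' overall-geochemistry Mantel test, diversity metrics, and the combined
#' geochemistry-diversity correlation matrix.  All results are written
#' under `cfg$outdir` together with a `MANIFEST` and a run log; a stage
#' failure aborts with the stage name, leaving partial outputs and a
#' MANIFEST marked incomplete.  Identical config and seed give
#' bit-identical outputs.
#'
#' @param cfg a [pipeline_config].
#' @return An object of class `mcgeo_run` collecting every intermediate
#'   (graph, clusters, presence and distance matrices, tree, Mantel
#'   tables, PCA, diversity and correlation results) plus output paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$outdir) &&
      !dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", cfg$outdir)
  outfile <- function(name) file.path(cfg$outdir, name)
  manifest <- character(0)
  log_lines <- c(sprintf("mcgeo %s / %s", packageVersion("mcgeo"),
                         R.version.string),
                 sprintf("seed=%d e_threshold=%g inflation=%g permutations=%d",
                         cfg$seed, cfg$e_threshold, cfg$inflation,
                         cfg$n_permutations),
                 sprintf("pca_scale=%s pc_k=%d percentile=%g min_hits=%d",
                         cfg$pca_scale, cfg$pc_k, cfg$percentile,
                         cfg$min_hits))
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))
  finish <- function(complete) {
    status <- if (complete) "complete" else "INCOMPLETE"
    writeLines(c(paste("status:", status), manifest), outfile("MANIFEST"))
    writeLines(log_lines, outfile("run_log.txt"))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      finish(FALSE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  emit <- function(name) manifest <<- c(manifest, name)
  set.seed(cfg$seed)

  res <- list(config = cfg)

  records <- stage("read_inputs", {
    recs <- lapply(cfg$fasta, function(f) {
      r <- read_fasta(f)
      if (anyNA(r$sample_id))
        r <- read_fasta(f, sample_id = sub("\\.[^.]*$", "", basename(f)))
      r
    })
    out <- do.call(rbind, recs)
    class(out) <- c("protein_records", "data.frame")
    if (anyDuplicated(out$id)) stop("duplicate protein ids across files")
    out
  })
  note("proteins=%d samples=%d", nrow(records),
       length(unique(records$sample_id)))
  geochem <- stage("read_inputs", {
    if (inherits(cfg$geochem, "geochem_table")) cfg$geochem
    else read_geochem_csv(cfg$geochem)
  })

  graph <- stage("similarity_graph", {
    if (is.null(cfg$hits)) {
      all_vs_all(records, e_threshold = cfg$e_threshold)
    } else {
      graph_from_hits(read_tabular_hits(cfg$hits),
                      records[, c("id", "sample_id")],
                      e_threshold = cfg$e_threshold)
    }
  })
  note("edges=%d", nrow(graph$edges))
  stage("similarity_graph", write_edge_list(graph, outfile("edges.tsv")))
  emit("edges.tsv")

  clusters <- stage("markov_clustering",
                    mcl(graph, inflation = cfg$inflation))
  note("clusters=%d iterations=%d converged=%s", length(clusters$clusters),
       clusters$iterations_run, clusters$converged)
  stage("markov_clustering",
        write_mcl_clusters(clusters, outfile("clusters.txt")))
  emit("clusters.txt")

  p <- stage("community_distance", {
    presence_matrix(clusters, setNames(records$sample_id, records$id))
  })
  jac <- stage("community_distance", dissimilarity_matrix(p))
  stage("community_distance",
        write_phylip_distance(jac, outfile("jaccard.phylip")))
  emit("jaccard.phylip")

  tree <- stage("community_distance", neighbor_joining(jac))
  stage("community_distance", {
    write_newick(tree, outfile("dendrogram.nwk"))
    writeLines(ascii_tree(tree), outfile("dendrogram.txt"))
  })
  emit("dendrogram.nwk"); emit("dendrogram.txt")

  patristic <- stage("community_distance", patristic_distances(tree))
  stage("community_distance",
        write_phylip_distance(patristic, outfile("patristic.phylip"),
                              allow_negative = TRUE))
  emit("patristic.phylip")

  mantel_geo <- stage("mantel_tests",
                      mantel_table(patristic, geochem,
                                   cfg$n_permutations, seed = cfg$seed))
  stage("mantel_tests",
        write.csv(mantel_geo, outfile("mantel_geochem.csv"),
                  row.names = FALSE))
  emit("mantel_geochem.csv")

  pca <- stage("pca", geochem_pca(geochem, scale = cfg$pca_scale))
  stage("pca", {
    vf <- sprintf("# variance_fraction: %s",
                  paste(sprintf("%.6f", pca$variance_fraction),
                        collapse = " "))
    k <- min(cfg$pc_k, ncol(pca$scores))
    scores <- data.frame(item = rownames(pca$scores), type = "site",
                         pca$scores[, seq_len(k), drop = FALSE],
                         check.names = FALSE)
    loads <- data.frame(item = rownames(pca$loadings), type = "loading",
                        pca$loadings[, seq_len(k), drop = FALSE],
                        check.names = FALSE)
    con <- file(outfile("pca_biplot.csv"), "w")
    writeLines(vf, con)
    write.csv(rbind(scores, loads), con, row.names = FALSE)
    close(con)
  })
  emit("pca_biplot.csv")
  pc_dist <- stage("pca", pc_space_distance(pca, min(cfg$pc_k,
                                                     ncol(pca$scores))))
  stage("pca", write_phylip_distance(pc_dist, outfile("pc_distance.phylip")))
  emit("pc_distance.phylip")
  pca_mantel <- stage("pca", {
    shared <- intersect(rownames(pc_dist), rownames(patristic))
    if (length(shared) >= 4L) {
      m <- mantel_test(dist_matrix(patristic[shared, shared],
                                   allow_negative = TRUE),
                       dist_matrix(pc_dist[shared, shared]),
                       cfg$n_permutations, seed = cfg$seed)
      write.csv(data.frame(comparison = "patristic_vs_pc_space",
                           n_sites = m$n, mantel_r = m$r,
                           p_value = m$p_value),
                outfile("pca_mantel.csv"), row.names = FALSE)
      m
    } else {
      write.csv(data.frame(comparison = character(0),
                           n_sites = integer(0), mantel_r = numeric(0),
                           p_value = numeric(0)),
                outfile("pca_mantel.csv"), row.names = FALSE)
      NULL
    }
  })
  emit("pca_mantel.csv")

  diversity <- stage("diversity_metrics", {
    ref <- if (is.null(cfg$reference)) NULL else read_fasta(cfg$reference)
    diversity_table(p, records, ref, e_threshold = cfg$e_threshold,
                    percentile = cfg$percentile, min_hits = cfg$min_hits)
  })
  stage("diversity_metrics",
        write.csv(diversity, outfile("diversity.csv"), row.names = FALSE))
  emit("diversity.csv")

  corr <- stage("correlation_matrix", {
    shared <- intersect(rownames(geochem$values), diversity$sample_id)
    extra <- diversity[match(shared, diversity$sample_id),
                       c("genus_count", "ec_count", "cluster_count"),
                       drop = FALSE]
    extra <- extra[, colSums(is.na(extra)) == 0, drop = FALSE]
    g2 <- geochem_table(geochem$values[shared, , drop = FALSE])
    correlation_matrix(g2, if (ncol(extra)) extra else NULL, digits = 2L)
  })
  stage("correlation_matrix",
        write.csv(corr, outfile("correlation_matrix.csv")))
  emit("correlation_matrix.csv")

  finish(TRUE)
  res <- c(res, list(records = records, geochem = geochem, graph = graph,
                     clusters = clusters, presence = p, jaccard = jac,
                     tree = tree, patristic = patristic,
                     mantel_geochem = mantel_geo, pca = pca,
                     pc_distance = pc_dist, pca_mantel = pca_mantel,
                     diversity = diversity, correlation = corr,
                     outdir = cfg$outdir, manifest = manifest))
  class(res) <- "mcgeo_run"
  res
}

#' @export
print.mcgeo_run <- function(x, ...) {
  cat("mcgeo pipeline run\n")
  cat("  proteins:  ", nrow(x$records), " in ",
      ncol(x$presence), " samples\n", sep = "")
  cat("  clusters:  ", length(x$clusters$clusters),
      " (inflation ", x$config$inflation, ")\n", sep = "")
  cat("  outputs:   ", x$outdir, " (", length(x$manifest), " files)\n",
      sep = "")
  invisible(x)
}

#' @export
summary.mcgeo_run <- function(object, ...) {
  cat("Per-parameter Mantel tests (community distance vs geochemistry):\n")
  tab <- object$mantel_geochem
  tab <- tab[order(tab$p_value), ]
  print(utils::head(tab, 10L), row.names = FALSE)
  if (!is.null(object$pca_mantel)) {
    cat("\nOverall geochemical distance (PC space):\n")
    print(object$pca_mantel)
  }
  cat("\nDiversity metrics:\n")
  print(object$diversity, row.names = FALSE)
  invisible(object)
}
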