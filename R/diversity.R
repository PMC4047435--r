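# Per-metagenome biodiversity metrics: genus counts (taxonomic), EC-number
# counts (functional) and Markov cluster counts (community complexity).

#' Best reference hit per query protein
#'
#' For every query, the annotated reference protein with the smallest
#' E-value strictly below `e_threshold`.  Ties are broken by higher raw
#' alignment score, then by smaller reference id.  Queries with no
#' qualifying hit are unassigned (absent from the result).
#'
#' When `hits` is supplied (imported tabular search results with
#' reference proteins as subjects) it is used directly; otherwise every
#' query is aligned against every reference with the internal aligner.
#'
#' @param queries a [protein_records] data frame.
#' @param reference a [protein_records] data frame carrying `genus`
#'   and/or `ec` annotations.
#' @param e_threshold strict E-value cutoff (default `1e-40`).
#' @param hits optional data frame from [read_tabular_hits()].
#' @return Data frame with one row per assigned query: `query_id`,
#'   `ref_id`, `e_value`, `genus`, and list column `ec`.
#' @export
best_hits <- function(queries, reference, e_threshold = 1e-40, hits = NULL) {
  if (nrow(reference) == 0L) stop("empty reference database")
  if (is.null(hits)) {
    qs <- Biostrings::AAStringSet(setNames(clean_aa(queries$sequence),
                                           queries$id))
    rs <- Biostrings::AAStringSet(setNames(clean_aa(reference$sequence),
                                           reference$id))
    m <- sum(Biostrings::width(qs))
    n <- sum(Biostrings::width(rs))
    sub <- blosum62_neutral_x()
    rows <- vector("list", nrow(queries))
    for (i in seq_len(nrow(queries))) {
      scores <- pmax(0, Biostrings::pairwiseAlignment(
        rs, qs[[i]], type = "local", substitutionMatrix = sub,
        gapOpening = 11, gapExtension = 1, scoreOnly = TRUE))
      e <- evalue(scores, m = m, n = n)
      ok <- which(e < e_threshold)
      if (!length(ok)) next
      ord <- order(e[ok], -scores[ok], reference$id[ok])
      pick <- ok[ord[1L]]
      rows[[i]] <- data.frame(query_id = queries$id[i],
                              ref_id = reference$id[pick],
                              e_value = e[pick], stringsAsFactors = FALSE)
    }
    asg <- do.call(rbind, rows)
  } else {
    h <- hits[hits$e_value < e_threshold &
                hits$subject_id %in% reference$id, , drop = FALSE]
    if (nrow(h)) {
      ord <- order(h$query_id, h$e_value, -h$bit_score, h$subject_id)
      h <- h[ord, , drop = FALSE]
      h <- h[!duplicated(h$query_id), , drop = FALSE]
      asg <- data.frame(query_id = h$query_id, ref_id = h$subject_id,
                        e_value = h$e_value, stringsAsFactors = FALSE)
    } else asg <- NULL
  }
  if (is.null(asg))
    asg <- data.frame(query_id = character(0), ref_id = character(0),
                      e_value = numeric(0), stringsAsFactors = FALSE)
  ri <- match(asg$ref_id, reference$id)
  asg$genus <- reference$genus[ri]
  asg$ec <- reference$ec[ri]
  rownames(asg) <- NULL
  asg
}

#' Genus count with low-abundance filtering
#'
#' Tallies best-hit assignments per genus and counts the genera retained
#' after excluding low-count genera.  Two filtering readings are
#' available:
#' \describe{
#'   \item{`"coverage"` (default)}{sort genera by hit count (ties by
#'     name) and retain the minimal prefix whose cumulative count reaches
#'     `percentile` of all hits -- the dominant genera covering e.g. 80%
#'     of assignments.}
#'   \item{`"quantile"`}{retain genera whose hit count is at least the
#'     `percentile` quantile of per-genus counts.}
#' }
#'
#' @param assignments data frame from [best_hits()] with a `genus`
#'   column.
#' @param percentile retention level in `(0, 1]` (default 0.80).
#' @param method `"coverage"` or `"quantile"`.
#' @return Number of retained genera (0 when nothing is assigned).
#' @export
genus_count <- function(assignments, percentile = 0.80,
                        method = c("coverage", "quantile")) {
  method <- match.arg(method)
  if (percentile <= 0 || percentile > 1)
    stop("'percentile' must be in (0, 1]")
  genera <- assignments$genus[!is.na(assignments$genus)]
  if (!length(genera)) return(0L)
  counts <- table(genera)
  if (method == "coverage") {
    ord <- order(-as.integer(counts), names(counts))
    cum <- cumsum(as.integer(counts)[ord])
    sum(cum < percentile * sum(counts)) + 1L
  } else {
    sum(as.integer(counts) >= quantile(as.integer(counts), percentile))
  }
}

#' EC-number count with a minimum-hit rule
#'
#' Number of distinct EC numbers hit by at least `min_hits` query
#' proteins (each query contributes once to every EC number carried by
#' its best reference hit).
#'
#' @param assignments data frame from [best_hits()] with an `ec` list
#'   column.
#' @param min_hits minimum queries per EC number (default 2).
#' @return Number of distinct qualifying EC numbers.
#' @export
ec_count <- function(assignments, min_hits = 2L) {
  if (min_hits < 1L) stop("'min_hits' must be >= 1")
  ecs <- unlist(lapply(assignments$ec, unique), use.names = FALSE)
  if (!length(ecs)) return(0L)
  sum(table(ecs) >= min_hits)
}

#' Markov cluster count of one metagenome
#'
#' Column sum of the presence matrix: the number of Markov clusters that
#' contain at least one protein from the sample.
#'
#' @param p presence matrix from [presence_matrix()].
#' @param sample_id sample column name.
#' @return Non-negative integer.
#' @export
cluster_count <- function(p, sample_id) {
  if (!sample_id %in% colnames(p)) stop("unknown sample: ", sample_id)
  sum(p[, sample_id])
}

#' Per-sample diversity table
#'
#' Combines the three biodiversity metrics for every sample in a
#' presence matrix: genus count, EC count (both `NA` when no annotated
#' reference is given) and Markov cluster count.
#'
#' @param p presence matrix from [presence_matrix()].
#' @param records [protein_records] of the query proteins (needed for
#'   genus/EC counts).
#' @param reference optional annotated reference [protein_records].
#' @param e_threshold strict E-value cutoff for best hits.
#' @param percentile genus retention level (default 0.80).
#' @param min_hits minimum queries per EC number (default 2).
#' @param hits optional imported hit table against the reference.
#' @return Data frame with columns `sample_id`, `genus_count`,
#'   `ec_count`, `cluster_count`.
#' @export
diversity_table <- function(p, records = NULL, reference = NULL,
                            e_threshold = 1e-40, percentile = 0.80,
                            min_hits = 2L, hits = NULL) {
  samples <- colnames(p)
  out <- data.frame(sample_id = samples, genus_count = NA_integer_,
                    ec_count = NA_integer_,
                    cluster_count = vapply(samples, function(s)
                      cluster_count(p, s), 1L),
                    stringsAsFactors = FALSE)
  if (!is.null(reference) && !is.null(records)) {
    asg <- best_hits(records, reference, e_threshold, hits = hits)
    sample_of <- setNames(records$sample_id, records$id)
    asg$sample_id <- unname(sample_of[asg$query_id])
    for (i in seq_along(samples)) {
      sub <- asg[asg$sample_id == samples[i], , drop = FALSE]
      out$genus_count[i] <- genus_count(sub, percentile)
      out$ec_count[i] <- ec_count(sub, min_hits)
    }
  }
  rownames(out) <- NULL
  out
}
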