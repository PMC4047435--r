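# Readers/writers for the formats the pipeline touches: amino-acid FASTA,
# 12-column tabular homology hits, PHYLIP square distance matrices, Newick
# trees and geochemistry CSV tables.

AA_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYX"

#' Protein record table
#'
#' Canonical in-memory form for protein sequences: a data frame with one
#' row per protein and columns `id`, `sample_id`, `sequence`, `genus` and
#' `ec` (a list column of EC-number character vectors).  Sequences are
#' amino-acid strings over the 20 standard residues plus `X`.
#'
#' @param id character vector of unique protein identifiers.
#' @param sample_id character vector naming the source metagenome of each
#'   protein (may be `NA` for reference databases).
#' @param sequence character vector of amino-acid sequences.
#' @param genus optional character vector of genus annotations.
#' @param ec optional list of EC-number character vectors (`"a.b.c.d"`).
#' @return A `data.frame` of class `protein_records`.
#' @export
protein_records <- function(id, sample_id = NA_character_, sequence,
                            genus = NA_character_, ec = NULL) {
  id <- as.character(id)
  sequence <- toupper(as.character(sequence))
  n <- length(id)
  if (length(sequence) != n)
    stop("'id' and 'sequence' must have equal length")
  if (anyDuplicated(id))
    stop("duplicate protein id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(sequence)))
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(sequence)], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", AA_ALPHABET), sequence)
  if (any(bad))
    stop("non amino-acid character in record(s): ",
         paste(id[bad], collapse = ", "))
  if (is.null(ec)) ec <- rep(list(character(0)), n)
  df <- data.frame(id = id,
                   sample_id = rep_len(as.character(sample_id), n),
                   sequence = sequence,
                   genus = rep_len(as.character(genus), n),
                   stringsAsFactors = FALSE)
  df$ec <- ec
  class(df) <- c("protein_records", "data.frame")
  df
}

#' Read an amino-acid FASTA file
#'
#' Headers follow the `"sample|protein"` convention used when several
#' metagenomes are pooled into one file: the substring before the first
#' `|` is taken as the sample id.  Alternatively a single `sample_id` can
#' be supplied (e.g. the file stem when reading per-sample files).
#' Annotated reference databases may carry `genus=<name>` and
#' `ec=<a.b.c.d[,...]>` tags in the description, which are parsed into the
#' `genus` and `ec` columns.
#'
#' @param path path to a FASTA file.
#' @param sample_id optional sample id applied to every record, overriding
#'   header parsing.
#' @return A [protein_records] data frame, in file order.
#' @export
read_fasta <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  # read as raw strings so alphabet violations reach our validator
  # instead of being silently dropped
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    return(protein_records(character(0), character(0), character(0)))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(sample_id)) {
    samples <- ifelse(grepl("|", ids, fixed = TRUE),
                      sub("\\|.*$", "", ids), NA_character_)
  } else {
    samples <- rep_len(as.character(sample_id), length(ids))
  }
  genus <- ifelse(grepl("genus=", headers),
                  sub("^.*genus=([^ ]+).*$", "\\1", headers), NA_character_)
  ec <- lapply(headers, function(h) {
    if (grepl("ec=", h)) {
      strsplit(sub("^.*ec=([^ ]+).*$", "\\1", h), ",", fixed = TRUE)[[1]]
    } else character(0)
  })
  protein_records(ids, samples, as.character(set), genus, ec)
}

#' Write protein records as FASTA
#'
#' Inverse of [read_fasta()]: ids become headers, with `genus=`/`ec=` tags
#' appended when annotations are present.
#'
#' @param records a [protein_records] data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  headers <- records$id
  for (i in seq_along(headers)) {
    tags <- character(0)
    if (!is.na(records$genus[i]))
      tags <- c(tags, paste0("genus=", records$genus[i]))
    if (length(records$ec[[i]]))
      tags <- c(tags, paste0("ec=", paste(records$ec[[i]], collapse = ",")))
    if (length(tags)) headers[i] <- paste(headers[i], paste(tags, collapse = " "))
  }
  set <- Biostrings::AAStringSet(setNames(records$sequence, headers))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Read 12-column tabular homology hits
#'
#' Parses the standard tab-separated search-output dialect with columns
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore.  Lines starting with `#` are skipped.
#'
#' @param path path to a tab-separated hit table.
#' @return A data frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatch`, `gap_open`, `qstart`,
#'   `qend`, `sstart`, `send`, `e_value`, `bit_score`.
#' @export
read_tabular_hits <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- data.frame(query_id = character(0), subject_id = character(0),
                    percent_identity = numeric(0), align_length = integer(0),
                    mismatch = integer(0), gap_open = integer(0),
                    qstart = integer(0), qend = integer(0),
                    sstart = integer(0), send = integer(0),
                    e_value = numeric(0), bit_score = numeric(0),
                    stringsAsFactors = FALSE)
  if (!any(keep)) return(out)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L))
    stop("line ", lineno[which(nf != 12L)[1L]], ": expected 12 tab-separated ",
         "columns, found ", nf[which(nf != 12L)[1L]])
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(apply(num, 1, anyNA))[1L]
    stop("line ", lineno[bad], ": unparseable numeric field")
  }
  out <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                    percent_identity = num[, 1L],
                    align_length = as.integer(num[, 2L]),
                    mismatch = as.integer(num[, 3L]),
                    gap_open = as.integer(num[, 4L]),
                    qstart = as.integer(num[, 5L]), qend = as.integer(num[, 6L]),
                    sstart = as.integer(num[, 7L]), send = as.integer(num[, 8L]),
                    e_value = num[, 9L], bit_score = num[, 10L],
                    stringsAsFactors = FALSE)
  if (any(out$e_value < 0))
    stop("negative e-value at line ", lineno[which(out$e_value < 0)[1L]])
  if (any(out$align_length < 1L))
    stop("alignment length < 1 at line ",
         lineno[which(out$align_length < 1L)[1L]])
  out
}

#' Labelled distance matrix
#'
#' Validating constructor for the symmetric non-negative zero-diagonal
#' matrices used throughout (community, geochemical and patristic
#' distances).  `allow_negative` relaxes the non-negativity check for
#' patristic matrices derived from trees with negative branch lengths.
#'
#' @param values square numeric matrix.
#' @param labels optional character labels; defaults to existing dimnames.
#' @param allow_negative allow negative entries (off by default).
#' @param tol symmetry/diagonal tolerance.
#' @return The validated matrix with `labels` as dimnames.
#' @export
dist_matrix <- function(values, labels = NULL, allow_negative = FALSE,
                        tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("S", seq_len(nrow(values)))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate labels in distance matrix")
  if (any(!is.finite(values))) stop("non-finite entries in distance matrix")
  if (max(abs(values - t(values))) > tol) stop("distance matrix not symmetric")
  if (max(abs(diag(values))) > tol) stop("distance matrix diagonal not zero")
  if (!allow_negative && min(values) < -tol)
    stop("negative entries in distance matrix")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  values
}

#' Write / read a PHYLIP square distance matrix
#'
#' A relaxed PHYLIP dialect: first line is the taxon count; each following
#' line is a label padded (with spaces) or truncated to 10 characters,
#' followed by the full matrix row to 6 decimals.  Truncation collisions
#' are an error rather than being silently accepted.
#'
#' @param d a distance matrix as from [dist_matrix()].
#' @param path file path.
#' @param allow_negative permit negative entries (patristic matrices from
#'   trees with negative branch lengths).
#' @return `path` invisibly (writer); a validated distance matrix (reader).
#' @export
write_phylip_distance <- function(d, path, allow_negative = FALSE) {
  d <- dist_matrix(d, allow_negative = allow_negative)
  labels <- rownames(d)
  if (nrow(d) > 250L) stop("PHYLIP writer limited to 250 taxa")
  short <- substr(labels, 1L, 10L)
  if (anyDuplicated(short))
    stop("labels collide after truncation to 10 characters: ",
         paste(unique(short[duplicated(short)]), collapse = ", "))
  rows <- vapply(seq_len(nrow(d)), function(i) {
    paste0(formatC(short[i], width = -10L),
           paste(sprintf("%10.6f", d[i, ]), collapse = " "))
  }, "")
  writeLines(c(as.character(nrow(d)), rows), path)
  invisible(path)
}

#' @rdname write_phylip_distance
#' @export
read_phylip_distance <- function(path, allow_negative = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("bad taxon count on line 1")
  if (length(lines) < n + 1L) stop("expected ", n, " matrix rows")
  labels <- character(n)
  values <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    line <- lines[i + 1L]
    labels[i] <- trimws(substr(line, 1L, 10L))
    row <- suppressWarnings(as.numeric(strsplit(trimws(substring(line, 11L)),
                                                "\\s+")[[1L]]))
    if (length(row) != n || anyNA(row))
      stop("bad matrix row for taxon ", labels[i])
    values[i, ] <- row
  }
  dist_matrix(values, labels, allow_negative = allow_negative, tol = 1e-5)
}

#' Write / read a Newick tree with branch lengths
#'
#' Thin wrappers over \pkg{ape}'s Newick support, with a parenthesis
#' balance pre-check that reports the offending character position on
#' malformed input.  Round trips preserve topology and branch lengths to
#' at least 6 decimals.
#'
#' @param tree an \pkg{ape} `phylo` object with branch lengths.
#' @param path file path.
#' @return `path` invisibly (writer); a `phylo` object (reader).
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  txt <- paste(readLines(path), collapse = "")
  chars <- strsplit(txt, "")[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unmatched ')' at position ", i)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at position ",
         length(chars))
  if (!grepl(";", txt, fixed = TRUE))
    stop("malformed Newick: missing terminating ';' at position ",
         length(chars))
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("malformed Newick tree")
  tree
}

#' Geochemistry table
#'
#' Sites-by-parameters matrix of geochemical measurements with optional
#' per-parameter units.  Missing measurements are `NA`; downstream
#' operations define their own missing-data policy.
#'
#' @param values numeric matrix (sites in rows, parameters in columns)
#'   with dimnames.
#' @param units optional named character vector of units per parameter.
#' @return An object of class `geochem_table`.
#' @export
geochem_table <- function(values, units = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("geochem table needs site and parameter names")
  if (anyDuplicated(rownames(values))) stop("duplicate site id(s)")
  if (anyDuplicated(colnames(values))) stop("duplicate parameter name(s)")
  if (!is.numeric(values)) stop("geochem values must be numeric")
  if (any(is.infinite(values))) stop("non-finite geochem value")
  structure(list(values = values, units = units), class = "geochem_table")
}

#' @export
print.geochem_table <- function(x, ...) {
  cat("Geochemistry table: ", nrow(x$values), " sites x ",
      ncol(x$values), " parameters\n", sep = "")
  cat("parameters:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.geochem_table <- function(x, ...) x$values

#' Read a geochemistry CSV table
#'
#' First column holds site ids, the header row parameter names; cells are
#' numeric or empty (recorded as missing, never as zero).
#'
#' @param path path to a CSV file.
#' @return A [geochem_table].
#' @export
read_geochem_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (ncol(df) < 2L) stop("geochem CSV needs a site column and >=1 parameter")
  sites <- df[[1L]]
  if (anyDuplicated(sites))
    stop("duplicate site id(s): ",
         paste(unique(sites[duplicated(sites)]), collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(apply(raw, 2, function(col) {
    col <- trimws(col)
    out <- as.numeric(col)
    out[col == ""] <- NA_real_
    out
  }))
  vals <- matrix(vals, nrow = length(sites),
                 dimnames = list(sites, colnames(df)[-1L]))
  bad <- which(is.na(vals) & trimws(raw) != "", arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric cell at site '", sites[bad[1L, 1L]], "', parameter '",
         colnames(vals)[bad[1L, 2L]], "'")
  geochem_table(vals)
}

#' Write a geochemistry table as CSV
#'
#' @param g a [geochem_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geochem_csv <- function(g, path) {
  stopifnot(inherits(g, "geochem_table"))
  df <- data.frame(site = rownames(g$values), g$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
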