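# Niche-based synthetic metagenome generator.  Ortholog families carry
# Gaussian environmental niches along a site gradient; presence and
# sequence divergence both scale with environmental distance, and the
# geochemistry table is drawn with a planted correlation structure.  The
# generator emits exactly the formats the pipeline consumes plus a truth
# record for parameter-recovery tests.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Published hot-spring geochemistry/diversity correlation matrix
#'
#' The Pearson correlation matrix (2-decimal precision) of twenty
#' geochemical variables -- and, optionally, three biodiversity metrics
#' (genus, EC and Markov cluster counts) -- across twenty-two Yellowstone
#' National Park hot-spring metagenome sites, from a published survey of
#' hydrothermal systems.  Shipped with the package; used both as the
#' default planted correlation structure of [simulate_geochem()] and as
#' input for correlation-matrix ordination via [cor_pca()].
#'
#' @param include_diversity keep the three diversity rows/columns
#'   (default FALSE: the twenty geochemical variables only).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
ynp_correlation <- function(include_diversity = FALSE) {
  path <- system.file("extdata", "ynp_geochem_diversity_cor.csv",
                      package = "mcgeo", mustWork = TRUE)
  m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  if (!include_diversity) {
    keep <- setdiff(rownames(m), c("Genera", "EC", "Clusters"))
    m <- m[keep, keep]
  }
  m
}

#' Configuration for the synthetic metagenome generator
#'
#' Defaults describe an eight-site hot-spring outflow gradient: 300
#' ortholog families with Gaussian niches along a 56.1-92.1 degree C
#' temperature gradient, moderate niche breadth, low background
#' occupancy, and sequence divergence growing with environmental
#' distance.
#'
#' @param n_sites number of sites/metagenomes (default 8).
#' @param n_families number of ortholog families (default 300).
#' @param gradient named list of gradient parameters; each entry is
#'   either a length-2 range (laid out as a linear gradient across
#'   sites) or a length-`n_sites` vector.  Default: temperature (`T`)
#'   from 56.1 to 92.1 degrees C.
#' @param nuisance_correlation correlation matrix for the jointly normal
#'   geochemical parameters (default: the published hot-spring matrix
#'   from [ynp_correlation()], which includes e.g. a 0.99 Ca-Mg pair).
#'   Must contain the gradient parameter names.
#' @param sigma niche tolerance (standard deviation of the Gaussian
#'   presence kernel) in normalised gradient units (default 0.25).
#' @param seq_length_range integer range of ancestral sequence lengths
#'   (default 100-140 residues).
#' @param divergence_rate per-residue substitution probability per unit
#'   of normalised environmental distance (default 0.05).
#' @param background_noise probability of niche-independent presence
#'   (default 0.02).
#' @param n_genera,n_ec sizes of the genus and EC label pools (defaults
#'   40 and 60).
#' @param seed integer seed; every downstream draw is deterministic
#'   given it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites = 8L, n_families = 300L,
                             gradient = list(T = c(56.1, 92.1)),
                             nuisance_correlation = ynp_correlation(),
                             sigma = 0.25,
                             seq_length_range = c(100L, 140L),
                             divergence_rate = 0.05,
                             background_noise = 0.02,
                             n_genera = 40L, n_ec = 60L, seed = 1L) {
  stopifnot(n_sites >= 2L, n_families >= 1L, sigma > 0,
            length(seq_length_range) == 2L,
            seq_length_range[1L] >= 10L,
            seq_length_range[2L] >= seq_length_range[1L],
            divergence_rate >= 0, background_noise >= 0,
            background_noise <= 1, n_genera >= 1L, n_ec >= 1L)
  if (!length(gradient) || is.null(names(gradient)))
    stop("'gradient' must be a named list")
  for (nm in names(gradient)) {
    v <- gradient[[nm]]
    if (!length(v) %in% c(2L, n_sites) || any(!is.finite(v)))
      stop("gradient '", nm, "' must be a finite range or per-site vector")
  }
  nuisance_correlation <- as.matrix(nuisance_correlation)
  if (!all(names(gradient) %in% colnames(nuisance_correlation)))
    stop("gradient parameters must appear in the nuisance correlation matrix")
  structure(list(n_sites = as.integer(n_sites),
                 n_families = as.integer(n_families), gradient = gradient,
                 nuisance_correlation = nuisance_correlation,
                 sigma = sigma,
                 seq_length_range = as.integer(seq_length_range),
                 divergence_rate = divergence_rate,
                 background_noise = background_noise,
                 n_genera = as.integer(n_genera), n_ec = as.integer(n_ec),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Cholesky factor of a correlation matrix, repairing the marginal
# indefiniteness of 2-decimal published tables; truly non-PD input errors.
planted_chol <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -0.01)
    stop("nuisance correlation matrix is not positive definite")
  if (min(ev) < 1e-10) {
    R <- as.matrix(Matrix::nearPD(R, corr = TRUE,
                                  posd.tol = 1e-8)$mat)
    dimnames(R) <- NULL
  }
  chol(R)
}

#' Simulate a geochemistry table with planted correlation structure
#'
#' Draws all parameters of the configured correlation matrix jointly
#' from a multivariate normal, then rank-maps every gradient parameter
#' onto its prescribed gradient values (exactly linear ranges stay
#' exact), and orders sites along the first gradient parameter (site ids
#' `S1`, `S2`, ... follow the gradient).  Non-gradient parameters are
#' reported in standardised units.
#'
#' @param cfg a [synthetic_config].
#' @return A [geochem_table]; deterministic given `cfg$seed`.
#' @export
simulate_geochem <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  R <- cfg$nuisance_correlation
  params <- colnames(R)
  L <- planted_chol(unname(R))
  z <- matrix(rnorm(cfg$n_sites * ncol(R)), cfg$n_sites) %*% L
  colnames(z) <- params
  for (nm in names(cfg$gradient)) {
    v <- cfg$gradient[[nm]]
    if (length(v) == 2L)
      v <- seq(v[1L], v[2L], length.out = cfg$n_sites)
    z[, nm] <- sort(v)[rank(z[, nm], ties.method = "first")]
  }
  ord <- order(z[, names(cfg$gradient)[1L]])
  z <- z[ord, , drop = FALSE]
  rownames(z) <- paste0("S", seq_len(cfg$n_sites))
  units <- setNames(rep("sd", length(params)), params)
  units[names(cfg$gradient)] <- ""
  if ("T" %in% names(cfg$gradient)) units["T"] <- "degC"
  geochem_table(z, units)
}

#' Gaussian niche presence probability
#'
#' `exp(-d^2 / (2 sigma^2)) + background_noise` (capped at 1), the
#' probability that a family with niche tolerance `sigma` occurs at
#' environmental distance `d` from its optimum.  At `d = sigma` the
#' niche term equals `exp(-1/2)`.
#'
#' @param distance environmental distance(s) from the niche optimum.
#' @param sigma niche tolerance (> 0).
#' @param background_noise niche-independent occupancy probability.
#' @return Probability vector.
#' @export
niche_presence_probability <- function(distance, sigma,
                                       background_noise = 0) {
  stopifnot(sigma > 0, background_noise >= 0, background_noise <= 1)
  pmin(exp(-distance^2 / (2 * sigma^2)) + background_noise, 1)
}

# normalised 0-1 environment coordinates from the gradient parameters
site_environment <- function(cfg, geo) {
  x <- geo$values[, names(cfg$gradient), drop = FALSE]
  apply(x, 2, function(col) {
    if (diff(range(col)) == 0) rep(0, length(col))
    else (col - min(col)) / diff(range(col))
  })
}

mutate_sequence <- function(seq, q) {
  if (q <= 0) return(seq)
  chars <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(chars)) < q)
  for (i in hit) {
    alt <- AA20[AA20 != chars[i]]
    chars[i] <- alt[sample.int(19L, 1L)]
  }
  paste(chars, collapse = "")
}

#' Simulate ortholog families along the environmental gradient
#'
#' Each family receives a random ancestral sequence, a niche optimum
#' uniform over normalised gradient space, a genus and (for most
#' families) an EC label.  Presence of family `f` at site `i` is
#' Bernoulli with the Gaussian niche probability plus background noise;
#' each present copy mutates the ancestor with per-residue substitution
#' probability `min(0.9, divergence_rate * distance)`.
#'
#' @param cfg a [synthetic_config].
#' @param geochem the matching [simulate_geochem()] output (regenerated
#'   from `cfg` when omitted).
#' @return An object of class `synthetic_truth`: `records` (the emitted
#'   [protein_records]), `families` (per-family metadata), `presence`
#'   (families x sites logical matrix), `substitutions` (realised
#'   per-copy substitution counts), `environment` (normalised site
#'   coordinates) and `geochem`.
#' @export
simulate_families <- function(cfg, geochem = simulate_geochem(cfg)) {
  stopifnot(inherits(cfg, "synthetic_config"))
  env <- site_environment(cfg, geochem)
  sites <- rownames(geochem$values)
  set.seed(cfg$seed + 1L)
  nf <- cfg$n_families
  fam_ids <- sprintf("F%0*d", max(3L, nchar(nf)), seq_len(nf))
  opts <- matrix(runif(nf * ncol(env)), nf, ncol(env),
                 dimnames = list(fam_ids, colnames(env)))
  genus_pool <- sprintf("Genus%02d", seq_len(cfg$n_genera))
  ec_pool <- sprintf("%d.%d.%d.%d",
                     sample.int(6L, cfg$n_ec, TRUE),
                     sample.int(20L, cfg$n_ec, TRUE),
                     sample.int(20L, cfg$n_ec, TRUE),
                     seq_len(cfg$n_ec))
  genus <- sample(genus_pool, nf, TRUE, prob = 1 / seq_len(cfg$n_genera))
  ec <- ifelse(runif(nf) < 0.7, sample(ec_pool, nf, TRUE), NA_character_)
  lens <- sample(seq(cfg$seq_length_range[1L], cfg$seq_length_range[2L]),
                 nf, TRUE)
  ancestral <- vapply(lens, function(L)
    paste(sample(AA20, L, TRUE), collapse = ""), "")
  presence <- matrix(FALSE, nf, length(sites),
                     dimnames = list(fam_ids, sites))
  nsub <- matrix(NA_integer_, nf, length(sites),
                 dimnames = list(fam_ids, sites))
  ids <- samples <- seqs <- character(0)
  for (f in seq_len(nf)) {
    d <- sqrt(colSums((t(env) - opts[f, ])^2))
    pres <- runif(length(sites)) <
      niche_presence_probability(d, cfg$sigma, cfg$background_noise)
    presence[f, ] <- pres
    for (s in which(pres)) {
      q <- min(0.9, cfg$divergence_rate * d[s])
      mutated <- mutate_sequence(ancestral[f], q)
      ids <- c(ids, paste0(sites[s], "|", fam_ids[f]))
      samples <- c(samples, sites[s])
      seqs <- c(seqs, mutated)
      nsub[f, s] <- sum(strsplit(mutated, "")[[1L]] !=
                          strsplit(ancestral[f], "")[[1L]])
    }
  }
  fam_ec <- lapply(ec, function(e) if (is.na(e)) character(0) else e)
  structure(list(
    records = protein_records(ids, samples, seqs),
    families = {
      df <- data.frame(family_id = fam_ids, genus = genus, ec = ec,
                       length = lens, ancestral = ancestral,
                       stringsAsFactors = FALSE)
      opt_df <- as.data.frame(opts)
      names(opt_df) <- paste0("optimum_", colnames(opts))
      cbind(df, opt_df)
    },
    reference = protein_records(fam_ids, NA_character_, ancestral,
                                genus, fam_ec),
    presence = presence, substitutions = nsub, environment = env,
    geochem = geochem, config = cfg),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic metagenome set: ", ncol(x$presence), " sites, ",
      nrow(x$presence), " families, ", nrow(x$records),
      " protein copies\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits one FASTA per site (headers `site|family`), the annotated
#' ancestral reference FASTA (`genus=`/`ec=` tags), the geochemistry CSV
#' and a JSON truth file -- exactly the formats the pipeline reads.
#' Re-running with the same truth produces byte-identical files.
#'
#' @param truth a `synthetic_truth` from [simulate_families()].
#' @param outdir output directory (created if needed).
#' @return Named list of written paths (`fasta`, `reference`, `geochem`,
#'   `truth`), invisibly.
#' @export
emit_dataset <- function(truth, outdir) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir)
  sites <- colnames(truth$presence)
  fasta <- character(0)
  for (s in sites) {
    path <- file.path(outdir, paste0(s, ".fasta"))
    write_fasta(truth$records[truth$records$sample_id == s, , drop = FALSE],
                path)
    fasta <- c(fasta, path)
  }
  ref_path <- file.path(outdir, "reference.fasta")
  write_fasta(truth$reference, ref_path)
  geo_path <- file.path(outdir, "geochemistry.csv")
  write_geochem_csv(truth$geochem, geo_path)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(
    sites = sites,
    environment = as.data.frame(truth$environment),
    families = truth$families[, c("family_id", "genus", "ec", "length")],
    presence = as.data.frame(truth$presence),
    substitutions = as.data.frame(truth$substitutions)),
    truth_path, auto_unbox = TRUE, digits = 10, na = "null")
  invisible(list(fasta = fasta, reference = ref_path, geochem = geo_path,
                 truth = truth_path))
}
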