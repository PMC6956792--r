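#' SNAPP run settings (pass-through)
#'
#' Prior and chain settings recycled into posterior predictive SNAPP XML
#' files.  These are recorded, not interpreted: inference itself is
#' external to this package.  Defaults mirror a typical SNAPP setup:
#' Yule speciation prior with a gamma(alpha = 2, beta = 200) prior on the
#' divergence rate lambda, mutation rates u = v = 1.0, a 1M-step chain
#' with 100K burn-in sampled every 1K steps.
#'
#' @param chain_length,burnin_steps,sample_every Positive chain counts.
#' @param lambda_alpha,lambda_beta Gamma prior on the Yule lambda.
#' @param mutation_u,mutation_v Forward/backward mutation rates.
#' @return A `snapp_run_settings` object.
#' @export
snapp_run_settings <- function(chain_length = 1e6, burnin_steps = 1e5,
                               sample_every = 1e3, lambda_alpha = 2,
                               lambda_beta = 200, mutation_u = 1,
                               mutation_v = 1) {
  stopifnot(chain_length > 0, burnin_steps > 0, sample_every > 0,
            lambda_alpha > 0, lambda_beta > 0,
            mutation_u > 0, mutation_v > 0)
  structure(list(chain_length = chain_length, burnin_steps = burnin_steps,
                 sample_every = sample_every, lambda_alpha = lambda_alpha,
                 lambda_beta = lambda_beta, mutation_u = mutation_u,
                 mutation_v = mutation_v),
            class = "snapp_run_settings")
}

#' Write a SNP matrix and run settings as a SNAPP-style XML file
#'
#' A minimal compatible dialect: a `data` block with one binary sequence
#' per haploid individual, a `taxonsets` block grouping individuals by
#' species, and a `settings` element carrying the recycled chain and prior
#' parameters.  [read_snapp_xml()] inverts it exactly.
#'
#' @param snps A [snp_matrix()] (binary, no missing data).
#' @param settings A [snapp_run_settings()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_snapp_xml <- function(snps, settings = snapp_run_settings(), path) {
  stopifnot(inherits(snps, "snp_matrix"),
            inherits(settings, "snapp_run_settings"))
  if (nrow(snps) == 0L || ncol(snps) == 0L)
    stop("cannot write an empty SNP matrix")
  if (anyNA(snps)) {
    bad <- which(is.na(snps), arr.ind = TRUE)[1L, ]
    stop("non-binary genotype for individual '", rownames(snps)[bad[1L]],
         "' at locus ", bad[2L])
  }
  map <- attr(snps, "sample_map")
  doc <- xml2::xml_new_root("snapp", version = "1.0")
  data <- xml2::xml_add_child(doc, "data", id = "snps", dataType = "binary")
  for (i in seq_len(nrow(snps))) {
    xml2::xml_add_child(data, "sequence",
                        paste(snps[i, ], collapse = ""),
                        taxon = rownames(snps)[i],
                        species = map$species[i])
  }
  ts <- xml2::xml_add_child(doc, "taxonsets")
  for (sp in unique(map$species)) {
    set <- xml2::xml_add_child(ts, "taxonset", species = sp)
    for (id in map$individual[map$species == sp])
      xml2::xml_add_child(set, "taxon", id = id)
  }
  xml2::xml_add_child(doc, "settings",
                      chainLength = format(settings$chain_length,
                                           scientific = FALSE),
                      burnin = format(settings$burnin_steps,
                                      scientific = FALSE),
                      sampleEvery = format(settings$sample_every,
                                           scientific = FALSE),
                      lambdaAlpha = as.character(settings$lambda_alpha),
                      lambdaBeta = as.character(settings$lambda_beta),
                      mutationU = as.character(settings$mutation_u),
                      mutationV = as.character(settings$mutation_v))
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a SNAPP-style XML file
#'
#' Inverse of [write_snapp_xml()] on its own output; unknown XML elements
#' are ignored with a message.
#'
#' @param path Path to the XML file.
#' @return List with `snps` (a [snp_matrix()]) and `settings` (a
#'   [snapp_run_settings()], `NULL` when the file carries none).
#' @export
read_snapp_xml <- function(path) {
  stopifnot(file.exists(path))
  doc <- xml2::read_xml(path)
  known <- c("data", "taxonsets", "settings")
  extra <- setdiff(xml2::xml_name(xml2::xml_children(doc)), known)
  if (length(extra))
    message("ignoring unknown XML elements: ", paste(extra, collapse = ", "))
  data <- xml2::xml_find_first(doc, "./data")
  if (inherits(data, "xml_missing"))
    stop("SNAPP XML has no <data> block")
  seqs <- xml2::xml_find_all(data, "./sequence")
  if (!length(seqs)) stop("SNAPP XML <data> block holds no sequences")
  ids <- xml2::xml_attr(seqs, "taxon")
  species <- xml2::xml_attr(seqs, "species")
  rowsv <- lapply(xml2::xml_text(seqs), function(s) {
    v <- as.integer(strsplit(gsub("\\s", "", s), "")[[1L]])
    v
  })
  if (length(unique(lengths(rowsv))) != 1L)
    stop("sequences differ in length")
  m <- do.call(rbind, rowsv)
  rownames(m) <- ids
  colnames(m) <- paste0("locus_", seq_len(ncol(m)))
  # species may also come from the taxonsets block
  if (anyNA(species)) {
    sets <- xml2::xml_find_all(doc, "./taxonsets/taxonset")
    for (set in sets) {
      sp <- xml2::xml_attr(set, "species")
      for (id in xml2::xml_attr(xml2::xml_find_all(set, "./taxon"), "id"))
        species[ids == id] <- sp
    }
  }
  st <- xml2::xml_find_first(doc, "./settings")
  settings <- if (inherits(st, "xml_missing")) NULL else {
    num <- function(a) as.numeric(xml2::xml_attr(st, a))
    snapp_run_settings(chain_length = num("chainLength"),
                       burnin_steps = num("burnin"),
                       sample_every = num("sampleEvery"),
                       lambda_alpha = num("lambdaAlpha"),
                       lambda_beta = num("lambdaBeta"),
                       mutation_u = num("mutationU"),
                       mutation_v = num("mutationV"))
  }
  list(snps = snp_matrix(m, sample_map(ids, species)), settings = settings)
}

#' Write a SNP matrix as a NEXUS binary matrix
#'
#' `datatype=standard symbols="01"`, one row per haploid individual.
#'
#' @param snps A [snp_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_snp_nexus <- function(snps, path) {
  stopifnot(inherits(snps, "snp_matrix"))
  rows <- apply(snps, 1L, function(r)
    paste(ifelse(is.na(r), "?", r), collapse = ""))
  lines <- c("#NEXUS", "BEGIN DATA;",
             sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(snps),
                     ncol(snps)),
             "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
             "  MATRIX",
             sprintf("    %s %s", format(rownames(snps)), rows),
             "  ;", "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Read a NEXUS binary SNP matrix
#'
#' @param path Path to a NEXUS file with a standard-datatype 0/1 matrix.
#' @param map A [sample_map()]; when `NULL`, individual IDs of the form
#'   `species_index` are split on the final underscore.
#' @return A [snp_matrix()].
#' @export
read_snp_nexus <- function(path, map = NULL) {
  dat <- ape::read.nexus.data(path)
  m <- do.call(rbind, lapply(dat, function(x) {
    x[x %in% c("?", "-", "N", "n")] <- NA
    as.integer(x)
  }))
  rownames(m) <- names(dat)
  colnames(m) <- paste0("locus_", seq_len(ncol(m)))
  if (is.null(map))
    map <- sample_map(rownames(m), sub("_[^_]*$", "", rownames(m)))
  snp_matrix(m, map)
}

#' Write / read a SNP matrix as plain TSV
#'
#' Rows are haploid individuals (first two columns `individual` and
#' `species`), remaining columns are loci.
#'
#' @param snps A [snp_matrix()].
#' @param path File path.
#' @return `write_snp_tsv`: invisibly, `path`; `read_snp_tsv`: a
#'   [snp_matrix()].
#' @export
write_snp_tsv <- function(snps, path) {
  stopifnot(inherits(snps, "snp_matrix"))
  map <- attr(snps, "sample_map")
  df <- data.frame(individual = rownames(snps), species = map$species,
                   as.data.frame(unclass(snps)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_tsv
#' @export
read_snp_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$individual
  snp_matrix(m, sample_map(df$individual, df$species))
}

#' Write / read the metadata config
#'
#' Small key=value text file recording the quantities the pipeline needs
#' about the original analysis: the number of SNPs, an estimated mutation
#' rate, and the haploid sample count per species.
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `write_metadata`: invisibly, `path`; `read_metadata`: a
#'   [simulation_config()].
#' @export
write_metadata <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  sps <- config$samples_per_species
  writeLines(c(paste0("n_snps=", config$n_snps),
               paste0("mutation_rate=", format(config$mutation_rate,
                                               digits = 15)),
               paste0("samples_per_species=",
                      paste(names(sps), sps, sep = ":", collapse = ","))),
             path)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  kv <- strsplit(readLines(path, warn = FALSE), "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  need <- c("n_snps", "mutation_rate", "samples_per_species")
  miss <- setdiff(need, names(vals))
  if (length(miss))
    stop("metadata file missing keys: ", paste(miss, collapse = ", "))
  parts <- strsplit(strsplit(vals[["samples_per_species"]], ",")[[1L]], ":")
  sps <- stats::setNames(as.integer(vapply(parts, `[`, "", 2L)),
                         vapply(parts, `[`, "", 1L))
  simulation_config(n_snps = as.integer(vals[["n_snps"]]),
                    samples_per_species = sps,
                    mutation_rate = as.numeric(vals[["mutation_rate"]]))
}

#' Synthetic posterior configuration
#'
#' Parameters of the stand-in generator that emulates a Bayesian
#' species-tree posterior (trees plus a trace log) so the full pipeline
#' can be exercised without an external inference run.
#'
#' @param center_tree The `phylo` tree posterior samples scatter around.
#' @param topology_jitter Probability that a sampled tree undergoes one
#'   random nearest-neighbour interchange.
#' @param length_jitter_cv Coefficient of variation of the mean-1
#'   lognormal noise multiplying each branch length independently.
#' @param likelihood_mean,likelihood_sd Normal parameters of the i.i.d.
#'   synthetic trace likelihoods.
#' @param n_samples Number of posterior samples (>= 2).
#' @param seed Integer seed.
#' @return A `synthetic_posterior_config` object.
#' @export
synthetic_posterior_config <- function(center_tree, topology_jitter = 0.1,
                                       length_jitter_cv = 0.1,
                                       likelihood_mean = -5000,
                                       likelihood_sd = 5,
                                       n_samples = 100L, seed = 1L) {
  stopifnot(inherits(center_tree, "phylo"),
            topology_jitter >= 0, topology_jitter <= 1,
            length_jitter_cv >= 0, likelihood_sd >= 0, n_samples >= 2L)
  structure(list(center_tree = center_tree,
                 topology_jitter = topology_jitter,
                 length_jitter_cv = length_jitter_cv,
                 likelihood_mean = likelihood_mean,
                 likelihood_sd = likelihood_sd,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "synthetic_posterior_config")
}

# One random NNI move: pick an internal edge (u,v), swap a child of v with
# v's sibling, keeping each moved clade's stem length.  Edges hanging off
# the root are excluded: swapping across them leaves the unrooted topology
# unchanged (the root collapses on unrooting).
random_nni <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  internal <- which(edge[, 2L] > ntip & edge[, 1L] != root)
  if (!length(internal)) return(tree)
  e <- if (length(internal) == 1L) internal else sample(internal, 1L)
  u <- edge[e, 1L]; v <- edge[e, 2L]
  kids_v <- which(edge[, 1L] == v)
  sib <- setdiff(which(edge[, 1L] == u), e)
  if (!length(sib) || length(kids_v) < 2L) return(tree)
  kid <- if (length(kids_v) == 1L) kids_v else sample(kids_v, 1L)
  # swap subtree attachment; stem lengths travel with their new parent slot
  tmp <- edge[kid, 2L]
  edge[kid, 2L] <- edge[sib[1L], 2L]
  edge[sib[1L], 2L] <- tmp
  tree$edge <- edge
  attr(tree, "order") <- NULL  # force a true reorder of the edited edges
  stats::reorder(tree, "cladewise")
}

#' Generate a synthetic posterior tree set and trace log
#'
#' Each sampled tree is the centre tree, optionally perturbed by one
#' random NNI (probability `topology_jitter`), with every branch length
#' multiplied by independent mean-1 lognormal noise of coefficient of
#' variation `length_jitter_cv`.  Trace likelihoods are i.i.d.
#' `Normal(likelihood_mean, likelihood_sd)`.  Deterministic under the
#' config seed.
#'
#' @param cfg A [synthetic_posterior_config()].
#' @return List with `trees` (`multiPhylo`) and `log` ([trace_log()]).
#' @export
generate_synthetic_posterior <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_posterior_config"))
  cv <- cfg$length_jitter_cv
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- -sdlog^2 / 2  # mean-1 lognormal
  out <- with_seed(cfg$seed, {
    trees <- vector("list", cfg$n_samples)
    for (k in seq_len(cfg$n_samples)) {
      tr <- cfg$center_tree
      if (cfg$topology_jitter > 0 &&
          stats::runif(1L) < cfg$topology_jitter)
        tr <- random_nni(tr)
      if (cv > 0)
        tr$edge.length <- tr$edge.length *
          stats::rlnorm(length(tr$edge.length), meanlog, sdlog)
      trees[[k]] <- tr
    }
    lik <- stats::rnorm(cfg$n_samples, cfg$likelihood_mean,
                        cfg$likelihood_sd)
    list(trees = trees, lik = lik)
  })
  trees <- out$trees
  class(trees) <- "multiPhylo"
  attr(trees, "source") <- "synthetic-posterior"
  log <- trace_log(data.frame(Sample = seq_along(out$lik) - 1L,
                              posterior = out$lik,
                              likelihood = out$lik,
                              prior = 0),
                   "likelihood")
  list(trees = trees, log = log)
}

#' Write a complete synthetic fixture bundle
#'
#' Emits, under `dir`: a Newick posterior (`posterior.trees`), the same
#' trees as NEXUS (`posterior.nex`), a trace log (`trace.log`), an
#' empirical SNP matrix as NEXUS + TSV (`snps.nex`, `snps.tsv`), the
#' metadata config (`metadata.txt`) and a SNAPP XML (`snapp.xml`).  The
#' bundle exercises every reader in the package without any external run.
#'
#' @param dir Output directory (created if needed).
#' @param n_trees,n_snps Bundle sizes.
#' @param ne Effective population size of the generating model.
#' @param seed Integer seed.
#' @return Invisibly, a named character vector of the file paths.
#' @export
make_fixture_bundle <- function(dir, n_trees = 100L, n_snps = 200L,
                                ne = 1e5, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- design_species_tree(ne)
  post <- generate_synthetic_posterior(synthetic_posterior_config(
    tree, n_samples = n_trees, seed = derive_seed(seed, 1L)))
  sps <- stats::setNames(rep(2L, length(tree$tip.label)), tree$tip.label)
  cfg <- simulation_config(n_snps, sps, seed = derive_seed(seed, 2L))
  snps <- simulate_snp_matrix(build_demography(tree, ne), cfg)

  paths <- c(trees = file.path(dir, "posterior.trees"),
             nexus_trees = file.path(dir, "posterior.nex"),
             log = file.path(dir, "trace.log"),
             snps_nexus = file.path(dir, "snps.nex"),
             snps_tsv = file.path(dir, "snps.tsv"),
             metadata = file.path(dir, "metadata.txt"),
             xml = file.path(dir, "snapp.xml"))
  writeLines(vapply(post$trees, write_newick, ""), paths[["trees"]])
  ape::write.nexus(post$trees, file = paths[["nexus_trees"]])
  utils::write.table(post$log$data, paths[["log"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_snp_nexus(snps, paths[["snps_nexus"]])
  write_snp_tsv(snps, paths[["snps_tsv"]])
  write_metadata(cfg, paths[["metadata"]])
  write_snapp_xml(snps, snapp_run_settings(), paths[["xml"]])
  invisible(paths)
}
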