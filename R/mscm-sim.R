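#' Define a secondary-contact migration event
#'
#' Symmetric gene flow between two extant species at `rate_m` migrants per
#' generation, active (looking backward in time) from the present until
#' `start_time` generations ago.  Backward in time each lineage currently
#' in one of the two species migrates to the other at rate
#' `rate_m / (2 * Ne)` per generation.
#'
#' @param species_a,species_b Tip labels of the two species (distinct).
#' @param rate_m Migrants per generation (> 0), symmetric.
#' @param start_time Generations before present at which gene flow began
#'   (> 0); must predate neither species' divergence from the other.
#' @return A `migration_event` object.
#' @export
migration_event <- function(species_a, species_b, rate_m, start_time) {
  stopifnot(is.character(species_a), is.character(species_b))
  if (identical(species_a, species_b))
    stop("migration requires two distinct species")
  if (!is.numeric(rate_m) || rate_m <= 0)
    stop("rate_m must be > 0 migrants per generation")
  if (!is.numeric(start_time) || start_time <= 0)
    stop("start_time must be > 0 generations")
  structure(list(species_a = species_a, species_b = species_b,
                 rate_m = rate_m, start_time = start_time),
            class = "migration_event")
}

#' Build a demographic model from a species tree
#'
#' Attaches effective population sizes and optional migration events to a
#' species tree, converting branch lengths to generations if needed.  Node
#' ages are taken as the maximum root-to-tip descent below each node (exact
#' for ultrametric trees; a mild normalisation for posterior samples whose
#' branch lengths carry independent noise).
#'
#' @param tree A rooted binary `phylo` species tree.
#' @param ne Diploid effective population size: a scalar applied to every
#'   branch, or a vector of length `2 * n_tips - 1` indexed by ape node
#'   number (tips first).
#' @param migrations List of [migration_event()] objects (empty for the
#'   pure multispecies coalescent).
#' @param time_unit `"generations"` (branch lengths used as-is) or
#'   `"coalescent-units"` (lengths multiplied by `2 * ne` generations;
#'   requires scalar `ne`).
#' @return A `demographic_model` object.
#' @export
build_demography <- function(tree, ne, migrations = list(),
                             time_unit = c("generations",
                                           "coalescent-units")) {
  time_unit <- match.arg(time_unit)
  validate_species_tree(tree)
  if (is.null(tree$edge.length))
    stop("species tree must have branch lengths")
  ntip <- length(tree$tip.label)
  nnode <- 2L * ntip - 1L
  if (length(ne) == 1L) ne <- rep(ne, nnode)
  if (length(ne) != nnode || any(!is.finite(ne)) || any(ne <= 0))
    stop("ne must be a positive scalar or a positive vector of length ",
         nnode)
  if (time_unit == "coalescent-units") {
    if (length(unique(ne)) != 1L)
      stop("coalescent-unit input requires a single shared ne")
    tree$edge.length <- tree$edge.length * 2 * ne[1L]
  }
  if (inherits(migrations, "migration_event")) migrations <- list(migrations)

  # node ages: tips at 0, internal nodes by deepest descent
  ages <- numeric(nnode)
  edge <- tree$edge
  for (i in ape::postorder(tree)) {  # children resolved before parents
    ages[edge[i, 1L]] <- max(ages[edge[i, 1L]],
                             ages[edge[i, 2L]] + tree$edge.length[i])
  }
  # ensure strict rootward increase (guaranteed for positive edge lengths)
  parent_of <- integer(nnode); parent_of[] <- NA_integer_
  parent_of[edge[, 2L]] <- edge[, 1L]
  root <- setdiff(edge[, 1L], edge[, 2L])[1L]
  if (any(ages[edge[, 1L]] <= ages[edge[, 2L]]))
    stop("degenerate species tree: a divergence time is not older than ",
         "its descendants (zero-length internal branch?)")

  mig <- lapply(migrations, function(ev) {
    stopifnot(inherits(ev, "migration_event"))
    ia <- match(ev$species_a, tree$tip.label)
    ib <- match(ev$species_b, tree$tip.label)
    if (is.na(ia) || is.na(ib))
      stop("migration species '",
           if (is.na(ia)) ev$species_a else ev$species_b,
           "' is not a tip of the species tree")
    mrca <- ape::getMRCA(tree, c(ia, ib))
    if (ev$start_time >= ages[mrca])
      stop("migration between '", ev$species_a, "' and '", ev$species_b,
           "' starts ", ev$start_time, " generations ago, older than ",
           "their divergence at ", ages[mrca],
           " generations (gene flow between non-extant lineages)")
    list(pop_a = ia, pop_b = ib, rate_m = ev$rate_m,
         # window closes at the first event that removes either species
         end = min(ev$start_time, ages[parent_of[ia]], ages[parent_of[ib]]),
         event = ev)
  })

  structure(list(tree = tree, ne = ne, ages = ages, root = root,
                 parent_of = parent_of, migrations = mig),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat("Demographic model:", ntip, "species, root age",
      format(x$ages[x$root], big.mark = ","), "generations, Ne",
      if (length(unique(x$ne)) == 1L) format(x$ne[1L], big.mark = ",")
      else "per-branch", "\n")
  if (length(x$migrations)) {
    for (m in x$migrations)
      cat("  gene flow: ", m$event$species_a, " <-> ", m$event$species_b,
          ", m = ", signif(m$event$rate_m, 4),
          " migrants/generation since ", format(m$event$start_time,
          big.mark = ","), " generations ago\n", sep = "")
  } else cat("  no migration (pure multispecies coalescent)\n")
  invisible(x)
}

#' Simulation configuration
#'
#' @param n_snps Number of polymorphic SNP loci to emit.
#' @param samples_per_species Named integer vector: haploid sample count
#'   per species.
#' @param mutation_rate Per-locus mutation rate, recorded as metadata only:
#'   the SNP generator conditions on exactly one mutation per retained
#'   locus, so `mutation_rate` does not alter the simulated genotypes.
#' @param seed Master integer seed; per-locus streams are derived from it
#'   by counter so earlier loci are invariant to `n_snps`.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_snps, samples_per_species,
                              mutation_rate = 1e-8, seed = 1L) {
  stopifnot(is.numeric(n_snps), n_snps >= 1,
            is.numeric(samples_per_species),
            !is.null(names(samples_per_species)),
            all(samples_per_species >= 1))
  structure(list(n_snps = as.integer(n_snps),
                 samples_per_species = samples_per_species,
                 mutation_rate = mutation_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate one gene genealogy under the structured coalescent
#'
#' Runs the standard backward-in-time structured coalescent inside the
#' species tree: within a population holding `k` lineages any pair
#' coalesces at rate `1 / (2 Ne)` per generation; at each species-tree node
#' the daughter populations merge; during an active secondary-contact
#' window each lineage in one of the two connected species migrates to the
#' other at rate `m / (2 Ne)`.  Waiting times are exponential with
#' rate-sum competition among all coalescence and migration events.
#' Uses the current R random number stream.
#'
#' @param model A `demographic_model`.
#' @param samples_per_species Named haploid sample counts (names must be
#'   tip labels of the model's tree).
#' @return A `gene_genealogy`: list with `edge_length` and `edge_tips`
#'   (parallel; tips as indices into `sample_id`), `sample_id`,
#'   `sample_species`, `tmrca`, `total_length`, `n_samples`.
#' @export
simulate_gene_tree <- function(model, samples_per_species) {
  stopifnot(inherits(model, "demographic_model"))
  tiplab <- model$tree$tip.label
  if (!all(names(samples_per_species) %in% tiplab))
    stop("samples_per_species names must match species-tree tips")
  counts <- samples_per_species[tiplab]
  counts[is.na(counts)] <- 0L
  K <- sum(counts)
  if (K < 2L) stop("need at least 2 sampled lineages in total")

  # lineage state
  pop <- rep(seq_along(tiplab), times = counts)
  born <- numeric(K)
  tips <- as.list(seq_len(K))
  alive <- rep(TRUE, K)
  n_alive <- K
  sample_species <- rep(tiplab, times = counts)
  sample_id <- paste0(sample_species, "_",
                      unlist(lapply(counts, seq_len), use.names = FALSE))

  ne <- model$ne
  # boundaries: species-tree merge events, then open-ended root epoch
  merge_nodes <- order(model$ages)[model$ages[order(model$ages)] > 0]
  merge_nodes <- merge_nodes[merge_nodes > length(tiplab)]
  merge_times <- model$ages[merge_nodes]
  children <- lapply(merge_nodes, function(v)
    model$tree$edge[model$tree$edge[, 1L] == v, 2L])

  migs <- model$migrations
  n_mig <- length(migs)

  maxE <- 2L * (K - 1L)
  edge_length <- numeric(maxE)
  edge_tips <- vector("list", maxE)
  ne_count <- 0L

  t <- 0
  ev <- 1L
  repeat {
    boundary <- if (ev <= length(merge_times)) merge_times[ev] else Inf
    repeat {
      if (n_alive == 1L) break
      live <- which(alive)
      cnt <- tabulate(pop[live], nbins = length(ne))
      coal_rate <- cnt * (cnt - 1L) / 2 / (2 * ne)
      mig_rate <- numeric(2L * n_mig)
      if (n_mig) for (j in seq_len(n_mig)) {
        if (t < migs[[j]]$end) {
          mig_rate[2L * j - 1L] <-
            cnt[migs[[j]]$pop_a] * migs[[j]]$rate_m / (2 * ne[migs[[j]]$pop_a])
          mig_rate[2L * j] <-
            cnt[migs[[j]]$pop_b] * migs[[j]]$rate_m / (2 * ne[migs[[j]]$pop_b])
        }
      }
      # next rate change from a closing migration window
      mig_ends <- if (n_mig)
        vapply(migs, function(m) m$end, 0)[vapply(migs, function(m) m$end, 0) > t]
      else numeric(0)
      horizon <- min(boundary, if (length(mig_ends)) min(mig_ends) else Inf)
      R <- sum(coal_rate) + sum(mig_rate)
      if (R == 0) { t <- horizon; if (horizon == boundary) break else next }
      dt <- stats::rexp(1L, R)
      if (t + dt >= horizon) { t <- horizon; if (horizon == boundary) break else next }
      t <- t + dt
      # pick event category
      u <- stats::runif(1L) * R
      acc <- 0
      done <- FALSE
      for (p in which(coal_rate > 0)) {
        acc <- acc + coal_rate[p]
        if (u <= acc) {
          pair <- sample(live[pop[live] == p], 2L)
          a <- pair[1L]; b <- pair[2L]
          edge_length[ne_count + 1L] <- t - born[a]
          edge_tips[[ne_count + 1L]] <- tips[[a]]
          edge_length[ne_count + 2L] <- t - born[b]
          edge_tips[[ne_count + 2L]] <- tips[[b]]
          ne_count <- ne_count + 2L
          alive[b] <- FALSE
          born[a] <- t
          tips[[a]] <- c(tips[[a]], tips[[b]])
          n_alive <- n_alive - 1L
          done <- TRUE
          break
        }
      }
      if (!done && n_mig) for (j in seq_len(n_mig)) {
        for (dir in 1:2) {
          r <- mig_rate[2L * (j - 1L) + dir]
          if (r <= 0) next
          acc <- acc + r
          if (u <= acc) {
            from <- if (dir == 1L) migs[[j]]$pop_a else migs[[j]]$pop_b
            to <- if (dir == 1L) migs[[j]]$pop_b else migs[[j]]$pop_a
            cand <- live[pop[live] == from]
            mover <- if (length(cand) == 1L) cand else sample(cand, 1L)
            pop[mover] <- to
            done <- TRUE
            break
          }
        }
        if (done) break
      }
    }
    if (n_alive == 1L) break
    # species-tree node: daughters merge into the ancestral population
    v <- merge_nodes[ev]
    pop[alive & pop %in% children[[ev]]] <- v
    ev <- ev + 1L
  }

  structure(list(edge_length = edge_length[seq_len(ne_count)],
                 edge_tips = edge_tips[seq_len(ne_count)],
                 sample_id = sample_id,
                 sample_species = sample_species,
                 tmrca = t,
                 total_length = sum(edge_length[seq_len(ne_count)]),
                 n_samples = K),
            class = "gene_genealogy")
}

#' Place a single mutation on a genealogy
#'
#' Drops one mutation on an edge chosen with probability proportional to
#' edge length; tips descending from the mutated edge carry allele 1, the
#' rest allele 0.  The genealogy stores no edge above the root, so every
#' draw subtends a proper non-empty subset of the samples and the returned
#' column is always polymorphic; `NULL` is returned only for a degenerate
#' genealogy with no positive-length edge.
#'
#' @param genealogy A `gene_genealogy` from [simulate_gene_tree()].
#' @return Integer 0/1 vector of length `n_samples`, or `NULL`.
#' @export
drop_single_mutation <- function(genealogy) {
  stopifnot(inherits(genealogy, "gene_genealogy"))
  len <- genealogy$edge_length
  if (!length(len) || sum(len) <= 0) return(NULL)
  e <- sample.int(length(len), 1L, prob = len)
  col <- integer(genealogy$n_samples)
  col[genealogy$edge_tips[[e]]] <- 1L
  col
}

#' Simulate a biallelic SNP matrix under the (migration-extended) MSCM
#'
#' Each locus is an independent gene genealogy simulated by
#' [simulate_gene_tree()] with one mutation dropped by
#' [drop_single_mutation()]; every emitted locus is therefore polymorphic
#' by construction.  Per-locus random streams are L'Ecuyer-CMRG substreams
#' derived from `config$seed` by counter, so the genealogy of locus i does
#' not depend on `n_snps`.
#'
#' @param model A `demographic_model`.
#' @param config A [simulation_config()].
#' @return A `snp_matrix`: integer matrix (individuals x loci, values 0/1)
#'   with row names the haploid sample IDs and attribute `sample_map`.
#' @export
simulate_snp_matrix <- function(model, config) {
  stopifnot(inherits(model, "demographic_model"),
            inherits(config, "simulation_config"))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  old_kind <- RNGkind()[1L]
  on.exit({
    RNGkind(old_kind)
    if (had) assign(".Random.seed", old, envir = globalenv())
  })
  RNGkind("L'Ecuyer-CMRG")
  set.seed(config$seed)
  stream <- get(".Random.seed", envir = globalenv())

  sps <- config$samples_per_species
  first <- NULL
  cols <- vector("list", config$n_snps)
  for (i in seq_len(config$n_snps)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    g <- simulate_gene_tree(model, sps)
    if (is.null(first)) first <- g
    cols[[i]] <- drop_single_mutation(g)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- first$sample_id
  colnames(m) <- paste0("locus_", seq_len(config$n_snps))
  snp_matrix(m, sample_map(first$sample_id, first$sample_species))
}

#' Construct a SNP matrix object
#'
#' @param genotypes Integer matrix, individuals x loci, values in
#'   `{0, 1}` (haploid binary alleles; `NA` allowed for empirical data).
#' @param map A [sample_map()] covering every row.
#' @return A `snp_matrix` object.
#' @export
snp_matrix <- function(genotypes, map) {
  stopifnot(is.matrix(genotypes), inherits(map, "sample_map"))
  if (is.null(rownames(genotypes)))
    stop("genotype matrix must have individual IDs as row names")
  bad <- setdiff(rownames(genotypes), map$individual)
  if (length(bad))
    stop("individuals missing from the sample map: ",
         paste(head(bad, 3L), collapse = ", "))
  vals <- genotypes[!is.na(genotypes)]
  if (length(vals) && !all(vals %in% c(0L, 1L)))
    stop("genotypes must be binary 0/1 (haploid encoding)")
  storage.mode(genotypes) <- "integer"
  structure(genotypes,
            sample_map = map[match(rownames(genotypes), map$individual), ,
                             drop = FALSE],
            class = c("snp_matrix", "matrix", "array"))
}

#' @export
print.snp_matrix <- function(x, ...) {
  map <- attr(x, "sample_map")
  cat("SNP matrix:", nrow(x), "haploid samples x", ncol(x), "loci;",
      length(unique(map$species)), "species\n")
  invisible(x)
}

#' Diploid genotype view of a haploid SNP matrix
#'
#' Pairs consecutive haploid rows within each species into diploid
#' individuals with genotypes `{0, 1, 2}` (derived-allele dosage).
#'
#' @param snps A `snp_matrix` with an even haploid count per species.
#' @return Integer matrix, diploid individuals x loci.
#' @export
as_diploid <- function(snps) {
  stopifnot(inherits(snps, "snp_matrix"))
  map <- attr(snps, "sample_map")
  out <- NULL; ids <- character(0)
  for (sp in unique(map$species)) {
    rows <- which(map$species == sp)
    if (length(rows) %% 2L != 0L)
      stop("species '", sp, "' has an odd haploid count; cannot pair")
    for (k in seq_len(length(rows) / 2L)) {
      pair <- rows[c(2L * k - 1L, 2L * k)]
      out <- rbind(out, snps[pair[1L], ] + snps[pair[2L], ])
      ids <- c(ids, paste0(sp, "_d", k))
    }
  }
  rownames(out) <- ids
  out
}

#' Draw a random secondary-contact (MSCM+m) scenario
#'
#' Picks one unordered pair of extant species uniformly at random and a
#' migration rate from `rate_range` (uniform), and attaches a
#' secondary-contact window starting `contact_time * ne` generations ago.
#' Defaults follow the gene-flow simulation design: m ~ U(0.5, 5) migrants
#' per generation from 2.5N generations ago to the present.
#'
#' @param tree Species tree with branch lengths in generations.
#' @param ne Diploid effective population size (scalar).
#' @param rate_range Length-2 numeric, uniform support for the migration
#'   rate in migrants per generation.
#' @param contact_time Start of gene flow, in units of `ne` generations.
#' @param seed Optional integer seed.
#' @return A `demographic_model` whose `scenario` attribute records the
#'   chosen pair and rate.
#' @export
draw_mscm_m_scenario <- function(tree, ne, rate_range = c(0.5, 5),
                                 contact_time = 2.5, seed = NULL) {
  stopifnot(length(tree$tip.label) >= 2L, length(rate_range) == 2L)
  pairs <- utils::combn(tree$tip.label, 2L)
  drawn <- with_seed(seed, {
    j <- sample.int(ncol(pairs), 1L)
    m <- stats::runif(1L, rate_range[1L], rate_range[2L])
    list(j = j, m = m)
  })
  ev <- migration_event(pairs[1L, drawn$j], pairs[2L, drawn$j],
                        rate_m = drawn$m, start_time = contact_time * ne)
  model <- build_demography(tree, ne, migrations = list(ev))
  attr(model, "scenario") <- list(species_a = ev$species_a,
                                  species_b = ev$species_b,
                                  rate_m = ev$rate_m,
                                  start_time = ev$start_time)
  model
}

#' The symmetric six-species simulation-design tree
#'
#' A symmetric six-taxon species tree with speciation events at
#' `n_times[1] * ne`, `n_times[2] * ne` and `n_times[3] * ne` generations
#' (defaults 5N, 10N, 20N): two (sp1,sp2)/(sp4,sp5)-style cherries, each
#' joined by a third species, mirrored about the root.
#'
#' @param ne Diploid effective population size.
#' @param n_times Speciation event times in units of `ne` generations.
#' @return A `phylo` object with branch lengths in generations.
#' @export
design_species_tree <- function(ne = 1e5, n_times = c(5, 10, 20)) {
  stopifnot(length(n_times) == 3L, all(diff(n_times) > 0))
  t1 <- n_times[1L] * ne; t2 <- n_times[2L] * ne; t3 <- n_times[3L] * ne
  txt <- sprintf(
    "(((sp1:%g,sp2:%g):%g,sp3:%g):%g,((sp4:%g,sp5:%g):%g,sp6:%g):%g);",
    t1, t1, t2 - t1, t2, t3 - t2, t1, t1, t2 - t1, t2, t3 - t2)
  parse_newick(txt)
}
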