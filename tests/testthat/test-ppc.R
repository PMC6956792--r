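test_that("two_tailed_ppp counts tails, caps at 1 and resolves ties", {
  expect_equal(two_tailed_ppp(5, c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11)), 0.8)
  expect_equal(two_tailed_ppp(0, 1:10), 0)     # empirical below everything
  expect_equal(two_tailed_ppp(3, rep(3, 10)), 1)  # ties only
  expect_equal(two_tailed_ppp(0, c(-1, 1)), 1)    # balanced tails cap at 1
  expect_error(two_tailed_ppp(1, numeric(0)), "empty")
})

test_that("two_tailed_ppp is invariant under joint monotone transforms", {
  set.seed(1)
  for (i in 1:20) {
    emp <- rnorm(1)
    pred <- rnorm(30)
    f <- function(x) exp(2 * x) + 1  # strictly increasing
    expect_equal(two_tailed_ppp(emp, pred),
                 two_tailed_ppp(f(emp), f(pred)))
  }
})

test_that("two_tailed_ppp is super-uniform under the null", {
  set.seed(99)
  p <- replicate(1000, two_tailed_ppp(rnorm(1), rnorm(99)))
  for (alpha in c(0.05, 0.1)) {
    # Monte-Carlo slack: 3 binomial SEs
    slack <- 3 * sqrt(alpha * (1 - alpha) / 1000)
    expect_lte(mean(p <= alpha), alpha + slack)
  }
})

test_that("fst_outlier_test applies the 1.5 IQR hinge rule across pairs", {
  mk <- function(v) {
    k <- 5
    sp <- paste0("s", 1:k)
    f <- matrix(NA_real_, k, k, dimnames = list(sp, sp))
    f[upper.tri(f)] <- v
    f[lower.tri(f)] <- t(f)[lower.tri(f)]
    structure(list(species = sp, fst = f, n_loci = f * 0 + 1),
              class = "pairwise_fst")
  }
  # 10 pairs; empirical deviates on exactly one pair
  base <- rep(0.3, 10)
  emp_v <- base + c(0.01, 0.00, 0.02, 0.01, 0.50, 0.01, 0.00, 0.02,
                    0.01, 0.01)
  pred <- list(mk(base), mk(base), mk(base))
  res <- fst_outlier_test(mk(emp_v), pred)
  expect_true(res$violation)
  expect_equal(res$outlier_pairs, names(res$d)[5])
  # no deviation -> no violation
  res0 <- fst_outlier_test(mk(base), pred)
  expect_false(res0$violation)
  # constant differences -> no outliers even with nonzero shift
  resc <- fst_outlier_test(mk(base + 0.2), pred)
  expect_false(resc$violation)
})

test_that("fst_outlier_test is equivariant under species relabelling", {
  set.seed(3)
  sp <- paste0("s", 1:5)
  mk <- function(v, labels) {
    f <- matrix(NA_real_, 5, 5, dimnames = list(labels, labels))
    f[upper.tri(f)] <- v
    f[lower.tri(f)] <- t(f)[lower.tri(f)]
    structure(list(species = labels, fst = f, n_loci = f * 0 + 1),
              class = "pairwise_fst")
  }
  v_emp <- runif(10, 0.2, 0.3); v_emp[7] <- 0.9
  v_pred <- runif(10, 0.2, 0.3)
  r1 <- fst_outlier_test(mk(v_emp, sp), list(mk(v_pred, sp),
                                             mk(v_pred, sp)))
  # relabel: permute species names consistently everywhere
  perm <- c(s1 = "x3", s2 = "x1", s3 = "x5", s4 = "x2", s5 = "x4")
  relabel <- function(m) {
    m$species <- unname(perm[m$species])
    dimnames(m$fst) <- list(m$species, m$species)
    m
  }
  r2 <- fst_outlier_test(relabel(mk(v_emp, sp)),
                         list(relabel(mk(v_pred, sp)),
                              relabel(mk(v_pred, sp))))
  expect_equal(length(r1$outlier_pairs), length(r2$outlier_pairs))
  expect_equal(unname(sort(r1$d)), unname(sort(r2$d)))
})

test_that("tree_distance_null draws distinct pairs and is seed-stable", {
  tr <- design_tree()
  same <- replicate(10, tr, simplify = FALSE)
  class(same) <- "multiPhylo"
  expect_equal(as.numeric(tree_distance_null(same, "RF", n = 50,
                                             seed = 1)), 0)
  # posterior containing two topologies: every drawn pair distance is
  # either 0 (same topology) or d(A,B); with only unequal *trees* forced,
  # the threshold from a two-tree posterior is exactly d(A,B)
  t2 <- same
  t2[[2]] <- parse_newick(
    "(((sp1:5,sp3:5):5,sp2:10):10,((sp4:5,sp5:5):5,sp6:10):10);")
  two <- t2[1:2]
  class(two) <- "multiPhylo"
  thr <- tree_distance_null(two, "RF", n = 100, seed = 2)
  expect_equal(as.numeric(thr), rf_distance(t2[[1]], t2[[2]]))
  expect_equal(tree_distance_null(two, "KF", n = 50, seed = 3),
               tree_distance_null(two, "KF", n = 50, seed = 3))
  expect_error(tree_distance_null(same[1], "RF"), ">= 2")
})

test_that("tree_distance_ppp pools comparisons against the null threshold", {
  set.seed(11)
  post <- generate_synthetic_posterior(synthetic_posterior_config(
    design_tree(), topology_jitter = 0.5, length_jitter_cv = 0.1,
    n_samples = 30, seed = 5))$trees
  cfg <- ppc_config(n_null_comparisons = 200, n_pp_tree_comparisons = 20,
                    seed = 6)
  # pp trees identical to their source tree -> all distances 0 -> p = 0
  pp <- lapply(1:5, function(k) {
    trees <- replicate(10, post[[k]], simplify = FALSE)
    class(trees) <- "multiPhylo"
    list(source_tree = post[[k]], trees = trees)
  })
  res <- tree_distance_ppp(post, pp, kind = "KF", config = cfg)
  expect_equal(res$p_value, 0)
  expect_false(res$violation)
  # pp trees wildly distant -> p = 1 -> violation
  far <- parse_newick(paste0("(((sp1:1,sp4:1):1,sp6:2):98,",
                             "((sp2:1,sp5:1):1,sp3:2):98);"))
  pp_far <- lapply(1:5, function(k) {
    trees <- replicate(10, far, simplify = FALSE)
    class(trees) <- "multiPhylo"
    list(source_tree = post[[k]], trees = trees)
  })
  res_far <- tree_distance_ppp(post, pp_far, kind = "KF", config = cfg)
  expect_equal(res_far$p_value, 1)
  expect_true(res_far$violation)
  # p is non-increasing in the threshold
  d <- attr(res_far, "distances")
  thresholds <- quantile(c(0, d), c(0.1, 0.5, 0.9))
  ps <- vapply(thresholds, function(th) sum(d > th) / length(d), 1)
  expect_true(all(diff(ps) <= 0))
})

test_that("run_data_based_check returns the requested statistics", {
  tr <- design_tree()
  sps <- two_per_species(tr)
  model <- build_demography(tr, 1e5)
  emp <- simulate_snp_matrix(model, simulation_config(80, sps, seed = 31))
  post <- generate_synthetic_posterior(synthetic_posterior_config(
    tr, topology_jitter = 0, length_jitter_cv = 0.05,
    n_samples = 12, seed = 32))$trees
  rep1 <- run_data_based_check(
    emp, post, model_builder = function(t) build_demography(t, 1e5),
    config = ppc_config(seed = 33),
    sim_config = simulation_config(80, sps), n_pp = 12)
  expect_setequal(rep1$results$statistic, c("FSTA", "FSTR", "PFST"))
  expect_true(all(rep1$results$p_value[1:2] >= 0 &
                  rep1$results$p_value[1:2] <= 1, na.rm = TRUE))
  # deterministic under (seed, inputs)
  rep2 <- run_data_based_check(
    emp, post, model_builder = function(t) build_demography(t, 1e5),
    config = ppc_config(seed = 33),
    sim_config = simulation_config(80, sps), n_pp = 12)
  expect_identical(rep1$results, rep2$results)
  # an empirical dataset that IS a predictive draw lies inside the
  # predictive distribution
  expect_gt(rep1$results$p_value[rep1$results$statistic == "FSTA"], 0)
})

test_that("run_inference_based_check evaluates RF/KF/MLM/MLSD", {
  tr <- design_tree()
  post <- generate_synthetic_posterior(synthetic_posterior_config(
    tr, topology_jitter = 0.3, length_jitter_cv = 0.1,
    n_samples = 20, likelihood_mean = -1000, likelihood_sd = 4,
    seed = 41))
  pp <- lapply(1:6, function(k) {
    g <- generate_synthetic_posterior(synthetic_posterior_config(
      tr, topology_jitter = 0.3, length_jitter_cv = 0.1,
      n_samples = 10, likelihood_mean = -1000, likelihood_sd = 4,
      seed = 100 + k))
    list(source_tree = post$trees[[k]], trees = g$trees, log = g$log)
  })
  cfg <- ppc_config(n_null_comparisons = 100, n_pp_tree_comparisons = 10,
                    seed = 42)
  rep <- run_inference_based_check(post$trees, post$log, pp, config = cfg)
  expect_equal(rep$results$statistic, c("RF", "KF", "MLM", "MLSD"))
  # pp logs statistically identical to the posterior log: no violation
  expect_false(rep$results$violation[rep$results$statistic == "MLM"])
  # posterior SD far outside every pp SD -> MLSD p = 0 -> violation
  wide <- trace_log(data.frame(likelihood =
    rnorm(200, -1000, 50)))
  rep2 <- run_inference_based_check(post$trees, wide, pp, config = cfg,
                                    statistics = "MLSD")
  expect_equal(rep2$results$p_value, 0)
  expect_true(rep2$results$violation)
  # missing logs are reported
  pp_nolog <- lapply(pp, function(x) x[c("source_tree", "trees")])
  expect_error(run_inference_based_check(post$trees, post$log, pp_nolog,
                                         statistics = "MLSD"), "lack")
})

test_that("ppc reports serialise to JSON with per-statistic entries", {
  tr <- design_tree()
  sps <- two_per_species(tr)
  emp <- simulate_snp_matrix(build_demography(tr, 1e5),
                             simulation_config(40, sps, seed = 51))
  post <- generate_synthetic_posterior(synthetic_posterior_config(
    tr, n_samples = 8, seed = 52))$trees
  rep <- run_data_based_check(
    emp, post, model_builder = function(t) build_demography(t, 1e5),
    config = ppc_config(seed = 53),
    sim_config = simulation_config(40, sps), n_pp = 8)
  js <- jsonlite::fromJSON(ppc_report_json(rep))
  expect_setequal(js$results$statistic, c("FSTA", "FSTR", "PFST"))
  f <- withr::local_tempfile(fileext = ".json")
  ppc_report_json(rep, f)
  expect_true(file.exists(f))
})
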