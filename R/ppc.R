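#' Posterior predictive check configuration
#'
#' @param alpha Significance level for violation calls (default 0.05).
#' @param n_null_comparisons Random posterior tree pairs used to build the
#'   tree-distance null distribution (default 1000).
#' @param n_pp_tree_comparisons Trees drawn per posterior predictive
#'   distribution for the tree-distance comparison (default 100).
#' @param null_quantile Quantile of the null distribution used as the
#'   tree-distance threshold (default 0.95).
#' @param seed Integer seed governing every stochastic step of a check.
#' @return A `ppc_config` object.
#' @export
ppc_config <- function(alpha = 0.05, n_null_comparisons = 1000L,
                       n_pp_tree_comparisons = 100L, null_quantile = 0.95,
                       seed = 1L) {
  stopifnot(alpha > 0, alpha < 1,
            n_null_comparisons >= 1, n_pp_tree_comparisons >= 1,
            null_quantile > 0, null_quantile < 1)
  structure(list(alpha = alpha,
                 n_null_comparisons = as.integer(n_null_comparisons),
                 n_pp_tree_comparisons = as.integer(n_pp_tree_comparisons),
                 null_quantile = null_quantile,
                 seed = as.integer(seed)),
            class = "ppc_config")
}

#' Two-tailed posterior predictive p-value
#'
#' Counts predictive values strictly above and strictly below the
#' empirical value, doubles the smaller tail and divides by the number of
#' predictive datasets; capped at 1.  Ties count in neither tail; if every
#' predictive value ties the empirical one there is no evidence of
#' discrepancy and the p-value is 1.
#'
#' @param empirical Scalar empirical statistic.
#' @param predictive Numeric vector of the statistic over posterior
#'   predictive datasets (non-empty).
#' @return p-value in `[0, 1]`.
#' @export
two_tailed_ppp <- function(empirical, predictive) {
  stopifnot(is.numeric(empirical), length(empirical) == 1L,
            !is.na(empirical))
  predictive <- predictive[!is.na(predictive)]
  if (!length(predictive)) stop("empty predictive distribution")
  above <- sum(predictive > empirical)
  below <- sum(predictive < empirical)
  if (above + below == 0L) return(1)
  min(1, 2 * min(above, below) / length(predictive))
}

#' Pairwise F_ST outlier test
#'
#' For every species pair, computes the mean difference between the
#' empirical pairwise F_ST and the posterior predictive values of the same
#' pair, then applies the standard boxplot outlier rule
#' ([grDevices::boxplot.stats()], Tukey hinges, 1.5 x IQR fences) across
#' pairs.  Any flagged pair indicates a model violation, and the flagged
#' pairs themselves point at lineages likely to be exchanging genes.
#'
#' @param empirical A [pairwise_fst()] of the observed data.
#' @param predictive List (length >= 2) of `pairwise_fst` objects from
#'   posterior predictive datasets, on the same species set.
#' @return List with `violation` (flag), `outlier_pairs` (character), and
#'   `d` (named mean differences per pair).
#' @export
fst_outlier_test <- function(empirical, predictive) {
  stopifnot(inherits(empirical, "pairwise_fst"),
            is.list(predictive), length(predictive) >= 2L)
  emp <- fst_pair_values(empirical)
  pred <- vapply(predictive, function(p) {
    stopifnot(inherits(p, "pairwise_fst"))
    if (!setequal(p$species, empirical$species))
      stop("predictive F_ST matrix has a different species set")
    fst_pair_values(p)[names(emp)]
  }, numeric(length(emp)))
  d <- emp - rowMeans(pred, na.rm = TRUE)
  d <- d[!is.na(d)]
  if (!length(d)) stop("all species pairs have undefined F_ST")
  fences <- grDevices::boxplot.stats(d, coef = 1.5)
  out <- names(d)[d %in% fences$out]
  list(violation = length(out) > 0L, outlier_pairs = out, d = d)
}

#' Tree-distance null threshold from the posterior
#'
#' Draws `n` random pairs of distinct trees from the posterior, computes
#' their pairwise distances, and returns the `null_quantile` empirical
#' quantile.  Posterior predictive distances above this threshold signal
#' that the posterior and posterior predictive trees differ more than the
#' posterior's internal spread.
#'
#' @param posterior A `multiPhylo` with >= 2 trees.
#' @param kind `"RF"` or `"KF"`.
#' @param n Number of random pairs (default 1000).
#' @param null_quantile Quantile returned (default 0.95).
#' @param seed Optional integer seed.
#' @return Scalar threshold, with the null distances as attribute
#'   `"distances"`.
#' @export
tree_distance_null <- function(posterior, kind = c("RF", "KF"), n = 1000L,
                               null_quantile = 0.95, seed = NULL) {
  kind <- match.arg(kind)
  if (inherits(posterior, "phylo")) posterior <- c(posterior)
  N <- length(posterior)
  if (N < 2L) stop("need >= 2 posterior trees for a null distribution")
  dist_fun <- if (kind == "RF") rf_distance else kf_distance
  d <- with_seed(seed, {
    i <- sample.int(N, n, replace = TRUE)
    j <- sample.int(N - 1L, n, replace = TRUE)
    j <- ifelse(j >= i, j + 1L, j)  # force the two members distinct
    vapply(seq_len(n),
           function(k) dist_fun(posterior[[i[k]]], posterior[[j[k]]]),
           numeric(1L))
  })
  structure(unname(stats::quantile(d, null_quantile)), distances = d)
}

#' Tree-distance posterior predictive p-value
#'
#' For each posterior predictive tree distribution, draws
#' `n_pp_tree_comparisons` trees (without replacement when the set is
#' large enough, otherwise with replacement) and computes their distance
#' to the posterior tree the dataset was simulated from.  All comparisons
#' are pooled and p is the fraction exceeding the null threshold; p above
#' `alpha` indicates a model violation (posterior predictive trees sit
#' further from the posterior than the posterior's own spread).
#'
#' @param posterior The posterior `multiPhylo` (builds the null threshold
#'   unless one is supplied).
#' @param pp_tree_sets List of `list(source_tree =, trees =)` pairs: the
#'   posterior tree each predictive dataset was simulated from and the
#'   tree distribution inferred from that dataset.
#' @param kind `"RF"` or `"KF"`.
#' @param config A [ppc_config()].
#' @param threshold Optional precomputed null threshold.
#' @return A one-row data.frame: `statistic`, `p_value`, `violation`, with
#'   the pooled distances as attribute `"distances"`.
#' @export
tree_distance_ppp <- function(posterior, pp_tree_sets,
                              kind = c("RF", "KF"), config = ppc_config(),
                              threshold = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(pp_tree_sets) >= 1L)
  if (is.null(threshold))
    threshold <- tree_distance_null(posterior, kind,
                                    n = config$n_null_comparisons,
                                    null_quantile = config$null_quantile,
                                    seed = config$seed)
  dist_fun <- if (kind == "RF") rf_distance else kf_distance
  d <- with_seed(derive_seed(config$seed, 1L), {
    unlist(lapply(seq_along(pp_tree_sets), function(k) {
      s <- pp_tree_sets[[k]]
      trees <- s$trees
      if (inherits(trees, "phylo")) trees <- c(trees)
      if (length(trees) < 1L)
        stop("posterior predictive tree set ", k, " is empty")
      nn <- config$n_pp_tree_comparisons
      idx <- sample.int(length(trees), nn, replace = length(trees) < nn)
      vapply(idx, function(i) dist_fun(trees[[i]], s$source_tree),
             numeric(1L))
    }))
  })
  p <- sum(d > threshold) / length(d)
  structure(data.frame(statistic = kind, p_value = p,
                       violation = p > config$alpha,
                       stringsAsFactors = FALSE),
            distances = d, threshold = unname(threshold))
}

# Assemble rows + details into a ppc_report.
new_ppc_report <- function(rows, details, config, provenance = character()) {
  structure(list(results = rows, details = details, config = config,
                 provenance = provenance),
            class = "ppc_report")
}

#' Data-based posterior predictive check
#'
#' Stage-one check requiring no re-inference: for each sampled posterior
#' tree, simulates one posterior predictive SNP dataset under the
#' multispecies coalescent, computes pairwise Hudson F_ST on the empirical
#' and every predictive dataset, and evaluates
#' \itemize{
#'   \item `FSTA` - mean pairwise F_ST, two-tailed posterior predictive
#'     p-value (violation when p < alpha);
#'   \item `FSTR` - range of pairwise F_ST, same evaluation;
#'   \item `PFST` - the per-pair F_ST outlier test (violation when any
#'     pair is a boxplot outlier).
#' }
#'
#' @param empirical The observed [snp_matrix()].
#' @param posterior The posterior `multiPhylo`.
#' @param model_builder Function `phylo -> demographic_model` used to turn
#'   each sampled posterior tree into a simulation model (e.g.
#'   `function(tr) build_demography(tr, ne = 1e5)`).
#' @param config A [ppc_config()].
#' @param sim_config A [simulation_config()]; its `samples_per_species`
#'   and `n_snps` should mirror the empirical data, and its seed is
#'   re-derived per predictive dataset from `config$seed`.
#' @param n_pp Number of posterior predictive datasets (posterior trees
#'   sampled at random); default `min(100, length(posterior))`.
#' @param statistics Subset of `c("FSTA", "FSTR", "PFST")`.
#' @return A `ppc_report`.
#' @export
run_data_based_check <- function(empirical, posterior, model_builder,
                                 config = ppc_config(), sim_config,
                                 n_pp = NULL,
                                 statistics = c("FSTA", "FSTR", "PFST")) {
  stopifnot(inherits(empirical, "snp_matrix"),
            is.function(model_builder),
            inherits(sim_config, "simulation_config"))
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (inherits(posterior, "phylo")) posterior <- c(posterior)
  emp_species <- unique(attr(empirical, "sample_map")$species)
  if (!all(emp_species %in% posterior[[1L]]$tip.label))
    stop("empirical species not in the posterior tip set: ",
         paste(setdiff(emp_species, posterior[[1L]]$tip.label),
               collapse = ", "))
  if (is.null(n_pp)) n_pp <- min(100L, length(posterior))
  trees <- sample_posterior_trees(posterior, n_pp, mode = "random",
                                  seed = config$seed)
  pred_fst <- vector("list", n_pp)
  for (k in seq_len(n_pp)) {
    model <- model_builder(trees[[k]])
    cfg_k <- sim_config
    cfg_k$seed <- derive_seed(config$seed, k + 1L)
    pred_fst[[k]] <- pairwise_fst(simulate_snp_matrix(model, cfg_k))
  }
  emp_fst <- pairwise_fst(empirical)

  rows <- NULL; details <- list(empirical_fst = emp_fst,
                                predictive_fst = pred_fst)
  if ("FSTA" %in% statistics) {
    p <- two_tailed_ppp(fst_mean(emp_fst),
                        vapply(pred_fst, fst_mean, 1))
    rows <- rbind(rows, data.frame(statistic = "FSTA", p_value = p,
                                   violation = p < config$alpha))
  }
  if ("FSTR" %in% statistics) {
    p <- two_tailed_ppp(fst_range(emp_fst),
                        vapply(pred_fst, fst_range, 1))
    rows <- rbind(rows, data.frame(statistic = "FSTR", p_value = p,
                                   violation = p < config$alpha))
  }
  if ("PFST" %in% statistics) {
    ot <- fst_outlier_test(emp_fst, pred_fst)
    rows <- rbind(rows, data.frame(statistic = "PFST", p_value = NA_real_,
                                   violation = ot$violation))
    details$outlier <- ot
  }
  new_ppc_report(rows, details, config,
                 provenance = attr(posterior, "source") %||% "<memory>")
}

#' Inference-based posterior predictive check
#'
#' Stage-two check comparing the original posterior with re-analyses of
#' the posterior predictive datasets:
#' \itemize{
#'   \item `RF`, `KF` - tree distances between posterior predictive trees
#'     and their source posterior trees, against the posterior's own null
#'     distribution ([tree_distance_ppp()]; violation when p > alpha);
#'   \item `MLM`, `MLSD` - mean and SD of tree likelihoods, two-tailed
#'     posterior predictive p-values against the per-dataset predictive
#'     means/SDs (violation when p < alpha).
#' }
#'
#' @param posterior The posterior `multiPhylo`.
#' @param posterior_log The posterior [trace_log()].
#' @param pp_results List of `list(source_tree =, trees =, log =)`: the
#'   posterior tree each predictive dataset came from, plus the tree set
#'   and trace log from re-analysing that dataset.
#' @param config A [ppc_config()].
#' @param statistics Subset of `c("RF", "KF", "MLM", "MLSD")`.
#' @return A `ppc_report`.
#' @export
run_inference_based_check <- function(posterior, posterior_log, pp_results,
                                      config = ppc_config(),
                                      statistics = c("RF", "KF",
                                                     "MLM", "MLSD")) {
  statistics <- match.arg(statistics, several.ok = TRUE)
  stopifnot(inherits(posterior_log, "trace_log"), length(pp_results) >= 1L)
  has_trees <- vapply(pp_results, function(x) !is.null(x$trees), TRUE)
  has_logs <- vapply(pp_results, function(x) !is.null(x$log), TRUE)
  if (any(c("RF", "KF") %in% statistics) && !all(has_trees))
    stop("pp_results ", paste(which(!has_trees), collapse = ", "),
         " lack tree sets")
  if (any(c("MLM", "MLSD") %in% statistics) && !all(has_logs))
    stop("pp_results ", paste(which(!has_logs), collapse = ", "),
         " lack trace logs")

  rows <- NULL; details <- list()
  for (kind in intersect(c("RF", "KF"), statistics)) {
    res <- tree_distance_ppp(posterior, pp_results, kind = kind,
                             config = config)
    rows <- rbind(rows, as.data.frame(res))
    details[[paste0(kind, "_threshold")]] <- attr(res, "threshold")
  }
  if (any(c("MLM", "MLSD") %in% statistics)) {
    emp <- likelihood_mean_sd(posterior_log)
    pred <- lapply(pp_results, function(x) likelihood_mean_sd(x$log))
    if ("MLM" %in% statistics) {
      p <- two_tailed_ppp(emp$mean, vapply(pred, `[[`, 1, "mean"))
      rows <- rbind(rows, data.frame(statistic = "MLM", p_value = p,
                                     violation = p < config$alpha))
    }
    if ("MLSD" %in% statistics) {
      p <- two_tailed_ppp(emp$sd, vapply(pred, `[[`, 1, "sd"))
      rows <- rbind(rows, data.frame(statistic = "MLSD", p_value = p,
                                     violation = p < config$alpha))
    }
    details$likelihood_empirical <- emp
  }
  rows <- rows[match(statistics, rows$statistic), , drop = FALSE]
  rownames(rows) <- NULL
  new_ppc_report(rows, details, config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ppc_report <- function(x, ...) {
  cat("Posterior predictive check (alpha = ", x$config$alpha, ")\n",
      sep = "")
  df <- x$results
  df$p_value <- ifelse(is.na(df$p_value), "-", signif(df$p_value, 4))
  print(df, row.names = FALSE)
  if (!is.null(x$details$outlier) && x$details$outlier$violation)
    cat("F_ST outlier pairs:",
        paste(x$details$outlier$outlier_pairs, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a PPC report to JSON
#'
#' @param report A `ppc_report`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
ppc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ppc_report"))
  obj <- list(alpha = report$config$alpha,
              results = report$results)
  if (!is.null(report$details$outlier))
    obj$outlier_pairs <- report$details$outlier$outlier_pairs
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
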