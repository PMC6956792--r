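#' Construct a confusion matrix
#'
#' Positive class: a model violation detected on a dataset simulated with
#' gene flow (MSCM+m).  False positives are MSCM datasets called as
#' violations; false negatives are MSCM+m datasets not called.
#'
#' @param tp,tn,fp,fn Non-negative counts.
#' @return A `confusion_matrix` object.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  structure(as.list(counts), class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{tp \cdot tn - fp \cdot fn}
#'   {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}}
#' with the convention that a zero factor in the denominator (a degenerate
#' classifier that never, or always, emits one of the classes) yields 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Scalar in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.double(cm$tp); tn <- as.double(cm$tn)
  fp <- as.double(cm$fp); fn <- as.double(cm$fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Fraction of correctly classified datasets
#'
#' @param cm A [confusion_matrix()].
#' @return `(tp + tn) / (tp + tn + fp + fn)`.
#' @export
fraction_correct <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tot <- cm$tp + cm$tn + cm$fp + cm$fn
  if (tot == 0) stop("empty confusion matrix")
  (cm$tp + cm$tn) / tot
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix: tp=", x$tp, " tn=", x$tn, " fp=", x$fp,
      " fn=", x$fn, "  MCC=", round(mcc(x), 2),
      "  correct=", round(100 * fraction_correct(x)), "%\n", sep = "")
  invisible(x)
}

#' Tabulate violation calls against the generating model
#'
#' @param truth Character vector, one of `"MSCM"` (no gene flow) or
#'   `"MSCM+m"` per dataset; a logical vector (`TRUE` = gene flow) is also
#'   accepted.
#' @param calls Logical vector of violation calls, same length.
#' @return A [confusion_matrix()].
#' @export
tabulate_confusion <- function(truth, calls) {
  if (is.character(truth)) {
    bad <- setdiff(unique(truth), c("MSCM", "MSCM+m"))
    if (length(bad)) stop("unknown model label: ", bad[1L])
    truth <- truth == "MSCM+m"
  }
  stopifnot(is.logical(truth), is.logical(calls))
  if (length(truth) != length(calls))
    stop("truth has ", length(truth), " entries but calls has ",
         length(calls))
  confusion_matrix(tp = sum(truth & calls), tn = sum(!truth & !calls),
                   fp = sum(!truth & calls), fn = sum(truth & !calls))
}

#' Run the MSCM vs MSCM+m simulation study
#'
#' The evaluation harness: for each replicate a "true" dataset is
#' simulated either under the pure multispecies coalescent (MSCM) or with
#' a random secondary-contact gene-flow scenario (MSCM+m,
#' [draw_mscm_m_scenario()]); a synthetic posterior centred on the design
#' species tree stands in for an external Bayesian re-inference; the
#' data-based posterior predictive check is run; and the violation calls
#' are tabulated into one confusion matrix (and MCC) per summary
#' statistic.  Defaults are deliberately reduced-scale relative to the
#' full design of 100 replicates per model at 2000 SNPs, which requires an
#' external inference engine and hundreds of CPU hours per replicate.
#'
#' @param n_reps_per_model Replicates per model (default 10).
#' @param tree Species tree template with branch lengths in generations
#'   (default [design_species_tree()]).
#' @param ne Diploid effective population size (default 1e5).
#' @param n_snps SNPs per simulated dataset (default 200).
#' @param samples_per_species Haploid samples per species (default 2 each).
#' @param n_posterior_trees Synthetic posterior size per replicate
#'   (default 20).
#' @param n_pp_datasets Posterior predictive datasets per replicate
#'   (default 20).
#' @param statistics Data-based statistics to evaluate.
#' @param rate_range,contact_time Gene-flow scenario parameters passed to
#'   [draw_mscm_m_scenario()].
#' @param topology_jitter,length_jitter_cv Synthetic posterior noise
#'   (see [generate_synthetic_posterior()]).
#' @param alpha Significance level for violation calls.
#' @param seed Master seed; the whole study is deterministic given it.
#' @return An `evaluation_result`: list with `per_statistic` (one
#'   [confusion_matrix()], `mcc`, `fraction_correct` per statistic),
#'   `calls` (per-replicate data.frame) and `trend` (MSCM+m replicates:
#'   migration rate and per-statistic p-value).
#' @export
run_simulation_study <- function(n_reps_per_model = 10L,
                                 tree = design_species_tree(ne),
                                 ne = 1e5, n_snps = 200L,
                                 samples_per_species = NULL,
                                 n_posterior_trees = 20L,
                                 n_pp_datasets = 20L,
                                 statistics = c("FSTA", "FSTR", "PFST"),
                                 rate_range = c(0.5, 5),
                                 contact_time = 2.5,
                                 topology_jitter = 0.1,
                                 length_jitter_cv = 0.05,
                                 alpha = 0.05, seed = 1L) {
  stopifnot(n_reps_per_model >= 1L)
  statistics <- match.arg(statistics, several.ok = TRUE)
  if (is.null(samples_per_species))
    samples_per_species <- stats::setNames(rep(2L, length(tree$tip.label)),
                                           tree$tip.label)
  null_model <- build_demography(tree, ne)
  calls <- NULL
  rep_id <- 0L
  for (model_kind in c("MSCM", "MSCM+m")) {
    for (r in seq_len(n_reps_per_model)) {
      rep_id <- rep_id + 1L
      s <- derive_seed(seed, rep_id)
      if (model_kind == "MSCM+m") {
        truth_model <- draw_mscm_m_scenario(tree, ne,
                                            rate_range = rate_range,
                                            contact_time = contact_time,
                                            seed = derive_seed(s, 1L))
        m_rate <- attr(truth_model, "scenario")$rate_m
      } else {
        truth_model <- null_model
        m_rate <- 0
      }
      emp <- simulate_snp_matrix(truth_model,
        simulation_config(n_snps, samples_per_species,
                          seed = derive_seed(s, 2L)))
      post <- generate_synthetic_posterior(synthetic_posterior_config(
        center_tree = tree, topology_jitter = topology_jitter,
        length_jitter_cv = length_jitter_cv,
        n_samples = n_posterior_trees, seed = derive_seed(s, 3L)))
      report <- run_data_based_check(
        emp, post$trees,
        model_builder = function(tr) build_demography(tr, ne),
        config = ppc_config(alpha = alpha, seed = derive_seed(s, 4L)),
        sim_config = simulation_config(n_snps, samples_per_species),
        n_pp = min(n_pp_datasets, n_posterior_trees),
        statistics = statistics)
      row <- data.frame(replicate = rep_id, model = model_kind,
                        m = m_rate, stringsAsFactors = FALSE)
      for (st in statistics) {
        i <- which(report$results$statistic == st)
        row[[paste0("p_", st)]] <- report$results$p_value[i]
        row[[paste0("call_", st)]] <- report$results$violation[i]
      }
      calls <- rbind(calls, row)
    }
  }
  per_statistic <- lapply(stats::setNames(nm = statistics), function(st) {
    cm <- tabulate_confusion(calls$model, calls[[paste0("call_", st)]])
    list(confusion = cm, mcc = mcc(cm),
         fraction_correct = fraction_correct(cm))
  })
  trend <- calls[calls$model == "MSCM+m",
                 c("replicate", "m",
                   paste0("p_", setdiff(statistics, "PFST"))),
                 drop = FALSE]
  structure(list(per_statistic = per_statistic, calls = calls,
                 trend = trend, alpha = alpha, seed = seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Simulation study (", nrow(x$calls), " replicates, alpha = ",
      x$alpha, ")\n", sep = "")
  for (st in names(x$per_statistic)) {
    cat(sprintf("  %-5s", st))
    print(x$per_statistic[[st]]$confusion)
  }
  invisible(x)
}

#' Gene-flow trend for one statistic
#'
#' The per-replicate (migration rate, p-value) pairs over the MSCM+m
#' replicates, with the Spearman rank correlation between the two: a
#' negative correlation means stronger gene flow yields smaller p-values
#' for that statistic.
#'
#' @param result An `evaluation_result`.
#' @param statistic One of the p-value-based statistics in the study.
#' @return A data.frame with columns `replicate`, `m`, `p`; Spearman
#'   correlation as attribute `"spearman"`.
#' @export
gene_flow_trend <- function(result, statistic) {
  stopifnot(inherits(result, "evaluation_result"))
  col <- paste0("p_", statistic)
  if (!col %in% names(result$trend))
    stop("statistic '", statistic, "' has no p-values in this study; ",
         "available: ",
         paste(sub("^p_", "", grep("^p_", names(result$trend),
                                   value = TRUE)), collapse = ", "))
  df <- data.frame(replicate = result$trend$replicate,
                   m = result$trend$m, p = result$trend[[col]])
  rho <- if (stats::sd(df$p) == 0 || stats::sd(df$m) == 0) 0
         else stats::cor(df$m, df$p, method = "spearman")
  structure(df, spearman = rho)
}

#' Export an evaluation result as CSV tables
#'
#' Writes `<stem>_confusion.csv` (statistic, tp, tn, fp, fn, mcc,
#' fraction_correct) and `<stem>_trend.csv` (replicate, m, statistic, p).
#'
#' @param result An `evaluation_result`.
#' @param stem Output path stem.
#' @return Invisibly, the two file paths.
#' @export
write_evaluation_csv <- function(result, stem) {
  stopifnot(inherits(result, "evaluation_result"))
  conf <- do.call(rbind, lapply(names(result$per_statistic), function(st) {
    e <- result$per_statistic[[st]]
    data.frame(statistic = st, tp = e$confusion$tp, tn = e$confusion$tn,
               fp = e$confusion$fp, fn = e$confusion$fn, mcc = e$mcc,
               fraction_correct = e$fraction_correct)
  }))
  pcols <- grep("^p_", names(result$trend), value = TRUE)
  trend <- do.call(rbind, lapply(pcols, function(cl)
    data.frame(replicate = result$trend$replicate, m = result$trend$m,
               statistic = sub("^p_", "", cl), p = result$trend[[cl]])))
  f1 <- paste0(stem, "_confusion.csv")
  f2 <- paste0(stem, "_trend.csv")
  utils::write.csv(conf, f1, row.names = FALSE)
  utils::write.csv(trend, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
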