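#' Per-locus Hudson F_ST components
#'
#' Hudson's estimator of F_ST for one biallelic locus and one population
#' pair, in numerator/denominator form so multi-locus values can be
#' combined as a ratio of sums:
#' \deqn{N_l = (p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1}
#'       - \frac{p_2(1-p_2)}{n_2 - 1}, \qquad
#'       D_l = p_1(1 - p_2) + p_2(1 - p_1)}
#' with \eqn{p_i} the sample derived-allele frequencies and \eqn{n_i} the
#' haploid sample sizes.  `N_l / D_l` equals `1 - Hw/Hb`, one minus the
#' ratio of within- to between-population heterozygosity.
#'
#' @param n1_derived,n1_total Derived-allele count and haploid sample size
#'   in population 1 (vectorised over loci).
#' @param n2_derived,n2_total Same for population 2.
#' @return A list with numeric vectors `numerator` and `denominator`.
#' @export
hudson_fst_locus <- function(n1_derived, n1_total, n2_derived, n2_total) {
  if (any(n1_total < 2) || any(n2_total < 2))
    stop("Hudson F_ST needs >= 2 haploid samples per population at a locus")
  p1 <- n1_derived / n1_total
  p2 <- n2_derived / n2_total
  num <- (p1 - p2)^2 -
    p1 * (1 - p1) / (n1_total - 1) -
    p2 * (1 - p2) / (n2_total - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(numerator = num, denominator = den)
}

#' Pairwise multi-locus Hudson F_ST
#'
#' For every unordered species pair, combines per-locus Hudson components
#' as a ratio of sums across the loci informative for that pair (loci
#' monomorphic within the pooled pair contribute a zero denominator and
#' drop out; loci with missing data are used only where both species
#' retain >= 2 called haploids).  Negative values are reported as computed,
#' not clamped.  Pairs whose denominator sums to zero are `NA` with a
#' warning.
#'
#' @param snps A [snp_matrix()] with >= 2 species, each with >= 2 haploid
#'   samples.
#' @return A `pairwise_fst` object: list with `species`, symmetric matrix
#'   `fst`, and matrix `n_loci` of informative-locus counts.
#' @export
pairwise_fst <- function(snps) {
  stopifnot(inherits(snps, "snp_matrix"))
  map <- attr(snps, "sample_map")
  species <- unique(map$species)
  if (length(species) < 2L) stop("need >= 2 species for pairwise F_ST")
  rows <- lapply(species, function(sp) which(map$species == sp))
  names(rows) <- species
  small <- species[vapply(rows, length, 1L) < 2L]
  if (length(small))
    stop("species with < 2 haploid samples: ", paste(small, collapse = ", "))

  # per-species derived counts and call totals per locus
  der <- t(vapply(rows, function(r)
    colSums(snps[r, , drop = FALSE], na.rm = TRUE), numeric(ncol(snps))))
  tot <- t(vapply(rows, function(r)
    colSums(!is.na(snps[r, , drop = FALSE])), numeric(ncol(snps))))

  k <- length(species)
  fst <- matrix(NA_real_, k, k, dimnames = list(species, species))
  nlo <- matrix(0L, k, k, dimnames = list(species, species))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ok <- tot[i, ] >= 2 & tot[j, ] >= 2
    h <- hudson_fst_locus(der[i, ok], tot[i, ok], der[j, ok], tot[j, ok])
    inf <- h$denominator > 0
    nlo[i, j] <- nlo[j, i] <- sum(inf)
    D <- sum(h$denominator[inf])
    if (D > 0) fst[i, j] <- fst[j, i] <- sum(h$numerator[inf]) / D
  }
  if (anyNA(fst[upper.tri(fst)]))
    warning("some species pairs have no informative loci; ",
            "their F_ST is undefined (NA)")
  structure(list(species = species, fst = fst, n_loci = nlo),
            class = "pairwise_fst")
}

# Defined off-diagonal pair values of a pairwise_fst, named "a:b".
fst_pair_values <- function(m) {
  stopifnot(inherits(m, "pairwise_fst"))
  k <- length(m$species)
  idx <- which(upper.tri(m$fst), arr.ind = TRUE)
  v <- m$fst[upper.tri(m$fst)]
  names(v) <- paste(m$species[idx[, 1L]], m$species[idx[, 2L]], sep = ":")
  v
}

#' Mean of defined pairwise F_ST values
#' @param m A `pairwise_fst` object.
#' @return Arithmetic mean over defined off-diagonal pairs.
#' @export
fst_mean <- function(m) {
  v <- fst_pair_values(m)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no defined F_ST pairs")
  mean(v)
}

#' Range (max minus min) of defined pairwise F_ST values
#' @param m A `pairwise_fst` object.
#' @return `max - min` over defined off-diagonal pairs (0 for one pair).
#' @export
fst_range <- function(m) {
  v <- fst_pair_values(m)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no defined F_ST pairs")
  max(v) - min(v)
}

#' @export
print.pairwise_fst <- function(x, digits = 3, ...) {
  cat("Pairwise Hudson F_ST (", length(x$species), " species)\n", sep = "")
  print(round(x$fst, digits))
  invisible(x)
}

# shared guard for tree-distance functions
check_same_tips <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different tip sets: {",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ","),
         "} vs {", paste(setdiff(t2$tip.label, t1$tip.label),
                         collapse = ","), "}")
}

#' Robinson-Foulds distance between two species trees
#'
#' Symmetric-difference count of non-trivial bipartitions of the unrooted
#' trees; when `normalized`, divided by the maximum `2 * (n - 3)` so the
#' value lies in `[0, 1]` (0 = identical topologies, 1 = no shared
#' internal split).  Trees with fewer than 4 tips have no internal splits
#' and distance 0.
#'
#' @param t1,t2 `phylo` objects over the same tip set.
#' @param normalized Divide by the maximum possible distance?
#' @return Non-negative scalar.
#' @export
rf_distance <- function(t1, t2, normalized = TRUE) {
  check_same_tips(t1, t2)
  n <- length(t1$tip.label)
  if (n < 4L) return(0)
  d <- phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2),
                         normalize = FALSE, check.labels = TRUE)
  if (normalized) d / (2 * (n - 3)) else d
}

#' Kuhner-Felsenstein (branch-score) distance between two species trees
#'
#' Square root of the sum, over the union of bipartitions of the two
#' unrooted trees, of squared branch-length differences (a bipartition
#' absent from a tree counts with length 0).  Combines topology and branch
#' lengths; 0 iff topology and all branch lengths agree.  Unnormalised:
#' posterior predictive comparisons only ever contrast KF values computed
#' on the same tip set, so the scale cancels.
#'
#' @param t1,t2 `phylo` objects with branch lengths over the same tip set.
#' @return Non-negative scalar.
#' @export
kf_distance <- function(t1, t2) {
  check_same_tips(t1, t2)
  if (is.null(t1$edge.length) || is.null(t2$edge.length))
    stop("Kuhner-Felsenstein distance requires branch lengths")
  phangorn::KF.dist(ape::unroot(t1), ape::unroot(t2), check.labels = TRUE)
}

#' Mean and standard deviation of tree likelihoods
#'
#' @param log A [trace_log()] with at least 2 post-burn-in rows.
#' @return A `likelihood_summary`: list with `mean`, `sd` (sample SD,
#'   n - 1 denominator) and `n`.
#' @export
likelihood_mean_sd <- function(log) {
  v <- trace_likelihoods(log)
  if (length(v) < 2L)
    stop("need >= 2 trace rows for a likelihood mean and SD; got ",
         length(v))
  structure(list(mean = mean(v), sd = stats::sd(v), n = length(v)),
            class = "likelihood_summary")
}

#' @export
print.likelihood_summary <- function(x, ...) {
  cat("Tree likelihoods: mean ", signif(x$mean, 6), ", sd ",
      signif(x$sd, 4), " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
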