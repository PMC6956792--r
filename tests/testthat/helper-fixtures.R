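# Shared fixture builders and independent brute-force oracles.

design_tree <- function(ne = 1e5) design_species_tree(ne)

two_per_species <- function(tree)
  stats::setNames(rep(2L, length(tree$tip.label)), tree$tip.label)

# A tiny hand-built SNP matrix: two species, rows are haploids.
toy_snps <- function(a_rows, b_rows) {
  m <- rbind(a_rows, b_rows)
  rownames(m) <- c(paste0("A_", seq_len(nrow(a_rows))),
                   paste0("B_", seq_len(nrow(b_rows))))
  snp_matrix(m, sample_map(rownames(m),
                           rep(c("A", "B"), c(nrow(a_rows), nrow(b_rows)))))
}

# ---- brute-force oracles (independent of the implementation path) ----

# tips below a node, by direct recursion over the edge matrix
tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, tips_below, tree = tree))
}

# canonical non-trivial bipartitions of the unrooted tree
brute_splits <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  vs <- tree$edge[tree$edge[, 2] > ntip, 2]
  unique(vapply(vs, function(v) {
    s <- sort(tips_below(tree, v))
    comp <- sort(setdiff(tree$tip.label, s))
    a <- paste(s, collapse = ",")
    b <- paste(comp, collapse = ",")
    if (a < b) a else b
  }, ""))
}

brute_rf <- function(t1, t2, normalized = TRUE) {
  s1 <- brute_splits(t1)
  s2 <- brute_splits(t2)
  d <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  if (normalized) d / (2 * (length(t1$tip.label) - 3)) else d
}

# Hudson F_ST as 1 - Hw/Hb by enumerating every within/between allele pair
brute_hudson <- function(m, rows1, rows2) {
  num <- den <- 0
  mismatch_within <- function(x) {
    cnt <- 0; tot <- 0
    for (i in seq_along(x)) for (j in seq_along(x)) if (i < j) {
      tot <- tot + 1; cnt <- cnt + (x[i] != x[j])
    }
    cnt / tot
  }
  for (l in seq_len(ncol(m))) {
    a <- m[rows1, l]; b <- m[rows2, l]
    hb <- 0; n <- 0
    for (i in seq_along(a)) for (j in seq_along(b)) {
      n <- n + 1; hb <- hb + (a[i] != b[j])
    }
    hb <- hb / n
    hw <- (mismatch_within(a) + mismatch_within(b)) / 2
    num <- num + (hb - hw)
    den <- den + hb
  }
  num / den
}

# MCC by an independent route: Pearson correlation of the reconstructed
# truth/call label vectors
cor_mcc <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp + fn), rep(0, tn + fp))
  call <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  suppressWarnings(stats::cor(truth, call))
}
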