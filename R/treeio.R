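#' Parse a single Newick species tree
#'
#' Reads one rooted Newick statement into an [ape::phylo] object and
#' validates it as a species tree: binary, unique non-empty tip labels,
#' non-negative branch lengths.
#'
#' @param text A single Newick string ending in `";"`.
#' @return An object of class `phylo`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
#' is_ultrametric(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("malformed Newick: unmatched ')' at character ", i)
    }
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at character ",
         length(chars))
  if (!endsWith(text, ";"))
    stop("malformed Newick: missing terminal ';' at character ",
         nchar(text) + 1L)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || inherits(tr, "multiPhylo"))
    stop("malformed Newick: could not parse a single tree from the string")
  validate_species_tree(tr)
  tr
}

#' Write a species tree as Newick
#'
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths; the default
#'   preserves lengths through a parse/write round trip to well below 1e-9.
#' @return A Newick string ending in `";"`.
#' @export
write_newick <- function(tree, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, digits = digits)
}

# Species-tree invariants shared by all readers.
validate_species_tree <- function(tree) {
  tips <- tree$tip.label
  if (any(!nzchar(tips)) || anyNA(tips))
    stop("invalid species tree: empty tip label")
  if (anyDuplicated(tips))
    stop("invalid species tree: duplicated tip label '",
         tips[duplicated(tips)][1L], "'")
  if (length(tips) >= 3L && !ape::is.binary(tree))
    stop("invalid species tree: not fully bifurcating")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("invalid species tree: negative branch length")
  invisible(tree)
}

#' Test whether a tree is ultrametric
#'
#' All root-to-tip path lengths equal within `tol` (absolute, in the tree's
#' branch-length unit).
#'
#' @param tree A `phylo` object with branch lengths.
#' @param tol Absolute tolerance on root-to-tip depth differences.
#' @return Logical scalar.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  max(depths) - min(depths) <= tol
}

#' Read a posterior set of species trees
#'
#' Reads a posterior distribution of species trees from either a plain
#' Newick file (one tree per line) or a NEXUS trees block (translate tables
#' are resolved), discards burn-in, and checks that all trees share one tip
#' set.  Fewer than 100 retained trees triggers a warning: the posterior
#' predictive machinery needs a reasonably rich posterior sample.
#'
#' @param path Path to the tree file.
#' @param format `"auto"` (sniff for `#NEXUS`), `"newick-lines"` or
#'   `"nexus-trees"`.
#' @param burnin_fraction Fraction in `[0, 1)`; the first
#'   `ceiling(burnin_fraction * N)` trees are discarded.
#' @return A `multiPhylo` object with a `"source"` attribute.
#' @export
read_tree_set <- function(path,
                          format = c("auto", "newick-lines", "nexus-trees"),
                          burnin_fraction = 0) {
  format <- match.arg(format)
  stopifnot(file.exists(path),
            is.numeric(burnin_fraction), length(burnin_fraction) == 1L,
            burnin_fraction >= 0, burnin_fraction < 1)
  if (format == "auto") {
    first <- toupper(trimws(readLines(path, n = 1L, warn = FALSE)))
    format <- if (startsWith(first, "#NEXUS")) "nexus-trees" else "newick-lines"
  }
  trees <- if (format == "nexus-trees") ape::read.nexus(path)
           else ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  n <- length(trees)
  if (n < 1L) stop("no trees found in '", path, "'")
  drop <- ceiling(burnin_fraction * n)
  if (drop > 0L) trees <- trees[-seq_len(drop)]
  as_posterior_trees(trees, source = path)
}

# Validate a multiPhylo as a posterior tree set: shared tip sets, each tree
# a valid species tree.  Warns below the recommended minimum of 100 trees.
as_posterior_trees <- function(trees, source = "<memory>") {
  if (inherits(trees, "phylo")) trees <- c(trees)
  stopifnot(inherits(trees, "multiPhylo"), length(trees) >= 1L)
  ref <- sort(trees[[1L]]$tip.label)
  for (i in seq_along(trees)) {
    validate_species_tree(trees[[i]])
    if (!identical(sort(trees[[i]]$tip.label), ref))
      stop("posterior tree ", i, " has a different tip set than tree 1")
  }
  if (length(trees) < 100L)
    warning("only ", length(trees), " trees in the posterior set; ",
            "at least 100 are recommended for posterior predictive checks")
  attr(trees, "source") <- source
  trees
}

#' Read a BEAST/SNAPP-style trace log
#'
#' Tab-delimited table with a header row; lines starting with `#` are
#' ignored.  Burn-in rows are removed with the same ceiling rule as
#' [read_tree_set()].
#'
#' @param path Path to the log file.
#' @param likelihood_column Name of the column holding tree likelihoods.
#' @param burnin_fraction Fraction in `[0, 1)` of leading rows to discard.
#' @return A `trace_log` object: list with `data` (data.frame) and
#'   `likelihood_column`.
#' @export
read_trace_log <- function(path, likelihood_column = "likelihood",
                           burnin_fraction = 0) {
  stopifnot(file.exists(path),
            burnin_fraction >= 0, burnin_fraction < 1)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  drop <- ceiling(burnin_fraction * nrow(df))
  if (drop > 0L) df <- df[-seq_len(drop), , drop = FALSE]
  trace_log(df, likelihood_column)
}

#' Construct a trace log object
#'
#' @param data A data.frame of numeric MCMC trace columns, one row per
#'   sample.
#' @param likelihood_column Column name holding tree likelihoods.
#' @return A `trace_log` object.
#' @export
trace_log <- function(data, likelihood_column = "likelihood") {
  stopifnot(is.data.frame(data))
  if (!likelihood_column %in% names(data))
    stop("likelihood column '", likelihood_column,
         "' not found; available columns: ",
         paste(names(data), collapse = ", "))
  if (!is.numeric(data[[likelihood_column]]))
    stop("likelihood column '", likelihood_column, "' is not numeric")
  structure(list(data = data, likelihood_column = likelihood_column),
            class = "trace_log")
}

# Likelihood series of a trace log.
trace_likelihoods <- function(log) {
  stopifnot(inherits(log, "trace_log"))
  log$data[[log$likelihood_column]]
}

#' @export
print.trace_log <- function(x, ...) {
  cat("Trace log:", nrow(x$data), "samples,",
      ncol(x$data), "columns (likelihood column: '",
      x$likelihood_column, "')\n", sep = "")
  invisible(x)
}

#' Sample species trees from a posterior set
#'
#' `mode = "uniform"` takes an evenly spaced stride over the retained
#' posterior, indices `round(i * (N - 1) / (n - 1)) + 1` for
#' `i = 0, ..., n - 1` (both endpoints included); `mode = "random"` draws
#' `n` indices without replacement.  Output order follows index order.
#'
#' @param trees A `multiPhylo` posterior set.
#' @param n Number of trees to sample, `1 <= n <= length(trees)`.
#' @param mode `"uniform"` or `"random"`.
#' @param seed Optional integer seed (used only for `mode = "random"`).
#' @return A `multiPhylo` of the sampled trees, with attribute
#'   `"indices"` giving the 1-based source positions.
#' @export
sample_posterior_trees <- function(trees, n, mode = c("uniform", "random"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  if (inherits(trees, "phylo")) trees <- c(trees)
  N <- length(trees)
  if (n < 1L || n > N)
    stop("cannot sample ", n, " trees from a posterior of ", N)
  idx <- if (mode == "uniform") {
    if (n == 1L) N else round((0:(n - 1L)) * (N - 1) / (n - 1)) + 1L
  } else {
    sort(with_seed(seed, sample.int(N, n, replace = FALSE)))
  }
  out <- trees[idx]
  attr(out, "indices") <- as.integer(idx)
  attr(out, "source") <- attr(trees, "source")
  out
}

#' Construct a sample map
#'
#' Assigns each sampled individual to a species.  At least two species,
#' every species non-empty, every individual assigned exactly once.
#'
#' @param individual Character vector of unique individual IDs.
#' @param species Character vector (same length) of species labels.
#' @return A data.frame with columns `individual` and `species`, class
#'   `sample_map`.
#' @export
sample_map <- function(individual, species) {
  stopifnot(length(individual) == length(species), length(individual) >= 2L)
  individual <- as.character(individual)
  species <- as.character(species)
  if (anyDuplicated(individual))
    stop("sample map: individual '",
         individual[duplicated(individual)][1L], "' assigned more than once")
  if (length(unique(species)) < 2L)
    stop("sample map must contain at least 2 species")
  structure(data.frame(individual = individual, species = species,
                       stringsAsFactors = FALSE),
            class = c("sample_map", "data.frame"))
}
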