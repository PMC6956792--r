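---
title: "Checking the multispecies coalescent with posterior predictive simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Checking the multispecies coalescent with posterior predictive simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snappcheck)
```

## The problem

Bayesian species-tree inference from biallelic SNPs (SNAPP and relatives)
assumes the multispecies coalescent model (MSCM): all discordance between
gene genealogies and the species tree is attributed to incomplete lineage
sorting. Real radiations frequently violate that assumption — most
commonly through gene flow between incompletely isolated lineages — and
fitting the MSCM to such data can bias both topology and divergence-time
estimates without any warning from the inference itself.

snappcheck implements posterior predictive model checking for this
setting. Species trees drawn from the posterior parameterise a
structured-coalescent simulator; replicate SNP datasets simulated under
the pure MSCM form the posterior predictive distribution; and summary
statistics compare either the empirical data (data-based checks) or
re-analyses of the replicates (inference-based checks) with that
distribution. If the observed data are unlike data the fitted model
generates, the model is violated for these data.

## Summary statistics and their evaluation

Seven statistics are implemented, following the two-stage design:

* **FSTA, FSTR** — mean and range of pairwise Hudson F~ST~ across all
  species pairs. Gene flow shares alleles between the connected pair and
  depresses their F~ST~, shifting the mean down and stretching the range.
  Both use the two-tailed posterior predictive p-value: count predictive
  datasets whose statistic falls above and below the empirical value,
  double the smaller count, divide by the number of predictive datasets
  (capped at 1; exact ties fall in neither tail, and an all-tied
  comparison returns 1 because identical distributions are no evidence of
  misfit). p < α flags a violation (α defaults to 0.05).
* **PFST** — the per-pair F~ST~ outlier test: for each species pair, the
  mean difference between empirical and predictive F~ST~; a pair outside
  the Tukey fences (1.5 × IQR beyond the hinges, exactly
  `grDevices::boxplot.stats`) flags a violation and names candidate
  gene-exchanging lineages.
* **RF, KF** — Robinson–Foulds (topology only, normalised by its maximum
  2(n−3) so it lies in [0, 1]) and Kuhner–Felsenstein (branch-score)
  distances between trees inferred from predictive datasets and the
  posterior trees they were simulated from. A null distribution is built
  from 1,000 random distinct pairs of posterior trees; predictive-to-source
  comparisons (100 per predictive distribution, pooled across
  distributions) exceeding the null's 95% quantile are counted, and a
  pooled fraction above α flags a violation. The branch-score distance is
  left unnormalised: it is only ever compared with other KF values on the
  same tip set, so its scale cancels; we found no defensible rescaling
  that maps it to [0, 1] in general.
* **MLM, MLSD** — mean and standard deviation of tree likelihoods from
  the trace logs, evaluated like FSTA/FSTR. Data violating the MSCM are
  harder to fit, typically inflating the spread of sampled likelihoods;
  MLSD is the best-performing statistic in simulation testing.

## The simulator

The package carries its own structured-coalescent simulator rather than
shelling out to an external program. Backward in time, each species-tree
branch is a population: with k lineages present, any pair coalesces at
rate 1/(2N~e~) per generation (N~e~ diploid, constant per branch, scalar
by default); daughter populations merge at each speciation node; waiting
times are exponential with rate-sum competition among all events.

SNPs follow a one-mutation-per-locus convention: each locus is an
independent genealogy on which a single mutation is dropped on an edge
chosen in proportion to edge length. Because no edge above the root
exists, every emitted locus is polymorphic by construction — matching the
fixed SNP counts of typical SNAPP datasets. The recorded mutation rate is
pass-through metadata and does not alter genotypes. Per-locus random
streams are L'Ecuyer-CMRG substreams derived from the master seed by
counter, so locus i is reproducible independently of how many loci are
requested.

The MSCM+m extension models secondary contact: symmetric gene flow
between one pair of extant species at m migrants per generation, active
from `start_time` generations ago to the present. The backward
per-lineage migration rate is m/(2N~e~) (m counted in gene copies); the
choice of a symmetric, gene-copy parameterisation is this package's
convention, documented here because published descriptions of comparable
pipelines do not pin it down. Migration windows are validated against the
pair's divergence time and close automatically at the first event that
removes either species.

The simulator was verified two ways: closed-form coalescent expectations
(E[TMRCA] = 2N~e~ for two lineages; E[total length] = 4N~e~(1 + 1/2) for
three) at 10,000 replicates, and an independent-implementation check in
which the mean Hudson F~ST~ of a two-population secondary-contact model
was compared against the same quantity computed with msprime under
identical parameters; the frozen reference value and its Monte-Carlo
error live in the test suite.

## Hudson F~ST~

Pairwise F~ST~ uses Hudson's estimator with per-locus components
N = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1) and
D = p₁(1−p₂) + p₂(1−p₁), combined across loci as a ratio of sums
(ΣN/ΣD), which is robust to unequal and small sample sizes. N/D equals
1 − H~w~/H~b~, one minus the within/between heterozygosity ratio, which
is the form the brute-force oracle in the tests enumerates. Loci
monomorphic within a pair contribute D = 0 and drop out; negative values
are reported as computed — clamping at zero would bias the posterior
predictive comparison. The per-pair ratio-of-sums is a deliberate,
documented reading of "F~ST~ across all loci"; a per-locus-averaged
variant would weight rare-allele loci differently.

## The synthetic posterior generator

Posterior predictive checking brackets an external inference program: it
consumes a posterior (trees + trace) and, for inference-based statistics,
re-analyses of the predictive datasets. To test the machinery end to end
without that program, `generate_synthetic_posterior()` emulates a
posterior: each sample is a centre tree, perturbed by one random
nearest-neighbour interchange with probability `topology_jitter`
(root-adjacent exchanges are excluded — they do not change the unrooted
topology), with every branch length multiplied by independent mean-one
lognormal noise of coefficient of variation `length_jitter_cv`; trace
likelihoods are i.i.d. normal.

What this emulates: posterior spread around a point estimate, topological
uncertainty, and trace variability. What it does not: posterior
correlation structure between topology and branch lengths, MCMC
autocorrelation, and — critically — the systematic distortion a model
violation induces in an inferred posterior (a real analysis of gene-flow
data returns a *biased* tree, not a noisy correct one). Passing
end-to-end tests on synthetic posteriors therefore demonstrates that the
machinery is correct and calibrated, not that any statistic will detect
violations through a real inference; the likelihood-based statistics in
particular can only be exercised against stipulated trace distributions
here.

Edge-length jitter makes sampled trees slightly non-ultrametric, as real
posterior samples are once converted to generations. `build_demography()`
therefore derives node ages by maximum root-to-tip descent — exact on
ultrametric trees, a mild normalisation otherwise — instead of rejecting
such trees.

## The evaluation harness

`run_simulation_study()` reproduces the logic of the simulation-testing
design: replicates are simulated under MSCM and under MSCM+m (random
species pair, m ~ U(0.5, 5) migrants/generation, contact from 2.5N
generations ago), checks are run, and violation calls are tabulated into
one confusion matrix per statistic with the Matthews correlation
coefficient (MCC) and the fraction of correct classifications. A
violation call on a gene-flow replicate is a true positive. MCC returns 0
when any margin of the confusion matrix is empty — the convention needed
for degenerate always-call or never-call classifiers. `gene_flow_trend()`
exposes the per-replicate (m, p) pairs with their Spearman correlation.

The full published-scale design (100 replicates per model, 2,000 SNPs,
six species, N~e~ = 100K, symmetric topology with splits at 5N/10N/20N
generations, each replicate re-analysed with an external Bayesian run)
is out of reach without that external program; the harness defaults are
deliberately reduced (10 replicates per model, 200 SNPs, 20-tree
synthetic posteriors) and the design tree is available as
`design_species_tree()`. The test suite runs the calibration experiment
at 50 replicates × 100 SNPs × 40 predictive datasets, sizes chosen so
that the two-tailed p-value has enough resolution (with 40 predictive
draws, P(p < 0.05) under the null is 2/41 ≈ 0.049).

## Numerical and design choices

* **Burn-in** is exposed as a fraction (default 0) on both tree and
  trace readers, discarding the first ⌈fraction × N⌉ rows; published
  pipelines assume pre-processed input, but raw logs are common.
* **Uniform posterior sampling** uses the stride
  round(i·(N−1)/(n−1)), i = 0…n−1, including both endpoints; a single
  requested tree returns the last retained sample. Random sampling is
  without replacement.
* **Null-distribution pairs** are drawn with replacement over pairs, the
  two members forced distinct; the tree-distance p-value pools all
  predictive-to-source comparisons into one fraction rather than
  averaging per-dataset p-values (the pooled form uses every comparison
  at equal weight and is the natural reading of "dividing by the total
  number of comparisons").
* **Ploidy**: "kN generations" is read with diploid N~e~ (pairwise
  coalescence rate 1/(2N~e~)); "two individuals per species" is
  implemented as two haploid sequences per species by default, mirroring
  the binary SNAPP encoding, with `as_diploid()` providing a 0/1/2
  dosage view.
* **Degenerate inputs**: posteriors under 100 trees warn; species with
  fewer than two haploids are rejected for F~ST~; pairs with no
  informative loci are NA and excluded with a warning; a trace with
  fewer than two rows cannot yield an SD and errors.
* **Determinism**: every stochastic entry point takes a seed; checks and
  studies are reproducible bit-for-bit given (inputs, seed).

## Limitations

Within-locus recombination, multiallelic sites, linked loci, selection
and per-branch population-size variation in the scenario drawer are not
modelled. The SNAPP XML dialect is a minimal round-trippable subset
(data, taxon sets, recycled chain/prior settings), not a full BEAST2
template. Inference-based checks require the user to supply re-analyses
of the predictive datasets (or synthetic stand-ins); the package does
not launch external inference runs.
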