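---
title: "Gene-based quantitative trait association with genotype trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based quantitative trait association with genotype trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genotree)
```

## The problem

Rare variants that are individually undetectable can jointly explain a large
share of a quantitative trait's genetic variance at a gene. genotree tests
genes, not single sites: it collapses a gene's diploid genotypes into
*binary multilocus genotypes* (BMGs), clusters them on a *lexical genotype
tree*, and asks whether some cluster of carriers has an unusual trait mean.
The tree makes the search over carrier subsets both fast and interpretable —
the maximising node set names the variant combinations driving the signal —
and because BMGs are carrier indicators, no haplotype phasing is required
(rare variants are almost never carried in two copies, and their phase is
the least certain).

## The model and the statistic

**Recoding.** At each site of a gene an individual is coded 0 if homozygous
for the common allele and 1 otherwise. By default the reference allele is
taken as common (`polarize = FALSE`); optionally the sample-major allele is
used, with ties keeping the reference. Missing genotypes default to 0
("as common", conservative toward the null) with a per-gene count reported;
a strict mode refuses them.

**Tree construction.** All individuals start at the root. Sites are
processed one at a time (genomic order by default; carrier-frequency orders
are available): whenever the individuals at a current leaf differ at the
site, the leaf splits — 0-carriers to one child, 1-carriers to the other.
Leaves end up in one-to-one correspondence with the distinct observed BMGs,
and two BMGs separate exactly at their first differing site, so genotypes
one mutation apart always cluster. Internal nodes carry partial BMGs
(patterns with `#` where members differ); patterns are derived lazily from
member sets so memory stays linear in individuals.

**Node score.** At node $i$ with $n_i$ members,
$$z_i = \sqrt{n_i}\,\frac{\bar x_i - \bar x}{s},$$
with $\bar x$ and $s$ the sample mean and standard deviation (n−1
denominator) of the trait over all individuals, computed once: they are
invariant under trait relabelling, so permutation replicates reuse them.
The per-node score is $f(z_i)$; the default $f(z) = z^2$ is two-sided and
monotone in $|z|$, with $|z|$ and $\max(z,0)^2$ selectable.

**Gene statistic.** $S_k$ is the maximum of $\sum f(z_i)$ over sets of at
most $k$ pairwise *disjoint* nodes — no node an ancestor of another, i.e.
an antichain. A post-order dynamic program computes all of $S_1 \le S_2 \le
\dots \le S_k$ in one pass in $O(\text{nodes} \times k^2)$; empty selections
are allowed, so negative scores (possible under non-default $f$) are never
forced in and the sequence is monotone. The default budget is $k = 10$;
power summaries usually report $S_1$ and $S_5$. An exhaustive antichain
enumeration (`brute_force_disjoint`) serves as an independent oracle in the
tests and agrees exactly with the dynamic program on every random instance
tried.

**Significance.** The null distribution of $S_k$ is not available in closed
form, and samples drawn from different populations make a plain permutation
invalid: trait means differ between populations, so exchanging labels across
populations manufactures signal. genotree therefore randomises trait labels
*within* populations, preserving each population's trait multiset (hence
mean and sd) exactly in every replicate. p-values use the add-one estimator
$p_j = (1 + \#\{S_j^* \ge S_j\})/(n_{\mathrm{reps}}+1)$, never zero, minimum
$1/(n_{\mathrm{reps}}+1)$. The estimator the original description of the
method used is not stated; the add-one form is the standard valid choice.
The replicate loop is compiled (Rcpp): each replicate shuffles within
strata, re-accumulates node sums bottom-up, and reruns the dynamic program.
The observed statistic is computed by the same compiled path so permutation
ties compare exactly; a $10^{-12}$ relative slack absorbs float reordering.
Replicates compose in-place Fisher–Yates shuffles; uniform increments on the
permutation group make the successive states independent uniform draws.

In a genome scan each gene's permutation stream is seeded by a deterministic
hash of the master seed and the gene label, so scans are bit-identical
regardless of gene order and trivially parallelisable.

## Phenotype preparation

Structure- and artefact-driven confounding is handled upstream of the test,
by replacing the raw trait with a *derived phenotype*: the standardized
residuals of a linear model chosen by backwards stepwise selection under
BIC. Starting from the full model over the offered candidates (Age, Sex,
Smoke, and optionally the first $N$ principal-component loadings of the
allele-count matrix; `--pcs N`, default 6 components read as components
1–6), the term whose removal most decreases BIC is dropped until no removal
decreases it; ties drop the smallest-|t| term, and the greedy criterion
makes the result independent of candidate order. A selected model can be
refitted to replicate data sets without re-selection (`refit_selected`).

Why PC loadings: per-individual heterozygosity (fraction of heterozygous
sites) can correlate with a trait — in sequencing data plausibly through
coverage differences, since higher-coverage samples have more variants
called — and then *every* gene's carrier nodes are slightly trait-shifted,
inflating the scan even under within-population permutation. A
heterozygosity axis of this kind dominates leading principal components, so
residualizing on PC loadings removes it. PCA is computed with `prcomp` on
the column-centred allele counts (site-mean imputation for missing entries)
with component signs fixed deterministically.

## The synthetic-data generator

No public data set accompanies the package, so calibration and power claims
rest on a generator that emulates a multi-population mini-exome panel:

* **Scale defaults.** 7 populations of 100 individuals and 7 sites per gene,
  matching the order of magnitude of a 697-individual, 22,487-site,
  3,205-gene panel.
* **Allele frequencies.** Ancestral frequencies from Beta(0.2, 1.8)
  (rare-skewed, clipped to [0.001, 0.5]); population frequencies from the
  Balding–Nichols construction with divergence $F$ (default 0.1,
  continental-scale). $\hat F_{st}$ rises monotonically with configured $F$
  in the tests.
* **Genotypes.** Hardy–Weinberg draws per population, optionally tilted per
  individual: heterozygote probability is multiplied by
  $w_i = e^{h_i}$, $h_i \sim N(0, \texttt{het\_effect\_sd})$, renormalised.
  This creates a genuine genome-wide heterozygosity axis of the
  coverage-artefact kind discussed above; `het_effect_sd = 0.8` is used in
  the confound study, giving heterozygosity variation large enough to
  dominate a leading PC.
* **Trait.** Sum of a population mean shift, covariate effects
  (Age 0.02/yr around a population-specific mean age, Smoke 0.3), causal
  carrier effects, an optional confound term
  $\gamma \times$ standardized genome-wide heterozygosity, and N(0, 1)
  noise. Causal genes use carrier indicators (matching what the test
  collapses to), effects spread over several variants drawn from a
  carrier-frequency window (0.02–0.2), topped up with the most polymorphic
  sites when the window is short; fully monomorphic causal genes are redrawn
  (bounded retries).

What the generator does **not** emulate: linkage disequilibrium beyond the
exchangeable-sites model, realistic site-frequency spectra per population,
sequencing-read-level error, relatedness, and non-Gaussian traits. Passing
calibration here shows the machinery is correct under the stated model, not
that real exome panels carry no further structure.

## Reference studies and their problem sizes

The packaged experiments (`calibration_experiment`, `power_experiment`,
`confound_experiment`, `bic_recovery_experiment`) fix one set of study
conditions — two populations of 100, a 1-noise-sd trait mean shift between
them, $F = 0.1$, 7 sites per gene — and these sizes, chosen to make the
studies informative yet quick on a single core:

* calibration: 1,000 null genes, 999 permutations, $\alpha = 0.05$ on $S_5$;
  the stratified scan should land in the three-sigma binomial band around
  0.05 while the unstratified scan on the same data inflates well beyond it;
* power: 200 genes with 20 causal (4 variants each at $\beta = 0.5$,
  a carrier effect of roughly half a trait sd);
* confound: 1,000 null genes with `het_effect_sd = 0.8` and
  $\gamma = 0.25$. $\gamma = 0.25$ places the planted trait–heterozygosity
  coupling near 0.2; the *realized marginal* correlation varies by seed
  (typically 0.2–0.3) because the populations also differ in expected
  heterozygosity under Balding–Nichols, adding a between-population
  covariance term. The inflation that matters for the test is the
  within-population part, which the residualization removes;
* model recovery: 100 replicates of $n = 500$ with a planted Age effect
  ($\beta = 2$/yr, noise sd 5).

`scripts/acceptance.R` reruns all of these from scratch and writes the
resulting rates as JSON.

## Numerical and design notes

* A node containing the whole sample is set to $z = 0$ exactly rather than
  within float noise.
* The transformed-score sum under the default $f(z)=z^2$ is non-negative,
  and $S_j = 0$ iff every node has $z = 0$.
* Branch convention is fixed (child0 = 0-carriers); display order in
  figures is presentational.
* Node ids are assigned in construction order, so a child's id always
  exceeds its parent's; post-order traversal is just decreasing id order,
  which both the R and compiled scorers exploit.
* Antichain tie-breaking prefers smaller sets, then the lexicographically
  smallest id sequence — deterministic reports.
* `bonferroni_threshold` is exact division; with 3,205 genes at
  $\alpha = 0.05$ that is $1.56\times10^{-5}$.
* Degenerate inputs: constant traits are refused; genes with no polymorphic
  recoded site are flagged and reported with $S \equiv 0$, $p \equiv 1$;
  singleton permutation strata are fixed points and are counted in a
  message.

## Worked example

The packaged example data — 100 individuals at a four-site gene, six
distinct codes — reproduce the canonical small tree:

```{r example}
g <- example_genotype_matrix()
b <- recode_to_bmg(g, "exampleGene")
t <- build_tree(b)
t
leaves <- which(is.na(t$child0))
sort(setNames(lengths(t$members[leaves]), node_patterns(t)[leaves]),
     decreasing = TRUE)
```

A scan of a small simulated data set:

```{r scan}
cfg <- simulation_config(n_populations = 2, n_per_population = 50,
                         n_genes = 10, sites_per_gene = 7,
                         n_causal_genes = 2, seed = 7)
d <- simulate_dataset(cfg)
scan <- scan_genes(d$genotypes, d$phenotypes, trait = "Q",
                   k = 5, n_reps = 499, seed = 7)
scan[, c("gene", "n_leaves", "S_1", "S_5", "p_1", "p_5")]
d$truth$causal_genes
```

## Limitations

* Partial statistics must depend only on a node's own members; covariate
  adjustment therefore happens upstream (derived phenotypes), not inside
  the node score.
* Significance is reported per $S_j$ with no correction across the $j$
  budgets; report one pre-chosen budget or account for the multiplicity.
* The lexical tree depends on the site order; the default is genomic
  position, and alternative orders explore, not correct, that dependence.
* Case-control partial statistics and family designs are out of scope.
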