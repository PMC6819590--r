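---
title: "Measuring the genetic diversity held by merged breeding lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the genetic diversity held by merged breeding lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpdiv)
```

## The problem

When commercial breeding lines are merged, the consolidated population may
or may not retain the genetic variation that the parent lines held
separately. Gene banks face the complementary question: how much diversity
does each cryopreserved line add to what is already conserved? `snpdiv`
answers both questions from SNP genotypes alone, for panels of the kind
produced by livestock genotyping arrays: a few dozen to a few hundred
individuals per line, tens of thousands of biallelic markers, and a line
label for every animal.

## Kinship from markers

All diversity quantities rest on the genomic relationship matrix in the
Yang et al. form. With dosages $x_{ik} \in \{0,1,2\}$ and pooled allele
frequencies $p_k$,

$$G_{ij} = \frac{1}{m}\sum_k \frac{(x_{ik}-2p_k)(x_{jk}-2p_k)}{2p_k(1-p_k)},
\qquad
G_{ii} = 1 + \frac{1}{m}\sum_k
  \frac{x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2}{2p_k(1-p_k)}.$$

Two choices matter and are deliberate:

* **Pooled frequencies.** $p_k$ is estimated once from all lines together.
  Centring every line on the same reference is what makes between-line
  relationships negative for lines on opposite sides of the pooled mean;
  per-line frequencies would wipe out exactly the between-line structure
  the core-set method needs.
* **Kinship scale.** Kinship is half the relationship, $f = G/2$, so an
  outbred individual has self-kinship near $0.5$. Line averages include the
  self pairs: the within-line entry of the line-kinship matrix $M$ averages
  $f$ over all $n_\ell^2$ ordered pairs of a line including $i = j$. This
  means within-line values carry a $\approx 0.5/n_\ell$ self-kinship
  contribution, which is visible for small lines (at $n_\ell = 11$ it is
  about $0.045$) and is one reason within-line kinship is not a pure drift
  read-out.

## The core set

A "core set" is a hypothetical mixture of lines with weights
$c \ge 0,\ \sum_\ell c_\ell = 1$, chosen to minimise mean kinship and hence
maximise conserved diversity

$$g_{div} = 1 - c^\top M c .$$

The stationary solution on the sum-to-one plane is the closed form
$c_{max} = M^{-1}\mathbf{1}/(\mathbf{1}^\top M^{-1}\mathbf{1})$, with
maximal diversity $1 - 1/(\mathbf{1}^\top M^{-1}\mathbf{1})$. The closed
form ignores the non-negativity of contributions, and on real matrices it
does go negative, so `solve_core_set()` adds an iterative projection by
default: remove the line with the most negative weight, re-solve the
reduced system, repeat until all remaining weights are non-negative.
Removed lines get contribution zero and are listed in the result; the
unconstrained solution is always reported alongside, because the two
disagreeing is itself diagnostic.

The *unique diversity* of line $\ell$ is the rise in the optimal mean
kinship when $\ell$ is barred from contributing — its irreplaceable share.
`unique_diversity()` re-solves the leave-one-out problem for every line;
by construction the unique diversity of a line equals the difference
between the leave-one-out and full-set optimal mean kinships, exactly.

Numerical choices: the linear system $Mx = \mathbf{1}$ is solved directly
rather than by forming $M^{-1}$; matrices with condition number above
$10^{12}$ are rejected with a pointer to line merging or ridging; a matrix
that is not positive definite triggers a warning that the stationary point
is not a maximum, but the computation proceeds, because diagnosing a
published or estimated matrix is a legitimate use.

## The shipped worked example

`landrace_kinship()` returns a published 7-line kinship matrix for Dutch
Landrace pig breeding lines (six former lines, CNF/DL/DN/FL/FZ/SB, plus
the current merged line TN), with within-line kinships on the diagonal and
between-line kinships off it, as printed to three decimals. It is the
package's standing worked example, and also a cautionary one: **the
printed matrix is internally inconsistent with the core-set results
published alongside it.** The matrix is indefinite (its smallest eigenvalue
is about $-0.05$, far beyond what three-decimal rounding could cause), and
uniform contributions already achieve $1 - c^\top M c \approx 1.005$,
above the published maximal diversity of $0.993$ — so no contribution
vector optimal for this matrix can reproduce the published optimum. The
published text also states a between-line kinship range that contradicts
two entries of its own table. `snpdiv` reports what the printed matrix
actually implies (stationary diversity $\approx 1.13$ unconstrained, or
$\approx 1.01$ with TN projected out) rather than adjusting inputs to
recover the published numbers; the acceptance suite records the
discrepancy openly. The same source reports a single-line diversity for TN
($0.894$) that is inconsistent with $1 - 0.051 = 0.949$ under the stated
definition, corroborating that the published numbers cannot all be
reconciled.

There is also a structural reason why a pooled-frequency GRM-derived $M$
cannot yield a diversity like $0.993$: the columns of a pooled-centred
relationship matrix sum to approximately zero, so the sample-weight vector
$w_\ell = n_\ell / n$ gives $w^\top M w \approx 0$ and the maximal
diversity on such a matrix sits at $\approx 1$ by construction (the
package's own simulations reproduce this). A published optimum of $0.993$
with strictly positive mean kinship $0.007$ therefore points to a kinship
matrix on a different scale (for example similarity-based kinships bounded
to $[0,1]$) than the one printed.

## Population structure

* **Fst.** `pairwise_fst()` implements the Weir–Cockerham (1984) moment
  estimator from per-locus variance components $a$ (among populations),
  $b$ (among individuals within populations) and $c$ (within individuals),
  using observed heterozygosity. The multi-locus estimate is the ratio of
  sums $\sum a / \sum(a+b+c)$ — standard practice, and much less biased
  than averaging per-locus ratios. Loci with $a+b+c=0$ are uninformative
  and skipped with a count. Negative per-locus and per-pair estimates are
  reported as computed; they are clipped to zero only when the matrix is
  used as a tree distance.
* **PCA.** `run_pca()` is the centred, unscaled singular value
  decomposition — the common default for genotype data, where scaling
  would up-weight rare alleles.
* **NJ tree.** `nj_tree()` builds the Saitou–Nei neighbor-joining tree
  (via `ape::nj()`); negative branch lengths, which NJ can produce on
  non-additive input, are clipped to zero with a warning. The default
  distance is the pairwise Fst matrix; `line_distance(..., "kinship")`
  offers $1 - $ between-line kinship as the alternative, since either is a
  defensible reading of "the distance matrix" in this literature.

## The outlier scan

The scan for selection signatures is deliberately *not* a reimplementation
of Bayesian Fst-outlier software. `locus_scan()` uses a transparent
permutation analog: per-locus Weir–Cockerham $\theta$ as the statistic, a
null built by permuting line labels, the add-one p-value
$p = (1 + \#\{\theta_{perm} \ge \theta_{obs}\})/(B+1)$, and
Benjamini–Hochberg q-values with outliers at $q \le 0.05$. Ties count
against the observed value, which is the conservative convention. Because
$\theta$ on dosage data is discrete and the same permutations are shared
across loci, null p-values are *super-uniform* (conservative) rather than
exactly uniform — the test suite checks $P(p \le \alpha) \le \alpha$ at
several $\alpha$, which is the property that matters for error control,
instead of a distributional uniformity test that discreteness would fail.
Outliers are annotated against gene intervals within 5 kb up- or
downstream (a 10 kb window), inclusive at both boundaries, with GFF3 read
1-based inclusive and BED converted from 0-based half-open.

## What the simulator emulates — and what it does not

`simulate_panel()` generates the structure the analyses assume, under the
Balding–Nichols model: an ancestral allele-frequency spectrum (uniform
minor-allele frequency, reflected about $0.5$), per-line frequencies drawn
$\mathrm{Beta}\!\left(p\frac{1-F}{F},(1-p)\frac{1-F}{F}\right)$ so that a
line's differentiation from the ancestor is $F$, Hardy–Weinberg genotypes,
and an admixed line whose individuals draw ancestry proportions from a
Dirichlet and mix the parent frequencies individually. Under this model
the Weir–Cockerham $\theta$ between two lines with drifts $F_1, F_2$ comes
out near $(F_1+F_2)/2$ (the estimator measures the among-population
variance share), which the suite verifies against a Monte-Carlo oracle
rather than a folk formula.

The default configuration (`default_sim_config()`) is the study design the
package accompanies: six parent lines of sizes 46, 49, 24, 11, 11 and 12
with drift coefficients 0.045, 0.04, 0.12, 0.07, 0.08 and 0.06 — chosen
once so pairwise Fst lands in the reported 0.02–0.10 band, with the
Dumeco N-line the most drifted — plus a 34-animal merged line with
Dirichlet mean echoing the reported admixture proportions (concentration
10, so individual ancestries visibly vary). Missingness is completely at
random at $5\times10^{-4}$ per call, which with 187 samples removes a
realistic share of SNPs under the 100%-call-rate rule; the default
48,000 SNPs then leave a post-QC panel in the low-40k range, matching the
scale of array data after QC. Real data differ in ways the simulator does
not model: linkage disequilibrium (every SNP is independent here),
ascertainment bias of array content, inbreeding within lines, selection,
and informative missingness. Passing tests therefore validate the
estimators and the pipeline logic, not those aspects of real panels.

## Quality control order

Filters run in a fixed order: samples with call rate not strictly above
0.90 are removed first; minor allele frequency (pooled across lines,
threshold 0.02) is computed on the survivors; then SNPs with any missing
call among the survivors are dropped. The order matters — a SNP missing
only in a discarded sample is retained — and the suite includes a panel
engineered so that swapping the order changes the outcome. MAF pooling is
configurable (`maf_pooled = FALSE` switches to a per-line criterion) but
pooled is the default, matching QC of one combined dataset. An
intensity-score filter stage is accepted as a flag and logged as skipped,
since dosage data carry no intensities.

## Problem sizes and reproducibility

Statistical checks in the test suite run at 20,000 simulated SNPs
(estimator calibration), 5,000 loci for scan null calibration across ten
seeds, 1,000 loci for scan power with 50 planted frequency shifts of 0.4,
and an end-to-end pipeline at the full 187-individual design with
10,000 SNPs — sizes at which Monte-Carlo error is comfortably inside the
asserted tolerances while the whole suite stays quick on one core. Every
stochastic step (simulation, permutations) is seeded explicitly;
`simulate_panel()` is bit-reproducible from its config seed.

## Known limitations

* The core-set machinery assumes a positive definite kinship matrix;
  indefinite inputs (possible with published, rounded, or
  pooled-frequency-centred matrices) yield stationary rather than optimal
  solutions, flagged by a warning.
* The scan's permutation null tests *no differentiation at any locus*
  between the pair of lines; genome-wide drift inflates per-locus
  $\theta$ everywhere, so on strongly drifted pairs the scan flags the
  tail of the drift distribution rather than selection per se. The
  published analyses this substitutes for model genome-wide structure
  explicitly; counts of outliers are therefore not comparable.
* No LD pruning, no imputation (deliberately: with complete-call-rate QC
  there is nothing to impute), no pedigree information.
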