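# snpdiv

Genetic diversity and population structure of SNP-genotyped breeding
lines — for animal breeders, gene-bank curators and population geneticists
who need to know how much diversity a set of related lines holds, which
line holds the irreplaceable share of it, and where in the genome the
lines have diverged.

The package covers the full workflow on biallelic SNP dosage panels
(individuals × SNPs, 0/1/2/NA, one line label per individual):

* **QC** — sample call rate (> 0.90), pooled minor allele frequency
  (≥ 0.02), SNP call rate (100%), in that order (`apply_qc()`).
* **Kinship** — Yang et al. genomic relationship matrix with pooled allele
  frequencies (`compute_grm()`); line-average kinship matrix *M* including
  self pairs, with kinship *f = G/2* (`aggregate_line_kinship()`).
* **Core set** (Eding's method) — the contribution vector maximising the
  conserved diversity *g*<sub>div</sub> = 1 − **c**′**Mc**, via the closed
  form **c**<sub>max</sub> = **M**⁻¹**1** / (**1**′**M**⁻¹**1**) plus an
  iterative non-negativity projection, and per-line *unique diversity* by
  leave-one-out re-solving (`solve_core_set()`, `unique_diversity()`).
* **Structure** — pairwise Weir–Cockerham Fst (ratio-of-sums over the
  *a*, *b*, *c* variance components), centred unscaled PCA, and a
  neighbor-joining tree of lines (`all_pairwise_fst()`, `run_pca()`,
  `nj_tree()`).
* **Selection signatures** — a permutation Fst-outlier scan with
  Benjamini–Hochberg FDR control and gene-window annotation
  (`locus_scan()`, `annotate_outliers()`); an explicitly simplified,
  transparent analog of model-based Bayesian outlier scans.
* **Simulation** — Balding–Nichols panels of drifted parent lines plus an
  admixed merged line with individual-varying ancestry
  (`simulate_panel()`), used throughout the test suite for
  parameter-recovery checks.

I/O: VCF (GT field) or dosage TSV in, TSV/JSON/Newick out;
`run_pipeline()` chains everything from one YAML config, and
`inst/scripts/snpdiv` exposes the same steps as shell subcommands.

## Worked example: seven Dutch Landrace lines

The package ships the published within-/between-line kinship matrix for
seven Dutch Landrace pig breeding lines (six former lines and the current
merged TN line):

```r
library(snpdiv)
M <- landrace_kinship()
solve_core_set(M)
#> Warning: kinship matrix is not positive definite: the stationary
#> contribution vector is not a diversity maximum
#> <core_set_result>
#>   diversity 1 - c'Mc = 1.0088 (mean kinship -0.0088)
#>   contributions (%):
#>   CNF    DL    DN    FL    FZ    SB    TN
#> 15.47  7.96 15.05 20.40 15.34 25.79  0.00
#>   zeroed by non-negativity projection: TN
```

The warning is the point of this example: the printed matrix is
indefinite, and the core-set output published next to it cannot be
reproduced from it (uniform contributions already exceed the published
maximum). The vignette (`vignettes/line-diversity.Rmd`) walks through the
diagnosis. On well-behaved matrices the same call returns the maximising
contributions; `unique_diversity(M)` adds each line's irreplaceable share.

A fully simulated analysis, from genotypes to results:

```r
cfg <- sim_config(
  n_snps = 20000,
  parent_lines = data.frame(name = c("A", "B"), size = c(30, 30),
                            drift_F = c(0.05, 0.10)),
  admixed_line = list(name = "X", size = 20, dirichlet_alpha = c(2, 2)),
  seed = 42)
panel <- apply_qc(simulate_panel(cfg))$panel
all_pairwise_fst(panel)
#> <fst_result> multi-locus Weir-Cockerham theta
#>        A      B      X
#> A 0.0000 0.0737 0.0143
#> B 0.0737 0.0000 0.0239
#> X 0.0143 0.0239 0.0000
```

The A–B estimate sits near the Balding–Nichols expectation
(F₁ + F₂)/2 ≈ 0.075, and the admixed line X is closer to both parents
than they are to each other. The full pipeline — QC through kinship, core
set, Fst, PCA, tree and scan — runs from one config:

```r
run_pipeline(system.file("extdata", "pipeline_example.yaml",
                         package = "snpdiv"), "results/landrace")
```

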