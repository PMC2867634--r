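# mixpart

Penalized normal-mixture partitioning of multi-locus genotypes for
quantitative phenotypes.

## What it is for

Candidate-gene association studies — CYP2D6 metabolizer genetics being the
canonical example — produce dozens of distinct multi-locus genotypes
(diplotypes such as `*1/*4`). The analyst needs two answers at once: *is*
the quantitative phenotype associated with genotype, and *how many*
phenotypically distinct groups do the genotypes form? `mixpart` answers
both with a single model: each genotype cell $g$ (all samples sharing a
genotype) is assigned a latent component $z_g$ of a $K$-component normal
mixture, and the penalized log-likelihood

$$
pl_M(K) = \sum_g \log \sum_{k=1}^{K} p_k \,\Pr(\mathbf y_g \mid \mu_k,
\sigma^2_k) + \sum_{k=1}^{K} \log p_k
$$

is maximized by a multi-start EM algorithm. The penalty
$\sum_k \log p_k$ removes the non-identifiability of the mixing
proportions under the null (it forces $p_k = 1/K$ when the likelihood is
flat), which is what makes a likelihood-ratio test for the number of
components workable. $K$ is chosen by a sequential LRT — (1 vs 2),
(2 vs 3), ... — with parametric-bootstrap p-values and a cumulative
(family-wise) error bound; the selected model's responsibilities give the
genotype partition.

The package also ships:

* an implementation of the **Restricted Partition Method** (RPM) comparator
  — Tukey–Kramer merging of mean-adjacent genotype groups plus a permutation
  $R^2$ test;
* a **two-locus epistasis simulator** (checkerboard and diagonal
  architectures; equal-variance, unequal-variance and gamma phenotypes);
* a **Monte Carlo harness** estimating power and exact true-partition
  recovery for both methods;
* a thin command line (`inst/cli/mixpart.R`) with `fit`, `rpm`, `simulate`
  and `evaluate` subcommands.

The EM fitter and the bootstrap inner loop are written in C++ on per-cell
sufficient statistics, so a full sequential test with hundreds of bootstrap
refits takes well under a second on a nine-cell dataset.

## Worked example

Simulate a checkerboard-epistasis dataset (nine two-locus genotype cells,
four baseline cells at mean 1, five elevated cells at mean 2, n = 500) and
run the full analysis:

```r
library(mixpart)
sim <- simulate_epistasis("checkerboard", mu = 1, situation = "equal",
                          n = 500, seed = 42)
res <- sequential_lrt(sim$data, alpha = 0.05, n_boot = 999, seed = 42)
res
#> sequential penalized-mixture LRT
#>  K1 K2    lambda n_boot p_value decision
#>   1  2 53.228883    999   0.001   reject
#>   2  3 -3.855343    999   1.000   accept
#> selected K = 2, cumulative p-value = 0.001 (alpha = 0.05)
#> mixture_params with 2 component(s):
#>   1: N(1.044, 0.9909; p = 0.4546)
#>   2: N(1.838, 1.171; p = 0.5454)
#>   cluster 1: AaBB, AABb, aaBb, Aabb
#>   cluster 2: AABB, aaBB, AaBb, AAbb, aabb
```

Reading the output: the first step rejects one component against two
(λ = 53.2, bootstrap p = 0.001), the second step cannot justify a third
component (its λ is negative — the penalty outweighs any likelihood gain —
so p = 1), and the procedure stops with K = 2 at a family-wise cost of
0.001. The hard partition splits the cells exactly along the generating
checkerboard (the four single-heterozygote cells against the rest), and the
component estimates sit close to the generating N(1, 1) and N(2, 1):

```r
recovered(res$assignment, sim$truth[sim$data$labels])
#> [1] TRUE
```

The RPM comparator on the same data also detects the association and here
lands on the same two groups:

```r
rpm_test(sim$data, n_perm = 999, hsd_alpha = 0.05, seed = 42)
#> RPM test: 2 group(s), R^2 = 0.1249, permutation p = 0.001 (999 permutations)
```

Real tables are read with
`read_cell_dataset("genotypes.tsv", transform = "log")` (columns
`sample_id`, `genotype_cell`, `phenotype`), and `run_analysis()` writes
TSV/JSON reports for both methods.

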