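---
title: "Methods: clustering-based multi-phenotype association in agnep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clustering-based multi-phenotype association in agnep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agnep)
```

## The model

For one genetic variant and d phenotypes over n individuals, `agnep` works
under the multivariate linear model

$$Y_{d \times n} = \alpha W + B X + E, \qquad
  E \sim MN_{d \times n}(0, V, I_n),$$

where $X = (x_1, \dots, x_n)$ holds minor-allele counts in $\{0,1,2\}$, $B$
is the vector of per-phenotype allele effects, $W$ is a matrix of ones, and
the residual matrix is matrix-normal with an arbitrary between-phenotype
covariance $V$ and independent individuals. Testing $B = 0$ jointly over
all d phenotypes wastes power when only a correlated subset responds to the
variant; testing each phenotype separately wastes the correlation
structure. The method therefore groups phenotypes first and tests a
low-dimensional summary of each group.

### Clustering and choosing K

Phenotypes are standardized (mean 0, SD 1 across individuals) and compared
by Euclidean distance. Agglomerative nesting starts from singletons and
repeatedly merges the closest pair of clusters under single linkage,
$d_{\min}(c_i, c_j) = \min_{p \in c_i, q \in c_j} d(p, q)$; complete and
average linkage are options. Equal-distance merges are broken by the
lexicographically smallest (min member index, max member index) pair, which
makes the hierarchy fully deterministic.

The cut K is chosen to maximize the mean silhouette coefficient over
$K = 2, \dots, d-1$. For sample $i$ in cluster $c_k$, $a(i)$ is the mean
distance to the other members of $c_k$ and $b(i)$ the smallest mean
distance to another cluster, and $s(i) = (b(i)-a(i))/\max(a(i), b(i))$.

**Singleton convention (a deliberate divergence between two functions).**
The printed definition sets $a(i) = 0$ when $|c_k| = 1$, which forces
$s(i) = 1$ for every singleton with $b(i) > 0$. `silhouette()` implements
that convention by default (`singleton = "unit"`). But *selecting* K by
maximizing the mean of that score is degenerate: peeling off singletons
always raises the mean, so the search would return $K = d-1$ on any data,
and the true group count could never be recovered. `select_k()` therefore
defaults to the standard convention $s(i) = 0$ for singletons
(`singleton = "zero"`, as in Rousseeuw's construction and every major
implementation), under which the simulated five-group design is recovered
in essentially every seed. Both functions expose both conventions.

Degenerate input (all pairwise distances zero) has no cluster structure:
`silhouette()` returns $s(i) = 0$ and `select_k()` refuses to choose.

### Representative phenotypes

Each cluster is standardized per phenotype, then reduced by one of:

* **mean** — elementwise average of member phenotypes (one row per cluster);
* **median** — elementwise median, even sizes averaging the two central
  order statistics;
* **pca** — principal components of the member phenotypes (individuals as
  observations, correlation scale because members are pre-standardized),
  keeping the smallest number of components whose cumulative
  explained-variance fraction *strictly exceeds* `cum_threshold`
  (default 0.85).

Component signs are arbitrary in theory; each component is flipped so its
largest-magnitude loading is positive, making outputs bit-reproducible.

### The association scan

For each variant, the r representatives are regressed on intercept +
allele count and the genotype term is tested with Wilks'
$\Lambda = |E|/|E+H|$. With a single tested regressor,
$F = \frac{1-\Lambda}{\Lambda}\cdot\frac{n-1-r}{r} \sim F(r,\, n-1-r)$
exactly, so no approximation error enters; the Pillai option reports
$V = 1-\Lambda$ with the identical p-value (the two statistics coincide as
tests when the hypothesis has one degree of freedom). The scan is
vectorized across variants through cross-products
($\Lambda_j = 1 - a_j^\top T^{-1} a_j / x_j^\top x_j$ with
$a_j = Y_c^\top x_{c,j}$), so a 10,000-variant scan is a handful of matrix
products. Monomorphic variants get p = 1 and a flag; individuals with a
missing call are dropped for that variant only; rank-deficient
representative sets are rejected naming the collinear rows.

The univariate baseline (`anova_scan`) is the 1-df regression F-test per
phenotype per variant (optionally genotype-as-factor, 2 df), plus a
per-variant minimum-p summary used **only** for ranking in power
comparisons — it is not a calibrated p-value. Covariates beyond the
intercept (population structure, kinship) are outside the model and are a
known limitation.

## The synthetic world

`make_design()` + `simulate_phenotypes()` implement an additive factor
model chosen because it produces the block/overlap correlation patterns of
the three benchmark designs by construction:

$$y_{ij} = \sum_{q:\, i \in S_{g(q)}} \beta_q x_{qj}
  + \sum_{g:\, i \in S_g} \lambda_{ig} f_{gj} + e_{ij},$$

with latent group factors $f_g \sim N(0,1)$ i.i.d. over individuals.
Genotypes are independent draws under Hardy–Weinberg equilibrium with MAF
uniform on [0.1, 0.5]. The three presets place d = 20 phenotypes in five
disjoint groups (simI), five overlapping groups (simII), or d = 100
phenotypes in eight overlapping groups (simIII); the benchmark scenarios
use 10 or 50 QTNs assigned round-robin so every group carries signal.

Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `loading` λ | 0.8 | within-group correlation λ²/(λ²+σ²) = 0.64, a strong but not degenerate block structure |
| `residual_sd` σ | 0.6 | makes the baseline variance of a one-group phenotype λ²+σ² = 1, so effects are on the SD scale |
| `qtn_variance_frac` | 0.005 | each QTN explains 0.5% of baseline phenotype variance, a typical weak-polygenic size at the full n = 5000 scale |
| `maf_range` | [0.1, 0.5] | the stated genotype regime |
| QTN→group map | round-robin | every group causal in both scenarios |
| `mixed_sign` | FALSE | TRUE alternates loading signs within groups to induce negative correlations |

Effect sizes are realized at simulation time as
$\beta_q = \sqrt{h\, v_0 / (2 p_q (1-p_q))}$ with $h$ =
`qtn_variance_frac` and $v_0$ the one-group baseline variance, so the
explained fraction is held constant across allele frequencies. Open
modeling questions resolved here: QTN effects act directly on the member
phenotypes of one group (not through the latent factor), and the unstated
simulator constants above are this package's choices, fixed once.

What the generator does **not** emulate: linkage disequilibrium (variants
are independent), population structure and kinship, non-normal residuals,
and missing data. A green test on this world therefore establishes
correctness of the algorithms and calibration under independence — not
robustness to confounding in real cohorts.

## Evaluation machinery

Power is rank-based: variants sorted by ascending p, empirical FDR at cut
depth t is (non-QTNs in top t)/t, power is (QTNs in top t)/(#QTNs), and the
curve reports the maximum power at empirical FDR ≤ f per grid value,
averaged over replicates. A QTN counts as found only at its own variant —
there is no window matching, because simulated variants are independent.
This definition is invariant to monotone transformations of the p-values.
Permutation thresholds shuffle individuals jointly across all
representative rows (preserving between-phenotype correlation under the
null), rerun the scan, and take the `ceiling(alpha * n_perm)`-th order
statistic of the genome-wide minimum p (default 10 permutations); an alpha
below 1/n_perm cannot be resolved and falls back to the most extreme
minimum with a warning. Replicate counts default to 100 for full studies
and 20 in the shipped benchmark/tests to stay inside CI budgets.

## Numerical and interface choices

* Distances are computed on standardized phenotypes by default (raw scale
  via `standardize = FALSE`); clustering should not be dominated by units.
* `select_k` breaks exact mean-silhouette ties toward the smaller K.
* Λ is clamped to (eps, 1] before the F transform; flagged (monomorphic)
  variants report p = 1 rather than NA so downstream counts are total.
* Genotype files are re-oriented to minor-allele counts on read (columns
  with frequency > 0.5 flipped and flagged); the optional MAF filter
  removes variants with MAF strictly below the cutoff (default 0.05).
* Phenotype input uses the complete-case rule: any individual missing any
  phenotype is dropped, with a logged count.
* Genotype/phenotype alignment is by individual-id intersection;
  unmatched ids are logged and dropped.
* Every pipeline output carries a seed + config-hash header; reruns with an
  equal manifest are byte-identical (the output directory is excluded from
  the hash so identical analyses into different directories match).

## Known limitations

* **The scaled-down power ordering is not guaranteed.** At the shipped
  benchmark scale (simI, n = 500, m = 1000, 10 QTNs, default 0.5% per-QTN
  variance) every method sits near the power floor (~0.01–0.03 at FDR
  0.05) because scaling n down tenfold without rescaling effects drops the
  per-variant noncentrality to ≈2.5; the AGNEP-vs-ANOVA ordering there is
  Monte-Carlo noise, and the corresponding acceptance test is expected to
  fail for some seeds. Measured in a noncentrality-preserving regime (5%
  per-QTN variance at n = 500), the minimum-p ANOVA baseline in fact
  slightly outperforms the PCA variant (≈0.92 vs ≈0.70 at FDR 0.05, with
  the mean-representative variant ≈0.90 and all-phenotype MANOVA ≈0.58).
  Two structural reasons: (i) rank-based FDR evaluation neutralizes the
  multiplicity penalty that usually handicaps min-p combining, and
  (ii) with within-group correlation 0.64 the 85% rule keeps 3 PCs per
  4-phenotype cluster, so two thirds of the tested dimensions are noise —
  while in an equicorrelated block the SNR-optimal linear combination
  $\Sigma^{-1}\mu$ is proportional to the group mean, capping the
  achievable multivariate gain. Simulator parameters were not adjusted
  after observing this; the measurement is reported as-is.
* No mixed-model correction: confounding by relatedness or structure in
  real data will inflate the scan.
* The univariate min-p summary is a ranking device only.
* Single-linkage chaining can merge loosely connected groups in data whose
  structure is weaker than the simulated blocks; complete/average linkage
  are available.
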