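---
title: "Entropy-based detection of gene-gene interactions with rigscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based detection of gene-gene interactions with rigscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rigscan)
```

## The problem

Complex diseases rarely trace back to single loci; joint effects of two or
more SNPs (epistasis) can carry association signal that single-marker tests
miss entirely. `rigscan` scores every combination of `k` SNPs in a
case-control panel by how much knowing the joint genotype reduces the
uncertainty about disease status, and calibrates those scores against a
permutation null so that combinations of different orders can be compared on
one scale and tested with family-wise error control.

## The statistic

For a combination `X` of `k` SNPs (a factor with `3^k` joint genotype
levels) and disease status `Y`, the package builds the `3^k x 2` contingency
table of joint genotype against case/control and computes, in bits,

* the phenotype entropy `H(Y) = -sum_j p_j log2 p_j`,
* the conditional entropy `H(Y|X) = sum_g p_g H(Y | X = g)`, where empty
  genotype rows contribute zero (the `0 log 0 = 0` convention), and
* the information gain `IG = H(Y) - H(Y|X)`, normalized to the **relative
  information gain** `R0 = IG / H(Y)` (the normalized mutual information).

`R0` lives in `[0, 1]`: it is 0 exactly when every genotype row shows the
same case proportion and 1 exactly when every non-empty row is
single-class. Because empty cells simply drop out, the statistic stays
well-defined for the sparse tables that high-order scans inevitably
produce. `2 n ln(2) IG` is identically the likelihood-ratio (G-squared)
independence statistic, which is asymptotically chi-square with `3^k - 1`
degrees of freedom -- `g_statistic()` reports it together with the count of
non-empty rows, since the asymptotics are unreliable for sparse tables.

### Why standardize

`R0` is monotone under refinement: adding a SNP to a combination can never
decrease it, whatever that SNP contributes. Raw values therefore inflate
mechanically with the interaction order and cannot be compared across
orders. The remedy is an order-specific permutation null: shuffle the
phenotype labels (genotypes fixed, margins preserved), rescan, and record
the **maximum** `R0` over all combinations of that order; repeating this
`n_perm` times gives an ensemble `M_1..M_n` with mean `mu` and unbiased
standard deviation `sigma`. The standardized score is

```
U_r = (R0 - mu) / sigma .
```

Standardization is affine, so within an order the `U_r` ranking is the `R0`
ranking; across orders it removes the mechanical inflation. Because the
null is built from the *maximum*, it simultaneously yields family-wise
multiplicity control: the adjusted p-value of an observed `R0` is the
fraction of `M_i` at least as large (with ties counted, a conservative
choice), and the level-`alpha` cutoff is the empirical upper-`alpha` order
statistic of `M` -- `rigscan` takes the `ceiling((1-alpha) n_perm)`-th
smallest element, again conservative for small ensembles. A combination is
flagged significant when its `R0` strictly exceeds the cutoff; the strict
inequality and the tie-counting p-value agree wherever `alpha * n_perm` is
not an integer and `R0` does not tie an `M_i` exactly.

One ensemble per order serves all combinations of that order -- the maximum
is taken across combinations *within* each permuted dataset, never one
ensemble per combination. The ensemble is generated as independent label
shuffles (permutations without replacement of the phenotype vector), which
is what keeps the case/control margins fixed; resampling labels with
replacement would break them. All shuffles are drawn sequentially from one
seeded RNG stream, so a single integer seed reproduces the ensemble, the
cutoffs and every p-value exactly.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `order` | 2 | interaction order `k`; tables have `3^k` rows |
| `n_perm` | 1000 | permutation ensemble size; the p-value floor is `1/n_perm` |
| `alpha` | 0.05 | family-wise significance level; requires `n_perm * alpha >= 1` |
| `top_n` | 100 | combinations kept in results and scree plots |
| `max_combinations` | 1e6 | refusal threshold on `choose(p, k)` |

Entropies are in bits throughout; the base cancels in `R0` and is carried
explicitly (`ln 2`) in the G-squared identity. Only the mean and standard
deviation of the null enter `U_r`, so moderate ensembles standardize well;
`n_perm` mainly buys p-value resolution.

## Conventions and degenerate inputs

* **Row order.** Joint genotypes index table rows by a mixed-radix code
  with the first SNP most significant and genotype order AA < Aa < aa
  (0 < 1 < 2). Any bijection would do; this one is fixed so results are
  reproducible byte for byte.
* **Missing genotypes.** Samples missing any genotype of a combination are
  excluded from that combination's table only (per-combination
  complete-case analysis); the exclusion count is kept on the table.
* **Ties.** Ranked outputs break `R0` ties lexicographically on SNP
  indices, so scans are deterministic.
* **Degenerate input.** Single-class phenotypes (`H(Y) = 0`) are refused up
  front; a panel of constant SNPs makes every permutation maximum zero and
  raises a degenerate-null error rather than returning `0/0` scores.
* **Roundoff.** `R0` is clamped to `[0, 1]`; the clamp only ever absorbs
  floating-point residue of order 1e-16.

## The simulator

`simulate_case_control()` generates the balanced case-control panels used
to validate the method. A two-locus disease model is specified by a 3x3
grid of genotype odds ratios, a minor allele frequency shared by both
causal loci, and a population prevalence. Each cell's odds of disease is
its odds ratio times a common baseline odds `b`,
`penetrance = OR b / (1 + OR b)`, and `b` is solved by root bisection over
`(1e-8, 1e3)` so that the Hardy-Weinberg-weighted mean penetrance equals
the prevalence (residual below 1e-10). An odds ratio of exactly 0 is a
structural zero (penetrance 0). Eight built-in models cover effect sizes
from strong (odds ratios of 5) to weak, with minor allele frequencies of
0.1-0.4 and prevalences of 1.7-5.2%, all with little marginal effect --
the regime in which interaction detection is actually hard.

Case and control genotypes at the causal pair are drawn retrospectively:
cell probabilities proportional to `hwe_i hwe_j penetrance_ij` for cases
and `hwe_i hwe_j (1 - penetrance_ij)` for controls. The remaining SNPs are
phenotype-independent Hardy-Weinberg noise with per-SNP minor allele
frequencies drawn once from Uniform(0.05, 0.5) -- a realistic spread for a
genotyping panel; a fixed value can be requested instead. The causal pair
sits at positions 1 and 2 by default (hit detection compares unordered
index sets, so placement is cosmetic). Fifteen design groups cross panels
of 10/50/100/500/1000 SNPs with 400/1000/2000 balanced samples.

What the generator deliberately does **not** emulate: linkage
disequilibrium (all SNPs independent), population stratification,
genotyping error and missingness patterns, and covariates. Passing power
and error-control checks on these panels therefore demonstrates the
statistical machinery under clean conditions, not robustness to the
correlation structure of real genotype data.

## The MDR baseline

For power comparisons the package re-implements multifactor dimensionality
reduction: cells of the `3^k` table are labelled high-risk when their
case:control ratio reaches the training fold's overall ratio (ties high, a
common convention; empty cells low), and a combination is scored by the
balanced accuracy -- mean of sensitivity and specificity -- of that
two-level classifier. Under 10-fold phenotype-stratified cross-validation,
each fold selects the combination with the best training balanced
accuracy; cross-validation consistency (CVC) counts selections, and the
winner is the highest-CVC combination with mean testing balanced accuracy
breaking ties. Selection inside folds uses training accuracy only, so the
two reported criteria (BA and CVC) stay distinct. A repeat parameter
allows averaging CVC over repeated cross-validations (default 1).

## The power protocol

`power_experiment()` measures empirical power as the **hit ratio**: the
fraction of replicate datasets in which the embedded causal pair ranks
first among all two-locus combinations. For the entropy method the hit is
decided by the `R0` ranking, which equals the `U_r` ranking by rank
invariance -- so the power experiment spends no permutations. The MDR
methods rank by testing balanced accuracy (`MDR_BA`) or CVC (`MDR_CVC`).
Replicate seeds derive deterministically from one master seed, so any cell
of the experiment reproduces in isolation.

## Visualization

The scree plot draws ranked scores against rank with the cutoff as a
dotted line and the top combination labelled; the elbow judgment is left
to the viewer, while the count of combinations above the cutoff is
reported numerically. The MDS map applies classical (Torgerson) scaling --
double-centering plus eigendecomposition, via `stats::cmdscale` -- to the
matrix of pairwise `R0` values, read here as a similarity-style distance:
the plotted distance between two SNPs approximates their two-locus
interaction strength, and point sizes grow affinely with single-locus
`R0`, so main effects and pairwise effects are read off one figure. A
shifted-`U_r` variant (adding `-min U` so all entries are non-negative)
gives an equivalent configuration. When fewer than two eigenvalues are
positive the embedding falls back to one dimension with a warning. Every
figure writes its numbers to a sidecar table, so nothing is visible in a
plot that is not available as data.

## Validation problem sizes

The package's own checks run at deliberately chosen scales: the
family-wise error rate is estimated from 500 global-null panels (10 SNPs,
200 cases / 200 controls) with 200-permutation order-2 nulls -- enough for
a Monte-Carlo standard error of about 1% on a 5% rate; the prevalence
constraint is verified by forward-simulating one million unselected
individuals; the power comparison runs Model 1 on the 10-SNP groups at 400
and 2000 samples with 50 replicates, where binomial noise on a hit ratio
is about 7%. These sizes are the package's validation design and are
encoded in its tests and acceptance script.

## Limitations

The scan is exhaustive, so it suits candidate-gene panels; genome-wide use
requires pre-screening, which is out of scope here. `R0` does not separate
main effects from pure interaction -- a pair containing one strong marginal
SNP can rank high without genuine epistasis; the MDS plot's point sizes
are the intended diagnostic for that situation. Adjusted p-values cannot
fall below `1/n_perm`, and the chi-square reading of the G-squared
statistic should not be trusted on sparse high-order tables.
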