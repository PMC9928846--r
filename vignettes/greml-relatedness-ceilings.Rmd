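---
title: "Genomic heritability and correlations under relatedness ceilings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic heritability and correlations under relatedness ceilings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpgreml)
```

## The model

`snpgreml` estimates how much of the phenotypic variation in a genotyped
population is captured by common SNPs, and how strongly the genetic
components of two traits covary. The single-trait model is the animal
model

$$ y = Xb + g + e, \qquad g \sim N(0,\, G\sigma_g^2), \qquad
   e \sim N(0,\, I\sigma_e^2), $$

where $G$ is a genomic relationship matrix computed from SNP dosages.
The SNP heritability is $h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$.
For two traits the stacked model has random-effect covariance
$\Sigma_g \otimes G + \Sigma_e \otimes I$ with $2\times 2$ genetic and
residual (co)variance matrices; the genetic correlation is
$r_G = \mathrm{cov}_{A12} / \sqrt{\sigma^2_{A1}\sigma^2_{A2}}$ and the
phenotypic correlation
$r_P = (\mathrm{cov}_{A12}+\mathrm{cov}_{E12}) /
\sqrt{\sigma^2_{P1}\sigma^2_{P2}}$. Each animal contributes one record,
so the incidence matrix linking records to genetic effects is the
identity. Phenotypes are assumed pre-adjusted for systematic fixed
effects; the design matrix defaults to an intercept but any covariate
matrix is accepted.

The assumptions worth keeping in mind: effects are additive and
normally distributed; every SNP contributes to $G$ with equal weight
after standardization; residuals are independent across animals; and
for the bivariate model both traits are recorded on every analyzed
animal (complete-case).

## The GRM

`compute_grm()` uses the standard SNP-dosage estimator. With per-SNP
allele frequency $p_i$ estimated from the sample, the off-diagonal
entry for animals $j,k$ averages
$(x_{ij}-2p_i)(x_{ik}-2p_i)/(2p_i(1-p_i))$ over the SNPs non-missing in
both animals, while the diagonal uses the distinct form
$1 + \mathrm{mean}_i\,[x_{ij}^2-(1+2p_i)x_{ij}+2p_i^2]/(2p_i(1-p_i))$,
which estimates $1$ plus the genomic inbreeding coefficient.
Monomorphic SNPs carry no information and are excluded; a pair sharing
no genotyped SNP is an error rather than a silently undefined entry.

Two consequences of estimating $p_i$ in-sample are documented because
tests rely on them: dosages are centred exactly, so the mean
off-diagonal of a GRM of $n$ unrelated animals is $-1/(n-1)$ rather
than 0; and the realized matrix can be slightly indefinite (the
diagonal estimator is not the Gram form), so consumers that factor $G$
must tolerate small negative eigenvalues. The trait simulator factors
the positive-semidefinite projection of $G$ with a $10^{-8}$ jitter,
and the likelihood code treats non-positive-definite $V$ as an invalid
parameter point during line search.

## Quality control

`apply_qc()` mirrors conventional PLINK-style filtering: individuals
with more than 10% missing genotypes, then SNPs with call rate below
90%, minor allele frequency below 5%, or a Hardy–Weinberg exact-test
p-value below $10^{-3}$ (all thresholds configurable, all comparisons
strict). Removing SNPs changes individual missingness on the surviving
panel, so the two stages repeat until a fixpoint; this makes the filter
idempotent — a property the test suite asserts — while the first round
equals the conventional single pass. The HWE test is the standard exact
(not mid-p) test, computed by a ratio recurrence across heterozygote
counts and verified against full enumeration for every genotype triple
with up to 100 samples.

## REML: algorithm and numerical choices

The restricted log-likelihood is
$-\tfrac12[\log|V| + \log|X'V^{-1}X| + y'Py]$; the additive constant
$-\tfrac{n-p}{2}\log 2\pi$ is dropped, a convention shared by
`reml_loglik()` (the dense reference evaluator) and both fitters, so
grid-search oracles and fitted values are directly comparable.

Fitting follows the strategy of standard GREML software: one EM
iteration to move safely from the starting values (half the OLS
residual variance in each component), then average-information updates
$\theta \leftarrow \theta + \mathrm{AI}^{-1} s$ with step-halving
whenever a proposed update would decrease the likelihood, and an EM
fallback when halving stalls or the AI matrix is singular. Variance
components are floored at $10^{-6} \times V_p$ so they cannot go
negative; convergence is declared when the log-likelihood changes by
less than $10^{-4}$ (both tunable via `greml_control()`). In the
bivariate fitter the same scheme runs on the six parameters
$(\sigma^2_{g1}, \sigma_{g12}, \sigma^2_{g2}, \sigma^2_{e1},
\sigma_{e12}, \sigma^2_{e2})$, and after every update $\Sigma_g$ and
$\Sigma_e$ are bent to positive definiteness by flooring their
eigenvalues. Bending rather than hard constraints lets $|r_G|$ approach
1; a fit whose $|r_G| \ge 1 - 10^{-3}$ is flagged `boundary` rather
than treated as an error. With duplicated or perfectly correlated
traits the AI matrix is structurally singular, and the fitter converges
along EM steps with `NA` standard errors — the honest answer for a
non-identifiable corner.

Both fitters rotate the data by the eigenvectors of $G$, after which
$V$ is diagonal (univariate) or $2\times2$-block-diagonal per
eigenvalue (bivariate) and every iteration costs $O(np)$. A literal
dense implementation (`method = "dense"`) exists purely as a
verification path; tests assert the two agree to $10^{-8}$. A GRM
numerically proportional to the identity makes $\sigma_g^2$ and
$\sigma_e^2$ jointly unidentifiable and is rejected up front with a
singular-information error.

Standard errors come from the inverse AI matrix at convergence via the
delta method: for $h^2$ the gradient $(\sigma_e^2, -\sigma_g^2)/V_p^2$,
and the analogous gradients for $r_G$ and $r_P$ on the 6-parameter
sampling covariance. These are the same transforms standard GREML tools
report; alternative information-matrix parameterizations give slightly
different SEs, which is expected and not adjudicated here.

## Relatedness-ceiling pruning

`prune_by_relatedness()` builds the sub-populations for the sensitivity
analysis: individuals are removed until no retained pair has a GRM
entry above the ceiling. The base rule is greedy max-degree
elimination (repeatedly drop the individual in the most over-ceiling
pairs, ties broken toward the later input index, which is deterministic
and tends to maximize the retained count). Greedy alone can fall two
short of the optimal retained set on dense conflict graphs, so two
deterministic refinements follow: a minimality pass that re-adds any
removed individual no longer in conflict, and a (1,2)-swap pass that
exchanges one retained individual for two compatible removed ones.
Both only enlarge the result and never violate the ceiling. On
12-individual GRM-like matrices (family blocks plus noise) the refined
result matched an exhaustive optimum in 5,000 of 5,000 probe cases; the
acceptance suite re-checks near-optimality against exhaustive search on
50 random cases.

`run_sweep()` repeats prune → subset → fit over a ceiling grid,
recording estimates, SEs and convergence per trait and per pair, with a
no-ceiling row for the full data. Sub-population phenotypes are matched
by family/individual ID after pruning; fits that fail (e.g.
non-convergence at tiny $n$) are recorded in a `status` column rather
than aborting, and ceilings retaining fewer than `min_n` (default 50)
individuals are flagged `skipped` — small sub-populations below the
lowest usable ceiling are not analyzable, only flagged.

## The simulator: what it emulates, what it does not

`simulate_genotypes()` builds a two-generation population: unrelated
founders with per-SNP allele frequencies uniform on a configurable
range (default 0.05–0.5), and families of offspring produced by gene
dropping — each parent transmits one allele per SNP, independently
across SNPs. Full-sib families share both parents (expected relatedness
0.5), half-sib families share the sire only (0.25). There is no linkage
disequilibrium by design: the model's assumptions concern the GRM, and
LD-free simulation keeps expected relatedness analytic. There is also
no selection, no assortative mating, no genotyping error, and no
multi-generation depth; the half-sib preset approximates a
sire-structured herd rather than reproducing any particular herd or
sire count. A green estimation test on these data therefore establishes
correctness of the estimator under its own assumptions, not robustness
to LD structure, stratification, or missing-trait patterns.

`simulate_traits()` is the exact sampling counterpart of the model:
breeding values are drawn with covariance $\Sigma_g \otimes G$ against
the realized (not expected) GRM, residuals with $\Sigma_e \otimes I$,
with $\Sigma_g = D^{1/2} R_g D^{1/2}$, $D = \mathrm{diag}(h^2 V_p)$ and
$\Sigma_e$ built analogously from $(1-h^2)V_p$. Because the generator
conditions on the realized $G$ that the fitter also uses, parameter
recovery is a closure property with no missing-heritability gap; the
acceptance suite quantifies it (mean $\hat h^2$ within $\pm 0.05$ of
0.5 at $n = 1000$, delta-method SEs within 30% of the empirical spread,
null fits piling up at the floor).

`wagyu_preset()` packages a six-trait configuration (CW, REA, RT, SFT,
YI, BMS) on the reporting scale of a large published carcass-trait
analysis: phenotypic variances, heritabilities and genetic correlations
from its tables, with the residual correlation matrix derived from the
genetic and phenotypic ones and both correlation matrices bent to the
nearest PSD matrix if the printed tables are slightly indefinite. The
preset is a synthetic stand-in for scale-realistic testing, not a
reproduction of the original data.

Determinism: every generator call is reproducible from its config seed;
trait simulation defaults to `seed + 1` so genotype and trait draws are
decoupled but jointly reproducible, and the global RNG state is
restored afterwards.

## File formats

The GCTA binary GRM triplet is supported bit-exactly: little-endian
32-bit floats of the row-wise lower triangle including the diagonal in
`.grm.bin`, per-pair SNP counts in `.grm.N.bin`, and a two-column text
`.id` file. Values survive a write/read cycle up to one float32
quantization, after which round trips are bit-identical. PLINK text
`.ped/.map` is read with "0 0" (or any half-missing call) as missing
and dosages counting the lexicographically later observed allele —
`.map` carries no allele columns, so a monomorphic SNP's orientation is
not recoverable from a `.ped` file alone (the dosage-TSV dialect has no
such ambiguity). Phenotypes use the `.phen` layout with `NA`/`-9` as
missing codes.

## Known limitations

* One GRM, one random effect: no multi-component or GxE models, no
  BLUP output of individual breeding values.
* Bivariate fits are complete-case; unbalanced designs would require a
  substantially different likelihood implementation.
* The pruning rule is a declared convention; other tools' undocumented
  removal orders can retain slightly different (equally valid) sets, so
  retained counts from other software are not expected to match
  exactly.
* Delta-method SEs are first-order; near parameter-space boundaries
  (components at the floor, $|r_G| \to 1$) they understate the true
  uncertainty, and at structurally singular points they are reported as
  `NA`.
* The eigendecomposition fast path assumes the full sample shares one
  GRM; it costs one $O(n^3)$ eigendecomposition per fit, which is the
  dominant cost at large $n$.
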