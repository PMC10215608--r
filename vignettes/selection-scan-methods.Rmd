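---
title: "Methods: selection-signature scans between divergent milk-yield populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-signature scans between divergent milk-yield populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkscan)
library(dplyr)
```

milkscan detects genomic regions under divergent selection between two
populations of dairy sheep bred toward opposite extremes of milk yield,
then validates candidate genes against expression and breeding-value
data. This vignette records the statistical methods, every tunable
parameter with its default and the reason for it, the behaviour on
degenerate inputs, and the limitations of the synthetic data generator
used for testing.

## 1. Study design being modelled

Two cohorts of diploid animals (defaults: 50 high-yield, 50 low-yield)
are genotyped at biallelic SNPs across several contigs. Selection for
high yield is expected to have swept favourable haplotypes toward
fixation in the high group, locally depressing its diversity and
inflating differentiation from the low group. Three windowed statistics
are therefore intersected:

* **Weir–Cockerham $F_{ST}$** — between-group differentiation,
* **$\log_2(\pi_{high}/\pi_{low})$** — the nucleotide-diversity ratio,
* **$ZH_p$** — Z-transformed pooled heterozygosity within the swept
  group.

A sweep in the high group shows up as high $F_{ST}$, a *low* diversity
ratio, and a *low* $ZH_p$ in the high group.

## 2. Variant quality control

`apply_site_filters()` applies, in order: per-site call rate, minor
allele frequency (MAF), missingness, and a Hardy–Weinberg equilibrium
(HWE) exact test. Each removed site is charged to the *first* filter it
fails, so the report's `n_failed` column sums with `n_retained` to the
input count — exact bookkeeping that the tests verify by hand
enumeration.

Two profiles mirror common practice:

| parameter       | `"structure"` | `"scan"` | rationale |
|-----------------|--------------|----------|-----------|
| `min_call_rate` | 0.90         | 0.996    | structure analyses tolerate missingness; scans need dense windows |
| `min_maf`       | 0.05         | 0.01     | PCA/GRM are dominated by common variants; scans keep rarer alleles because sweeps *create* rare alleles |
| `max_missing`   | 0.05         | 0.10     | complements call rate on the per-genotype scale |
| `hwe_p_floor`   | 1e-6         | 1e-6     | only gross genotyping artefacts are removed; selection itself perturbs HWE, so the floor is deliberately loose |

The HWE test is the exact conditional test computed from the Levene
distribution via log-gamma terms; monomorphic sites return $p = 1$.
The two-sided p-value sums all heterozygote counts whose probability
does not exceed the observed one.

**LD pruning** (`ld_prune()`) is the greedy sliding-window algorithm:
windows of 50 SNPs advanced in steps of 5; within a window, for any
pair with $r^2 > 0.5$ the lower-MAF member is removed (ties: the
later site). $r^2$ is the squared Pearson correlation of dosages over
pairwise-complete samples. The 0.5 cutoff corresponds to a
variance-inflation factor of 2, the conventional pruning strength for
structure analyses. Pruning is idempotent: re-running it on its own
output removes nothing (a property test).

Degenerate inputs: a site with zero variance has $r^2 = 0$ with
everything (it carries no LD information); fewer than 2 complete pairs
gives `NA` and the pair is never treated as linked.

## 3. Windowed selection statistics

`scan_windows()` tiles each contig with sliding windows; defaults are
`window_bp = 100000` and `step_bp = 10000` (100-kb windows, 10-kb
steps), the standard resolution for sheep-density SNP data: wide enough
to average noise over tens of sites, stepped finely enough to localise
peaks. Windows with fewer than `min_sites_per_window = 10` genotyped
sites get `NA` statistics rather than noisy estimates.

### 3.1 $F_{ST}$ (Weir & Cockerham 1984)

Per site, with two populations of $n_1, n_2$ genotyped diploids, allele
frequencies $p_1, p_2$ and heterozygote frequencies $h_1, h_2$, the
variance components $a$ (between populations), $b$ (between individuals
within populations) and $c$ (within individuals) are computed from the
standard moment estimators. The window estimate is the *ratio of sums*

$$\hat F_{ST} = \frac{\sum_{s} a_s}{\sum_{s} (a_s + b_s + c_s)},$$

not the mean of per-site ratios — ratio-of-sums is the consistent
estimator and is far more stable at low per-site information. Sites
where $a + b + c = 0$ (e.g. monomorphic overall) contribute nothing.

### 3.2 Nucleotide diversity and its ratio

Per site with $n$ called alleles and $c$ alternate copies, the unbiased
heterozygosity is $2c(n-c)/(n(n-1))$; window $\theta_\pi$ sums this over
sites (divided by window length when `per_site_pi = TRUE`). The contrast
is $\log_2(\pi_{high}/\pi_{low})$, which is `NA` when either diversity
is zero — a zero-diversity window is reported as missing rather than
$\pm\infty$ and is excluded from the intersection (the count of such
exclusions is attached as an attribute).

### 3.3 Pooled heterozygosity

Within one group, summing major- and minor-allele counts over the
window's sites,

$$H_p = \frac{2\,\Sigma n_{MAJ}\,\Sigma n_{MIN}}{(\Sigma n_{MAJ} + \Sigma n_{MIN})^2},
\qquad ZH_p = \frac{H_p - \mu_{H_p}}{\sigma_{H_p}},$$

with $\mu$ and $\sigma$ the mean and *population* (divisor-$n$) standard
deviation over all non-missing windows, so that the $ZH_p$ vector has
exactly zero mean and unit root-mean-square — an identity the tests
check to $10^{-9}$. A constant $H_p$ vector (zero $\sigma$) is an error,
not a silent division by zero.

### 3.4 Candidate selection

`select_candidates()` takes the top `top_quantile = 0.05` (5%) of each
statistic using type-7 empirical quantiles, with ties *kept* (the
comparisons are $\ge$ / $\le$). Default tail directions follow the sweep
logic above: $F_{ST}$ upper tail, diversity ratio lower tail, $ZH_p$ of
the high group lower tail. `tails = "paper"` selects the upper tail of
all three, matching analyses that fold the ratio and $ZH_p$ so extreme
values are large. Windows passing all three tails are merged when they
overlap or abut into candidate regions.

Degenerate case: if a statistic is constant over the defined windows its
tail is empty (no threshold separates anything), so the intersection is
empty rather than everything. Fewer than 20 fully-defined windows is an
error — a 5% cut of fewer than 20 values selects on noise.

## 4. Population structure

* `compute_grm()` — genomic relationship matrix from standardised
  dosages $(g - 2p)/\sqrt{2p(1-p)}$, missing genotypes mean-imputed,
  monomorphic sites excluded with a warning (their standardisation is
  undefined).
* `grm_pca()` — eigendecomposition of the GRM; `pve` is each
  eigenvalue as a percentage of the sum of non-negative eigenvalues.
* `ibs_distance()` — $1 - \mathrm{IBS}$ over pairwise-complete sites;
  a pair with no jointly-called sites is an error.
* `neighbor_joining()` — the Saitou–Nei algorithm, hand-implemented
  with a deterministic lexicographic tie-break so trees are reproducible
  across platforms; negative branch estimates are clamped to zero with
  the deficit moved to the sister branch, preserving path lengths.
  Recovering an additive distance exactly is verified to $10^{-9}$.
* `group_silhouette()` and `groups_monophyletic()` quantify group
  separation on PC1 and on the tree.

## 5. Animal-model BLUP and expression validation

`solve_animal_model()` fits the single-trait animal model

$$y = \mathbf{X}b + \mathbf{Z}u + e, \qquad u \sim (0, \mathbf{A}\sigma_a^2),$$

with fixed effects (sum-to-zero contrasts), one continuous covariate,
and the pedigree relationship matrix $\mathbf{A}$ built by the tabular
method. Henderson's mixed-model equations are solved directly with
$\lambda = (1 - h^2)/h^2$. The default `h2 = 0.3` is a typical
literature value for dairy-sheep milk yield; tests also run at
$h^2 = 0.5$, where the simulated design recovers true breeding values
with correlation above 0.6. The MME solution is verified against the
closed-form GLS/BLUP expressions on small fixtures.

qPCR expression is summarised by
$\Delta C_T = \overline{C_T}(\text{target}) - \overline{C_T}(\text{reference})$,
replicates averaged *before* subtraction; this makes $\Delta C_T$
invariant to per-ewe plate offsets (a property test). Because $C_T$ is
inversely related to abundance, a *negative* expression–yield relation
appears as a *positive* $\Delta C_T$ slope.
`expression_production_report()` regresses per-gene $\Delta C_T$ on
yield and on estimated breeding value via ordinary least squares,
reporting slope, $R^2$ and p-value; a zero-variance response warns and
reports $R^2 = 0$, a zero-variance covariate is an error.

Enrichment of candidate genes in annotation terms uses the
hypergeometric upper tail ($P[X \ge k]$) with Benjamini–Hochberg
adjustment; the query must be a subset of the background.

## 6. The synthetic-data generator

`simulate_two_pop_genotypes()` draws ancestral frequencies
$p \sim U(0.05, 0.95)$ and group frequencies from the Balding–Nichols
model, $p_g \sim \mathrm{Beta}(p(1-F)/F,\, (1-p)(1-F)/F)$ with
`background_fst = 0.05` (moderate divergence between selection lines of
one breed). Inside planted sweep windows, a fraction `sweep_intensity`
(default 0.9) of sites in the swept group is driven to alternate
frequency $\sim U(0, 0.02)$ — near-fixation of one allele, the
diversity signature of a hard sweep. Genotypes are binomial draws
(Hardy–Weinberg within groups). Defaults (2 × 50 animals, 5 × 1-Mb
contigs, 2000 sites/contig) match the scale at which the scan is
designed to operate.

`simulate_pedigree_phenotypes()` builds a founder generation plus
`n_generations` of offspring with breeding values following the additive
infinitesimal model ($\sigma_a^2 = h^2$, Mendelian-sampling variance
$\sigma_a^2/2$), four crossed fixed-effect factors and a covariate with
known $\beta$ (default 0.5).

`simulate_qpcr_table()` generates per-ewe reference $C_T \sim N(20,
0.2)$ and target $C_T$ = reference + intercept + slope × yield + noise,
two replicates. Yields are drawn uniformly on `yield_range = c(1, 4)`
kg/day — the realistic range for dairy-sheep daily milk yield, wide
enough that a planted slope is identifiable at $n = 11$ ewes. With
`noise_sd = 0` the $\Delta C_T$–yield regression is exactly linear
($R^2 = 1$), which anchors the validation tests.

**What the generator does not emulate:** linkage disequilibrium along
the chromosome (sites are independent given frequencies), soft or
partial sweeps, hitch-hiking gradients at sweep edges, genotyping error
that is correlated with allele frequency, pedigree structure in the
genotyped cohorts, and genotype-by-environment interaction in the
phenotypes. Conclusions about real data should not lean on properties
the generator lacks.

## 7. Problem sizes and numerical behaviour

The full pipeline at default scale (10 000 sites, 100 animals, ~500
windows) runs in seconds. The dense MME solve is $O((p + q)^3)$ in the
number of fixed-effect levels $p$ plus animals $q$; it is comfortable to
a few thousand animals, beyond which sparse solvers would be needed.
All statistics are deterministic given the input; all simulation is
controlled by explicit seeds and restores the caller's random-number
state.
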