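---
title: "Methods: casein-SNP-augmented genetic evaluation of dairy goat milk traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: casein-SNP-augmented genetic evaluation of dairy goat milk traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capragen)
```

## The problem

Dairy-goat breeding programs evaluate animals for milk yield and
composition (fat, protein, solids, lactose, somatic cell count) from
repeated lactation records and a herdbook pedigree. The casein complex
(the αS1-, αS2-, β- and κ-casein genes) carries polymorphisms with
additive, dominance and epistatic effects on these traits. `capragen`
implements an evaluation procedure that encodes a casein SNP panel as
*nominal* genetic fixed effects, compresses the panel into cluster
effects by categorical principal component analysis (CATPCA), encodes
inter-cluster epistasis through nonlinear canonical correlation
(OVERALS), and fits the repeatability animal model by REML with and
without those genetic fixed effects to quantify what their inclusion
does to heritabilities, correlations, breeding values and their
accuracies.

## The animal model

For a trait $y$ with repeated records,

$$ y = Xb + Z_a a + Z_{pe} p + e, \qquad
   a \sim N(0, A\sigma^2_a),\;
   p \sim N(0, I\sigma^2_{pe}),\;
   e \sim N(0, I\sigma^2_e), $$

where $b$ collects the management fixed effects (farm, parity, control
month, birth type in the synthetic default; the full herdbook factor
list is supported as columns of the record table), the optional SNP
cluster factors and epistasis factor, and a centered linear + quadratic
age covariate; $a$ is the additive genetic effect structured by the
pedigree numerator relationship matrix $A$; $p$ is the permanent
environment effect shared by a doe's records. Heritability is
$h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_{pe}+\sigma^2_e)$ and
repeatability $(\sigma^2_a+\sigma^2_{pe})/\sigma^2_p$.

$A$ is built by the tabular recursion
($a_{ij} = \tfrac12(a_{j,s(i)}+a_{j,d(i)})$, diagonal $1+F_i$); its
sparse inverse comes directly from Henderson's rules with inbreeding,
with $F$ computed by the Meuwissen–Luo ancestor-tracing algorithm, so no
dense matrix is formed in the mixed-model path.

### REML

Variance components are estimated by restricted maximum likelihood on
the mixed-model equations, with the convergence criterion set to a
squared relative component change below $10^{-12}$. Each iteration
attempts an average-information (AI) Newton step; the step is accepted
only when it keeps components positive (negative proposals are clamped
at a floor, i.e. boundary estimates) and does not decrease the
restricted likelihood, otherwise the EM update — monotone by
construction — is taken. The reported $-2\log L$ trace is therefore
non-increasing. Components that drift below 0.1% of the phenotypic
variance are treated as boundary estimates and excluded from the
convergence test; a likelihood plateau ($|\Delta(-2\log L)| <
10^{-10}$) is accepted as convergence when parameter changes are
already small. Standard errors come from the inverse AI matrix at
convergence; the SE of $h^2$ by the delta method.

The six-trait analysis is realized as univariate runs plus bivariate
runs per trait pair (not a joint six-trait fit). The bivariate fit
estimates full 2×2 additive, permanent-environment and residual
covariance matrices by EM (expectation–conditional maximization on the
same equations) accelerated by SQUAREM extrapolation, each jump guarded
by the likelihood; non-PSD updates are projected back by eigenvalue
clipping and flagged. Genetic and phenotypic correlations and their
delta-method SEs follow from the fitted matrices. EM was chosen over AI
here because the guarded-monotone property extends naturally to the
matrix-valued updates; the SQUAREM jumps recover most of the speed an
AI implementation would give at these problem sizes.

### BLUP, accuracy, reliability

At the converged (or supplied) components, the sparse symmetric system
gives BLUE estimates of fixed effects and BLUP predicted breeding
values (PBV). The animal block of the inverted coefficient matrix is
the prediction error (co)variance: $SEP_i=\sqrt{PEV_i}$,
$RTi_i=\sqrt{1-PEV_i/((1+F_i)\sigma^2_a)}$, $Rap_i=RTi_i^2$. The
$(1+F_i)$ factor in the accuracy denominator is the default (a flag
removes it), because the prior variance of an inbred animal's breeding
value is $(1+F_i)\sigma^2_a$. A dense inverse is used below 4,000
equations; above that the animal block is obtained by columnwise sparse
solves.

## Encoding the casein panel

Genotype calls are encoded per SNP as nominal factors: major-allele
homozygote 1, heterozygote 2, minor-allele homozygote 3 (additive
factor) and homozygote 1 / heterozygote 2 (dominance factor). The codes
are labels, not scores — no ordinal relationship is assumed anywhere
downstream, which is the reason for the optimal-scaling machinery
below. "Dominant homozygote" is operationalized as the major-allele
homozygote: allele frequency is computable from the data while
biochemical dominance is not. Monomorphic SNPs are flagged and dropped
from scaling; missing genotypes are excluded pairwise, never imputed.

Allele-frequency and LD summaries accompany the encoding: MAF with a
0.05 rare-variant flag, observed heterozygosity, and pairwise D, D′ and
r² from haplotype frequencies fitted by EM on the unphased two-locus
genotype table (only the double heterozygote is phase-ambiguous; 100
iterations or $\Delta<10^{-8}$; the biallelic likelihood is unimodal
for non-degenerate data, so no restarts are needed). When no double
heterozygotes exist the EM solution equals the direct haplotype count.

## CATPCA

`fit_catpca()` alternates between (i) the PCA of the correlation matrix
of the currently quantified variables and (ii) re-quantifying each
nominal variable's levels as within-level means of its model
projection, standardized. Numeric-declared variables keep their values,
so an all-numeric fit is exactly the correlation-matrix PCA — the
oracle used in the tests. Iteration stops when the fit changes by less
than $10^{-8}$. Two starts are tried (deterministic integer-code start
and one seeded random start; best fit kept); the sign of each dimension
is fixed by forcing its top-loading variable positive.

Dimensions are rotated by Varimax with Kaiser row normalization
(`stats::varimax`), which preserves communalities; internal consistency
per dimension is Cronbach's $\alpha = \frac{m}{m-1}(1-1/\lambda)$. The
number of dimensions, when not given, is chosen as the largest (up to
7) whose every dimension keeps $\alpha$ above a configurable floor
(default 0.8). SNPs are retained on every dimension where the absolute
rotated loading is at least 0.5 (inclusive, with a max-only flag);
SNPs qualifying nowhere are reported discarded. Each dimension then
yields one composite fixed effect whose levels are the observed
combinations of its retained SNPs' codes, with combinations rarer than
`min_count` (default 5 in the pipeline) merged into an `"other"` level
to keep the model estimable.

## OVERALS and the epistasis factor

`fit_overals()` minimizes the average squared distance between common
object scores $X$ ($X'X=nI$) and per-set scores $\sum_j z_j a_j'$ over
optimally scaled variables, by backfitting within sets and a Procrustes
update of $X$. The per-dimension eigenvalue is defined as $1-$ mean
dimension loss, the convention under which eigenvalues lie in $[0,1]$,
total fit is their sum, average loss is `n_dims` minus total fit, and
with two numeric singleton sets the leading eigenvalue equals
$(1+\rho)/2$ of classical canonical correlation — the second oracle in
the tests. Because the total loss is invariant to rotation of $X$
within the fitted subspace, the solution is rotated post hoc to the
principal axes of the symmetric fit matrix $X'\bar S/n$, which makes
the per-dimension eigenvalues canonical and ordered.

The sets passed to OVERALS are the CATPCA clusters. Variables with an
absolute component loading ≥ 0.5 on any dimension *and* multiple fit
> 0.1 define the epistatic signature; animals are assigned one nominal
level from the cross-classification of those variables' codes, with the
rarest combinations merged pairwise until at most 10 levels remain (an
equal-frequency binning of object scores is the documented
alternative). The mapping from the canonical solution to a 10-level
factor is a design choice of this package: the cross-classification
keeps levels interpretable as genotype combinations.

## Screening

Candidate fixed effects are screened per trait with the Kruskal–Wallis
H test (midranks, tie-corrected; exact permutation p by full
enumeration when total $n \le 10$, chi-square otherwise), Dunn post-hoc
z tests with Bonferroni correction, and the effect size
$\eta_p^2 = (H-k+1)/(n-k)$ clipped to $[0,1]$ (an $H/(n-1)$ variant is
available; since one factor is tested at a time, partial and plain
eta-squared coincide). Continuous covariates are screened by Pearson
correlation. Screening is diagnostic: the genetic model keeps its full
factor list regardless, and a simple configurable min/max range purge
is provided for record cleaning.

## 210-day standardization

Test-day controls become 210-day yields by the test-interval
(Fleischmann) method: the first control's rate is carried back to
kidding, consecutive controls contribute trapezoids, the last control
extends to `min(days in milk, 210)` and any interval crossing day 210
is linearly interpolated at the horizon — yield beyond day 210 never
contributes. Component kilograms are accumulated per interval from
interval milk times the mean component fraction (respecting
within-lactation composition drift); somatic cell count is summarized
as the milk-weighted mean. Whether short lactations should be extended
exactly to 210 days or stop at the recorded length is exposed as a
flag; the default extends from the first/last control and truncates at
210.

## The synthetic herd

The generator exists so every downstream stage is testable with known
truth. Defaults emulate the structure of a Murciano-Granadina-style
herdbook study scaled to desk size: 120 founders, two bred generations,
a 48-SNP panel in four LD blocks (the four casein genes) with
within-block haplotype copying (`ld_rho = 0.8`) reproducing D′/r² decay
without a coalescent model, founder MAF in (0.15, 0.5) targeting ~40%
heterozygosity, 2–5 lactations per doe with ~5 controls each at
~42-day spacing, and four management factors (farm, parity, control
month, birth type) with level shifts drawn once per level. True
per-trait phenotypic variances and baseline heritabilities are set to
magnitudes typical of published dairy-goat repeatability-model
estimates (e.g. milk $\sigma^2_p \approx 1.64$, $h^2 = 0.21$ on the
210-day kg scale), repeatability is
$h^2 + 0.2$, and a handful of SNPs carry additive effects of 0.2
phenotypic SD by default. Somatic cell count is simulated on the log
scale and exponentiated, because controlling $h^2$ on the raw
cells/mL scale (variances ~10⁶) is numerically awkward; a raw-scale
option remains. Breeding values follow the pedigree exactly: founders
$N(0,\sigma^2_a)$ (multivariate across traits), offspring parent
average plus Mendelian sampling with variance
$\tfrac12\sigma^2_a(1-\bar F)$.

What the generator does *not* emulate: selection and assortative
mating, genotyping error, coalescent-accurate LD, seasonal lactation
curves (controls are constant-rate within lactation so the
test-interval total closes exactly), and the 244k-animal scale of a
real herdbook. Passing tests therefore demonstrate correctness of the
estimators under the stated model, not robustness to those real-data
features.

## Numerical choices and problem sizes

* REML convergence $10^{-12}$ (squared relative change); AI step
  acceptance tolerance $10^{-10}$ on $-2\log L$; EM fallback always
  available.
* Optimal-scaling loss tolerance $10^{-8}$; Varimax communality
  preservation checked to $10^{-10}$.
* LD EM tolerance $10^{-8}$, 100 iterations.
* Ties in rank sampling break by animal id; exact KW enumeration only
  up to total $n = 10$ (the count of distinct assignments grows
  multinomially).
* The parameter-recovery experiments run 20 replicates of 800 does ×
  4 records under an 80-sire paternal half-sib pedigree per setting —
  large enough that the mean estimate pins the bias below 0.05, small
  enough to run on one desktop core in minutes. The pipeline's default
  herd (~360 animals, ~700 records) completes a two-variant six-trait
  evaluation in a few minutes.

## Known limitations

* The bivariate a/pe covariance split is weakly identified in shallow
  pedigrees; with few sires the genetic correlation estimate is
  noticeably skewed toward ±1 even though the estimator matches the
  balanced MANOVA closed form exactly where one exists.
* The epistasis factor caps at 10 levels by rare-combination merging;
  with many qualifying SNPs the merged levels lose interpretability.
* Fixed effects with hundreds of levels (day-count factors) are
  treated as covariates by default; binning them as factors is
  supported but can easily exceed what a desk-scale dataset can
  estimate.
* No genomic relationship matrix: the package is pedigree-BLUP only by
  design.
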