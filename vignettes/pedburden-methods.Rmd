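---
title: "Relatedness-corrected rare-variant burden tests: models and design"
author: "pedburden maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relatedness-corrected rare-variant burden tests: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedburden)
```

## The problem

Rare variants underlying common disease are hard to detect in unrelated
case-control panels: each variant is seen a handful of times, so evidence
must be pooled ("collapsed") across a gene, and even then power is modest.
Families with several affected members are a natural enrichment device --
a rare risk allele segregating in a multiplex family is present in many of
its affected members -- but affected relatives are not independent
observations. Treating them as if they were inflates the type I error of
every population-based burden statistic.

pedburden implements a family of burden tests built on one correction
principle. Collapse the rare variants of a region into a carrier indicator
$z_i \in \{0,1\}$ with presence probability $p$ and variance
$\sigma^2 = p(1-p)$. The score comparing affected and unaffected
individuals is $H = c^\top z$, where $c = u - (n_c/n)\mathbf{1}$ is the
case/control contrast over the $n = n_c + n_G$ phenotyped individuals.
Under relatedness the covariance of $z$ is $\sigma^2 K$, with $K$ the
genetic relationship matrix ($K_{ij} = 2\phi_{ij}$ for $i \ne j$,
$K_{ii} = 1 + h_i$ with inbreeding $h_i$), so
$$ T_{CF} \;=\; \frac{H^2}{c^\top K c\,\sigma^2}
   \;=\; \frac{T_C}{P_{corr}}, \qquad
   P_{corr} \;=\; \frac{n}{n_c n_G}\, c^\top K c , $$
which is $\chi^2_1$ under the null. For unrelated, non-inbred samples
$c^\top c = n_c n_G / n$, hence $P_{corr} = 1$ and the family statistic
reduces exactly to the population one. The same scalar correction converts
the weighted-sum (WSS) and variable-threshold (VT) statistics
($T_{WSSF} = T_{WSS}/P_{corr}$, $T_{VTF} = T_{VT}/P_{corr}$; permutation
p-values) and a single-marker dosage chi-squared (min-p across a gene with
an empirical permutation p-value).

A note on coefficients: the kinship coefficient $\phi_{ij}$ is half the
relationship coefficient. The carrier-indicator covariance between, say,
full sibs is empirically $\approx 0.5\,\sigma^2$, i.e. $K_{ij}\sigma^2$
with $K_{ij} = 2\phi_{ij} = 0.5$ -- so it is $K$, not $\Phi$, that enters
every quadratic form here. This is also the unique reading under which the
unrelated case gives $P_{corr} = 1$ and the diagonal $1 + h_i$ matches
$\mathrm{Var}(z_i) = (1+h_i)\sigma^2$.

## Obtaining $K$

Three routes, selected per analysis:

* **Estimated** (`grmEstimate`): the genotype-based estimator with
  off-diagonal $\frac{1}{m}\sum_k (x_{ik}-2p_k)(x_{jk}-2p_k)/(2p_k(1-p_k))$
  and the dedicated diagonal estimator
  $1 + \frac{1}{m}\sum_k (x_{ik}^2-(1+2p_k)x_{ik}+2p_k^2)/(2p_k(1-p_k))$.
  Only common variants (MAF $\ge$ 0.05 by default) enter: rare variants
  make the per-variant ratio terms explode. Missing dosages are mean
  imputed. `grmCorrectionFactor` computes $P_{corr}$ for this estimator in
  $O(nm)$ without materializing $K$ (the contrast sums to zero, so the
  cross-product part collapses to column sums); the two routes agree to
  machine precision and the fast one keeps thousand-replicate experiments
  tractable.
* **Theoretical** (`pedigreeKinship`, `designKinship`): recursive pedigree
  kinship with founders unrelated and cross-pedigree entries zero.
* **Identity**: no correction; used to quantify the inflation that the
  correction removes.

When reference allele frequencies are unknown, `iterateKinshipFreq`
alternates a generalized-least-squares (GLS) frequency estimate
$\hat p = (\mathbf 1^\top K^{-1}\mathbf 1)^{-1} \mathbf 1^\top K^{-1} x/2$
with a relationship update, starting from pooled observed frequencies.
Frequencies are clipped to $[1/(2n+2),\,1-1/(2n+2)]$ and near-singular $K$
is ridge-regularized ($10^{-6} I$) -- numerical guards for monomorphic or
rank-deficient inputs. One design choice deserves emphasis: the
**convergence tolerance adapts to the estimator's noise floor**. The GLS
update cannot change by less than the sampling noise of $\widehat K$'s
inverse weights (empirically a few times $10^{-3}$ at $n \approx 60$,
$m = 1000$), so demanding a fixed $10^{-4}$ simply runs into the iteration
cap while the frequencies wander within noise. The default stops when the
largest update falls below a quarter of the typical frequency standard
error, $0.25\sqrt{\bar p (1-\bar p)/(2n)}$; passing an explicit `tol`
overrides this, and hitting `maxIter` returns with a warning and a
`converged = FALSE` flag rather than an error. In a parameter-recovery
check (three-generation families, 1000 common markers) the iterated
estimate recovers twice the pedigree kinship with off-diagonal RMSE
below 0.05.

## The statistics and their p-values

* **Collapsing** (`collapseRegion` + `familyCollapsingTest`): $z_i = 1$
  iff the individual carries at least one minor allele at at least one
  variant with MAF $\le$ 0.01 (inclusive threshold; 0.05 recommended for
  sparse chip data). $\hat p = \bar z$ (pooled null MLE; a GLS-weighted
  option exists). P-value from $\chi^2_1$. Degenerate indicators
  (constant $z$) report $p = 1$ with a flag, never `NaN`.
* **WSS** (`wssScore` + `familyPermutationTest`): Madsen-Browning weights
  estimated from unaffected individuals with a pseudo-count,
  $\zeta_k = (m^U_k+1)/(2n_U+2)$, $w_k = \sqrt{n\,\zeta_k(1-\zeta_k)}$;
  per-individual scores $\sum_k x_{ik}/w_k$ are midranked and the case
  rank sum is standardized by its permutation moments.
* **VT** (`vtTest`): carrier counts $C_i(t)$ accumulated over all variants
  with MAF $\le t$ for every observed candidate threshold $t \le 0.05$;
  the statistic is the maximal squared standardized score over $t$.
* **Single marker** (`correctedSingleMarker`, `minpEmpirical`): dosage
  score $c^\top x/2$ against $c^\top K c\,\hat p(1-\hat p)/2$; at $K = I$
  this equals the classical allelic chi-squared, which fixes the dosage
  (not carrier) coding. The gene-level p-value is the empirical
  probability, over label permutations, that the permuted minimum
  p-value is at most the observed one -- reported literally as
  count/$B$ with $B = 5000$ by default.

Permutations redraw the affection labels over the whole sample and
recompute everything label-dependent: the Madsen-Browning weights (they
depend on who is unaffected) and $P_{corr}$ (it depends on $u$). This
unrestricted scheme matches a null in which affection is exchangeable
across the sample -- which is exactly how the null data here are
generated -- while a within-pedigree-restricted scheme and a frozen
$P_{corr}$ are available for sensitivity analyses. WSS/VT permutation
p-values use $(1 + \#\{T^{(b)} \ge T\})/(B+1)$, which cannot return an
exact zero; the single-marker min-p uses the plain count/$B$ form. Ties
in ranks take midranks; ties between permuted and observed statistics
count against the hypothesis (the $\ge$ is inclusive).

## What the simulator emulates

`buildFounderPool` runs a neutral forward Wright-Fisher simulation with
infinite-sites mutation (rate $2.5\times10^{-8}$/bp/generation over a
100 kb region, 100 generations) in a population of 1000 diploids that
expands by a factor 2.1 per generation over its final generations up to
5000. (A growth factor applied over all 100 generations would be
astronomically impossible; reading it as the late-expansion multiplier is
our choice.) The resulting site-frequency spectrum is strongly
rare-skewed -- at the defaults, roughly 90% of segregating sites have
MAF $\le$ 0.01 and the collapsed carrier probability of the rare set is
$\approx$ 0.13 in unrelated samples, a realistic operating point for a
burden test. The pool is built once per experiment; replicates draw
founders from it, i.e. the population is fixed and sampling varies.

Family designs are ascertained multiplex units plus unrelated controls:

| design | affected unit | affected:unaffected |
|---|---|---|
| `case_control` | singleton case | 1:1 |
| `sibpair1` / `sibpair2` | 2 affected full sibs (parents ungenotyped) | 1:1 / 2:1 |
| `nuclear1` / `nuclear2` | affected parent + 2 affected children | 1:1 / 2:1 |
| `threegen1` / `threegen2` | affected grandparent, parent, 2 grandchildren | 1:1 / 2:1 |
| `mix1` | 33/33/34% sibpair2/nuclear2/threegen2 units | 2:1 |
| `mix2` | 50/50% sibpair2/nuclear2 units | 2:1 |
| `mix_cc` | 50% nuclear units, 50% singleton cases | 1:1 |

Every unit carries at least two affected members. The choice to place the
*unaffected* individuals outside the families (rather than as balanced
within-family controls) is deliberate and is the configuration consistent
with the published operating characteristics this package reproduces:
with affected members clustered in families, ignoring relatedness
*inflates* the uncorrected test (the within-case kinship adds positive
covariance to the score), e.g. the predicted uncorrected level for
affected sib pairs with half the sample as unrelated controls is
$P(\chi^2_1 > 3.84/1.275) \approx 0.08$ at nominal 0.05. Balanced
within-family contrasts would instead *deflate* the uncorrected test and
would also give family designs no power advantage over case-control
sampling. With multiplex units, power rises with the depth of the
affected cluster (mean within-unit kinship 0.25, 0.5, 0.625 for sib-pair,
nuclear, three-generation units), reproducing the expected design
ordering three-generation > nuclear > sib-pair > case-control.

**Penetrance.** Baseline (non-carrier) penetrance is $f_0 = 0.01$; each
causal variant multiplies risk by $\gamma_{1k}$ (het) or $\gamma_{2k}$
(hom), independently across variants. Model identities: dominant
$\gamma_2 = \gamma_1$, additive $\gamma_2 = 2\gamma_1 - 1$,
multiplicative $\gamma_2 = \gamma_1^2$, recessive $\gamma_1 = 1$. Risks
are calibrated from a per-variant population attributable risk of 0.006
via $\gamma_{1k} = 1 + PAR_k / (f_k(1-PAR_k))$ with $f_k$ the carrier
frequency, making $\gamma$ inversely related to MAF. A `parMode =
"total"` option splits one PAR across the causal set instead. Causal
variants are a PCV fraction of the rare variants with pool MAF in
$[0.001, 0.01]$: the lower bound exists because a pool singleton
(frequency $10^{-4}$) would receive $\gamma \approx 30$ under the inverse
mapping, and every ascertained multiplex family would then carry copies
of that one founder haplotype -- a degenerate sample in which the neutral
variant structure collapses and max-type statistics saturate.
`calibrateBaseline` optionally rescales $f_0$ to hit a target prevalence
(0.09) instead of fixing it at 0.01.

**Ascertainment.** Under the null the test gene is unlinked to the
phenotype, so conditioning on the affection pattern does not change its
genotype distribution: null replicates fix the labels by design template
and gene-drop directly (exact, and avoids rejection at rate
$f_0^{a} \approx 10^{-6}$ per family). Under the alternative, family
units are drawn by sampling-importance-resampling: a batch of candidate
units is gene-dropped (about 150 times the number needed), each weighted
by the probability that its designated members are all affected (the
product of their penetrances), and units are resampled proportionally.
This is exact as the batch grows; the implementation errors out if all
weights vanish. Controls are rejection-sampled unaffected (acceptance
$\approx 1 - f_0$). Rare/common status under the alternative is decided
by frequencies estimated in the *unaffected* individuals: ascertainment
inflates the sample frequency of exactly the variants carrying the
signal, and a full-sample filter would discard them.

**What passing tests do not show.** The simulator reproduces the
*statistical structure* of a family study -- a rare-skewed founder
spectrum, Mendelian transmission, penetrance-based multiplex
ascertainment -- not real sequencing data: there is no within-gene
recombination, no genotyping error or missingness (the Mendel checker and
missing-data rules are exercised on constructed fixtures), no population
stratification, and linkage equilibrium among kinship markers. Calibrated
type I error transfers to real data in so far as the relationship matrix
captures the actual covariance of the carrier indicator; power figures
are qualitative (orderings, monotonicities), not point predictions --
they depend on an unobservable site-frequency spectrum and effect-size
model.

## Numerical and scale choices

* Quadratic forms for estimated $K$ run through the $O(nm)$ path;
  theoretical $P_{corr}$ for a fixed-label design is a constant computed
  once per experiment.
* Type-I experiments default to $N = 2100$, 1000 kinship markers, and
  $R = 1000$ replicates in the acceptance script; the package test suite
  runs the same checks at $R = 600$ with exact binomial bands computed
  for that $R$. Power checks in the suite use $R = 50$--$80$ and
  $B = 150$ with two-standard-error Monte-Carlo tolerances; these sizes
  were fixed in advance to keep the default suite comfortably inside a
  desk-scale run while leaving the assertions decisive for the effect
  sizes involved.
* Per-replicate seeds derive from the master seed by a fixed counter map
  (`childSeed`), so replicates are independent, reproducible and
  order-invariant; every simulation function takes an explicit seed.
* Degenerate situations have defined outcomes: constant indicators or
  zero variances give $p = 1$ plus a flag; monomorphic variants are
  degenerate in the single-marker test; empty rare sets raise an error
  that the evaluation harness converts into a counted non-rejection.

## Known limitations

* The GLS/relationship iteration estimates $n(n-1)/2$ relationships from
  $m$ markers; for $m$ not much larger than $n$ its frequency updates are
  noise-dominated (hence the adaptive stopping rule) and the estimated
  $\widehat K$ carries $O(1/\sqrt m)$ entry noise into $P_{corr}$
  (about 2--3% at $n = 2100$, $m = 1000$ -- visible as slight
  over-dispersion of the corrected statistic, well inside the acceptance
  bands).
* Permutation p-values have granularity $1/B$; at $B = 500$ the smallest
  achievable p-value is 0.002, which limits the resolvable significance
  level in power studies.
* The collapsing variance uses the pooled $\hat p = \bar Z$; under
  extreme case:control imbalance a GLS-weighted estimate (provided as an
  option) is preferable.
* `mix_cc` ("half family, half case-control") follows one reading of an
  ambiguous description; the composition is configurable through the
  design list.
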