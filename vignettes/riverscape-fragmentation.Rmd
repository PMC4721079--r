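---
title: "Methods: quantifying river fragmentation from microsatellite genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying river fragmentation from microsatellite genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery of riverpopgen: the
estimators, the candidate-model set, the simulator that stands in for real
data, and the numerical and design choices a maintainer would want
explained. The running system is a lowland river catchment fragmented by
hydroelectric power stations (most with fishpasses), a few fishpass-free
stations and weirs, and one natural falls; the data are codominant diploid
microsatellite genotypes sampled at sites spread over the network.

## Diversity estimators

Expected heterozygosity uses Nei's unbiased gene diversity,
$\hat H_e = \frac{2n}{2n-1}\bigl(1-\sum_k p_k^2\bigr)$, with $n$ the
non-missing diploid count at the locus and site. Multilocus $H_o$, $H_e$
and AR are unweighted means over loci, the convention of the classical
F-statistics packages; alternates (weighting by sample size) would change
third-decimal results only and are not offered.

Allelic richness is hypergeometric rarefaction to a common number of gene
copies: the expected number of distinct alleles among $2g$ copies drawn
without replacement from the $2n$ sampled,
$AR(g)=\sum_k\bigl[1-\binom{2n-N_k}{2g}/\binom{2n}{2g}\bigr]$. The
rarefaction size is expressed in diploid individuals ($g$ diploids = $2g$
copies) because field studies standardize on the smallest per-site sample
size; the default $g$ is the smallest per-locus non-missing count over all
sites and loci, and a locus with fewer than $g$ genotypes at some site is
skipped there with a warning rather than extrapolated. Binomials are
evaluated as `exp(lchoose(...) - lchoose(...))`, which is exact to within
double rounding and returns 0 cleanly when $2n-N_k < 2g$. AR($g$) is
non-decreasing in $g$ and equals the observed allele count at $g=n$; both
properties are tested.

$F_{IS}$ is the Weir–Cockerham within-population $f$: per allele,
$b = \frac{n}{n-1}\bigl[p(1-p)-\frac{2n-1}{4n}h\bigr]$ and $c = h/2$ with
$h$ the proportion of individuals heterozygous for that allele, combined
over alleles and loci as $f = 1-\sum c/\sum(b+c)$. Ratio-of-sums
combination (not mean-of-ratios) is what makes multilocus $f$ robust to
near-monomorphic loci; a site with no polymorphic locus has no information
and returns `NA` flagged rather than 0. Significance is by permuting
alleles among individuals within the site (missingness pattern preserved),
two-sided on $|f|$, with the $+1$ correction so $p \in (0,1]$.
Hardy–Weinberg scans run the same permutation test per locus and site.

## Differentiation

Pairwise and global $F_{ST}$ use the Weir–Cockerham variance components
$a$ (among populations), $b$ (among individuals within) and $c$ (within
individuals), computed per allele with unequal sample sizes and summed over
alleles and loci: $\hat\theta = \sum a / \sum(a+b+c)$. Negative estimates
are retained — truncating at zero would bias the downstream regressions.
Loci monomorphic in the pooled pair carry no information and are dropped
for that pair; a locus entirely missing at one member of a pair likewise.
The pairwise path precomputes per-locus site summaries (allele frequencies
and heterozygote proportions) and is verified against the general
estimator to $10^{-12}$ and against naive definitional arithmetic to
$10^{-10}$.

Uncertainty is by bootstrap over loci. With a typical microsatellite panel
(9 loci) the percentile interval is coarse — resamples tie heavily — and is
documented as such; this mirrors the behaviour of the classical software.
An optional permutation test shuffles genotypes between the two sites.

## LD effective population size

For each locus pair, Burrows' composite disequilibrium is computed per
allele pair on the individuals scored at both loci:
$\hat\Delta_{AB} = \frac{S}{S-1}\bigl(\frac{1}{S}\sum_i X_iY_i/2 -
2\hat p_A\hat p_B\bigr)$ with $X,Y$ allele dosages, squared and normalized
by $[p_A(1-p_A)+(P_{AA}-p_A^2)][p_B(1-p_B)+(P_{BB}-p_B^2)]$ — the
composite denominator that does not assume Hardy–Weinberg. Alleles are
screened to frequency strictly above $P_{crit}$ (default 0.02, the
recommended rare-allele cutoff; "strictly" because the rule excludes
frequencies *at* the cutoff). Locus-pair $r^2$ values are averaged with
the pair sample size $S$ as weight, the random-mating sampling expectation
$E[r^2|S]=1/S+3.19/S^2$ (for $S\ge30$; the small-$S$ coefficients are used
below that) is subtracted, and
$\hat N_e = \bigl(1/3+\sqrt{1/9-2.76\,r^2_{drift}}\bigr)/(2\,r^2_{drift})$.
A non-positive drift residual means no detectable drift signal and maps to
$\infty$, which is legitimate output (serialized as `"inf"` in CSVs); a
negative discriminant is clamped to zero. Confidence intervals jackknife
over locus pairs on the adjusted-$r^2$ scale and transform the normal
bounds through the (monotone) $N_e$ map, so the interval always brackets
the point estimate. The mating-model variant (random mating, not
monogamy) and the jackknife unit are the classical defaults; simulation
shows median $\hat N_e \approx 50$ and ~86% interval coverage at a true
size of 50 with 9 loci and $S=50$.

## Mantel machinery

Mantel $R$ is the Pearson correlation of the off-diagonal vectorizations
(a fixed lower-triangle order shared by every pairwise consumer in the
package). Significance permutes site labels — rows and columns together —
of one matrix; tests are one-sided for positive association by default
because the isolation-by-distance and isolation-by-barrier hypotheses are
directional (two-sided by flag). The partial test residualizes both the
response and the predictor on the covariate, then permutes the
*residualized response matrix* by site label (Smouse–Long–Sokal), which
preserves the covariate structure under the null. Perfect collinearity of
predictor and covariate is refused. Monte-Carlo p matches full
enumeration on 5-site problems and is uniform under the null (KS-checked).

## Candidate models, AIC and commonality

Six nested-and-crossed candidate regressions of pairwise $F_{ST}$:
(i) distance; (ii) + all barriers; (iii) distance + barriers without
fishpass (incl. the falls) + barriers with fishpass; (iv) distance +
falls; (v) distance + falls + all other barriers; (vi) distance + falls +
fishpass + no-fishpass counts. Pairwise responses are not independent;
following the riverscape literature the coefficients are reported as
fitted, while (a) AIC uses the number of populations as $n$ —
$AIC = n\ln(RSS/n) + 2k$, $k$ = intercept + slopes — and (b) coefficient
inference is by Freedman–Lane permutation (residuals of the reduced model
permuted onto its fitted values, $|t|$ compared). The Gaussian constant
and the variance parameter shift all candidates equally and cancel in
$\Delta AIC$; with $k$ = intercept + slopes the machinery reproduces the
published $\Delta AIC$ column of the reference system from its printed
$R^2$ values to within 0.03, which is the validation for that convention.
Exactly collinear designs are refused by a QR rank check rather than
silently dropped.

Commonality analysis fits all $2^p-1$ predictor subsets and combines their
$R^2$ via
$C(T) = -\sum_{S\subseteq T}(-1)^{|S|}R^2((V\setminus T)\cup S)$; the
coefficients sum to the full-model $R^2$ and unique + common per predictor
equals its squared simple correlation, both asserted to $10^{-10}$ in
tests. The subset count is capped at 6 predictors. Virtual distance is
the ratio $\beta_{barrier}/\beta_{distance}$, in km per barrier; it is
scale-equivariant under unit changes and deliberately undefined (with a
warning) when the distance slope is non-positive, which happens in
simulated systems whose differentiation is dominated by barriers.
Cumulative barrier age is computable from the barrier tables but excluded
from the candidate set: it is nearly collinear with barrier count
($r \approx 0.97$ in the reference system), so its effect cannot be
separated.

## Stream-tree model

Pairwise genetic distance is modelled as the sum of non-negative section
distances along the unique tree path: minimize $\|Ad-f\|^2$ with $A$ the
pairs × sections incidence matrix, subject to $d\ge0$ by default. The
prevalence of exact zeros in published fits indicates an active constraint
in the original method, hence non-negativity on by default; the
unconstrained solver (QR) is available and its residuals are checked
orthogonal to the design. Sections traversed by no site pair are reported
unidentifiable (never silently zero); sections with identical incidence
columns are estimable only as a group and are merged with the merge map
reported — the fitted value shown for each member is the group total.
Loop-flagged edges (a canal closing a drainage loop) are never routed;
sites whose paths would need them should be excluded via
`exclude_sites`, matching the practice of restricting the model to a tree.

## The simulator: what it emulates, and what not

`run_forward()` places a Wright–Fisher deme of $N$ diploids on every
network node (rivers are populated everywhere, confluences included).
Each generation, every offspring first draws a source deme — at rate $m$
per adjacent deme, multiplied by the permeability of each barrier on the
connecting section ($p_{fishpass}$, $p_{nofishpass}$, $p_{falls}$) and
divided by the downstream-bias factor when moving upstream — then two
parents from that deme, inheriting one allele per parent per locus with
stepwise mutation ($\pm1$ repeat, reflecting at 5–60). Migration precedes
reproduction; generations do not overlap. The defaults are the study-like
conditions used throughout the tests: $N=200$, $m=0.1$,
$p_{fishpass}=0.7$, $p_{nofishpass}=0.1$, $p_{falls}=0.05$, bias 1.5,
$\mu=5\times10^{-4}$, 9 loci, burn-in $10N$ generations, 45 diploids
sampled per site. $m=0.1$ reflects the high connectivity of a mobile
cyprinid between adjacent river reaches; $\mu=5\times10^{-4}$ is a
standard microsatellite rate; the permeabilities encode the planted
contrast "fishpasses leak, fishpass-free barriers nearly block".

The simulator reproduces the *statistical* structure the analyses assume —
drift–migration equilibrium on a dendritic graph, barrier-typed
attenuation, stepwise-mutation allele distributions, Hardy–Weinberg and
linkage equilibrium within demes — and deliberately not the biology of an
iteroparous, long-lived fish (no age structure, no overlapping
generations, no density dependence) nor geometry below the node scale:
migration between adjacent demes does not depend on section length, so
waterway distance acts on the genetics only through the number of
intervening demes and barriers. Passing recovery tests therefore shows
the estimators detect what was planted under the model's assumptions, not
that real rivers satisfy those assumptions.

Two deliberate deviations from mutation–drift realism serve specific
experiments. For LD-$N_e$ calibration at small true size (50), demes are
founded from a diverse eight-allele pool and run ~40 generations instead
of to equilibrium: at $N_e=50$ and realistic $\mu$, equilibrium diversity
($4N\mu\approx0.1$) would leave almost no allele above the screening
cutoff, while the drift LD that the estimator measures equilibrates within
a few generations. And with `burnin = 0` the founders themselves are the
sample — iid draws, hence an exact null for Hardy–Weinberg and LD
calibration, used for the 423-test chance-level check (47 sites × 9 loci
at $\alpha=0.05$ gives 21.15 expected rejections).

The bundled `example_riverscape()` is entirely synthetic: 36 sites plus
confluences (40 demes), one main stem with a natural falls, a large and
two small tributaries, 33 fishpass barriers, 5 without, one falls — the
reference system's barrier inventory on an invented geometry, including
its statistical nuisances (distance–barrier collinearity, a barrier-dense
tributary near the mouth, free-flowing stretches).

## Problem sizes and seeds

The test suite and the acceptance script run, as the package's chosen
study sizes: 50 study-scale recovery replicates (40 demes × 200 diploids,
burn-in 2000 generations); 200 LD-$N_e$ replicates at true size 50; 100–
200-replicate Monte-Carlo property checks elsewhere; 10 000 permutations
for headline Mantel runs and 99–999 wherever a p-value only needs rank
accuracy. Every stochastic step is seeded; `sim_config()` carries its
seed, and the pipeline writes all seeds to its run log.

## Known limitations

* Bootstrap-over-loci intervals are coarse with few loci (ties).
* The LD-$N_e$ jackknife interval is a normal approximation on the
  $r^2$ scale; its ~86% coverage at nominal 95% in the calibration
  experiment is consistent with the known anti-conservatism of the method
  at small locus numbers.
* Pairwise-regression coefficients inherit the non-independence of pairs;
  only the AIC $n$ and the permutation tests compensate, as in the
  riverscape literature — standard errors from these fits should not be
  quoted.
* The stream-tree $R^2$ is computed on the pairwise vector; with the
  non-negativity constraint active it is not guaranteed to exceed naive
  baselines for adversarial inputs, though tests check it beats a
  constant-rate strawman on random data.
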