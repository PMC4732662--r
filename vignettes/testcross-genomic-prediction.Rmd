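---
title: "Genomic prediction of testcross performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction of testcross performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tcrossgs` implements a complete genomic-selection analysis for hybrid
breeding programmes that evaluate candidate pollinator lines through
testcrosses: each candidate is crossed to a small set of common (male-sterile)
testers, the hybrids are grown in unreplicated multi-location trials, and the
candidate's value is summarised by its general combining ability (GCA). The
package covers marker quality control, population-structure inference,
phenotype modelling, a ridge-regression BLUP (RR-BLUP) mixed model, and a
repeated-random-split cross-validation engine, plus a synthetic-data
generator with known truth that makes every stage testable.

This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic data do and do not
establish about behaviour on real panels.

## Phenotype model

Trials are unreplicated within location, so the observation for hybrid
$i$ (pollinator x tester) at location $l$ is modelled additively:

$$ y_{il} = \mu + g_i + \ell_l + \varepsilon_{il}. $$

Two fits of this model serve different purposes:

* **BLUEs** (`fit_blues()`): hybrids fixed, locations fixed with sum-to-zero
  contrasts, solved by least squares. The hybrid BLUE is its expected value
  at the average location; with complete balanced data this reduces to the
  plain mean across locations, and with missing cells it corrects for the
  location effects a plain mean would absorb.
* **Variance components** (`estimate_variance_components()`): hybrids random
  with variance $\sigma^2_g$, locations fixed, residual variance
  $\sigma^2_\varepsilon$, estimated by REML via `lme4::lmer`. Treating the
  hybrid as fixed for estimation of its value but random for variance
  partitioning is the standard reading when BLUEs and REML components are
  reported side by side. No genotype-by-location interaction is fitted: with
  one replicate per location it is confounded with the residual.

Broad-sense heritability is computed on the trial-mean basis,

$$ H^2(\%) = 100\,\frac{\sigma^2_g}{\sigma^2_g + \sigma^2_\varepsilon/n}, $$

with $n$ the number of locations: the unit of selection is a hybrid mean
over $n$ locations, so the residual is divided by $n$.

```{r, eval = FALSE}
broad_sense_heritability(1.56, 7.95, n_locations = 4)   # 43.97 -> "44%"
```

**GCA** (`compute_gca()`) is the mean of a pollinator's hybrid BLUEs over
its available testers, expressed as a deviation from the grand mean of all
hybrid BLUEs for the trait. The source material never writes its GCA formula;
this definition was chosen because (a) it is the textbook estimator for a
testcross design with common testers and (b) in a purely additive, noiseless
simulation it recovers the true breeding values up to an affine transform
(correlation > 0.9999 in the test suite). Centring is global rather than
per tester pool; with both testers present for every pollinator the two
choices differ only in the tester main effect, which GCA averages out.

## RR-BLUP mixed model

The prediction model is

$$ y = W\beta + X a + e, \qquad
   a_j \sim N(0, \sigma^2_a), \quad e \sim N(0, \sigma^2_e I), $$

with $y$ the per-line GCA (or BLUE) vector, $X$ the $N \times N_m$ additive
marker matrix coded $-1/0/+1$ (mean-imputed; heterozygote 0 occurs only
through imputation since the lines are inbred), and $W$ an intercept plus
optional fixed covariates such as cluster indicators. All markers share one
effect variance, $\sigma^2_a = \sigma^2_G/N_m$ — the defining RR-BLUP
assumption.

`fit_rrblup()` estimates the single variance ratio
$\delta = \sigma^2_e/\sigma^2_a$ by REML, profiling the restricted
likelihood through the spectral decomposition of $K = XX^\top$ projected
onto the complement of the fixed-effect space. The decomposition is done on
the $N \times N$ line space (not marker space) because $N \approx 475 \ll
N_m \approx 24{,}403$. Numerical details that matter:

* The projected matrix actually decomposed is $S(K + I)S$ with the
  eigenvalues shifted back by one. This pins the fixed-effect null space at
  eigenvalue exactly 0 and keeps it out of the retained spectrum; naively
  decomposing $SKS$ lets the degenerate null space leak into the profile
  when $N_m < N$.
* The ratio is optimised on $\log\delta \in [-10, 10]$ (natural log) by
  golden-section search with tolerance $10^{-8}$. A noiseless response
  drives the optimum to the lower boundary, where training predictions
  reproduce $y$ to $\sim\delta/\mathrm{eig}(K)$.
* Given $\hat\delta$, fixed effects are GLS estimates and marker effects are
  their BLUP $\hat a = X^\top (K + \hat\delta I)^{-1}(y - W\hat\beta)$ —
  algebraically identical to ridge regression with penalty
  $\lambda = \hat\delta$ and an unpenalised intercept. The test suite
  verifies this identity against `ridge_fixed_lambda()` to $10^{-6}$, and
  verifies equivalence with the kinship (GBLUP) formulation under arbitrary
  rescaling of $K$.

## Population structure

* **Rogers distance** (`rogers_distance()`): the per-locus Euclidean
  distance between within-individual allele-frequency vectors, averaged over
  loci. For additive coding this collapses to $|x_i - x_j|/2$ per locus,
  bounded in $[0,1]$. The inner pairwise kernel is compiled (Rcpp); the full
  475 x 24,403 panel takes a few seconds.
* **PCoA** (`pcoa()`): Gower double-centring of $-\tfrac12 D^2$ and
  eigendecomposition; coordinates are eigenvectors scaled by
  $\sqrt{\lambda}$. Rogers distances need not be Euclidean, so negative
  eigenvalues can occur; they are excluded from both the coordinates and the
  explained-variance denominator. Reconstruction of Euclidean-embeddable
  inputs is tested to $10^{-8}$ against `stats::cmdscale` as an independent
  oracle.
* **K-means + Caliński–Harabasz** (`kmeans_cluster()`, `select_k()`):
  clustering operates on the leading PCoA coordinates (default 4 axes) —
  the leading axes concentrate the between-group signal, and the published
  analyses report exactly four. The clustering space is configurable via
  `axes` since the original choice is not documented. K-means uses
  `stats::kmeans` (Hartigan–Wong) with `n_restarts` = 50 independent starts
  under a fixed seed; Hartigan–Wong with many restarts finds equal or better
  optima than plain Lloyd and there is no reason to re-implement a base-R
  facility. The cluster count maximises the CH index
  $[B/(k-1)]\,/\,[W/(n-k)]$ over `k_range` (ties break toward the smallest
  $k$); with one point per cluster ($k = n$) the partition is returned
  directly with zero within-cluster variance.

## Cross-validation engine

`run_cv()` repeats, for `n_rounds` (default 500): draw a training population
of `round(tp_fraction * N)` lines (default 70 %) uniformly without
replacement from the scenario's sampling frame, fit RR-BLUP on it, predict
the held-out lines, and record the prediction accuracy
$r_{GPA} = r(y, \hat y)$ (Pearson). The summary is the mean over rounds with
its standard error $\mathrm{sd}/\sqrt{\text{rounds}}$ (the source material
prints "approximate standard errors" without a formula; the SEM over rounds
is the natural choice). Rounds with a degenerate validation set (zero
variance) are excluded from the mean and counted. Every round's seed is
derived from the master seed by a documented scheme (`stage_seed()`), so any
single round can be reproduced in isolation.

Scenarios (`run_scenario()`):

* `whole_population` — frame is all lines;
* `within_cluster` — frame restricted to one cluster (refused below 15
  lines, where a 70/30 split stops being meaningful);
* `cross_cluster_train` — training drawn from the whole population,
  validation restricted to the target cluster's held-out members, with the
  training size matched to the within-cluster scenario so the comparison is
  size-controlled (the exact sizing rule of the original analysis is not
  documented; size-matching removes the known confounder);
* `structure_covariate` — whole-population split with cluster-indicator
  columns in $W$ for both fit and prediction. Note that because the
  covariate also enters prediction, data whose only signal is a cluster mean
  shift remain predictable; what the covariate does is absorb between-cluster
  signal out of the *marker* effects, which the test suite checks directly.

`tp_sweep()` traces accuracy against training fraction (default 10–90 %),
each fraction under an independently derived seed.

## Synthetic-data generator

`simulate_structured_genotypes()` draws, per marker, an ancestral allele
frequency uniform on $[0.1, 0.9]$ and per-subpopulation frequencies from the
Balding–Nichols beta model
$p_s \sim \mathrm{Beta}(p(1-F)/F,\ (1-p)(1-F)/F)$; lines are fully
homozygous ($\pm1$), missing calls are injected after truth is computed.
Defaults emulate the motivating study design: 475 lines in subpopulations of
286/147/42, 24,403 markers, 2 testers, 4 locations. Values the study does
not pin down were fixed once at field-realistic levels:

* `fst = 0.15` per subpopulation — modest divergence typical of related
  breeding pools rather than maize-style heterotic groups (at this level the
  structure pipeline still recovers the three designed clusters exactly);
* `missing_rate = 0.02` — a typical post-calling array missing rate (the QC
  threshold of 20 % is far above it);
* `n_qtl = 100`, normally distributed effects — a polygenic but not
  infinitesimal architecture;
* `sca_variance_fraction = 0.1` — the study reports GCA variance dominating
  SCA variance without quantifying it; 10 % makes the non-additive term
  present but minor.

`simulate_testcross_phenotypes()` builds
$y = \mu + GCA_p + T_t + SCA_{pt} + L_l + e$ with fixed tester and location
offsets (location is a nuisance absorbed by the BLUE step, hence fixed, not
random) and calibrates the residual variance against the *realised* hybrid
genetic variance so that $H^2$ on the $n$-location basis equals `h2_target`
exactly; parameter-recovery tests confirm the REML estimate lands within
±0.05 of the target on average over 50 seeds.

Two model facts worth recording, both verified empirically in the test
suite:

* For fully inbred $\pm1$ lines the per-locus genotypic variance is
  $4p(1-p)$, not the random-mating $2p(1-p)$, so
  $\mathrm{var}(GCA) \to \sum_q 4 p_q(1-p_q) a_q^2$ — the classical doubling
  of additive variance under complete inbreeding.
* Under Balding–Nichols, subpopulation frequencies are drawn independently
  around the ancestral frequency, so the *expected between-subpopulation*
  distance does not change with $F$; it is the within-subpopulation
  distance that shrinks (by the factor $1-F$), and therefore the
  between-minus-within contrast that grows. The divergence test asserts the
  contrast, not the raw between-group mean.

## What the synthetic study does and does not show

The generator reproduces the study's *design* (population sizes, structure,
trial layout, heritability spectrum) but deliberately omits linkage:
markers are unlinked, and recombination/linkage maps are out of scope. That
has a predictable consequence for whole-panel prediction accuracy, which is
bounded by roughly $\sqrt{Nh^2/(Nh^2 + M_e)}$ with $M_e$ the number of
*independent* marker segments. On a real array panel, linkage
disequilibrium collapses ~24k markers onto a few hundred effective segments
and accuracies of 0.3–0.8 result; with ~6,000 truly independent simulated
markers the same engine honestly yields accuracies near 0.2. The acceptance
script therefore reports both regimes: the full-density study (structure,
heritability, GCA recovery) and a segment-scale study (500 markers,
matching the effective dimension of an LD-rich panel) whose accuracies land
in the real-data range and reproduce the expected ordering in heritability
and the 70→90 % training-size plateau. Passing tests establish the
correctness of the machinery and its statistical calibration — not that
unlinked-marker simulations reproduce LD-driven accuracy levels, which they
cannot by construction.

## Problem sizes used in the automated checks

The test suite exercises the full 475 x 24,403 panel once (structure +
phenotype path, a few seconds with the compiled distance kernel) and runs
all stochastic calibrations at reduced sizes chosen so the whole suite
completes in well under a minute: cluster recovery at 100 lines x 2,000
markers over 20 seeds, heritability recovery at 400 lines over 50 seeds,
cross-validation properties at 150–250 lines x 500–1,500 markers with
10–50 rounds. The acceptance script uses the full population with 6,000
markers and 100-round cross-validations. These sizes are the package's own
trade-off between Monte Carlo error and turnaround; all of them can be
scaled up through the exported configuration objects.

## Known limitations

* No linkage, recombination or multi-generation breeding; SCA is a single
  independent draw per hybrid (no epistasis).
* No genotype-by-location interaction term (unidentifiable in unreplicated
  single-year trials) and no multi-year modelling.
* REML variance components are clipped at zero by the fitting machinery;
  traits with essentially no genetic variance return $H^2 \approx 0$ rather
  than an error.
* `import_vcf()` assumes biallelic SNPs and skips multi-allelic records
  with a count rather than attempting to decompose them.
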