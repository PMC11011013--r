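---
title: "Weighted Bayesian whole-genome regression: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted Bayesian whole-genome regression: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Genomic selection in dairy cattle predicts an animal's additive genetic
merit — its molecular breeding value (MBV) — from genome-wide SNP
genotypes. The workflow implemented here is the one used in practice for
body-conformation traits in Holstein populations: SNPs pass quality
control; estimated breeding values (EBVs) from a national evaluation are
deregressed into quasi-independent response records with
reliability-based weights; marker effects are estimated by weighted
BayesB or BayesC mixture regression over a grid of prior null-marker
proportions $\pi$; the posterior genetic variance is partitioned into
1-Mb windows to locate trait-associated regions; and prediction accuracy
is estimated by cross-validation with folds built to minimize pedigree
relatedness between training and validation animals.

Because evaluation data of this kind are proprietary, the package ships
a synthetic-data generator that reproduces the *statistical contracts*
each stage assumes — a multi-generation pedigree, gene-dropped
genotypes, spike-and-slab trait architectures, and EBV records whose
reliabilities keep their textbook meaning. Every stage is tested against
those contracts.

## Models

### Deregression and record weights

An EBV is a shrunken predictor: `EBV = r² · TBV + noise` with
reliability $r^2 = \mathrm{cor}^2(\mathrm{EBV}, \mathrm{TBV})$. Using
EBVs directly as responses double-shrinks; deregression removes the
shrinkage. Two modes are provided:

* **incPA** — the full-information deregression
  $\mathrm{DEBV} = \mathrm{EBV}/r^2$, with reliability unchanged.
  Re-multiplying by $r^2$ recovers the EBV exactly, a round-trip the
  tests pin to $10^{-8}$.
* **excPA** — removes the parent-average (PA) contribution first. The
  EBV is modelled as the solution of 2×2 mixed-model equations in a PA
  effect (prior variance $\sigma_a^2/2$) and the animal's own effect,
  with $\lambda = (1-h^2)/h^2$:
  $$\begin{pmatrix} Z'_{PA}Z_{PA} + 4\lambda & -2\lambda \\
  -2\lambda & Z'_iZ_i + 2\lambda \end{pmatrix}
  \begin{pmatrix}\widehat{PA}\\ \widehat{g}_i\end{pmatrix} =
  \begin{pmatrix}y_{PA}\\ y_i\end{pmatrix}.$$
  The effective record contributions $Z'Z$ are unobserved but are
  recoverable from the reported reliabilities: writing
  $r^2_{PA,\mathrm{eff}} = (r^2_s + r^2_d)/2$ (the PA *effect*
  reliability; the familiar predictor reliability
  $(r^2_s + r^2_d)/4$ is half of it because the PA effect has prior
  variance $\sigma_a^2/2$, not $\sigma_a^2$), the quantity
  $b = Z'_iZ_i + 2\lambda$ solves
  $b^2(1-r^2) - \lambda b - 2\lambda^2(1 - r^2_{PA,\mathrm{eff}}) = 0$,
  taken at its positive root. The deregressed record is
  $y_i/Z'_iZ_i$ with $y_i = -2\lambda\,PA + (Z'_iZ_i + 2\lambda)\,EBV$
  and reliability $Z'_iZ_i/(Z'_iZ_i+\lambda)$. The boundary
  $Z'_iZ_i = 0$ falls exactly at $r^2 = (r^2_s+r^2_d)/4$: an EBV that is
  parent average and nothing else. Such animals are dropped with a
  logged reason. The test suite validates the inversion against a
  forward-map oracle: choose $Z'Z$ values, build the coefficient matrix,
  read reliabilities off its inverse, and demand the code recover the
  $Z'Z$ values exactly.

Records are weighted by
$$w = \frac{1-h^2}{\left[c + (1-r^2)/r^2\right]h^2},$$
where $c$ is the fraction of genetic variance the markers cannot
capture, 0.4 by default. The printed rendering of this formula is
typographically ambiguous (the trailing $h^2$ could multiply or
divide); the form above is the one in the deregression literature and
makes reliable records weigh more, which is the behaviour a weighting
factor is for. The alternative flat reading,
$(1-h^2)[c+(1-r^2)/r^2]/h^2$, is available via `form = "flat"` on
`garrick_weight()` for comparison.

### Weighted BayesB/BayesC

The regression model is
$$y_i = \mu + \sum_{j=1}^{k} Z_{ij}\,u_j\,\delta_j + e_i,\qquad
e_i \sim N(0, \sigma_e^2 / w_i),$$
with $\delta_j$ a 0/1 inclusion indicator, $P(\delta_j = 0) = \pi$, and
$u_j \sim N(0, \sigma_{u_j}^2)$ when included. BayesB gives each locus
its own scaled-inverse-$\chi^2$ variance (a t-like marginal prior);
BayesC shares one variance across included markers. The Gibbs sweep
updates, in order: $\mu$; each $(\delta_j, u_j)$ with $u_j$ integrated
out analytically when sampling $\delta_j$ (the standard GenSel-style
collapsed update, which mixes far better than joint proposals); the
marker variance(s); and $\sigma_e^2$ with the per-record weights. The
production schedule is 110,000 iterations, 10,000 burn-in, thinning by
10 — exactly 10,000 retained samples; tests and examples use shorter
chains with the same arithmetic.

Numerical and prior choices:

* Genotypes are centered by twice the allele frequency **of the
  training animals only**, so cross-validation folds leak nothing from
  validation animals. Predictions re-use the training centering.
* The internal coding is 0/1/2 dosages. The GenSel −10/0/10 dialect is
  an exact affine conversion; marker effects scale by 1/10 between the
  conventions and predictions are invariant (tested).
* Marker-effect prior: df 4.2 with scale solved so the prior mean
  variance spreads the target genetic variance over the expected
  included heterozygosity $(1-\pi)\sum_j 2p_jq_j$. 4.2 is the customary
  default in the GenSel lineage; the df is exposed in the configuration
  because analyses differ on it.
* Residual prior: df 4, scale from the target residual variance
  (default: half the weighted response variance).
* `pi = 0` with fixed variances collapses BayesC to weighted
  ridge regression; the suite checks posterior means against the
  closed form $(Z_c'Z_c + \lambda I)^{-1}Z_c'y$ within 3 Monte-Carlo
  standard errors.
* $\mu$ is the only fixed effect, as in the model statement.

### Window variance partitioning

Each SNP belongs to the 1-Mb window
`chr_Mb`, `Mb = floor((pos − 1)/10^6)`; windows are closed on the right
in bp (position 1,000,000 is still window 0). For **every retained
sample** the window genomic values $g_w = Z_{c,w}u_w$ are computed and
the window's share is $\mathrm{var}(g_w)/\sum_{w'}\mathrm{var}(g_{w'})
\times 100$, variance across animals with the population ($1/n$)
denominator — shares are scale-free, so the denominator choice is inert
(tested). Averaging shares over samples gives the reported GV%.
Averaging per sample rather than plugging in posterior-mean effects
matters: mixture posteriors concentrate variance in different markers in
different samples, and posterior-mean effects understate window
variance. Normalizing by the *sum of window variances* rather than the
variance of the summed genomic values makes shares sum to exactly 100
within every sample; with unlinked loci the two denominators differ
negligibly, and the exact-partition property is the more useful
invariant.

A window is significant when its GV% meets the threshold, 1.0% by
default. With 2,524 windows the infinitesimal expectation is
$100/2524 \approx 0.04\%$ per window, so the 1% threshold is a 25-fold
enrichment. Nearest-gene annotation labels SNPs genic (distance 0) or
intergenic with the bp distance to the closest gene span, reporting all
equidistant genes in symbol order.

### Relationship matrix and relatedness-minimizing folds

The pedigree numerator relationship matrix is built by Henderson's
tabular recursion with inbreeding. Its correctness is checked two ways:
textbook rational values on toy pedigrees, and exhaustive agreement with
an independent Wright path-counting oracle over every valid
parent-assignment pedigree of four animals (273 structures) plus seeded
random pedigrees of five to eight.

Folds for cross-validation cluster animals on the distance
$d_{ij} = 1 - a_{ij}/\sqrt{a_{ii}a_{jj}}$; of the several ways to turn
a relationship matrix into a distance matrix, this normalization was
chosen so inbred diagonals do not distort distances. Clustering uses a
classical MDS embedding (components covering ≥ 90% of the positive
eigenvalue mass, capped at 20) and K-means with 25 restarts by default,
keeping the best inertia. MDS + Lloyd was chosen over medoid clustering
for scalability. Per-fold diagnostics mirror the usual reporting: mean
inbreeding, mean of per-animal maximum relationships within and between
folds, and mean pairwise relationships within and between, plus an
unweighted average row.

Accuracy is the Pearson correlation between MBV and the deregressed
response within each validation fold — deliberately *not* divided by
$\sqrt{h^2}$ or mean reliability, so the reported number is the raw
predictive correlation on the response scale; a reliability-scaled
variant sits behind `scale = "reliability"`. The summary is the
unweighted fold mean with standard error $\mathrm{sd}/\sqrt{k}$ across
folds ($k = 5$ by default).

## The synthetic-data generator

* `simulate_pedigree()` — discrete non-overlapping generations, random
  pairing without selfing, fixed offspring per mating.
* `gene_drop_genotypes()` — founder MAFs uniform on a configurable
  interval, founders in Hardy–Weinberg proportions, Mendelian
  transmission at unlinked loci. No linkage map is simulated: the
  analyses here do not require LD at desk scale, and window-level tests
  instead plant clustered causal loci in chosen windows via
  `simulate_trait(causal_idx = ...)`.
* `simulate_trait()` — spike-and-slab effects ($\delta_j \sim
  \mathrm{Bern}(1-\pi)$, normal slab rescaled so the realized genetic
  variance of centered dosages hits the target exactly), unit
  phenotypic scale ($\sigma_a^2 = h^2$, $\sigma_e^2 = 1 - h^2$).
* `simulate_ebv_records()` — reliabilities uniform on
  `[rel_low, rel_high]`, `EBV = r²·TBV + e` with
  `var(e) = r²(1−r²)σₐ²`, which makes $\mathrm{cor}^2(EBV, TBV) = r^2$
  by construction; parent EBVs join from the same table.
* `corrupt_for_qc()` — injects the three QC failure modes (missingness
  strictly above 5%, sample MAF strictly below 0.01, forced
  heterozygote excess) and returns the manifest so filter tests can
  demand exact recovery.

What the generator does **not** emulate: linkage disequilibrium,
selection and assortative mating, genotyping-error models beyond the QC
failure modes, multi-panel structure and imputation (the package works
with one complete post-QC panel), or a real multi-trait national
evaluation behind the EBVs. Passing tests therefore demonstrate the
pipeline's internal correctness and its behaviour under the stated
statistical contracts — not that real Holstein accuracies or specific
QTL windows would be reproduced, which would require the proprietary
data.

## Tunable parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `pi` | 0.99 | prior fraction of null markers; analysis grid 0.75/0.90/0.99/0.995 |
| `c` | 0.4 | genetic variance not captured by markers, in the record weight |
| chain | 110000 / 10000 / 10 | iterations / burn-in / thinning (10,000 kept) |
| `nu_effects` | 4.2 | marker-variance prior df (t-like tails) |
| QC thresholds | 0.95 / 0.01 / 1e-4 | call rate / MAF / HWE p; strictly-below removes |
| `k`, `restarts` | 5, 25 | folds and K-means restarts |
| `window_mb`, `gv_threshold` | 1, 1.0 | window width and significance level |

## Degenerate inputs and tie rules

Monomorphic SNPs get MAF 0 and fall to the MAF filter; SNPs with no
calls are filterable by call rate with undefined MAF/HWE. HWE uses the
Pearson 1-df $\chi^2$ by default (the classical choice, monotone enough
at the 1e-4 threshold; an exact conditional test is a flag away).
Filters apply sequentially — map, call rate, MAF, HWE — so per-criterion
counts are unambiguous and sum to the total, and the filter is
idempotent. In annotation, equidistant genes are all reported in symbol
order. Samples with zero total genetic variance are skipped in window
profiling with a logged count. K-means ties are resolved by the
best-inertia restart under a fixed seed.

## Problem sizes used in the checks

The shipped checks run the full pipeline at n = 1,000–1,200 animals and
k = 1,000–2,000 markers with chains of 1,500–3,000 iterations — sizes
chosen so the whole suite exercises every stage, including ten-seed
recovery runs and five-seed cross-validation comparisons, in a few
minutes on a laptop while leaving the statistical margins wide (e.g.
recovery correlations near 0.99 against a 0.4 requirement).

## Known limitations

* Unlinked loci mean no realistic LD decay; window GV under a *null*
  trait is heavy-tailed when $\pi$ is high and the marker count small,
  so null-calibration checks use the dense-mixture regime
  ($\pi = 0.75$) where the posterior spreads thinly across windows.
* BayesB's locus variances are summarized by their mean in the variance
  trace; per-locus variance traces are not stored.
* The excPA reliability algebra assumes the two-proof decomposition
  (parent average + own/progeny); genomic information in the original
  EBVs would violate it.
* `pi` is fixed per run, never estimated from the data.
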