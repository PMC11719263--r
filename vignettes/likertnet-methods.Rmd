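---
title: "Methods: partial-correlation networks for ordinal survey items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: partial-correlation networks for ordinal survey items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likertnet)
```

## The model

`likertnet` analyses a respondents-by-items table of 5-point ordinal
scores split into two declared communities (lifestyle items and health
outcomes). The statistical object is a Gaussian graphical model: nodes are
items, and the weight of edge *(i, j)* is the partial correlation

$$w_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii} K_{jj}}},$$

where $K$ is the precision (inverse covariance) matrix. A zero weight means
conditional independence given all other items. $K$ is estimated by the
graphical lasso,

$$\hat K = \arg\max_{K \succ 0}\; \log\det K - \operatorname{tr}(SK)
  - \lambda \sum_{i \ne j} |K_{ij}|,$$

with $S$ the item correlation matrix. The solver (block coordinate descent
over columns, each block an inner lasso, warm-started along the path) is
implemented in C++ in `src/glasso.cpp`; the diagonal is not penalised. The
penalty is chosen by minimising the extended BIC over a path of 100
log-spaced values from $\lambda_{\max} = \max_{i\ne j} |S_{ij}|$ down to
$0.01\,\lambda_{\max}$:

$$\mathrm{EBIC}(\lambda) = -2L + E \log n + 4 E \gamma \log p,
  \qquad L = \tfrac{n}{2}\left(\log\det K - \operatorname{tr}(SK)\right),$$

with $E$ the number of nonzero upper-triangle entries (counted with a
$10^{-8}$ tolerance) and $\gamma = 0.5$. The likelihood constant is fixed
to this convention so that reported EBIC values are reproducible;
constants cancel in model selection.

Node importance uses signed, one-step indices: expected influence
$EI(i) = \sum_j w_{ij}$ within a network, and bridge expected influence
$BEI_1(i) = \sum_{j:\,\mathrm{comm}(j)\ne\mathrm{comm}(i)} w_{ij}$ across
the community partition. The *central* lifestyle/outcome is the EI argmax
of its within-community network; the *bridge* lifestyle is the $BEI_1$
argmax with selection restricted to lifestyle nodes ($BEI_1$ itself is
computed for all nodes, and difference tests span all nodes). Nodes whose
Holm-adjusted difference-test p-value against the argmax is ≥ 0.05 are
reported as co-central ("=" ties).

## Correlation choice

The ordinal scores enter Pearson correlations directly (Spearman is an
option). A polychoric front end would estimate the latent correlations the
simulator uses, but it is iterative, occasionally non-convergent on sparse
cells, and not clearly what reference analyses of this kind used; the
deterministic Pearson default trades a known attenuation (about 10% for
equiprobable 5-point items) for robustness and reproducibility. All
benchmark properties in this package are defined under that default.

## Redundancy screening

Before estimation, item pairs that measure the same construct are
collapsed. For every pair with $|r_{ab}| \ge 0.5$ the screen compares the
two items' correlations with each third item $z$ using the
back-transformed-average Fisher-z test for dependent overlapping
correlations: with $z_1 = \operatorname{atanh} r_{az}$,
$z_2 = \operatorname{atanh} r_{bz}$, $\bar r = \tanh\{(z_1+z_2)/2\}$,

$$\psi = r_{ab}(1 - 2\bar r^2) - \tfrac12 \bar r^2 (1 - 2\bar r^2 - r_{ab}^2),
  \quad c = \frac{\psi}{(1-\bar r^2)^2},
  \quad Z = \frac{(z_1 - z_2)\sqrt{n-3}}{\sqrt{2 - 2c}}.$$

A pair is flagged when fewer than 25% of these $p-2$ comparisons are
significant at α = 0.01. Flagged pairs are grouped by connected components
and each group collapses to one item — by default the member with the
largest mean |r| to items outside the group (ties to the lowest id), or an
explicit keep-list. The 0.5 candidate floor and the keep rule are
configuration, since reference analyses state only the 0.25/0.01
thresholds and a one-shot removal. Two caveats are documented rather than
hidden: correlations of exactly ±1 with a third item are clamped to keep
the Fisher transform finite (the comparison then counts as significant),
and the screen's power to *not* flag an imperfect clone grows with n — at
n = 2000 a 95%-agreement clone of a well-connected item escapes flagging
in a minority of runs because its 5% noise is detectably attenuating.

## Bootstrap validation

*Edge precision.* Nonparametric bootstrap: B row-resamples with
replacement, each re-estimated end-to-end with identical tuning; per-edge
95% intervals use type-7 empirical quantiles (fixed so interval values are
bit-reproducible). Replicates that leave an item with zero variance are
redrawn (at most 10 times, logged).

*Centrality differences.* For each node pair, a paired two-sided Wilcoxon
signed-rank test on the B replicate index values, Holm-adjusted across all
p(p−1)/2 pairs, flags at α = 0.05. All-zero difference vectors give p = 1.
Applying a paired location test across bootstrap replicates follows the
reporting convention of the studies this package models; it is
statistically unorthodox (replicates are not independent observations),
which is why the package also exposes the raw replicate matrix for
CI-based alternatives. Under exchangeable nodes whose estimated networks
are empty the procedure is conservative by construction; under
non-degenerate exchangeability it can be anti-conservative.

*Centrality stability.* Case-dropping subset bootstrap: for each drop
proportion q in a 10-point grid evenly spaced over 0.05–0.75, B subsamples
without replacement of size (1−q)n are re-estimated and their index
vectors correlated (Pearson) with the full-sample vector; zero-variance
vectors contribute correlation 0, a conservative convention that also
handles empty networks. The CS coefficient is the largest q\* such that
every q ≤ q\* keeps ≥ 95% of replicates above correlation 0.7, reported
to 2 decimals — hence the attainable lattice
{0.00, 0.05, 0.13, 0.21, 0.28, 0.36, 0.44, 0.52, 0.59, 0.67, 0.75}. The
grid and B = 1000 defaults were chosen because published CS values in
this literature lie on exactly this rounded lattice. A network is
*interpretable* when CS strictly exceeds 0.25 (0.5 preferable); the
pipeline reports NA for central/bridge variables of non-interpretable
networks.

## The per-country pipeline

`run_country()` chains: redundancy reduction on the pooled item set (or a
fixed global drop-list, mirroring analyses that removed overlapping
exercise items once for all countries) → three networks (lifestyle-only,
outcome-only, bridge over all items) → per network, bootstrap difference
tests and a case-dropping CS on the relevant index (EI within
communities, BEI1 for the bridge) → gated central/bridge sets, top-3
edges with weights printed to 2 decimals, and the strongest
cross-community edge of the selected bridge node. Sample sizes below the
3-per-parameter planning rule (3·p(p−1)/2) warn but do not abort, since
the CS gate is the operative reliability filter. All randomness descends
from one seed, and re-running with the same seed reproduces the summary
exactly.

## The synthetic-data generator

The generator emulates the measurement model conventionally assumed for
5-point items: a latent multivariate normal with a sparse two-community
partial-correlation truth (unit-diagonal precision $K = I - P$), each
coordinate discretised by per-item cutpoints. Defaults: exact within-
community edge counts at density 0.2, exactly 2 cross-community bridge
edges, weights uniform on (0.2, 0.5) and positive — after reverse coding,
empirical lifestyle/outcome networks are predominantly positive —
equiprobable 20% category masses (a "skewed" preset matches item means of
about 2.6–3.9 seen in real data), and per-country n inside the observed
150–2238 range. Positive definiteness is enforced by shrinking all
off-diagonals by 0.9 until the smallest eigenvalue reaches 0.05, which
preserves the zero pattern but can shrink realised weights below the
requested range (density 0.2 truths land near 0.15–0.33).

What passing tests show — and what they do not: the generator produces
symmetric, unimodal category distributions from an exactly Gaussian
latent; real survey data add skew, floor effects, differential item
functioning across countries, and missingness, none of which are
modelled. Results on the generator validate the estimator and the
machinery around it, not the substantive conclusions of any survey.

## Numerical choices and degenerate inputs

- glasso convergence: outer and inner tolerances scale with the mean
  |off-diagonal| of S (1e-8 relative); exact zeros come from the soft
  threshold, so the edge census is not a rounding artefact.
- λ grid endpoints are checked structurally: the largest λ yields the
  empty graph (KKT), λ → 0 approaches $S^{-1}$.
- Listwise deletion per network, so the three networks may have different
  effective n; penalised likelihood needs one coherent S.
- An indefinite correlation matrix (impossible under listwise Pearson,
  possible under future pairwise options) is repaired by eigenvalue
  clipping and rescaling, and flagged.
- Ties in top-edge lists, keep policies and cross-country groupings break
  lexicographically, for byte-stable reports.

## Known limitations

Measured at the study scale (p = 15, n = 2000, 20 seeds), EBIC-glasso
with γ = 0.5 recovers every true edge (median sensitivity 1.0) but admits
a substantial share of small spurious edges (median false-positive rate
about 0.36 under the positive-weight truth; about 0.12 under a mixed-sign
variant). This is the documented behaviour of the estimator under dense
positive-manifold marginals, not a solver defect — the path's edge sets
match an independent graphical-lasso implementation exactly. Consumers of
edge lists should treat weak edges as unreliable and lean on the
bootstrap CIs; centrality-based conclusions are much less affected, as
the hub/bridge benchmarks (recovery rates at or near 1.0) show. Polychoric
correlations, Ising/mixed models, two-step bridge indices and estimated
(rather than declared) communities are out of scope.

## Problem sizes used in the shipped checks

Module tests run on p ≤ 15, n ≤ 20 000 fixtures generated in code. The
study-scale benchmarks use 20 seeds at p = 15 (+13 for the bridge case),
n = 2000, B = 200 bootstrap replicates for difference tests and B = 50
case-dropping subsamples per grid point — sizes chosen so the full suite
re-estimates several thousand networks while remaining a desk-scale run.
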