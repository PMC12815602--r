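---
title: "Methods: cognitive–affective symptom networks, bridge centrality, and moderated mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cognitive-affective symptom networks, bridge centrality, and moderated mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bridgenet` implements a complete analysis pipeline for asking how affective
symptoms (7 depression items and 7 anxiety items, each scored 0–3) and
cognitive performance (5 domain proportions in $[0,1]$) hang together as a
network, how the *bridging* symptoms that link the two domains differ between
young and older adults, and whether cognition mediates the association
between gray-matter volume (GMV) and depressive symptoms. Because the
motivating cohort data are only available under a data-sharing agreement,
the package ships a synthetic-data generator with fully known ground truth;
every stage of the pipeline is tested against that truth.

## The network model

For each age group separately, the 19 analysis variables are modeled as a
Gaussian graphical model: edges are **regularized partial correlations**
$w_{ij} = -\theta_{ij}/\sqrt{\theta_{ii}\theta_{jj}}$ obtained from a sparse
precision matrix $\hat\Theta$ estimated by the **graphical lasso**,

$$\hat\Theta = \arg\min_{\Theta \succ 0}\; -\log\det\Theta +
\operatorname{tr}(S\Theta) + \lambda \sum_{i \neq j} |\theta_{ij}|,$$

where $S$ is the Pearson correlation matrix of the preprocessed columns. The
diagonal is unpenalized. The solver is a block coordinate descent
(`fit_glasso()`, in compiled code); every fit is checked against the KKT
stationarity condition $\max_{i\neq j} |s_{ij} - [\hat\Theta^{-1}]_{ij}| \le
\lambda$, and the test suite verifies the solver against an independent
proximal-gradient implementation.

**Preprocessing.** Non-categorical columns are z-scored (sample-SD
convention) and, by default, first residualized on sex and education by OLS
(`preprocess()`), then re-standardized. Residualization keeps the 19-node
topology instead of adding covariates as nodes; `residualize = FALSE`
disables it, and `covariates_as_nodes = TRUE` instead appends the z-scored
covariates as network nodes (community label `"covariate"`), the main
alternative convention for covariate control in network models.
Preprocessing is idempotent and leaves each column exactly orthogonal to
the covariates.

**Model selection.** The penalty $\lambda$ is chosen on a 100-point
log-spaced grid spanning $[\lambda_{\max}/1000, \lambda_{\max}]$
($\lambda_{\max}$ = largest absolute off-diagonal correlation, the exact
full-shrinkage threshold) by the **Extended Bayesian Information
Criterion**,

$$\mathrm{EBIC}(\gamma) = -2\,\ell(\hat\Theta) + E \log n + 4 E \gamma \log p,$$

with $E$ the number of edges, $p = 19$, and $\gamma = 0.5$ (the standard
conservative default; exposed as an argument). A deliberate design choice:
each candidate graph on the path is scored at its **support-restricted
maximum-likelihood refit** rather than at the shrunk estimate
(`refit_ebic = TRUE`, the default). Scoring shrunk estimates confounds two
things — which edges exist, and how much the penalty biases the strong
edges — and in simulation it systematically admits a few spurious tiny
edges because relaxing $\lambda$ "pays" for them by unshrinking the true
ones. Scoring the refit judges the graph alone; in the package's selection
tests this raises exact-support recovery on a 5-node chain (partial
correlation 0.3, $n = 500$) from under one-half to nearly always. The
reported edge weights are still the regularized partial correlations at the
selected penalty, as is conventional for symptom networks. Ties in EBIC
along the path resolve to the sparsest (largest-$\lambda$) model, and a
strict minimum at a grid endpoint triggers a warning rather than a silent
boundary selection.

## Centrality and bridging

`centrality_table()` reports three per-node measures:

* **Strength** — $\sum_j |w_{ij}|$, overall embeddedness of a node.
* **Weighted betweenness** — how often a node lies on weighted shortest
  paths between other nodes (Brandes accumulation, credit split equally
  among equal-length paths with a $10^{-10}$ relative tie tolerance).
  Edge length is a decreasing transform of edge magnitude: `1/|w|` by
  default, `1 - |w|` as an alternative (`distance` argument), since the
  literature is not unanimous. Both raw and normalized
  (÷ $(p-1)(p-2)/2$) values are emitted.
* **Bridge expected influence (BEI)** — the signed sum of a node's edge
  weights to nodes of *other* pre-defined communities (1-step variant; a
  2-step variant is available behind `two_step = TRUE`). Because
  cross-domain edges in these networks are predominantly negative, bridges
  are ranked by $|\mathrm{BEI}|$ while the sign is reported.

Cross-group comparison (`centrality_rank_correlation()`) uses Spearman rank
correlation with average ranks and the t-approximation p-value. The
depression-vs-anxiety contrast (`domain_permutation_test()`) fixes the
centrality values (the network topology is untouched) and re-draws the 7/7
depression/anxiety label split uniformly over the 14 affective nodes;
cognitive nodes never enter the shuffle. The default p-value uses the
add-one convention $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B+1)$ so
that $p$ is never 0; the plain proportion is available via
`p_convention = "raw"`. Two-sided (on $|\cdot|$) is the default sidedness;
the directional one-sided test is used when a direction is hypothesized.

## The synthetic generator as the study's stand-in

`synthetic_spec()` fixes a ground-truth precision matrix per group over the
19 nodes, built so that every planted feature is identifiable at the study's
reference sample sizes (756 young, 1,230 older participants):

* within-domain structure, identical across groups, with deliberately
  *heterogeneous* positive weights (partial correlations 0.22–0.42): a
  chain plus one chord over the five cognitive domains, a chain plus one
  chord over the seven depression items, and a ring plus one chord over
  the seven anxiety items. The weight ladder gives the nodes distinct
  strengths shared by both groups, so the cross-group strength profile is
  reproducible — uniform weights would leave strengths near-tied and their
  cross-group rank correlation would be pure noise;
* one positive depression–anxiety link (`ha1`–`hd1`, $+0.32$), so the
  affective block is connected;
* the **planted bridge**: `hd3` (dysphoria) in the young group, `hd7`
  (anhedonia) in the old group, with edges $-0.28$ to memory and fluency —
  by construction the maximal-$|\mathrm{BEI}|$ affective node. The chain
  weights around both bridge candidates give them similar mid-ladder base
  strengths in both groups, so moving the bridge reorganizes *bridging*
  centralities far more than it reorganizes strength — the dissociation
  the cross-group comparison is designed to detect;
* a young-only positive anxiety–cognition edge (`ha3`–memory, $+0.28$).
  With that gateway absent in the old group, all old-group anxiety traffic
  toward cognition routes through the depressive chain, which is what
  makes old-group depression-node betweenness systematically exceed
  anxiety-node betweenness.

Latent scores are drawn from $N(0, \Theta^{-1})$; affective columns are
discretized at thresholds $(0.8, 1.6, 2.4)$ into 0–3 scores, which
reproduces the zero-inflation characteristic of population-based symptom
data (≈ 79% zeros per item at unit variance); cognitive columns go through
a monotone logistic squash into $(0,1)$ with group-specific locations, so
older groups score lower (slope 0.7, gentle enough that the transform stays
near-linear over the bulk of the latent range). Covariates are sex
(Bernoulli 0.43), a group-specific 4-level education distribution, and age
drawn within each group's band; they are independent of the latent network,
so covariate residualization is exercised but cannot distort recovery.

Two generator-design points deserve emphasis. First, the latent magnitudes
are set *above* what one would plant for continuous data because ordinal
discretization attenuates observed Pearson correlations by roughly
0.5–0.75 here; the chosen values keep every true edge above, and the
discretization artifacts below, the EBIC selection threshold at the
reference sample sizes. Second, discretizing a variable does not exactly
preserve conditional independence: the observed item distribution carries
small spurious partial correlations (up to ≈ 0.05 in magnitude) around
strongly connected discretized nodes. This is a real property of ordinal
data, not a bug; the structure (bridge nodes at chain endpoints, two
contiguous bridge targets) was chosen to keep those artifacts small, and
recovery is always measured against the stored (post-construction) truth.

If the requested pattern is not positive definite, the constructor inflates
the diagonal by the smallest $\delta \in \{10^{-4}\cdot 2^k\}$ reaching a
minimum eigenvalue of $10^{-6}$, attenuating all partial correlations by
$1/(1+\delta)$, and stores the attenuated matrix as the new ground truth
(the default spec needs no inflation).

A design lesson encoded here: a single dominant bridge node alone cannot
produce a depression-vs-anxiety *mean* centrality difference detectable by
the label-permutation test — under a 7/7 shuffle one extreme value lands on
either side with equal probability, so the test would hover near
$p = 0.5$ regardless of sample size. The contrast requires most depression
nodes to carry elevated betweenness collectively, which the routing
structure above provides.

**What passing tests do and do not show.** The generator shares the real
data's dimensionality, group sizes, ordinal zero-inflated margins, domain
block structure and bridge asymmetry, but its latent distribution is
exactly Gaussian, its within-domain graphs are stylized (chain/ring), its
covariates are independent of the symptoms, and item thresholds are
identical across items and groups. Recovery results on it certify the
estimator and pipeline logic, not the substantive findings on any real
cohort.

## Moderated mediation

`moderated_mediation()` fits the recursive two-equation path model

$$M:\; \text{cognition} = a\,\text{gmv} + a_{\text{int}}\,\text{gmv}\times\text{age}
+ \beta_{\text{age}}\text{age} + \gamma' \text{controls} + \varepsilon_1$$
$$Y:\; \text{outcome} = b\,\text{cognition} + c'\,\text{gmv}
+ \beta_{\text{age}}'\text{age} + \gamma'' \text{controls} + \varepsilon_2$$

by least squares with all continuous variables z-scored on entry, so the
coefficients are standardized. In this fully observed, just-identified
recursive system equation-wise OLS equals the maximum-likelihood path
solution (verified in the tests against a direct likelihood optimization).
The indirect effect at mean age is $a\cdot b$, the **index of moderated
mediation** — the change in the indirect effect per SD of age — is
$a_{\text{int}}\cdot b$, and the conditional indirect effect at age $z$ is
$(a + a_{\text{int}} z)\,b$; these identities hold exactly at the point
estimates by construction. Inference is by case-resampling bootstrap
(default 5,000 resamples; both equations refit jointly per resample, in
compiled code) with percentile intervals; bootstrap-proportion and
normal-approximation p-values are reported side by side, and a residual
bootstrap is available behind `boot = "residual"`. The age main effect is
included in both equations by default — an interaction without its main
effect is malformed — with `age_main = FALSE` to drop it. Ordinal outcome
items are treated as continuous after z-scoring, mirroring common practice
in linear path models; no ordinal-probit link is offered in this version.

The mediation generator (`simulate_mediation_data()`) defaults its paths to
$a = 0.142$, $a_{\text{int}} = 0.186$, $b = -0.147$, $c' = 0.013$, with the
second outcome's mediation path null ($b_2 = 0$) to represent a symptom
whose link to cognition vanishes. Error SDs are derived internally so every
structural outcome has unit population variance, making the planted
coefficients exactly standardized.

## Numerical choices, in one place

* z-scoring: sample SD ($n-1$); degenerate (zero-variance) columns error by
  name rather than propagating NaNs.
* glasso: outer tolerance $10^{-9}$ (relative to mean off-diagonal
  magnitude), inner coordinate-descent tolerance $10^{-11}$; $\lambda = 0$
  is computed directly as $S^{-1}$; edge zeroing threshold $10^{-8}$
  stabilizes edge counts.
* Shortest paths: Dijkstra with a $10^{-10}$ relative tolerance for length
  ties, so equal-length path counting is robust to floating-point noise.
* Permutation test: minimum 100 permutations enforced; seeds are explicit
  everywhere and every stochastic stage logs its seed to the run manifest.
* RNG: Mersenne-Twister with inversion sampling, pinned in
  `.with_seed()`, so seeded output is identical across platforms; seeded
  helpers restore the caller's RNG state.
* Bootstrap intervals: percentile at 2.5/97.5%; resample indices are drawn
  once from the seeded stream and passed to compiled code, so case and
  residual bootstraps of the same seed use the same resamples.

## Problem sizes used by the test suite

The suite exercises the pipeline at the reference group sizes (756/1,230)
across 100 seeded replicates for support recovery and bridge
identification; selection consistency uses 200 replicates of a 5-node chain
at $n = 500$; permutation calibration uses 1,000 simulated exchangeable
centrality sets; mediation recovery uses 200 replicates at $n = 10{,}000$
and interval coverage 500 replicates at $n = 733$ with 1,000 resamples —
sizes chosen to give stable Monte-Carlo estimates of each property while
keeping a full run of the suite comfortably interactive.

## Known limitations

* Ordinal items enter the network through Pearson correlations of 0–3
  scores (the paper-trail convention for z-scored items); no polychoric
  option exists yet, so edge magnitudes are attenuated relative to the
  latent scale. Recovery targets account for this.
* Betweenness on regularized networks is sensitive to small edges near the
  selection threshold; the permutation test inherits that variability.
* The exact BEI variant (1-step vs 2-step) and the betweenness
  normalization convention differ across the applied literature; both are
  exposed, with 1-step and unnormalized as defaults.
* The mediation model is linear-Gaussian with a single-indicator mediator
  and outcome; no latent measurement structure, no global SEM fit indices.
* `middle` groups are accepted by the data model and generator but have no
  default planted bridge.
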