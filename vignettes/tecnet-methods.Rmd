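---
title: "Methods: co-expression network analysis of paired endothelial transcriptomes"
author: "tecnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-expression network analysis of paired endothelial transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tecnet)
```

# The design and the generative model

The package targets a paired 2×2 microarray design: each subject donates up
to four endothelial cell fractions, crossing tissue *origin* (non-tumour vs
tumour) with angiogenic *activation* (ENG⁻ vs ENG⁺). Arrays drop out per
(subject, fraction); with 16 subjects and the default per-fraction dropout
probabilities (1/16, 8/16, 2/16, 10/16) the expected used-array counts are
15, 8, 14 and 6 — 43 arrays in total. The heavy ENG⁺ dropout reflects that
the activated fraction is sampled for only a subset of donors.

`simulate_expression()` mirrors the mixed model fitted downstream. Per
planted module $m$ the eigengene is

$$e_m(s) \;=\; \beta_{1m}\,\mathrm{origin}(s) + \beta_{2m}\,\mathrm{activation}(s)
 + b_{m,\mathrm{subject}(s)} + u_m(s) + \varepsilon_m(s),$$

with subject intercepts $b \sim N(0, \sigma_\text{subject}^2)$, a
module-specific latent factor $u \sim N(0, \sigma_\text{module}^2)$, and
residual noise $\varepsilon \sim N(0, \sigma_\text{noise}^2)$. Each module
gene is a high-Gaussian baseline plus `loading` × eigengene plus residual
noise; loadings are uniform on (0.8, 1]. Background genes are i.i.d. draws
from the low-expression Gaussian, giving the pooled intensity histogram its
characteristic two-component shape.

**Why the module factor.** With only shared covariates and subject
intercepts, two modules carrying the same trait effect would have eigengene
correlation near 0.8 and be indistinguishable to any clustering method. In
real tissue, each module reflects a distinct co-regulated programme whose
variation the design factors do not explain; $\sigma_\text{module} = 1$
(log2 units) encodes that and keeps equally-affected modules separable.
Effect sizes default to ±1.5–2 log2 units per trait; these are chosen for
test power, not biological realism, since effect magnitudes on real module
eigengenes are dataset-specific.

**Outlier arrays** are emulated by replacing a sample's whole profile with
i.i.d. noise at the global intensity level. This removes both the per-gene
baselines and the low/high class pattern that all intact arrays share, so
the corrupted sample loses essentially all correlation with the cohort —
precisely the signal the zK diagnostic is designed to detect. A mean-shift
would not do this.

**What the generator does not emulate:** probe-level effects, array batch
structure, heteroscedastic intensity-dependent noise, correlated background
genes, or partial corruption. Passing tests therefore demonstrate that the
*methods* behave as specified under their own model assumptions; they say
nothing about robustness to, for example, batch effects, which are assumed
to be handled upstream.

# Preprocessing

*Two-Gaussian filter.* A two-component Gaussian mixture with free means,
variances and weights is fitted to the pooled log2 values by EM
(k-means initialization with a fixed seed, ≤ 500 iterations,
log-likelihood tolerance $10^{-8}$). The filter threshold is the smallest
point between the component means where the posterior probability of the
high (expressed) component reaches 0.5, located on a grid of 2,001 points;
genes below the threshold in every sample are removed. For a symmetric
equal-weight mixture this reduces to the midpoint of the means, which the
tests exploit as a closed form. The fitted threshold is a property of the
data — on the default synthetic cohort it lands near 6.2 — not a constant.

*Sample outliers.* Connectivity $k_i = \sum_{j \ne i}\mathrm{cor}(i, j)$
(Pearson, configurable) is standardized to zK; samples with zK < −1.96 are
excluded. The rule is one-sided by default: low connectivity is what
characterises a corrupted array, and a sample can only be "too connected"
by being unusually average. A `two_sided` switch restores the symmetric
rule. Degenerate cases: constant samples get zero correlations with a
warning; when all connectivities coincide (sd = 0), no sample is an
outlier.

# Moderated differential expression

The four-level group factor (origin × activation) is fitted per gene as
`expression ~ 0 + group` by generalized least squares under within-subject
equicorrelation $\rho$. The consensus $\rho$ is estimated by a one-way
random-intercept REML fit on the residuals of each gene's group-means fit,
then pooled by a 10% trimmed mean on the atanh scale and clamped to
(−0.99, 0.99). This is the same estimand as limma's duplicateCorrelation
without its boosting refinements; on blocked simulations the two agree
closely and the resulting moderated t-statistics correlate above 0.999
(asserted in the test suite).

Variance moderation follows the standard moment matching on
$\log s^2$: the prior degrees of freedom solve
$\mathrm{trigamma}(d_0/2) = \mathrm{var}(e) - \mathrm{trigamma}(d_f/2)$
(Newton inversion), and the prior variance is the bias-corrected
$\exp\{\overline{e}\}$ with
$e = \log s^2 - \psi(d_f/2) + \log(d_f/2)$. Two limits pin the
implementation down: with fewer than 10 genes moderation is disabled
($d_0 = 0$, ordinary t, with a warning), and with identical residual
variances $d_0 = \infty$ and every gene shares the posterior variance.
Zero residual variances are floored at $10^{-12}$. DE calls use
|log2FC| > 2 and BH-adjusted p < 0.05; the adjustment method is
configurable (`"hochberg"` is available) because the upstream tooling is
ambiguous between Benjamini–Hochberg and Hochberg, and BH is the default.

# Single-sample gene-set scores

Gene-level normalisation uses the Gaussian-kernel CDF across samples with
bandwidth sd/4 (the standard choice for continuous intensity data); within
each sample genes are ranked by decreasing score, ties broken by gene id so
results are invariant to input row order, and converted to the symmetric
statistic $|r - (n+1)/2|$. The set score is the weighted random walk down
the ranking — in-set steps weighted by the statistic (exponent τ = 1),
out-of-set steps uniform — summarised as (largest positive deviation) +
(largest negative deviation). This is the signed-sum convention of the two
published score variants; the source method's documentation treats it as
the default and it preserves the sign of coordinated shifts.

Two conventions are worth noting. A set covering *every* gene has no
out-of-set steps, leaving the decrement undefined; the score is defined as
0 (no contrast). And the score of a set and of its complement oppose each
other only statistically, not identically: both walk extremes can be
negative when set genes concentrate mid-ranking, so exact antisymmetry
fails in a small fraction of samples. The tests assert the statistical
version. Sets are scored on their intersection with the filtered gene
universe, minimum overlap 2.

# Signed network and iterative module detection

The network uses biweight midcorrelation (tuning constant 9 × MAD,
median-centred Tukey weights, per-vector Pearson fallback at MAD = 0),
signed adjacency $a = ((1+c)/2)^\beta$ with β = 12 — so anti-correlated
genes are disconnected — and the topological overlap measure. β is taken
as given; no scale-free-fit selection is performed.

*Tree cut.* Modules are branches of the average-linkage tree of 1 − TOM.
Instead of a fixed merge-height quantile, the cut height is chosen
adaptively: among candidate heights up to the deepsplit-derived quantile
cap (deepsplit 0–4 → 0.999, 0.995, 0.99, 0.98, 0.95), the cut maximizing
the number of clusters of at least `min_module_size` wins, ties going to
the highest (most conservative) cut. A fixed quantile fails on realistic
data because the topmost merges are noise-gene attachments: cutting there
yields one giant cluster, and the pruning loop then discards whole modules.
The adaptive rule keeps the same simplified-hybrid structure (height cut +
minimum size + PAM-style adoption) while making the granularity
data-driven; the contract asserted by the tests is planted-module
recovery, not the identity of any particular cut. `min_module_size`
defaults to 30. Genes in dissolved clusters are adopted by the module whose
eigengene they correlate with most, provided kME ≥ 0.8 (the PAM stage —
it needs expression, so `detect_modules()` takes an optional `expr`
argument and the iterative driver always supplies it).

*Eigengenes* are the first principal component of the gene-standardized
module submatrix, scaled to unit variance and oriented so the mean
correlation with the module's genes is non-negative. Consequently,
flipping all of a module's genes flips its eigengene; orientation follows
the genes, keeping mean kME ≥ 0 by construction. kME uses the same
correlation estimator as the network.

*Iteration.* Each cycle rebuilds the network on the currently assigned
genes, detects modules, computes each gene's kME against its own module
eigengene, and prunes genes with kME < 0.8. The loop stops as soon as an
iteration prunes nothing — at that point the assignment is a fixed point —
or after `max_iterations` (10). Finally, ever-pruned genes are re-adopted
where their kME reaches the threshold; genes the detection stage itself
left unassigned are not re-adopted here, because they pass through the PAM
stage every iteration. A pruning threshold of 0 disables pruning entirely,
making the loop provably identical to a single detection pass. Median
module kME > 0.8 at convergence is a direct consequence of pruning and is
asserted as a test. There is no eigengene-similarity merge step. The dense
implementation is capped at 20,000 genes, comfortably above the
~15,000-gene scale of filtered microarray data.

# Eigengene–trait association and hubs

Each eigengene is fitted with
`y ~ origin + activation + (1 | subject)` by REML via lme4, with
Satterthwaite degrees of freedom from lmerTest (a normal approximation is
available as a fallback). Traits are coded 0/1 (non-tumour/tumour,
ENG⁻/ENG⁺), so positive t means up-regulation in tumour or activated
cells. BH adjustment is applied across modules separately per trait; the
family choice is configurable. Perfectly fitting eigengenes (zero
residual) break the REML machinery; such fits are retried with a
deterministic infinitesimal perturbation and flagged `singular`. Module
selection (median |kME| strictly > 0.8) is computed independently of the
association so both full and selected results are reported.

Hub genes: kWithin is the sum of a gene's adjacencies to its module
partners, normalized by the module maximum; the top
`ceiling(0.1 · size)` genes per module are hubs, with ties resolved by
gene id for determinism. Pairwise group comparisons of eigengenes use
Student's t-tests BH-adjusted within module; pairs with fewer than two
samples in a group (possible under heavy dropout) yield NA with a warning
rather than aborting the pipeline. Druggability is a case-insensitive left
join of hub genes onto a user-supplied gene→drug table — a local stand-in
for live interaction-database queries, which are out of scope.

# GO enrichment and term reduction

Over-representation uses the one-sided hypergeometric upper tail with the
full analysed-gene set as background; term sizes are computed on the
ancestor-propagated background annotation and the [15, 500] window is
inclusive at both ends. BH-adjusted p < 0.05 defines significance.

Wang similarity assigns each ancestor a semantic value decaying along the
path to the term (edge weights 0.8 for `is_a`, 0.6 for `part_of`, maximum
over paths) and scores two terms by the shared-ancestor mass over total
mass. Term reduction embeds 1 − similarity in two dimensions and clusters
with DBSCAN (ε = 0.6, minPts = 5) in the embedded space, then takes the
highest −log10(p_adj) term per cluster as representative (ties to the
smaller term id); noise points (label −1) represent themselves, and fewer
than minPts significant terms are all noise. The embedding is classical
metric scaling: it is deterministic, which keeps cluster topology
reproducible across runs, whereas stochastic manifold embeddings make the
cluster count seed-dependent; the `seed` argument remains in the interface
so a stochastic embedder can be slotted in. Tests assert cluster-level
structure (two semantic families → two clusters), never coordinates.

# Orchestration, determinism and problem sizes

`run_pipeline()` executes simulate → preprocess → diffexpr → gsva →
coexnet → association → enrichment, persists every intermediate as TSV or
JSON, validates stage dependencies (association and enrichment refuse to
run without the network stage), and writes a manifest with the package
version, full configuration and input hashes. All randomness flows from
one integer seed through deterministically derived per-stage streams, so
identical configuration and seed give byte-identical outputs — asserted
file-by-file in the tests.

Test and acceptance problem sizes are chosen for a desk-scale machine:
module recovery runs 20 simulations at 2,000 genes × ~43 samples (about
3 s each), calibration uses 500 null mixed-model fits and 5,000 null genes
for the moderated t, and score-sign recovery uses 100 simulations at 200
genes. At these sizes the whole suite completes in well under five
minutes.

# Known limitations

- The adaptive height cut is not the published dynamic hybrid tree-cut
  algorithm; on dendrograms with strongly nested module structure the two
  can split branches differently.
- The consensus correlation omits the boosting refinements of the original
  estimator; with very few subjects it is noticeably conservative.
- GSVA-style scores are computed with the Gaussian kernel only; count data
  (Poisson kernel) are out of scope.
- The two-Gaussian filter assumes exactly two intensity components;
  three-component marginals (e.g., mixed platforms) will misplace the
  threshold.
- Mixed-model p-values rely on the Satterthwaite approximation, which is
  anti-conservative for very small cohorts (< 6 subjects).
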