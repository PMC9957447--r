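---
title: "Network-based annotation of transcription factors: models and methods"
author: "trnannot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based annotation of transcription factors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnannot)
```

## The problem

Most transcription factors (TFs) are annotated only as DNA-binding
regulators, without the biological processes they control or the sequence
motifs they recognize. When a large expression compendium is available, the
regulatory network inferred from it can serve as statistical evidence: if
the inferred target pool of a TF is coherently enriched in a biological
process, or in a promoter k-mer, the TF itself very likely participates in
that process or binds that motif. `trnannot` implements this strategy as a
reusable pipeline: network inference by sparse regression, then target-pool
enrichment for Gene Ontology (GO) biological-process terms and for k-mer
binding motifs, each with a calibrated null model.

## The regression model

Expression of gene $j$ across $m$ samples, $Y_j$, is approximated as a
linear function of the TF expression matrix $X$ ($m \times n_T$):
$Y_j \simeq X A_j$. Regulation is of course nonlinear and
context-dependent; the linear approximation buys convexity, speed, and
interpretable signed coefficients, and in community benchmarks more complex
models improve expression fits only marginally. Coefficients are estimated
per gene by the lasso,

$$\hat A_j = \arg\min_{A_j} \frac{1}{2m}\lVert Y_j - X A_j\rVert_2^2
  + \lambda \sum_i |a_{ij}|,$$

with a free intercept. Two conventions matter and are therefore fixed and
documented here rather than left to a solver default:

* **No feature rescaling.** TF features enter as-is
  (`standardize = FALSE`), because a single global coefficient cutoff
  $\alpha$ across all TFs only makes sense if coefficients share the
  compendium's common (log-intensity) scale. An opt-in `standardize` flag
  exists for data on heterogeneous scales.
* **Objective scaling.** The penalty is per the $1/(2m)$ residual scaling
  above (the `glmnet` convention), so $\lambda$ values are comparable
  across sample counts. The univariate solution with a centered,
  unit-variance feature is the soft threshold
  $\mathrm{sign}(\beta)\max(|\beta| - \lambda, 0)$ with
  $\beta = x^\top y / m$; the test suite holds the implementation to this
  closed form at $10^{-6}$.

A TF's model would trivially select itself, so its own feature column is
zeroed before fitting (self-masking); the coefficient vector keeps full
length and $a_{jj} = 0$ exactly.

$\lambda$ is tuned by 10-fold cross-validation to maximize the mean over
genes of the per-gene mean out-of-fold $R^2$. Folds are a random partition
driven by an explicit seed; a contiguous-block mode (`contiguous = TRUE`)
is available since alternating tenths of the sample order is an equally
defensible reading. Genes in the lowest quartile of mean CV $R^2$ are
dropped before the final fit (`filter_by_r2`, linear-interpolation
percentile, R's type-7 quantile; genes strictly below the cutoff are
removed, so ties keep everything).

The fitted coefficient matrix $A$ becomes a network by thresholding:
an edge $(i, j)$ with weight $a_{ij}$ survives iff $|a_{ij}| \ge \alpha$
(boundary included), the sign encoding up- versus down-regulation. Nodes
with no surviving edge (singletons) do not exist in the edge-list
representation. Defaults $\lambda = 0.008$ and $\alpha = 0.075$ follow the
compendium-scale analysis this package operationalizes; on synthetic data
with planted weights bounded away from zero ($|w| \ge 0.2$),
$\alpha = 0.075$ cleanly separates signal from shrinkage noise, which is
exactly why the generator bounds them. Treatment-specific networks are
refit on each sample category and thresholded by `match_density_alpha`,
which exploits that edge count is a step function of $\alpha$ to match a
reference density exactly.

## Network statistics

`summarize_topology` reports node/edge counts, degree summaries, and three
statistics whose variants deserve naming:

* **Clustering coefficient**: the *average local* clustering of the
  undirected projection, with nodes of degree $< 2$ contributing 0 (the
  NetworkX convention). A near-bipartite TF–target graph keeps this small.
* **Diameter**: longest shortest path on the largest connected component
  of the undirected projection, unweighted.
* **Degree coefficient**: the Pearson correlation of the undirected
  degrees at the two endpoints of each edge, taken over both orientations.
  For a degree-regular graph the endpoint degrees have zero variance and
  the value is reported as `NaN` with a warning, never silently 0.

`dispersion_index` is $\mathrm{sd}(Y_i)/\mathrm{mean}(Y_i)$ with the
sample (n−1) standard deviation — scale-invariant, undefined (and
excluded with a warning) for genes with nonpositive mean.
`architecture_correlations` reports Pearson $r$ and two-sided p-values
among gene length, regulator count $|in_j|$, mean expression, and
dispersion.

## GO annotation with a sampling-calibrated null

Enrichment of a target pool uses the **EASE score**: the upper-tail
hypergeometric probability with the observed overlap penalized by one gene
($P(X \ge \ell - 1)$; overlaps of 0 or 1 score exactly 1). The penalty
makes single-gene coincidences worthless and is always at least as
conservative as the plain hypergeometric tail. Terms are tested only when
at least 2 pool genes carry them; annotations are propagated to all
ancestors (true-path rule) before counting, which affects both term sizes
and specificity. Raw EASE $\le 0.05$ defines "significant" for the
calibration below — this matches the threshold the calibration is designed
to vet — while Benjamini–Hochberg adjusted values are reported alongside
for conventional reporting.

Significance *counts* are calibrated by sampling: for pool sizes $k$ on a
dyadic grid, 100 uniform random gene sets are drawn and the significant
term count recorded; the means $\mu_k$ and standard deviations $\sigma_k$
are each fitted as linear functions of $k$ by ordinary least squares, and
a TF with observed count $t(k_i)$ gets
$z_i = (t(k_i) - \hat\mu_{k_i})/\hat\sigma_{k_i}$, flagged when
$z_i \ge 2$. If the fitted $\hat\sigma$ is nonpositive the z-score is
undefined and reported `NaN` with a warning.

**Choosing calibration sizes.** The linear approximation for $\mu_k$ holds
when pools are a small fraction of the universe — the regime of a
genome-scale corpus. At desk scale (universes of a few thousand genes) the
count curve is sigmoid: quadratic onset below $k \approx 10$ (a term needs
two pool genes before it is tested at all) and saturation once $k$ is a
sizable fraction of the universe. The `sizes` argument of
`build_null_curves` should therefore cover the range of observed pool
sizes rather than the full dyadic schedule; the pipeline truncates the
schedule to the universe automatically, and the package's own validation
calibrates on sizes 32–1024 against pools of ~200 genes. This is a
limitation of small universes, not of the calibration idea.

**Specificity** of a term is the reciprocal of its annotated-gene count
(propagated); a term set inherits the maximum — its most specific member.
**Wang semantic similarity** between term sets is computed from scratch on
the corpus DAG: each ancestor of a term carries an S-value decaying
multiplicatively from 1 at the term itself (0.8 per `is_a` edge, 0.6 per
`part_of` edge, maximum over paths); two terms are compared by the summed
S-values of shared ancestors over both semantic totals, and sets by the
best-match average. The tests pin hand-computed S-values on a small DAG.

## Motif discovery

All k-mers (default $k = 7$; 6 and 8 supported; lengths 6–8 enumerate
86,016 candidates) are indexed against promoter sequences by exact
forward-strand substring match — presence is binary per gene, windows
containing `N` never match, and a `both_strands` flag ORs in
reverse-complement matches. Enrichment of motif $f$ in a pool is the plain
upper-tail hypergeometric probability (no EASE penalty here — the
motif test is the textbook tail), BH-corrected per TF by default
(`global_fdr` pools all TF–motif tests; the correction scope is a
documented choice, as either reading of "the p-values were corrected" is
defensible).

Two nulls validate the discoveries:

* **Degree-preserving rewiring**: each TF's pool is replaced by a uniform
  random gene set of identical cardinality (or, behind
  `permute_targets = TRUE`, by permuting the pooled target multiset), the
  whole enrichment + BH pipeline is rerun, and the count of significant
  TF–motif pairs recorded; on planted data the observed count exceeds
  every rewired count and most rewired runs yield zero pairs.
* **Motif shuffling**: enriched motifs are scored against their own TF's
  reference PWM and against PWMs after permuting assignments across TFs,
  with an independent two-sample t-test between the score distributions.

The **IC alignment score** of a 7-mer against a PWM column $c$ uses the
per-symbol contribution $p_{ck}\log_2(p_{ck}/b_k)$ (with
$0\log 0 := 0$): the unmasked column score is the maximum over symbols,
the masked score selects the motif's own symbol, and the final score is
the best masked 7-column window sum divided by the best unmasked window
sum $s_{\max}(p,7)$. One sign convention question is genuinely open — a
flattened rendering of the column score carries a leading minus — and the
package defaults to the positive convention because only then do conserved,
over-background columns score highest, which is required for enriched
motifs to align with conserved PWM regions; `convention = "literal"`
provides the negated variant. Window ties resolve to the smallest start; a
PWM with no information ($s_{\max} = 0$, e.g. all-uniform columns) yields
`NaN` with a warning; PWMs shorter than 7 columns are an error (skipped
with a warning in batch scoring).

## The synthetic-data generator

The generator exists so every stage is testable without downloads, and it
emulates the statistical structure the method assumes:

* **Expression** (`generate_expression`): TF rows i.i.d. standard normal;
  each target receives $\lceil \text{density} \cdot n_T \rceil$ regulators
  with weights drawn from $\pm U(0.2, 1)$ and Gaussian noise
  (`noise_sd`). Weights bounded away from zero make the documented
  $\alpha$ meaningful; with no TF→TF edges by default, ordinary least
  squares on the true support is an exact recovery oracle (a
  `tf_tf_edges` flag adds a TF hierarchy and still exercises
  self-masking). Everything is a pure function of the seed.
* **Promoters** (`generate_promoters`): i.i.d. uniform ACGT background
  (configurable composition), default length 1577 bp — a typical median
  promoter length for a compact plant genome — with each planted TF's
  motif overwriting a uniform random window in each target promoter with
  probability $\pi$.
* **Ontology** (`generate_go_corpus`): a root, three branches, and leaf
  terms (mostly `is_a`, a minority `part_of`). Background annotation
  rates across leaves follow a Zipf (1/rank) profile with mean
  `background_rate`, mirroring the heavy-tailed term sizes of real GO
  — a few broad terms annotate many genes, most terms are specific —
  which is also the regime in which the linear null calibration is
  sensible; a `uniform_background` flag gives flat rates. Each planted TF
  annotates its targets with its planted term set (several terms per TF,
  as real regulons enrich several related processes) with probability
  $\rho$ per term.

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: nonlinear and combinatorial regulation,
microarray probe and batch effects, correlated sample structure (time
courses, tissues), the depth and multiple inheritance of the real GO DAG,
evidence-code heterogeneity in annotations, positional and strand biases
of real binding sites, and compendium-scale universes. Headline
compendium-scale quantities (tens of thousands of edges, thousands of
significant TF–motif pairs) are consequently out of reach at desk scale;
the package validates the machinery on planted truth instead.

## Numerical choices and degenerate inputs

* Lasso solves use a descending warm-start path ending at the requested
  $\lambda$, convergence threshold $10^{-12}$ (fits) / $10^{-9}$
  (cross-validation), and up to $10^7$ coordinate updates.
* All-constant feature matrices or constant responses return all-zero
  coefficients rather than erroring (they arise under self-masking with
  degenerate fixtures); cross-validation scores such genes `NA` and means
  skip them.
* Percentiles interpolate linearly (type 7); ties at the cutoff are kept.
* `match_density_alpha` scans the sorted unique |coefficients|, so the
  returned cutoff is exact, never bisected approximately.
* Hypergeometric tails come from `phyper` on the log-safe side; EASE
  clamps to $[0,1]$ and returns exactly 1 for overlap $\le 1$.
* Deterministic orderings throughout: lexicographic edge lists, smallest
  window start on IC ties, lexicographic term order on p-value ties.
* Every stochastic routine takes an explicit seed and restores the RNG
  state afterwards (`withr::local_seed`), so generators are pure and
  pipelines reproduce bit-identically under a fixed config.

## Validation problem sizes

The test suite and the acceptance script validate on: parameter recovery
with $n_T = 20$, $n = 500$, $m = 200$, density 0.1, noise 0.1 over 5
seeds (edge precision and recall vs planted truth ≥ 0.9 at
$\lambda = 0.01$, $\alpha = 0.075$); z-score calibration on a
4000-gene universe with 20 TFs and 5 planted terms per TF; rewiring nulls
on 1000 promoters, 10 TFs, $\pi = 0.5$, 100 rewirings; 200 exhaustive
hypergeometric enumerations; 1000 random PWM/7-mer pairs. These sizes are
the package's chosen desk-scale study conditions; the statistics above are
stable across seeds at these sizes.

## Known limitations

* Linear regulation only; no interactions, saturation, or time lags.
* The EASE implementation follows the documented "overlap minus one"
  convention; byte-parity with the DAVID service is not a goal.
* Wang similarity follows the standard contribution factors (0.8/0.6);
  parity with GOSemSim's numeric output is not asserted.
* The null-curve linear fit degrades outside the $k \ll n$ regime (see
  above); calibration sizes should match observed pool sizes.
* Motif matching is exact-substring; degenerate (IUPAC) motifs, motif
  merging, and EM/Gibbs refinement are deliberately out of scope.
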