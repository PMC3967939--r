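---
title: "chromcode: maximum-entropy models of combinatorial chromatin factor binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chromcode: maximum-entropy models of combinatorial chromatin factor binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromcode)
```

## The model

Genome-wide binding profiles of histone modifications, histone variants
and chromatin proteins ("chromatin factors") are strongly co-dependent:
at any genomic bin only a tiny fraction of the $2^n$ possible
presence/absence combinations is ever observed. `chromcode` models the
distribution of these binary *chromatin codes*
$x \in \{0,1\}^n$ with the maximum-entropy (log-linear / Ising-type)
family

$$
P(x) \;=\; \frac{1}{Z}\exp\Big(\sum_i h_i x_i
  + \sum_{i<j} J_{ij} x_i x_j
  + \sum_{i<j<k} K_{ijk}\, x_i x_j x_k\Big),
$$

the least-structured distribution consistent with the observed
occupancy, co-occupancy, and (optionally) triple co-occupancy
frequencies. The self-energy $h_i$ tunes how often factor $i$ occurs;
the pairwise energy $J_{ij}$ is the log fold change in pattern
frequency attributable to the $i$–$j$ interaction *conditioned on all
other modeled factors*, which is what lets it discount transitive
correlations that contaminate marginal measures such as correlation or
mutual information; $K_{ijk}$ captures cooperativity or competition
beyond pairs. With the convention $P \propto \exp(+E)$, positive
energies mean enriched co-occurrence. The all-zero code has energy 0,
so $P(\mathbf 0) = 1/Z$ — an identity the package exploits to estimate
the partition function by sampling.

## From continuous signal to binary codes

Continuous per-bin signal (`signal_matrix`) is converted to binary
calls (`chromatin_code`) by a mixture decomposition that assumes only
that the background is symmetric about its center and that the signal
(enrichment, or depletion for linker/core-histone-like factors) lies on
one side of it with negligible mass on the other:

1. *Binning* (`bin_track`): extent-weighted averaging into fixed-width
   bins (default 200 bp); bins with less than 50% measurement coverage
   are withheld.
2. *Mixture fit* (`fit_background_signal`): the signal side is the
   heavier tail (sign of the third moment about the coarse density
   mode). The background center is then located by a CDF-level
   symmetry balance — the root of
   $[F(c+t)-F(c)] - [F(c)-F(c-t)]$ pooled over several window widths
   $t$ of one robust background scale. We deliberately do *not* center
   on the argmax of the kernel density: on a flat peak the argmax
   jitters by $\sim 0.1\sigma$ even at $5\times10^4$ observations,
   which leaks several percent of background mass into the inferred
   signal; the CDF balance locates the center at near-root-$n$
   accuracy. The signal weight is the (clamped) difference of the two
   tail masses about the center — exact under the one-sided-signal
   assumption. Component densities are carved from the kernel density
   estimate (normal-reference bandwidth, 512-point grid) by reflecting
   the clean side about the center.
3. *Thresholding* (`optimal_threshold`): the call boundary is the
   signal value at which the weighted background and signal densities
   are equally likely — the first grid crossing outward from the
   center, refined by linear interpolation. If the densities never
   cross (no detectable signal), the caller can fall back to the 0.95
   background quantile; factors whose signal weight falls below 0.005
   are flagged rather than silently binarized.
4. *Binarization* (`binarize`): calls are made beyond the threshold
   toward the signal side; depletion-side factors are suffixed `-` so
   a call records loss of the factor. Withheld or incomplete bins are
   dropped jointly across factors, so every retained row is a complete
   code. (Whether to drop such bins per-factor instead was an open
   choice; joint dropping keeps every row a full pattern, which the
   fitting stage requires.)

Expression tracks enter through the same machinery on
$\log_2(\mathrm{RPKM}+1)$ (`discretize_expression`), so a transcription
state can be appended as one more "factor" and imputed like any other.
Note the $+1$ transform piles unexpressed genes at exactly zero; when
the low mode sits at 0 the symmetric-background assumption is violated
at the pile and class agreement degrades gracefully rather than
holding at the levels seen for well-separated bimodal input.

## Learning

**Structure** is learned by penalized pseudo-likelihood: the
conditional of each factor given the rest is logistic in its local
field, so the negative log pseudo-likelihood (`neg_log_pseudolikelihood`)
is convex, exactly differentiable, and free of $Z$. The pairwise model
minimizes it plus $\lambda \sum |J_{ij}|$ (`fit_pairwise_l1`,
FISTA with backtracking; exact zeros from the soft-threshold; $h$ never
penalized). The third-order model uses an overlapping group penalty
$\lambda \sum_{i<j} \lVert (J_{ij}, K_{ij\cdot}) \rVert_2$
(`fit_hierarchical_group_l1`): a triplet survives only if all three of
its pair groups are active, making the support hierarchical. It is
solved by ADMM on the duplicated-variable formulation with a
*linearized* $\theta$-step (one gradient per outer iteration, with a
descent-style backtracking on the step size); the group soft-threshold
gives exact zeros, and any triplet whose member pairs did not all
survive is pruned. $\lambda$ is chosen to minimize the validation-set
negative log pseudo-likelihood over a descending warm-started grid
(`select_lambda`, default 30 log-spaced values from $\lambda_{\max}$
down to $\lambda_{\max}/1000$), with ties to the sparser side.

A practical note on validation-selected supports: the validation curve
genuinely keeps improving into the small-$\lambda$ regime, where the
exact-zero support acquires many spurious pairs of tiny magnitude
(|J| < 0.06 in our benchmarks). Recovered interactions are therefore
reported and evaluated above a relevance threshold of 0.2 — the same
cutoff used when checking recovered signs — rather than at bare
machine-nonzero.

**Calibration.** Pseudo-likelihood estimates rank interactions well but
the implied distribution is miscalibrated, so the structure-fixed model
is refined toward the maximum likelihood estimate (`fit_mle_mcmc`):
the gradient for each active feature is the empirical moment minus the
model moment, the latter estimated each iteration from Gibbs samples
(sequential single-site sweeps, one sample per sweep, persistent chain
across iterations so only the first pays burn-in), with a fixed step
(default 0.05, 10,000 samples/iteration). Progress is monitored by the
Pearson correlation between observed and model statistics; iteration
stops at the cap or at $r > 0.999$; divergence (mean $|\theta| > 50$)
aborts with diagnostics.

## Evaluation and inference

* `estimate_log_partition_mc`: $\hat Z = 1/\hat P(\mathbf 0)$ from
  Gibbs samples (default $10^6$), valid because the all-zero code is
  the most common pattern in sparse occupancy data; `exact_log_partition`
  enumerates up to $n = 20$.
* `coherence_score`: $\exp(\text{mean log-likelihood})$ on held-out
  data — a per-bin geometric-mean probability in $(0,1]$, reported
  normalized to the best model in a comparison.
* `split_genome`: contiguous near-equal slices (default 50) assigned
  half to training at random, the rest alternating validation/test in
  genome order — slices, not bins, are randomized, limiting leakage
  between sets from local genomic dependence. (The alternation rule is
  our choice; any fixed rule that keeps slices intact would do.)
* `predict_pattern_frequencies`: model frequencies of subset patterns
  by Gibbs marginalization versus observed test frequencies.
* `conditional_probability` / `impute_profile`: a missing factor's
  per-bin probability is logistic in its local field — context-based
  imputation of unmeasured profiles, evaluated by Mann-Whitney AUC
  (`auc`). `cross_model_predict` applies a model trained on another
  cell type's data for the shared factor set; no marginalization over
  non-shared factors is attempted (models must be retrained on the
  consensus set).
* `interaction_energy_scores` ranks nonzero $J$ (or $K$) entries;
  `precision_recall_bootstrap` resamples the curated positives (2000
  rounds), computes each round's precision-recall over the scored pair
  universe, and averages precision at 100 recall levels with step
  interpolation. Negatives are the scored pairs outside the curated
  standard; positives left out of a resample are excluded from that
  round, not counted as false — so a perfect ranking scores precision
  1 at every recall level regardless of seed. Unscored standard pairs
  are kept with score $-\infty$. Baselines (`baseline_scores`):
  Pearson and precision-matrix partial correlation on continuous
  signal, plug-in mutual information (natural log) on binary calls.

## Synthetic study conditions

All tests and the acceptance benchmark run on planted models with
known truth (`random_sparse_model`, `sample_dataset`,
`synthetic_signal_tracks`). Defaults are fixed once: 15 factors, 12
planted pairs with $|J| \in [0.8, 2]$, 30% negative interactions,
self-energies uniform in $[-2.5, -1]$ — chosen so per-factor occupancy
stays sparse (roughly 0.1–0.4 after interaction effects) and the
all-zero code is the most common pattern, as in binarized chromatin
data. Continuous tracks are symmetric unit-variance background plus a
$+4$ (or $-4$ for depletion factors) shift times the call. Bins are
i.i.d. draws: the generator does not emulate genomic autocorrelation,
mappability structure, or factor-specific noise, so passing recovery
tests demonstrates correctness of the estimators under the model's own
assumptions, not robustness to real-data artifacts.

The fixed benchmark (`planted_benchmark`, seeds 1–5, N = 20,000
training + 5,000 validation bins, 20-point $\lambda$ grid) yields
support F1 = 1.0 at the 0.2 relevance threshold, all recovered signs
correct, and Spearman correlation of planted versus recovered $|J|$
above 0.8 on every seed. The third-order benchmark (12 factors, 10
pairs closing 2 planted triplets, N = 30,000) recovers both planted
triplets within the top-5 $|K|$. Problem sizes throughout (n of 8–15,
$2\times10^4$–$5\times10^4$ bins, $5\times10^5$-sample partition
estimates) are chosen so that every quantity has an exact enumeration
or closed-form oracle and the whole suite runs on a single CPU in
minutes.

## Numerical choices and limitations

* Optimality tolerance $10^{-5}$ on the subgradient residual for the
  L1 fit; $2\times10^{-4}$ on the scaled ADMM residuals; interaction
  entries below $10^{-8}$ dropped as zeros.
* Gibbs sampling uses a fixed sequential site order, all-zero
  initialization, burn-in default 1,000 sweeps, single chain, and R's
  RNG (so every result is reproducible from a seed; seeds are
  mandatory arguments).
* A pseudocount of 0.5 (Jeffreys-style) guards the independent
  baseline's logits; constant columns warn and clamp at $|h| \le 15$.
* Exact enumeration is hard-capped at 20 factors; the Monte-Carlo
  $Z$ estimator fails loudly when the all-zero pattern is never
  sampled and warns below 10 occurrences.
* Imputation follows the leave-one-out protocol (single target, fully
  observed context). Joint imputation of several missing factors is
  available only as an explicitly experimental routine
  (`impute_profiles_joint`, short clamped-Gibbs chains, no convergence
  diagnostics). The extension to transcription is expressed by
  appending the binarized expression track as one more factor, with no
  dedicated code path.
* The group-L1 path returns penalized (shrunk) estimates; magnitudes
  are therefore biased toward zero and are meant for ranking and
  support identification, with `fit_mle_mcmc` as the calibration
  stage.
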