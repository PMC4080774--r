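---
title: "Multi-peak models for mass-spectral differential analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-peak models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipeak)
```

# The problem

A compound in an LC-MS run produces several spectral peaks — adducts and
isotopes — whose chromatographic shapes are nearly identical because they
elute together, while peaks from different compounds rarely share a
shape. Conventional differential analysis uses one peak per compound.
`multipeak` models all of them, in two stages: a nonparametric clustering
of peaks by shape similarity, then a hierarchical Gaussian model for
group effects on each cluster using every member peak's height. The two
stages are deliberately separate: shape information identifies *which*
peaks belong together far more reliably than height correlation does, and
once the clustering is fixed the effects model is fully conjugate.

# Stage 1: clustering by shape similarity

## Data and likelihood

The inputs are per-sample similarity matrices $Q_i \in [0,1]^{P \times
P}$ and a co-observation mask $R \in \{0,1\}^{N \times P \times P}$. From
raw extracted-ion chromatograms, `build_similarity()` computes each
$q_{ijj'}$ as the Pearson correlation of the two traces, linearly
interpolated onto the union of their retention-time points inside the
overlap of their windows, with negative correlations truncated to zero.
A pair is masked out ($r = 0$) when the apexes are farther apart than
the co-elution window, when fewer than three common grid points exist,
or when either trace has zero variance.

Each (sample, pair) observation contributes a spike-and-slab term: with
probability $p_0$ the pair is not co-observed (the spike; this is itself
informative, because unrelated peaks are less often co-observed), and
otherwise $q$ follows a beta slab whose shape depends on the co-cluster
indicator $\varepsilon_{jj'}$:

$$q_{ijj'} \mid \varepsilon_{jj'} = 1 \sim (1 - p_0^{in})\,
\mathrm{Beta}(a_{in}, b_{in}) + p_0^{in}\,\delta(r_{ijj'}), \qquad
\text{and likewise with } (a_{out}, b_{out}, p_0^{out}) \text{ for }
\varepsilon = 0.$$

The full likelihood is the product over samples and unordered pairs.

## Prior and inference

The partition of peaks has a Dirichlet-process prior: any two peaks
co-cluster a priori with probability $1 / (P - 1 + \alpha_{DP})$, and a
Gibbs sweep reassigns each peak in ascending index order to an existing
cluster with weight $s_k \mathcal{L}$ or to a new singleton with weight
$\alpha_{DP} \mathcal{L}$. Only the pair terms involving the moved peak
enter the conditional (everything else cancels), which keeps a sweep at
$O(K P^2)$ pair evaluations; since the likelihood parameters are fixed,
the package precomputes the per-pair evidence difference
$D_{jj'} = \log \mathcal{L}_{in} - \log \mathcal{L}_{out}$ once, after
which a sweep costs $O(P^2 + PK)$ arithmetic. Conditional weights are
normalized in log space (subtracting the maximum) so they can never
underflow to an unnormalizable vector.

The posterior is summarized by the co-occurrence matrix
$\hat{\pi}_{jj'} = \Pr(\varepsilon_{jj'} = 1 \mid Q, R)$ and the
least-squares clustering: the retained draw minimizing
$\sum_{j<j'} (\varepsilon^{(s)}_{jj'} - \hat{\pi}_{jj'})^2$, ties broken
by the earliest draw. This point estimate is always one of the sampled
partitions, so it is guaranteed to be a coherent clustering.

## Defaults and their rationale

| parameter | default | why |
|---|---|---|
| $a_{in}, b_{in}$ | 10, 1 | co-eluting peaks from one compound have near-identical shapes; Beta(10,1) puts its mass near 1 |
| $a_{out}, b_{out}$ | 1, 1 | no prior shape preference for unrelated pairs |
| $p_0^{in}, p_0^{out}$ | 0.1, 0.5 | a missing co-observation is much more likely across compounds than within one |
| $\alpha_{DP}$ | 1.0 | weak preference for few clusters; the posterior cluster count is insensitive to its order of magnitude on well-separated data, though it grows with $\alpha_{DP}$ as the prior dictates |
| window | 30 s | a typical UPLC peak width; configurable |
| sweeps / burn-in / thin | 500 / 250 / 2 | ample for the strong likelihoods shape data produce; the small-problem validation below uses far longer chains |

Initialization is all-singletons, which avoids biasing early sweeps
toward merged solutions; an all-together start is available by flag.
Similarities are clamped to $[10^{-6}, 1 - 10^{-6}]$ at likelihood
evaluation only (the beta density is degenerate at the boundary, and
truncation makes exact zeros legitimate data); stored similarities are
never modified.

# Stage 2: covariate effects from peak heights

With the clustering $V$ fixed, centered log2 heights follow the
hierarchy

$$x_{\cdot i} \mid V, x^{lat}, \sigma^2 \sim N(V x^{lat}_{\cdot i},
\Lambda), \quad x^{lat}_{\cdot i} \mid \alpha, a_i \sim
N(\alpha_{\cdot a_i}, I), \quad \alpha_{\cdot l} \sim N(0, I)\ (l > 1),
\quad \sigma^2_j \sim \text{Scale-Inv-}\chi^2(n_0, \sigma_0^2),$$

with the baseline column $\alpha_{\cdot 1}$ fixed at zero for
identifiability. Every full conditional is conjugate — Gaussian for
latent means and effects, scaled inverse-$\chi^2$ for peak variances —
and missing heights contribute to none of them (omission, not
imputation). The latent prior covariance is the identity by design: the
unit latent variance is the model's scale anchor, and it is what limits
how sharply a small effect can ever be resolved, no matter how many
peaks a cluster has. Defaults $n_0 = 1$, $\sigma_0^2 = 1$ make the
variance prior weakly informative on the log2 scale.

Multiple covariates (at most two, optionally with their pairwise
interaction) enter as a sum of effect columns: the modelled cluster mean
of a sample is the sum of the columns applying to its covariate levels,
with the all-baseline cell fixed at zero. Significance of an effect is a
central 95% credible interval excluding zero; a one-sided
sign-probability variant is available by flag since "the posterior
probability of the effect being greater or less than zero" admits either
reading, and the two-sided rule is the more conservative choice.

Centering is provenance-tracked: `center_heights()` subtracts each
peak's observed control-group mean exactly once, and a dataset already
generated on the centered scale passes through untouched. This matters
more than it looks: empirically re-centering data that are already
centered injects an extra $1/n_{ctl}$ variance into every effect
estimate through the noise of the control mean.

# The baselines

`model2_effects()` is the height-only comparator: the same Gaussian
hierarchy, but the clustering is unknown, has a uniform multinomial
prior over `k_max` labels (default one per peak, so any partition is
expressible), and is resampled jointly with the effects — a peak's label
conditional is proportional to the Gaussian likelihood of its heights
under each cluster's current latent means, conditioning on the current
draws. Because labels switch freely, the run is summarized by its
co-occurrence matrix and least-squares point estimate, and the reported
effect posteriors are re-drawn at that fixed point estimate with the
stage-2 sampler; per-label averages across the joint run would mix
unrelated clusters.

`single_peak_effects()` is the conventional approach: per cluster, the
member with the largest mean observed (pre-centering) intensity —
annotated members take priority when annotations exist, ties break by
peak id — and the group-mean difference of its log2 heights (the log2
fold change), with a Welch t-test supplying a significance flag.

# The synthetic-data generator

`simulate_peaks()` draws data from exactly the stage-2 hierarchy plus a
similarity layer mirroring the stage-1 likelihood: latent cluster
concentrations $N(\alpha_{\cdot a_i}, I)$, heights with
$N(0, \sigma^2)$ peak noise, within-cluster similarities Beta(10, 1),
between-cluster Beta(1, 1), and co-observations masked with the same
within/between spike rates (0.1, 0.5) the clustering likelihood assumes.
A scalar missingness rate is accepted and recycled to both. The
reference conditions are 7 clusters × 7 peaks, two groups of 7 samples,
$\sigma^2 = 1$, and second-group effects $(2, -1, 0.5, 0, 0, 0, 0)$;
sample size, noise and peaks-per-cluster are the standard dials of the
evaluation grid.

Heights are generated directly on the centered scale (per-peak baseline
0) by default, because that is what the hierarchy itself specifies —
control latents fluctuate around the fixed zero baseline. Setting
`baseline_range` adds uniform per-peak baseline intensities, which
downstream fits must then remove by empirical centering, paying the
control-mean noise cost above; this is the realistic real-data regime.

What the generator does **not** emulate — and what passing simulations
therefore cannot certify: correlated compound concentrations
(co-regulated metabolism), batch and drift effects, intensity-dependent
noise, ionization competition that couples adduct ratios across
samples, retention-time misalignment, and annotation errors. Shape
similarities are drawn from the model's own beta slabs rather than
computed from simulated chromatograms, so the generator validates the
inference, not the Pearson-similarity front-end (which has its own
trace-level tests).

# Numerical and evaluation choices

* **Seeds.** Every stochastic function takes a `seed` and is bit
  reproducible; multi-replicate drivers draw per-replicate seeds from
  the master seed once, up front.
* **Cluster matching for scoring.** Inferred clusters are matched to
  generating clusters by greedy maximum peak-overlap (ties to the lower
  id; unmatched truth falls back to the largest-overlap inferred
  cluster) before effect MSE and sign-sensitive detection accuracy are
  computed.
* **NID.** $1 - I(A;B)/\max(H(A), H(B))$ from the label contingency
  table, defined as 0 when both partitions are trivial.
* **Degenerate inputs.** Single-peak datasets have an empty similarity
  product (log-likelihood 0); a cluster with no observed heights keeps
  its prior; peaks with no observed control value cannot be centered and
  are dropped with a warning; a fold change with an empty group is
  flagged `NA` rather than fabricated.
* **Problem sizes.** The validation suite enumerates all 15 partitions
  of 4 peaks against a 50,000-sweep chain, checks each conjugate
  conditional with $10^5$ draws, and runs the evaluation grid at
  $\sigma^2 \in \{1, 5\}$, 3 or 15 samples per group, 3–15 peaks per
  cluster with 10 replicates per cell — sizes chosen so the full suite
  completes in minutes on one CPU while keeping Monte-Carlo error well
  below the effect sizes being checked.

# Known limitations

* Detection power for small effects is bounded by the fixed unit latent
  variance: with $n$ samples per group the posterior SD of an effect
  cannot fall below roughly $1/\sqrt{n+1}$ however many peaks are
  observed, so e.g. a 0.5 log2 effect at $n = 15$ is flagged only about
  half the time. More peaks sharpen the *latent means*, not the
  between-sample scatter.
* The clustering assumes shape similarity is informative; co-eluting
  but unrelated compounds can be merged, and the model has no chemistry
  (no adduct mass rules or isotope spacing) to separate them.
* Hyperparameters of the similarity likelihood are fixed, not learned;
  grossly miscalibrated slabs (e.g. noisy similarities concentrated
  near 0.5) would need user adjustment.
* One or two covariates with independent effects only; no random
  effects, batch terms, or dependent-effect priors.
* The samplers are plain Gibbs: adequate for peak-table sizes (hundreds
  of peaks), but no split-merge moves for pathologically multimodal
  partition posteriors.
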