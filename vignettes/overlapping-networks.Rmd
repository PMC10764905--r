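---
title: "Detecting overlapping functional brain networks with a mixed-membership blockmodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting overlapping functional brain networks with a mixed-membership blockmodel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overnet)
```

## The problem

Functional connectivity (FC) analyses of brain-imaging time series usually
partition regions into *disjoint* networks: every region gets one label. Yet
association regions plausibly take part in several systems at once. This
package implements an *overlapping* network analysis for regional time series
from hierarchical designs (animals scanned over sessions, with several runs
per session): each region receives a membership vector over K networks —
a point on the K-simplex — rather than a single label, and every downstream
statistic (entropy, belonging counts, overlap scores, tiers) is built on
those graded memberships. Because the motivating recordings are restricted
access, the package ships first-class synthetic generators that emulate the
hierarchical design and planted community structure, and the whole pipeline
is exercised and calibrated against them.

## The model

The core is an assortative mixed-membership stochastic blockmodel (MMSB).
Every node $i$ has a membership vector $\pi_i \in \Delta^{K-1}$ drawn from a
Dirichlet prior. For each unordered pair $(i, j)$, each endpoint draws a
community indicator from its own membership vector; the pair links when the
indicators agree on some community $k$, with per-community rate $\beta_k$:

$$p(A_{ij} = 1 \mid \pi_i, \pi_j) = \sum_{k=1}^{K} \pi_{ik}\,\pi_{jk}\,\beta_k .$$

With $\beta_k = 1$ (the default of the graph sampler) the rule is the literal
"link on agreement" process. Node memberships therefore control both the
density inside communities and the mixing between them, and a fitted
$\pi$ matrix directly quantifies overlap.

### Inference

`fit_mmsb()` uses stochastic variational inference: Dirichlet variational
factors per node, Beta factors per community rate, and multinomial factors
for the per-pair indicators. Each iteration processes all observed links plus
a fresh uniform mini-batch of non-links (reweighted to keep the natural
gradient unbiased) and takes a step of size $\rho_t = (\tau + t)^{-\kappa}$.

Two numerical choices deserve explanation:

* **Step-size schedule.** $\kappa = 0.9$ follows the standard
  stochastic-approximation prescription ($\kappa \in (0.5, 1]$). For the
  offset we default to $\tau = 1$ rather than the large offsets used for
  massive graphs: at the few-hundred-node scale of a cortical parcellation, a
  large $\tau$ keeps the effective step near zero for the entire fit and the
  optimizer cannot leave the symmetric (uninformative) fixed point. With all
  links in every mini-batch, the gradient estimate is already low-variance,
  so an aggressive early step is safe. Both parameters are exposed in
  `mmsb_control()`.
* **Initialization.** The default is spectral: k-means (seed-controlled, so
  different seeds explore different basins and label orders) on the leading
  adjacency eigenvectors. A small random perturbation of the uniform
  membership matrix — the obvious neutral choice — empirically *stays*
  near-uniform on noisy graphs: the symmetric point is a fixed point of the
  variational updates and the schedule above cannot amplify microscopic
  asymmetries within a realistic iteration budget. Spectral hard labels break
  the symmetry while leaving the soft overlap structure to be learned by the
  variational updates; the planted-recovery tests confirm that genuinely
  overlapping memberships are recovered, not just the initializing partition.
* **Convergence.** The full-data objective is checked every 10 iterations;
  the fit stops early when its relative change stays below $10^{-6}$ for 10
  consecutive checks, otherwise at `max_iters`. Because non-link mini-batches
  are resampled, the trace jitters and typical runs stop at the iteration
  cap; the cap is therefore the effective tuning knob, and the planted
  benchmarks are already recovered at 60 iterations for 542-node graphs.

Isolated nodes carry no link information: they end near the uniform
membership and the fit warns. An empty graph is an error, not a uniform
answer.

## Consensus and aggregation

Community labels are arbitrary per fit, so solutions are combined by
alignment: membership columns from all seeds are clustered into K centroids
(k-means, 50 restarts, best inertia kept), each seed is aligned to the
centroids by maximum cosine similarity under an optimal one-to-one
assignment (a hand-written $O(K^3)$ Hungarian solver, brute-force-verified
for $K \le 6$), and the aligned matrices are averaged and row-renormalized.
The result is exactly invariant to per-seed column permutations (its column
*order* is anchored to the first seed). The generous restart counts here and
in the spectral initialization matter more than they look: when K exceeds
the number of planted communities, the surplus communities split large
blocks along weakly determined directions, and a poorly clustered consensus
blends incompatible splits, diluting every node's peak membership. With
enough restarts the per-seed solutions and their consensus agree to a mean
L1 distance of a few hundredths on the calibration benchmarks.

Aggregation follows the experimental hierarchy: runs are averaged within
session, sessions within animal, animals into the group, aligning each
matrix to the running centroid of its level before averaging. The
specification of whether re-alignment happens at *every* level is genuinely
open in this design; we align at every stage, which is a no-op when
solutions already share an order and protects against label drift when they
do not. Assignment ties break to the lowest column index.

## Node statistics

* **Membership entropy** (diversity): $h_i = -\sum_k \pi_{ik} \log_K
  \pi_{ik} \in [0, 1]$, computed on thresholded, renormalized memberships
  (`node_entropy`). A node split evenly across two of seven networks sits at
  $\log_7 2 \approx 0.356$.
* **Thresholding**: per animal, each node-community entry is tested against
  zero across runs (one-sample t, Benjamini–Hochberg FDR at $q = 0.05$ per
  animal); non-significant entries are zeroed and rows renormalized.
* **Belonging**: an entry belongs to a network when $t_{ik} = (\bar\pi_{ik}
  - \mu_0)/\mathrm{SE}_{ik}$ is significant one-sided, with $\mu_0 = 1/K$
  and SEs from the hierarchical bootstrap. The overlap score is the fraction
  of nodes belonging to more than one network. **Tiers** generalize this to
  multiples of $1/K$; the lowest tier multiplier is configurable because the
  two natural readings (0.05 or 0.5 times $1/K$) disagree in the motivating
  analyses, and we assert neither.
* **Distributions**: membership histograms use bins of width 0.2 over
  $(0.2, 1]$; values below 0.2 are excluded because a fully disjoint
  benchmark still spreads up to 0.2 of residual strength across the other
  networks (the calibrated "floor"; see below).
* **Degree, participation**: degree, degree normalized by region count,
  weighted degree over retained edges, and the participation coefficient
  $1 - \sum_s (k_{is}/k_i)^2$ over disjointified labels (isolated nodes are
  assigned 0 by convention, with a count reported).
* **Network similarity**: the three anchor points used to compare network
  maps (1 identical, 0.5 orthogonal, 0 inversely related) are only
  consistent with an affine rescaling $s = (c + 1)/2$ of a cosine that can
  go negative, so columns are mean-centered before the cosine; the raw
  uncentered cosine is attached as an attribute.

## Graph construction

Runs are band-pass filtered (zero-phase Butterworth — the forward-backward
pass doubles the effective order, a deliberate choice since phase handling
is otherwise unspecified — with 15 frames trimmed at each end), censored at
0.1 mm framewise displacement (a run is flagged when half its frames
exceed the threshold), correlated (Pearson), and binarized by keeping the
top $d = 15\%$ of signed correlation values so all graphs share one edge
count; ties at the cutoff break deterministically in lexicographic order,
and a magnitude-ranking mode exists but is off by default since "strongest
edges" is read as largest signed correlation. Group FC matrices for
gradients are Fisher r-to-z averaged and back-transformed.

## Gradients

`compute_gradients()` implements the diffusion-map embedding used in the
FC-gradient literature: each row of the group FC is sparsified to its top
10%, a cosine-affinity kernel is formed between sparsified profiles
(negative affinities clipped at zero to keep the kernel admissible),
anisotropically normalized with $\alpha = 0.5$, and eigendecomposed.
None of these kernel constants is dictated by the motivating analyses, so
all are configurable. Components are ordered by eigenvalue magnitude,
z-scored, and sign-fixed by making the largest-magnitude loading positive;
variance fractions are $\lambda_m / \sum \lambda$. A perfectly
block-diagonal FC yields a disconnected affinity graph, for which the
embedding is undefined — the function errors with the component count
rather than silently embedding one block, so block-structure tests use
weakly coupled blocks.

## Inference

The hierarchical bootstrap resamples animals with replacement, then sessions
within each sampled animal, then runs within each sampled session, keeping
every resampled path one that exists in the data. Intervals are BCa with the
acceleration from a jackknife over animals — the natural exchangeable unit,
since nothing smaller is exchangeable across animals; with a single animal
the acceleration is undefined and a percentile interval is returned with a
warning. The default 10,000 iterations (tests and the pipeline use fewer)
stands in for the very large budgets used on compute clusters; the estimate
simply tightens with more iterations. Paired condition comparisons use
two-sided sign-flip permutation tests (exact enumeration when $2^n$ fits the
budget, Monte-Carlo with the $(b+1)/(B+1)$ correction otherwise), with
Holm–Bonferroni for family-wise control and Benjamini–Hochberg where an FDR
is wanted.

## Synthetic data: what it emulates, and what it does not

`generate_hierarchical_dataset()` emulates the nested design (by default 10
animals × 3 sessions × 4 runs × 10 min at 1 Hz — 1200 minutes in total):
community latent time courses are low-pass-smoothed white noise (so slow
versus fast band analyses are meaningful), regional signals are
membership-weighted mixtures plus Gaussian noise, animal identity perturbs
the planted memberships on the logit scale, and each run carries a synthetic
motion trace with occasional spikes. `sample_mmsb_graph()` draws graphs from
the model's own generative process, and `generate_lfr_graph()` builds
LFR-style benchmarks: truncated power-law degrees (lower cutoff solved
numerically so the mean degree matches a 15% edge density), power-law
community sizes with exponent 0.1 truncated to 27–190 nodes (for the
542-node default), an exact number of overlapping nodes with an exact number
of memberships each, and a target fraction `mu` of external links. Degrees
and community sizes are rejection-resampled jointly with the
capacity-constrained membership assignment (cap 100); internal edges are
realized exactly per community by degree-sequence sampling, external edges
by a calibrated expected-degree construction, so degree and mixing are
matched to a few percent while ON and OM are exact. The mixing level for
the disjoint calibration defaults to `mu = 0.1`, a value typical of strongly
modular FC graphs, chosen a priori since it cannot be estimated from the
restricted recordings.

These generators reproduce the *structure* of the motivating data — nesting,
band-limited dynamics, planted overlap, motion spikes — but not its
physiology: no hemodynamics, no spatial autocorrelation, no condition-specific
noise spectra, no registration error. Passing tests therefore demonstrate
that the algorithms recover known structure under the stated noise model,
not that any particular biological claim transfers.

## Calibration: the 0.2 membership floor

The analysis pipeline treats membership values below 0.2 as unreliable. That
floor is calibrated, not assumed: fitting the model with 10-seed consensus
on a *fully disjoint* 542-node benchmark (where every node truly belongs to
one community) yields maximal membership values above 0.8 for the bulk of
nodes — the test suite checks the median — so even in the complete absence
of overlap, up to 0.2 of strength leaks to other communities. Real overlap
must therefore be claimed only above that leakage. `scripts/acceptance.R`
recomputes this calibration end to end.

## Problem sizes and limitations

The bundled tests and the acceptance script run at desk scale: one 542-node
benchmark with 10 fit seeds, 200-node recovery benchmarks, bootstrap
simulations with a few hundred iterations over a few hundred replicates.
These sizes were chosen so the full suite completes in minutes while leaving
every qualitative conclusion unchanged at larger budgets.

Known limitations: K is fixed in advance (no model selection); graphs are
binary and undirected; the variational fit finds a local optimum and relies
on the spectral initialization plus seed consensus rather than global
guarantees; LFR degree/mixing targets are met approximately (exactly only
for ON/OM); and BCa acceleration uses the animal-level jackknife, which is
a modeling choice wherever the hierarchy offers several exchangeable units.
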