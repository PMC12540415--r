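---
title: "Functional network topology from calcium imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional network topology from calcium imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calnet)
```

## The analysis problem

Two-photon calcium imaging of mouse primary visual cortex (V1) records the
activity of hundreds of neurons simultaneously while the animal receives
either unimodal visual (V) or bimodal visuotactile (V+T) stimulation. The
scientific question is topological: does cross-modal input reorganize the
functional connectivity network of V1 from a hub-centric, modular
architecture (few high-betweenness neurons mediating most shortest paths,
strong community structure) toward a distributed, globally integrated one
(uniformly elevated connectivity, higher closeness centrality and global
efficiency, dissolved modules)?

`calnet` implements the full analysis chain for this question: per-ROI trace
preprocessing and quality control, per-animal correlation-network
construction, graph-theoretic characterization, and paired nonparametric
comparison across animals, together with a synthetic data generator that
plants either architecture so the whole chain can be validated end to end.

## Preprocessing model

Each animal contributes one fluorescence trace matrix (ROIs × frames) per
condition. Processing stages advance in a fixed order — background
subtraction, exponential detrending, scaling, quality control, smoothing,
normalization — and the `trace_matrix` container enforces that stages may be
skipped but never reordered.

**Exponential detrending.** Photobleaching produces a slow exponential decay
of the baseline. Each ROI trace is fitted with
`f(t) = a exp(-t/tau) + c` by profiled least squares: for a candidate `tau`
the optimal `(a, c)` are solved linearly, and `tau` is located by a
log-spaced grid (the residual-sum profile can be nearly flat or multimodal
when transients dominate the trend) followed by local refinement. The fitted
trend is subtracted and its temporal mean added back, so the mean
fluorescence level — which the downstream maximum-response threshold needs —
is preserved. Subtraction rather than division keeps units linear and the
later min–max normalization well behaved. ROIs whose exponential fit fails
fall back to a linear detrend and are flagged in the attached report.

**Quality control.** Manually drawn ROIs include contaminants. After scaling
raw values by 0.001, an ROI is retained only if its variance is at least 1.0
and its maximum response at least 4.0 *under both conditions*. The variance
threshold removes spike-like artifacts (rare large transients over a flat
baseline leave overall variance low); the maximum threshold removes
white-noise ROIs (high variance but no genuine response excursions). QC
statistics are computed on the detrended, scaled, *pre-smoothing* traces:
a threshold of 4.0 cannot refer to min–max-normalized values (bounded by 1),
and smoothing would mask exactly the artifact signatures the filter targets.
Whether the statistics should be taken before or after detrending is not
fixed by the thresholds themselves; computing them after detrending was
chosen so that bleaching depth cannot push a genuine ROI below threshold.

**Smoothing and normalization.** Retained traces are smoothed with a
Savitzky–Golay filter. The nominal window of 20 frames is even, and a
symmetric least-squares window must be odd, so the default is the closest
valid width, 21 frames (configurable). Each trace is then min–max
normalized, `(F - F_min)/(F_max - F_min)`, spanning exactly [0, 1]. Constant
(degenerate) traces cannot be normalized; they are zeroed and flagged rather
than aborting a whole-study run.

## Network construction

For each animal and condition separately — neurons from different animals
are never mixed into one graph — the Pearson correlation between all pairs
of processed traces defines the edge weights. The correlation type is the
default reading of "correlation matrix" and Spearman is available in the
configuration. Three conventions matter downstream:

* **Negative correlations are clipped to zero.** Path-based measures require
  nonnegative weights; the number of clipped edges is recorded on the
  network object and in the run log.
* **The graph stays fully weighted** (threshold 0 by default). The
  unimodal condition is characterized by many near-zero connections rather
  than pruned ones; a threshold option exists for sensitivity analyses.
* **Weight-to-distance rule.** Shortest-path measures act on distances
  `d = 1/w` (the common convention in weighted brain-network analysis);
  `d = 1 - w` is available. Absent edges have infinite distance and
  unreachable pairs contribute nothing to path sums.

## Graph measures

All five measures are implemented from scratch and validated against
independent brute-force oracles (exhaustive simple-path enumeration,
Floyd–Warshall, pairwise modularity sums) in the test suite.

* **Betweenness centrality**: for node `v`, the sum over node pairs of the
  fraction of shortest paths through `v`, computed by Dijkstra traversals
  with exact shortest-path counting (equal-length multiplicities accumulate;
  ties are resolved by counting, never arbitrarily) and Brandes dependency
  accumulation. Reported normalized by `(n-1)(n-2)/2` so values lie in
  [0, 1]; raw values are retained alongside.
* **Closeness centrality**: `r_u / sum(d)` over the `r_u` reachable nodes,
  additionally scaled by `r_u/(n-1)` when the graph is disconnected
  (Wasserman–Faust correction), because "reachable nodes" implies
  per-component computation and a node reaching only a small component
  should not outscore one reaching the whole graph. Isolated nodes score 0.
* **Degree centrality**: node strength (summed edge weight) over `n - 1`;
  on a binary graph this is the classical degree centrality.
* **Global efficiency**: mean reciprocal shortest-path distance over ordered
  pairs; unreachable pairs contribute 0.
* **Louvain modularity**: standard two-phase Louvain on the edge weights,
  maximizing `Q = sum_c [L_c/m - gamma (k_c/(2m))^2]` with resolution
  parameter `gamma` (default 1.0 — no value is dictated by the analysis
  itself, and 1.0 is the conventional choice). Moves are accepted while the
  gain exceeds 1e-7, ties break toward the lowest community id, and the node
  visit order is shuffled deterministically from a seed, so results are
  reproducible per seed. The community-sum form of `Q` equals the pairwise
  form within 1e-12 (cross-checked in tests).

## Statistics

**Paired comparisons across animals.** Each animal is the unit of analysis:
per metric, the 11 per-animal values under V are compared with those under
V+T by a Wilcoxon signed-rank test with exact two-sided p-values. Zero
differences are dropped, absolute differences are midranked, and for up to
25 retained pairs the full null distribution of the rank sum over all `2^n`
sign assignments is computed by a generating-function recursion (identical
to explicit enumeration). Above 25 pairs a normal approximation is used with
moments that are exact under midranks, a continuity correction and an
Edgeworth kurtosis term; without the Edgeworth term the approximation can
miss the exact p-value by almost 0.02 at n near 10. A paired t-test p-value
is reported as a secondary column. No multiple-testing correction is applied
across the six metric comparisons; every output row carries a flag saying
so.

**Response hierarchy.** For each centrality measure the top five nodes
(deterministic tie-break toward the lower node id) are compared with the
remaining nodes by a two-sided Wilcoxon rank-sum test — the nonparametric
stance of the rest of the analysis, since no specific test is dictated for
this comparison. Response amplitude is defined as the mean over trials of
the per-trial peak inside the stimulus window (extended by 1 s for the
indicator lag) minus a pooled late-ISI baseline, measured on the smoothed,
scaled, *pre-normalization* traces: min–max normalization bounds every
trace by 1 and would erase precisely the amplitude differences this
analysis quantifies. The definition is configurable and logged.

## The synthetic generator

No public recording accompanies the study design, so the generator is a
first-class module that emulates its conditions: 11 animals, two paired
conditions over the same ROI set, 150 neurons per animal, trials of 2 s
stimulus and 4 s inter-stimulus interval, 12 directions, 10 repeats, 10 Hz
sampling, plus 10 contaminant ROIs per animal.

It is a second-order (common-input) model, not a spiking simulation: the
analysis consumes only correlations, so the contract is the correlation
structure. Per neuron, events are drawn from a stimulus-locked Poisson
process; events are then shared between coupled pairs with probability
proportional to the latent coupling; event trains are convolved with a
difference-of-exponentials calcium kernel (rise 0.1 s, decay 1.0 s, peak at
about 0.26 s with a ~1 s response footprint); hub amplitudes are multiplied
by the regime's gain; and an exponential bleaching trend plus Gaussian
noise are added.

Three design choices deserve justification because naive alternatives
demonstrably fail:

* **Sharing normalization.** Copy probabilities are `alpha * C_ij` with a
  single constant `alpha = share_scale / max_i sum_j C_ij` (default
  `share_scale` 1.5). Using the couplings directly as probabilities makes a
  150-neuron population receive tens of times its own event mass; every
  trace then collapses onto the population average and all pairwise
  correlations saturate near 1, erasing the planted architecture.
* **Direction tuning.** Non-hub neurons are direction-tuned
  (`((1 + cos(d - theta))/2)^4`); in the hub-centric regime neurons of a
  module share a preferred direction — the like-to-like functional coupling
  well documented in mouse V1 — and hubs are untuned integrators, while the
  distributed regime is broadly tuned (`tuning_strength` 0.3) with uniform
  random preferences. Without tuning, the stimulus envelope common to all
  neurons dominates every correlation after low-pass smoothing and no
  architecture is expressible.
* **Expression heterogeneity.** Each neuron carries a lognormal indicator
  expression gain (sd 0.2), drawn once per animal and shared across the
  paired conditions. Pearson correlations are invariant to per-trace
  scaling, so networks are unaffected, but amplitudes gain a dominant
  centrality-independent variance component. This mirrors real GCaMP
  expression variability and removes a subtle artifact: without it, neurons
  that receive more shared input have both higher amplitudes and higher
  degree, and a spurious response hierarchy appears in the distributed
  condition.

Artifact ROIs are planted by construction on the wrong side of exactly one
QC threshold: spike-like contaminants are near-constant with three large
transients (variance far below 1 after scaling, maximum above 4), and
white-noise contaminants are high-variance Gaussian traces clipped at a raw
value of 3200 (variance above 1, maximum below 4). The fluorescence
calibration (`event_amplitude` 6000, baseline 1000, bleach amplitude 500)
puts the weakest genuine neuron's post-detrend scaled variance near 3 —
comfortably above threshold — so the filter's planted/genuine separation is
exact rather than marginal. All calibration constants live in the
configuration, not the code.

The recording length and frame rate of the original experiments are not
part of the protocol description; 10 Hz and the full 12 × 10 trial grid
(720 s) are exposed defaults.

### What the generator does not emulate

Spiking dynamics, image stacks and motion (the pipeline consumes trace
matrices; image registration and ROI segmentation are out of scope),
neuropil contamination beyond a single background series, direction-tuning
curve analysis, and non-stationarities other than exponential bleaching.
Passing tests on synthetic data therefore demonstrate that the analysis
chain recovers planted second-order structure and planted response
hierarchies under realistic trial statistics — not that any particular
biological claim holds in real recordings.

## Validation design

The test suite checks, among others:

* betweenness and closeness against an exhaustive simple-path enumeration
  oracle and global efficiency against Floyd–Warshall on random graphs
  (tolerance 1e-9), plus closed forms on stars, complete graphs, paths and
  disjoint triangles;
* the exact signed-rank distribution against R's reference implementation
  on tie-free inputs, the exact-vs-approximate agreement (within 0.01 for
  n = 10..15), and the null rejection rate at alpha = 0.05 (within
  [0.03, 0.07] over 2000 replicates of n = 11);
* recovery runs: an 11-animal default study must show significantly higher
  mean betweenness and modularity under V and significantly higher mean
  closeness, mean degree and global efficiency under V+T; with hub gain 2
  in V and 1 in V+T the top-5 hierarchy must be present in V and absent in
  V+T across five seeded single-animal studies; the QC filter must exclude
  exactly the planted artifacts across five seeds;
* end-to-end determinism: identical configuration and seed produce
  bitwise-identical result bundles.

Problem sizes in the suite are the package's own choices: the full study
conditions (11 animals × 150 neurons × 7200 frames) for the direction
recovery run, and reduced sizes (e.g. 2 animals × 30 neurons for the
bitwise-determinism check, 12 neurons × 80 repeats for the
coupling-ordering recovery property, where identifiability — not scale — is
what the property needs).

One property deserves a caveat: the rank agreement between recovered edge
weights and latent couplings is verified in a sparse, high-contrast,
long-recording configuration. In the dense distributed regime the pairwise
ordering is intrinsically diluted — most of any pair's correlation is
carried by shared third-party input, a property of every common-input
model — so near-perfect edgewise recovery there is not a meaningful target.

## Known limitations

* Pearson correlation captures only linear, zero-lag dependence; no
  directionality or lagged coupling is estimated.
* The exact signed-rank test is two-sided only; one-sided variants are not
  exposed.
* Louvain is a greedy heuristic: Q is reproducible per seed and stable
  across seeds on these dense networks (within 0.02 in the suite), but
  global optimality is not guaranteed.
* Betweenness tie handling relies on a floating-point tolerance (1e-10
  relative on path lengths); exactly tied real-valued path sums beyond this
  tolerance are treated as distinct.
* The generator's correlations approximate, but do not equal, the latent
  couplings (see above); ground-truth-based assertions are therefore about
  ordering and architecture, not edgewise values.
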