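---
title: "Dynamic functional connectome patterns: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional connectome patterns: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dfcpattern` treats a resting-state scan as a sequence of *quasistable
connectome epochs*. The fitted object returned by `fit_dfcp()` is a
clustering of epoch-level summaries, built in four stages per subject and
one pooled stage:

1. **Windowed connectivity.** With window length $W$ (time points) and
   step 1, window $b$ of the ROI $\times$ time matrix yields a Pearson
   correlation matrix $\mathrm{dFC}(\cdot,\cdot,b)$ with zero diagonal.
   Correlations are left on the raw $r$ scale; no Fisher transform is
   applied anywhere, because every downstream quantity (strength sums,
   centroid averaging, the 0.75 visualization threshold) is defined on
   $r$.
2. **Strength profiles.** $\mathrm{dFCS}(i,b) = \sum_j
   |\mathrm{dFC}(i,j,b)|$ compresses each window to an
   $N$-vector. Absolute values mean anticorrelations count as
   connectivity; entries are bounded by $N-1$.
3. **Automatic segmentation.** Euclidean distances between adjacent
   strength columns form a curve whose *strict* local maxima are segment
   points: index $i$ is selected iff $d_i > d_{i-1}$ and $d_i > d_{i+1}$.
   Plateaus produce no peak (the rule is "larger than", not "no
   smaller"), the first and last distances can never be peaks, and a
   series with no peaks becomes one whole-series segment rather than an
   error. Segmentation runs along time; storage orientation of the
   strength matrix is irrelevant.
4. **WQCP samples.** Each segment's time-averaged strength vector is a
   whole-brain quasistable connectome pattern (WQCP) sample, weighted by
   its window count.
5. **Twice-clustering.** All subjects' samples are pooled and clustered:
   Ward-linkage hierarchical clustering (Euclidean, `ward.D2`) cut at $K$
   supplies initial centers; Lloyd iterations refine them with no random
   restarts, lowest-index tie-breaking, and reseeding of emptied clusters
   with the farthest sample. The stage is a pure function of its input:
   rerunning a fit reproduces it bit for bit. $K$ is selected by the
   minimum Davies–Bouldin index (ties to the smallest $K$).

Group inference then works on the fitted model: per-subject occupancy
ratios (sample counts, not window-weighted) feed a two-sample
equal-variance t-test per pattern at $p < 0.0001/K$ to separate
*specific* from *general* patterns; edgewise tests inside each general
pattern use one mean matrix per subject at $p < 0.0001/n_\text{edges}$;
and critical ROIs of a specific pattern are nodes whose degree AUC *and*
participation AUC exceed the network mean by more than one (sample,
$n-1$) standard deviation, with AUCs integrated over proportional
densities 0.10–0.40 in steps of 0.01.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| window duration | 36 | s | gives $W=12$ at TR 3.0 s and $W=18$ at TR 2.0 s; $W<3$ is rejected as degenerate. Explicit `w` override supports 12 s / 60 s sensitivity runs |
| window step | 1 | time points | maximal temporal resolution of the strength curve |
| `k_range` | 2–30 | — | selection range for the Davies–Bouldin minimum; reduced-scale analyses in the test suite use 2–8 (state-count recovery) and 2–6 (default cohort) purely as an analysis-scale choice |
| ratio threshold | 0.0001 / K | — | Bonferroni-style control over patterns |
| edge threshold | 0.0001 / $n_\text{edges}$ | — | $n_\text{edges} = N(N-1)/2$, i.e. 30,135 at 246 ROIs; parameterized so reduced-scale analyses scale correctly |
| density grid | 0.10–0.40 by 0.01 | proportion | only the range is canonical; the 0.01 step (31 points) makes the trapezoidal AUC stable |
| visualization threshold | 0.75 | $|r|$ | edges below it are zeroed in exported `.edge` files |
| motion limits | 1.5 / 1.5 | mm / degrees | strict inequalities; boundary values are kept |

## What the synthetic cohort emulates

`simulate_cohort()` produces two groups of 34 subjects by default, with
group-specific acquisition (TR 3.0 s, 150 retained volumes vs TR 2.0 s,
215 retained volumes — the cross-scanner situation the pipeline must
tolerate). Each subject's signal switches between latent states; within a
state, every time point is an independent draw from a zero-mean
multivariate normal with that state's covariance, plus isotropic
observation noise.

**State process.** The chain is $P = (1-\lambda)I + \lambda\,
\mathbf{1}\pi^\top$ with $\lambda = 1/\texttt{mean\_dwell}$. This is the
simplest family whose stationary distribution is *exactly* the configured
occupancy vector $\pi$ for any group; state $i$'s expected dwell per
visit is $\texttt{mean\_dwell}/(1-\pi_i)$, i.e. slightly above the
nominal value for high-occupancy states. A literal "self-transition
$1 - 1/\texttt{mean\_dwell}$ with occupancy-proportional jumps" chain was
rejected because its stationary distribution collapses to uniform in the
two-state case, destroying the planted occupancy signal that the whole
validation rests on. The default dwell of 60 time points (≈ 2–3 min)
keeps epochs long relative to the window so that most windows are
state-pure.

**State covariances.** Each state is a block (modular) correlation
matrix: unit diagonal, `within_r = 0.9` inside blocks, `between_r = 0`
across blocks, with the ROI-to-block assignment permuted per state.
Two structural choices matter and were found by analyzing the pipeline's
failure modes on this generator, not by aesthetics:

- *Unequal block sizes* (weights $(j+1)^2$, four blocks at 40 ROIs).
  With equal blocks, every ROI has the same expected strength in every
  state, so permuted states are invisible in WQCP space *by
  construction* — strength profiles, not correlation patterns, are what
  the clustering sees. Size-graded blocks give each state a distinctive
  profile.
- *Several blocks rather than two.* Windowed correlations of all edges
  joining one block pair co-fluctuate through a single factor-pair
  sample correlation. With only two large blocks this produces windows
  of globally elevated strength — a compact "transient
  hyperconnectivity" cloud that the Davies–Bouldin criterion happily
  carves out as an extra cluster. Spreading variance over four block
  pairs decoheres these fluctuations. The residual phenomenon is real
  and worth knowing about: sliding-window strength pipelines can
  manufacture a transient cluster from sampling covariance alone.

**Group difference.** Four states by default; state 1 occupies 45% of
group A's time and 5% of group B's. Four rather than three because
occupancies sum to one: the complement of the planted difference must go
somewhere, and with only two background states each would carry a real
0.2 occupancy shift of its own — occasionally crossing the conservative
threshold and making "exactly one specific pattern" false for a
legitimate reason. With three background states the shift is spread thin
and the background behaves as effectively null at realistic sample
sizes.

**What it does not emulate.** No haemodynamic response, no scan-to-scan
autocorrelation within a state, no subject-level random effects, no
scanner drift or physiological noise, no spatial structure beyond the
block pattern, and no NIfTI geometry. Passing tests demonstrate that the
pipeline recovers planted state structure under idealized switching
dynamics; they do not certify behavior on real BOLD data, where slower
autocorrelation makes windowed estimates noisier than the i.i.d. case.

## Numerical and procedural choices

- **Zero-variance windows** produce correlation 0 with a single warning
  per series, never NaN.
- **Ties** are resolved deterministically everywhere: lowest cluster
  index in K-means assignment, smallest $K$ at equal Davies–Bouldin
  values, ascending lexicographic edge order at the proportional
  threshold cutoff.
- **Edgewise tests use subjects, not windows, as the unit of analysis.**
  Windows within a subject are strongly dependent (adjacent windows share
  $W-1$ points); treating them as independent samples would inflate the
  effective $n$ by orders of magnitude. Each subject contributes the
  window-weighted mean of its matrices within the pattern; subjects
  absent from a pattern are excluded, and a pattern with fewer than two
  subjects in a group is skipped with a warning.
- **Student (equal-variance) t-tests** are used for both ratio and edge
  comparisons, matching the stated two-sample procedure; zero pooled
  variance gives $p = 1$ when group means agree and $p = 0$ otherwise.
- **Proportional thresholding ranks by absolute weight**: centroids
  contain negative correlations, and strength already treats
  anticorrelation as connectivity, so binarization must not silently
  drop it.
- **Participation coefficients need a node partition.** By default each
  thresholded graph is partitioned by greedy modularity maximization
  (deterministic); a user-supplied partition is accepted. Published
  critical-ROI tables cannot be replicated exactly without knowing the
  original partition, which is why validation here is against synthetic
  centroids with known structure.
- **No feature normalization of WQCP vectors** before clustering:
  strength entries share a common scale by construction, and rescaling
  would change which differences the clustering sees.
- **K is held fixed during resampling reproducibility** (at the
  reference model's K) so that run-to-run differences reflect sampling,
  not model-order jumps; subjects are resampled without replacement
  within group.
- **Per-subject seeds** derive from the master seed by 32-bit-safe
  modular mixing, so cohorts are reproducible and subjects independent.

## Problem sizes used by the test suite

The validation suites run at desk scale: 40 ROIs, 10 subjects/group for
state-count recovery (planted 2, 3 and 5 states over 10 seeds each), 34
subjects/group for specific-pattern detection (10 seeds) and 90%
resampling (4 runs), and 20 null cohorts at 10 subjects/group for
specificity. Full-scale 246-ROI cohorts are supported by the same code
paths. The bundled atlas ships abbreviations and gyrus-level descriptions
for all 246 regions but no stereotactic coordinates; only
`export_brainnet_files()` needs coordinates, and it takes them from the
atlas table the caller supplies.

## Known limitations

- The strict-peak rule yields short segments (typically ~3 windows) on
  noisy distance curves, so single WQCP samples remain noisy; the
  pipeline compensates with sample volume, not smoothing (none is
  applied, and no minimum segment length is imposed).
- Window-length differences between groups (W = 12 vs 18) bias windowed
  $|r|$ sums differently in the two groups; with weak true connectivity
  this can push clusterings toward group- rather than state-structure.
  The generator's strong state contrast makes state structure dominate;
  on real data this acquisition confound deserves explicit attention.
- Only two groups are supported in classification and edgewise testing.
- The Davies–Bouldin curve is recomputed with a full twice-clustering
  per candidate K, which is the dominant cost at large sample counts.
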