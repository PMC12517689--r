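---
title: "Phase-coherence coordination dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-coherence coordination dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one page

`phasecoord` quantifies how a multichannel brain recording moves through
recurrent whole-brain coordination patterns, and how strongly those patterns
are anchored to the anatomical connectome. The pipeline is:

1. **Conditioning.** Each regional time series (N regions x T volumes, one
   matrix per scanning run) is cleaned by global-signal regression, a
   zero-phase band-pass (0.0025-0.05 Hz) with a fast-Fourier notch at
   0.03 Hz, and per-region z-scoring. The order is fixed: GSR, filters,
   z-score, phase extraction.
2. **Instantaneous phase.** The analytic representation
   $\tilde{x}(t) = x(t) + i\,H[x(t)]$ yields amplitude $A(t)$ and phase
   $\varphi(t)$ per region; $A(t)\cos\varphi(t)$ reconstructs the input
   exactly. The first and last volume are dropped because the transform of
   a finite record is least reliable at its edges (111 volumes give 109
   phase frames).
3. **Phase-coherence frames.** At every retained volume the pairwise
   coherence $PC(i,j,t) = \cos(\varphi_i(t) - \varphi_j(t))$ forms a
   symmetric unit-diagonal matrix; its strict upper triangle (row-major
   pair order, length $N(N-1)/2$) is one *frame*. Frames from all runs of
   an analysis set are stacked in a canonical order (condition, subject,
   run, volume) with full provenance.
4. **Pattern discovery.** Euclidean k-means (k-means++ seeding, Lloyd
   iterations, best of `n_init` restarts by within-cluster sum of squares)
   clusters the frames into k coordination patterns. The number of patterns
   is chosen by maximising the inter-pattern correlation variance (IPCV) --
   the population variance of all pairwise Pearson correlations between
   centroids -- with the elbow of the WSS curve as a cross-check.
5. **Anatomical anchoring.** Each pattern's structure-function correlation
   (SFC) is the Pearson correlation between its upper triangle and the
   connectome's. Patterns are relabelled in ascending SFC; pattern k, the
   "anatomical pattern", tracks the structural backbone most closely.
6. **Dynamics metrics.** Per run: pattern occupancies (fraction of frames
   per pattern), Shannon entropy $S = -\sum_i P_i \log_2 P_i$ of the
   occupancy distribution (optionally divided by $\log_2 k$), and the OLS
   slope of occupancy on SFC. A steep positive slope and low entropy are
   the signature of dynamics pinned to anatomy, as seen under
   unconsciousness; a flat slope and high entropy characterise rich awake
   dynamics.
7. **Markov transitions.** Transitions between *distinct* consecutive
   patterns (self-transitions ignored, run boundaries never crossed) are
   counted and row-normalised. Reliability is assessed against a
   permutation null: the label order is shuffled uniformly within each run,
   the matrix recomputed (10,000 draws by default), and a transition is
   accepted only if its empirical probability strictly exceeds the null's
   upper quantile at 90/95/99% confidence.
8. **Group statistics.** Condition contrasts use independent two-sample
   t-tests with Bonferroni correction, either from raw per-run metric
   vectors or directly from published mean/SD/n summaries, plus two- or
   three-way type-II factorial ANOVA (sum-to-zero coding, aliased terms
   reported rather than dropped).

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| band edges | 0.0025, 0.05 | Hz | the band of slow hemodynamic coordination; also defines the narrowband regime the Hilbert phase needs |
| notch | 0.03 +/- 0.002 | Hz | removes a pure artifact line; width chosen to kill the line while sparing the 0.02 Hz region |
| filter order | 2 | -- | Butterworth magnitude response per edge; flat passband |
| trim | first + last volume | -- | edge distortion of the discrete Hilbert transform |
| `n_init`, `max_iter` | 100, 200 | -- | clustering restarts/iterations; planted-recovery experiments converge with far fewer, so the bundled experiments scale `n_init` down (5 for a fixed-k fit, 2 per k in a selection sweep) |
| `n_permutations` | 10,000 | -- | transition null; quantiles change by <0.02 beyond ~1,000 draws on run-sized sequences, so the calibration experiment uses 1,000 |
| Bonferroni family | contrasts per metric | -- | the family is the set of condition contrasts tested for one metric |

# The synthetic generator

No raw imaging data ships with the package, so a generator produces studies
with the statistical structure the pipeline assumes; every pipeline claim is
validated against its planted ground truth.

**Connectome.** Symmetric, hollow, lognormal (heavy-tailed) weights;
82 regions by default in two mirrored hemispheres with enriched
within-hemisphere wiring and mostly connected homotopic pairs; edge count
matches `density` (default 0.3) to one entry.

**Templates.** Each of k coordination templates is an exact
cosine-difference matrix $T_{ij} = \cos(o_i - o_j)$ of a per-region offset
vector. Template m scales the m-th non-trivial harmonic (Laplacian
eigenvector) of the connectome by a dispersion that grows geometrically
from 0.4 to 2.4 rad, plus 10% jitter. Harmonic gradients make the templates
anatomically structured yet mutually well separated; small dispersions give
near-global coherence, large ones mix in- and anti-phase pairs. Templates
are ordered by ascending SFC, so the planted "anatomical pattern" is always
pattern k.

**Dynamics.** A sticky Markov chain per condition,
$P = \lambda I + (1-\lambda)\,\mathbf{1}\pi^\top$, has exactly the
requested stationary occupancy $\pi$. The default persistence
$\lambda = 0.85$ gives mean dwell times of ~6.7 volumes (16 s), long
enough for the band-limited phase to settle between switches, and per-run
occupancy standard deviations of ~0.15 at 109 frames -- matching the
run-to-run spread reported for the stimulation study this design emulates.
The default five-condition set plants anatomical-pattern occupancies of
0.37 / 0.33 / 0.34 / 0.50 / 0.51 (baseline, anodal, post-anodal, cathodal,
post-cathodal), the published effect sizes; remaining mass is spread evenly
over the other patterns, a deliberate simplification.

**Signals.** Region i carries $\cos(2\pi f t + o_i(\text{state}(t)))$ at
f = 0.02 Hz (mid-passband, clear of the notch) plus white Gaussian noise of
standard deviation 1/snr (default snr 5) added *before* filtering, so the
conditioning filters define the effective noise band as in real
acquisition. State switches blend the outgoing and incoming carriers with a
raised-cosine cross-fade over 2 volumes to avoid broadband transients.

**What the generator does not emulate:** hemodynamic convolution, spatially
correlated physiological noise, motion artifacts, multi-oscillator
broadband dynamics, or template variability within a state. Passing the
planted-recovery experiments therefore demonstrates the pipeline's
correctness under its own assumptions, not its robustness to everything
real data can do.

# Numerical and design choices

* **Zero-phase filtering.** The band-pass applies the squared magnitude
  response of a 2nd-order Butterworth in the frequency domain (the exact
  zero-phase equivalent of forward-backward filtering), and the notch
  zeroes the FFT bins within +/-0.002 Hz of 0.03 Hz. A time-domain
  forward-backward recursion would carry a transient with a ~64 s time
  constant from the 0.0025 Hz corner -- a third of a 111-volume run -- and
  is not exactly symmetric under time reversal; the frequency-domain
  realisation has neither problem (filtering commutes exactly with
  reversing the series, at the cost of assuming periodic boundaries).
* **GSR at region level.** The global regressor is the mean across regions;
  voxel-level regression would happen upstream of this package's inputs.
  When planted templates contain a strong common component, GSR removes it;
  the recovery experiments therefore run with `gsr = FALSE`, and the flag
  is exposed.
* **Phase convention.** Phases are wrapped to the half-open interval
  $[-\pi, \pi)$; pair order is row-major (i < j).
* **IPCV convention.** Population (divide-by-m) variance over the
  $k(k-1)/2$ pairwise correlations; exact ties in the k selection break
  toward smaller k.
* **k-means.** `stats::kmeans` Lloyd iterations behind the package surface,
  with package-own k-means++ seeding; an initialisation that produces an
  empty cluster is redrawn and counted. Convergence is Lloyd's assignment
  fixpoint or `max_iter`, whichever comes first.
* **t-tests.** Pooled (Student) by default, which reproduces the majority
  of the recomputable published statistics; the Welch form is a flag. One
  published transition contrast (2 to 6, baseline vs. cathodal) is
  reproducible only under Welch -- the package keeps both routes and the
  discrepancy is visible in the acceptance outputs.
* **Entropy conventions.** "Raw" entropy is in bits; "normalised" divides
  by $\log_2 k$. Both are computed per run, and group tests treat runs as
  independent observations.
* **Within-run shuffling.** The transition null permutes labels within each
  run only, because frames from different runs are not temporally adjacent
  -- matching the empirical matrix, which never counts transitions across
  run boundaries. Null quantiles use the inclusive (type-7) convention; for
  a single sequence of up to 7 labels the null is enumerated exactly
  instead of sampled.
* **Degenerate inputs** are first-class: zero-variance global signal falls
  back to centring with a warning, zero-variance regions and undefined
  correlations raise errors naming the culprit, all-zero transition rows
  are flagged rather than renormalised, and aliased ANOVA terms appear as
  `NA` rows.

# Known limitations

* **IPCV-based k selection over-selects on cleanly planted clusters.** On
  synthetic studies with well-separated templates, splitting a true cluster
  produces two nearly identical centroids whose correlation (~1) *raises*
  the variance of pairwise correlations, so the IPCV maximum tends to land
  above the planted k (the elbow diagnostic flags the disagreement). The
  statistic is informative on heterogeneous empirical repertoires -- where
  centroid correlations spread widely and extra clusters add mid-range
  values -- but it is not a consistent estimator of a planted cluster
  count, and the package reports it alongside the WSS curve rather than
  treating it as ground truth.
* The generator's hidden-state model (phase templates switched by a Markov
  chain) is a stand-in for whatever latent process generates real data; it
  makes the pipeline testable, not a claim about biology.
* Slope values depend on the spread of SFC values in a pattern set;
  comparing slopes is meaningful within one analysis set, not across
  different clusterings.
* Group tests treat runs as independent observations, ignoring session and
  animal nesting (the factorial ANOVA surface exists to examine those
  factors explicitly).

# Experiment sizes

The bundled validation experiments use: a 20-run, 82-region, 111-volume
study at snr 5 for planted-pattern recovery; 200 replicates of length-800
iid sequences with 1,000-permutation nulls for false-positive calibration;
and 100 replicates of an 80-runs-per-condition two-condition study
(hidden sequences only) for effect-direction recovery. These sizes were
chosen so each experiment is decisive for its question while remaining
comfortably runnable on a laptop.
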