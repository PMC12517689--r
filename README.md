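# phasecoord

Dynamic functional-coordination analysis of multichannel brain time series.

Resting brain activity is not static: regional fMRI signals drift through
recurrent whole-brain coordination patterns, and how much those patterns
resemble the anatomical connectome separates conscious from unconscious
dynamics. `phasecoord` implements the full phase-coherence pipeline used to
study such dynamics — in particular how perturbations such as transcranial
direct current stimulation reshape them — for anyone analysing
region-by-time recordings against a structural connectome.

The core quantities, in the field's standard notation:

* analytic signal `x̃(t) = x(t) + i H[x(t)] = A(t) e^{iφ(t)}` per region,
  after zero-phase band-pass (0.0025–0.05 Hz) and notch (0.03 Hz) filtering;
* per-volume phase coherence `PC(i,j,t) = cos(φ_i(t) − φ_j(t))`, vectorised
  over the `N(N−1)/2` region pairs;
* k-means *brain patterns* (centroids of the coherence frames), with the
  inter-pattern correlation variance (IPCV) and the WSS elbow as
  k-selection diagnostics;
* structure–function correlation (SFC) of each pattern against the
  connectome, pattern occupancies `P_i`, Shannon entropy
  `S = −Σ P_i log₂ P_i`, and the OLS slope of occupancy on SFC;
* off-diagonal Markov transition matrices with a within-run
  temporal-shuffle permutation null (90/95/99% envelopes);
* pooled/Welch two-sample t-tests (from raw samples or printed summaries),
  Bonferroni correction, and type-II factorial ANOVA.

A synthetic-data module generates state-switching narrowband studies with
planted coherence templates, hidden Markov state sequences, and
condition-dependent occupancies, so the whole pipeline is exercisable and
calibrated without access to raw imaging data.

## Worked example

Simulate a two-condition study in which the "stimulated" condition spends
more time in the anatomical pattern, then run the pipeline:

```r
library(phasecoord)

cfg <- simulation_config(
  n_rois = 20, n_volumes = 111, k_states = 3,
  conditions = list(
    list(name = "before", n_runs = 6, occupancy = c(0.35, 0.35, 0.30)),
    list(name = "stim",   n_runs = 6, occupancy = c(0.20, 0.20, 0.60))),
  seed = 7)

res <- run_pipeline(simulation = cfg, k = 3, gsr = FALSE,
                    n_init = 10, n_permutations = 1000, seed = 7)

res$patterns
#> <pattern_set> k = 3 patterns, WSS = 2.048e+04
#>   SFC (ascending):  0.188, 0.262, 0.281

aggregate(cbind(p3, entropy_bits, slope) ~ condition, res$metrics, mean)
#>   condition        p3 entropy_bits     slope
#> 1    before 0.1376147    1.3309891 -3.452859
#> 2      stim 0.7262997    0.9754522  4.207248

subset(res$group_tests, metric == "slope")
#>   metric condition baseline     mean       sd baseline_mean baseline_sd
#> 3  slope      stim   before 4.207248 2.662185     -3.452859    1.144948
#>          t df            p   p_adjusted
#> 3 6.474691 10 7.120551e-05 7.120551e-05
```

Pattern 3 — the highest-SFC, "anatomical" pattern — dominates under
stimulation (73% of frames vs. 14% at baseline); accordingly the per-run
Shannon entropy drops (0.98 vs. 1.33 bits) and the occupancy-vs-SFC slope
flips from negative to strongly positive (t = 6.5, df = 10, p ≈ 7e-5).
That triplet — occupancy shift toward the anatomical pattern, lower
entropy, steeper slope — is the pipeline's signature of dynamics
collapsing onto the anatomical backbone.

Per-condition transition structure against the permutation null:

```r
res$transitions$stim$empirical
#> <transition_matrix> 3 patterns, 35 counted transitions
#>       [,1]  [,2]  [,3]
#> [1,] 0.000 0.600 0.400
#> [2,] 0.308 0.000 0.692
#> [3,] 0.333 0.667 0.000
res$transitions$stim$significant$`0.95`
#>       [,1]  [,2]  [,3]
#> [1,] FALSE  TRUE FALSE
#> [2,]  TRUE FALSE FALSE
#> [3,] FALSE  TRUE FALSE
```

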