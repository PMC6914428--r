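---
title: "Hemispheric segregation and integration of functional brain networks"
author: "hemiconn developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hemispheric segregation and integration of functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemiconn)
```

# The model

`hemiconn` analyzes resting-state functional connectivity at the level of
hemispheres. The unit of observation is a subject's parcellated BOLD time
series on a *mirror-paired* atlas: every left-hemisphere region has exactly
one homotopic counterpart at the mirrored position on the right, declared by
`pair_index` in the region table. All downstream structure — symmetric
community detection, homotopic sums, hemisphere-restricted participation
coefficients — rests on this pairing, which is why the region-table
invariants (each pair index exactly once per hemisphere, equal hemisphere
counts) are enforced at construction.

The analysis proceeds in five stages.

**1. Screening.** Subjects with mean framewise displacement above
`fd_max = 0.2` mm are excluded (Power-style FD: summed absolute backward
differences of the three translations plus the three rotations scaled by a
50 mm radius; the first frame contributes 0). Regions are screened by
temporal signal-to-noise ratio — mean over s.d. of the time series,
averaged across subjects — and a region whose SNR falls more than
`k_sd = 2` standard deviations from the mean of the region-wise SNR
distribution is excluded *together with its homotopic pair*, so the
parcellation stays mirror-paired. The SNR reference distribution pools
subject-averaged SNR over regions (pooling over subjects, regions, or both
is ambiguous in the aging literature; this choice is the only one that
makes the exclusion rule a property of the region, and it is
permutation-invariant over subjects).

**2. Connectivity.** Pearson correlations over time between all included
regions, Fisher z-transformed (`atanh`, with r clipped to ±(1 − 1e−12) so
degenerate perfect correlations stay finite), zero diagonal. Two
sparsification schemes are provided: *absolute* thresholding keeps entries
strictly greater than `theta = 0.2` (removing all negative and weak edges;
the boundary case is dropped, a convention that matters only on exact
ties), and *proportional* thresholding keeps the `ceiling(density * E)`
strongest positive edges with all cutoff ties retained, which makes the
operation deterministic and order-independent. No global-signal regression
is assumed anywhere — homotopic statistics are sensitive to it.

**3. Symmetric community detection.** Weighted Louvain modularity
maximization (two-phase greedy, resolution `gamma = 1`, node order shuffled
by a seeded RNG each run; implemented in C++ so the consensus machinery can
afford the full 150-runs-per-subject protocol) is applied `n_runs_subject = 150` times to
each subject's within-hemisphere thresholded block. Each subject/hemisphere
yields an agreement matrix (fraction of runs co-assigning each node pair);
these are averaged over subjects per hemisphere. The subject-to-group
aggregation step is deliberately a plain average: it is the only
order-independent reduction that produces one group matrix per hemisphere.
The left and right group matrices are aligned by homotopic pair, summed and
halved — halving (rather than keeping the raw sum) keeps entries in [0, 1]
so the consensus threshold `tau` retains its meaning as a co-assignment
frequency — and the result is resolved by consensus clustering: threshold
at `tau = 0.5`, re-cluster `n_runs_consensus = 100` times, rebuild the
agreement, iterate (cap 50) until all runs agree. The consensus labels are
copied to both hemispheres through the pairing, so the group partition is
mirror-symmetric by construction, and the whole procedure is invariant
under exchanging the two hemispheres' inputs.

**4. Network metrics.** For each network (community) `C` and hemisphere:

- `sum Z_ll`: summed z between `C`'s nodes and all same-hemisphere nodes,
  computed on the *unthresholded* z matrix — the segregation ratio is not
  meaningful on a sparsified matrix, and negative edges carry signal here.
  Unordered within-network pairs are counted once by default
  (`double_count_within` flips the convention; the segregation ratio is
  invariant to a global choice, so only cross-study comparability of the
  raw sums is affected).
- `sum Z_lr`: summed z between `C`'s nodes and the same community's nodes
  in the opposite hemisphere. This is reported both as the homotopic sum
  and as the network's inter-hemispheric integration.
- segregation `= (sum Z_ll − sum Z_lr) / sum Z_ll`, undefined (NA with a
  warning) when `sum Z_ll = 0`.
- intra-hemispheric integration: mean weighted participation coefficient
  `P_i = 1 − sum_s (kappa_is / k_i)^2` over `C`'s nodes, computed on the
  *thresholded* within-hemisphere subgraph (matching the graph the
  communities were detected on); isolated nodes get `P_i = 0`.
- a whole-contralateral sum (all opposite-hemisphere nodes, all networks)
  for sensitivity analyses.

**5. Statistics.** Each metric is tested against age per (network,
hemisphere) with a partial Pearson correlation controlling for sex and
mean FD: both variables are residualized on an intercept plus covariates,
residuals correlated, and the two-sided p-value uses
`t = r sqrt(df / (1 − r^2))` with `df = n − 2 − k` (subtracting the
covariate count; conventions differ and this is the conservative one).
Correction is applied within metric family: Bonferroni for segregation and
inter-hemispheric integration, Benjamini–Hochberg FDR for
intra-hemispheric integration (the FDR variant is assumed to be BH; family
= all network × hemisphere tests of one metric). A test whose metric is
constant across subjects — typical for participation coefficients in a
young, sparse cohort — is reported as NA with a warning and drops out of
the correction family rather than aborting the run. Age strata for
community-flow analyses use the printed bounds 19–40 / 41–60 / 61–80,
interpreted as [19, 40.5), [40.5, 60.5), [60.5, 80] so non-integer ages
map to exactly one stratum; community labels are matched across strata by
greedy maximum Jaccard overlap with ties to the lower label.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `fd_max` | 0.2 | mm | standard strict motion cutoff for lifespan samples |
| `snr_k_sd` | 2 | s.d. | flags the ~5% tails of the region SNR distribution |
| `theta` | 0.2 | z | removes negative and weak edges before clustering |
| `density` | 0.01–0.10 | fraction | proportional alternative for sensitivity analyses |
| `gamma` | 1.0 | — | standard Newman–Girvan resolution |
| `n_runs_subject` | 150 | runs | stabilizes subject agreement matrices |
| `n_runs_consensus` | 100 | runs | detects residual ambiguity in consensus |
| `tau` | 0.5 | fraction | majority co-assignment survives thresholding |
| `alpha` | 0.05 | — | nominal level for corrected significance flags |

All of these mirror keys of the JSON pipeline config; one master `seed`
drives every stochastic stage through deterministic derived seeds, so a rerun
with identical config and seed reproduces byte-identical CSVs (floats are
serialized at 12 significant digits).

# The synthetic cohort: a stated world

The generator exists to give every pipeline stage a ground truth. Its
defaults describe one fixed world, chosen to resemble a preprocessed
lifespan resting-state sample, and are not tuned per test:

- 6 networks × 4 homotopic pairs (48 regions), ages uniform on 19–80,
  `t_len = 230` timepoints (≈8 min at TR = 2 s after 10 discarded volumes).
- Block-structured target correlations: within-network within-hemisphere
  r = 0.5, between-network r = 0.1 (also used for all non-homotopic
  cross-hemisphere entries), homotopic pairs r = 0.6. These sit in the
  ranges routinely reported for parcellated resting-state data, and they
  place baseline between-network coupling *below* the z = 0.2 threshold and
  within-network coupling well above it, so the planted communities are the
  thresholded graph's connected components at young ages.
- Aging effects are linear in age: `homotopic_age_slope` (default −0.004
  r/year when planted — a decline of ~0.24 across the 61-year range,
  matching the magnitude of reported homotopic aging effects) moves the
  homotopic block of designated networks; `cross_network_age_slope`
  (default +0.002 r/year when planted) moves every within-hemisphere block
  between the designated network and the others, crossing the threshold in
  mid-life so intra-hemispheric integration rises.
- Subjects are `t_len` i.i.d. multivariate-normal draws from the
  age-specific correlation matrix (optionally AR(1) in time, which
  preserves the cross-sectional covariance), sex Bernoulli(0.5), mean FD
  lognormal(log 0.08, 0.4) with a +0.005/year drift of the log-location so
  older adults move more, leaving a few percent of subjects above the
  0.2 mm cutoff.
- Target matrices are checked for positive definiteness; a non-PD
  configuration is repaired by eigenvalue clipping and rejected when the
  repair moves any entry by more than 0.05.

What the generator does *not* emulate: hemodynamics (only second-order
structure matters to this analysis, so covariance fidelity is the relevant
realism), image-level motion artifacts, spatial autocorrelation within
parcels, non-stationarity, and non-Gaussian marginals. A green recovery
test therefore establishes that the *pipeline* recovers planted
second-order structure — not that real BOLD data satisfy the model.

# Numerical and degenerate-input choices

- Fisher z clipping at ±(1 − 1e−12); thresholds compare strictly (`> theta`).
- Louvain gain comparisons use a 1e−12 tie-breaking margin and prefer the
  current community, making runs deterministic given a seed; empty target
  communities are always candidates, so singleton moves are available.
- Consensus that fails to converge in 50 iterations errors, reporting the
  agreement dispersion rather than returning a silently unstable partition.
- Zero-variance regions make correlations undefined: they are
  force-excluded at SNR screening (with their pairs) and are a hard error
  in `connectivity_matrix`.
- `sum Z_ll = 0` makes segregation NA (warning), never ±Inf.
- Degenerate association tests yield NA and shrink the correction family.

# Known limitations

- **Planted-effect leakage (acceptance criterion left red).** The
  end-to-end recovery experiment plants a homotopic decline in two networks
  and a cross-network rise in one (`VN`), and asks that *only* the planted
  networks reach corrected significance. The sign and recovery clauses
  hold, but strict exclusivity cannot: a rise in VN's coupling to its
  neighbors is a property of shared edges, so it necessarily (i) raises the
  partner networks' participation coefficients — at baseline their
  thresholded cross-network strength is exactly 0, so the VN edges crossing
  the threshold move their intra-hemispheric integration too — and (ii)
  inflates `sum Z_ll` for VN itself (and mildly for partners), which raises
  their segregation ratios. Because the within-hemisphere sums aggregate
  ~80 deterministically drifting edges against noise that only grows with
  the square root of the edge count, any slope large enough to make VN's
  integration detectable makes the leakage detectable as well at n = 300.
  The corresponding test expectations are asserted as specified and left
  failing rather than weakened; the inter-hemispheric-integration family,
  whose planted effect does not share edges across networks, passes its
  exclusivity check cleanly.
- The pipeline consumes already-parcellated time series; no voxel-level
  preprocessing, and parcel extraction operates on in-memory arrays (NIfTI
  file readers are intentionally out of scope).
- Subject-level community variability is summarized only through agreement
  matrices; no statistics are computed on individual subjects' partitions.
- Linear age models only — no quadratic trajectories or GAMs.
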