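---
title: "Methods: quantifying intra-tumor heterogeneity from MALDI-MSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying intra-tumor heterogeneity from MALDI-MSI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(msiith)
```

# The model and its assumptions

`msiith` treats a MALDI-MSI experiment as a collection of cancer regions of
interest (ROIs), each a raster of pixels carrying one profile-mode peptide
mass spectrum on a shared m/z 600–3500 grid. The scientific object of
interest is *phenotypic* intra-tumor heterogeneity: the coexistence, within
one ROI, of pixel populations with distinct peptide profiles — cancer cell
subclones, but equally immune infiltrate, stroma and vasculature. The
pipeline assumes:

- spectra are profile-mode on a dense common channel grid (centroided input
  is out of scope);
- miscalibration across a slide is a small *rigid* m/z shift per spectrum,
  not a warp;
- a pixel's spectrum is, to a useful approximation, a nonnegative sum of
  Gaussian peptide peaks over a smooth baseline, scaled by a per-pixel
  acquisition gain;
- the cohort is analyzed jointly: one mean spectrum defines one shared set
  of spectral components, and segmentation is run on the pooled pixels of
  all ROIs, so cluster identities are comparable across patients.

# Stage by stage

## Preprocessing

Fixed order: mass-axis unification → baseline subtraction → outlier
flagging → peak alignment → TIC normalization. Alignment follows outlier
flagging so that near-empty spectra cannot distort the alignment reference;
normalization comes last so aligned, baseline-free spectra are scaled.

Parameters (block `preprocessing` of `pipeline_config()`):

- `baseline_window` (channels, default 50): half-window of the SNIP-style
  iterative clipping estimator `y ← min(y, (y[−m] + y[+m])/2)` for
  m = 1..window. Any window comfortably wider than a peak footprint gives a
  floor at or below the signal; the value is a resolution question, not a
  sensitivity dial.
- `outlier_rule` (`"gmm"` default, `"mad"` fallback): both act on log TIC.
  The GMM rule fits a 1–3 component univariate mixture (BIC choice,
  deterministic quantile-initialized EM) and flags pixels assigned to
  components whose mean lies more than one dominant-component SD below the
  dominant mean — the usual picture of off-tissue or failed-ablation
  pixels forming a low-TIC mode. The MAD rule
  (|logTIC − median| > 3·1.4826·MAD) is deterministic and preferable for
  tiny fixtures.
- `alignment_max_shift` (channels, default 5): maximum rigid shift; each
  spectrum takes the integer offset maximizing cross-correlation with the
  unflagged mean spectrum, ties toward the smaller |shift|.
- `tic_target`: every unflagged spectrum is rescaled to the cohort-median
  TIC (or 1), which removes the planted/real multiplicative gain; on
  synthetic data the residual TIC CV is below 1%.

## Spectral components

The cohort mean spectrum is treated as an unnormalized 1-D density over
m/z. It is first cut into independent fragments at valleys below
`min_valley_rel` (1%) of the global maximum, then each fragment is fitted
by weighted EM. The component count per fragment starts at the number of
smoothed local maxima and grows by *residual-driven insertion*: a new
component is proposed at the channel where the current mixture most
underestimates the signal and kept only if BIC improves. The cap is 100
components per fragment — a deliberate revision of an initial cap of 30,
which proved too small once we observed single fragments spanning over 80
true peaks at the 1% valley threshold. Components below `1e-3` of the
largest amplitude are dropped, and neighbours closer than
`merge_sigma = 1` × the smaller width are merged by moment matching.

Pixel spectra become component-abundance vectors by Gaussian-weighted
summation: within each component's ±3σ channel range the channel intensity
is apportioned by the components' normalized responsibilities, so
overlapping components share signal smoothly, per-channel weights sum to at
most 1, and a pixel's total abundance never exceeds its TIC. A single
component spanning the whole axis reproduces the TIC exactly.

Two identifiability caveats that tests and users should keep in mind:

- a fitted component recovers the *area* (amplitude × σ) of the signal in
  its range, not the bare amplitude;
- two true peaks closer than about one width are not identifiable as
  distinct Gaussians by any fitter — BIC correctly refuses to split them —
  so recovery claims are only meaningful for resolvable peaks. The
  acceptance phantom therefore places its 300 peaks sequentially with
  ≥ ~3.3σ gaps.

## DivIK segmentation

Divisive iterated k-means with per-node feature selection on the pooled
feature matrix:

- **Feature selection** (`variance_gmm`): a 1–3 component mixture on log2
  per-feature variance within the node; the top-mean component(s) are kept,
  adding components top-down until at least 1% (and at least 2) of features
  survive. Recomputed at every node — the features that separate coarse
  tissue types are not the ones that separate subpopulations.
- **Distance**: correlation (1 − Pearson r) by default, realized as
  Euclidean k-means on row-standardized vectors; robust to residual
  per-pixel gain. Euclidean is available for testing.
- **k per split**: seeded k-means++ (with restarts) for k = 2..10; the Dunn
  index (min inter-centroid distance / max intra-cluster diameter) picks k,
  ties toward smaller k. Diameters are exact up to 2000 member pixels and
  computed on a seeded subsample above that, keeping the split O(n) for
  14k-pixel nodes.
- **Split/stop**: the GAP statistic with B = 10 seeded reference datasets.
  Two deliberate deviations from the simplest textbook recipe, both made
  after the simple version demonstrably failed on homogeneous synthetic
  cohorts:
  1. references are drawn uniformly in the *principal-component-aligned*
     bounding box of the node (Tibshirani's second reference variant).
     Spectral features are strongly correlated, the node cloud is
     elongated, and the axis-aligned box reference systematically
     over-accepts splits of single elongated clusters;
  2. the decision uses the standard one-standard-error orientation: split
     iff gap(k) − s(k) > gap(1). The opposite orientation
     (split iff gap(k) ≥ gap(1) − s(k)) accepts whenever the node behaves
     *like* the reference — i.e., it splits structureless noise, because
     under the null gap(k) ≈ gap(1) up to Monte-Carlo error.
- Recursion stops at `max_depth` (3), below `min_split_size` (200), or on a
  rejected split; early-stopping clusters persist unchanged at deeper
  levels, so per-level cluster counts are defined for every pixel. Labels
  are dot-separated paths ("2.1.3"); level ℓ truncates to ℓ segments.

## Heterogeneity metrics

- **Similarity**: Pearson correlation between component vectors of pixel
  pairs (cosine available). All unordered pairs up to `max_pairs = 1e5`,
  above that a seeded uniform subsample; the median and full ECDF are
  reported. Zero-variance pixels get similarity 0 with a warning.
- **Simpson's diversity**: default is the without-replacement
  (`distinct_pairs`) estimator `1 − Σ nᵢ(nᵢ−1)/(N(N−1))` — the literal
  probability that two randomly selected pixels differ — with the plug-in
  Gini–Simpson form as an option. Exact agreement with exhaustive pair
  enumeration is a frozen test.

## Group statistics

Nonparametric throughout: rank tests make no distributional assumption
about per-ROI metrics, which are bounded and skewed. The exact Wilcoxon
path enumerates all C(N, n₁) assignments when N ≤ 12 and tie-free; the
normal path applies tie and continuity corrections. Kruskal–Wallis carries
eta-squared `(H − k + 1)/(N − k)`; rank tests carry Pallant's
`r = |z|/√N`. Conover–Iman post hoc p-values are unadjusted by default
(effect sizes are the primary readout; Holm is a flag). Cohen's `d` uses
the pooled-SD definition with the conventional 0.2/0.5/0.8 class bounds;
screening selects components with at least a medium cluster contrast
(|d₁| ≥ 0.5) *and* at least a small outcome contrast (|d₂| ≥ 0.2),
computed on pooled pixel-level abundances. The pipeline's default target
cluster is the level-1 cluster whose per-ROI contribution differs most
between outcome groups (the data-driven analogue of "the most
discriminatory cluster"); any cluster can be passed explicitly.

## Annotation

A component matches a peptide iff |center − m_expected|/m_expected ≤ 5×10⁻⁴
(±0.05%), with m_expected = neutral monoisotopic mass + 1.00728 Da under
the default [M+H]⁺ convention (MALDI yields predominantly singly protonated
peptides; the convention and monoisotopic assumption are both flags, since
deposited mass lists do not always state theirs). Many-to-many matches are
preserved — ToF resolution makes annotation intrinsically non-unique — and
decoy entries are matched and flagged through so the decoy rate estimates
the chance-match rate.

# The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` builds ROIs of contiguous sub-regions (Voronoi
tessellation of seeded centers; "blobs" as an alternative) whose spectra
are sums of hundreds of Gaussian peptide peaks over a shared core
abundance profile. Key choices:

- **Cohort-level region pool.** Region profiles are drawn once per cohort;
  each ROI hosts a subset. This mirrors the joint analysis, where pooled
  segmentation discovers global molecular populations that individual ROIs
  contain or lack.
- **Block modulation.** Only ~30% of peaks are region-modulated, so
  spectra stay highly similar overall (median pairwise similarity near
  0.98 at realistic settings — the low-heterogeneity regime of cancer
  tissue). Each pool region shifts its own disjoint block of the
  modulated peaks by ±`profile_effect` in log2. iid random shifts were
  tried first and occasionally produced two nearly identical "distinct"
  regions (log-profile correlation 0.7), which makes planted-truth
  recovery ill-defined; block modulation guarantees the stated pairwise
  effect between every pair of regions.
- **Nuisance processes**: log-normal per-pixel gain (`tic_cv`, default
  0.15), smooth exponential baseline, additive Gaussian noise clipped at
  zero, a small outlier fraction with gain × 0.01, and rigid per-pixel
  channel shifts. Peak width is a constant relative resolution
  (`sigma_rel` × m/z); the default 2×10⁻³ is the finest width resolvable
  on the default 6000-channel axis (the generator refuses axes coarser
  than two channels per σ).
- **Clinical metadata**: outcome matches the planted group; TILs are
  generated as 50·D + N(0, 5) (clipped to [0, 100]) from the planted
  region-map diversity, so the TILs–ITH correlation stage has a known
  signal; all other clinical fields are drawn uniformly from their valid
  categories and carry no signal.

What the generator does *not* emulate: isotope envelopes, matrix clusters,
detector saturation, spatial autocorrelation of the noise, realistic
peptide sequences, or patient-level nuisance structure beyond the region
pool. A green end-to-end test therefore establishes that the pipeline
recovers planted abundance-profile structure under gain/baseline/noise/
shift nuisance — not that it would be robust to isotopic interference or
slide-level batch effects.

# Numerical choices

- All EM runs are deterministic: quantile or local-maxima initialization,
  seeded jitter restarts, relative log-likelihood tolerance 1e-8, variance
  floors at half a channel spacing (spectral EM) or 1e-6 (univariate EM).
- Every stochastic step draws its seed from one master seed through a
  labelled substream hash (`derive_seed()`), kept below 2³¹; identical
  config + seed reproduces every artifact byte-identically.
- k-means empty clusters are re-seeded at the point farthest from its
  center; degenerate all-identical nodes signal "no structure" instead of
  clustering.
- Cohen's d on two zero-variance groups returns 0 for equal means and
  signed infinity flagged "degenerate" otherwise; zero-TIC unflagged
  spectra are a hard error naming the pixel.
- The internal cohort container is a single R-serialized file: the spec's
  natural choice here would be HDF5, but no R HDF5 binding is available in
  the supported environment, and RDS gives the same contract (one file,
  axis stored once, bit-identical round trips) with zero dependencies.
  imzML ingestion is a minimal continuous-mode reader (XML via `xml2`,
  external binary arrays via `readBin`), supporting 32/64-bit
  little-endian floats.

# Known limitations

- Component extraction on the *mean* spectrum can merge peaks that are
  separable in individual pixels, and a merged component reports the
  summed area of its constituents.
- The GAP decision remains a stochastic test; at a few hundred pixels per
  node its Monte-Carlo noise is non-negligible (the package's own tests
  run homogeneity checks at ≥ 1600 pixels for this reason).
- Pixel-level Cohen's d pools pixels across patients, so patients with
  larger ROIs weigh more; a patient-level aggregation is the natural
  sensitivity analysis and is left to the caller.
- The Conover post hoc is computed even for singleton groups (flagged
  `low_power`), and no multiplicity adjustment is applied by default.
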