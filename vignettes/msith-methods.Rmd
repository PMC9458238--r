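---
title: "Quantifying intratumor heterogeneity from MALDI-MSI peptide maps: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumor heterogeneity from MALDI-MSI peptide maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msith)
```

## The problem

MALDI mass spectrometry imaging (MSI) records a full mass spectrum at every
position (pixel) of a tissue section. After on-tissue tryptic digestion, each
pixel's spectrum is a superposition of peptide peaks, and the spatial pattern
of those spectra carries information about intratumor heterogeneity (ITH):
how molecularly diverse a pathologist-delineated cancer region of interest
(ROI) is, and how much a primary tumor (T) differs from its lymph-node
metastasis (N). `msith` implements the full chain from raw pixel spectra to
ITH statistics:

1. **Preprocessing** — mass-channel unification, baseline subtraction,
   outlier-spectrum removal, peak alignment, TIC normalization.
2. **Componentization** — Gaussian mixture modeling (GMM) of the average
   spectrum; each retained component is treated as one tryptic peptide
   species, and per-pixel abundances are inner products of the pixel spectrum
   with unit-area component profiles.
3. **Segmentation** — DivIK, a divisive iterative k-means with region-driven
   feature selection, producing nested cluster labels over all pooled pixels.
4. **Heterogeneity indices** — pairwise spectral similarity distributions
   (intra- and inter-ROI) and the Gini–Simpson diversity of cluster
   membership per ROI.
5. **Differential analysis** — Cohen's *d* per component and Cohen's *h* per
   cluster proportion, with magnitude classes; rank tests and Fisher's exact
   tests for group comparisons and clinical tables.
6. **Annotation** — matching component centroids against an LC-MS/MS peptide
   library within a relative mass tolerance (default ±0.05 %).

Because raw clinical MSI datasets of this kind are not freely
redistributable, the package ships a synthetic generator that emulates the
statistical structure the analysis assumes, with full ground truth. All
validation in the test suite runs against that generator.

## The synthetic data model

A simulated pixel spectrum is

```
s(mz) = TIC_scale * ( sum_k A[cluster, k] * Gauss(mz; mu_k, sigma_k) + baseline(mz) ) + noise
```

* **Peaks.** `n_peaks` Gaussian species are placed uniformly at random with a
  minimum spacing of 3 maximal peak widths, so the planted model is
  identifiable by a mixture fit; widths are uniform on `peak_sigma_range`.
  The default axis spans m/z 700–3000 (the acquisition range of the
  instrument class being emulated) at 0.5 Da spacing, giving roughly ten
  samples across a peak.
* **Clusters.** Each ROI contains `n_clusters_per_roi` molecular clusters
  laid out as contiguous patches: a Voronoi diagram whose cells are grown to
  prescribed pixel counts by greedy capacity-constrained nearest-seed
  assignment. Cluster mean profiles are i.i.d. log-normal across peaks, which
  makes distinct clusters weakly correlated (separable) by construction.
* **Study structure.** `simulate_two_arm_study()` draws one peptide set and
  one cluster-profile library per study and shares them across all patients
  and both arms. This mirrors pooled segmentation of many patients: clusters
  correspond to recurring tissue structures, not patient-private signals.
  Arms differ only in heterogeneity parameters (number and balance of
  clusters per ROI).
* **Nuisance structure.** A smooth exponentially decaying baseline; a
  log-normal per-pixel TIC scale with configurable coefficient of variation
  (mean 1); additive Gaussian noise clipped at zero; and a configurable
  fraction of outlier pixels whose TIC is scaled ×10 or ×0.1, matching the
  TIC-based outlier screening in preprocessing.
* **Paired T/N.** With `paired_tn = TRUE` a second ROI is emitted whose
  cluster profiles have a fraction `tn_divergence` of peaks scaled ×2 or
  ×0.5.

What the generator deliberately does **not** emulate: isotope envelopes (one
Gaussian per species; the componentization treats a species with its envelope
as one component), detector saturation, nonlinear mass drift, or histology
images. Passing tests therefore demonstrate correctness of the algorithms
under the stated statistical model, not instrument-level realism; the
generator's noise magnitudes are chosen for testability, as no quantitative
noise model is available for the emulated data.

## Preprocessing choices

The published processing chains for this data type are cited rather than
specified in the primary literature, so each stage here is the simplest
method satisfying its contract; all are exposed with tunable parameters.

* **Channel unification** interpolates linearly onto the intersection range
  at the finest native spacing; exact for linear spectra, identity for
  already-matching axes.
* **Baseline** is a rolling minimum followed by a moving average of the
  minimum envelope (window default 101 channels, chosen much wider than a
  peak), subtracted with negatives clipped. Re-running it on its own output
  changes at most the Gaussian-tail floor between peaks (tested to < 0.1 % of
  the maximum intensity).
* **Outliers** are pixels whose log-TIC deviates from the median by more
  than 3 robust SDs. The robust SD is the MAD scaled to normal consistency,
  floored at 0.25 log units: on nearly noise-free data the MAD collapses and
  an unfloored rule flags entire molecular clusters whose total signal is
  biologically different; the floor encodes the smallest TIC spread still
  considered ordinary acquisition variation, while true acquisition outliers
  (×10/×0.1, |log| ≈ 2.3) remain far outside the band.
* **Alignment** estimates a constant integer channel shift per pixel (±5 by
  default) maximizing cross-correlation with the pooled mean spectrum;
  channels shifted out of range are zero-padded.
* **TIC normalization** divides by the per-pixel total and multiplies by the
  pooled mean TIC so intensities keep their scale.
* **Stage order** is fixed (unify → baseline → outliers → align → TIC →
  GMM → abundance) and recorded in a provenance log that the tests assert.

## GMM componentization

The baseline-subtracted pooled average spectrum is treated as a binned
density over m/z. One component is initialized at every local maximum above
an intensity quantile threshold (default: the median), and weighted EM
refines centers, widths and weights to a relative log-likelihood change of
1e-8 (at most 500 iterations). Components with weight below 1e-5 or widths
outside plausible peak-width bounds (default 0.5–50 channel spacings) are
pruned. Each component's density is evaluated only within ±8 SD, which keeps
models with a couple of thousand narrow peaks linear in the number of
components; a full-range model of that size fits in well under five minutes
on one CPU in the test suite. Abundance of component *k* in pixel *p* is the
inner product of the pixel spectrum with the unit-area component profile, so
a pure spectrum `a·Gauss(mu, sigma)` yields abundance `a/(2·sigma·sqrt(pi))`
(the Gaussian self-overlap integral) — the closed form the tests check.
An optional merge of components spaced like isotope envelopes (1.00235 Da) is
available but off by default, since a species and its envelope are modeled as
a single component.

## DivIK segmentation

Each node of the divisive tree re-selects features on its own pixels
("region-driven"): stage 1 fits a two-component 1-D GMM to log mean
abundance per feature and drops the low-mean (noise) component; stage 2 fits
the same model to log variance of the survivors and keeps the high-variance
component. A stage is skipped when its fit is degenerate — components
overlapping (mean gap below the larger SD), SD ratio above 10, or a single
Gaussian at least as good by BIC — or when it would leave fewer than
`min_features` features (default 8): with only two features every
row-standardized vector collapses onto two points and correlation distance
becomes meaningless.

Clustering uses k-means under Pearson correlation distance. Since
`1 − r(x, y)` equals the squared Euclidean distance between row-standardized
vectors divided by `2(p − 1)`, Lloyd iterations on standardized rows optimize
the correlation objective exactly; the implementation verifies this against
brute-force assignment enumeration on tiny instances. Initialization is
seeded k-means++ with 10 restarts; cluster numbering is canonicalized by
centroid order so identical partitions get identical labels.

The number of children *k* (2..`k_max`, default 10) is chosen by the Dunn
index in the correlation metric — minimum inter-centroid distance over
maximum intra-cluster diameter — with ties broken toward smaller *k*.
Diameters of clusters above 2000 pixels are estimated on a seeded 2000-pixel
subsample (the exact diameter is quadratic in cluster size). A split is
accepted only if the best Dunn index reaches `tau` and every child holds at
least `min_cluster_fraction` of the input pixels. The default `tau = 2` has a
geometric justification measured during development: an arbitrary bisection
of an unstructured point cloud in the correlation metric produces
anti-correlated centroids (inter-centroid distance near 2) over an
intra-cluster diameter approaching 2, so null Dunn values concentrate near 1
regardless of sample size, while genuinely clustered nodes score an order of
magnitude higher. Requiring the centroid separation to exceed twice the
largest diameter therefore rejects null splits; the suite checks this over
20 seeds of homogeneous data and, conversely, full recovery of planted and
nested structure. Pixels whose node stops splitting keep their label at all
deeper levels, so every level is a complete, nested partition.

## Heterogeneity indices

* **Similarity** between two pixels is the Pearson correlation of their
  component-abundance vectors (cosine similarity available by option). The
  formula behind the published index is specified only by citation, and
  correlation matches both the clustering metric and the behavior of the
  published summaries (identical spectra → 1); this interpretation is
  deliberate and flagged here.
* **Distributions** are computed over all unordered intra-ROI pairs or the
  full inter-ROI cross product, with a cap (default 1e7 pairs) beyond which a
  seeded uniform subsample is taken — ROIs of ~17k pixels imply ~1.5e8
  pairs. The subsampled median is tested to agree with the exhaustive median
  within 0.01. Group-level values aggregate as the median over patients of
  per-patient medians (a robust two-stage summary; an interpretation, since
  the published aggregation is not spelled out).
* **Simpson diversity** is the Gini–Simpson form `D = 1 − Σ p_i²` — the
  probability that two pixels drawn with replacement belong to different
  clusters — matching the "two randomly selected spectra" reading; the
  finite-sample (without-replacement) form is exposed as an option and
  differs by less than `1/N`, which the tests confirm. `D` is checked against
  brute-force pair enumeration for all tried count vectors with `N ≤ 50`.
* **Group comparisons** use the two-sided Wilcoxon rank-sum test (exact for
  ≤ 20 observations without ties, normal approximation with tie correction
  otherwise) or Kruskal–Wallis for more than two groups.

## Differential analysis and annotation

Cohen's `d = (mean_a − mean_b)/s_pooled` treats pixels as observations (the
compared units are groups of spectra); a patient-aggregated mode can be built
from per-patient means for sensitivity analyses. Magnitude classes use the
conventional 0.2/0.5/0.8 thresholds on |d| (and |h|); selection is by
magnitude class, not p-value, and no multiple-testing correction is applied
— effect sizes, unlike p-values, do not inflate with pixel count. Cohen's
`h = 2·asin(√p1) − 2·asin(√p2)` quantifies cluster-proportion shifts, and is
computed on pooled pixels by default (per-patient pooling being the main open
alternative). Fisher's exact test (hypergeometric two-sided for 2×2,
Freeman–Halton for r×c, a seeded Monte Carlo mode above 1e4 observations) and
the equal-variance two-sample t-test cover the clinical descriptor tables.

Annotation matches component centers (for a symmetric Gaussian, center and
mode coincide) to library peptide masses within relative tolerance
`|mu − m|/m ≤ 5e-4`, the library's measured mass being the reference
denominator; matching uses binary search on the mass-sorted library and is
tested against brute-force all-pairs comparison. Matches are not unique by
design; protein lists are deduplicated accessions over matched peptides.

## Numerical choices and degenerate inputs

* EM: relative log-likelihood tolerance 1e-8, 500-iteration cap, SD floored
  at half a channel spacing (feature-filter fits: a relative floor).
* Constant pixels: rows with zero variance standardize to the zero vector
  (distance 1 to everything); wholly constant nodes become leaves.
* k selection ties break toward smaller k; k-means restarts that produce
  empty clusters are discarded.
* Zero-TIC pixels are an error after outlier removal (they indicate an
  upstream problem), and empty peptide libraries yield an empty annotation
  table with a warning.
* All randomness is seeded: the simulator end-to-end from its config seed,
  per-patient seeds derived from the study seed, k-means++ restarts from the
  DivIK seed, pair subsampling and Monte Carlo modes from explicit arguments.

## Problem sizes in the validation suite

The test and acceptance runs use desk-scale versions of the study design:
default ROIs of 20×20 pixels, 150 peptide species over the full m/z range
(reduced ranges for unit tests), two arms of 20 patients with per-patient
seeds 1..40, a pooled segmentation of ~16k retained pixels, and 200
replicates for the null calibration of the rank test (10 patients per
identical arm, using the per-patient median intra-ROI similarity as the
calibrated statistic — the cluster-based index would require hundreds of
full segmentation runs for the same check of the same test). These sizes are
the package's validation design; every number reported by the suite or the
acceptance script is computed at run time from these simulations.

## Known limitations

* The similarity index and the feature-filter details are interpretations of
  methods specified by citation; both are documented above and exposed as
  options where alternatives exist.
* Published cluster counts and similarity medians from the original clinical
  material are scale references only — the raw data are not public, and the
  synthetic generator does not attempt to reproduce them numerically.
* Correlation-distance k-means with Dunn-based k selection can under-split
  when clusters are strongly positively correlated with small separation;
  the threshold `tau` trades null-split rejection against sensitivity to
  such weak structure.
* imzML ingestion is not provided; datasets enter through the package's
  documented text/float32 container, TSV metadata and JSON models.
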