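# msith — intratumor heterogeneity analysis for MALDI mass spectrometry imaging

`msith` quantifies molecular intratumor heterogeneity (ITH) from MALDI-MSI
peptide maps: spatially resolved mass spectra acquired pixel-by-pixel over
tissue sections after on-tissue tryptic digestion. It is aimed at analysts of
MSI cohort studies who need a tested, reproducible route from raw pixel
spectra to per-region heterogeneity statistics and group comparisons — for
example, contrasting patients with no evidence of disease against patients
with progressive disease, or primary tumors (T) against lymph-node
metastases (N).

The pipeline implements, end to end:

* **Preprocessing** — mass-channel unification, rolling-minimum baseline
  subtraction, robust TIC-based outlier-spectrum removal, cross-correlation
  peak alignment, TIC normalization.
* **GMM componentization** — the pooled average spectrum is modeled as a
  Gaussian mixture; each component is one tryptic peptide species, and the
  abundance of component *k* in pixel *p* is the inner product
  `a[p,k] = Σ_mz s_p(mz) · N(mz; μ_k, σ_k) · Δmz`.
* **DivIK segmentation** — divisive iterative k-means under Pearson
  correlation distance `1 − r`, with region-driven feature selection per
  node, Dunn-index model selection, and nested multi-level labels.
* **Heterogeneity indices** — pairwise spectral similarity distributions
  (`S(x, y) = r(x, y)`, intra- and inter-ROI, with seeded subsampling beyond
  10⁷ pairs) and the Gini–Simpson diversity `D = 1 − Σ p_i²` of cluster
  membership per ROI — the probability that two random pixels belong to
  different clusters.
* **Effect-size differential analysis** — Cohen's
  `d = (x̄_a − x̄_b)/s_pooled` per component, Cohen's
  `h = 2·asin(√p₁) − 2·asin(√p₂)` per cluster proportion, magnitude classes
  at |·| = 0.2/0.5/0.8, Wilcoxon/Kruskal–Wallis group tests, Fisher's exact
  test (2×2 and Freeman–Halton r×c) for clinical tables.
* **Peptide annotation** — matching component m/z centroids to an LC-MS/MS
  library within ±0.05 % relative mass tolerance.
* **Synthetic MSI generator** — planted clusters, peaks, baseline, TIC
  variation, noise and outliers with full ground truth, used by the entire
  validation suite.

## Worked example

A small synthetic two-arm study: a high-ITH arm (4 balanced molecular
clusters per tumor ROI) versus a low-ITH arm (1 cluster), 6 patients per arm,
run through the full pipeline (preprocess → segment → heterogeneity):

```r
library(msith)

cfg_high <- simulation_config(mz_min = 700, mz_max = 1500, n_channels = 1601L,
                              n_peaks = 60L, peak_sigma_range = c(1, 2),
                              roi_shape = c(16L, 16L),
                              n_clusters_per_roi = 4L,
                              n_patients_per_group = 6L, seed = 42L)
cfg_low <- cfg_high
cfg_low$n_clusters_per_roi <- 1L

res <- run_pipeline(run_config(simulation = list(high = cfg_high, low = cfg_low),
                               divik = divik_params(max_levels = 2L),
                               max_pairs = 5e3, seed = 7L))
rep <- res$report
```

Output (abridged):

```
components: 58
clusters per level: 8 8
    roi group n_clusters simpson_d median_similarity
1 H01_T  high          4      0.75            0.2454
2 H02_T  high          4      0.75           -0.0606
3 H03_T  high          4      0.75           -0.0588
4 H04_T  high          4      0.75           -0.0207
Simpson D medians: high 0.750 / low 0.000 (Wilcoxon p = 0.0024)
similarity medians: high -0.037 / low 1.000 (Wilcoxon p = 0.0022)
```

Reading this: the mixture model recovered 58 of the 60 planted peptide
species; pooled DivIK found the 8 cluster profiles shared across patients;
every high-arm tumor ROI contains its 4 planted clusters (Simpson
`D = 1 − 4·(1/4)² = 0.75`, the balanced-4 maximum), while single-cluster ROIs
give `D = 0` and near-perfect intra-ROI similarity. The Wilcoxon tests report
the planted contrast: higher cluster diversity and lower spectral similarity
in the high-ITH arm.

The same stages are callable individually (`preprocess_study()`, `divik()`,
`heterogeneity_summary()`, `differential_components()`,
`match_components()`, ...), and a thin command-line front-end over the same
functions lives in `inst/scripts/msi_ith.R`.

## Repository layout

```
R/                     implementation (simulator, preprocessing, segmentation,
                       heterogeneity, differential, annotation, pipeline)
tests/testthat/        unit, property and acceptance tests
scripts/acceptance.R   end-to-end reproduction script
vignettes/             methods vignette: model, assumptions, design choices
inst/scripts/          command-line front-end
```
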