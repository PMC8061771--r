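# AdductIMS

Adduct-resolved analysis of MALDI imaging mass spectrometry (IMS) lipid
data, built around the sodium/potassium adduct pair ratio of membrane
lipids in colon mucosa.

In positive-ion MALDI-IMS, each lipid species appears as three cation
adducts — `[M+H]+`, `[M+Na]+`, `[M+K]+`. For a species with corrected
adduct intensities *I*<sub>Na</sub> and *I*<sub>K</sub>, the pair ratio

&nbsp;&nbsp;&nbsp;&nbsp;*f*<sub>Na</sub> = *I*<sub>Na</sub> / (*I*<sub>Na</sub> + *I*<sub>K</sub>), &nbsp; *f*<sub>K</sub> = 1 − *f*<sub>Na</sub>

is a per-pixel reporter of tissue ion homeostasis: ~0.5:0.5 in healthy
colon mucosa, shifting to ~0.3:0.7 in adenomatous mucosa for every
phosphatidylcholine (PC) species and for sphingomyelin SMd34:1, in both
the epithelium and the lamina propria. The package provides:

- **`lipidPanel()` / `colonPanel()`** — exact-mass registry (formula-derived
  monoisotopic masses, cation = atom − electron), ppm matching, candidate
  lookup. The colon panel contains two engineered isobaric pairs
  ([PC 34:1+Na]+ / [PC 36:4+H]+ at 3.07 ppm and [PC 36:1+Na]+ /
  [PC 38:4+H]+ at 2.97 ppm) that the instrument cannot resolve.
- **`buildLayout()` / `simConfig()` / `simulateDataset()`** — a
  ground-truthed synthetic colon-mucosa generator (crypt geometry, adduct
  partitions, abundance gradients, ppm jitter, intensity/TIC noise,
  chemical-noise peaks, resolution-limited channel merging).
- **`ticNormalize()` / `alignToAxis()` / `filterLowIntensity()`** — TIC
  normalization, greedy centroid-clustering alignment to a common mass
  axis, and relative-intensity filtering (0.5% of the base peak).
- **`annotateChannels()` / `estimateClassRatios()` /
  `apportionOverlaps()`** — per-spectrum class-wise H/Na/K ratio
  estimation from unambiguous channels and linear apportionment of
  isobaric overlaps; results in a `SummarizedExperiment` with one assay
  per adduct.
- **`extractPathProfile()` / `roiSummary()` / `compareGroups()`** —
  pixel-by-pixel profiles along crypt paths, compartment summaries, and
  subject-level healthy-vs-adenoma t-tests with stacked adduct
  proportions.

## Worked example

```r
library(AdductIMS)

panel <- colonPanel()
matchCandidates(panel, 782.568)
#>   species lipid_class adduct  theo_mz ppm_error flagged
#> 1 PC 34:1          PC     Na 782.5670  1.244721   FALSE
#> 2 PC 36:4          PC      H 782.5694  1.829370   FALSE

demo <- runDemo(seed = 1)   # 4 healthy + 3 adenoma synthetic sections
demo
#> Synthetic healthy-vs-adenoma IMS experiment
#>   4 healthy + 3 adenoma sections, seed 1
#>   adenoma / epithelium: mean K pair fraction 0.697
#>   healthy / epithelium: mean K pair fraction 0.501
#>   adenoma / lamina_propria: mean K pair fraction 0.697
#>   healthy / lamina_propria: mean K pair fraction 0.500

head(subset(demo$summary_table, compartment == "epithelium"), 4)
#>   condition compartment species mean_f_Na mean_f_K  sem_f_K
#> 1   healthy  epithelium PC 32:0     0.498    0.502 0.002036
#> 2   healthy  epithelium PC 34:1     0.501    0.499 0.001573
#> 3   healthy  epithelium PC 34:2     0.501    0.499 0.001413
#> 4   healthy  epithelium PC 36:1     0.497    0.503 0.001819
```

The single observed channel at m/z 782.568 is an unresolved overlap of a
sodiated and a protonated ion; after per-spectrum class-ratio
deconvolution, the recovered K pair fraction per species lands on the
generating preset (0.5 healthy, 0.7 adenoma) to within sampling error.
Subject-level t-tests on the epithelium report the K+-ward shift for all
nine species:

```r
fk <- subset(demo$comparison$epithelium$tests, metric == "f_K")
head(fk[, c("species", "mean_healthy", "mean_adenoma", "t", "p")], 3)
#>    species mean_healthy mean_adenoma     t        p
#> 4  PC 32:0        0.502        0.695 -55.9 3.46e-08
#> 9  PC 34:1        0.499        0.698 -74.2 8.40e-09
#> 14 PC 34:2        0.499        0.695 -94.6 2.50e-09
```

Profiles along a crypt (base to top) and plots:

```r
run <- processDataset(simulateDataset(buildLayout(seed = 1), simConfig("healthy")))
path <- cryptPaths(buildLayout(seed = 1))[[1]]
prof <- extractPathProfile(run$se, path, species = "PC 34:1")
plotPathProfile(prof)
```

See `vignettes/adduct-shift-analysis.Rmd` for the model, the estimator
design (balanced-anchor class ratios, occupancy-filtered annotation) and
the simulator's assumptions.

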