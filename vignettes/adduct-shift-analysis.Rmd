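---
title: "Resolving H+/Na+/K+ lipid adducts in imaging mass spectrometry of colon mucosa"
author: "AdductIMS"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Resolving H+/Na+/K+ lipid adducts in imaging mass spectrometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

In positive-ion MALDI imaging mass spectrometry (IMS) of tissue, most
membrane lipids are not detected once but three times: as the protonated,
sodiated and potassiated ion, `[M+H]+`, `[M+Na]+` and `[M+K]+`. For a
phosphatidylcholine (PC) species this triples the peak count, complicates
assignment — and carries biology. The relative intensity of the Na+ and K+
adducts of a given species tracks the tissue concentrations of the two
cations, so the *pair ratio*

$$ f_{Na} = \frac{I_{Na}}{I_{Na} + I_{K}}, \qquad f_K = 1 - f_{Na} $$

acts as a spatially resolved reporter of ion homeostasis. In healthy colon
mucosa the pair ratio of every detected PC species is close to 0.5:0.5, in
both the epithelium and the lamina propria, and stays flat along the crypt
axis even for species whose total abundance shows a crypt gradient. In
adenomatous mucosa it shifts to roughly 0.3:0.7 — a K+-ward shift affecting
every PC species and the single consistently detected sphingomyelin
(SMd34:1) alike, regardless of whether the species' total level rises,
falls or stays put. `AdductIMS` implements the full analysis that produces
such pair-ratio maps from pixel spectra, together with a ground-truthed
synthetic data generator used to validate every stage.

## Exact-mass registry

Neutral monoisotopic masses are computed from elemental formulas
(`PC n:d` = C(n+8) H(2n−2d+16) N O8 P; d-series `SM n:d` = C(n+5)
H(2n−2d+13) N2 O6 P) against a single atomic-mass table; cation masses
subtract one electron mass. At m/z below 1000 the electron mass (0.55 mDa,
about 0.7 ppm) is not negligible against a 3 ppm accuracy target, which is
why cation rather than atomic masses are used throughout.

The default colon panel registers eight PC species (32:0, 34:1, 34:2,
36:1, 36:2, 36:3, 36:4, 38:4) and SMd34:1. It contains two *engineered*
isobaric pairs:

* `[PC 34:1+Na]+` at 782.56703 vs `[PC 36:4+H]+` at 782.56943 (3.07 ppm),
* `[PC 36:1+Na]+` at 810.59833 vs `[PC 38:4+H]+` at 810.60073 (2.97 ppm).

At a resolving power of 100,000 at m/z 400 (decaying as
$R(m/z) = R_{400}\sqrt{400/(m/z)}$, the Orbitrap scaling), the FWHM at
m/z 783 is ~11 mDa, several times the 2.4 mDa separation: each pair is
observed as one merged channel. These overlaps are exactly the situation
the deconvolution stage exists for. Candidate lookup accepts matches
within 9 ppm (the worst-case accuracy) and flags anything worse than 3 ppm
(the typical accuracy).

## The synthetic generator

No public raw dataset exists for this tissue/instrument combination, so
the package ships a simulator whose defaults *are* the study conditions;
they are fixed once and the validation experiments inherit them.

* **Geometry** — a 64×64 raster at 10 µm spacing with 3 crypts gives ~300
  epithelial pixels per section; the epithelium is a one-pixel U-shaped
  band invaginating into the lamina propria, with a crypt-axis coordinate
  running 0→1 from base to top. Lamina propria pixels carry a basal→luminal
  mucosa axis.
* **Signal** — per species, noiseless abundance is
  `base * (1 + slope * crypt_axis)` in the epithelium (flat in the
  stroma); PC 32:0 gets slope −0.5 and PC 38:4 +0.5, the two species known
  to show crypt gradients; all others are flat. The adduct partition
  (f_H, f_Na, f_K) is (0.30, 0.35, 0.35) for the healthy preset and
  (0.30, 0.21, 0.49) for the adenoma preset, pinning the Na:K pair ratio
  at exactly 0.5:0.5 and 0.3:0.7. The H fraction is not constrained by the
  pair statistic; 0.30 is a plausible free choice.
* **Noise** — Gaussian m/z jitter of 1.5 ppm (so ~95% of peaks fall within
  3 ppm), lognormal intensity noise with CV 0.2, a per-pixel TIC factor
  with CV 0.3, and 50 uniform-random chemical-noise peaks per spectrum
  over the 480–1000 Da scan range. These levels are desk-scale stand-ins —
  the real instrument's noise is not published — chosen to be hard enough
  that the pipeline's corrections matter.
* **Determinism** — one root seed drives a single random stream with a
  fixed draw order; regenerating with the same seed is byte-identical.
  Subject-level seeds are derived from the run seed by a fixed affine map
  modulo 2^31−1.

What the generator deliberately does *not* emulate: isotope envelopes,
matrix cluster chemistry, detector saturation, profile-mode peak shapes,
spatial intensity drift, and histology-derived irregular crypt geometry.
Passing the recovery experiments therefore demonstrates correctness of the
estimators under the stated statistical structure, not robustness to every
artefact of real acquisitions.

## Preprocessing

The pipeline order is TIC normalization → alignment → relative-intensity
filtering.

* **TIC normalization** rescales each spectrum to unit total; empty or
  zero-TIC pixels are excluded with a warning rather than an error.
* **Alignment** builds a common mass axis by greedy 1-D clustering of the
  pooled sorted peak list: a new reference channel opens when the next m/z
  is more than the tolerance (default 5 ppm) above the running
  intensity-weighted centroid. The published description of the original
  software names its alignment method without specifying it; greedy
  centroid clustering reproduces the functional contract (a shared axis
  with per-spectrum re-addressing that conserves total intensity exactly)
  with one interpretable parameter. The inner loop is compiled (Rcpp).
* **Filtering** keeps peaks at or above 0.5% of the base-peak intensity.
  The threshold is applied per spectrum by default — spectrum-level
  processing, and the retained set is then invariant to whether
  normalization happens before or after filtering — with a dataset-global
  variant behind a flag. The base peak always survives, and the retained
  set is monotone in the threshold.

## Annotation and deconvolution

Aligned channels are matched against the registry within 9 ppm. One design
choice matters here: a channel must be observed in at least 1% of spectra
to be annotated. Genuine lipid channels occupy essentially every tissue
pixel while a uniform chemical-noise peak occupies one; without the
occupancy filter, noise peaks that land 5–9 ppm from a lipid mass generate
spurious single-pixel annotations. Any threshold between ~0.5% and ~50%
separates the two populations by orders of magnitude; 1% is deliberately
conservative.

**Class-ratio estimation.** The correction assumes the (H, Na, K) ratio is
constant across the species of a lipid class within one spectrum, and is
computed per spectrum — never from the average spectrum, because the ratio
differs between tissue types. The estimator sums intensities over the
*balanced anchor set*: species of the class whose three adduct channels
are all unambiguous in that spectrum. This restriction is essential with
the colon panel: ambiguity removes PC 34:1 and PC 36:1 from the Na column
and PC 36:4 and PC 38:4 from the H column, so the naive sum over all
unambiguous channels weighs the three adduct columns by different species
subsets and is biased (it would report a K pair fraction near 0.59 for a
true 0.50 even at zero noise). With balanced anchors the estimator is
exactly unbiased at zero noise and its sampling error stays well inside
±0.05 at the default noise levels. Spectra where a class has no fully
anchored species fall back, in order, to the mean ratio of the same
tissue compartment, the dataset mean, then the naive single-spectrum
ratio; fallbacks are flagged.

**Apportionment** is a single linear pass. For an ambiguous channel, each
candidate species' latent total is estimated from its unambiguous
channels, `T_s = Σ_a I(s,a) / Σ_a r_a`, the predicted contribution of
candidate (s, a) is `T_s · r_a` (each candidate uses its own class's
ratio), and the observed intensity is split proportionally. The split
conserves intensity exactly by construction, and at zero noise it inverts
the mixing: with the healthy preset the merged 782.568 channel splits back
into PC 34:1+Na and PC 36:4+H at machine-level accuracy. Candidates with
no anchor receive the mean anchored prediction (an equal-split prior) and
the channel is flagged low-confidence; if nothing in a channel is
anchored it is split equally. No iteration between ratio estimation and
apportionment is performed — the one-pass scheme is already exact in the
noiseless limit, and an iterative refinement would trade transparency for
at best second-order gains.

The deconvolved result is a `SummarizedExperiment` with one assay per
adduct (species × pixels), pixel metadata in `colData`, and the
annotation, ratio table and flags in `metadata()`.

## Spatial statistics

* **Pair fractions** exclude the H+ adduct; where `I_Na + I_K = 0` the
  fraction is reported missing, not 0.5. The statistic is invariant to any
  global rescaling of a spectrum, hence to normalization choices.
* **Path profiles** follow ordered 8-connected pixel chains (waypoints are
  densified by Bresenham segments; the simulator stores one reference
  base-to-top path per crypt). Smoothing is off by default; an optional
  centered moving average (typically 5 px) exists for plotting only.
* **ROI summaries** average over compartment pixels with SEM from the
  pixel count; a single-pixel compartment reports SEM 0 by convention.
* **Group comparisons** operate on subject-level means (one value per
  section) — pixel-level tests would pseudo-replicate thousands of
  correlated pixels. Two-sided Student's t-tests (pooled variance),
  paired or unpaired; with identical degenerate groups the test reports
  t = 0, p = 1 instead of failing. Per-species tests are reported
  unadjusted by default, mirroring per-species significance stars;
  Benjamini–Hochberg adjustment is available behind a flag. Normalized
  stacked adduct proportions (each species' three group-mean intensities
  rescaled to sum to 1) accompany the tests.

## The demonstration experiment

`runDemo()` simulates 4 healthy and 3 adenomatous sections (the section
counts of the motivating study design), runs the full pipeline per
section, and compares the groups per compartment. At the default problem
size (64×64, 3 crypts, ~3,600 tissue spectra per section) one section
takes a few seconds and the whole demo under a minute on one CPU; these
sizes were chosen so that the complete validation suite, including a
five-seed replication of the group comparison, runs comfortably on a
laptop. `scripts/acceptance.R` reruns the demo from scratch for a given
seed and reports the recovered healthy and adenoma K pair fractions and
the realized annotation mass accuracy.

## Numerical choices and degenerate inputs

* Alignment tolerance 5 ppm; annotation tolerance 9 ppm with a 3 ppm
  warning tier; channel occupancy threshold 1%; filter fraction 0.5%.
* Instrument-resolution merging uses the consecutive-gap rule (break when
  the gap to the previous peak exceeds the local FWHM) with
  intensity-weighted centroids; it is idempotent and conserves intensity.
* Zero-intensity weights in centroid computations are floored at 1e-300 to
  avoid 0/0 without affecting any realistic value.
* Empty spectra pass through filters unchanged; zero-TIC spectra are
  excluded with a warning at normalization; paths that leave the raster or
  the stated compartment raise an error naming the offending pixel.

## Known limitations

* The pair-ratio biomarker is only as good as the assumption that
  adduct formation tracks tissue cation concentrations; the package
  quantifies the ratio, it cannot validate that assumption.
* The class-ratio correction assumes within-class constancy per spectrum;
  lipid classes whose species genuinely differ in adduct behaviour would
  bias the apportionment.
* Only H+/Na+/K+ singly charged adducts of PC and SM are registered;
  negative-ion adducts, multiply charged ions, in-source fragments and
  isotopologue channels are out of scope.
* The synthetic validation bounds estimator error under the modelled noise
  structure; real data add artefacts (isotopes, matrix clusters, spatial
  drift) the generator does not produce.
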