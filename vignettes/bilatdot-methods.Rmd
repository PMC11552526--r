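---
title: "Methods: bilateral transillumination time-series classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bilateral transillumination time-series classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data model

Continuous-wave diffuse optical transillumination of the breast records, for
every source-detector pair ("channel"), the transmitted light intensity as a
time series. The instrument this package models scans both breasts
simultaneously at two wavelengths (760 and 830 nm) with 32 sources and 64
detectors per side — 2048 channels — at about 1.8 Hz, and each session opens
with a resting phase of at least 400 frames that is the only part analyzed
(recordings are truncated to the leading 400 frames so all feature vectors
have equal length). A subject therefore contributes four channels-by-time
matrices (`scan_block`s): {left, right} x {760, 830}.

Two physical facts drive every design choice downstream:

1. **Readings are uncalibrated.** Channel gains span several decades
   (source-detector geometry, coupling), so only *relative* variations carry
   information, and every block must be normalized by its own statistics.
2. **The signal of interest is slow.** Breast hemodynamics concentrate below
   0.1 Hz (vasomotion). A unilateral tumor perturbs the local vascular
   regulation, increasing the temporal and spatial heterogeneity of these
   fluctuations in the affected breast — while the contralateral breast
   provides a within-subject reference, since bilateral symmetric cancer is
   rare.

The classification task is binary: cancer-positive versus cancer-negative,
either per breast (unilateral mode) or per patient (bilateral mode).

## The pipeline

A candidate *data representation* (`representation_spec`) is one point in a
three-step design space:

* **A — wavelength selection:** 760 nm, 830 nm, or both;
* **B — normalization:** 1 to 3 of {relative change `x/mu`, z-score
  `(x-mu)/sigma`, zero-centering `x-mu`, robust `(x-median)/IQR`}, each
  computed from the *global* statistics of one block (never across subjects
  or sides — normalization is within-measurement rescaling). The standard
  deviation uses the population convention and quantiles interpolate
  linearly at rank `q(N-1)`; any consistent convention only rescales
  features, but one must be fixed for reproducibility.
* **C — pooling:** raw flattening (RF, length `R*T`, channel-major),
  temporal standard deviation (TSD, length `R`), spatial standard deviation
  (SSD, length `T`), their concatenation (TF, length `R+T`), or six scalar
  heterogeneity biomarkers (SF).

Each (wavelength, normalization) pair contributes one pooled part; parts are
concatenated in canonical order (wavelength ascending, then the fixed
normalization order) — early fusion, so a single classifier can exploit
correlations between parts. With 3 wavelength choices, 14 normalization
subsets (sizes 1-3 of 4), and 5 poolings, the space holds 3 x 14 x 5 = 210
representations. The bounds of the normalization subsets (never empty, never
all four) are an interpretive choice that reproduces this count; the
enumerator takes them as parameters so other readings can be explored.

The **six SF biomarkers** are the ordered mean/std compositions over the two
axes minus the two all-mean compositions (which equal the global mean and
are uninformative after normalization): spatial mean and std of the temporal
std, spatial std of the temporal mean, temporal mean and std of the spatial
std, temporal std of the spatial mean. An SF vector of a constant block is
the zero vector, not an error — unlike the normalizations, nothing divides
by a spread here.

**Bilateral representations** replace each part by the Euclidean distance
between its right- and left-side vectors, giving an `L`-vector of
asymmetry magnitudes. Distances are accumulated part-by-part, so raw-feature
specs never materialize the multi-million-entry concatenations. No
per-dimension scaling of the distance is applied; the norm is taken as is.

## Model selection and evaluation

Analysis units are breasts (unilateral; the two breasts of one patient are
deliberately treated as independent records and may fall into different
subsets) or patients (bilateral). Units are split once into a
model-selection set and a *single predefined test set* using the floor rule
`floor(frac * n)` with stratification by label; for 63 subjects and 20%
fractions this gives 126 breasts split 101/25 (then 81/20 per shuffle split)
and 63 patients split 51/12 (then 41/10). Stratification allocates
per-stratum floors and distributes the remainder by largest fractional part;
with test sets of 12-25 units an unstratified draw could produce
single-class test sets, for which AUC is undefined. Twenty overlapping
stratified shuffle splits of the model-selection set, all shared across
every candidate, drive selection: for each (representation, C) pair a linear
SVM is trained per split and scored on the held-out validation units; the
pair with the highest mean validation AUC wins, ties broken by smaller
feature dimension, then candidate order, then smaller C. The winner is
retrained on the full model-selection set and scored once on the test set.

The classifier is a linear SVM (libsvm via e1071), chosen for its robustness
in the small-n / large-p regime the raw-feature representations create. The
cost grid defaults to 7 values log-spaced over `1e-3 ... 1e3`; it is a
configuration, not a constant. Class weighting is not used. Unilateral
labels mark the tumor-bearing breast positive and the contralateral breast
of a cancer patient negative.

Two numerical choices deserve explanation:

* **No per-column standardization.** Rescaling features is exactly what the
  normalization step under study does, so the SVM must see features as
  built. However, representations differ in overall magnitude by orders of
  magnitude (zero-centered features carry raw gain scales), and libsvm's
  solver can hit its iteration cap on such data. The training matrix is
  therefore divided by a *single global scalar* — the root-mean-square of
  its entries — before solving. One scalar preserves every relative scale
  within and between feature columns and only re-anchors the dimensionless
  cost grid; it is numerical conditioning, not feature engineering.
* **Score orientation.** libsvm's decision-value sign depends on class
  ordering; the package normalizes scores so that higher always means more
  cancer-like.

**ROC/AUC** is computed by the package itself: the AUC is the Mann-Whitney
statistic (fraction of correctly ordered positive/negative pairs, ties one
half), which equals the trapezoidal area under the threshold-swept ROC
points; the test suite asserts the equality to 1e-12 and cross-checks
against an independent reference implementation. Sensitivity/specificity at
a fixed threshold are deliberately not reported: with 12-25 test units the
ROC is strongly discretized and any threshold choice would misstate one of
the two.

## The synthetic cohort generator

`generate_cohort()` makes the whole pipeline testable without clinical
data. Per channel `r`, side `b`, wavelength:

    x(r, t) = g_r * (1 + S_b(t) + T_r(t) + eps(r, t))

* `g_r` — log-uniform channel gain over `gain_log10_range` decades (default
  5, a realistic dynamic range for transillumination through breast
  tissue), drawn per (subject, wavelength, channel) and **shared between
  sides**: the optode geometry is mirrored on the two breasts, and this
  sharing is what makes within-subject bilateral referencing physically
  meaningful. Gains are the dominant spatial structure, as in real
  continuous-wave data.
* `S_b(t)` — the vasomotion surrogate: a sum of `n_vasomotion_components`
  (default 3) sinusoids with frequencies uniform in 0.01-0.1 Hz, shared
  amplitudes and frequencies within a subject, side-specific phases. The
  two wavelengths of one breast mix a shared and an independent copy with
  correlation 0.8 (real dual-wavelength readings are highly correlated).
  Default relative amplitude 0.05 — a few-percent intensity fluctuation,
  typical of hemodynamic rhythms riding on a large static transmission.
* `T_r(t)` — the tumor effect: in a contiguous source-major block of
  `ceil(0.15 * R)` channels of the tumor-bearing breast only, each channel
  receives an additional *independent* low-frequency fluctuation scaled so
  the channel's fluctuation variance is multiplied by exactly
  `1 + effect_size` (default 2). Per-channel independence produces both the
  temporal and the spatial heterogeneity the TSD/SSD/SF features target.
  The contiguous block is a crude stand-in for a spatially coherent lesion
  footprint; a realistic photon-sensitivity model is out of scope.
* `eps` — white noise, uniform on `+/- 0.02`, bounded so intensities stay
  strictly positive by construction (validated by a crest-factor bound,
  `sqrt(2K)` for an RMS-normalized K-component sum, plus a hard runtime
  check).

**Realized-RMS scaling.** Every fluctuation time course is rescaled to its
realized root-mean-square within the acquisition window (`v/sqrt(2)` for
the shared rhythm, `sqrt(effect_size)` times that for tumor components).
Sub-0.02 Hz sinusoids cover a fraction of a cycle in a 100-frame window, so
without this the realized variance would depend on the random phase and the
two breasts of a *healthy* subject would differ in temporal variance by
phase accident — contradicting the left/right statistical symmetry the
cohort is meant to emulate, and making the tumor's variance multiplier hold
only in expectation. With the scaling, `effect_size = 0` yields cohorts in
which every downstream feature is label-independent.

Labels: `round(prevalence * n_subjects)` subjects (default 18 of 63) are
positive, laterality uniform at random (random rather than alternating, to
avoid accidental confounds with split order). One global seed drives a
global stream for labels and per-subject substreams for signals, so
generation is a pure function of the parameters.

**What the generator does not emulate** — and hence what passing tests do
not show about clinical data: motion artifacts and probe-coupling drift,
heteroscedastic and channel-dependent detector noise, physiological rhythms
outside the vasomotion band (cardiac, respiratory aliasing), true lesion
optics (wavelength-dependent absorption contrast; here the tumor time
course is identical at both wavelengths), inter-subject anatomy, and any
departure from exact left/right gain symmetry. Recovery results on
synthetic cohorts demonstrate that the pipeline detects the *kind* of
asymmetry it was designed for; they do not predict clinical AUC.

## Problem sizes and determinism

The test suite and the acceptance script run the full machinery at a
reduced scale chosen to preserve the statistical structure while keeping
the exhaustive parts exhaustive: 63 subjects with 18 positive, 8 x 16 = 128
channels, 100 frames (performance is known to degrade below roughly 100
frames, so 100 is the floor used), SF pooling with single normalizations
(12 candidate representations) and the default 7-point cost grid. Signal
recovery averages 5 seeded replicates; the null calibration
(`effect_size = 0`) averages 20. Full 32 x 64 x 400 scale is
configuration-selectable; raw-feature bilateral specs stream their
distances so memory stays proportional to one block even there.

Everything is deterministic given two seeds (cohort, split plan): libsvm is
deterministic, all draws are seeded, and re-running a pipeline configuration
reproduces its artifacts byte-for-byte.

## Known limitations

* The bilateral distance discards the *direction* of asymmetry; a
  representation retaining signed part differences might carry more
  information at the cost of dimensionality.
* With 12 (bilateral) or 25 (unilateral) test units, test AUC is strongly
  discretized; differences below ~0.1 between single runs are not
  meaningful, which is why recovery statements average over seeds.
* The enumeration bound of at most three normalizations per representation
  is an interpretive reconstruction of the design-space count; the
  enumerator exposes the bounds for sensitivity analyses.
* Sparse-grid ablations depend on the curated geometries supplied;
  `example_grids()` ships evenly spaced layouts satisfying the
  homogeneous-coverage principle, not the hand-curated layouts an
  instrument designer would draw.
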