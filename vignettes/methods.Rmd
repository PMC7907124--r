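---
title: "Methods: one-class anomaly detection in Raman maps and targeted metabolome contrasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-class anomaly detection in Raman maps and targeted metabolome contrasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanomaly)
```

## The problem

Confocal Raman mapping of a tissue section produces a grid of spectra
— at each pixel, scattered-light intensity over a wavenumber axis
(here 350–1800 cm⁻¹ at 1.4 cm⁻¹ steps, the biological fingerprint
window). All pixels of a biopsy share the same molecular constituents;
disease does not introduce new bands but changes band *ratios*
(component concentrations, read as vertical intensity changes) and
band *positions* (molecular composition, read as horizontal shifts of
a few cm⁻¹). Supervised classification is not an option when only one
diseased specimen exists, so the package frames the question as
novelty detection: learn what physiological spectra look like, then
score every pixel of the diseased map by how far it falls outside that
model. The same study design often adds a targeted serum metabolite
panel measured at a handful of time points, analysed as log₂ ratios
against a control.

## Preprocessing model

**Polyline baseline.** Tissue Raman spectra ride on a smooth
fluorescence background. The estimator divides the axis into
`n_segments` equal-width segments (default 10 for the full window, 5
for sub-bands), anchors the baseline at the minimum-intensity point of
each segment (endpoints always anchored) and interpolates linearly.
Anchoring at minima assumes peaks are sparse enough that each segment
contains background-dominated channels — true for fingerprint-region
tissue spectra with band widths of 10–20 cm⁻¹ and segments of
~145 cm⁻¹. The corrected spectrum is floored at −5% of the raw
maximum: interpolation can overshoot slightly in valleys between
anchors, and the floor bounds that artefact without biasing peak
heights. On noisy spectra the anchors sit at noise minima
(≈ −2 SD), so correction subtracts a small, spatially correlated
random offset per segment; this inflates the between-pixel variance
that the anomaly model must absorb and is the main reason corrected
maps score slightly "looser" than ideal ones. Correction is idempotent
to within 1% of the corrected maximum.

**Substrate removal.** Pixels that contain only substrate or noise
carry no tissue signal and would dilute the reference model. A pixel
is flagged when its integrated corrected intensity falls strictly
below the map's `quantile` threshold (default 0.10, configurable; the
threshold is a fraction, not a fixed count — on a map of identical
spectra nothing is flagged because of the strict inequality). The
stage runs after baseline correction because substrate pixels are
defined by missing Raman signal, not by background level.

## One-class model

**PCA.** Reference spectra are mean-centred; the covariance
eigendecomposition gives loadings, and the component count is the
smallest *k* whose cumulative explained variance reaches
`variance_target` (default 0.95, capped at min(n−1, p); an
unreachable target falls back to full rank with a warning). Loadings
are sign-fixed (largest-magnitude element positive) so fits are
bit-reproducible and serialisable. With white channel noise at a few
percent of the strongest band, most variance beyond the first ~10
structured components is noise, so *k* is large (typically 700–900 of
1036 channels at 95%); this costs memory, not correctness — the RBF
kernel depends only on distances, which the retained subspace
preserves to 95%.

**One-class SVM.** On the PCA scores a ν-SVM one-class boundary is
fitted with RBF kernel. ν = 0.05 upper-bounds the training-outlier
fraction: at most ~5% of physiological training spectra fall outside
their own boundary (we allow ν + 0.03 slack for finite-sample
effects, and warn beyond it). γ = 0.0005 sets the kernel length scale,
√(1/γ) ≈ 45 intensity-distance units in score space; scores are
deliberately *not* rescaled before the kernel, because absolute
intensity differences are themselves signal in these maps. The
quadratic programme is convex, so fitting is deterministic. The
fitted boundary is stored as support vectors, coefficients and offset,
and the package evaluates the decision function itself (BLAS matrix
kernel), so a JSON-serialised model reproduces decision values
exactly and scoring does not depend on the fitting library being
present.

**Confidence.** The SVM decision value f is signed but unit-less and
its scale varies with training-set size, so it is mapped through a
logistic with scale s = median |f| over the training spectra:
c = 1/(1 + exp(f/s)). The boundary (f = 0) maps to 0.5; confidence is
strictly decreasing in f; the conventional 80% reporting threshold
corresponds to f < −s·ln 4. The median-absolute scaling makes
thresholds comparable across maps and bands. Note that confidence is
monotone in the decision value, not in every spectral perturbation: a
displacement *within* the reference cloud (e.g. adding lipid signal to
an unusually lipid-poor pixel) can move a pixel towards the centre and
lower its confidence; monotone growth holds once a perturbation
carries the pixel beyond the within-cloud variation, which is the
regime planted and real lesions occupy.

**Regions.** Pixels above the confidence threshold are grouped by
4-connectivity (edge-adjacent pixels; diagonal contact does not merge
regions), ordered by size with ties broken by the first pixel in
row-major order. Per-region mean spectra and their differences to the
physiological mean are the objects inspected band by band; the three
fingerprint sub-bands (775–1160, 1138–1523, 1500–1800 cm⁻¹) are each
cropped and baseline-corrected independently, and a separate model is
fitted per band.

## Band assignment and shift classification

Peaks are local maxima filtered by topographic prominence (default 5%
of the spectrum maximum *and* at least 8× the robust channel-noise SD
estimated from the median absolute first difference — the latter keeps
structureless noise from producing peaks) and by a minimum width
(default 4 cm⁻¹). Widths are measured at half prominence with linear
interpolation. Assignment matches each peak to library entries within
a tolerance (default 8 cm⁻¹; published ranges such as 1058–1065 cm⁻¹
match as intervals extended by the tolerance). All entries within
tolerance are reported because literature assignments genuinely
overlap around 1430–1465 cm⁻¹; the nearest is flagged primary, ties
broken by smaller |offset| then lower shift. Vertical/horizontal
classification compares band maxima between two spectra inside the
entry window: |Δposition| > 2 cm⁻¹ (just above the 1.4 cm⁻¹
instrument step) is horizontal, |Δheight|/reference > 10% is
vertical; a band whose window maximum sits at the window edge or at
non-positive intensity is treated as absent and the comparison
declined rather than guessed.

## Metabolite panel statistics

Panels are normalised per metabolite as log₂(value/control); control
values ≤ 0 cannot normalise and those metabolites are dropped with a
warning. Fold changes are differences of condition means on the log₂
scale with pairwise deletion of missing values — with n of 2–4
samples, imputation would fabricate signal, so it is never done.
Regulation calls use the conventional |log₂FC| > 0.3 rule (strict
inequality) and two-sided paired Student t-tests at α = 0.05 on the
per-pair differences; with two pairs the test has one degree of
freedom and is extremely weak, which the implementation reports
faithfully rather than hiding (degenerate difference vectors are
flagged: all-zero differences give p = 1, zero variance with non-zero
mean gives p = 0). No multiple-testing correction is applied by
default — the analysis mirrors the raw-p convention used with such
tiny paired panels — but `call_regulation(adjust = "BH")` provides
Benjamini–Hochberg for users who want it. Volcano tables cap
−log₁₀(p) at 300 and flag the cap.

## What the synthetic generator emulates

`simulate_map()` builds: (i) a tissue background as a sum of
Lorentzian bands at fingerprint-library shifts — Lorentzian because
that is the natural Raman line shape — with per-pixel log-normal
amplitude jitter (SD 10%) giving PCA a structured variance floor;
(ii) a smooth polynomial fluorescence baseline with a per-pixel
log-normal scale factor (SD 20%); (iii) a fixed fraction (default
10%) of substrate pixels carrying only attenuated baseline plus
noise; (iv) lesion regions (a disc and a rectangle, ~9% of pixels)
that scale the phosphatidylcholine 722/876, phenylalanine 1003,
cholesterol 1442 and sphingomyelin 1643 bands by 1.3 and shift the
722 band by +3 cm⁻¹ — a concentration-plus-composition perturbation;
(v) white Gaussian channel noise with SD 5% of the largest band
amplitude. Band amplitudes (order 10 counts, with the five lipid
bands dominant as in lipid-rich tissue) were chosen so that
pixel-to-pixel spectral distances sit in the operating regime of the
fixed kernel width γ = 0.0005 — the regime in which that empirical
setting is meaningful — and so that the default diseased map meets
the generator's design target of ≥ 0.85 downstream pixel recall at
80% confidence. The default evaluation fits the reference model on
two pooled physiological maps (7200 spectra), mirroring the two
measurements per biopsy of the motivating protocol.

What the generator does *not* emulate: spatially correlated tissue
texture (background pixels are exchangeable), cosmic-ray spikes,
detector nonlinearity, wavelength miscalibration, and composition
mixtures of distinct tissue archetypes. Passing tests therefore show
that the pipeline recovers planted concentration/composition
anomalies under realistic noise and background — not that it is
robust to every instrumental artefact of real maps.

`simulate_panel()` draws log-normal control concentrations and
multiplies condition samples by 2^(effect + ε), ε ~ N(0, 0.1²)
(log₂-scale noise), over a class composition mirroring a 163-analyte
targeted kit; planted effects are exact log₂ fold changes, so
recovery can be checked against truth.

## Problem sizes and numerical choices

Validation runs at the study's native scale: 60 × 60 maps
(3600 spectra × 1036 channels), 50 simulated references for the
ν-property, 20 seeds for lesion recovery, 2000 null replicates for
t-test calibration and 1000 replicates for fold-change recovery —
sizes chosen so the full validation completes in minutes on a single
CPU while estimating each rate to ~1% precision. Axes compare equal
within 1e-8 relative tolerance; PCA eigenvalues are clipped at zero;
the SVM uses libsvm's default 1e-3 KKT tolerance (well below the
decision-value scale of fitted models); JSON serialisation keeps full
double precision. Ties in region ordering, assignment and anchor
selection are all broken deterministically, and every stochastic step
flows from one user-visible seed, so identical inputs give identical
outputs across platforms with the same RNG stream.

## Known limitations

- The ν guarantee is asymptotic; very small maps (≲ 300 usable
  spectra) can exceed ν by more than the 0.03 slack, which the fit
  reports as a warning.
- A lesion whose spectral displacement stays within the reference
  cloud's variation (effects ≲ 10% on single weak bands at 5% noise)
  is undetectable at the 80% confidence threshold by construction.
- With two sample pairs the paired t-test has one degree of freedom;
  significance calls at that size rest on an assumption of
  near-identical pair noise and should be read descriptively.
- The polyline baseline assumes each segment contains
  background-dominated channels; spectra that are one broad band wide
  relative to the segment width will be partially subtracted.
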