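# ramanomaly

Anomaly detection in Raman hyperspectral tissue maps, Raman-band
metabolite assignment, and targeted serum-metabolome differential
analysis — the computational toolkit behind studies that look for
disease-associated metabolic change (for example recurrent focal
segmental glomerulosclerosis, FSGS, in kidney transplants) with
label-free Raman micro-spectroscopy and targeted LC-MS/MS panels.

It is written for analysts who have per-pixel Raman spectra of tissue
sections or cells (a *hyperspectral map*), plus optionally a targeted
metabolite panel, and want to ask: *which parts of the diseased sample
look different from physiological tissue, which molecular bands drive
the difference, and do serum metabolites move consistently?*

## What it computes

**Preprocessing.** Spectra are restricted to the fingerprint window
(350–1800 cm⁻¹), fluorescence background is removed with a polyline
baseline (piecewise-linear interpolation through per-segment intensity
minima), and pixels carrying only substrate/noise signal are removed by
thresholding the integrated corrected intensity at a map quantile.

**One-class anomaly model.** Physiological reference spectra are
mean-centred and reduced by PCA to the minimal number of components
reaching 95% cumulative explained variance. A one-class SVM with RBF
kernel (ν = 0.05, γ = 0.0005) learns a boundary around the reference
cloud in score space. For any spectrum *x* the signed decision value

  f(x) = Σᵢ αᵢ K(svᵢ, x) − ρ,  K(u, v) = exp(−γ‖u − v‖²)

is positive inside the physiological boundary; the per-pixel anomaly
confidence is the logistic map

  c(x) = 1 / (1 + exp(f(x) / s)),

with *s* the median absolute training decision value, so the boundary
maps to 0.5 and deep anomalies approach 1. Pixels above 80% confidence
are grouped into 4-connected regions, and each region's mean spectrum
is compared with the physiological mean, band by band
(775–1160, 1138–1523, 1500–1800 cm⁻¹, each baseline-corrected
independently).

**Band assignment.** Detected peaks are matched against a built-in
library of literature Raman assignments (cholesterol 1442/1464,
sphingomyelin 1643, phenylalanine 1003/1030, phosphatidylcholine
876/1058–1065, alkyl components 480–500 cm⁻¹, …) within a tolerance
(default 8 cm⁻¹), and band changes are classified as *vertical*
(intensity, i.e. concentration) or *horizontal* (position, i.e.
molecular composition).

**Targeted metabolomics.** Panels (e.g. 163 analytes: acylcarnitines,
amino acids/biogenic amines, lyso-/phosphatidylcholines,
sphingomyelins, hexoses) are normalised as log₂(sample/control);
metabolites with |log₂FC| > 0.3 are called up/down-regulated and
two-sided paired Student t-tests flag significance at p < 0.05, with
volcano tables and per-class summaries.

**Synthetic data with ground truth.** `simulate_map()` and
`simulate_panel()` generate hyperspectral maps (Lorentzian bands,
fluorescence baselines, substrate pixels, planted lesion regions with
amplitude and position perturbations) and metabolite panels with known
log₂ effects, so that every stage of the pipeline is testable against
known truth.

## Worked example

Simulate a physiological biopsy map and a diseased map whose lesions
carry +30% on the lipid bands (722, 876, 1003, 1442, 1643 cm⁻¹) and a
+3 cm⁻¹ shift of the 722 cm⁻¹ phosphatidylcholine band, then fit and
score:

```r
library(ramanomaly)

ref  <- simulate_map(fsgs_map_spec(seed = 1, lesions = FALSE))
fsgs <- simulate_map(fsgs_map_spec(seed = 2))

ref_corr <- baseline_correct_map(ref$map)
mask     <- substrate_mask(ref_corr)
model    <- fit_reference(ref_corr, mask)
model
#> <anomaly_model> 816 components (95.0% variance), 181 support vectors, nu=0.05 gamma=0.0005

test_corr <- baseline_correct_map(fsgs$map)
amap      <- score_map(model, test_corr, substrate_mask(test_corr))
regions   <- anomaly_regions(amap, threshold = 0.8)
regions
#> <anomaly_regions> 6 regions above confidence 0.80
#>   region n_pixels min_row min_col max_row max_col
#> 1      1      142      11      13      26      28
#> 2      2       89      36      38      45      49
#> 3      3        3      24      22      25      23
#> ...
```

The two large regions are the two planted lesions (a disc around row
18 / col 20 and a rectangle at rows 36–45); the remaining single-pixel
regions are scattered false positives. Asking which bands distinguish
region 1 from physiological tissue:

```r
spectra <- region_mean_spectra(test_corr, regions,
                               mean_spectrum(ref_corr, mask))
diff1  <- dplyr::filter(spectra, region == 1)
peaks  <- detect_peaks(
  dplyr::transmute(diff1, wavenumber_cm1, intensity = difference),
  min_prominence = 0.1)
assign_peaks(peaks, tolerance = 8)
#>   position_cm1 height name                                    delta_cm1 primary
#> 1         727.   6.30 Membrane bound/free phosphatidylcholine      4.60 TRUE
#> 3         875    3.63 Phosphatidylcholine                         -1    TRUE
#> 4        1004.   3.63 Phenylalanine                                0.80 TRUE
#> 6        1442    3.93 Cholesterol                                  0    TRUE
#> 7        1644.   3.65 Sphingomyelin                                0.60 TRUE
```

The difference spectrum recovers exactly the five planted bands — and
the phosphatidylcholine band is found ~5 cm⁻¹ above its library
position, reflecting the planted horizontal (composition) shift, while
the other four are vertical (concentration) changes.

`autoplot(amap)` draws the confidence heat map; `plot_volcano()` and
`run_metabolome_analysis()` cover the metabolite-panel side.

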