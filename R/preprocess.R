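#' Crop a spectral map to a wavenumber band
#'
#' Restricts the axis to `[low, high]`, e.g. the 350-1800 1/cm
#' fingerprint window used for whole-spectrum analysis, or the
#' 775-1160 / 1138-1523 / 1500-1800 1/cm sub-bands analysed separately.
#'
#' @param map A [spectral_map()].
#' @param low,high Band limits in 1/cm, `0 < low < high`.
#' @return A [spectral_map()] on the cropped axis; pixel count and
#'   validity are unchanged.
#' @export
crop_band <- function(map, low, high) {
  stopifnot(inherits(map, "spectral_map"), low > 0, low < high)
  keep <- map$axis >= low & map$axis <= high
  if (!any(keep)) abort("band does not overlap the map axis")
  spectral_map(map$intensity[, keep, drop = FALSE], map$axis[keep],
               map$n_rows, map$n_cols, map$valid, map$pixel_pitch)
}

# Polyline baseline on a plain intensity vector: anchors are the
# per-segment minima over n_segments equal-width axis segments, with the
# first and last axis point always anchored; the baseline interpolates
# linearly through the anchors.
polyline_baseline_vec <- function(axis, y, n_segments) {
  n <- length(axis)
  breaks <- seq(axis[1], axis[n], length.out = n_segments + 1)
  seg <- pmin(pmax(findInterval(axis, breaks, rightmost.closed = TRUE), 1L),
              n_segments)
  anchors <- vapply(split(seq_len(n), seg), function(ix) ix[which.min(y[ix])],
                    integer(1))
  anchors <- sort(unique(c(1L, anchors, n)))
  base <- approx(axis[anchors], y[anchors], xout = axis, rule = 2)$y
  base
}

#' Polyline baseline correction
#'
#' Fits a piecewise-linear background through per-segment intensity
#' minima (fluorescence background estimation standard for tissue
#' Raman): the axis is divided into `n_segments` equal-width segments,
#' the minimum point of each segment becomes an anchor (endpoints are
#' always anchored), and the baseline interpolates linearly between
#' anchors.  The corrected spectrum is the input minus the baseline,
#' floored at -5% of the spectrum maximum so that interpolation
#' overshoot cannot produce large negative intensities.
#'
#' @param spectrum Tibble with columns `wavenumber_cm1` and `intensity`.
#' @param n_segments Number of segments, at least 2; the default 10
#'   suits the full 350-1800 1/cm window, use ~5 for sub-bands.
#' @return The input tibble with added columns `baseline` and
#'   `corrected`.
#' @export
polyline_baseline <- function(spectrum, n_segments = 10) {
  spectrum <- as_spectrum(spectrum)
  n_segments <- as.integer(n_segments)
  stopifnot(n_segments >= 2)
  if (nrow(spectrum) < 2 * n_segments) {
    abort("axis too short: need at least 2 points per baseline segment")
  }
  base <- polyline_baseline_vec(spectrum$wavenumber_cm1, spectrum$intensity,
                                n_segments)
  floor_at <- -0.05 * max(spectrum$intensity, 0)
  spectrum$baseline <- base
  spectrum$corrected <- pmax(spectrum$intensity - base, floor_at)
  spectrum
}

as_spectrum <- function(x) {
  if (inherits(x, "data.frame")) {
    if (!all(c("wavenumber_cm1", "intensity") %in% names(x))) {
      abort("a spectrum needs columns wavenumber_cm1 and intensity")
    }
    x <- tibble::as_tibble(x)
    if (is.unsorted(x$wavenumber_cm1)) x <- x[order(x$wavenumber_cm1), ]
    return(x)
  }
  abort("expected a spectrum data frame")
}

#' Baseline-correct every pixel of a map
#'
#' Applies [polyline_baseline()] per pixel and returns the corrected
#' map.  Run before [substrate_mask()] so that substrate pixels are
#' identified by lack of Raman signal rather than background level.
#'
#' @inheritParams crop_band
#' @inheritParams polyline_baseline
#' @return A [spectral_map()] of corrected intensities.
#' @export
baseline_correct_map <- function(map, n_segments = 10) {
  stopifnot(inherits(map, "spectral_map"))
  n_segments <- as.integer(n_segments)
  stopifnot(n_segments >= 2, length(map$axis) >= 2 * n_segments)
  out <- map$intensity
  for (i in which(map$valid)) {
    y <- map$intensity[i, ]
    base <- polyline_baseline_vec(map$axis, y, n_segments)
    out[i, ] <- pmax(y - base, -0.05 * max(y, 0))
  }
  spectral_map(out, map$axis, map$n_rows, map$n_cols, map$valid,
               map$pixel_pitch)
}

#' Flag substrate / noise pixels
#'
#' A pixel is flagged as substrate when its integrated baseline-corrected
#' intensity over the analysis band falls strictly below the map-level
#' `quantile` threshold of the integrated intensities of valid pixels.
#' Flagged pixels carry no tissue signal and are excluded from model
#' fitting and scoring.  On a map of identical spectra nothing is
#' flagged (the strict inequality makes the degenerate threshold empty).
#'
#' @param map A baseline-corrected [spectral_map()].
#' @param quantile Fraction in (0, 1); default 0.10.
#' @param band Optional `c(low, high)` restricting the integration band.
#' @return Logical vector, one flag per pixel in row-major order;
#'   invalid pixels are flagged `TRUE` (excluded).
#' @export
substrate_mask <- function(map, quantile = 0.10, band = NULL) {
  stopifnot(inherits(map, "spectral_map"), quantile > 0, quantile < 1)
  keep <- if (is.null(band)) rep(TRUE, length(map$axis)) else {
    stopifnot(length(band) == 2, band[1] < band[2])
    map$axis >= band[1] & map$axis <= band[2]
  }
  if (!any(keep)) abort("integration band does not overlap the map axis")
  integ <- rowSums(map$intensity[, keep, drop = FALSE])
  thr <- stats::quantile(integ[map$valid], probs = quantile, names = FALSE)
  flags <- integ < thr
  flags[!map$valid] <- TRUE
  flags
}

#' Mean spectrum over unmasked pixels
#'
#' @param map A [spectral_map()].
#' @param mask Optional logical vector (`TRUE` = excluded), e.g. from
#'   [substrate_mask()].
#' @return Tibble with columns `wavenumber_cm1`, `intensity`
#'   (pointwise arithmetic mean over the retained pixels).
#' @export
mean_spectrum <- function(map, mask = NULL) {
  stopifnot(inherits(map, "spectral_map"))
  use <- map$valid
  if (!is.null(mask)) {
    stopifnot(length(mask) == n_pixels(map))
    use <- use & !mask
  }
  if (!any(use)) abort("all pixels are masked; no spectra to average")
  tibble::tibble(
    wavenumber_cm1 = map$axis,
    intensity = colMeans(map$intensity[use, , drop = FALSE])
  )
}

#' Crop and baseline-correct a map per band
#'
#' For each band the map is cropped with [crop_band()] and every pixel
#' is baseline-corrected within that band, mirroring band-wise analyses
#' where each spectral window is corrected individually.
#'
#' @param map A [spectral_map()] of raw intensities.
#' @param bands List of `c(low, high)` band limits.
#' @param n_segments Baseline segments per band (default 5).
#' @return Named list of corrected [spectral_map()]s, one per band,
#'   named `"<low>-<high>"`.
#' @export
split_bands <- function(map, bands, n_segments = 5) {
  stopifnot(inherits(map, "spectral_map"), length(bands) >= 1)
  out <- lapply(bands, function(b) {
    baseline_correct_map(crop_band(map, b[1], b[2]), n_segments = n_segments)
  })
  names(out) <- vapply(bands, function(b) paste0(b[1], "-", b[2]), character(1))
  out
}

#' The three fingerprint sub-bands analysed separately
#'
#' @return List of `c(low, high)` pairs: 775-1160, 1138-1523 and
#'   1500-1800 1/cm.
#' @export
fingerprint_bands <- function() {
  list(c(775, 1160), c(1138, 1523), c(1500, 1800))
}
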