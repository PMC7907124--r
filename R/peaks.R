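#' Detect peaks in a baseline-corrected spectrum
#'
#' Finds local maxima, computes their topographic prominence (height
#' above the higher of the two saddle minima separating the peak from
#' taller neighbours or the spectrum edge) and their full width at half
#' prominence by linear interpolation of the half-prominence crossings.
#' Besides the relative prominence cut, a peak must clear `min_snr`
#' times the channel noise (estimated robustly from the median absolute
#' first difference), so structureless white noise reports no peaks.
#'
#' @param spectrum Tibble with `wavenumber_cm1` and either `corrected`
#'   (preferred, from [polyline_baseline()]) or `intensity`.
#' @param min_prominence Minimum prominence as a fraction of the
#'   spectrum maximum (default 0.05).
#' @param min_fwhm Minimum width in 1/cm (default 4, about three axis
#'   steps at 1.4 1/cm resolution, rejecting single-channel noise
#'   spikes; Raman bands in tissue are an order of magnitude wider).
#' @param min_snr Minimum prominence in units of the estimated channel
#'   noise SD (default 8).
#' @return Tibble of peaks sorted by position: `position_cm1`,
#'   `height`, `fwhm_cm1`, `prominence`.  Empty for flat spectra.
#' @export
detect_peaks <- function(spectrum, min_prominence = 0.05, min_fwhm = 4,
                         min_snr = 8) {
  spectrum <- as_spectrum_any(spectrum)
  x <- spectrum$wavenumber_cm1
  y <- spectrum$value
  n <- length(y)
  empty <- tibble::tibble(position_cm1 = numeric(), height = numeric(),
                          fwhm_cm1 = numeric(), prominence = numeric())
  if (n < 3 || max(y) <= min(y)) return(empty)
  is_max <- which(diff(sign(diff(y))) < 0) + 1L
  is_max <- is_max[y[is_max] > 0]
  if (length(is_max) == 0) return(empty)
  noise_sigma <- median(abs(diff(y))) / (sqrt(2) * 0.6745)
  prom_floor <- max(min_prominence * max(y), min_snr * noise_sigma)
  rows <- lapply(is_max, function(i) {
    # walk outwards to the nearest higher point (or edge), tracking the
    # minimum on the way: prominence = height - max(left min, right min)
    left_min <- y[i]
    j <- i
    while (j > 1 && y[j - 1] <= y[i]) {
      j <- j - 1
      left_min <- min(left_min, y[j])
    }
    if (j == 1) left_min <- min(y[1:i])
    right_min <- y[i]
    j <- i
    while (j < n && y[j + 1] <= y[i]) {
      j <- j + 1
      right_min <- min(right_min, y[j])
    }
    if (j == n) right_min <- min(y[i:n])
    prom <- y[i] - max(left_min, right_min)
    if (prom < prom_floor) return(NULL)
    half <- y[i] - prom / 2
    xl <- cross_left(x, y, i, half)
    xr <- cross_right(x, y, i, half)
    tibble::tibble(position_cm1 = x[i], height = y[i],
                   fwhm_cm1 = xr - xl, prominence = prom)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(empty)
  out <- out[out$fwhm_cm1 >= min_fwhm, , drop = FALSE]
  out[order(out$position_cm1), ]
}

as_spectrum_any <- function(spectrum) {
  spectrum <- tibble::as_tibble(spectrum)
  if (!"wavenumber_cm1" %in% names(spectrum)) {
    abort("a spectrum needs a wavenumber_cm1 column")
  }
  col <- if ("corrected" %in% names(spectrum)) "corrected" else "intensity"
  if (!col %in% names(spectrum)) {
    abort("a spectrum needs an intensity or corrected column")
  }
  out <- spectrum[c("wavenumber_cm1", col)]
  names(out) <- c("wavenumber_cm1", "value")
  if (is.unsorted(out$wavenumber_cm1)) out <- out[order(out$wavenumber_cm1), ]
  out
}

cross_left <- function(x, y, i, level) {
  j <- i
  while (j > 1 && y[j - 1] >= level) j <- j - 1
  if (j == 1) return(x[1])
  # interpolate between j-1 (below) and j (above)
  x[j - 1] + (level - y[j - 1]) / (y[j] - y[j - 1]) * (x[j] - x[j - 1])
}

cross_right <- function(x, y, i, level) {
  n <- length(y)
  j <- i
  while (j < n && y[j + 1] >= level) j <- j + 1
  if (j == n) return(x[n])
  x[j] + (y[j] - level) / (y[j] - y[j + 1]) * (x[j + 1] - x[j])
}

#' Assign detected peaks to library entries
#'
#' Each peak is matched to every assignment-library entry within
#' `tolerance` of its position (range entries match within the range
#' extended by the tolerance).  The nearest entry is flagged as the
#' primary assignment, with ties broken by smaller absolute offset and
#' then lower library shift; peaks with no entry within tolerance are
#' reported unassigned.  The default tolerance of 8 1/cm absorbs the
#' small offsets between measured band positions and published
#' literature shifts.
#'
#' @param peaks Tibble from [detect_peaks()].
#' @param library Assignment library tibble
#'   (default [builtin_assignment_library()]).
#' @param tolerance Match window in 1/cm.
#' @return Tibble with one row per (peak, matching entry) plus one row
#'   per unassigned peak: `position_cm1`, `height`, `name`,
#'   `shift_low_cm1`, `shift_high_cm1`, `delta_cm1`, `primary`,
#'   `assigned`.
#' @export
assign_peaks <- function(peaks, library = builtin_assignment_library(),
                         tolerance = 8) {
  validate_assignment_library(library)
  stopifnot(tolerance > 0)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(position_cm1 = numeric(), height = numeric(),
                          name = character(), shift_low_cm1 = numeric(),
                          shift_high_cm1 = numeric(), delta_cm1 = numeric(),
                          primary = logical(), assigned = logical()))
  }
  purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
    p <- peaks[i, ]
    hits <- lookup_shift(library, p$position_cm1, tolerance)
    if (nrow(hits) == 0) {
      return(tibble::tibble(position_cm1 = p$position_cm1, height = p$height,
                            name = NA_character_, shift_low_cm1 = NA_real_,
                            shift_high_cm1 = NA_real_, delta_cm1 = NA_real_,
                            primary = FALSE, assigned = FALSE))
    }
    tibble::tibble(
      position_cm1 = p$position_cm1, height = p$height,
      name = hits$name, shift_low_cm1 = hits$shift_low_cm1,
      shift_high_cm1 = hits$shift_high_cm1, delta_cm1 = hits$delta_cm1,
      primary = seq_len(nrow(hits)) == 1L, assigned = TRUE
    )
  })
}

#' Ratio of band intensities at two Raman shifts
#'
#' Ratio of the maximum baseline-corrected intensity within
#' `+/- window` of `shift_a` to that within `+/- window` of `shift_b`,
#' e.g. the sphingomyelin (1643) to cholesterol (1442) band ratio.
#'
#' @param spectrum Baseline-corrected spectrum tibble.
#' @param shift_a,shift_b Band positions in 1/cm (numerator,
#'   denominator).
#' @param window Half-window in 1/cm (default 10).
#' @return A single ratio.
#' @export
peak_ratio <- function(spectrum, shift_a, shift_b, window = 10) {
  s <- as_spectrum_any(spectrum)
  win_max <- function(shift) {
    sel <- abs(s$wavenumber_cm1 - shift) <= window
    if (!any(sel)) abort(sprintf("shift %g is not on the spectrum axis", shift))
    max(s$value[sel])
  }
  num <- win_max(shift_a)
  den <- win_max(shift_b)
  if (den <= 0) abort("denominator band maximum is not positive")
  num / den
}

#' Classify a band change as vertical and/or horizontal
#'
#' Vertical differences in band intensity reflect concentration changes
#' of the underlying component; horizontal displacements of the band
#' position reflect changes in molecular composition.  The band maximum
#' is located within the entry window in both spectra; the change is
#' `"horizontal"` when the position moved by more than `position_tol`,
#' `"vertical"` when the relative height change exceeds `height_tol`,
#' `"both"` or `"none"` accordingly.
#'
#' @param reference,test Baseline-corrected spectrum tibbles on one axis.
#' @param entry Band position: a single shift, a `c(low, high)` range,
#'   or a one-row library entry.
#' @param position_tol Position tolerance in 1/cm (default 2, just above
#'   a 1.4 1/cm instrument step).
#' @param height_tol Relative height tolerance (default 0.10).
#' @param window Search half-window around the entry in 1/cm.
#' @return One-row tibble: `kind` (one of none/vertical/horizontal/both),
#'   `d_height` (relative), `d_position_cm1`, `absent` (band missing in
#'   either spectrum, in which case `kind` is `"none"`).
#' @export
classify_shift <- function(reference, test, entry, position_tol = 2,
                           height_tol = 0.10, window = 15) {
  ref <- as_spectrum_any(reference)
  tst <- as_spectrum_any(test)
  if (!isTRUE(all.equal(ref$wavenumber_cm1, tst$wavenumber_cm1))) {
    abort("reference and test spectra must share one axis")
  }
  rng <- entry_range(entry)
  sel <- ref$wavenumber_cm1 >= rng[1] - window & ref$wavenumber_cm1 <= rng[2] + window
  if (!any(sel)) abort("entry window does not overlap the axis")
  band_peak <- function(s) {
    v <- s$value[sel]
    i <- which.max(v)
    # a maximum at the window edge or non-positive height = band absent
    if (v[i] <= 0 || i == 1L || i == length(v)) return(NULL)
    list(pos = s$wavenumber_cm1[sel][i], height = v[i])
  }
  pr <- band_peak(ref)
  pt <- band_peak(tst)
  if (is.null(pr) || is.null(pt)) {
    return(tibble::tibble(kind = "none", d_height = NA_real_,
                          d_position_cm1 = NA_real_, absent = TRUE))
  }
  d_pos <- pt$pos - pr$pos
  d_h <- (pt$height - pr$height) / pr$height
  horizontal <- abs(d_pos) > position_tol
  vertical <- abs(d_h) > height_tol
  kind <- if (horizontal && vertical) "both" else if (horizontal) "horizontal"
          else if (vertical) "vertical" else "none"
  tibble::tibble(kind = kind, d_height = d_h, d_position_cm1 = d_pos,
                 absent = FALSE)
}

entry_range <- function(entry) {
  if (inherits(entry, "data.frame")) {
    stopifnot(nrow(entry) == 1)
    return(c(entry$shift_low_cm1, entry$shift_high_cm1))
  }
  entry <- as.numeric(entry)
  if (length(entry) == 1) c(entry, entry) else sort(entry[1:2])
}
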