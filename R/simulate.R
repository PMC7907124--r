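#' Default wavenumber axis
#'
#' 350 to 1800 1/cm in steps of 1.4 1/cm, the fingerprint window at the
#' spectral resolution of the mapped measurements (1037 points).
#'
#' @return Numeric axis vector.
#' @export
default_axis <- function() seq(350, 1800, by = 1.4)

lorentzian <- function(axis, shift, fwhm) {
  hw2 <- (fwhm / 2)^2
  hw2 / ((axis - shift)^2 + hw2)
}

poly_baseline <- function(axis, coefs) {
  if (is.null(coefs) || length(coefs) == 0) return(rep(0, length(axis)))
  u <- (axis - axis[1]) / (axis[length(axis)] - axis[1])
  drop(outer(u, seq_along(coefs) - 1, `^`) %*% coefs)
}

#' Simulate a single Raman spectrum
#'
#' Intensity is a sum of Lorentzian lines (the natural Raman line
#' shape) plus a smooth polynomial baseline and white Gaussian noise.
#'
#' @param components Tibble with columns `shift`, `amplitude`, `fwhm`
#'   (1/cm); amplitudes must be positive.
#' @param baseline Polynomial coefficients (constant first) evaluated
#'   on the axis rescaled to \[0, 1\].
#' @param noise_sd Gaussian noise SD as a fraction of the largest
#'   component amplitude (0 when there are no components).
#' @param axis Wavenumber axis (default [default_axis()]).
#' @param seed Optional integer seed for reproducibility.
#' @return Spectrum tibble (`wavenumber_cm1`, `intensity`).
#' @export
simulate_spectrum <- function(components, baseline = NULL, noise_sd = 0,
                              axis = default_axis(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- poly_baseline(axis, baseline)
  amp_max <- 0
  if (!is.null(components) && nrow(components) > 0) {
    if (any(components$amplitude < 0)) abort("component amplitudes must be positive")
    for (i in seq_len(nrow(components))) {
      y <- y + components$amplitude[i] *
        lorentzian(axis, components$shift[i], components$fwhm[i])
    }
    amp_max <- max(components$amplitude)
  }
  if (noise_sd > 0 && amp_max > 0) {
    y <- y + rnorm(length(axis), sd = noise_sd * amp_max)
  }
  tibble::tibble(wavenumber_cm1 = axis, intensity = y)
}

#' Specification of a synthetic hyperspectral map
#'
#' Describes the study conditions a generated map emulates: a tissue
#' background built from fingerprint-library bands with per-pixel
#' amplitude jitter, near-flat substrate pixels, planted lesion regions
#' perturbing band amplitudes (concentration changes) and band
#' positions (composition changes), a fluorescence-like polynomial
#' baseline and white noise.
#'
#' @param n_rows,n_cols Grid size.
#' @param axis Wavenumber axis.
#' @param components Background bands: tibble `shift`, `amplitude`,
#'   `fwhm`.
#' @param lesion_regions List of regions, each a list with `shape`
#'   (`"disc"` or `"rect"`), geometry (`row`, `col`, `radius` for discs;
#'   `row`, `col`, `height`, `width` for rectangles, 0-based top-left),
#'   `amplitude_scale` (named numeric, by component shift) and
#'   `position_shift` (named numeric, 1/cm, by component shift).
#' @param substrate_fraction Fraction of pixels that carry only
#'   substrate background, in \[0, 0.5).
#' @param baseline Polynomial baseline coefficients.
#' @param baseline_jitter Log-normal sdlog of the per-pixel baseline
#'   scale factor.
#' @param amplitude_jitter Log-normal sdlog of the per-pixel,
#'   per-component amplitude factor (default 0.10).
#' @param noise_sd Noise SD as a fraction of the largest component
#'   amplitude (default 0.05).
#' @param seed Integer seed; the whole map is reproducible from it.
#' @return A `synthetic_map_spec` list.
#' @seealso [simulate_map()], [fsgs_map_spec()]
#' @export
map_spec <- function(n_rows, n_cols, axis = default_axis(),
                     components,
                     lesion_regions = list(),
                     substrate_fraction = 0.10,
                     baseline = c(15, -8, 3),
                     baseline_jitter = 0.2,
                     amplitude_jitter = 0.10,
                     noise_sd = 0.05,
                     seed = 1L) {
  stopifnot(n_rows >= 1, n_cols >= 1,
            substrate_fraction >= 0, substrate_fraction < 0.5,
            all(components$amplitude > 0))
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         axis = axis, components = tibble::as_tibble(components),
         lesion_regions = lesion_regions,
         substrate_fraction = substrate_fraction,
         baseline = baseline, baseline_jitter = baseline_jitter,
         amplitude_jitter = amplitude_jitter, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_map_spec"
  )
}

#' Default recurrent-disease map specification
#'
#' The default study conditions used throughout validation: a 60 x 60
#' grid (3600 spectra) on the 350-1800 1/cm axis, ten background bands
#' drawn from the fingerprint library with amplitudes of order ten
#' counts (chosen so that the pixel-to-pixel spectral variability
#' matches the operating regime of the fixed RBF width
#' `gamma = 0.0005`) and the lipid bands dominant as in lipid-rich
#' tissue, 10% substrate pixels, and two lesion regions
#' (one disc, one rectangle, together about 9% of pixels) carrying a
#' +30% amplitude change on the membrane-phosphatidylcholine (722),
#' phosphatidylcholine (876), phenylalanine (1003), cholesterol (1442)
#' and sphingomyelin (1643) bands plus a +3 1/cm position shift of the
#' 722 band.
#'
#' @param seed Integer seed.
#' @param n_rows,n_cols Grid size (default 60 x 60); lesion geometry
#'   scales with the grid.
#' @param lesions Plant the two lesion regions (`TRUE`, a diseased
#'   biopsy) or none (`FALSE`, a physiological reference map).
#' @param lesion_scale Amplitude factor on the lesion bands (default 1.3).
#' @param noise_sd Noise SD as fraction of the largest amplitude.
#' @return A `synthetic_map_spec`.
#' @export
fsgs_map_spec <- function(seed = 1L, n_rows = 60, n_cols = 60,
                          lesions = TRUE, lesion_scale = 1.3,
                          noise_sd = 0.05) {
  comps <- tibble::tibble(
    shift = c(722, 760, 876, 1003, 1065, 1125, 1303, 1442, 1643, 1660),
    amplitude = c(12, 7, 12, 12, 8, 6, 9, 12, 12, 10),
    fwhm = c(16, 12, 16, 12, 16, 14, 18, 17, 17, 18)
  )
  lesion_bands <- c(722, 876, 1003, 1442, 1643)
  scale <- stats::setNames(rep(lesion_scale, length(lesion_bands)),
                           lesion_bands)
  shift <- c("722" = 3)
  regions <- if (lesions) list(
    list(shape = "disc", row = round(0.30 * n_rows), col = round(0.33 * n_cols),
         radius = round(0.133 * n_rows),
         amplitude_scale = scale, position_shift = shift),
    list(shape = "rect", row = round(0.60 * n_rows), col = round(0.63 * n_cols),
         height = round(0.167 * n_rows), width = round(0.20 * n_cols),
         amplitude_scale = scale, position_shift = shift)
  ) else list()
  map_spec(
    n_rows = n_rows, n_cols = n_cols, components = comps,
    lesion_regions = regions,
    substrate_fraction = 0.10, noise_sd = noise_sd, seed = seed
  )
}

region_pixels <- function(region, n_rows, n_cols) {
  idx0 <- seq_len(n_rows * n_cols) - 1L
  r <- idx0 %/% n_cols
  c <- idx0 %% n_cols
  inside <- switch(
    region$shape,
    disc = (r - region$row)^2 + (c - region$col)^2 <= region$radius^2,
    rect = r >= region$row & r < region$row + region$height &
           c >= region$col & c < region$col + region$width,
    abort(paste0("unknown lesion shape: ", region$shape))
  )
  if (any(r[inside] < 0 | r[inside] >= n_rows)) abort("lesion outside grid")
  which(inside)
}

#' Simulate a hyperspectral map with known ground truth
#'
#' Background pixels share the spec's components with per-pixel
#' log-normal amplitude jitter and a jittered polynomial baseline;
#' lesion pixels additionally apply their region's amplitude scales and
#' position shifts; substrate pixels carry only an attenuated baseline
#' plus noise.  When a sampled substrate pixel falls inside a lesion
#' region the substrate wins and the pixel is dropped from the lesion
#' mask (reported via a message).
#'
#' @param spec A [map_spec()] / [fsgs_map_spec()].
#' @return List with elements `map` (a [spectral_map()]) and `truth`
#'   (class `synthetic_ground_truth`): logical `lesion_mask` and
#'   `substrate_mask` per pixel, and a `planted_effects` tibble
#'   (`region`, `shift`, `amplitude_scale`, `position_shift_cm1`).
#' @export
simulate_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_map_spec"))
  set.seed(spec$seed)
  npx <- spec$n_rows * spec$n_cols
  axis <- spec$axis
  comps <- spec$components
  ncomp <- nrow(comps)

  lesion_mask <- rep(FALSE, npx)
  lesion_of <- integer(npx)
  for (i in seq_along(spec$lesion_regions)) {
    px <- region_pixels(spec$lesion_regions[[i]], spec$n_rows, spec$n_cols)
    lesion_mask[px] <- TRUE
    lesion_of[px] <- i
  }
  n_sub <- round(spec$substrate_fraction * npx)
  substrate_mask <- rep(FALSE, npx)
  if (n_sub > 0) substrate_mask[sample.int(npx, n_sub)] <- TRUE
  overlap <- substrate_mask & lesion_mask
  if (any(overlap)) {
    inform(sprintf("%d lesion pixel(s) overlap substrate; substrate wins",
                   sum(overlap)))
    lesion_mask[overlap] <- FALSE
    lesion_of[overlap] <- 0L
  }

  shapes <- t(vapply(seq_len(ncomp), function(i) {
    lorentzian(axis, comps$shift[i], comps$fwhm[i])
  }, numeric(length(axis))))
  jitter <- matrix(rlnorm(npx * ncomp, 0, spec$amplitude_jitter), npx, ncomp)
  amps <- jitter * matrix(comps$amplitude, npx, ncomp, byrow = TRUE)

  intensity <- matrix(0, npx, length(axis))
  bg <- !substrate_mask & !lesion_mask
  intensity[bg, ] <- amps[bg, , drop = FALSE] %*% shapes
  for (i in seq_along(spec$lesion_regions)) {
    px <- which(lesion_of == i)
    if (length(px) == 0) next
    reg <- spec$lesion_regions[[i]]
    a <- amps[px, , drop = FALSE]
    shp <- shapes
    for (j in seq_len(ncomp)) {
      key <- as.character(comps$shift[j])
      if (!is.null(reg$amplitude_scale) && key %in% names(reg$amplitude_scale)) {
        a[, j] <- a[, j] * reg$amplitude_scale[[key]]
      }
      if (!is.null(reg$position_shift) && key %in% names(reg$position_shift)) {
        shp[j, ] <- lorentzian(axis, comps$shift[j] + reg$position_shift[[key]],
                               comps$fwhm[j])
      }
    }
    intensity[px, ] <- a %*% shp
  }

  base <- poly_baseline(axis, spec$baseline)
  base_scale <- rlnorm(npx, 0, spec$baseline_jitter)
  base_scale[substrate_mask] <- base_scale[substrate_mask] * 0.3
  intensity <- intensity + base_scale %o% base
  if (spec$noise_sd > 0) {
    intensity <- intensity +
      matrix(rnorm(npx * length(axis),
                   sd = spec$noise_sd * max(comps$amplitude)),
             npx, length(axis))
  }

  effects <- purrr::imap_dfr(spec$lesion_regions, function(reg, i) {
    sc <- reg$amplitude_scale
    ps <- reg$position_shift
    shifts <- union(names(sc), names(ps))
    tibble::tibble(
      region = i,
      shift = as.numeric(shifts),
      amplitude_scale = ifelse(shifts %in% names(sc),
                               unname(sc[shifts]), 1),
      position_shift_cm1 = ifelse(shifts %in% names(ps),
                                  unname(ps[shifts]), 0)
    )
  })
  list(
    map = spectral_map(intensity, axis, spec$n_rows, spec$n_cols),
    truth = structure(
      list(lesion_mask = lesion_mask, substrate_mask = substrate_mask,
           planted_effects = effects, seed = spec$seed),
      class = "synthetic_ground_truth"
    )
  )
}

#' Simulate a targeted metabolite panel with known effects
#'
#' Emulates the structure of a 163-analyte targeted kit (acylcarnitines,
#' amino acids / biogenic amines, lyso- and phosphatidylcholines,
#' sphingomyelins, hexose and one analyte ratio).  Control
#' concentrations are log-normal; each condition sample multiplies the
#' control by `2^(effect + noise)`, so planted effects are exact log2
#' fold changes.
#'
#' @param n_metabolites Total number of analytes (default 163).
#' @param class_mix Named integer vector of analytes per class summing
#'   to `n_metabolites`; the default mirrors the kit composition.
#' @param effects Planted log2 effects: a tibble with columns
#'   `condition`, `effect` and either `metabolite` or `class`.
#' @param n_samples_per_condition Samples per condition (default 2).
#' @param noise_sd_log2 SD of the log2-scale noise (default 0.1).
#' @param conditions Condition labels (default relapse, remission).
#' @param control_meanlog,control_sdlog Log-normal parameters of the
#'   control concentrations.
#' @param seed Integer seed.
#' @return List with `panel` (a linear-scale [metabolite_panel()] whose
#'   samples are `CTRL` plus `<condition>_<i>`) and `truth` (tibble
#'   `metabolite`, `condition`, `effect` covering every analyte and
#'   condition, zero where unperturbed).
#' @export
simulate_panel <- function(n_metabolites = 163,
                           class_mix = c("amino acid/biogenic amine" = 13,
                                         "acylcarnitine" = 41,
                                         "lysophosphatidylcholine" = 15,
                                         "phosphatidylcholine" = 77,
                                         "sphingomyelin" = 15,
                                         "hexose" = 1,
                                         "ratio" = 1),
                           effects = NULL,
                           n_samples_per_condition = 2,
                           noise_sd_log2 = 0.1,
                           conditions = c("relapse", "remission"),
                           control_meanlog = log(50), control_sdlog = 1,
                           seed = 1L) {
  stopifnot(sum(class_mix) == n_metabolites)
  set.seed(as.integer(seed))
  classes <- rep(names(class_mix), class_mix)
  prefix <- c("amino acid/biogenic amine" = "AA", "acylcarnitine" = "AC",
              "lysophosphatidylcholine" = "lysoPC", "phosphatidylcholine" = "PC",
              "sphingomyelin" = "SM", "hexose" = "H", "ratio" = "Ratio",
              "other" = "X")
  metabolites <- paste0(prefix[classes], ".",
                        stats::ave(seq_along(classes), classes, FUN = seq_along))
  control <- rlnorm(n_metabolites, control_meanlog, control_sdlog)

  eff <- matrix(0, n_metabolites, length(conditions),
                dimnames = list(metabolites, conditions))
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    for (i in seq_len(nrow(effects))) {
      cond <- effects$condition[i]
      if (!cond %in% conditions) abort(paste0("unknown condition: ", cond))
      rows <- if ("metabolite" %in% names(effects) && !is.na(effects$metabolite[i])) {
        which(metabolites == effects$metabolite[i])
      } else {
        which(classes == effects$class[i])
      }
      if (length(rows) == 0) abort("effect row matches no metabolite")
      eff[rows, cond] <- effects$effect[i]
    }
  }

  values <- tibble::tibble(metabolite = metabolites, class = classes,
                           CTRL = control)
  for (cond in conditions) {
    for (s in seq_len(n_samples_per_condition)) {
      noise <- rnorm(n_metabolites, sd = noise_sd_log2)
      values[[paste0(cond, "_", s)]] <- control * 2^(eff[, cond] + noise)
    }
  }
  long <- tidyr::pivot_longer(values, -c("metabolite", "class"),
                              names_to = "sample", values_to = "value")
  truth <- tibble::as_tibble(as.data.frame.table(eff, stringsAsFactors = FALSE))
  names(truth) <- c("metabolite", "condition", "effect")
  list(panel = metabolite_panel(long, scale = "linear"), truth = truth)
}
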