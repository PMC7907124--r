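write_if <- function(dir, name, writer) {
  if (is.null(dir)) return(NULL)
  path <- file.path(dir, name)
  writer(path)
  name
}

#' Full biopsy-map anomaly analysis
#'
#' Orchestrates the map pipeline: crop to the analysis band, polyline
#' baseline correction, substrate removal, one-class model fitting on
#' the physiological reference map(s), anomaly scoring of the test map,
#' connected anomaly regions, region mean and difference spectra, and
#' peak assignment of the difference spectra.  The same sequence is
#' repeated per analysis sub-band with an independently fitted model,
#' since each band is baseline-corrected and modelled on its own.
#'
#' @param reference A [spectral_map()] or list of maps (physiological).
#' @param test A [spectral_map()] to score.
#' @param config An [anomaly_config()].
#' @param band Global analysis band `c(low, high)` (default 350-1800).
#' @param bands Sub-bands to analyse separately (default
#'   [fingerprint_bands()]); use `list()` to skip.
#' @param baseline_segments,band_segments Polyline segments for the
#'   global band and the sub-bands.
#' @param substrate_quantile Quantile for [substrate_mask()].
#' @param library Assignment library for difference-spectrum peaks.
#' @param tolerance Assignment tolerance in 1/cm.
#' @param output_dir Optional directory; when given, tables and a run
#'   `manifest.json` are written there.
#' @param write_model Also serialise the fitted model(s) to JSON
#'   (default `FALSE`; loadings of full-size maps make large files).
#' @return A list bundle: `model`, `anomaly_map`, `regions`,
#'   `region_spectra`, `assignments`, `band_results` (one sub-bundle
#'   per sub-band) and `manifest`.
#' @export
run_biopsy_analysis <- function(reference, test,
                                config = anomaly_config(),
                                band = c(350, 1800),
                                bands = fingerprint_bands(),
                                baseline_segments = 10,
                                band_segments = 5,
                                substrate_quantile = 0.10,
                                library = builtin_assignment_library(),
                                tolerance = 8,
                                output_dir = NULL,
                                write_model = FALSE) {
  if (inherits(reference, "spectral_map")) reference <- list(reference)
  stopifnot(length(reference) >= 1, inherits(test, "spectral_map"))
  if (!is.null(output_dir)) dir.create(output_dir, showWarnings = FALSE,
                                       recursive = TRUE)
  prep <- function(map, segments) {
    corrected <- baseline_correct_map(crop_band(map, band[1], band[2]),
                                      n_segments = segments)
    list(map = corrected,
         mask = substrate_mask(corrected, quantile = substrate_quantile))
  }
  ref_prep <- lapply(reference, prep, segments = baseline_segments)
  test_prep <- prep(test, baseline_segments)

  model <- fit_reference(lapply(ref_prep, `[[`, "map"),
                         masks = lapply(ref_prep, `[[`, "mask"),
                         config = config)
  amap <- score_map(model, test_prep$map, mask = test_prep$mask)
  regions <- anomaly_regions(amap, threshold = config$confidence_threshold)
  ref_mean <- mean_spectrum(ref_prep[[1]]$map, ref_prep[[1]]$mask)
  region_spectra <- NULL
  assignments <- NULL
  if (nrow(regions$summary) > 0) {
    region_spectra <- region_mean_spectra(test_prep$map, regions, ref_mean)
    assignments <- region_spectra |>
      dplyr::group_by(.data$region) |>
      dplyr::group_map(~ {
        diff_spec <- tibble::tibble(wavenumber_cm1 = .x$wavenumber_cm1,
                                    intensity = .x$difference)
        peaks <- detect_peaks(diff_spec, min_prominence = 0.1)
        a <- assign_peaks(peaks, library, tolerance)
        a$region <- .y$region
        a
      }) |>
      dplyr::bind_rows()
  }

  band_results <- lapply(seq_along(bands), function(i) {
    b <- bands[[i]]
    rp <- lapply(reference, function(m) {
      corrected <- baseline_correct_map(crop_band(m, b[1], b[2]),
                                        n_segments = band_segments)
      list(map = corrected,
           mask = substrate_mask(corrected, quantile = substrate_quantile))
    })
    tc <- baseline_correct_map(crop_band(test, b[1], b[2]),
                               n_segments = band_segments)
    tmask <- substrate_mask(tc, quantile = substrate_quantile)
    bm <- fit_reference(lapply(rp, `[[`, "map"),
                        masks = lapply(rp, `[[`, "mask"), config = config)
    ba <- score_map(bm, tc, mask = tmask)
    br <- anomaly_regions(ba, threshold = config$confidence_threshold)
    list(band = b, model = bm, anomaly_map = ba, regions = br)
  })
  names(band_results) <- vapply(bands, function(b) paste0(b[1], "-", b[2]),
                                character(1))

  files <- c(
    write_if(output_dir, "anomaly_map.csv",
             function(p) readr::write_csv(as_tibble(amap), p, progress = FALSE)),
    write_if(output_dir, "regions.csv",
             function(p) readr::write_csv(regions$summary, p, progress = FALSE)),
    if (!is.null(region_spectra))
      write_if(output_dir, "region_spectra.csv",
               function(p) readr::write_csv(region_spectra, p, progress = FALSE)),
    if (!is.null(assignments))
      write_if(output_dir, "region_assignments.csv",
               function(p) readr::write_csv(assignments, p, progress = FALSE)),
    if (write_model)
      write_if(output_dir, "model.json",
               function(p) write_anomaly_model(model, p))
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("ramanomaly")),
    config = unclass(config),
    band = band,
    sub_bands = bands,
    n_reference_maps = length(reference),
    n_reference_spectra = model$n_train,
    n_components = model$n_components,
    n_scored_pixels = sum(amap$scored),
    n_regions = nrow(regions$summary),
    n_regions_per_band = vapply(band_results,
                                function(b) nrow(b$regions$summary),
                                integer(1)),
    files = as.character(files)
  )
  if (!is.null(output_dir)) {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(model = model, anomaly_map = amap, regions = regions,
       region_spectra = region_spectra, assignments = assignments,
       band_results = band_results, manifest = manifest)
}

#' Compare mean spectra between labelled groups
#'
#' Baseline-corrects every spectrum, averages per group, and
#' characterises each fingerprint band of the reference group's mean
#' against every other group: peak detection and library assignment,
#' band-intensity ratios, and vertical / horizontal change
#' classification.
#'
#' @param spectra Long tibble with columns `group`, `id` (spectrum
#'   within group), `wavenumber_cm1`, `intensity`.
#' @param reference Reference group label (default: first group).
#' @param baseline_segments Polyline segments (default 10).
#' @param library Assignment library.
#' @param tolerance Assignment tolerance in 1/cm.
#' @param ratio_pairs List of `c(shift_a, shift_b)` band ratios to
#'   report per group (default sphingomyelin 1643 vs cholesterol 1442
#'   and vs cholesteryl palmitate 1068).
#' @param position_tol,height_tol Thresholds for [classify_shift()].
#' @param output_dir Optional output directory.
#' @return Bundle with `means`, `differences`, `peaks`, `assignments`,
#'   `ratios`, `shift_changes`, `manifest`.
#' @export
run_spectrum_comparison <- function(spectra, reference = NULL,
                                    baseline_segments = 10,
                                    library = builtin_assignment_library(),
                                    tolerance = 8,
                                    ratio_pairs = list(c(1643, 1442),
                                                       c(1643, 1068)),
                                    position_tol = 2, height_tol = 0.10,
                                    output_dir = NULL) {
  need <- c("group", "id", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(spectra))) {
    abort("spectra need columns group, id, wavenumber_cm1, intensity")
  }
  groups <- unique(spectra$group)
  if (length(groups) < 2) abort("need at least two spectrum groups")
  if (is.null(reference)) reference <- groups[1]
  if (!reference %in% groups) abort("reference group not present")

  corrected <- spectra |>
    dplyr::group_by(.data$group, .data$id) |>
    dplyr::group_modify(~ {
      if (nrow(.x) == 0) abort("empty spectrum group")
      polyline_baseline(.x, n_segments = baseline_segments)
    }) |>
    dplyr::ungroup()
  means <- corrected |>
    dplyr::group_by(.data$group, .data$wavenumber_cm1) |>
    dplyr::summarise(corrected = mean(.data$corrected), .groups = "drop")

  ref_mean <- dplyr::filter(means, .data$group == reference)
  others <- setdiff(groups, reference)
  differences <- purrr::map_dfr(others, function(g) {
    gm <- dplyr::filter(means, .data$group == g)
    tibble::tibble(group = g, wavenumber_cm1 = gm$wavenumber_cm1,
                   difference = gm$corrected - ref_mean$corrected)
  })
  peaks <- means |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ detect_peaks(.x, min_prominence = 0.05)) |>
    dplyr::ungroup()
  assignments <- peaks |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ assign_peaks(.x, library, tolerance)) |>
    dplyr::ungroup()
  ratios <- purrr::map_dfr(groups, function(g) {
    gm <- dplyr::filter(means, .data$group == g)
    purrr::map_dfr(ratio_pairs, function(p) {
      tibble::tibble(group = g, shift_a = p[1], shift_b = p[2],
                     ratio = peak_ratio(gm, p[1], p[2]))
    })
  })
  lib_entries <- dplyr::distinct(library, .data$shift_low_cm1,
                                 .data$shift_high_cm1, .keep_all = TRUE)
  shift_changes <- purrr::map_dfr(others, function(g) {
    gm <- dplyr::filter(means, .data$group == g)
    purrr::map_dfr(seq_len(nrow(lib_entries)), function(i) {
      sc <- classify_shift(ref_mean, gm, lib_entries[i, ],
                           position_tol = position_tol,
                           height_tol = height_tol)
      sc$group <- g
      sc$name <- lib_entries$name[i]
      sc$shift_low_cm1 <- lib_entries$shift_low_cm1[i]
      sc$shift_high_cm1 <- lib_entries$shift_high_cm1[i]
      sc
    })
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("ramanomaly")),
    groups = groups, reference = reference,
    n_spectra = nrow(dplyr::distinct(spectra, .data$group, .data$id)),
    n_peaks = nrow(peaks)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(means, file.path(output_dir, "group_means.csv"),
                     progress = FALSE)
    readr::write_csv(assignments, file.path(output_dir, "assignments.csv"),
                     progress = FALSE)
    readr::write_csv(ratios, file.path(output_dir, "ratios.csv"),
                     progress = FALSE)
    readr::write_csv(shift_changes, file.path(output_dir, "shift_changes.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(means = means, differences = differences, peaks = peaks,
       assignments = assignments, ratios = ratios,
       shift_changes = shift_changes, manifest = manifest)
}

#' Full targeted-metabolome differential analysis
#'
#' Normalises a linear panel to the control sample, contrasts two
#' conditions, runs the paired t-test over the given sample pairs, and
#' produces regulation calls, the volcano table and per-class
#' summaries.
#'
#' @param panel A [metabolite_panel()] (linear scale, or log2 with
#'   `control_sample = NULL`).
#' @param control_sample Control sample for [log2_normalize()]; `NULL`
#'   if the panel is already log2.
#' @param condition_a,condition_b Sample labels of the two conditions.
#' @param pairs Sample pairs for [paired_test()].
#' @param fc_threshold,alpha Regulation and significance thresholds.
#' @param output_dir Optional output directory.
#' @return Bundle with `panel_log2`, `contrast`, `tests`, `results`,
#'   `volcano`, `classes`, `manifest`.
#' @export
run_metabolome_analysis <- function(panel, control_sample,
                                    condition_a, condition_b, pairs,
                                    fc_threshold = 0.3, alpha = 0.05,
                                    output_dir = NULL) {
  stopifnot(inherits(panel, "metabolite_panel"))
  panel_log2 <- if (is.null(control_sample)) panel else {
    log2_normalize(panel, control_sample)
  }
  contrast <- condition_contrast(panel_log2, condition_a, condition_b)
  tests <- paired_test(panel_log2, pairs)
  results <- call_regulation(contrast, tests, fc_threshold = fc_threshold,
                             alpha = alpha)
  volcano <- volcano_table(results, fc_threshold = fc_threshold, alpha = alpha)
  classes <- class_summary(results)
  manifest <- list(
    package_version = as.character(utils::packageVersion("ramanomaly")),
    n_metabolites = length(panel_log2$metabolites),
    n_tested = sum(!is.na(results$p_value)),
    n_significant = sum(results$significant, na.rm = TRUE),
    fc_threshold = fc_threshold, alpha = alpha
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(results, file.path(output_dir, "differential_results.csv"),
                     progress = FALSE)
    readr::write_csv(volcano, file.path(output_dir, "volcano.csv"),
                     progress = FALSE)
    readr::write_csv(classes, file.path(output_dir, "class_summary.csv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(panel_log2 = panel_log2, contrast = contrast, tests = tests,
       results = results, volcano = volcano, classes = classes,
       manifest = manifest)
}
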