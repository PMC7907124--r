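#' Built-in Raman fingerprint assignment library
#'
#' Literature assignments of Raman shifts to metabolites and tissue
#' components in the biological fingerprint region, covering the lipid
#' bands (cholesterol, cholesteryl palmitate, phosphatidylcholine,
#' sphingomyelin, fatty-acid CH2/CH3 deformations), amino-acid and
#' nucleic-acid markers, and alkyl components.  Single published shifts
#' are stored with `shift_low_cm1 == shift_high_cm1`; published ranges
#' (e.g. 480-500 1/cm alkyl components) keep their interval so that
#' tolerance matching respects the range semantics.
#'
#' @return A tibble with columns `shift_low_cm1`, `shift_high_cm1`,
#'   `name`, `reference` (literature tag grouping entries that share a
#'   source row).
#' @seealso [assign_peaks()], [read_assignment_library()]
#' @export
builtin_assignment_library <- function() {
  e <- function(lo, hi, name, ref) {
    tibble::tibble(shift_low_cm1 = lo, shift_high_cm1 = hi,
                   name = name, reference = ref)
  }
  dplyr::bind_rows(
    e(417, 417, "Cholesterol", "chol-417"),
    e(480, 500, "Alkyl components", "alkyl-480-500"),
    e(674, 674, "Palmitic acid", "palmitic-674-912"),
    e(912, 912, "Palmitic acid", "palmitic-674-912"),
    e(720, 720, "DNA/RNA", "nucleic-720-780"),
    e(780, 780, "DNA/RNA", "nucleic-720-780"),
    e(718, 718, "Membrane bound/free phosphatidylcholine", "pc-718-722-766"),
    e(722, 722, "Membrane bound/free phosphatidylcholine", "pc-718-722-766"),
    e(766, 766, "Membrane bound/free phosphatidylcholine", "pc-718-722-766"),
    e(743, 743, "Thymine", "thymine-743"),
    e(760, 760, "Phosphatidylethanolamine", "pe-760"),
    e(847, 847, "Triacylglycerols", "tag-847-849"),
    e(849, 849, "Triacylglycerols", "tag-847-849"),
    e(876, 876, "Phosphatidylcholine", "pc-876-1058-1065"),
    e(1058, 1065, "Phosphatidylcholine", "pc-876-1058-1065"),
    e(1003, 1003, "Phenylalanine", "phe-1003-1030"),
    e(1030, 1030, "Phenylalanine", "phe-1003-1030"),
    e(987, 987, "Membrane bound/free phosphatidylcholine", "pc-987-1002"),
    e(1002, 1002, "Membrane bound/free phosphatidylcholine", "pc-987-1002"),
    e(1068, 1068, "Cholesteryl palmitate", "cholpalm-1068"),
    e(1125, 1125, "Carbohydrates", "carb-1125"),
    e(1125, 1125, "Cytochrome c", "cytc-1125-1580"),
    e(1580, 1580, "Cytochrome c", "cytc-1125-1580"),
    e(1131, 1131, "Cholesterol/cholesteryl palmitate", "chol-cholpalm-1131"),
    e(1259, 1259, "Collagen", "collagen-1259"),
    e(1262, 1262, "Linoleic acid", "linoleic-1262"),
    e(1303, 1303, "Amide III, cytosine, adenine", "amide3-1303"),
    e(1433, 1433, "CH2/CH3 deformations of fatty acid", "fa-ch-1433-1457"),
    e(1457, 1457, "CH2/CH3 deformations of fatty acid", "fa-ch-1433-1457"),
    e(1442, 1442, "Cholesterol", "chol-1442-1464"),
    e(1464, 1464, "Cholesterol", "chol-1442-1464"),
    e(1643, 1643, "Sphingomyelin", "sm-1643"),
    e(1656, 1656, "tri-11-eicosenoin", "eicosenoin-1656"),
    e(1660, 1660, "Amide I", "amide1-1660"),
    e(1665, 1665, "CC lipids", "cc-lipids-1665")
  )
}

validate_assignment_library <- function(library) {
  need <- c("shift_low_cm1", "shift_high_cm1", "name", "reference")
  if (!all(need %in% names(library))) {
    abort("assignment library needs columns shift_low_cm1, shift_high_cm1, name, reference")
  }
  if (any(library$shift_low_cm1 <= 0 | library$shift_high_cm1 >= 4000) ||
      any(library$shift_low_cm1 > library$shift_high_cm1)) {
    abort("assignment library shifts must satisfy 0 < low <= high < 4000")
  }
  if (any(!nzchar(library$name))) abort("assignment library names must be non-empty")
  if (anyDuplicated(library[c("shift_low_cm1", "shift_high_cm1", "name")])) {
    abort("assignment library contains duplicate (shift, name) entries")
  }
  invisible(library)
}

#' Read / write an assignment library CSV
#'
#' CSV with columns `shift_low_cm1`, `shift_high_cm1`, `name`,
#' `reference`, so that users can extend the built-in table with shifts
#' observed in their own measurements.
#'
#' @param path CSV path.
#' @return `read_assignment_library()` returns the validated tibble.
#' @export
read_assignment_library <- function(path) {
  lib <- readr::read_csv(
    path,
    col_types = readr::cols(
      shift_low_cm1 = readr::col_double(),
      shift_high_cm1 = readr::col_double(),
      name = readr::col_character(),
      reference = readr::col_character()
    ),
    progress = FALSE
  )
  validate_assignment_library(lib)
  lib
}

#' @rdname read_assignment_library
#' @param library An assignment library tibble.
#' @export
write_assignment_library <- function(library, path) {
  validate_assignment_library(library)
  readr::write_csv(library, path, progress = FALSE)
  invisible(path)
}

#' Look up library entries near a Raman shift
#'
#' @param library Assignment library tibble.
#' @param shift Raman shift in 1/cm.
#' @param tolerance Match window in 1/cm; range entries match when the
#'   shift falls within the range extended by `tolerance` on both sides.
#' @return Matching library rows with a signed `delta_cm1` column
#'   (0 inside a range), ordered by `abs(delta_cm1)`.
#' @export
lookup_shift <- function(library, shift, tolerance = 8) {
  validate_assignment_library(library)
  stopifnot(tolerance > 0, length(shift) == 1)
  delta <- ifelse(
    shift < library$shift_low_cm1, shift - library$shift_low_cm1,
    ifelse(shift > library$shift_high_cm1, shift - library$shift_high_cm1, 0)
  )
  out <- library[abs(delta) <= tolerance, , drop = FALSE]
  out$delta_cm1 <- delta[abs(delta) <= tolerance]
  out[order(abs(out$delta_cm1), out$shift_low_cm1), , drop = FALSE]
}
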