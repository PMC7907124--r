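#' Construct a spectral map
#'
#' A spectral map is a rectangular grid of Raman spectra sharing one
#' wavenumber axis, as produced by confocal Raman mapping of a tissue
#' section.  Pixels are indexed 0-based, row-major, with `(0, 0)` the
#' top-left corner of the rendered heat map.
#'
#' @param intensity Numeric matrix, one row per pixel in row-major order
#'   (`pixel = row * n_cols + col`), one column per wavenumber.
#' @param axis Numeric vector of Raman shifts in 1/cm, strictly
#'   increasing after internal reordering; all values must lie in
#'   (0, 4000).  A descending axis is silently reversed together with
#'   the intensity columns.
#' @param n_rows,n_cols Grid dimensions; `n_rows * n_cols` must equal
#'   `nrow(intensity)`.
#' @param valid Logical vector flagging pixels that carry a complete
#'   spectrum.  Invalid pixels are ignored by every downstream stage.
#' @param pixel_pitch Optional pixel spacing in micrometres.
#'
#' @return An object of class `spectral_map`.
#' @seealso [read_spectral_map()], [as_tibble.spectral_map()]
#' @export
spectral_map <- function(intensity, axis, n_rows, n_cols,
                         valid = rep(TRUE, nrow(intensity)),
                         pixel_pitch = NULL) {
  intensity <- as.matrix(intensity)
  axis <- as.numeric(axis)
  stopifnot(is.numeric(intensity), length(axis) >= 2)
  if (any(!is.finite(axis)) || any(axis <= 0) || any(axis >= 4000)) {
    abort("wavenumber axis values must be finite and in (0, 4000)")
  }
  if (anyDuplicated(axis)) {
    abort("wavenumber axis contains duplicated values")
  }
  if (is.unsorted(axis)) {
    ord <- order(axis)
    axis <- axis[ord]
    intensity <- intensity[, ord, drop = FALSE]
  }
  if (ncol(intensity) != length(axis)) {
    abort("each pixel spectrum must have one intensity per axis value")
  }
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L || n_rows * n_cols != nrow(intensity)) {
    abort("n_rows * n_cols must equal the number of pixel spectra")
  }
  valid <- as.logical(valid)
  if (length(valid) != nrow(intensity)) {
    abort("valid mask must have one flag per pixel")
  }
  structure(
    list(
      intensity = unname(intensity),
      axis = axis,
      n_rows = n_rows,
      n_cols = n_cols,
      valid = valid,
      pixel_pitch = pixel_pitch
    ),
    class = "spectral_map"
  )
}

#' @export
print.spectral_map <- function(x, ...) {
  cat(sprintf(
    "<spectral_map> %d x %d pixels (%d valid), axis %g-%g 1/cm (%d points)\n",
    x$n_rows, x$n_cols, sum(x$valid),
    min(x$axis), max(x$axis), length(x$axis)
  ))
  invisible(x)
}

#' @export
dim.spectral_map <- function(x) c(x$n_rows, x$n_cols)

n_pixels <- function(map) map$n_rows * map$n_cols

# 0-based (row, col) for 1-based pixel index, row-major
pixel_coords <- function(map, idx = seq_len(n_pixels(map))) {
  idx0 <- idx - 1L
  list(row = idx0 %/% map$n_cols, col = idx0 %% map$n_cols)
}

pixel_index <- function(map, row, col) {
  as.integer(row) * map$n_cols + as.integer(col) + 1L
}

#' Convert a spectral map to a long tibble
#'
#' @param x A [spectral_map()].
#' @param ... Unused.
#'
#' @return A tibble with columns `row`, `col` (0-based), `wavenumber_cm1`
#'   and `intensity`; invalid pixels are omitted.
#' @method as_tibble spectral_map
#' @export
as_tibble.spectral_map <- function(x, ...) {
  keep <- which(x$valid)
  rc <- pixel_coords(x, keep)
  tibble::tibble(
    row = rep(rc$row, each = length(x$axis)),
    col = rep(rc$col, each = length(x$axis)),
    wavenumber_cm1 = rep(x$axis, length(keep)),
    intensity = as.vector(t(x$intensity[keep, , drop = FALSE]))
  )
}

#' Read a spectral map from CSV
#'
#' Two layouts are supported.  `"long"` files have columns `row`, `col`,
#' `wavenumber_cm1`, `intensity` with 0-based pixel coordinates; a pixel
#' missing one or more axis rows is loaded but marked invalid.  `"wide"`
#' files have the wavenumber in the first column and one column per
#' pixel named `r<i>_c<j>`; empty cells invalidate the pixel.  The axis
#' is sorted ascending regardless of file order.
#'
#' @param path Path to a CSV file.
#' @param layout `"long"` or `"wide"`.
#' @return A [spectral_map()].
#' @export
read_spectral_map <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (layout == "long") read_map_long(path) else read_map_wide(path)
}

read_map_long <- function(path) {
  first <- readLines(path, n = 1)
  grid <- NULL
  m <- regmatches(first, regexec("^# grid: ([0-9]+) x ([0-9]+)$", first))[[1]]
  if (length(m) == 3) grid <- as.integer(m[2:3])
  raw <- suppressWarnings(readr::read_csv(
    path,
    comment = "#",
    col_types = readr::cols(
      row = readr::col_double(),
      col = readr::col_double(),
      wavenumber_cm1 = readr::col_double(),
      intensity = readr::col_double()
    ),
    progress = FALSE
  ))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf(
      "non-numeric value in %s at file row %d", path, prob$row[1]
    ))
  }
  need <- c("row", "col", "wavenumber_cm1", "intensity")
  if (!all(need %in% names(raw))) {
    abort("long layout requires columns row, col, wavenumber_cm1, intensity")
  }
  axis <- sort(unique(raw$wavenumber_cm1))
  n_rows <- if (is.null(grid)) max(raw$row) + 1L else grid[1]
  n_cols <- if (is.null(grid)) max(raw$col) + 1L else grid[2]
  npx <- n_rows * n_cols
  idx <- raw$row * n_cols + raw$col + 1L
  wn_pos <- match(raw$wavenumber_cm1, axis)
  if (anyDuplicated(cbind(idx, wn_pos))) {
    abort("inconsistent axis: duplicated (pixel, wavenumber) rows")
  }
  intensity <- matrix(NA_real_, nrow = npx, ncol = length(axis))
  intensity[cbind(idx, wn_pos)] <- raw$intensity
  counts <- tabulate(idx, nbins = npx)
  valid <- counts == length(axis)
  if (!any(valid)) abort("inconsistent axis: no pixel covers the full axis")
  intensity[!valid, ] <- 0
  intensity[is.na(intensity)] <- 0
  spectral_map(intensity, axis, n_rows, n_cols, valid)
}

read_map_wide <- function(path) {
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()),
                    progress = FALSE)
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("non-numeric value in %s at file row %d", path, prob$row[1]))
  }
  pix_cols <- grep("^r[0-9]+_c[0-9]+$", names(raw), value = TRUE)
  if (length(pix_cols) == 0) abort("wide layout requires pixel columns named r<i>_c<j>")
  axis <- raw[[1]]
  ord <- order(axis)
  axis <- axis[ord]
  rows <- as.integer(sub("^r([0-9]+)_c[0-9]+$", "\\1", pix_cols))
  cols <- as.integer(sub("^r[0-9]+_c([0-9]+)$", "\\1", pix_cols))
  n_rows <- max(rows) + 1L
  n_cols <- max(cols) + 1L
  npx <- n_rows * n_cols
  intensity <- matrix(0, nrow = npx, ncol = length(axis))
  valid <- rep(FALSE, npx)
  for (k in seq_along(pix_cols)) {
    v <- raw[[pix_cols[k]]][ord]
    i <- rows[k] * n_cols + cols[k] + 1L
    if (!anyNA(v)) {
      intensity[i, ] <- v
      valid[i] <- TRUE
    }
  }
  if (!any(valid)) abort("no complete pixel column in wide file")
  spectral_map(intensity, axis, n_rows, n_cols, valid)
}

#' Write a spectral map to CSV
#'
#' Inverse of [read_spectral_map()]: `read_spectral_map(write_spectral_map(m))`
#' reproduces axis and intensities to better than 6 significant digits.
#' Invalid pixels are written as absent rows (long) or empty cells (wide).
#'
#' @param map A [spectral_map()].
#' @param path Output path.
#' @param layout `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_spectral_map <- function(map, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  stopifnot(inherits(map, "spectral_map"))
  if (layout == "long") {
    # grid header keeps the dimensions recoverable when edge pixels
    # are invalid (their rows are absent from the body)
    writeLines(sprintf("# grid: %d x %d", map$n_rows, map$n_cols), path)
    readr::write_csv(as_tibble(map), path, progress = FALSE, append = TRUE,
                     col_names = TRUE)
  } else {
    rc <- pixel_coords(map)
    out <- tibble::tibble(wavenumber_cm1 = map$axis)
    for (i in seq_len(n_pixels(map))) {
      nm <- sprintf("r%d_c%d", rc$row[i], rc$col[i])
      out[[nm]] <- if (map$valid[i]) map$intensity[i, ] else NA_real_
    }
    readr::write_csv(out, path, na = "", progress = FALSE)
  }
  invisible(path)
}
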