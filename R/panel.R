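panel_classes <- c(
  "acylcarnitine", "amino acid/biogenic amine", "lysophosphatidylcholine",
  "phosphatidylcholine", "sphingomyelin", "hexose", "ratio", "other"
)

#' Construct a targeted metabolite panel
#'
#' Holds a metabolite-by-sample value table of the kind produced by
#' targeted LC-MS/MS kits (concentrations, or log2 ratios relative to a
#' control once normalised).  Values live in a long tibble so that the
#' panel composes with dplyr verbs; the measurement scale is explicit
#' and checked by every downstream statistic.
#'
#' @param values Long tibble with columns `metabolite`, `class`,
#'   `sample`, `value`.  Missing (below detection) values are `NA`,
#'   never zero.
#' @param scale `"linear"` (concentrations) or `"log2"` (log2 ratios).
#' @return An object of class `metabolite_panel`.
#' @export
metabolite_panel <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  need <- c("metabolite", "class", "sample", "value")
  if (!all(need %in% names(values))) {
    abort("panel values need columns metabolite, class, sample, value")
  }
  values <- tibble::as_tibble(values)[need]
  bad <- setdiff(unique(values$class), panel_classes)
  if (length(bad) > 0) {
    abort(paste0("unknown metabolite class: ", paste(bad, collapse = ", ")))
  }
  cls <- dplyr::distinct(values, .data$metabolite, .data$class)
  if (anyDuplicated(cls$metabolite)) {
    abort("a metabolite is listed with more than one class")
  }
  if (anyDuplicated(values[c("metabolite", "sample")])) {
    abort("duplicate (metabolite, sample) entries in panel")
  }
  structure(
    list(values = values, scale = scale,
         metabolites = unique(values$metabolite),
         samples = unique(values$sample)),
    class = "metabolite_panel"
  )
}

#' @export
print.metabolite_panel <- function(x, ...) {
  cat(sprintf(
    "<metabolite_panel> %d metabolites x %d samples (%s scale), %d missing values\n",
    length(x$metabolites), length(x$samples), x$scale, sum(is.na(x$values$value))
  ))
  invisible(x)
}

#' @method as_tibble metabolite_panel
#' @export
as_tibble.metabolite_panel <- function(x, ...) x$values

#' Read a metabolite panel from CSV
#'
#' Expects a wide CSV with columns `metabolite`, `class`, then one
#' column per sample.  An optional leading comment line `# scale: log2`
#' (or `linear`) declares the value scale; the default is linear.
#' Empty cells are read as missing values, not zero.
#'
#' @param path CSV path.
#' @return A [metabolite_panel()].
#' @export
read_metabolite_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  first <- readLines(path, n = 1)
  scale <- "linear"
  if (grepl("^#", first)) {
    m <- regmatches(first, regexec("scale:\\s*(linear|log2)", first))[[1]]
    if (length(m) == 2) scale <- m[2]
  }
  raw <- suppressWarnings(readr::read_csv(path, comment = "#", na = c("", "NA"),
                         col_types = readr::cols(
                           metabolite = readr::col_character(),
                           class = readr::col_character(),
                           .default = readr::col_double()
                         ),
                         progress = FALSE))
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("non-numeric value in %s at file row %d", path, prob$row[1]))
  }
  if (!all(c("metabolite", "class") %in% names(raw))) {
    abort("panel CSV requires metabolite and class columns")
  }
  if (anyDuplicated(raw$metabolite)) abort("duplicate metabolite names in panel")
  long <- tidyr::pivot_longer(raw, -c("metabolite", "class"),
                              names_to = "sample", values_to = "value")
  metabolite_panel(long, scale = scale)
}

#' Write a metabolite panel to CSV
#'
#' @param panel A [metabolite_panel()].
#' @param path Output path.
#' @export
write_metabolite_panel <- function(panel, path) {
  stopifnot(inherits(panel, "metabolite_panel"))
  wide <- tidyr::pivot_wider(panel$values, names_from = "sample",
                             values_from = "value")
  writeLines(paste0("# scale: ", panel$scale), path)
  readr::write_csv(wide, path, na = "", append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}
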