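#' Normalise a panel to a control sample on the log2 scale
#'
#' Every value becomes `log2(value / control value)` for the same
#' metabolite, so the control column becomes zero and sample columns
#' are log2 ratios versus the control.  Metabolites whose control value
#' is missing or not positive cannot be normalised and are dropped with
#' a warning (their count is reported); missing sample values stay
#' missing.
#'
#' @param panel A linear-scale [metabolite_panel()].
#' @param control_sample Label of the control sample.
#' @return A log2-scale [metabolite_panel()].
#' @export
log2_normalize <- function(panel, control_sample) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$scale != "linear") abort("panel is already on the log2 scale")
  if (!control_sample %in% panel$samples) {
    abort(paste0("control sample not in panel: ", control_sample))
  }
  ctrl <- dplyr::filter(panel$values, .data$sample == control_sample)
  bad <- ctrl$metabolite[is.na(ctrl$value) | ctrl$value <= 0]
  if (length(bad) > 0) {
    warn(sprintf("dropping %d metabolite(s) with nonpositive control value",
                 length(bad)))
  }
  vals <- panel$values |>
    dplyr::filter(!.data$metabolite %in% bad) |>
    dplyr::left_join(dplyr::select(ctrl, "metabolite", control = "value"),
                     by = "metabolite") |>
    dplyr::mutate(value = log2(.data$value / .data$control)) |>
    dplyr::select(-"control")
  metabolite_panel(vals, scale = "log2")
}

panel_condition_means <- function(panel, samples) {
  panel$values |>
    dplyr::filter(.data$sample %in% samples) |>
    dplyr::group_by(.data$metabolite, .data$class) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     n = sum(!is.na(.data$value)), .groups = "drop") |>
    dplyr::mutate(mean = ifelse(.data$n == 0, NA_real_, .data$mean))
}

#' Per-metabolite log2 fold change between two conditions
#'
#' `log2fc = mean over condition A - mean over condition B` on the log2
#' scale, with missing values excluded pairwise (never imputed).  A
#' metabolite with no non-missing value in a condition gets `NA`.
#'
#' @param panel A log2-scale [metabolite_panel()].
#' @param condition_a,condition_b Character vectors of sample labels.
#' @return Tibble `metabolite`, `class`, `log2fc`, `n_a`, `n_b`.
#' @export
condition_contrast <- function(panel, condition_a, condition_b) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$scale != "log2") abort("condition_contrast needs a log2-scale panel")
  missing_samples <- setdiff(c(condition_a, condition_b), panel$samples)
  if (length(missing_samples) > 0) {
    abort(paste0("samples not in panel: ", paste(missing_samples, collapse = ", ")))
  }
  a <- panel_condition_means(panel, condition_a)
  b <- panel_condition_means(panel, condition_b)
  dplyr::inner_join(a, b, by = c("metabolite", "class"),
                    suffix = c("_a", "_b")) |>
    dplyr::transmute(.data$metabolite, .data$class,
                     log2fc = .data$mean_a - .data$mean_b,
                     n_a = .data$n_a, n_b = .data$n_b)
}

#' Two-sided paired t-test per metabolite
#'
#' For each metabolite the paired differences `d = value[a] - value[b]`
#' over the given sample pairs are tested with the two-sided paired
#' Student t-test (`t = mean(d) / (sd(d) / sqrt(n))`, `n - 1` degrees
#' of freedom).  Pairs with a missing value on either side are dropped;
#' metabolites with fewer than two complete pairs are reported
#' untested (`NA` p).  Degenerate difference vectors are flagged: all
#' differences zero gives `p = 1`, zero variance with nonzero mean
#' gives `p = 0`.
#'
#' @param panel A log2-scale [metabolite_panel()].
#' @param pairs List of `c(sample_a, sample_b)` pairs, or a two-column
#'   matrix / data frame (one pair per row).
#' @return Tibble `metabolite`, `class`, `n_pairs`, `mean_diff`,
#'   `t_statistic`, `p_value`, `degenerate`.
#' @export
paired_test <- function(panel, pairs) {
  stopifnot(inherits(panel, "metabolite_panel"))
  if (panel$scale != "log2") abort("paired_test needs a log2-scale panel")
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) as.character(pairs[i, 1:2]))
  }
  stopifnot(length(pairs) >= 1, all(lengths(pairs) == 2))
  missing_samples <- setdiff(unlist(pairs), panel$samples)
  if (length(missing_samples) > 0) {
    abort(paste0("samples not in panel: ", paste(missing_samples, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(panel$values, names_from = "sample",
                             values_from = "value")
  purrr::map_dfr(seq_len(nrow(wide)), function(i) {
    d <- vapply(pairs, function(p) wide[[p[1]]][i] - wide[[p[2]]][i], numeric(1))
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2) {
      return(tibble::tibble(metabolite = wide$metabolite[i],
                            class = wide$class[i], n_pairs = n,
                            mean_diff = if (n > 0) mean(d) else NA_real_,
                            t_statistic = NA_real_, p_value = NA_real_,
                            degenerate = FALSE))
    }
    if (sd(d) == 0) {
      p <- if (isTRUE(all.equal(mean(d), 0))) 1 else 0
      return(tibble::tibble(metabolite = wide$metabolite[i],
                            class = wide$class[i], n_pairs = n,
                            mean_diff = mean(d), t_statistic = NA_real_,
                            p_value = p, degenerate = TRUE))
    }
    tt <- stats::t.test(d, alternative = "two.sided", mu = 0)
    tibble::tibble(metabolite = wide$metabolite[i], class = wide$class[i],
                   n_pairs = n, mean_diff = mean(d),
                   t_statistic = unname(tt$statistic),
                   p_value = tt$p.value, degenerate = FALSE)
  })
}

#' Call regulation of each metabolite
#'
#' Joins fold changes and p-values and labels each tested metabolite:
#' `up` when `log2fc > fc_threshold`, `down` when
#' `log2fc < -fc_threshold` (both strict), otherwise `unchanged`;
#' `significant` when `p_value < alpha`.  No multiple-testing
#' correction is applied by default, matching the raw `p < 0.05` rule
#' used for these small paired panels; set `adjust = "BH"` for a
#' Benjamini-Hochberg adjusted call.
#'
#' @param contrast Tibble from [condition_contrast()].
#' @param tests Optional tibble from [paired_test()]; may be omitted if
#'   `contrast` already carries a `p_value` column.
#' @param fc_threshold Regulation threshold on |log2fc| (default 0.3).
#' @param alpha Significance level (default 0.05).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble `metabolite`, `class`, `log2fc`, `p_value`,
#'   `regulation`, `significant`.
#' @export
call_regulation <- function(contrast, tests = NULL, fc_threshold = 0.3,
                            alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  out <- tibble::as_tibble(contrast)
  if (!is.null(tests)) {
    out <- dplyr::left_join(out,
                            dplyr::select(tests, "metabolite", "p_value"),
                            by = "metabolite")
  }
  if (!"p_value" %in% names(out)) out$p_value <- NA_real_
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out |>
    dplyr::mutate(
      regulation = dplyr::case_when(
        is.na(.data$log2fc) ~ NA_character_,
        .data$log2fc > fc_threshold ~ "up",
        .data$log2fc < -fc_threshold ~ "down",
        TRUE ~ "unchanged"
      ),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) |>
    dplyr::select("metabolite", "class", "log2fc", "p_value",
                  "regulation", "significant")
}

#' Volcano table
#'
#' One row per tested metabolite with `neg_log10_p = -log10(p)` capped
#' at 300 (capping flagged), ready for a volcano plot; the regulation
#' and significance thresholds are carried as columns so a plot can
#' draw its dashed confidence limits from the data alone.
#'
#' @param results Tibble from [call_regulation()].
#' @param fc_threshold,alpha Thresholds echoed into the table.
#' @return Tibble `metabolite`, `class`, `log2fc`, `p_value`,
#'   `neg_log10_p`, `p_capped`, `regulation`, `significant`,
#'   `fc_threshold`, `alpha`.
#' @export
volcano_table <- function(results, fc_threshold = 0.3, alpha = 0.05) {
  stopifnot(nrow(results) > 0)
  results |>
    dplyr::filter(!is.na(.data$p_value)) |>
    dplyr::mutate(
      neg_log10_p = pmin(-log10(.data$p_value), 300),
      p_capped = .data$p_value > 0 & -log10(.data$p_value) > 300 |
        .data$p_value == 0,
      fc_threshold = fc_threshold, alpha = alpha
    ) |>
    dplyr::select("metabolite", "class", "log2fc", "p_value",
                  "neg_log10_p", "p_capped", "regulation", "significant",
                  "fc_threshold", "alpha")
}

#' Per-class regulation summary
#'
#' @param results Tibble from [call_regulation()].
#' @return Tibble per class: `n`, `n_up`, `n_down`, `n_unchanged`,
#'   `mean_log2fc`, `median_log2fc`.
#' @export
class_summary <- function(results) {
  results |>
    dplyr::filter(!is.na(.data$log2fc)) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_up = sum(.data$regulation == "up"),
      n_down = sum(.data$regulation == "down"),
      n_unchanged = sum(.data$regulation == "unchanged"),
      mean_log2fc = mean(.data$log2fc),
      median_log2fc = median(.data$log2fc),
      .groups = "drop"
    )
}
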