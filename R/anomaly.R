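#' Configuration of the one-class anomaly model
#'
#' Defaults follow the settings used for tissue Raman maps: the
#' one-class SVM margin parameter `nu = 0.05` (upper bound on the
#' training-outlier fraction), RBF kernel width `gamma = 0.0005`
#' applied in PCA-score space, PCA components retained up to 95% of
#' cumulative explained variance, and anomalies reported above 80%
#' confidence.
#'
#' @param nu Fraction in (0, 1).
#' @param gamma RBF kernel width, positive.
#' @param variance_target Fraction of PCA variance to retain, in (0, 1].
#' @param confidence_threshold Anomaly-confidence cut in (0, 1).
#' @return An object of class `anomaly_config`.
#' @export
anomaly_config <- function(nu = 0.05, gamma = 0.0005,
                           variance_target = 0.95,
                           confidence_threshold = 0.80) {
  stopifnot(nu > 0, nu < 1, gamma > 0,
            variance_target > 0, variance_target <= 1,
            confidence_threshold > 0, confidence_threshold < 1)
  structure(list(nu = nu, gamma = gamma, variance_target = variance_target,
                 confidence_threshold = confidence_threshold),
            class = "anomaly_config")
}

collect_reference_spectra <- function(reference, masks) {
  if (inherits(reference, "spectral_map")) reference <- list(reference)
  stopifnot(length(reference) >= 1)
  if (is.null(masks)) masks <- vector("list", length(reference))
  if (is.logical(masks)) masks <- list(masks)
  stopifnot(length(masks) == length(reference))
  axis <- reference[[1]]$axis
  rows <- lapply(seq_along(reference), function(i) {
    m <- reference[[i]]
    stopifnot(inherits(m, "spectral_map"))
    if (!isTRUE(all.equal(m$axis, axis))) {
      abort("all reference maps must share one wavenumber axis")
    }
    use <- m$valid
    if (!is.null(masks[[i]])) use <- use & !masks[[i]]
    m$intensity[use, , drop = FALSE]
  })
  list(x = do.call(rbind, rows), axis = axis)
}

# PCA by eigendecomposition of the feature covariance; loadings signed
# so the largest-magnitude loading of each component is positive.
pca_reduce <- function(x, variance_target) {
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  ev <- eigen(crossprod(xc) / (n - 1), symmetric = TRUE)
  lambda <- pmax(ev$values, 0)
  total <- sum(lambda)
  if (total <= 0) abort("reference spectra have zero variance")
  cs <- cumsum(lambda) / total
  k <- which(cs >= variance_target * (1 - 1e-12))[1]
  rank_cap <- min(n - 1L, ncol(x))
  if (is.na(k)) {
    warn("variance target unreachable; using full rank")
    k <- rank_cap
  }
  k <- min(k, rank_cap)
  v <- ev$vectors[, seq_len(k), drop = FALSE]
  flip <- apply(v, 2, function(col) sign(col[which.max(abs(col))]))
  v <- sweep(v, 2, flip, `*`)
  list(mean = mu, loadings = v, n_components = k,
       explained_variance = lambda[seq_len(k)] / total,
       scores = xc %*% v)
}

rbf_kernel <- function(a, b, gamma) {
  # exp(-gamma * ||a_i - b_j||^2) via BLAS
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

#' Fit the one-class anomaly model on physiological reference maps
#'
#' Learns what a physiological spectrum looks like: reference pixel
#' spectra (baseline-corrected, substrate removed) are mean-centred and
#' reduced by PCA to the minimal number of components reaching
#' `variance_target` cumulative explained variance, then a one-class
#' SVM with RBF kernel (`nu`, `gamma`) is trained on the PCA scores.
#' The signed SVM decision value `f` is positive inside the learned
#' boundary; the model stores the median absolute training decision
#' value as `decision_scale` so that scoring can map `f` to a
#' confidence in \[0, 1\].
#'
#' @param reference A [spectral_map()] or list of maps sharing one axis.
#' @param masks Optional logical mask (or list of masks) per map,
#'   `TRUE` = excluded, e.g. from [substrate_mask()].
#' @param config An [anomaly_config()].
#' @return An object of class `anomaly_model`.
#' @seealso [score_map()], [tidy.anomaly_model()]
#' @export
fit_reference <- function(reference, masks = NULL, config = anomaly_config()) {
  stopifnot(inherits(config, "anomaly_config"))
  ref <- collect_reference_spectra(reference, masks)
  n <- nrow(ref$x)
  if (n < 50) abort("need at least 50 unmasked reference spectra")
  pca <- pca_reduce(ref$x, config$variance_target)
  fit <- e1071::svm(pca$scores, type = "one-classification",
                    kernel = "radial", nu = config$nu, gamma = config$gamma,
                    scale = FALSE, cachesize = 512, tolerance = 0.001)
  model <- structure(
    list(
      axis = ref$axis,
      pca_mean = pca$mean,
      pca_loadings = pca$loadings,
      n_components = pca$n_components,
      explained_variance = pca$explained_variance,
      sv = unname(as.matrix(fit$SV)),
      sv_coefs = as.numeric(fit$coefs),
      rho = as.numeric(fit$rho),
      decision_scale = NA_real_,
      n_train = n,
      train_outlier_fraction = NA_real_,
      config = config
    ),
    class = "anomaly_model"
  )
  f_train <- decision_values(model, ref$x)
  model$decision_scale <- max(median(abs(f_train)), 1e-12)
  model$train_outlier_fraction <- mean(f_train < 0)
  if (model$train_outlier_fraction > config$nu + 0.03) {
    warn(sprintf("training outlier fraction %.3f exceeds nu + 0.03",
                 model$train_outlier_fraction))
  }
  model
}

#' Signed one-class decision values for spectra
#'
#' Projects spectra onto the model's PCA basis and evaluates the SVM
#' decision function `f(x) = sum_i alpha_i K(sv_i, x) - rho` directly
#' from the stored support vectors.  Positive values lie inside the
#' physiological boundary; anomalies are negative, increasingly so with
#' distance from the boundary.
#'
#' @param model An [fit_reference()] model.
#' @param x Matrix of spectra (rows) on the model axis.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(model, x) {
  stopifnot(inherits(model, "anomaly_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$axis)) {
    abort("spectra do not match the model axis length")
  }
  scores <- sweep(x, 2, model$pca_mean) %*% model$pca_loadings
  k <- rbf_kernel(scores, model$sv, model$config$gamma)
  as.numeric(k %*% model$sv_coefs - model$rho)
}

#' Score a map for anomalies
#'
#' Computes the per-pixel anomaly confidence
#' `1 / (1 + exp(f / s))`, where `f` is the one-class decision value of
#' the pixel's PCA projection and `s` the model's `decision_scale`.
#' The mapping is strictly decreasing in `f`: the boundary (`f = 0`)
#' maps to confidence 0.5 and deep anomalies approach 1.  A confidence
#' above 0.8 therefore corresponds to `f < -s * log(4)`.
#'
#' @param model An [fit_reference()] model.
#' @param map A [spectral_map()] on the model axis.
#' @param mask Optional logical exclusion mask (`TRUE` = not scored).
#' @return An object of class `anomaly_map` with per-pixel `confidence`
#'   (`NA` where unscored), the raw `decision` values, and the `scored`
#'   flags.
#' @export
score_map <- function(model, map, mask = NULL) {
  stopifnot(inherits(model, "anomaly_model"), inherits(map, "spectral_map"))
  if (length(map$axis) != length(model$axis) ||
      !isTRUE(all.equal(map$axis, model$axis))) {
    abort("map axis does not match the model axis")
  }
  scored <- map$valid
  if (!is.null(mask)) {
    stopifnot(length(mask) == n_pixels(map))
    scored <- scored & !mask
  }
  conf <- rep(NA_real_, n_pixels(map))
  dec <- rep(NA_real_, n_pixels(map))
  if (any(scored)) {
    f <- decision_values(model, map$intensity[scored, , drop = FALSE])
    dec[scored] <- f
    conf[scored] <- 1 / (1 + exp(f / model$decision_scale))
  }
  structure(
    list(confidence = conf, decision = dec, scored = scored,
         n_rows = map$n_rows, n_cols = map$n_cols),
    class = "anomaly_map"
  )
}

#' @export
print.anomaly_map <- function(x, ...) {
  cat(sprintf(
    "<anomaly_map> %d x %d pixels, %d scored, median confidence %.3f\n",
    x$n_rows, x$n_cols, sum(x$scored),
    median(x$confidence, na.rm = TRUE)
  ))
  invisible(x)
}

#' @method as_tibble anomaly_map
#' @export
as_tibble.anomaly_map <- function(x, ...) {
  idx0 <- seq_len(x$n_rows * x$n_cols) - 1L
  tibble::tibble(
    row = idx0 %/% x$n_cols,
    col = idx0 %% x$n_cols,
    confidence = x$confidence,
    decision = x$decision,
    scored = x$scored
  )
}

#' Connected anomaly regions of a confidence map
#'
#' Labels 4-connected components of pixels whose confidence exceeds
#' `threshold` (strictly), the operation that turns a confidence heat
#' map into discrete lesion / parietal-cell candidate regions.  Regions
#' are numbered by decreasing pixel count, ties broken by the first
#' (row-major) pixel.
#'
#' @param amap An [score_map()] result.
#' @param threshold Confidence cut in (0, 1); defaults to 0.8.
#' @return An object of class `anomaly_regions`: integer `labels` per
#'   pixel (0 = background) and a `summary` tibble with `region`,
#'   `n_pixels` and bounding box columns.
#' @export
anomaly_regions <- function(amap, threshold = 0.8) {
  stopifnot(inherits(amap, "anomaly_map"), threshold > 0, threshold < 1)
  nr <- amap$n_rows
  nc <- amap$n_cols
  hot <- !is.na(amap$confidence) & amap$confidence > threshold
  labels <- integer(nr * nc)
  comp <- 0L
  for (start in which(hot)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      r <- (cur - 1L) %/% nc
      c <- (cur - 1L) %% nc
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr < 0L || rr >= nr || cc < 0L || cc >= nc) next
        nb <- rr * nc + cc + 1L
        if (hot[nb] && labels[nb] == 0L) {
          labels[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  if (comp == 0L) {
    summary <- tibble::tibble(region = integer(), n_pixels = integer(),
                              min_row = integer(), min_col = integer(),
                              max_row = integer(), max_col = integer())
  } else {
    idx0 <- seq_len(nr * nc) - 1L
    summary <- tibble::tibble(lab = labels, row = idx0 %/% nc,
                              col = idx0 %% nc)[labels > 0L, ]
    first_px <- vapply(seq_len(comp), function(l) which(labels == l)[1],
                       integer(1))
    summary <- summary |>
      dplyr::group_by(.data$lab) |>
      dplyr::summarise(n_pixels = dplyr::n(),
                       min_row = min(.data$row), min_col = min(.data$col),
                       max_row = max(.data$row), max_col = max(.data$col),
                       .groups = "drop")
    ord <- order(-summary$n_pixels, first_px[summary$lab])
    summary <- summary[ord, ]
    relab <- integer(comp)
    relab[summary$lab] <- seq_len(comp)
    labels[labels > 0L] <- relab[labels[labels > 0L]]
    summary$region <- seq_len(comp)
    summary <- summary[c("region", "n_pixels", "min_row", "min_col",
                         "max_row", "max_col")]
  }
  structure(list(labels = labels, summary = summary, threshold = threshold,
                 n_rows = nr, n_cols = nc),
            class = "anomaly_regions")
}

#' @export
print.anomaly_regions <- function(x, ...) {
  cat(sprintf("<anomaly_regions> %d regions above confidence %.2f\n",
              nrow(x$summary), x$threshold))
  if (nrow(x$summary) > 0) print(x$summary)
  invisible(x)
}

#' Mean spectrum per anomaly region and difference to a reference
#'
#' For each labelled region the pointwise mean spectrum over its pixels
#' is computed, together with the difference to a reference mean
#' spectrum (typically the physiological mean), the quantity examined
#' band by band when characterising what distinguishes an anomalous
#' region.
#'
#' @param map The [spectral_map()] the regions were scored on.
#' @param regions An [anomaly_regions()] object on the same grid.
#' @param reference_mean Optional reference spectrum tibble
#'   (`wavenumber_cm1`, `intensity`) on the same axis.
#' @return Long tibble with columns `region`, `wavenumber_cm1`,
#'   `intensity` and, when a reference is given, `reference` and
#'   `difference`.
#' @export
region_mean_spectra <- function(map, regions, reference_mean = NULL) {
  stopifnot(inherits(map, "spectral_map"), inherits(regions, "anomaly_regions"))
  if (regions$n_rows != map$n_rows || regions$n_cols != map$n_cols) {
    abort("regions do not match the map grid")
  }
  if (nrow(regions$summary) == 0) abort("no regions to average")
  out <- purrr::map_dfr(regions$summary$region, function(l) {
    px <- which(regions$labels == l)
    tibble::tibble(
      region = l,
      wavenumber_cm1 = map$axis,
      intensity = colMeans(map$intensity[px, , drop = FALSE])
    )
  })
  if (!is.null(reference_mean)) {
    reference_mean <- as_spectrum(reference_mean)
    if (!isTRUE(all.equal(reference_mean$wavenumber_cm1, map$axis))) {
      abort("reference mean spectrum is not on the map axis")
    }
    out$reference <- rep(reference_mean$intensity, nrow(regions$summary))
    out$difference <- out$intensity - out$reference
  }
  out
}

#' @method tidy anomaly_model
#' @export
tidy.anomaly_model <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    explained_variance = x$explained_variance,
    cumulative_variance = cumsum(x$explained_variance)
  )
}

#' @method glance anomaly_model
#' @export
glance.anomaly_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    n_components = x$n_components,
    variance_retained = sum(x$explained_variance),
    nu = x$config$nu,
    gamma = x$config$gamma,
    n_support = nrow(x$sv),
    train_outlier_fraction = x$train_outlier_fraction,
    decision_scale = x$decision_scale
  )
}

#' @export
print.anomaly_model <- function(x, ...) {
  cat(sprintf(
    "<anomaly_model> %d components (%.1f%% variance), %d support vectors, nu=%g gamma=%g\n",
    x$n_components, 100 * sum(x$explained_variance), nrow(x$sv),
    x$config$nu, x$config$gamma
  ))
  invisible(x)
}

#' Serialise / restore an anomaly model as JSON
#'
#' The JSON file stores the axis, PCA mean and loadings, support
#' vectors, coefficients, offset and configuration at full double
#' precision, so a restored model reproduces decision values exactly.
#'
#' @param model An [fit_reference()] model.
#' @param path JSON path.
#' @return `read_anomaly_model()` returns the restored model.
#' @export
write_anomaly_model <- function(model, path) {
  stopifnot(inherits(model, "anomaly_model"))
  payload <- list(
    axis = model$axis,
    pca_mean = model$pca_mean,
    pca_loadings = model$pca_loadings,
    n_components = model$n_components,
    explained_variance = model$explained_variance,
    sv = model$sv,
    sv_coefs = model$sv_coefs,
    rho = model$rho,
    decision_scale = model$decision_scale,
    n_train = model$n_train,
    train_outlier_fraction = model$train_outlier_fraction,
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_anomaly_model
#' @export
read_anomaly_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      axis = as.numeric(p$axis),
      pca_mean = as.numeric(p$pca_mean),
      pca_loadings = as.matrix(p$pca_loadings),
      n_components = as.integer(p$n_components),
      explained_variance = as.numeric(p$explained_variance),
      sv = as.matrix(p$sv),
      sv_coefs = as.numeric(p$sv_coefs),
      rho = as.numeric(p$rho),
      decision_scale = as.numeric(p$decision_scale),
      n_train = as.integer(p$n_train),
      train_outlier_fraction = as.numeric(p$train_outlier_fraction),
      config = do.call(anomaly_config, p$config)
    ),
    class = "anomaly_model"
  )
}
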