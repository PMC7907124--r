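# Shared small-scale fitted model: reference and lesion maps at 24x24.
fixture_env <- new.env()
get_fixture <- function() {
  if (is.null(fixture_env$model)) {
    maps <- small_fixture_maps(seed = 42)
    corrected <- baseline_correct_map(maps$ref$map)
    mask <- substrate_mask(corrected)
    fixture_env$ref_corrected <- corrected
    fixture_env$ref_mask <- mask
    fixture_env$model <- fit_reference(corrected, mask)
    fixture_env$les <- maps$les
  }
  fixture_env
}

test_that("noiseless rank-2 references yield exactly two components", {
  axis <- short_axis()
  a <- exp(-(axis - 800)^2 / 500)
  b <- exp(-(axis - 1100)^2 / 800)
  set.seed(1)
  w <- cbind(runif(80, 1, 3), runif(80, 1, 3))
  x <- w %*% rbind(a, b)
  m <- spectral_map(x, axis, 8, 10)
  fit <- fit_reference(m, config = anomaly_config(variance_target = 0.95))
  expect_equal(fit$n_components, 2)
})

test_that("variance target 1 on full-rank data uses min(n-1, p) components", {
  axis <- seq(900, 960, by = 2)
  set.seed(2)
  x <- matrix(rexp(60 * length(axis)), 60)
  m <- spectral_map(x, axis, 6, 10)
  fit <- suppressWarnings(
    fit_reference(m, config = anomaly_config(variance_target = 1))
  )
  expect_equal(fit$n_components, min(60 - 1, length(axis)))
})

test_that("the nu-property bounds the training outlier fraction", {
  fx <- get_fixture()
  expect_gte(fx$model$train_outlier_fraction, 0)
  expect_lte(fx$model$train_outlier_fraction, 0.05 + 0.03)
})

test_that("stored decision function reproduces the library SVM decision values", {
  # brute-force check: our BLAS evaluation vs e1071 predict on the
  # same spectra must agree, and the sign must match the nu-property
  fx <- get_fixture()
  x <- fx$ref_corrected$intensity[which(!fx$ref_mask)[1:40], ]
  ours <- decision_values(fx$model, x)
  scores <- sweep(x, 2, fx$model$pca_mean) %*% fx$model$pca_loadings
  refit <- e1071::svm(
    sweep(fx$ref_corrected$intensity[!fx$ref_mask, ], 2, fx$model$pca_mean) %*%
      fx$model$pca_loadings,
    type = "one-classification", kernel = "radial",
    nu = 0.05, gamma = 5e-4, scale = FALSE)
  theirs <- attr(predict(refit, scores, decision.values = TRUE),
                 "decision.values")
  expect_equal(ours, as.numeric(theirs), tolerance = 1e-6)
})

test_that("PCA loadings are orthonormal with the sign convention", {
  fx <- get_fixture()
  v <- fx$model$pca_loadings
  gram <- crossprod(v)
  expect_equal(gram, diag(ncol(v)), tolerance = 1e-8)
  top <- apply(v, 2, function(col) col[which.max(abs(col))])
  expect_true(all(top > 0))
})

test_that("PCA retains at least the variance target", {
  fx <- get_fixture()
  expect_gte(sum(fx$model$explained_variance), 0.95 - 1e-9)
})

test_that("scoring the reference map gives median confidence below 0.5", {
  fx <- get_fixture()
  amap <- score_map(fx$model, fx$ref_corrected, fx$ref_mask)
  expect_lt(median(amap$confidence, na.rm = TRUE), 0.5)
  # interior point: the PCA mean spectrum itself is not anomalous
  centre <- matrix(fx$model$pca_mean, 1)
  f <- decision_values(fx$model, centre)
  expect_lt(1 / (1 + exp(f / fx$model$decision_scale)), 0.5)
})

test_that("confidence is a monotone map of the decision value through 0.5", {
  fx <- get_fixture()
  amap <- score_map(fx$model, fx$ref_corrected, fx$ref_mask)
  ok <- !is.na(amap$confidence)
  expect_true(all(amap$confidence[ok] >= 0 & amap$confidence[ok] <= 1))
  ord <- order(amap$decision[ok])
  expect_true(all(diff(amap$confidence[ok][ord]) <= 1e-12))
  expect_equal(1 / (1 + exp(0 / fx$model$decision_scale)), 0.5)
})

test_that("lesion pixels score higher confidence than background", {
  fx <- get_fixture()
  tc <- baseline_correct_map(fx$les$map)
  amap <- score_map(fx$model, tc, substrate_mask(tc))
  truth <- fx$les$truth
  lesion_conf <- amap$confidence[truth$lesion_mask]
  bg_conf <- amap$confidence[!truth$lesion_mask & !truth$substrate_mask]
  expect_gt(mean(lesion_conf, na.rm = TRUE), mean(bg_conf, na.rm = TRUE))
})

test_that("growing a lesion signature beyond the cloud raises confidence monotonically", {
  # RBF one-class decisions are not monotone for displacements inside
  # the reference cloud (moving a low-lipid pixel towards the mean can
  # raise its decision value); monotonicity holds once the signature
  # carries the pixel beyond the within-cloud variation, which is the
  # regime planted lesions live in.
  fx <- get_fixture()
  axis <- fx$ref_corrected$axis
  sig <- 3 * (8^2) / ((axis - 1442)^2 + 8^2) + 2 * (8^2) / ((axis - 1643)^2 + 8^2)
  set.seed(31)
  px <- sample(which(!fx$ref_mask), 200)
  steps <- c(4, 8, 16, 32)
  for (p in px) {
    x <- t(vapply(c(0, steps),
                  function(s) fx$ref_corrected$intensity[p, ] + s * sig,
                  numeric(length(axis))))
    f <- decision_values(fx$model, x)
    conf <- 1 / (1 + exp(f / fx$model$decision_scale))
    expect_true(all(diff(conf[-1]) >= -1e-9))
    expect_gt(conf[length(conf)], conf[1])
  }
})

test_that("model fitting is deterministic", {
  maps <- small_fixture_maps(seed = 77, n = 12)
  corrected <- baseline_correct_map(maps$ref$map)
  m1 <- suppressWarnings(fit_reference(corrected))
  m2 <- suppressWarnings(fit_reference(corrected))
  expect_identical(m1$pca_loadings, m2$pca_loadings)
  expect_identical(m1$sv_coefs, m2$sv_coefs)
  expect_identical(m1$decision_scale, m2$decision_scale)
})

test_that("model JSON round-trip preserves decision values exactly", {
  maps <- small_fixture_maps(seed = 78, n = 12)
  corrected <- baseline_correct_map(maps$ref$map)
  model <- suppressWarnings(fit_reference(corrected))
  path <- withr::local_tempfile(fileext = ".json")
  write_anomaly_model(model, path)
  model2 <- read_anomaly_model(path)
  x <- corrected$intensity[1:20, ]
  expect_equal(decision_values(model2, x), decision_values(model, x),
               tolerance = 1e-12)
  expect_equal(model2$config$gamma, model$config$gamma)
})

test_that("fit_reference rejects insufficient references and axis mismatch", {
  axis <- short_axis()
  m <- spectral_map(matrix(rexp(10 * length(axis)), 10), axis, 2, 5)
  expect_error(fit_reference(m), "at least 50")
  fx <- get_fixture()
  other <- spectral_map(matrix(1, 4, 3), c(900, 910, 920), 2, 2)
  expect_error(score_map(fx$model, other), "axis")
})

test_that("anomaly regions label 4-connected components with deterministic order", {
  conf <- rep(0.3, 36)
  amap <- structure(list(confidence = conf, decision = rep(1, 36),
                         scored = rep(TRUE, 36), n_rows = 6, n_cols = 6),
                    class = "anomaly_map")
  expect_equal(nrow(anomaly_regions(amap, 0.8)$summary), 0)

  # two diagonal pixels are NOT 4-connected
  conf2 <- conf
  conf2[c(1, 8)] <- 0.95          # (0,0) and (1,1)
  r2 <- anomaly_regions(structure(list(confidence = conf2, decision = conf2,
                                       scored = rep(TRUE, 36), n_rows = 6,
                                       n_cols = 6), class = "anomaly_map"), 0.8)
  expect_equal(nrow(r2$summary), 2)
  expect_equal(r2$summary$n_pixels, c(1, 1))
  expect_equal(r2$summary$min_row, c(0, 1))   # tie broken by top-left pixel

  # planted blobs: a 2x2 block and an L of 3 pixels
  conf3 <- conf
  conf3[c(1, 2, 7, 8)] <- 0.9                   # rows 0-1, cols 0-1
  conf3[c(23, 29, 30)] <- 0.9                   # (3,4),(4,4),(4,5)
  r3 <- anomaly_regions(structure(list(confidence = conf3, decision = conf3,
                                       scored = rep(TRUE, 36), n_rows = 6,
                                       n_cols = 6), class = "anomaly_map"), 0.8)
  expect_equal(r3$summary$n_pixels, c(4, 3))
  expect_equal(r3$summary$min_row[1], 0)
  expect_equal(sum(r3$labels == 1), 4)
})

test_that("region mean spectra recover planted signatures and differences", {
  axis <- short_axis()
  base <- 10 * exp(-(axis - 900)^2 / 5000)
  bump <- 5 * (8^2) / ((axis - 1003)^2 + 8^2)
  x <- rbind(base, base, base + bump, base + bump)
  m <- spectral_map(x, axis, 2, 2)
  conf <- c(0.1, 0.1, 0.9, 0.9)
  amap <- structure(list(confidence = conf, decision = -conf,
                         scored = rep(TRUE, 4), n_rows = 2, n_cols = 2),
                    class = "anomaly_map")
  regions <- anomaly_regions(amap, 0.8)
  ref <- tibble::tibble(wavenumber_cm1 = axis, intensity = base)
  out <- region_mean_spectra(m, regions, ref)
  expect_equal(unique(out$region), 1)
  expect_equal(out$intensity, base + bump, tolerance = 1e-12)
  expect_equal(out$wavenumber_cm1[which.max(out$difference)], 1003,
               tolerance = 2)
  # a region covering a uniform map reproduces the pixel spectrum exactly
  uni <- spectral_map(rbind(base, base, base, base), axis, 2, 2)
  amap_all <- structure(list(confidence = rep(0.9, 4), decision = rep(-1, 4),
                             scored = rep(TRUE, 4), n_rows = 2, n_cols = 2),
                        class = "anomaly_map")
  out_all <- region_mean_spectra(uni, anomaly_regions(amap_all, 0.5),
                                 tibble::tibble(wavenumber_cm1 = axis,
                                                intensity = base))
  expect_equal(out_all$intensity, base)
  expect_equal(out_all$difference, rep(0, length(axis)))
})

test_that("two regions with distinct signatures recover their own spectra", {
  axis <- short_axis()
  base <- rep(5, length(axis))
  sig1 <- 20 * (8^2) / ((axis - 800)^2 + 8^2)
  sig2 <- 20 * (8^2) / ((axis - 1100)^2 + 8^2)
  x <- rbind(base + sig1, base, base, base + sig2)
  m <- spectral_map(x, axis, 2, 2)
  conf <- c(0.9, 0.1, 0.1, 0.9)
  amap <- structure(list(confidence = conf, decision = -conf,
                         scored = rep(TRUE, 4), n_rows = 2, n_cols = 2),
                    class = "anomaly_map")
  out <- region_mean_spectra(m, anomaly_regions(amap, 0.8))
  s1 <- dplyr::filter(out, region == 1)$intensity
  s2 <- dplyr::filter(out, region == 2)$intensity
  expect_gt(cor(s1, base + sig1), 0.95)
  expect_gt(cor(s2, base + sig2), 0.95)
})

test_that("tidy and glance summarise the fitted model", {
  fx <- get_fixture()
  td <- tidy(fx$model)
  expect_equal(nrow(td), fx$model$n_components)
  expect_true(all(diff(td$cumulative_variance) >= 0))
  gl <- glance(fx$model)
  expect_equal(gl$nu, 0.05)
  expect_equal(gl$gamma, 5e-4)
})
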