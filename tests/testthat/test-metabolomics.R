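mk_panel <- function(df, scale = "linear") {
  long <- tidyr::pivot_longer(df, -c("metabolite", "class"),
                              names_to = "sample", values_to = "value")
  metabolite_panel(long, scale = scale)
}

test_that("log2 normalisation maps control to zero and doubling to +1", {
  p <- mk_panel(tibble::tibble(
    metabolite = c("a", "b"), class = "other",
    CTRL = c(10, 4), S1 = c(10, 4), S2 = c(20, 8)
  ))
  n <- log2_normalize(p, "CTRL")
  expect_equal(n$scale, "log2")
  v <- tidyr::pivot_wider(n$values, names_from = "sample", values_from = "value")
  expect_equal(v$CTRL, c(0, 0))
  expect_equal(v$S1, c(0, 0))
  expect_equal(v$S2, c(1, 1))
})

test_that("metabolites with nonpositive control are dropped with a warning", {
  p <- mk_panel(tibble::tibble(
    metabolite = c("a", "b", "c"), class = "other",
    CTRL = c(10, 0, NA), S1 = c(20, 5, 5)
  ))
  expect_warning(n <- log2_normalize(p, "CTRL"), "2 metabolite")
  expect_equal(sort(n$metabolites), "a")
  expect_error(log2_normalize(p, "NOPE"), "control sample")
})

test_that("condition contrast does hand arithmetic and pairwise exclusion", {
  p <- mk_panel(tibble::tibble(
    metabolite = c("m1", "m2"), class = "other",
    A1 = c(1, NA), A2 = c(2, NA), B1 = c(0, 1), B2 = c(1, 2)
  ), scale = "log2")
  cc <- condition_contrast(p, c("A1", "A2"), c("B1", "B2"))
  expect_equal(cc$log2fc[cc$metabolite == "m1"], 1)
  expect_true(is.na(cc$log2fc[cc$metabolite == "m2"]))  # no A values at all
  same <- condition_contrast(p, c("A1", "A2"), c("A1", "A2"))
  expect_equal(same$log2fc[same$metabolite == "m1"], 0)
})

test_that("contrast after normalisation ignores per-metabolite scaling", {
  base <- tibble::tibble(
    metabolite = c("m1", "m2"), class = "other",
    CTRL = c(5, 50), A1 = c(10, 100), B1 = c(5, 50)
  )
  scaled <- dplyr::mutate(base, dplyr::across(c("CTRL", "A1", "B1"), ~ .x * 7))
  fc <- function(df) {
    condition_contrast(log2_normalize(mk_panel(df), "CTRL"), "A1", "B1")$log2fc
  }
  expect_equal(fc(base), fc(scaled))
  expect_equal(fc(base), c(1, 1))
})

test_that("planted contrasts are recovered within the simulation band", {
  hits <- vapply(1:1000, function(seed) {
    sim <- simulate_panel(
      n_metabolites = 2, class_mix = c("other" = 2),
      effects = tibble::tibble(metabolite = "X.1", condition = "relapse",
                               effect = 1.33),
      n_samples_per_condition = 2, noise_sd_log2 = 0.1, seed = seed
    )
    p <- log2_normalize(sim$panel, "CTRL")
    fc <- condition_contrast(p, c("relapse_1", "relapse_2"),
                             c("remission_1", "remission_2"))
    abs(fc$log2fc[fc$metabolite == "X.1"] - 1.33) <= 0.3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("paired test matches the closed-form t oracle to 1e-6", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    d <- round(rnorm(n, sd = sample(c(0.2, 1, 5), 1)), 4)
    df <- tibble::tibble(metabolite = "m", class = "other")
    for (j in seq_len(n)) {
      df[[paste0("A", j)]] <- d[j]
      df[[paste0("B", j)]] <- 0
    }
    p <- mk_panel(df, scale = "log2")
    pairs <- lapply(seq_len(n), function(j) c(paste0("A", j), paste0("B", j)))
    got <- paired_test(p, pairs)
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    p_oracle <- 2 * stats::pt(-abs(t_oracle), n - 1)
    expect_equal(got$p_value, p_oracle, tolerance = 1e-6)
    expect_equal(got$t_statistic, t_oracle, tolerance = 1e-6)
  }
})

test_that("degenerate difference vectors hit the documented edge rules", {
  p <- mk_panel(tibble::tibble(
    metabolite = c("const", "zero", "single"), class = "other",
    A1 = c(2, 1, 1), B1 = c(1, 1, NA), A2 = c(3, 5, 2), B2 = c(2, 5, NA)
  ), scale = "log2")
  pairs <- list(c("A1", "B1"), c("A2", "B2"))
  out <- paired_test(p, pairs)
  expect_equal(out$p_value[out$metabolite == "const"], 0)  # d = {1, 1}
  expect_true(out$degenerate[out$metabolite == "const"])
  expect_equal(out$p_value[out$metabolite == "zero"], 1)   # d = {0, 0}
  expect_true(is.na(out$p_value[out$metabolite == "single"]))  # < 2 pairs
  expect_equal(out$n_pairs[out$metabolite == "single"], 0)
})

test_that("type-I error is calibrated at alpha = 0.05 for n = 5 pairs", {
  set.seed(1234)
  reps <- 2000
  rej <- vapply(seq_len(reps), function(i) {
    d <- rnorm(5)
    t <- mean(d) / (sd(d) / sqrt(5))
    2 * stats::pt(-abs(t), 4) < 0.05
  }, logical(1))
  # direct simulation through the package path on a subsample
  sub <- vapply(1:200, function(seed) {
    set.seed(seed + 5000)
    df <- tibble::tibble(metabolite = "m", class = "other")
    for (j in 1:5) {
      df[[paste0("A", j)]] <- rnorm(1)
      df[[paste0("B", j)]] <- 0
    }
    p <- mk_panel(df, scale = "log2")
    out <- paired_test(p, lapply(1:5, function(j) c(paste0("A", j), paste0("B", j))))
    out$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
  expect_lt(abs(mean(sub) - mean(rej)), 0.05)
})

test_that("power exceeds 0.8 for effect 1.0, SD 0.3, four pairs", {
  set.seed(77)
  rej <- vapply(1:2000, function(i) {
    d <- rnorm(4, mean = 1, sd = 0.3)
    t <- mean(d) / (sd(d) / sqrt(4))
    2 * stats::pt(-abs(t), 3) < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)
})

test_that("regulation calls use strict thresholds and partition the panel", {
  res <- call_regulation(
    tibble::tibble(metabolite = c("a", "b", "c", "d"), class = "other",
                   log2fc = c(0.3, 1.33, -0.75, -0.3)),
    tests = tibble::tibble(metabolite = c("a", "b", "c", "d"),
                           p_value = c(0.5, 0.009, 0.029, 0.04))
  )
  expect_equal(res$regulation, c("unchanged", "up", "down", "unchanged"))
  expect_equal(res$significant, c(FALSE, TRUE, TRUE, TRUE))
  expect_true(all(table(res$regulation) >= 0))
  expect_equal(sum(res$regulation %in% c("up", "down", "unchanged")), 4)
})

test_that("volcano table computes -log10 p with capping and bookkeeping", {
  res <- call_regulation(
    tibble::tibble(metabolite = c("a", "b", "c"), class = "other",
                   log2fc = c(1, -1, 0)),
    tests = tibble::tibble(metabolite = c("a", "b", "c"),
                           p_value = c(0.05, 0, NA))
  )
  v <- volcano_table(res)
  expect_equal(nrow(v), 2)  # untested metabolite excluded
  expect_equal(v$neg_log10_p[v$metabolite == "a"], -log10(0.05))
  expect_equal(v$neg_log10_p[v$metabolite == "b"], 300)
  expect_true(v$p_capped[v$metabolite == "b"])
  # an empty significant set still yields a table
  res2 <- call_regulation(
    tibble::tibble(metabolite = "a", class = "other", log2fc = 0.1),
    tests = tibble::tibble(metabolite = "a", p_value = 0.9)
  )
  expect_equal(nrow(volcano_table(res2)), 1)
  expect_false(any(volcano_table(res2)$significant))
})

test_that("class summaries aggregate planted directions", {
  sim <- simulate_panel(
    n_metabolites = 20,
    class_mix = c("acylcarnitine" = 10, "sphingomyelin" = 10),
    effects = tibble::tibble(class = "acylcarnitine", condition = "relapse",
                             effect = -0.5),
    n_samples_per_condition = 3, noise_sd_log2 = 0.05, seed = 3
  )
  p <- log2_normalize(sim$panel, "CTRL")
  cc <- condition_contrast(p, paste0("relapse_", 1:3), paste0("remission_", 1:3))
  res <- call_regulation(cc)
  cs <- class_summary(res)
  ac <- dplyr::filter(cs, class == "acylcarnitine")
  expect_equal(ac$n_down, 10)
  expect_equal(ac$mean_log2fc, -0.5, tolerance = 0.15)
  expect_equal(sum(cs$n_up + cs$n_down + cs$n_unchanged), 20)
  one <- class_summary(dplyr::filter(res, class == "sphingomyelin"))
  expect_equal(nrow(one), 1)
})
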