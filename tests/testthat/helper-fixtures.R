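# Small in-code fixtures shared across test files.

short_axis <- function(low = 600, high = 1200, step = 2) seq(low, high, by = step)

# A tiny deterministic map: smooth per-pixel spectra with known values.
tiny_map <- function(n_rows = 2, n_cols = 2, axis = c(1000, 1010, 1020)) {
  npx <- n_rows * n_cols
  intensity <- outer(seq_len(npx), seq_along(axis),
                     function(i, j) 10 * i + j)
  spectral_map(intensity, axis, n_rows, n_cols)
}

# Random valid map for round-trip properties.
random_map <- function(seed, n_rows = 3, n_cols = 4, n_wn = 12) {
  set.seed(seed)
  axis <- sort(runif(n_wn, 400, 1800))
  intensity <- matrix(rexp(n_rows * n_cols * n_wn), n_rows * n_cols, n_wn)
  valid <- runif(n_rows * n_cols) > 0.2
  if (!any(valid)) valid[1] <- TRUE
  spectral_map(intensity, axis, n_rows, n_cols, valid)
}

# Reference / lesion map pair at reduced scale for pipeline tests.
small_fixture_maps <- function(seed = 42, n = 24) {
  ref <- simulate_map(fsgs_map_spec(seed = seed, n_rows = n, n_cols = n,
                                    lesions = FALSE))
  les <- suppressMessages(
    simulate_map(fsgs_map_spec(seed = seed + 1, n_rows = n, n_cols = n))
  )
  list(ref = ref, les = les)
}

# Panel fixture with one planted effect.
small_panel <- function(seed = 7, effect = 1.0, noise = 0.05) {
  simulate_panel(
    n_metabolites = 12,
    class_mix = c("acylcarnitine" = 5, "amino acid/biogenic amine" = 4,
                  "sphingomyelin" = 3),
    effects = tibble::tibble(metabolite = "AC.1", condition = "relapse",
                             effect = effect),
    n_samples_per_condition = 3, noise_sd_log2 = noise, seed = seed
  )
}
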