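# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Small anatomical cohort (no fMRI) with default planted effects, plus a
# quickly trained VAE: enough signal for qualitative lesion-score checks.
small_vae_fixture <- function() {
  memo("small_vae", {
    cfg <- cohort_config(n_per_group = 12, grid_shape = c(24, 24, 8),
                         effect = "default", seed = 7)
    cohort <- generate_cohort(cfg, with_fmri = FALSE)
    parc <- cohort$parcellation
    anats <- lapply(cohort$subjects, function(s)
      histogram_match(s$anat, cohort$subjects[[1]]$anat, mask = parc$mask))
    arch <- vae_architecture(c(24, 24), channels = c(8, 16, 32),
                             latent_dim = 16)
    slices <- training_slices(anats, arch$input_size)
    model <- train_vae(slices, arch,
                       vae_train_config(epochs = 5, batch_size = 16,
                                        learning_rate = 5e-3, seed = 3))
    list(cohort = cohort, parc = parc, anats = anats, arch = arch,
         model = model)
  })
}

# Strong-lesion fixture for the score-contrast property: larger grid and
# slightly longer training give a well-converged normal-anatomy model.
contrast_fixture <- function() {
  memo("contrast", {
    cfg <- cohort_config(n_per_group = 16, grid_shape = c(32, 32, 10),
                         effect = "strong", seed = 7)
    cohort <- generate_cohort(cfg, with_fmri = FALSE)
    parc <- cohort$parcellation
    anats <- lapply(cohort$subjects, function(s)
      histogram_match(s$anat, cohort$subjects[[1]]$anat, mask = parc$mask))
    arch <- vae_architecture(c(32, 32), channels = c(8, 16, 32),
                             latent_dim = 16)
    model <- train_vae(training_slices(anats, arch$input_size), arch,
                       vae_train_config(epochs = 8, batch_size = 16,
                                        learning_rate = 5e-3, seed = 3))
    list(cohort = cohort, parc = parc, anats = anats, model = model)
  })
}

# Small functional cohort (with time series) for feature/stats tests.
small_fmri_cohort <- function() {
  memo("small_fmri", {
    generate_cohort(cohort_config(n_per_group = 6, grid_shape = c(20, 20, 8),
                                  effect = "default", seed = 21))
  })
}

# A feature table with a planted mean shift in the first `k` columns.
toy_features <- function(n_per_group, p, effect = 0, k = 3, seed = 1,
                         block = "lesion") {
  set.seed(seed)
  x <- matrix(stats::rnorm(2 * n_per_group * p), 2 * n_per_group, p)
  x[seq_len(n_per_group), seq_len(k)] <-
    x[seq_len(n_per_group), seq_len(k)] + effect
  rownames(x) <- sprintf("s%03d", seq_len(2 * n_per_group))
  colnames(x) <- sprintf("f%03d", seq_len(p))
  structure(list(x = x,
                 labels = rep(c("PTE", "nonPTE"), each = n_per_group),
                 feature_group = rep(block, p)),
            class = "pte_features")
}

# Brute-force reference median filter with reflect padding.
brute_median_filter <- function(img, size) {
  h <- (size - 1) / 2
  nr <- nrow(img); nc <- ncol(img)
  refl <- function(i, n) { i <- abs(i - 1) + 1; ifelse(i > n, 2 * n - i, i) }
  out <- img
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    vals <- c()
    for (dr in -h:h) for (dc in -h:h)
      vals <- c(vals, img[refl(r + dr, nr), refl(c + dc, nc)])
    out[r, c] <- stats::median(vals)
  }
  out
}
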