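# Shared fixtures: small cohorts and model configs sized for fast tests, and
# a memoised trained model so expensive training runs once per test session.

make_small_cohort <- function(n = 8, t_future = 2, n_classes = rep(3, t_future + 1),
                              image_size = c(32, 32), noise_sd = 0.02,
                              seed = 42, ...) {
  generate_cohort(trajectory_config(
    n_subjects = n, t_future = t_future, n_classes = n_classes,
    image_size = image_size, noise_sd = noise_sd, seed = seed, ...))
}

make_small_config <- function(t_future = 2, n_classes = rep(3, t_future + 1),
                              image_size = c(32, 32), cx = 16, cm = 16,
                              depths = c(2, 2, 2), heads = 4, ...) {
  dtf_config(t_future, n_classes, image_size = image_size, cx = cx, cm = cm,
             depths = depths, heads = heads,
             backbone = list(width = 8, n_stages = 3), ...)
}

subset_cohort <- function(cohort, idx) {
  out <- cohort[idx]
  class(out) <- class(cohort)
  attr(out, "config") <- attr(cohort, "config")
  attr(out, "covariate_spec") <- attr(cohort, "covariate_spec")
  out
}

# Balanced accuracy of predictions against label-permuted ground truth,
# averaged over `n_perm` permutations: the chance-level control.
permuted_ba <- function(labels, predictions, n_perm = 50, seed = 1) {
  withr::with_seed(seed, {
    mean(replicate(n_perm, balanced_accuracy(sample(labels), predictions)))
  })
}

# Memoised strong-signal training run shared across test blocks.
.fixture_cache <- new.env(parent = emptyenv())

trained_recovery_fixture <- function(seed = 1) {
  key <- paste0("recovery_", seed)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cohort <- generate_cohort(trajectory_config(
    n_subjects = 600, t_future = 2, n_classes = c(2, 2, 2),
    image_size = c(64, 64), noise_sd = 0, covariate_effect = 0.15,
    seed = 100 + seed))
  folds <- split_cohort(cohort, 5, seed = seed)
  mcfg <- dtf_config(2, c(2, 2, 2), image_size = c(64, 64), cx = 32, cm = 32,
                     depths = c(2, 2, 2), heads = 4, k_cls = 3)
  rc <- run_config(mcfg, epochs = 30, batch_size = 32, lr = 1e-3,
                   lambda = 0.5, loss = "club", seed = seed)
  ckpt <- train_dtf(rc, subset_cohort(cohort, folds[[1]]$train))
  res <- list(ckpt = ckpt, cohort = cohort, val = cohort[folds[[1]]$val])
  .fixture_cache[[key]] <- res
  res
}
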