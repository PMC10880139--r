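# Training orchestration: splitting, reproducibility, optimization progress,
# evaluation semantics.

test_that("k-fold split is subject-grouped, size-balanced and exhaustive", {
  cohort <- make_small_cohort(n = 100, seed = 1)
  folds <- split_cohort(cohort, 5, seed = 2)
  val_sizes <- vapply(folds, function(f) length(f$val), integer(1))
  expect_equal(val_sizes, rep(20L, 5))
  all_val <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_equal(all_val, 1:100)
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    expect_setequal(c(f$train, f$val), 1:100)
  }
  expect_error(split_cohort(cohort, 101, seed = 1), "exceeds")
  expect_error(split_cohort(cohort, 1, seed = 1), ">= 2")
})

test_that("augmented entries of one subject always land in the same fold", {
  cohort <- make_small_cohort(n = 10, seed = 3)
  tripled <- c(cohort, cohort[c(4, 4)])  # subject 4 appears three times
  ids <- vapply(tripled, function(r) r$subject_id, numeric(1))
  folds <- split_cohort(tripled, 3, seed = 5)
  where <- which(ids == 4)
  for (f in folds) {
    in_val <- where %in% f$val
    expect_true(all(in_val) || !any(in_val))
  }
})

test_that("same config and seed give identical splits and initial parameters", {
  cohort <- make_small_cohort(n = 12, seed = 4)
  expect_identical(split_cohort(cohort, 3, seed = 7),
                   split_cohort(cohort, 3, seed = 7))
  mcfg <- make_small_config()
  m1 <- dtf_model(mcfg, cohort, seed = 9)
  m2 <- dtf_model(mcfg, cohort, seed = 9)
  expect_identical(trajcast:::param_values(m1$params),
                   trajcast:::param_values(m2$params))
})

test_that("one smoke epoch trains to finite loss and logs tau with max 1", {
  cohort <- make_small_cohort(n = 32, seed = 5)
  rc <- run_config(make_small_config(), epochs = 1, batch_size = 8, seed = 1)
  ckpt <- train_dtf(rc, cohort)
  expect_true(all(is.finite(ckpt$log$total)))
  expect_equal(nrow(ckpt$log), 1L)
  expect_equal(max(ckpt$tau_trajectory[1, ]), 1)
})

test_that("training reduces the loss and overfits a small strong-signal cohort", {
  cohort <- generate_cohort(trajectory_config(
    48, 2, c(2, 2, 2), image_size = c(32, 32), noise_sd = 0,
    covariate_effect = 0.15, seed = 6))
  mcfg <- dtf_config(2, c(2, 2, 2), image_size = c(32, 32), cx = 16, cm = 16,
                     depths = c(2, 2, 2), heads = 4,
                     backbone = list(width = 8, n_stages = 2))
  rc <- run_config(mcfg, epochs = 25, batch_size = 16, lr = 1e-3, seed = 2)
  ckpt <- train_dtf(rc, cohort)
  expect_lt(ckpt$log$total[25], ckpt$log$total[1])
  # tau constraint holds at every logged epoch
  expect_equal(apply(ckpt$tau_trajectory, 1, max), rep(1, 25))
  expect_true(all(ckpt$tau_trajectory > 0 & ckpt$tau_trajectory <= 1))
  # heavily overfit model nails the baseline diagnosis on its training set
  rep <- evaluate_dtf(ckpt, cohort)
  expect_gte(rep$per_horizon$ba[1], 0.9)
})

test_that("evaluation reports T+1 horizons and ignores masked targets", {
  cohort <- make_small_cohort(n = 16, seed = 7)
  rc <- run_config(make_small_config(), epochs = 1, batch_size = 8, seed = 3)
  ckpt <- train_dtf(rc, cohort)
  rep1 <- evaluate_dtf(ckpt, cohort)
  expect_equal(nrow(rep1$per_horizon), 3L)
  # perturb every masked label: metrics must not move
  tampered <- lapply(cohort, function(r) {
    hidden <- which(!r$target_mask)
    r$targets[hidden] <- 0L
    r
  })
  rep2 <- evaluate_dtf(ckpt, tampered)
  expect_equal(rep1$per_horizon, rep2$per_horizon)
})

test_that("horizons with no observed targets are reported as NA", {
  cohort <- make_small_cohort(n = 6, seed = 8, missing_target_rate = 0)
  model <- dtf_model(make_small_config(), cohort, seed = 1)
  blind <- lapply(cohort, function(r) {
    r$target_mask[3] <- FALSE
    r$targets[3] <- NA_integer_
    r
  })
  rep <- evaluate_dtf(model, blind)
  expect_true(is.na(rep$per_horizon$ba[3]))
  expect_false(is.na(rep$per_horizon$ba[1]))
})

test_that("the end-stage baseline filter drops top-grade subjects", {
  cohort <- make_small_cohort(n = 20, seed = 9, missing_target_rate = 0)
  model <- dtf_model(make_small_config(), cohort, seed = 2)
  top <- vapply(cohort, function(r) r$targets[1] == 2, logical(1))
  if (!any(top)) skip("no top-grade baseline drawn")
  rep_all <- evaluate_dtf(model, cohort)
  rep_flt <- evaluate_dtf(model, cohort, exclude_baseline_top = TRUE)
  expect_equal(rep_flt$per_horizon,
               evaluate_dtf(model, cohort[!top])$per_horizon)
  expect_false(isTRUE(all.equal(rep_all$per_horizon, rep_flt$per_horizon)))
})

test_that("ce loss mode keeps tau fixed at one", {
  cohort <- make_small_cohort(n = 16, seed = 10)
  rc <- run_config(make_small_config(), epochs = 2, batch_size = 8,
                   loss = "ce", seed = 4)
  ckpt <- train_dtf(rc, cohort)
  expect_equal(unname(ckpt$tau_trajectory), matrix(1, 2, 3))
  expect_equal(as.vector(ckpt$model$params$sigma$value), rep(1, 3))
})
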