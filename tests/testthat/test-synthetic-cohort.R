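# Synthetic cohort generator: determinism, trajectory structure, image
# encoding of severity, missingness statistics.

test_that("config validation rejects invalid fields", {
  expect_error(trajectory_config(10, 2, rep(1, 3)), "class counts")
  expect_error(trajectory_config(10, 2, rep(3, 2)), "length")
  expect_error(trajectory_config(10, missing_target_rate = 1.5), "probability")
  expect_error(trajectory_config(10, image_size = c(4, 4)), ">= 8")
  expect_error(trajectory_config(10, noise_sd = -1), "nonnegative")
  expect_error(trajectory_config(10, progression_rate_range = c(0.5, 0.1)),
               "interval")
})

test_that("same config and seed give a bit-identical cohort", {
  cfg <- trajectory_config(12, 2, rep(3, 3), image_size = c(32, 32), seed = 7)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("cohorts have the right size, label ranges and mask consistency", {
  cfg <- trajectory_config(30, 3, c(5, 5, 4, 4), image_size = c(32, 32),
                           seed = 3)
  ch <- generate_cohort(cfg)
  expect_length(ch, 30)
  for (rec in ch) {
    expect_length(rec$targets, 4)
    expect_identical(is.na(rec$targets), !rec$target_mask)
    obs <- which(rec$target_mask)
    expect_true(all(rec$targets[obs] >= 0 &
                      rec$targets[obs] <= cfg$n_classes[obs] - 1))
    expect_true(all(rec$image >= 0 & rec$image <= 1))
    expect_true(rec$target_mask[1])  # baseline always observed
  }
})

test_that("progressive trajectories never decrease", {
  cfg <- trajectory_config(50, 4, rep(5, 5), image_size = c(32, 32),
                           progression_rate_range = c(0.3, 0.8),
                           missing_target_rate = 0, seed = 9)
  ch <- generate_cohort(cfg)
  for (rec in ch) expect_true(all(diff(rec$targets) >= 0))
})

test_that("baseline class frequencies match a uniform prior within 3 binomial SD", {
  cfg <- trajectory_config(2000, 0, 5L, image_size = c(32, 32), seed = 21)
  ch <- generate_cohort(cfg)
  base <- vapply(ch, function(r) r$targets[1], numeric(1))
  p <- 1 / 5
  tol <- 3 * sqrt(p * (1 - p) / 2000)
  for (k in 0:4) expect_lt(abs(mean(base == k) - p), tol)
})

test_that("zero rate and absorbing top class give constant trajectories", {
  set.seed(1)
  expect_identical(sample_trajectory(2, 0, 4, rep(5, 5)), rep(2L, 5))
  expect_identical(sample_trajectory(4, 0.9, 4, rep(5, 5)), rep(4L, 5))
  expect_error(sample_trajectory(5, 0.5, 2, rep(5, 3)), "out of range")
})

test_that("mean advances match the binomial expectation before clipping", {
  # start at 0 with ample headroom so no draw is clipped
  set.seed(31)
  t_ <- 4; rate <- 0.5; n <- 10000
  adv <- replicate(n, {
    tr <- sample_trajectory(0, rate, t_, rep(9, t_ + 1))
    tr[t_ + 1]
  })
  expected <- t_ * rate
  se <- sqrt(t_ * rate * (1 - rate) / n)
  expect_lt(abs(mean(adv) - expected), 4 * se)
})

test_that("rendered images are deterministic and gap shrinks strictly with severity", {
  expect_identical(render_image(1, 5, 17, 0.05, c(64, 64)),
                   render_image(1, 5, 17, 0.05, c(64, 64)))
  gaps <- vapply(0:4, function(s) {
    measure_band_gap(render_image(s, 5, 3, 0, c(64, 64)))
  }, integer(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("severity and measured gap are perfectly anti-correlated across morphologies", {
  set.seed(4)
  res <- replicate(100, {
    ms <- sample.int(1e6, 1)
    s <- sample(0:4, 1)
    c(s, measure_band_gap(render_image(s, 5, ms, 0, c(64, 64))))
  })
  expect_equal(cor(res[1, ], res[2, ], method = "spearman"), -1)
})

test_that("3D volumes encode severity the same way", {
  vol <- render_image(2, 5, 11, 0, c(16, 32, 32))
  expect_identical(dim(vol), c(16L, 32L, 32L))
  gaps <- vapply(0:4, function(s) {
    measure_band_gap(render_image(s, 5, 11, 0, c(16, 32, 32)))
  }, integer(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("missingness respects rates and the baseline exemption", {
  cfg <- trajectory_config(10, 2, rep(3, 3), image_size = c(32, 32),
                           missing_target_rate = 0, missing_covariate_rate = 0,
                           seed = 2)
  ch <- generate_cohort(cfg)

  set.seed(11)
  none <- apply_missingness(ch, 0, 0)
  expect_true(all(vapply(none, function(r) all(r$target_mask), logical(1))))

  set.seed(11)
  all_ <- apply_missingness(ch, 1, 0)
  for (rec in all_) {
    expect_identical(rec$target_mask, c(TRUE, FALSE, FALSE))
    expect_false(is.na(rec$targets[1]))
  }
})

test_that("empirical masked fraction matches the configured rate within 3 SD", {
  cfg <- trajectory_config(1000, 5, rep(3, 6), image_size = c(32, 32),
                           missing_target_rate = 0.3, seed = 13)
  ch <- generate_cohort(cfg)
  masked <- unlist(lapply(ch, function(r) !r$target_mask[-1]))
  tol <- 3 * sqrt(0.3 * 0.7 / length(masked))
  expect_lt(abs(mean(masked) - 0.3), tol)
})
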