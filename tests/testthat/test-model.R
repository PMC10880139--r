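# Model assembly: block shape contracts, pooling/context oracles,
# fusion layouts, attention extraction.

test_that("config validation enforces K and depth constraints", {
  expect_error(dtf_config(2, rep(3, 3), k_cls = 2), "k_cls")
  expect_error(dtf_config(2, rep(3, 2)), "length")
  expect_error(dtf_config(2, rep(3, 3), depths = c(0, 1, 1)), "depths")
})

test_that("radiologist block satisfies shape contracts and the pooling oracle", {
  cohort <- make_small_cohort(n = 3, seed = 1)
  model <- dtf_model(make_small_config(), cohort, seed = 2)
  img <- ad_no_grad(encode_image(model$params$img_enc, cohort[[1]]$image))
  n <- nrow(ad_value(img$tokens))
  r <- ad_no_grad(radiologist_forward(model, img$tokens))
  expect_identical(nrow(ad_value(r$state$out)), n + 1L)
  expect_length(as.vector(ad_value(r$f0r)), 3L)
  # pooled representation equals the element-wise mean, recomputed directly
  pooled <- matrix(colMeans(ad_value(r$state$out)), 1)
  expected <- ad_no_grad(trajcast:::head_forward(model$params$head_r, pooled))
  expect_equal(ad_value(r$f0r), expected, tolerance = 1e-12)
})

test_that("context block returns the first output vector of width CM", {
  cohort <- make_small_cohort(n = 3, seed = 2)
  model <- dtf_model(make_small_config(), cohort, seed = 3)
  ctoks <- ad_no_grad(trajcast:::encode_covariates(model, cohort[[1]]))
  cb <- ad_no_grad(context_forward(model, ctoks))
  expect_identical(dim(ad_value(cb$h0)), c(1L, 16L))
  expect_equal(ad_value(cb$h0), ad_value(cb$state$out)[1, , drop = FALSE])
  # deterministic in eval mode
  cb2 <- ad_no_grad(context_forward(model, ctoks))
  expect_identical(ad_value(cb$h0), ad_value(cb2$h0))
})

test_that("zeroed residual branches reduce the context token to its embeddings", {
  cohort <- make_small_cohort(n = 2, seed = 3)
  model <- dtf_model(make_small_config(), cohort, seed = 4)
  cb_params <- model$params$c_block
  for (l in seq_along(cb_params$layers)) {
    cb_params$layers[[l]]$o$w$value[] <- 0
    cb_params$layers[[l]]$o$b$value[] <- 0
    cb_params$layers[[l]]$mlp2$w$value[] <- 0
    cb_params$layers[[l]]$mlp2$b$value[] <- 0
  }
  ctoks <- ad_no_grad(trajcast:::encode_covariates(model, cohort[[1]]))
  cb <- ad_no_grad(context_forward(model, ctoks))
  expect_equal(as.vector(ad_value(cb$h0)),
               cb_params$cls$value[1, ] + cb_params$pos$value[1, ],
               tolerance = 1e-12)
})

test_that("practitioner block sees K+N+1 vectors and returns T+1 logit sets", {
  cohort <- make_small_cohort(n = 3, seed = 4)
  mcfg <- make_small_config(k_cls = 3)
  model <- dtf_model(mcfg, cohort, seed = 5)
  out <- ad_no_grad(dtf_forward(model, cohort[[1]]))
  n <- model$params$img_enc$n_tokens
  expect_identical(nrow(ad_value(out$states$p$out)), mcfg$k_cls + n + 1L)
  expect_length(out$f, 3L)
  for (t in 1:3) expect_length(as.vector(ad_value(out$f[[t]])), 3L)
})

test_that("with position-wise P block, perturbing CLS t' changes only horizon t'", {
  cohort <- make_small_cohort(n = 2, seed = 5)
  mcfg <- make_small_config(k_cls = 3, head_mode = "common")
  model <- dtf_model(mcfg, cohort, seed = 6)
  # zero the MSA output projections of P: no cross-position mixing remains
  for (l in seq_along(model$params$p_block$layers)) {
    model$params$p_block$layers[[l]]$o$w$value[] <- 0
    model$params$p_block$layers[[l]]$o$b$value[] <- 0
  }
  base <- ad_no_grad(dtf_forward(model, cohort[[1]]))
  # perturb one component (a uniform shift would sit in layer norm's null space)
  model$params$p_block$cls$value[2, 1] <-
    model$params$p_block$cls$value[2, 1] + 0.5
  pert <- ad_no_grad(dtf_forward(model, cohort[[1]]))
  expect_equal(ad_value(pert$f[[1]]), ad_value(base$f[[1]]), tolerance = 1e-12)
  expect_gt(max(abs(ad_value(pert$f[[2]]) - ad_value(base$f[[2]]))), 1e-4)
  expect_equal(ad_value(pert$f[[3]]), ad_value(base$f[[3]]), tolerance = 1e-12)
})

test_that("forward output matches the documented contract on a 64x64, T=4 record", {
  cohort <- generate_cohort(trajectory_config(
    2, 4, rep(5, 5), image_size = c(64, 64), seed = 6))
  mcfg <- dtf_config(4, rep(5, 5), image_size = c(64, 64), cx = 16, cm = 16,
                     depths = c(1, 1, 1), heads = 2,
                     backbone = list(width = 4))
  model <- dtf_model(mcfg, cohort, seed = 7)
  out <- ad_no_grad(dtf_forward(model, cohort[[1]]))
  expect_length(as.vector(ad_value(out$f0r)), 5L)
  expect_length(out$f, 5L)
  expect_identical(out$grid, c(2L, 2L))
  rec_no_img <- cohort[[1]]
  rec_no_img$image <- NULL
  expect_error(ad_no_grad(dtf_forward(model, rec_no_img)), "image")
})

test_that("missing covariates are tolerated through the full forward pass", {
  cohort <- make_small_cohort(n = 2, seed = 7, missing_covariate_rate = 0)
  model <- dtf_model(make_small_config(), cohort, seed = 8)
  rec <- cohort[[1]]
  for (nm in names(rec$covariates)) rec$covariates[[nm]] <- NA
  out <- ad_no_grad(dtf_forward(model, rec))
  expect_true(all(is.finite(ad_value(out$f0r))))
})

test_that("attention maps are normalized, head-averaged and fold to the grid", {
  cohort <- make_small_cohort(n = 2, seed = 8)
  # two-stage backbone: stride 16 on a 32x32 image -> 2x2 token grid
  mcfg <- dtf_config(2, rep(3, 3), image_size = c(32, 32), cx = 16, cm = 16,
                     depths = c(2, 2, 2), heads = 4, k_cls = 3,
                     backbone = list(width = 8, n_stages = 2))
  model <- dtf_model(mcfg, cohort, seed = 9)
  att <- extract_attention(model, cohort[[1]], t = 1)
  expect_equal(sum(att$clinical), 1)
  expect_true(all(att$clinical >= 0))
  expect_named(att$clinical, c("sex", "site", "age", "bmi"))
  expect_identical(dim(att$imaging), c(2L, 2L))
  expect_equal(sum(att$imaging), 1)
  expect_error(extract_attention(model, cohort[[1]], t = 5), "out of range")

  # head-averaging oracle: recompute clinical weights from the raw state
  out <- ad_no_grad(dtf_forward(model, cohort[[1]]))
  a_c <- out$states$c$attn[[length(out$states$c$attn)]]
  rows <- sapply(1:4, function(m1) mean(a_c[, 1, 1 + m1]))
  expect_equal(unname(att$clinical), rows / sum(rows), tolerance = 1e-12)
})

test_that("sequence-wise fusion and K = 1 produce the documented layouts", {
  cohort <- make_small_cohort(n = 2, seed = 9)
  mseq <- dtf_model(make_small_config(fusion = "sequence", k_cls = 3),
                    cohort, seed = 10)
  out <- ad_no_grad(dtf_forward(mseq, cohort[[1]]))
  n <- mseq$params$img_enc$n_tokens
  expect_identical(nrow(ad_value(out$states$p$out)), 3L + n + 2L)

  mk1 <- dtf_model(make_small_config(k_cls = 1), cohort, seed = 11)
  out1 <- ad_no_grad(dtf_forward(mk1, cohort[[1]]))
  expect_identical(nrow(ad_value(out1$states$p$out)), 1L + n + 1L)
  expect_length(out1$f, 3L)
})

test_that("checkpoints round-trip through save and load", {
  cohort <- make_small_cohort(n = 4, seed = 10)
  mcfg <- make_small_config()
  rc <- run_config(mcfg, epochs = 1, batch_size = 4, seed = 1)
  ckpt <- train_dtf(rc, cohort)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ckpt, path)
  ckpt2 <- load_checkpoint(path)
  p1 <- predict(ckpt$model, cohort[[1]])
  p2 <- predict(ckpt2$model, cohort[[1]])
  expect_equal(p1, p2, tolerance = 1e-12)
})
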