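# Transformer encoder: shape contracts, attention normalization, analytic
# oracles for the attention mechanism, equivariance and residual structure.

make_tokens <- function(n, c_, seed = 1) {
  withr::with_seed(seed, matrix(rnorm(n * c_), n, c_))
}

test_that("config validation enforces divisibility and positivity", {
  expect_error(transformer_config(width = 30, heads = 4), "divisible")
  expect_error(transformer_config(depth = 0), "depth")
  expect_error(transformer_config(mlp_ratio = 0), "mlp_ratio")
})

test_that("output length is n_cls + N, including the CLS-only case", {
  set.seed(1)
  cfg <- transformer_config(depth = 2, heads = 2, width = 8, n_cls = 1)
  p0 <- transformer_init(cfg, n_tokens = 0)
  st0 <- ad_no_grad(transformer_encode(p0, matrix(0, 0, 8)))
  expect_identical(nrow(st0$out), 1L)

  for (n in c(1L, 3L, 7L)) {
    p <- transformer_init(cfg, n_tokens = n)
    st <- ad_no_grad(transformer_encode(p, make_tokens(n, 8)))
    expect_identical(nrow(st$out), n + 1L)
    expect_identical(ncol(st$out), 8L)
  }
  p <- transformer_init(cfg, n_tokens = 3)
  expect_error(ad_no_grad(transformer_encode(p, make_tokens(3, 4))), "width")
  expect_error(ad_no_grad(transformer_encode(p, make_tokens(5, 8))), "expected")
})

test_that("attention rows sum to one at every layer and head", {
  set.seed(2)
  cfg <- transformer_config(depth = 3, heads = 4, width = 16, n_cls = 2)
  p <- transformer_init(cfg, n_tokens = 5)
  st <- ad_no_grad(transformer_encode(p, make_tokens(5, 16)))
  for (l in 1:3) for (h in 1:4) {
    a <- attention_map(st, l, h)
    expect_equal(rowSums(a), rep(1, 7), tolerance = 1e-5)
    expect_true(all(a >= 0))
  }
  expect_error(attention_map(st, 4, 1), "layer")
  expect_error(attention_map(st, 1, 5), "head")
})

test_that("zero Q/K projections give uniform attention (row means of values)", {
  set.seed(3)
  c_ <- 8; n <- 5
  cfg <- transformer_config(depth = 1, heads = 2, width = c_, n_cls = 0)
  p <- transformer_init(cfg, n_tokens = n)
  layer <- p$layers[[1]]
  layer$q$w$value[] <- 0; layer$q$b$value[] <- 0
  layer$k$w$value[] <- 0; layer$k$b$value[] <- 0
  x <- make_tokens(n, c_)
  res <- ad_no_grad(trajcast:::ad_mhsa(
    x, layer$q$w, layer$q$b, layer$k$w, layer$k$b,
    layer$v$w, layer$v$b, layer$o$w, layer$o$b, heads = 2))
  v <- x %*% layer$v$w$value + matrix(layer$v$b$value, n, c_, byrow = TRUE)
  expected <- matrix(colMeans(v), n, c_, byrow = TRUE) %*% layer$o$w$value +
    matrix(layer$o$b$value, n, c_, byrow = TRUE)
  expect_equal(res$out, expected, tolerance = 1e-12)
  expect_equal(res$attn[1, , ], matrix(1 / n, n, n))
})

test_that("single-token attention weight is one and output is the projected value", {
  set.seed(4)
  c_ <- 4
  cfg <- transformer_config(depth = 1, heads = 1, width = c_, n_cls = 0)
  p <- transformer_init(cfg, n_tokens = 1)
  layer <- p$layers[[1]]
  x <- make_tokens(1, c_)
  res <- ad_no_grad(trajcast:::ad_mhsa(
    x, layer$q$w, layer$q$b, layer$k$w, layer$k$b,
    layer$v$w, layer$v$b, layer$o$w, layer$o$b, heads = 1))
  expect_equal(as.vector(res$attn), 1)
  v <- x %*% layer$v$w$value + layer$v$b$value[1, ]
  expect_equal(res$out, v %*% layer$o$w$value +
                 matrix(layer$o$b$value, 1), tolerance = 1e-12)
})

test_that("single-head attention matches an independent dense-matrix oracle", {
  c_ <- 3; n <- 3
  cfg <- transformer_config(depth = 1, heads = 1, width = c_, n_cls = 0)
  set.seed(5)
  p <- transformer_init(cfg, n_tokens = n)
  layer <- p$layers[[1]]
  # small integer weights, zero biases
  layer$q$w$value <- matrix(c(1, 0, 1, 0, 1, 0, 1, 1, 0), 3, 3)
  layer$k$w$value <- matrix(c(0, 1, 1, 1, 0, 0, 0, 1, 1), 3, 3)
  layer$v$w$value <- matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3, 3)
  layer$o$w$value <- diag(3)
  for (nm in c("q", "k", "v", "o")) layer[[nm]]$b$value[] <- 0
  x <- matrix(c(1, 0, 2, 0, 1, 1, 1, 1, 0), 3, 3)
  res <- ad_no_grad(trajcast:::ad_mhsa(
    x, layer$q$w, layer$q$b, layer$k$w, layer$k$b,
    layer$v$w, layer$v$b, layer$o$w, layer$o$b, heads = 1))
  # brute-force evaluation
  q <- x %*% layer$q$w$value; k <- x %*% layer$k$w$value
  v <- x %*% layer$v$w$value
  logits <- q %*% t(k) / sqrt(3)
  a <- t(apply(logits, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(res$out, a %*% v, tolerance = 1e-12)
  expect_equal(res$attn[1, , ], a, tolerance = 1e-12)
})

test_that("a dominant key saturates its attention column", {
  c_ <- 4
  cfg <- transformer_config(depth = 1, heads = 1, width = c_, n_cls = 0)
  set.seed(6)
  p <- transformer_init(cfg, n_tokens = 3)
  layer <- p$layers[[1]]
  layer$q$w$value <- diag(c_); layer$k$w$value <- diag(c_)
  for (nm in c("q", "k")) layer[[nm]]$b$value[] <- 0
  x <- rbind(c(10, 0, 0, 0), c(10, 0, 0, 0), c(10, 0, 0, 0))
  x[2, ] <- c(0.1, 0, 0, 0)  # weak key
  x[3, ] <- c(0.1, 0.1, 0, 0)
  res <- ad_no_grad(trajcast:::ad_mhsa(
    x, layer$q$w, layer$q$b, layer$k$w, layer$k$b,
    layer$v$w, layer$v$b, layer$o$w, layer$o$b, heads = 1))
  expect_gt(res$attn[1, 1, 1], 0.99)  # key 1 has margin >> sqrt(dk)
})

test_that("identical query rows give identical attention rows", {
  set.seed(7)
  cfg <- transformer_config(depth = 1, heads = 2, width = 8, n_cls = 0)
  p <- transformer_init(cfg, n_tokens = 4)
  p$pos$value[] <- 0  # positions would break the row identity
  x <- make_tokens(4, 8)
  x[2, ] <- x[1, ]  # rows 1 and 2 identical -> identical queries
  st <- ad_no_grad(transformer_encode(p, x))
  a <- attention_map(st, 1, 1)
  expect_equal(a[1, ], a[2, ], tolerance = 1e-12)
})

test_that("encoder is permutation-equivariant without positional information", {
  set.seed(8)
  cfg <- transformer_config(depth = 2, heads = 2, width = 8, n_cls = 0)
  p <- transformer_init(cfg, n_tokens = 5)
  p$pos$value[] <- 0
  x <- make_tokens(5, 8)
  perm <- c(3, 1, 5, 2, 4)
  out1 <- ad_no_grad(transformer_encode(p, x))$out
  out2 <- ad_no_grad(transformer_encode(p, x[perm, ]))$out
  expect_equal(out2, out1[perm, ], tolerance = 1e-10)
})

test_that("zeroed MSA and MLP output projections make encode the identity on h0", {
  set.seed(9)
  cfg <- transformer_config(depth = 2, heads = 2, width = 8, n_cls = 1)
  p <- transformer_init(cfg, n_tokens = 3)
  for (l in seq_along(p$layers)) {
    p$layers[[l]]$o$w$value[] <- 0; p$layers[[l]]$o$b$value[] <- 0
    p$layers[[l]]$mlp2$w$value[] <- 0; p$layers[[l]]$mlp2$b$value[] <- 0
  }
  x <- make_tokens(3, 8)
  st <- ad_no_grad(transformer_encode(p, x))
  h0 <- rbind(p$cls$value, x) + p$pos$value
  expect_equal(st$out, h0, tolerance = 1e-12)
})
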