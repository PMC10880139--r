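# Minimal reverse-mode automatic differentiation over numeric matrices.
#
# Design: a global tape records intermediate nodes in forward order; leaves
# (parameters) live off-tape and accumulate gradients across samples, which
# gives mini-batch gradient accumulation for free.  Every op returns either an
# `ad` node (when gradients are enabled and at least one input is tracked) or
# a plain matrix (eval mode / constant folding), so a single forward
# implementation serves both training and inference.

.ad <- new.env(parent = emptyenv())
.ad$tape <- vector("list", 256L)
.ad$n <- 0L
.ad$grad_enabled <- TRUE
.ad$cache <- new.env(parent = emptyenv())

#' @keywords internal
ad_tape_reset <- function() {
  .ad$tape <- vector("list", 256L)
  .ad$n <- 0L
  invisible(NULL)
}

ad_grad_enabled <- function() .ad$grad_enabled

#' Evaluate an expression with gradient recording disabled
#' @param expr expression to evaluate
#' @return the value of `expr`
#' @keywords internal
ad_no_grad <- function(expr) {
  old <- .ad$grad_enabled
  .ad$grad_enabled <- FALSE
  on.exit(.ad$grad_enabled <- old)
  force(expr)
}

# Nodes are environments; values are matrices/arrays.  An environment test
# is much cheaper than dispatching inherits() in the hot path.
is_ad <- function(x) is.environment(x)

#' Extract the numeric value of a node or pass a plain matrix through
#' @keywords internal
ad_value <- function(x) if (is.environment(x)) x$value else x

# Leaf node: a trainable parameter.  Not recorded on the tape; its gradient
# persists until explicitly zeroed, so gradients accumulate across samples.
ad_param <- function(value) {
  node <- new.env(parent = emptyenv())
  node$value <- as.matrix(value)
  node$grad <- NULL
  node$backward <- NULL
  class(node) <- "ad"
  node
}

# Intermediate node: recorded on the tape.
ad_make <- function(value, backward) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$backward <- backward
  class(node) <- "ad"
  n <- .ad$n + 1L
  if (n > length(.ad$tape)) length(.ad$tape) <- 2L * length(.ad$tape)
  .ad$tape[[n]] <- node
  .ad$n <- n
  node
}

# Accumulate a gradient into a node (no-op for plain matrices).
ad_accum <- function(x, g) {
  if (is.environment(x)) {
    x$grad <- if (is.null(x$grad)) g else x$grad + g
  }
  invisible(NULL)
}

# Broadcast-add a length-C vector across the rows of an (n x C) matrix.
row_bcast <- function(m, v) m + matrix(v, nrow(m), ncol(m), byrow = TRUE)

#' Run backpropagation from a scalar loss node
#'
#' Seeds the loss gradient with `seed` and sweeps the tape in reverse
#' creation order (a valid topological order).
#' @keywords internal
ad_backward <- function(loss, seed = 1) {
  stopifnot(is_ad(loss))
  loss$grad <- matrix(seed, nrow(loss$value), ncol(loss$value))
  if (.ad$n > 0L) {
    for (i in .ad$n:1L) {
      nd <- .ad$tape[[i]]
      if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
    }
  }
  invisible(NULL)
}

# Decide whether an op must be recorded.
ad_tracked <- function(...) {
  if (!.ad$grad_enabled) return(FALSE)
  for (x in list(...)) if (is_ad(x)) return(TRUE)
  FALSE
}

## ---- primitive ops ---------------------------------------------------------

# Matrix product with optional transposes.
ad_mm <- function(a, b, ta = FALSE, tb = FALSE) {
  av <- ad_value(a); bv <- ad_value(b)
  val <- if (ta) {
    if (tb) crossprod(av, t(bv)) else crossprod(av, bv)
  } else {
    if (tb) tcrossprod(av, bv) else av %*% bv
  }
  if (!ad_tracked(a, b)) return(val)
  ad_make(val, function(g) {
    if (is_ad(a)) {
      da <- if (ta) {
        if (tb) t(bv) %*% t(g) else bv %*% t(g)
      } else {
        if (tb) g %*% bv else tcrossprod(g, bv)
      }
      ad_accum(a, da)
    }
    if (is_ad(b)) {
      db <- if (tb) {
        if (ta) t(g) %*% t(av) else crossprod(g, av)
      } else {
        if (ta) av %*% g else crossprod(av, g)
      }
      ad_accum(b, db)
    }
  })
}

# Elementwise addition; `b` may be a 1-row matrix broadcast over rows of `a`.
ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  bcast <- nrow(bv) == 1L && nrow(av) > 1L
  val <- if (bcast) row_bcast(av, as.vector(bv)) else av + bv
  if (!ad_tracked(a, b)) return(val)
  ad_make(val, function(g) {
    ad_accum(a, g)
    if (is_ad(b)) ad_accum(b, if (bcast) matrix(colSums(g), 1L) else g)
  })
}

ad_sub <- function(a, b) ad_add(a, ad_scale(b, -1))

# Elementwise product (equal shapes, or one operand 1x1 scalar).
ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  a_scalar <- length(av) == 1L; b_scalar <- length(bv) == 1L
  val <- if (a_scalar) as.vector(av) * bv else if (b_scalar) av * as.vector(bv) else av * bv
  if (!ad_tracked(a, b)) return(val)
  ad_make(val, function(g) {
    if (is_ad(a)) {
      da <- if (a_scalar) matrix(sum(g * bv), 1L, 1L) else if (b_scalar) g * as.vector(bv) else g * bv
      ad_accum(a, da)
    }
    if (is_ad(b)) {
      db <- if (b_scalar) matrix(sum(g * av), 1L, 1L) else if (a_scalar) g * as.vector(av) else g * av
      ad_accum(b, db)
    }
  })
}

# Multiply by a plain numeric constant.
ad_scale <- function(a, k) {
  av <- ad_value(a)
  val <- av * k
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, g * k))
}

# Add a plain numeric constant.
ad_addc <- function(a, k) {
  av <- ad_value(a)
  val <- av + k
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, g))
}

# Elementwise reciprocal.
ad_recip <- function(a) {
  av <- ad_value(a)
  val <- 1 / av
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, -g * val * val))
}

ad_square <- function(a) ad_mul(a, a)

# Exact GELU: x * Phi(x).
ad_gelu <- function(a) {
  av <- ad_value(a)
  p <- stats::pnorm(av)
  val <- av * p
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, g * (p + av * stats::dnorm(av))))
}

ad_relu <- function(a) {
  av <- ad_value(a)
  val <- av * (av > 0)
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, g * (av > 0)))
}

# Row-wise layer normalization with learnable gain/bias (1 x C each).
ad_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  av <- ad_value(a); gv <- as.vector(ad_value(gamma)); bv <- as.vector(ad_value(beta))
  mu <- rowMeans(av)
  xc <- av - mu
  sd_ <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd_
  gmat <- matrix(gv, nrow(av), ncol(av), byrow = TRUE)
  val <- row_bcast(xhat * gmat, bv)
  if (!ad_tracked(a, gamma, beta)) return(val)
  ad_make(val, function(g) {
    if (is_ad(gamma)) ad_accum(gamma, matrix(colSums(g * xhat), 1L))
    if (is_ad(beta)) ad_accum(beta, matrix(colSums(g), 1L))
    if (is_ad(a)) {
      dxhat <- g * gmat
      dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / sd_
      ad_accum(a, dx)
    }
  })
}

# Numerically-stable row-wise softmax.
ad_softmax_rows <- function(a) {
  av <- ad_value(a)
  m <- av[cbind(seq_len(nrow(av)), max.col(av, ties.method = "first"))]
  e <- exp(av - m)
  val <- e / rowSums(e)
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) {
    ad_accum(a, (g - rowSums(g * val)) * val)
  })
}

ad_rbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  val <- do.call(rbind, vals)
  if (!.ad$grad_enabled || !any(vapply(xs, is_ad, logical(1L)))) return(val)
  nr <- vapply(vals, nrow, integer(1L))
  ends <- cumsum(nr)
  starts <- ends - nr + 1L
  ad_make(val, function(g) {
    for (i in seq_along(xs)) {
      if (is_ad(xs[[i]])) ad_accum(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

ad_cbind <- function(xs) {
  vals <- lapply(xs, ad_value)
  val <- do.call(cbind, vals)
  if (!.ad$grad_enabled || !any(vapply(xs, is_ad, logical(1L)))) return(val)
  nc <- vapply(vals, ncol, integer(1L))
  ends <- cumsum(nc)
  starts <- ends - nc + 1L
  ad_make(val, function(g) {
    for (i in seq_along(xs)) {
      if (is_ad(xs[[i]])) ad_accum(xs[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_rows <- function(a, idx) {
  av <- ad_value(a)
  val <- av[idx, , drop = FALSE]
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) {
    da <- matrix(0, nrow(av), ncol(av))
    # idx may repeat (row replication): rowsum() accumulates per source row
    rs <- rowsum(g, idx)
    da[as.integer(rownames(rs)), ] <- rs
    ad_accum(a, da)
  })
}

# Per-sample mean over contiguous row groups: input (B*S x C) in sample-major
# order -> (B x C) of group means.
ad_rowgroup_mean <- function(a, b_, s_) {
  av <- ad_value(a)
  grp <- rep(seq_len(b_), each = s_)
  val <- rowsum(av, grp) / s_
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, g[grp, , drop = FALSE] / s_))
}

# Weighted sum of per-row cross-entropies: logits (B x Nc), 0-based labels,
# nonnegative weights.  Returns a 1x1 node.
ad_ce_batch <- function(logits, labels0, weights) {
  lv <- ad_value(logits)
  b_ <- nrow(lv)
  jj <- cbind(seq_len(b_), labels0 + 1L)
  m <- lv[cbind(seq_len(b_), max.col(lv, ties.method = "first"))]
  lse <- m + log(rowSums(exp(lv - m)))
  ces <- lse - lv[jj]
  val <- matrix(sum(weights * ces), 1L, 1L)
  if (!ad_tracked(logits)) return(val)
  ad_make(val, function(g) {
    p <- exp(lv - lse)
    p[jj] <- p[jj] - 1
    ad_accum(logits, as.vector(g) * weights * p)
  })
}

ad_cols <- function(a, idx) {
  av <- ad_value(a)
  val <- av[, idx, drop = FALSE]
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) {
    da <- matrix(0, nrow(av), ncol(av))
    for (k in seq_along(idx)) da[, idx[k]] <- da[, idx[k]] + g[, k]
    ad_accum(a, da)
  })
}

# Replicate a 1-row matrix n times.
ad_rep_rows <- function(a, n) {
  av <- ad_value(a)
  val <- matrix(as.vector(av), n, ncol(av), byrow = TRUE)
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, matrix(colSums(g), 1L)))
}

# Column-wise mean over rows -> 1 x C.
ad_mean_rows <- function(a) {
  av <- ad_value(a)
  n <- nrow(av)
  val <- matrix(colMeans(av), 1L)
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, matrix(as.vector(g), n, ncol(av), byrow = TRUE) / n))
}

# Divide a 1-row vector by its maximum element (subgradient at the argmax).
ad_div_max <- function(a) {
  av <- ad_value(a)
  j <- which.max(av)
  m <- av[j]
  val <- av / m
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) {
    da <- g / m
    da[j] <- da[j] - sum(g * av) / (m * m)
    ad_accum(a, da)
  })
}

# Cross-entropy of a single-row logit vector against a 0-based class label,
# computed log-sum-exp stably.  Returns a 1x1 node.
ad_ce <- function(logits, label0) {
  lv <- as.vector(ad_value(logits))
  j <- label0 + 1L
  m <- max(lv)
  lse <- m + log(sum(exp(lv - m)))
  val <- matrix(lse - lv[j], 1L, 1L)
  if (!ad_tracked(logits)) return(val)
  ad_make(val, function(g) {
    p <- exp(lv - lse)
    p[j] <- p[j] - 1
    ad_accum(logits, matrix(as.vector(g) * p, 1L))
  })
}

# L1 distance: sum(abs(a - b)) -> 1x1.  Subgradient 0 at ties.
ad_l1 <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  d <- av - bv
  val <- matrix(sum(abs(d)), 1L, 1L)
  if (!ad_tracked(a, b)) return(val)
  ad_make(val, function(g) {
    s <- as.vector(g) * sign(d)
    ad_accum(a, s)
    if (is_ad(b)) ad_accum(b, -s)
  })
}

# Fused affine map: x %*% w + b (b broadcast over rows).
ad_linear <- function(x, w, b) {
  xv <- ad_value(x); wv <- ad_value(w)
  val <- row_bcast(xv %*% wv, as.vector(ad_value(b)))
  if (!ad_tracked(x, w, b)) return(val)
  ad_make(val, function(g) {
    if (is.environment(x)) ad_accum(x, tcrossprod(g, wv))
    if (is.environment(w)) ad_accum(w, crossprod(xv, g))
    if (is.environment(b)) ad_accum(b, matrix(colSums(g), 1L))
  })
}

# Fused multi-head self-attention over an (S x C) sequence: per head
# Softmax(Q K' / sqrt(dk)) V, heads concatenated and projected by wo.
# Returns list(out, attn) with attn an H x S x S array of row-stochastic
# per-head attention maps.  One tape node with a hand-derived backward.
ad_mhsa <- function(x, wq, bq, wk, bk, wv, bv, wo, bo, heads) {
  xv <- ad_value(x)
  s <- nrow(xv); c_ <- ncol(xv)
  dk <- c_ %/% heads
  wqv <- ad_value(wq); wkv <- ad_value(wk); wvv <- ad_value(wv); wov <- ad_value(wo)
  q <- row_bcast(xv %*% wqv, as.vector(ad_value(bq)))
  k <- row_bcast(xv %*% wkv, as.vector(ad_value(bk)))
  vv <- row_bcast(xv %*% wvv, as.vector(ad_value(bv)))
  attn <- array(0, dim = c(heads, s, s))
  o <- matrix(0, s, c_)
  inv_sqrt_dk <- 1 / sqrt(dk)
  for (h in seq_len(heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    logits <- tcrossprod(q[, cols, drop = FALSE], k[, cols, drop = FALSE]) * inv_sqrt_dk
    e <- exp(logits - logits[cbind(seq_len(s), max.col(logits, ties.method = "first"))])
    a <- e / rowSums(e)
    attn[h, , ] <- a
    o[, cols] <- a %*% vv[, cols, drop = FALSE]
  }
  val <- row_bcast(o %*% wov, as.vector(ad_value(bo)))
  if (!ad_tracked(x, wq, wo)) return(list(out = val, attn = attn))
  node <- ad_make(val, function(g) {
    if (is.environment(wo)) ad_accum(wo, crossprod(o, g))
    if (is.environment(bo)) ad_accum(bo, matrix(colSums(g), 1L))
    do <- tcrossprod(g, wov)
    dq <- matrix(0, s, c_); dkm <- matrix(0, s, c_); dvm <- matrix(0, s, c_)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      a <- matrix(attn[h, , ], s, s)
      doh <- do[, cols, drop = FALSE]
      da <- tcrossprod(doh, vv[, cols, drop = FALSE])
      dvm[, cols] <- crossprod(a, doh)
      dlogits <- (da - rowSums(da * a)) * a * inv_sqrt_dk
      dq[, cols] <- dlogits %*% k[, cols, drop = FALSE]
      dkm[, cols] <- crossprod(dlogits, q[, cols, drop = FALSE])
    }
    if (is.environment(wq)) ad_accum(wq, crossprod(xv, dq))
    if (is.environment(bq)) ad_accum(bq, matrix(colSums(dq), 1L))
    if (is.environment(wk)) ad_accum(wk, crossprod(xv, dkm))
    if (is.environment(bk)) ad_accum(bk, matrix(colSums(dkm), 1L))
    if (is.environment(wv)) ad_accum(wv, crossprod(xv, dvm))
    if (is.environment(bv)) ad_accum(bv, matrix(colSums(dvm), 1L))
    if (is.environment(x)) {
      ad_accum(x, tcrossprod(dq, wqv) + tcrossprod(dkm, wkv) + tcrossprod(dvm, wvv))
    }
  })
  list(out = node, attn = attn)
}

# Block-diagonal multi-head self-attention over b_ stacked sequences of
# length s_ (input (b_*s_ x C), sample-major).  Attention never crosses
# sample boundaries.  Returns list(out, attn) where attn is a b_ x H x s_ x s_
# array when collect_attn, else NULL.
ad_mhsa_blocks <- function(x, wq, bq, wk, bk, wv, bv, wo, bo, heads,
                           b_, s_, collect_attn = FALSE) {
  xv <- ad_value(x)
  c_ <- ncol(xv)
  dk <- c_ %/% heads
  wqv <- ad_value(wq); wkv <- ad_value(wk); wvv <- ad_value(wv); wov <- ad_value(wo)
  q <- row_bcast(xv %*% wqv, as.vector(ad_value(bq)))
  k <- row_bcast(xv %*% wkv, as.vector(ad_value(bk)))
  vv <- row_bcast(xv %*% wvv, as.vector(ad_value(bv)))
  o <- matrix(0, b_ * s_, c_)
  inv_sqrt_dk <- 1 / sqrt(dk)
  a_store <- vector("list", b_ * heads)
  attn <- if (collect_attn) array(0, dim = c(b_, heads, s_, s_)) else NULL
  sidx <- seq_len(s_)
  for (b in seq_len(b_)) {
    rows <- (b - 1L) * s_ + sidx
    qb <- q[rows, , drop = FALSE]; kb <- k[rows, , drop = FALSE]
    vb <- vv[rows, , drop = FALSE]
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dk + 1L):(h * dk)
      logits <- tcrossprod(qb[, cols, drop = FALSE], kb[, cols, drop = FALSE]) * inv_sqrt_dk
      e <- exp(logits - logits[cbind(sidx, max.col(logits, ties.method = "first"))])
      a <- e / rowSums(e)
      a_store[[(b - 1L) * heads + h]] <- a
      if (collect_attn) attn[b, h, , ] <- a
      o[rows, cols] <- a %*% vb[, cols, drop = FALSE]
    }
  }
  val <- row_bcast(o %*% wov, as.vector(ad_value(bo)))
  if (!ad_tracked(x, wq, wo)) return(list(out = val, attn = attn))
  node <- ad_make(val, function(g) {
    if (is.environment(wo)) ad_accum(wo, crossprod(o, g))
    if (is.environment(bo)) ad_accum(bo, matrix(colSums(g), 1L))
    do <- tcrossprod(g, wov)
    dq <- matrix(0, b_ * s_, c_); dkm <- matrix(0, b_ * s_, c_)
    dvm <- matrix(0, b_ * s_, c_)
    for (b in seq_len(b_)) {
      rows <- (b - 1L) * s_ + sidx
      qb <- q[rows, , drop = FALSE]; kb <- k[rows, , drop = FALSE]
      vb <- vv[rows, , drop = FALSE]
      dob <- do[rows, , drop = FALSE]
      for (h in seq_len(heads)) {
        cols <- ((h - 1L) * dk + 1L):(h * dk)
        a <- a_store[[(b - 1L) * heads + h]]
        doh <- dob[, cols, drop = FALSE]
        da <- tcrossprod(doh, vb[, cols, drop = FALSE])
        dvm[rows, cols] <- crossprod(a, doh)
        dlogits <- (da - rowSums(da * a)) * a * inv_sqrt_dk
        dq[rows, cols] <- dlogits %*% kb[, cols, drop = FALSE]
        dkm[rows, cols] <- crossprod(dlogits, qb[, cols, drop = FALSE])
      }
    }
    if (is.environment(wq)) ad_accum(wq, crossprod(xv, dq))
    if (is.environment(bq)) ad_accum(bq, matrix(colSums(dq), 1L))
    if (is.environment(wk)) ad_accum(wk, crossprod(xv, dkm))
    if (is.environment(bk)) ad_accum(bk, matrix(colSums(dkm), 1L))
    if (is.environment(wv)) ad_accum(wv, crossprod(xv, dvm))
    if (is.environment(bv)) ad_accum(bv, matrix(colSums(dvm), 1L))
    if (is.environment(x)) {
      ad_accum(x, tcrossprod(dq, wqv) + tcrossprod(dkm, wkv) + tcrossprod(dvm, wvv))
    }
  })
  list(out = node, attn = attn)
}

# Inverted dropout (train-time only).
ad_dropout <- function(a, p) {
  if (p <= 0) return(a)
  av <- ad_value(a)
  keep <- (matrix(stats::runif(length(av)), nrow(av)) >= p) / (1 - p)
  val <- av * keep
  if (!ad_tracked(a)) return(val)
  ad_make(val, function(g) ad_accum(a, g * keep))
}
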