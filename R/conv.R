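# n-dimensional (2D / 3D) convolution via im2col, differentiable through the
# autodiff tape.  Feature maps are represented as (n_cells x channels)
# matrices in row-major grid order (last spatial dimension fastest), which is
# also the token order used when a feature grid is unrolled into a sequence.

# Index plan for a conv: for each output cell (row-major) and each kernel
# offset (row-major), the linear index of the source cell in the zero-padded
# input grid.  Cached per (grid, k, stride, pad) since shapes repeat heavily.
conv_plan <- function(grid_in, k, stride, pad) {
  key <- paste(c(grid_in, k, stride, pad), collapse = "_")
  cached <- .ad$cache[[key]]
  if (!is.null(cached)) return(cached)

  d <- length(grid_in)
  padded <- grid_in + 2L * pad
  grid_out <- (padded - k) %/% stride + 1L  # floor semantics
  if (any(padded < k) || any(grid_out < 1L)) {
    stop("input grid ", paste(grid_in, collapse = "x"),
         " too small for kernel ", k, ", stride ", stride, ", pad ", pad)
  }

  # 0-based coordinates, row-major (last dim fastest)
  coords_rowmajor <- function(dims) {
    g <- expand.grid(rev(lapply(dims, function(n) 0:(n - 1L))))
    as.matrix(g[, rev(seq_len(d)), drop = FALSE])
  }
  oc <- coords_rowmajor(grid_out)          # n_out x d
  kc <- coords_rowmajor(rep(k, d))         # k^d  x d
  strides_lin <- rev(cumprod(rev(c(padded[-1L], 1L))))  # row-major linear strides

  n_out <- nrow(oc)
  kd <- nrow(kc)
  idx <- matrix(0L, n_out, kd)
  origin <- oc * stride
  for (q in seq_len(kd)) {
    pos <- sweep(origin, 2L, kc[q, ], "+")
    idx[, q] <- as.integer(pos %*% strides_lin) + 1L
  }

  # interior map: linear index in padded grid of each unpadded cell
  ic <- coords_rowmajor(grid_in)
  interior <- as.integer(sweep(ic, 2L, pad, "+") %*% strides_lin) + 1L

  plan <- list(idx = idx, interior = interior, grid_out = grid_out,
               n_pad = prod(padded), kd = kd)
  .ad$cache[[key]] <- plan
  plan
}

# Batched index plan: replicate a single-image plan for n_rep images stacked
# sample-major along rows.
conv_plan_batch <- function(grid_in, k, stride, pad, n_rep) {
  base <- conv_plan(grid_in, k, stride, pad)
  if (n_rep == 1L) return(base)
  key <- paste(c(grid_in, k, stride, pad, "B", n_rep), collapse = "_")
  cached <- .ad$cache[[key]]
  if (!is.null(cached)) return(cached)
  n_out <- nrow(base$idx)
  n_in <- length(base$interior)
  off_pad <- rep((0:(n_rep - 1L)) * base$n_pad, each = n_out)
  idx <- base$idx[rep(seq_len(n_out), n_rep), , drop = FALSE] + off_pad
  interior <- rep(base$interior, n_rep) +
    rep((0:(n_rep - 1L)) * base$n_pad, each = n_in)
  plan <- list(idx = idx, interior = interior, grid_out = base$grid_out,
               n_pad = base$n_pad * n_rep, kd = base$kd)
  .ad$cache[[key]] <- plan
  plan
}

# x: (n_rep * n_cells x c_in) matrix or ad node of n_rep stacked images;
# w: (k^d * c_in) x c_out; b: 1 x c_out.
# Returns list(out = node/matrix (n_rep * n_out x c_out), grid = grid_out).
ad_conv <- function(x, w, b, grid_in, k, stride, pad = 0L, n_rep = 1L) {
  xv <- ad_value(x)
  c_in <- ncol(xv)
  plan <- conv_plan_batch(as.integer(grid_in), as.integer(k), as.integer(stride),
                          as.integer(pad), as.integer(n_rep))
  xpad <- matrix(0, plan$n_pad, c_in)
  xpad[plan$interior, ] <- xv

  kd <- plan$kd
  n_out <- nrow(plan$idx)
  patches <- matrix(0, n_out, kd * c_in)
  for (q in seq_len(kd)) {
    patches[, ((q - 1L) * c_in + 1L):(q * c_in)] <- xpad[plan$idx[, q], , drop = FALSE]
  }

  wv <- ad_value(w); bv <- ad_value(b)
  val <- sweep(patches %*% wv, 2L, as.vector(bv), "+")

  if (!ad_tracked(x, w, b)) return(list(out = val, grid = plan$grid_out))

  node <- ad_make(val, function(g) {
    if (is_ad(w)) ad_accum(w, crossprod(patches, g))
    if (is_ad(b)) ad_accum(b, matrix(colSums(g), 1L))
    if (is_ad(x)) {
      dpatches <- tcrossprod(g, wv)
      dxpad <- matrix(0, plan$n_pad, c_in)
      for (q in seq_len(kd)) {
        cols <- ((q - 1L) * c_in + 1L):(q * c_in)
        rows <- plan$idx[, q]
        dxpad[rows, ] <- dxpad[rows, ] + dpatches[, cols, drop = FALSE]
      }
      ad_accum(x, dxpad[plan$interior, , drop = FALSE])
    }
  })
  list(out = node, grid = plan$grid_out)
}
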