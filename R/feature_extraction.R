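# Feature extraction: raw images/volumes and scalar clinical variables are
# turned into fixed-length token sequences.  Continuous variables are
# quantized into equal-width one-hot bins; every encoded variable passes
# through its own small feed-forward encoder (linear -> GELU -> layer norm)
# of shared architecture; images go through a small residual CNN whose final
# feature-grid cells become tokens, linearly projected to width CX.

#' One-hot quantization of a continuous variable
#'
#' The value is clipped to `[vmin, vmax]` and assigned to one of `bins`
#' equal-width bins by its relative position in the interval; bins are
#' half-open except the last, so `vmax` falls in the final bin.
#'
#' @param value numeric scalar
#' @param vmin,vmax interval bounds (`vmin < vmax`)
#' @param bins number of bins (>= 2)
#' @return a one-hot numeric vector of length `bins`
#' @export
quantize_continuous <- function(value, vmin, vmax, bins = 4L) {
  if (!is.numeric(vmin) || !is.numeric(vmax) || vmin >= vmax) {
    stop("vmin must be strictly less than vmax")
  }
  if (bins < 2L) stop("bins must be >= 2")
  x <- min(max(value, vmin), vmax)
  rel <- (x - vmin) / (vmax - vmin)
  idx <- min(floor(rel * bins), bins - 1)
  out <- numeric(bins)
  out[idx + 1L] <- 1
  out
}

#' Create a scalar-variable encoder
#'
#' One encoder per clinical variable, all sharing the same architecture:
#' affine map to width `c_out`, GELU, layer normalization.
#' @param in_dim length of the encoded (one-hot) input vector
#' @param c_out output feature length CM
#' @return an encoder parameter list
#' @export
scalar_encoder <- function(in_dim, c_out) {
  list(lin = param_linear(in_dim, c_out), ln = param_layernorm(c_out),
       in_dim = in_dim, c_out = c_out)
}

#' Apply a scalar encoder to an encoded variable
#' @param enc encoder from [scalar_encoder()]
#' @param x numeric vector of length `enc$in_dim`, or an (n x `in_dim`)
#'   matrix of stacked encoded values
#' @return an (n x `c_out`) token matrix (ad node during training)
#' @export
encode_scalar <- function(enc, x) {
  xv <- ad_value(x)
  width <- if (is.matrix(xv)) ncol(xv) else length(xv)
  if (width != enc$in_dim) {
    stop("input length ", width,
         " does not match encoder input size ", enc$in_dim)
  }
  if (!is.matrix(xv) && !is_ad(x)) x <- matrix(xv, 1L)
  h <- ad_linear(x, enc$lin$w, enc$lin$b)
  ad_layernorm(ad_gelu(h), enc$ln$g, enc$ln$b)
}

# Encoded width of one covariate: categorical -> levels + missing slot;
# continuous -> bins + missing slot.  Missingness is a dedicated one-hot
# position rather than an imputed value.
covariate_width <- function(var, bins) {
  if (var$type == "categorical") length(var$levels) + 1L else bins + 1L
}

# One-hot encode one covariate value (NA -> the missing slot).
encode_covariate_value <- function(var, value, bins, range_) {
  width <- covariate_width(var, bins)
  out <- numeric(width)
  if (is.null(value) || (length(value) == 1L && is.na(value))) {
    out[width] <- 1
  } else if (var$type == "categorical") {
    j <- match(as.character(value), var$levels)
    if (is.na(j)) stop("unknown level '", value, "' for ", var$name)
    out[j] <- 1
  } else {
    out[seq_len(bins)] <- quantize_continuous(value, range_[1L], range_[2L], bins)
  }
  out
}

# Per-variable quantization ranges computed on a training split only.
fit_covariate_ranges <- function(records, spec) {
  ranges <- list()
  for (var in spec) {
    if (var$type != "continuous") next
    vals <- unlist(lapply(records, function(r) r$covariates[[var$name]]))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 2L || min(vals) == max(vals)) {
      ranges[[var$name]] <- c(0, 1)
    } else {
      ranges[[var$name]] <- c(min(vals), max(vals))
    }
  }
  ranges
}

#' Create an image encoder (residual CNN backbone + token projection)
#'
#' A stem convolution (stride `stem_stride`) followed by `n_stages` residual
#' stages, each halving the grid (3^d stride-2 conv, 3^d stride-1 conv, 1^d
#' stride-2 skip).  Total stride is `stem_stride * 2^n_stages`; each cell of
#' the final feature grid becomes one token, linearly projected to `cx`.
#'
#' @param image_size `c(H, W)` or `c(D, H, W)`
#' @param cx token feature length CX
#' @param width backbone channel width
#' @param n_stages number of stride-2 residual stages
#' @param stem_stride stem patchify stride (and kernel)
#' @return encoder parameter list with `$grid` (token grid) and `$n_tokens`
#' @export
image_encoder <- function(image_size, cx, width = 16L, n_stages = 3L,
                          stem_stride = if (length(image_size) == 2L) 4L else 2L) {
  d <- length(image_size)
  total_stride <- stem_stride * 2L^n_stages
  if (any(image_size %% total_stride != 0L)) {
    stop("image dims ", paste(image_size, collapse = "x"),
         " are not divisible by total backbone stride ", total_stride)
  }
  grid <- as.integer(image_size / total_stride)
  if (any(grid < 1L)) stop("image too small for backbone stride")

  kd <- 3L^d
  stem <- param_linear(stem_stride^d * 1L, width)
  stages <- lapply(seq_len(n_stages), function(s) {
    list(conv1 = param_linear(kd * width, width),
         conv2 = param_linear(kd * width, width),
         skip = param_linear(width, width))
  })
  proj <- param_linear(width, cx)
  list(stem = stem, stages = stages, proj = proj,
       image_size = as.integer(image_size), d = d, width = width,
       stem_stride = as.integer(stem_stride), grid = grid,
       n_tokens = as.integer(prod(grid)), cx = cx)
}

# Convert an image array to the row-major (n_cells x 1) matrix the conv code
# expects.  R arrays are column-major with the first index fastest; row-major
# order here means the LAST spatial dimension fastest.
image_to_rowmajor <- function(image) {
  dm <- dim(image)
  matrix(as.vector(aperm(image, rev(seq_along(dm)))), ncol = 1L)
}

#' Encode an image into a token sequence
#'
#' @param enc encoder from [image_encoder()]
#' @param image numeric array matching the encoder's `image_size`
#' @param image_rm optional precomputed row-major column matrix of the image
#'   (a per-record cache used by the training loop)
#' @return list with `$tokens` (n_tokens x cx, row-major grid order) and
#'   `$grid` (feature-grid dims, for folding attention maps back)
#' @export
encode_image <- function(enc, image, image_rm = NULL) {
  img <- ad_value(image)
  if (!identical(as.integer(dim(img)), enc$image_size)) {
    stop("image dims ", paste(dim(img), collapse = "x"),
         " do not match encoder size ", paste(enc$image_size, collapse = "x"))
  }
  x <- image_rm %||% image_to_rowmajor(img)
  backbone_forward(enc, x, n_rep = 1L)
}

# Shared CNN trunk over n_rep stacked row-major images ((n_rep * n_pix) x 1).
backbone_forward <- function(enc, x, n_rep = 1L) {
  grid <- enc$image_size
  h <- ad_conv(x, enc$stem$w, enc$stem$b, grid,
               k = enc$stem_stride, stride = enc$stem_stride, pad = 0L,
               n_rep = n_rep)
  out <- ad_relu(h$out); grid <- h$grid
  for (st in enc$stages) {
    a <- ad_conv(out, st$conv1$w, st$conv1$b, grid, k = 3L, stride = 2L,
                 pad = 1L, n_rep = n_rep)
    a1 <- ad_relu(a$out)
    a2 <- ad_conv(a1, st$conv2$w, st$conv2$b, a$grid, k = 3L, stride = 1L,
                  pad = 1L, n_rep = n_rep)
    sk <- ad_conv(out, st$skip$w, st$skip$b, grid, k = 1L, stride = 2L,
                  pad = 0L, n_rep = n_rep)
    out <- ad_relu(ad_add(a2$out, sk$out))
    grid <- a$grid
  }
  tokens <- ad_linear(out, enc$proj$w, enc$proj$b)
  list(tokens = tokens, grid = grid)
}

#' Fold a token-indexed vector back onto the feature grid
#' @param x numeric vector of length `prod(grid)` in row-major token order
#' @param grid feature-grid dims
#' @return an array of dimension `grid`
#' @export
fold_to_grid <- function(x, grid) {
  stopifnot(length(x) == prod(grid))
  aperm(array(x, dim = rev(grid)), rev(seq_along(grid)))
}

#' Unfold a grid array into row-major token order
#' @param a array of dimension `grid`
#' @return numeric vector in row-major token order
#' @export
unfold_grid <- function(a) {
  as.vector(aperm(a, rev(seq_along(dim(a)))))
}
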