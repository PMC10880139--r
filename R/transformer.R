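# Pre-norm transformer encoder with learnable [CLS] tokens and positional
# embeddings.  Per layer: z = MSA(LN(h)) + h; h = MLP(LN(z)) + z, where MSA is
# scaled-dot-product multi-head self-attention (per head Softmax(QK'/sqrt(dk))V,
# heads concatenated and projected) and MLP is linear -> GELU -> linear.

#' Transformer encoder configuration
#'
#' @param depth number of layers L (>= 1)
#' @param heads number of attention heads H (`width` must be divisible by H)
#' @param width model width C
#' @param mlp_ratio hidden width of the MLP as a multiple of C
#' @param n_cls number of learnable `[CLS]` tokens prepended to the input
#' @param dropout dropout rate applied to MSA/MLP outputs during training
#' @return a `transformer_config` list
#' @export
transformer_config <- function(depth = 2L, heads = 4L, width = 32L,
                               mlp_ratio = 4, n_cls = 1L, dropout = 0) {
  if (depth < 1L) stop("depth must be >= 1")
  if (n_cls < 0L) stop("n_cls must be >= 0")
  if (width %% heads != 0L) stop("width must be divisible by heads")
  if (mlp_ratio <= 0) stop("mlp_ratio must be positive")
  structure(list(depth = as.integer(depth), heads = as.integer(heads),
                 width = as.integer(width), mlp_ratio = mlp_ratio,
                 n_cls = as.integer(n_cls), dropout = dropout),
            class = "transformer_config")
}

#' Initialize transformer parameters
#'
#' CLS and positional embeddings use truncated-normal init (sd 0.02); linear
#' maps use uniform Kaiming-style init.
#' @param config a [transformer_config()]
#' @param n_tokens number of input (non-CLS) tokens the encoder will see
#' @return parameter list
#' @export
transformer_init <- function(config, n_tokens) {
  c_ <- config$width
  seq_len_ <- config$n_cls + n_tokens
  layers <- lapply(seq_len(config$depth), function(l) {
    list(ln1 = param_layernorm(c_),
         q = param_linear(c_, c_), k = param_linear(c_, c_),
         v = param_linear(c_, c_), o = param_linear(c_, c_),
         ln2 = param_layernorm(c_),
         mlp1 = param_linear(c_, round(config$mlp_ratio * c_)),
         mlp2 = param_linear(round(config$mlp_ratio * c_), c_))
  })
  list(
    config = config,
    cls = if (config$n_cls > 0L)
      ad_param(matrix(trunc_normal(config$n_cls * c_), config$n_cls, c_))
    else NULL,
    pos = ad_param(matrix(trunc_normal(seq_len_ * c_), seq_len_, c_)),
    layers = layers,
    n_tokens = as.integer(n_tokens)
  )
}

# Multi-head self-attention over an (S x C) sequence.  Returns the output
# sequence and the per-head attention array (H x S x S, rows row-stochastic).
msa_forward <- function(x, layer, heads, dropout = 0, train = FALSE) {
  res <- ad_mhsa(x, layer$q$w, layer$q$b, layer$k$w, layer$k$b,
                 layer$v$w, layer$v$b, layer$o$w, layer$o$b, heads)
  if (train && dropout > 0) res$out <- ad_dropout(res$out, dropout)
  res
}

#' Run the transformer encoder over a token sequence
#'
#' Prepends the learnable CLS tokens, adds positional embeddings, applies the
#' pre-norm layer stack, and returns the final sequence plus per-layer
#' attention tensors.
#'
#' @param params parameters from [transformer_init()]
#' @param tokens (N x C) token matrix (or ad node); N must equal the token
#'   count the encoder was initialized for
#' @param train enable dropout
#' @return an `encoder_state`: `$out` ((n_cls + N) x C), `$attn` list of
#'   H x S x S arrays, one per layer
#' @export
transformer_encode <- function(params, tokens, train = FALSE) {
  cfg <- params$config
  tv <- ad_value(tokens)
  if (ncol(tv) != cfg$width) {
    stop("token width ", ncol(tv), " does not match model width ", cfg$width)
  }
  if (nrow(tv) != params$n_tokens) {
    stop("got ", nrow(tv), " tokens, expected ", params$n_tokens)
  }
  h0 <- if (cfg$n_cls > 0L) {
    if (nrow(tv) > 0L) ad_rbind(list(params$cls, tokens)) else params$cls
  } else tokens
  h <- ad_add(h0, params$pos)
  attn <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    layer <- params$layers[[l]]
    x <- ad_layernorm(h, layer$ln1$g, layer$ln1$b)
    msa <- msa_forward(x, layer, cfg$heads, cfg$dropout, train)
    z <- ad_add(msa$out, h)
    attn[[l]] <- msa$attn
    y <- ad_layernorm(z, layer$ln2$g, layer$ln2$b)
    m <- ad_linear(ad_gelu(ad_linear(y, layer$mlp1$w, layer$mlp1$b)),
                   layer$mlp2$w, layer$mlp2$b)
    if (train && cfg$dropout > 0) m <- ad_dropout(m, cfg$dropout)
    h <- ad_add(m, z)
  }
  structure(list(out = h, attn = attn, n_cls = cfg$n_cls), class = "encoder_state")
}

#' Retrieve one attention map from an encoder state
#'
#' @param state an `encoder_state` from [transformer_encode()]
#' @param layer layer index (1-based)
#' @param head head index (1-based)
#' @return a row-stochastic S x S matrix
#' @export
attention_map <- function(state, layer, head) {
  if (layer < 1L || layer > length(state$attn)) stop("layer index out of range")
  a <- state$attn[[layer]]
  if (head < 1L || head > dim(a)[1L]) stop("head index out of range")
  matrix(a[head, , ], dim(a)[2L], dim(a)[3L])
}
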