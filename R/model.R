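# Multi-agent forecasting model: block R (radiologist) encodes imaging
# tokens and diagnoses the baseline; block C (context) compresses clinical
# variables into one contextual token; block P (general practitioner) fuses
# both and emits one severity prediction per horizon through K [CLS] tokens.

#' Model configuration
#'
#' @param t_future number of future horizons T
#' @param n_classes integer vector of T+1 class counts
#' @param image_size image/volume dims the model will consume
#' @param cx imaging token width CX
#' @param cm clinical token width CM
#' @param depths named or unnamed vector of transformer depths `c(r, c, p)`
#' @param heads attention heads for all three blocks
#' @param mlp_ratio MLP expansion ratio
#' @param k_cls number of [CLS] tokens in block P: 1 or T+1 (default T+1,
#'   one output head per horizon)
#' @param head_mode `"common"` (one FFN shared across horizons) or
#'   `"separate"` (one per horizon)
#' @param fusion `"channel"` (context token concatenated onto every imaging
#'   feature vector) or `"sequence"` (context token projected to CX and
#'   appended as an extra sequence element)
#' @param pool `"mean"` (average pooling over block R's output sequence for
#'   the diagnosis head) or `"cls"` (first vector only)
#' @param backbone list of CNN knobs: `width`, `n_stages`, `stem_stride`
#' @param quantize_bins one-hot bins for continuous covariates
#' @param dropout dropout rate in all transformer blocks
#' @return a `dtf_config`
#' @export
dtf_config <- function(t_future, n_classes, image_size = c(64L, 64L),
                       cx = 32L, cm = 32L, depths = c(2L, 2L, 4L),
                       heads = 4L, mlp_ratio = 4, k_cls = t_future + 1L,
                       head_mode = c("common", "separate"),
                       fusion = c("channel", "sequence"),
                       pool = c("mean", "cls"),
                       backbone = list(), quantize_bins = 4L, dropout = 0) {
  head_mode <- match.arg(head_mode)
  fusion <- match.arg(fusion)
  pool <- match.arg(pool)
  if (length(n_classes) != t_future + 1L) stop("n_classes must have length T+1")
  if (any(n_classes < 2L)) stop("all class counts must be >= 2")
  if (!k_cls %in% c(1L, t_future + 1L)) stop("k_cls must be 1 or t_future + 1")
  if (any(depths < 1L)) stop("all depths must be >= 1")
  bb <- utils::modifyList(
    list(width = 16L, n_stages = 3L,
         stem_stride = if (length(image_size) == 2L) 4L else 2L),
    backbone)
  structure(list(
    t_future = as.integer(t_future), n_classes = as.integer(n_classes),
    image_size = as.integer(image_size), cx = as.integer(cx),
    cm = as.integer(cm), depths = as.integer(depths), heads = as.integer(heads),
    mlp_ratio = mlp_ratio, k_cls = as.integer(k_cls), head_mode = head_mode,
    fusion = fusion, pool = pool, backbone = bb,
    quantize_bins = as.integer(quantize_bins), dropout = dropout
  ), class = "dtf_config")
}

# Prediction head: LN -> linear -> GELU -> linear.
head_init <- function(c_in, c_hidden, n_out) {
  list(ln = param_layernorm(c_in), fc1 = param_linear(c_in, c_hidden),
       fc2 = param_linear(c_hidden, n_out))
}

head_forward <- function(head, x) {
  h <- ad_layernorm(x, head$ln$g, head$ln$b)
  h <- ad_gelu(ad_linear(h, head$fc1$w, head$fc1$b))
  ad_linear(h, head$fc2$w, head$fc2$b)
}

#' Build and initialize the forecasting model
#'
#' @param config a [dtf_config()]
#' @param cohort optional `trajcast_cohort` (or list of records) used to set
#'   the covariate schema and the training-split min/max ranges for
#'   continuous-variable quantization; otherwise `covariate_spec` must be
#'   given and ranges default to `[0, 1]`
#' @param seed RNG seed for parameter initialization
#' @param covariate_spec covariate schema (see [default_covariate_spec()])
#' @param sigma_init initial value of every per-task noise parameter sigma
#'   (1 gives tau = 1 everywhere, i.e. plain cross-entropy at the start)
#' @return a `dtf_model`
#' @export
dtf_model <- function(config, cohort = NULL, seed = 1L,
                      covariate_spec = NULL, sigma_init = 1) {
  stopifnot(inherits(config, "dtf_config"))
  if (is.null(covariate_spec)) {
    covariate_spec <- attr(cohort, "covariate_spec") %||% default_covariate_spec()
  }
  ranges <- if (!is.null(cohort)) {
    fit_covariate_ranges(cohort, covariate_spec)
  } else {
    rg <- list()
    for (v in covariate_spec) if (v$type == "continuous") rg[[v$name]] <- c(0, 1)
    rg
  }
  tt <- config$t_future + 1L

  withr::with_seed(as.integer(seed), {
    img_enc <- image_encoder(config$image_size, config$cx,
                             width = config$backbone$width,
                             n_stages = config$backbone$n_stages,
                             stem_stride = config$backbone$stem_stride)
    n_img <- img_enc$n_tokens
    m_vars <- length(covariate_spec)

    scalar_encs <- lapply(covariate_spec, function(v) {
      scalar_encoder(covariate_width(v, config$quantize_bins), config$cm)
    })
    names(scalar_encs) <- vapply(covariate_spec, `[[`, "", "name")

    r_block <- transformer_init(
      transformer_config(config$depths[1L], config$heads, config$cx,
                         config$mlp_ratio, n_cls = 1L, dropout = config$dropout),
      n_tokens = n_img)
    head_r <- head_init(config$cx, config$cx, config$n_classes[1L])

    c_block <- transformer_init(
      transformer_config(config$depths[2L], config$heads, config$cm,
                         config$mlp_ratio, n_cls = 1L, dropout = config$dropout),
      n_tokens = m_vars)

    cp <- if (config$fusion == "channel") config$cx + config$cm else config$cx
    n_p_tokens <- if (config$fusion == "channel") n_img + 1L else n_img + 2L
    p_block <- transformer_init(
      transformer_config(config$depths[3L], config$heads, cp,
                         config$mlp_ratio, n_cls = config$k_cls,
                         dropout = config$dropout),
      n_tokens = n_p_tokens)
    ctx_proj <- if (config$fusion == "sequence") param_linear(config$cm, config$cx) else NULL

    heads_p <- if (config$head_mode == "common") {
      shared <- list(ln = param_layernorm(cp), fc1 = param_linear(cp, cp))
      fc2 <- if (length(unique(config$n_classes)) == 1L) {
        shared_out <- param_linear(cp, config$n_classes[1L])
        lapply(seq_len(tt), function(t) shared_out)
      } else {
        lapply(config$n_classes, function(nc) param_linear(cp, nc))
      }
      lapply(seq_len(tt), function(t) {
        list(ln = shared$ln, fc1 = shared$fc1, fc2 = fc2[[t]])
      })
    } else {
      lapply(config$n_classes, function(nc) head_init(cp, cp, nc))
    }

    sigma <- ad_param(matrix(sigma_init, 1L, tt))

    params <- list(img_enc = img_enc, scalar_encs = scalar_encs,
                   r_block = r_block, head_r = head_r, c_block = c_block,
                   p_block = p_block, ctx_proj = ctx_proj, heads_p = heads_p,
                   sigma = sigma)
    structure(list(config = config, params = params,
                   covariate_spec = covariate_spec, ranges = ranges,
                   seed = as.integer(seed)),
              class = "dtf_model")
  })
}

# Encode one record's covariates into an (M x CM) token sequence.
encode_covariates <- function(model, record) {
  cfg <- model$config
  toks <- lapply(model$covariate_spec, function(var) {
    x <- encode_covariate_value(var, record$covariates[[var$name]],
                                cfg$quantize_bins, model$ranges[[var$name]])
    encode_scalar(model$params$scalar_encs[[var$name]], x)
  })
  ad_rbind(toks)
}

#' Radiologist block forward pass
#'
#' Encodes the imaging token sequence with one [CLS] token; the diagnosis
#' logits come from an FFN over the pooled output sequence (average pooling
#' by default, first vector under `pool = "cls"`).
#' @param model a `dtf_model`
#' @param imaging_tokens (N x CX) token matrix or ad node
#' @param train enable dropout
#' @return list with `$state` (encoder state, N+1 vectors) and `$f0r` logits
#' @export
radiologist_forward <- function(model, imaging_tokens, train = FALSE) {
  state <- transformer_encode(model$params$r_block, imaging_tokens, train)
  pooled <- if (model$config$pool == "mean") ad_mean_rows(state$out)
            else ad_rows(state$out, 1L)
  list(state = state, f0r = head_forward(model$params$head_r, pooled))
}

#' Context block forward pass
#'
#' Encodes the M clinical tokens with one [CLS] token and returns only the
#' first output vector as the common contextual token.
#' @param model a `dtf_model`
#' @param clinical_tokens (M x CM) token matrix or ad node
#' @param train enable dropout
#' @return list with `$state` and `$h0` (1 x CM contextual token)
#' @export
context_forward <- function(model, clinical_tokens, train = FALSE) {
  state <- transformer_encode(model$params$c_block, clinical_tokens, train)
  list(state = state, h0 = ad_rows(state$out, 1L))
}

#' General-practitioner block forward pass
#'
#' Channel-wise fusion concatenates a copy of the contextual token onto each
#' of the N+1 radiologist output vectors; sequence-wise fusion projects the
#' contextual token to CX and appends it as one extra sequence element.  K
#' [CLS] tokens are prepended and the first T+1 output vectors (the K CLS
#' outputs, or the single CLS output replicated when K = 1) feed the
#' per-horizon prediction FFNs.
#' @param model a `dtf_model`
#' @param h_r radiologist output sequence ((N+1) x CX)
#' @param h_c0 contextual token (1 x CM)
#' @param train enable dropout
#' @return list with `$state` and `$f` (list of T+1 logit vectors)
#' @export
practitioner_forward <- function(model, h_r, h_c0, train = FALSE) {
  cfg <- model$config
  n1 <- nrow(ad_value(h_r))
  fused <- if (cfg$fusion == "channel") {
    ad_cbind(list(h_r, ad_rep_rows(h_c0, n1)))
  } else {
    ctx <- ad_linear(h_c0, model$params$ctx_proj$w, model$params$ctx_proj$b)
    ad_rbind(list(h_r, ctx))
  }
  state <- transformer_encode(model$params$p_block, fused, train)
  tt <- cfg$t_future + 1L
  f <- lapply(seq_len(tt), function(t) {
    row <- if (cfg$k_cls == tt) t else 1L
    head_forward(model$params$heads_p[[t]], ad_rows(state$out, row))
  })
  list(state = state, f = f)
}

#' Full forward pass on one patient record
#'
#' @param model a `dtf_model`
#' @param record a `patient_record`; the image is mandatory, covariates may
#'   be missing
#' @param train enable dropout and gradient tracking of the call site
#' @return a `prognosis_output`: `$f0r` diagnosis logits, `$f` list of T+1
#'   prognosis logit vectors, `$states` (R, C, P encoder states), `$grid`
#'   (imaging feature grid), `$layout` (sequence layout of block P)
#' @export
dtf_forward <- function(model, record, train = FALSE) {
  if (is.null(record$image)) stop("record has no image; imaging is mandatory")
  cfg <- model$config
  img <- encode_image(model$params$img_enc, record$image, record$.image_rm)
  r <- radiologist_forward(model, img$tokens, train)
  ctoks <- encode_covariates(model, record)
  cblk <- context_forward(model, ctoks, train)
  p <- practitioner_forward(model, r$state$out, cblk$h0, train)
  structure(list(
    f0r = r$f0r, f = p$f,
    states = list(r = r$state, c = cblk$state, p = p$state),
    grid = img$grid,
    layout = list(k = cfg$k_cls, n = model$params$img_enc$n_tokens,
                  m = length(model$covariate_spec), fusion = cfg$fusion)
  ), class = "prognosis_output")
}

#' Predicted class probabilities for one record
#'
#' @param object a `dtf_model`
#' @param record a `patient_record`
#' @param ... unused
#' @return list with `$diagnosis` (softmax of the radiologist logits) and
#'   `$prognosis` (list of T+1 probability vectors from block P)
#' @export
predict.dtf_model <- function(object, record, ...) {
  out <- ad_no_grad(dtf_forward(object, record, train = FALSE))
  list(diagnosis = softmax(as.vector(ad_value(out$f0r))),
       prognosis = lapply(out$f, function(ft) softmax(as.vector(ad_value(ft)))))
}

#' Extract interpretation attention maps for one record
#'
#' Clinical weights are the last-layer attention row of block C's [CLS]
#' token over the M variable tokens, averaged over heads and renormalized;
#' the imaging map is the last-layer attention row of block P's horizon-t
#' [CLS] token over the N imaging-grid positions, head-averaged,
#' renormalized and folded back onto the feature grid.
#' @param model a `dtf_model`
#' @param record a `patient_record`
#' @param t 0-based horizon
#' @return list with `$imaging` (array over the feature grid) and
#'   `$clinical` (named nonnegative weights summing to 1)
#' @export
extract_attention <- function(model, record, t = 0L) {
  cfg <- model$config
  if (t < 0L || t > cfg$t_future) stop("horizon t out of range")
  out <- ad_no_grad(dtf_forward(model, record, train = FALSE))
  lay <- out$layout

  a_c <- out$states$c$attn[[length(out$states$c$attn)]]
  w_c <- colMeans(matrix(a_c[, 1L, 1L + seq_len(lay$m)], nrow = dim(a_c)[1L]))
  w_c <- w_c / sum(w_c)
  names(w_c) <- vapply(model$covariate_spec, `[[`, "", "name")

  a_p <- out$states$p$attn[[length(out$states$p$attn)]]
  row <- if (lay$k == cfg$t_future + 1L) t + 1L else 1L
  img_pos <- lay$k + 1L + seq_len(lay$n)  # skip K CLS + block R's CLS vector
  w_i <- colMeans(matrix(a_p[, row, img_pos], nrow = dim(a_p)[1L]))
  w_i <- w_i / sum(w_i)

  list(imaging = fold_to_grid(w_i, out$grid), clinical = w_c)
}
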