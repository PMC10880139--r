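# Batch-vectorized forward pass: a mini-batch of records is processed as
# row-stacked matrices (sample-major), so linear maps, layer norms and
# activations are single BLAS-level calls and attention runs block-diagonally
# per sample.  Numerically identical to the per-record path in
# dtf_forward(); the training loop and evaluator use this one for speed.

# Encode the transformer over b_ stacked sequences of n_tok tokens each.
# Returns list(out = (b_ * S x C), attn = per-layer b_ x H x S x S arrays
# when collect_attn).
transformer_encode_blocks <- function(params, tokens, b_, train = FALSE,
                                      collect_attn = FALSE) {
  cfg <- params$config
  n_tok <- params$n_tokens
  s_ <- cfg$n_cls + n_tok
  h <- if (cfg$n_cls > 0L) {
    combined <- if (n_tok > 0L) ad_rbind(list(params$cls, tokens)) else params$cls
    # sample-major interleave: [cls 1..K, tokens of sample b]
    idx <- unlist(lapply(seq_len(b_), function(b) {
      c(seq_len(cfg$n_cls), cfg$n_cls + (b - 1L) * n_tok + seq_len(n_tok))
    }))
    ad_rows(combined, idx)
  } else tokens
  h <- ad_add(h, ad_rows(params$pos, rep(seq_len(s_), b_)))
  attn <- if (collect_attn) vector("list", cfg$depth) else NULL
  for (l in seq_len(cfg$depth)) {
    layer <- params$layers[[l]]
    x <- ad_layernorm(h, layer$ln1$g, layer$ln1$b)
    msa <- ad_mhsa_blocks(x, layer$q$w, layer$q$b, layer$k$w, layer$k$b,
                          layer$v$w, layer$v$b, layer$o$w, layer$o$b,
                          cfg$heads, b_, s_, collect_attn)
    mo <- msa$out
    if (train && cfg$dropout > 0) mo <- ad_dropout(mo, cfg$dropout)
    z <- ad_add(mo, h)
    if (collect_attn) attn[[l]] <- msa$attn
    y <- ad_layernorm(z, layer$ln2$g, layer$ln2$b)
    m <- ad_linear(ad_gelu(ad_linear(y, layer$mlp1$w, layer$mlp1$b)),
                   layer$mlp2$w, layer$mlp2$b)
    if (train && cfg$dropout > 0) m <- ad_dropout(m, cfg$dropout)
    h <- ad_add(m, z)
  }
  list(out = h, attn = attn, s = s_)
}

# One-hot covariate matrices, one (b_ x width) matrix per variable.
covariate_onehots <- function(model, records) {
  cfg <- model$config
  lapply(model$covariate_spec, function(var) {
    do.call(rbind, lapply(records, function(r) {
      encode_covariate_value(var, r$covariates[[var$name]],
                             cfg$quantize_bins, model$ranges[[var$name]])
    }))
  })
}

#' Batched forward pass over a list of records
#'
#' Numerically identical to [dtf_forward()] applied record by record, but
#' vectorized across the mini-batch.
#' @param model a `dtf_model`
#' @param records list of `patient_record`s
#' @param train enable dropout
#' @return list with `$f0r` (B x Nc0 diagnosis logits) and `$f` (list of T+1
#'   B x Nct prognosis logit matrices)
#' @export
dtf_forward_batch <- function(model, records, train = FALSE) {
  cfg <- model$config
  b_ <- length(records)
  enc <- model$params$img_enc

  x <- do.call(rbind, lapply(records, function(r) {
    r$.image_rm %||% image_to_rowmajor(r$image)
  }))
  img <- backbone_forward(enc, x, n_rep = b_)
  n_img <- enc$n_tokens

  r_state <- transformer_encode_blocks(model$params$r_block, img$tokens, b_, train)
  s_r <- r_state$s
  pooled <- if (cfg$pool == "mean") {
    ad_rowgroup_mean(r_state$out, b_, s_r)
  } else {
    ad_rows(r_state$out, (0:(b_ - 1L)) * s_r + 1L)
  }
  f0r <- head_forward(model$params$head_r, pooled)

  m_vars <- length(model$covariate_spec)
  oneh <- covariate_onehots(model, records)
  var_tokens <- lapply(seq_len(m_vars), function(mi) {
    encode_scalar(model$params$scalar_encs[[mi]], oneh[[mi]])
  })
  # var-major (B rows per variable) -> sample-major (M tokens per sample)
  idx <- rep((0:(m_vars - 1L)) * b_, times = b_) + rep(seq_len(b_), each = m_vars)
  ctoks <- ad_rows(ad_rbind(var_tokens), idx)
  c_state <- transformer_encode_blocks(model$params$c_block, ctoks, b_, train)
  h_c0 <- ad_rows(c_state$out, (0:(b_ - 1L)) * c_state$s + 1L)

  n1 <- n_img + 1L
  fused <- if (cfg$fusion == "channel") {
    ad_cbind(list(r_state$out, ad_rows(h_c0, rep(seq_len(b_), each = n1))))
  } else {
    ctx <- ad_linear(h_c0, model$params$ctx_proj$w, model$params$ctx_proj$b)
    combined <- ad_rbind(list(r_state$out, ctx))
    idx2 <- unlist(lapply(seq_len(b_), function(b) {
      c((b - 1L) * n1 + seq_len(n1), b_ * n1 + b)
    }))
    ad_rows(combined, idx2)
  }
  p_state <- transformer_encode_blocks(model$params$p_block, fused, b_, train)
  tt <- cfg$t_future + 1L
  f <- lapply(seq_len(tt), function(t) {
    row <- if (cfg$k_cls == tt) t else 1L
    head_forward(model$params$heads_p[[t]],
                 ad_rows(p_state$out, (0:(b_ - 1L)) * p_state$s + row))
  })
  list(f0r = f0r, f = f)
}

# Batched differentiable total loss for one mini-batch.
# prognosis: sum over (sample, observed horizon) of CLUB with weight
# 1 / (n_observed_horizons(sample) * n_samples_with_observations);
# consistency: L1(f0r, f0) summed over the batch, weight lambda / B.
batch_loss_node <- function(model, records, out, tau_node, rc) {
  tt <- model$config$t_future + 1L
  b_ <- length(records)
  mask <- do.call(rbind, lapply(records, `[[`, "target_mask"))
  n_obs <- rowSums(mask)
  n_prog <- sum(n_obs > 0L)
  terms <- list()
  prog_val <- 0
  if (n_prog > 0L) {
    for (t in seq_len(tt)) {
      sel <- which(mask[, t])
      if (length(sel) == 0L) next
      labels <- vapply(sel, function(i) records[[i]]$targets[t], numeric(1L))
      w <- 1 / (n_obs[sel] * n_prog)
      logits_t <- if (length(sel) == b_) out$f[[t]] else ad_rows(out$f[[t]], sel)
      ce_sum <- ad_ce_batch(logits_t, labels, w)
      tau_t <- if (is.null(tau_node)) 1 else ad_cols(tau_node, t)
      tau_ce <- if (!is.null(tau_node) && rc$detach_tau) {
        as.vector(ad_value(tau_t))
      } else tau_t
      term <- ad_add(ad_mul(tau_ce, ce_sum),
                     ad_scale(ad_addc(ad_scale(tau_t, -1), 1),
                              log(model$config$n_classes[t]) * sum(w)))
      terms <- c(terms, list(term))
      prog_val <- prog_val + as.vector(ad_value(term))
    }
  }
  cons <- ad_l1(out$f0r, out$f[[1L]])
  cons_val <- as.vector(ad_value(cons))
  terms <- c(terms, list(ad_scale(cons, rc$lambda / b_)))
  list(node = Reduce(ad_add, terms), prog = prog_val, cons = cons_val / b_,
       n_prog = n_prog)
}
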