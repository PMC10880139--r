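# Shared numeric helpers, initializers and the Adam optimizer.

#' Numerically-stable softmax of a numeric vector
#' @param x numeric vector of logits
#' @return probability vector summing to 1
#' @export
softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Truncated-normal initializer (sd 0.02, truncated at 2 sd), the standard
# vision-transformer choice for embeddings.
trunc_normal <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > 2 * sd)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

# Kaiming-uniform style init for a fan_in x fan_out weight matrix.
init_linear <- function(fan_in, fan_out) {
  bound <- sqrt(6 / fan_in)
  matrix(stats::runif(fan_in * fan_out, -bound, bound), fan_in, fan_out)
}

param_linear <- function(fan_in, fan_out) {
  list(w = ad_param(init_linear(fan_in, fan_out)),
       b = ad_param(matrix(0, 1L, fan_out)))
}

param_layernorm <- function(c_) {
  list(g = ad_param(matrix(1, 1L, c_)), b = ad_param(matrix(0, 1L, c_)))
}

# Flatten a nested list of parameters into a flat list of ad leaves.
collect_params <- function(x) {
  if (is_ad(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

zero_grads <- function(leaves) {
  for (p in leaves) p$grad <- NULL
  invisible(NULL)
}

# Extract / restore plain numeric values of a nested parameter list (used for
# checkpoint serialization and reproducibility checks).
param_values <- function(x) {
  if (is_ad(x)) return(x$value)
  if (is.list(x)) return(lapply(x, param_values))
  x
}

set_param_values <- function(params, values) {
  if (is_ad(params)) {
    params$value <- values
    return(invisible(NULL))
  }
  if (is.list(params)) {
    for (i in seq_along(params)) set_param_values(params[[i]], values[[i]])
  }
  invisible(NULL)
}

# Adam step over a flat list of leaves; optimizer state lives on each leaf.
adam_step <- function(leaves, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      t_step = 1L) {
  bc1 <- 1 - beta1^t_step
  bc2 <- 1 - beta2^t_step
  for (p in leaves) {
    if (is.null(p$grad)) next
    if (is.null(p$m)) {
      p$m <- p$grad * 0
      p$v <- p$grad * 0
    }
    p$m <- beta1 * p$m + (1 - beta1) * p$grad
    p$v <- beta2 * p$v + (1 - beta2) * p$grad * p$grad
    p$value <- p$value - lr * (p$m / bc1) / (sqrt(p$v / bc2) + eps)
  }
  invisible(NULL)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a probability in [0, 1]", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
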