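# Calibration-aware multi-task losses.
#
# The calibrated upper-bound (CLUB) loss for task t with inverse temperature
# tau in [0, 1] is tau * CE + (1 - tau) * log(Nc): a convex combination of
# cross-entropy and the task's maximum-entropy loss, and an upper bound on
# temperature-scaled cross-entropy (TCE) by the reverse Hoelder inequality,
# tight iff tau = 1.  Per-task taus are derived from learnable noise
# parameters sigma_t by a constraint mapping that keeps max(tau) = 1.

#' Cross-entropy of a logit vector against a 0-based label
#'
#' Computed log-sum-exp stably: `logsumexp(logits) - logits[label]`.
#' @param logits numeric vector of unnormalized log-probabilities
#' @param label 0-based true class index
#' @return nonnegative scalar
#' @export
cross_entropy <- function(logits, label) {
  nc <- length(logits)
  if (label < 0 || label >= nc) stop("label out of range")
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[label + 1L]
}

#' Temperature-scaled cross-entropy
#'
#' Cross-entropy evaluated on `tau * logits`, i.e.
#' `-log(g_c^tau / sum(g^tau))` with `g = exp(logits)`.
#' @param logits numeric logit vector
#' @param label 0-based true class index
#' @param tau inverse temperature in (0, 1]
#' @return nonnegative scalar
#' @export
temperature_scaled_ce <- function(logits, label, tau) {
  if (!is.numeric(tau) || tau <= 0) stop("tau must be positive")
  cross_entropy(tau * logits, label)
}

#' Calibrated upper-bound (CLUB) loss
#'
#' `tau * CE(logits, label) + (1 - tau) * log(n_classes)`.  For tau in (0, 1]
#' this upper-bounds [temperature_scaled_ce()], with equality iff tau = 1;
#' at tau = 0 it degenerates to the maximum-entropy constant `log(n_classes)`.
#' @param logits numeric logit vector
#' @param label 0-based true class index
#' @param tau inverse temperature in `[0, 1]`
#' @param n_classes number of classes of this task (defaults to
#'   `length(logits)`)
#' @return nonnegative scalar
#' @export
club <- function(logits, label, tau, n_classes = length(logits)) {
  if (!is.numeric(tau) || tau < 0 || tau > 1) stop("tau must be in [0, 1]")
  tau * cross_entropy(logits, label) + (1 - tau) * log(n_classes)
}

#' Constrain per-task noise parameters into inverse temperatures
#'
#' `rho_t = 1 / (sigma_t^2 + eps)`; `rho~ = softmax(rho)`;
#' `tau_t = rho~_t / max(rho~)`.  The softmax prevents all taus from
#' collapsing to 1 while the final rescaling guarantees `max(tau) = 1` and
#' `tau in (0, 1]`; the whole mapping is differentiable in sigma.
#' @param sigma numeric vector of T+1 unconstrained noise parameters
#' @param eps positive stabilizer keeping `rho` finite for any sigma
#' @return numeric vector of inverse temperatures with `max(tau) = 1`
#' @export
constrain_temperatures <- function(sigma, eps = 1e-6) {
  if (!is.numeric(eps) || eps <= 0) stop("eps must be positive")
  rho <- 1 / (sigma^2 + eps)
  rho_t <- softmax(rho)
  rho_t / max(rho_t)
}

#' Masked prognosis loss
#'
#' Mean CLUB loss over the observed tasks:
#' `(1 / sum(mask)) * sum_t mask_t * CLUB_t`.
#' @param logits_list list of T+1 logit vectors
#' @param labels integer vector of T+1 0-based labels (`NA` where masked)
#' @param mask logical vector of T+1 observation indicators
#' @param tau numeric vector of T+1 inverse temperatures
#' @return nonnegative scalar
#' @export
prognosis_loss <- function(logits_list, labels, mask, tau) {
  tt <- length(logits_list)
  stopifnot(length(labels) == tt, length(mask) == tt, length(tau) == tt)
  if (!any(mask)) stop("no observed targets: prognosis loss undefined")
  total <- 0
  for (t in which(mask)) {
    total <- total + club(logits_list[[t]], labels[t], tau[t])
  }
  total / sum(mask)
}

#' Consistency loss between radiologist and practitioner diagnosis logits
#'
#' L1 distance between the two baseline-diagnosis logit vectors.  For
#' matrices (a batch, one row per sample) the per-sample L1 distances are
#' averaged.
#' @param f0r radiologist logits (vector, or n x Nc0 matrix)
#' @param f0 practitioner baseline logits of the same shape
#' @return nonnegative scalar
#' @export
consistency_loss <- function(f0r, f0) {
  if (is.matrix(f0r) || is.matrix(f0)) {
    f0r <- as.matrix(f0r); f0 <- as.matrix(f0)
    if (!all(dim(f0r) == dim(f0))) stop("logit shapes differ")
    return(mean(rowSums(abs(f0r - f0))))
  }
  if (length(f0r) != length(f0)) stop("logit lengths differ")
  sum(abs(f0r - f0))
}

#' Total training loss
#'
#' `prognosis + lambda * consistency`.
#' @param prognosis prognosis-loss value
#' @param consistency consistency-loss value
#' @param lambda nonnegative consistency regularization coefficient
#' @return scalar
#' @export
total_loss <- function(prognosis, consistency, lambda = 0.5) {
  if (lambda < 0) stop("lambda must be nonnegative")
  prognosis + lambda * consistency
}

## ---- autodiff versions used by the training loop ---------------------------

# Differentiable Algorithm-1 constraint over a 1 x (T+1) sigma node.
ad_constrain_temperatures <- function(sigma, eps = 1e-6) {
  rho <- ad_recip(ad_addc(ad_square(sigma), eps))
  ad_div_max(ad_softmax_rows(rho))
}

# Differentiable CLUB for one task.  `tau_el` is a 1x1 node (or constant);
# with detach_tau the temperature multiplying the CE term is treated as a
# constant, leaving only the (1 - tau) * log Nc path trainable in sigma.
ad_club <- function(logits, label0, tau_el, n_classes, detach_tau = FALSE) {
  ce <- ad_ce(logits, label0)
  tau_ce <- if (detach_tau) as.vector(ad_value(tau_el)) else tau_el
  ad_add(ad_mul(tau_ce, ce),
         ad_scale(ad_addc(ad_scale(tau_el, -1), 1), log(n_classes)))
}
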