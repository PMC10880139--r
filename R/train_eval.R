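# Training loop (Adam over the autodiff tape), subject-grouped k-fold
# splitting, evaluation and checkpointing.

#' Training-run configuration
#'
#' @param model a [dtf_config()] describing the architecture
#' @param epochs training epochs
#' @param batch_size mini-batch size
#' @param lr Adam learning rate
#' @param lambda consistency regularization coefficient
#' @param loss `"club"` (calibrated upper bound with learnable temperatures)
#'   or `"ce"` (plain cross-entropy, all tau fixed at 1)
#' @param epsilon stabilizer of the temperature constraint
#' @param sigma_init initial per-task noise parameter
#' @param detach_tau treat tau as a constant in the tau * CE product (the
#'   sigma gradient then flows only through the max-entropy term)
#' @param seed seed for init, shuffling and dropout
#' @return a `run_config`
#' @export
run_config <- function(model, epochs = 30L, batch_size = 32L, lr = 1e-4,
                       lambda = 0.5, loss = c("club", "ce"), epsilon = 1e-6,
                       sigma_init = 1, detach_tau = FALSE, seed = 1L) {
  loss <- match.arg(loss)
  if (lambda < 0) stop("lambda must be nonnegative")
  if (epsilon <= 0) stop("epsilon must be positive")
  structure(list(model = model, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 lambda = lambda, loss = loss, epsilon = epsilon,
                 sigma_init = sigma_init, detach_tau = isTRUE(detach_tau),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Subject-grouped k-fold split
#'
#' Partitions records into k folds by subject id (every record of a subject
#' lands in the same fold, so augmented entries never straddle a split) with
#' fold sizes balanced within one subject.
#' @param records list of `patient_record`s
#' @param k number of folds (2 <= k <= number of subjects)
#' @param seed shuffling seed
#' @return list of k folds, each `list(train = indices, val = indices)`
#' @export
split_cohort <- function(records, k, seed = 1L) {
  ids <- vapply(records, function(r) r$subject_id, numeric(1L))
  subjects <- unique(ids)
  if (k < 2L) stop("k must be >= 2")
  if (k > length(subjects)) stop("k exceeds the number of subjects")
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(subjects)
    fold_of <- stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
    lapply(seq_len(k), function(f) {
      val <- unname(which(fold_of[as.character(ids)] == f))
      list(train = setdiff(seq_along(records), val), val = val)
    })
  })
}

# Differentiable per-sample loss. Returns NULL contributions where undefined.
sample_loss_nodes <- function(model, record, tau_node, rc) {
  out <- dtf_forward(model, record, train = TRUE)
  tt <- model$config$t_future + 1L
  obs <- which(record$target_mask)
  prog <- NULL
  if (length(obs) > 0L) {
    terms <- lapply(obs, function(t) {
      ad_club(out$f[[t]], record$targets[t],
              if (is.null(tau_node)) 1 else ad_cols(tau_node, t),
              model$config$n_classes[t], rc$detach_tau)
    })
    prog <- ad_scale(Reduce(ad_add, terms), 1 / length(obs))
  }
  cons <- ad_l1(out$f0r, out$f[[1L]])
  list(prog = prog, cons = cons)
}

#' Train the forecasting model
#'
#' Minimizes `prognosis + lambda * consistency` with Adam.  The prognosis
#' term is the masked mean CLUB loss, averaged over the samples of a batch
#' that have at least one observed target; the consistency term is averaged
#' over all samples.  Per-task inverse temperatures are learned through the
#' softmax/max constraint when `loss = "club"`.
#'
#' @param rc a [run_config()]
#' @param cohort training records (a `trajcast_cohort` or list of
#'   `patient_record`s)
#' @return a `dtf_checkpoint`: `$model`, `$rc`, `$log` (per-epoch losses),
#'   `$tau_trajectory` (epochs x T+1 matrix of constrained taus)
#' @export
train_dtf <- function(rc, cohort) {
  stopifnot(inherits(rc, "run_config"))
  model <- dtf_model(rc$model, cohort, seed = rc$seed,
                     sigma_init = rc$sigma_init)
  use_club <- rc$loss == "club"
  leaves <- collect_params(model$params)
  if (!use_club) {
    leaves <- Filter(function(p) !identical(p, model$params$sigma), leaves)
  }
  # deduplicate shared heads (common-head fc2 appears once per horizon);
  # duplicated() compares environments by reference
  leaves <- leaves[!duplicated(leaves)]
  tt <- model$config$t_future + 1L
  n <- length(cohort)
  # cache row-major image matrices once; they are reused every epoch
  for (i in seq_len(n)) {
    cohort[[i]]$.image_rm <- image_to_rowmajor(cohort[[i]]$image)
  }

  log_rows <- vector("list", rc$epochs)
  tau_traj <- matrix(NA_real_, rc$epochs, tt)
  step <- 0L

  withr::with_seed(rc$seed + 1L, {
    for (epoch in seq_len(rc$epochs)) {
      order_ <- sample(n)
      ep_prog <- 0; ep_cons <- 0; n_prog <- 0L
      for (start in seq(1L, n, by = rc$batch_size)) {
        batch <- order_[start:min(start + rc$batch_size - 1L, n)]
        recs <- cohort[batch]
        zero_grads(leaves)
        ad_tape_reset()
        tau_node <- if (use_club) {
          ad_constrain_temperatures(model$params$sigma, rc$epsilon)
        } else NULL
        out <- dtf_forward_batch(model, recs, train = TRUE)
        bl <- batch_loss_node(model, recs, out, tau_node, rc)
        lv <- as.vector(ad_value(bl$node))
        if (!is.finite(lv)) {
          stop("training diverged: non-finite loss at epoch ", epoch)
        }
        ad_backward(bl$node)
        ep_prog <- ep_prog + bl$prog * bl$n_prog
        n_prog <- n_prog + bl$n_prog
        ep_cons <- ep_cons + bl$cons * length(recs)
        step <- step + 1L
        adam_step(leaves, rc$lr, t_step = step)
      }
      tau_now <- if (use_club) {
        constrain_temperatures(as.vector(model$params$sigma$value), rc$epsilon)
      } else rep(1, tt)
      tau_traj[epoch, ] <- tau_now
      log_rows[[epoch]] <- data.frame(
        epoch = epoch,
        prognosis = if (n_prog > 0L) ep_prog / n_prog else NA_real_,
        consistency = ep_cons / n,
        total = (if (n_prog > 0L) ep_prog / n_prog else 0) + rc$lambda * ep_cons / n
      )
    }
  })
  ad_tape_reset()
  structure(list(model = model, rc = rc, log = do.call(rbind, log_rows),
                 tau_trajectory = tau_traj),
            class = "dtf_checkpoint")
}

#' Evaluate a trained model on a set of records
#'
#' Per-horizon metrics are computed on observed targets only; probabilities
#' are the softmax of each horizon's logits.  Horizons with no observed
#' target report `NA`.
#' @param checkpoint a `dtf_checkpoint` or `dtf_model`
#' @param records records to evaluate
#' @param n_bins ECE confidence bins
#' @param windows optional horizon-window list passed to [metrics_report()]
#' @param exclude_baseline_top drop subjects whose baseline grade is already
#'   the top class (the clinical-relevance filter: no prognosis is made for
#'   end-stage baselines)
#' @return a `metrics_report`
#' @export
evaluate_dtf <- function(checkpoint, records, n_bins = 10L, windows = NULL,
                         exclude_baseline_top = FALSE) {
  model <- if (inherits(checkpoint, "dtf_checkpoint")) checkpoint$model else checkpoint
  stopifnot(inherits(model, "dtf_model"))
  tt <- model$config$t_future + 1L
  if (exclude_baseline_top) {
    keep <- vapply(records, function(r) {
      r$targets[1L] < model$config$n_classes[1L] - 1L
    }, logical(1L))
    records <- records[keep]
  }
  if (length(records) == 0L) stop("no records to evaluate")

  # batched inference, chunked to bound memory
  probs_t <- vector("list", tt)
  for (start in seq(1L, length(records), by = 64L)) {
    chunk <- records[start:min(start + 63L, length(records))]
    out <- ad_no_grad(dtf_forward_batch(model, chunk, train = FALSE))
    for (t in seq_len(tt)) {
      pm <- t(apply(ad_value(out$f[[t]]), 1L, softmax))
      probs_t[[t]] <- rbind(probs_t[[t]], pm)
    }
  }
  ba <- ece <- auroc <- rep(NA_real_, tt)
  for (t in seq_len(tt)) {
    sel <- which(vapply(records, function(r) isTRUE(r$target_mask[t]), logical(1L)))
    if (length(sel) == 0L) next
    labels <- vapply(sel, function(i) records[[i]]$targets[t], numeric(1L))
    probs <- probs_t[[t]][sel, , drop = FALSE]
    pred_cls <- max.col(probs, ties.method = "first") - 1L
    ba[t] <- balanced_accuracy(labels, pred_cls)
    ece[t] <- expected_calibration_error(probs, labels, n_bins)
    auroc[t] <- suppressWarnings(multiclass_auroc_ovo(probs, labels))
  }
  metrics_report(ba, ece, auroc, windows)
}

#' Save a checkpoint to a single file
#'
#' Parameters are stored as plain numeric values together with the model and
#' run configuration and the seed, so a checkpoint rebuilds bit-identically.
#' @param checkpoint a `dtf_checkpoint`
#' @param path output file
#' @return `path`, invisibly
#' @export
save_checkpoint <- function(checkpoint, path) {
  stopifnot(inherits(checkpoint, "dtf_checkpoint"))
  m <- checkpoint$model
  payload <- list(config = m$config, covariate_spec = m$covariate_spec,
                  ranges = m$ranges, seed = m$seed,
                  values = param_values(m$params),
                  rc = checkpoint$rc, log = checkpoint$log,
                  tau_trajectory = checkpoint$tau_trajectory)
  saveRDS(payload, path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file
#' @return a `dtf_checkpoint`
#' @export
load_checkpoint <- function(path) {
  payload <- readRDS(path)
  model <- dtf_model(payload$config, cohort = NULL, seed = payload$seed,
                     covariate_spec = payload$covariate_spec)
  model$ranges <- payload$ranges
  set_param_values(model$params, payload$values)
  structure(list(model = model, rc = payload$rc, log = payload$log,
                 tau_trajectory = payload$tau_trajectory),
            class = "dtf_checkpoint")
}
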