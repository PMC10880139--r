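# Performance and calibration metrics: balanced accuracy (mean per-class
# recall), expected calibration error (confidence-binned accuracy/confidence
# gap), and one-vs-one multiclass AUROC (Hand-Till construction).

#' Balanced accuracy
#'
#' Mean per-class recall, averaged over the classes present in `labels`
#' (absent classes contribute no 0-recall artifacts).
#' @param labels true class indices
#' @param predictions predicted class indices (same length)
#' @return value in `[0, 1]`
#' @export
balanced_accuracy <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions)) stop("length mismatch")
  classes <- sort(unique(labels))
  recalls <- vapply(classes, function(k) {
    mean(predictions[labels == k] == k)
  }, numeric(1L))
  mean(recalls)
}

#' Expected calibration error
#'
#' Predictions are binned by their max-probability confidence into `n_bins`
#' equal-width bins over (0, 1]; ECE is the sample-weighted mean absolute gap
#' between each bin's accuracy and mean confidence.
#' @param probabilities n x Nc matrix of predicted class probabilities (rows
#'   on the simplex)
#' @param labels 0-based true class indices of length n
#' @param n_bins number of confidence bins
#' @return value in `[0, 1]`
#' @export
expected_calibration_error <- function(probabilities, labels, n_bins = 10L) {
  p <- as.matrix(probabilities)
  n <- nrow(p)
  if (n == 0L) stop("empty input")
  if (any(abs(rowSums(p) - 1) > 1e-5)) {
    stop("probability rows must sum to 1")
  }
  conf <- apply(p, 1L, max)
  pred <- max.col(p, ties.method = "first") - 1L
  correct <- pred == labels
  # bin index over (0, 1]: bin b covers ((b-1)/B, b/B]
  bin <- pmax(ceiling(conf * n_bins), 1L)
  ece <- 0
  for (b in unique(bin)) {
    sel <- bin == b
    ece <- ece + (sum(sel) / n) * abs(mean(correct[sel]) - mean(conf[sel]))
  }
  ece
}

# AUROC of `scores` separating pos (label TRUE) from neg, by mean ranks
# (ties get 0.5 credit).
binary_auroc <- function(scores, is_pos) {
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-one multiclass AUROC (Hand-Till)
#'
#' Unweighted mean over ordered class pairs (i, j), i != j, of the AUROC of
#' the class-i probability column restricted to samples of classes i and j.
#' Pairs where either class is absent are skipped with a warning.
#' @param probabilities n x Nc matrix of class probabilities; column k scores
#'   class k-1
#' @param labels 0-based true class indices
#' @return value in `[0, 1]`, or `NA` if fewer than two classes are present
#' @export
multiclass_auroc_ovo <- function(probabilities, labels) {
  p <- as.matrix(probabilities)
  present <- sort(unique(labels))
  if (length(present) < 2L) {
    warning("fewer than two classes present; AUROC undefined")
    return(NA_real_)
  }
  all_classes <- 0:(ncol(p) - 1L)
  absent <- setdiff(all_classes, present)
  if (length(absent) > 0L) {
    warning("classes absent from labels, their pairs skipped: ",
            paste(absent, collapse = ", "))
  }
  total <- 0
  n_pairs <- 0L
  for (i in present) {
    for (j in present) {
      if (i == j) next
      sel <- labels %in% c(i, j)
      total <- total + binary_auroc(p[sel, i + 1L], labels[sel] == i)
      n_pairs <- n_pairs + 1L
    }
  }
  total / n_pairs
}

#' Assemble a per-horizon metrics report
#'
#' @param ba,ece,auroc numeric vectors of per-horizon values (NA where a
#'   horizon had no observed targets)
#' @param windows optional named list of horizon-index vectors (0-based) over
#'   which to average each metric, e.g. `list(first4 = 0:3)`
#' @return a `metrics_report`: data frame `$per_horizon` plus `$windows`
#' @export
metrics_report <- function(ba, ece, auroc, windows = NULL) {
  tt <- length(ba)
  per_horizon <- data.frame(horizon = 0:(tt - 1L), ba = ba, ece = ece,
                            auroc = auroc)
  win <- NULL
  if (!is.null(windows)) {
    win <- do.call(rbind, lapply(names(windows), function(nm) {
      idx <- windows[[nm]] + 1L
      data.frame(window = nm,
                 ba = mean(ba[idx], na.rm = TRUE),
                 ece = mean(ece[idx], na.rm = TRUE),
                 auroc = mean(auroc[idx], na.rm = TRUE))
    }))
  }
  structure(list(per_horizon = per_horizon, windows = win),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Per-horizon metrics:\n")
  print(x$per_horizon, row.names = FALSE, digits = 3)
  if (!is.null(x$windows)) {
    cat("Window averages:\n")
    print(x$windows, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Aggregate metrics reports over repeated seeds
#'
#' @param reports list of `metrics_report`s from runs with different seeds
#' @return data frame of per-horizon means and standard errors
#' @export
aggregate_metrics <- function(reports) {
  stopifnot(length(reports) >= 1L)
  mats <- lapply(c("ba", "ece", "auroc"), function(m) {
    do.call(rbind, lapply(reports, function(r) r$per_horizon[[m]]))
  })
  names(mats) <- c("ba", "ece", "auroc")
  n <- length(reports)
  out <- data.frame(horizon = reports[[1L]]$per_horizon$horizon)
  for (m in names(mats)) {
    out[[paste0(m, "_mean")]] <- colMeans(mats[[m]], na.rm = TRUE)
    out[[paste0(m, "_se")]] <- apply(mats[[m]], 2L, stats::sd, na.rm = TRUE) / sqrt(n)
  }
  out
}
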