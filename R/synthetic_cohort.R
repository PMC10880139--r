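# Synthetic longitudinal multimodal cohort generator.
#
# Each subject gets: a baseline grayscale image (2D) or volume (3D) whose
# geometry encodes the baseline severity grade via joint-space-narrowing-like
# band separation; four clinical covariates, one of which (bmi) shifts the
# latent progression rate; and an ordinal severity trajectory over T+1 time
# points produced by a Markov chain whose per-step advance probability is the
# subject's latent rate.  Follow-up labels and covariates can be masked at
# configurable rates; the baseline label is always observed.

#' Configuration for a synthetic longitudinal cohort
#'
#' @param n_subjects number of subjects to generate
#' @param t_future number of future time points T (>= 0); the trajectory has
#'   T+1 entries including the baseline diagnosis
#' @param n_classes integer vector of length T+1: number of ordinal classes
#'   per time point (each >= 2)
#' @param image_size `c(H, W)` for 2D images or `c(D, H, W)` for volumes;
#'   all dims >= 8
#' @param progression_rate_range interval from which each subject's base
#'   per-step advance probability is drawn uniformly
#' @param missing_target_rate probability that each non-baseline label is
#'   masked out
#' @param missing_covariate_rate probability that each covariate is missing
#' @param noise_sd standard deviation of additive Gaussian image noise
#'   (images are clipped back to `[0, 1]`)
#' @param progressive if `TRUE`, trajectories never decrease (the usual
#'   structural-severity assumption); if `FALSE`, small regressions occur
#' @param covariate_effect strength with which the standardized bmi covariate
#'   shifts the progression rate (0 makes all covariates uninformative)
#' @param class_prior prior over baseline classes (defaults to uniform)
#' @param seed RNG seed; the same config and seed give a bit-identical cohort
#' @return an object of class `trajectory_config`
#' @export
trajectory_config <- function(n_subjects,
                              t_future = 2L,
                              n_classes = rep(5L, t_future + 1L),
                              image_size = c(64L, 64L),
                              progression_rate_range = c(0.1, 0.5),
                              missing_target_rate = 0.3,
                              missing_covariate_rate = 0.1,
                              noise_sd = 0.05,
                              progressive = TRUE,
                              covariate_effect = 0.15,
                              class_prior = NULL,
                              seed = 1L) {
  if (!is.numeric(n_subjects) || n_subjects < 1) stop("n_subjects must be >= 1")
  if (t_future < 0) stop("t_future must be >= 0")
  if (length(n_classes) != t_future + 1L) {
    stop("n_classes must have length t_future + 1")
  }
  if (any(n_classes < 2L)) stop("all class counts must be >= 2")
  if (!length(image_size) %in% c(2L, 3L)) {
    stop("image_size must be (H, W) or (D, H, W)")
  }
  if (any(image_size < 8L)) stop("image dims must be >= 8")
  assert_prob(missing_target_rate, "missing_target_rate")
  assert_prob(missing_covariate_rate, "missing_covariate_rate")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  rr <- progression_rate_range
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] < 0 || rr[2] > 1) {
    stop("progression_rate_range must be an interval within [0, 1]")
  }
  nc0 <- n_classes[1L]
  if (is.null(class_prior)) class_prior <- rep(1 / nc0, nc0)
  if (length(class_prior) != nc0 || any(class_prior < 0)) {
    stop("class_prior must be a nonnegative vector of length n_classes[1]")
  }
  class_prior <- class_prior / sum(class_prior)
  # render_image needs enough vertical room for distinct gaps per grade
  hh <- if (length(image_size) == 2L) image_size[1L] else image_size[2L]
  if (max(n_classes) > floor(hh / 2) + 1L) {
    stop("image height too small to encode ", max(n_classes), " severity grades")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), t_future = as.integer(t_future),
    n_classes = as.integer(n_classes), image_size = as.integer(image_size),
    progression_rate_range = rr, missing_target_rate = missing_target_rate,
    missing_covariate_rate = missing_covariate_rate, noise_sd = noise_sd,
    progressive = isTRUE(progressive), covariate_effect = covariate_effect,
    class_prior = class_prior, seed = as.integer(seed)
  ), class = "trajectory_config")
}

#' Covariate schema used by the synthetic generator
#'
#' Two categorical variables (sex, site) and two continuous ones (age, bmi);
#' bmi linearly shifts the latent progression rate when `covariate_effect`
#' is nonzero, so it is the informative covariate multimodal fusion can learn.
#' @return a list of per-variable descriptors (name, type, levels)
#' @export
default_covariate_spec <- function() {
  list(
    list(name = "sex", type = "categorical", levels = c("0", "1")),
    list(name = "site", type = "categorical", levels = c("0", "1", "2")),
    list(name = "age", type = "continuous"),
    list(name = "bmi", type = "continuous")
  )
}

#' Sample an ordinal severity trajectory
#'
#' A Markov chain over ordinal states: at each of `t_future` steps the latent
#' state advances by one with probability `rate` (clipped at the top class).
#' When `progressive = FALSE` the state may also regress by one with
#' probability `rate / 4`.  The label at time t is the state clipped to the
#' class range of task t.
#'
#' @param baseline_class 0-based baseline grade, valid for task 0
#' @param rate per-step advance probability in `[0, 1]`
#' @param t_future number of future steps
#' @param n_classes integer vector of class counts per time point
#' @param progressive forbid regressions
#' @return integer vector of `t_future + 1` 0-based labels
#' @export
sample_trajectory <- function(baseline_class, rate, t_future, n_classes,
                              progressive = TRUE) {
  n_classes <- as.integer(n_classes)
  if (baseline_class < 0 || baseline_class >= n_classes[1L]) {
    stop("baseline_class out of range for task 0")
  }
  top <- max(n_classes) - 1L
  state <- as.integer(baseline_class)
  labels <- integer(t_future + 1L)
  labels[1L] <- min(state, n_classes[1L] - 1L)
  if (t_future > 0L) {
    for (t in seq_len(t_future)) {
      adv <- stats::rbinom(1L, 1L, rate)
      state <- min(state + adv, top)
      if (!progressive && adv == 0L) {
        reg <- stats::rbinom(1L, 1L, rate / 4)
        state <- max(state - reg, 0L)
      }
      labels[t + 1L] <- min(state, n_classes[t + 1L] - 1L)
    }
  }
  labels
}

#' Render a severity-encoded synthetic image
#'
#' Two bright horizontal bands whose separation (the "joint space") shrinks
#' strictly with the severity grade, plus `severity` small bright blobs on
#' the outer band edges at higher grades (osteophyte-like).  Deterministic
#' given its arguments: the morphology seed drives band placement jitter,
#' intensity variation, blob positions and the noise realization.
#'
#' @param severity 0-based grade
#' @param n_classes number of grades the geometry must distinguish
#' @param morphology_seed integer controlling per-subject shape variation
#' @param noise_sd additive Gaussian noise sd (image clipped to `[0, 1]`)
#' @param size `c(H, W)` or `c(D, H, W)`
#' @return numeric array in `[0, 1]` of dimension `size`
#' @export
render_image <- function(severity, n_classes, morphology_seed,
                         noise_sd = 0, size = c(64L, 64L)) {
  if (severity < 0 || severity >= n_classes) stop("severity out of range")
  is3d <- length(size) == 3L
  hw <- if (is3d) size[2:3] else size
  h <- hw[1L]; w <- hw[2L]
  gap_max <- floor(h / 2)
  step <- max(1L, floor((gap_max - 1L) / max(1L, n_classes - 1L)))
  gap <- gap_max - as.integer(severity) * step
  if (gap < 0L) stop("image height too small for this grade count")

  withr::with_seed(as.integer(morphology_seed), {
    th <- if (h >= 16L) 2L else 1L
    c0 <- floor(h / 2)
    # jitter limited so the widest-gap geometry still fits
    j_hi <- h - c0 - ceiling(gap_max / 2) - th
    j_lo <- -(c0 - floor(gap_max / 2) - th - 1L)
    jmax <- max(0L, min(2L, j_hi, -j_lo))
    jit <- if (jmax > 0L) sample(-jmax:jmax, 1L) else 0L
    cc <- c0 + jit
    band_int <- stats::runif(1L, 0.75, 0.9)
    margin <- max(1L, floor(w / 8) + sample(-1:1, 1L))
    cols <- margin:(w - margin)

    upper <- (cc - floor(gap / 2) - th):(cc - floor(gap / 2) - 1L)
    lower <- (cc + ceiling(gap / 2)):(cc + ceiling(gap / 2) + th - 1L)

    img <- matrix(0.1, h, w)
    img[upper, cols] <- band_int
    img[lower, cols] <- band_int

    # osteophyte-like blobs on the OUTER edges of the bands, one per grade,
    # kept away from the inter-band gap so the gap stays measurable
    if (severity > 0L) {
      for (b in seq_len(severity)) {
        col0 <- sample(cols[-length(cols)], 1L)
        on_top <- b %% 2L == 0L
        rows <- if (on_top) max(1L, upper[1L] - 2L):(upper[1L] - 1L)
                else (lower[length(lower)] + 1L):min(h, lower[length(lower)] + 2L)
        if (length(rows) > 0L && all(rows >= 1L & rows <= h)) {
          img[rows, col0:min(w, col0 + 1L)] <- 0.95
        }
      }
    }

    out <- if (is3d) {
      d <- size[1L]
      arr <- array(0, dim = size)
      for (k in seq_len(d)) arr[k, , ] <- img
      arr
    } else {
      img
    }
    if (noise_sd > 0) out <- out + stats::rnorm(length(out), 0, noise_sd)
    array(pmin(pmax(out, 0), 1), dim = if (is3d) size else c(h, w))
  })
}

#' Measure the inter-band gap of a rendered image
#'
#' Extracts the mean intensity profile over the central columns (central
#' in-plane region for volumes), thresholds it, and returns the number of
#' dark rows strictly between the two bright bands.
#' @param image array produced by [render_image()]
#' @return integer gap width in pixels
#' @export
measure_band_gap <- function(image) {
  img <- if (length(dim(image)) == 3L) image[ceiling(dim(image)[1L] / 2), , ] else image
  w <- ncol(img)
  cols <- max(1L, floor(w * 0.35)):ceiling(w * 0.65)
  profile <- rowMeans(img[, cols, drop = FALSE])
  thr <- (max(profile) + min(profile)) / 2
  bright <- profile > thr
  runs <- rle(bright)
  band_runs <- which(runs$values)
  if (length(band_runs) < 2L) return(0L)
  # gap = dark stretch between the first and last bright run
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  first_band_end <- ends[band_runs[1L]]
  last_band_start <- starts[band_runs[length(band_runs)]]
  as.integer(last_band_start - first_band_end - 1L)
}

sample_covariates <- function(effect) {
  sex <- sample(0:1, 1L)
  site <- sample(0:2, 1L)
  age <- min(max(stats::rnorm(1L, 60, 8), 40), 80)
  bmi <- min(max(stats::rnorm(1L, 27, 4), 18), 40)
  list(values = list(sex = sex, site = site, age = age, bmi = bmi),
       rate_shift = effect * (bmi - 27) / 4)
}

#' Generate a synthetic longitudinal cohort
#'
#' @param config a [trajectory_config()]
#' @return a list of `patient_record` objects (class `trajcast_cohort`) with
#'   the config and covariate schema attached as attributes.  Each record has
#'   `$image`, `$covariates` (named list, `NA` = missing), `$targets`
#'   (0-based grades, `NA` = masked), `$target_mask` and `$subject_id`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "trajectory_config"))
  withr::with_seed(config$seed, {
    records <- vector("list", config$n_subjects)
    for (i in seq_len(config$n_subjects)) {
      baseline <- sample(seq_along(config$class_prior), 1L,
                         prob = config$class_prior) - 1L
      cv <- sample_covariates(config$covariate_effect)
      rate <- stats::runif(1L, config$progression_rate_range[1L],
                           config$progression_rate_range[2L]) + cv$rate_shift
      rate <- min(max(rate, 0), 1)
      targets <- sample_trajectory(baseline, rate, config$t_future,
                                   config$n_classes, config$progressive)
      mseed <- sample.int(.Machine$integer.max, 1L)
      image <- render_image(baseline, config$n_classes[1L], mseed,
                            config$noise_sd, config$image_size)
      records[[i]] <- structure(list(
        subject_id = i,
        image = image,
        covariates = cv$values,
        targets = targets,
        target_mask = rep(TRUE, config$t_future + 1L),
        latent_rate = rate,
        morphology_seed = mseed
      ), class = "patient_record")
    }
    records <- apply_missingness(records, config$missing_target_rate,
                                 config$missing_covariate_rate)
    structure(records, class = "trajcast_cohort", config = config,
              covariate_spec = default_covariate_spec())
  })
}

#' Mask follow-up labels and covariates at random
#'
#' Each non-baseline target is masked independently with probability
#' `target_rate`; the baseline diagnosis (t = 0) is never masked, matching a
#' training regime where the baseline label is always supervised.  Each
#' covariate is set missing with probability `covariate_rate`.
#'
#' @param records list of `patient_record`s
#' @param target_rate probability of masking each follow-up label
#' @param covariate_rate probability of masking each covariate
#' @return the records with `targets`, `target_mask` and `covariates` updated
#' @export
apply_missingness <- function(records, target_rate, covariate_rate) {
  assert_prob(target_rate, "target_rate")
  assert_prob(covariate_rate, "covariate_rate")
  for (i in seq_along(records)) {
    rec <- records[[i]]
    tt <- length(rec$targets)
    if (tt > 1L) {
      drop <- stats::runif(tt - 1L) < target_rate
      rec$target_mask[-1L][drop] <- FALSE
      rec$targets[-1L][drop] <- NA_integer_
    }
    for (nm in names(rec$covariates)) {
      if (stats::runif(1L) < covariate_rate) rec$covariates[[nm]] <- NA
    }
    records[[i]] <- rec
  }
  records
}
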