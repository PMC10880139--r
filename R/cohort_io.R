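# Cohort serialization: images as PNG (2D) or NIfTI (3D), tabular data as one
# CSV row per subject, config as YAML.

#' Write a cohort to disk
#'
#' Layout: `dir/cohort.csv` (one row per subject: covariates, targets, masks,
#' latent rate), `dir/config.yaml`, and `dir/images/subject_<id>.png` (2D,
#' 8-bit grayscale) or `.nii` (3D).
#'
#' @param cohort a `trajcast_cohort`
#' @param dir output directory (created if absent)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "trajcast_cohort"))
  config <- attr(cohort, "config")
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  is3d <- length(config$image_size) == 3L

  rows <- lapply(cohort, function(rec) {
    tt <- length(rec$targets)
    row <- c(list(subject_id = rec$subject_id),
             rec$covariates,
             stats::setNames(as.list(rec$targets), paste0("target_", seq_len(tt) - 1L)),
             stats::setNames(as.list(rec$target_mask), paste0("observed_", seq_len(tt) - 1L)),
             list(latent_rate = rec$latent_rate,
                  morphology_seed = rec$morphology_seed))
    lapply(row, function(x) if (is.null(x) || (length(x) == 1L && is.na(x))) NA else x)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(df, file.path(dir, "cohort.csv"), row.names = FALSE)

  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))

  for (rec in cohort) {
    base <- file.path(img_dir, sprintf("subject_%05d", rec$subject_id))
    if (is3d) {
      RNifti::writeNifti(rec$image, paste0(base, ".nii"))
    } else {
      png::writePNG(rec$image, paste0(base, ".png"))
    }
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' 2D images round-trip through 8-bit PNG, so intensities are quantized to
#' 1/255; 3D volumes round-trip losslessly through NIfTI.
#' @param dir directory produced by [write_cohort()]
#' @return a `trajcast_cohort`
#' @export
read_cohort <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  config <- trajectory_config(
    n_subjects = cfg$n_subjects, t_future = cfg$t_future,
    n_classes = cfg$n_classes, image_size = cfg$image_size,
    progression_rate_range = unlist(cfg$progression_rate_range),
    missing_target_rate = cfg$missing_target_rate,
    missing_covariate_rate = cfg$missing_covariate_rate,
    noise_sd = cfg$noise_sd, progressive = cfg$progressive,
    covariate_effect = cfg$covariate_effect,
    class_prior = unlist(cfg$class_prior), seed = cfg$seed
  )
  df <- utils::read.csv(file.path(dir, "cohort.csv"))
  is3d <- length(config$image_size) == 3L
  tt <- config$t_future + 1L
  cov_names <- vapply(default_covariate_spec(), `[[`, "", "name")

  records <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    base <- file.path(dir, "images", sprintf("subject_%05d", row$subject_id))
    image <- if (is3d) {
      arr <- RNifti::readNifti(paste0(base, ".nii"))
      array(as.numeric(arr), dim = config$image_size)
    } else {
      img <- png::readPNG(paste0(base, ".png"))
      if (length(dim(img)) == 3L) img <- img[, , 1L]
      img
    }
    targets <- as.integer(row[paste0("target_", seq_len(tt) - 1L)])
    mask <- as.logical(row[paste0("observed_", seq_len(tt) - 1L)])
    covs <- lapply(cov_names, function(nm) {
      v <- row[[nm]]
      if (is.na(v)) NA else v
    })
    names(covs) <- cov_names
    structure(list(
      subject_id = row$subject_id, image = image, covariates = covs,
      targets = targets, target_mask = mask,
      latent_rate = row$latent_rate, morphology_seed = row$morphology_seed
    ), class = "patient_record")
  })
  structure(records, class = "trajcast_cohort", config = config,
            covariate_spec = default_covariate_spec())
}
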