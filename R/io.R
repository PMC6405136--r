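# Readers and writers: NIfTI / PNG images and masks, manifest and feature
# CSVs, YAML run configuration.

read_array <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (!file.exists(path)) {
    abort(paste("File not found:", path), class = "texrepro_error_io")
  }
  x <- switch(ext,
    nii = {
      a <- as.array(RNifti::readNifti(path))
      array(as.numeric(a), dim(a)) # strip NIfTI metadata attributes
    },
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- a[, , 1]
      a * 65535 # 16-bit integer scale
    },
    abort(paste("Unsupported image format:", path),
          class = "texrepro_error_io")
  )
  # accept trivial trailing dimensions (e.g. 128 x 128 x 1)
  d <- dim(x)
  if (length(d) > 2) {
    if (all(d[-(1:2)] == 1)) {
      dim(x) <- d[1:2]
    } else {
      abort("Only 2D (single-slice) images are supported.",
            class = "texrepro_error_io")
    }
  }
  x
}

#' Read an image/mask pair
#'
#' Reads a 2D intensity image and its binary ROI mask from NIfTI
#' (`.nii`/`.nii.gz`) or PNG files, validating shape agreement, mask
#' binarity and non-emptiness. A trailing singleton third dimension is
#' squeezed.
#'
#' @param image_path,mask_path File paths.
#' @return A `roi_image` list with `image` and `mask` matrices.
#' @export
read_roi <- function(image_path, mask_path) {
  image <- read_array(image_path)
  mask <- read_array(mask_path)
  if (!all(dim(image) == dim(mask))) {
    abort("Image and mask shapes differ.", class = "texrepro_error_shape")
  }
  mask <- round(mask / max(1, max(mask))) # tolerate 0/255-coded masks
  if (!all(mask %in% c(0, 1))) {
    abort("Mask is not binary.", class = "texrepro_error_mask")
  }
  storage.mode(mask) <- "integer"
  check_nonempty_mask(mask)
  structure(list(image = image, mask = mask), class = "roi_image")
}

write_array <- function(x, path, format = c("nifti", "png"), max_value = NULL) {
  format <- match.arg(format)
  if (format == "nifti") {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else {
    scale <- max_value %||% max(x, 1)
    png::writePNG(pmin(pmax(x / scale, 0), 1), path)
  }
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Writes every image and session mask as NIfTI (default) or PNG, plus a
#' manifest CSV with one row per (patient, region, sequence, session) and
#' the relative file paths.
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param format `"nifti"` or `"png"`.
#' @return The manifest tibble, invisibly.
#' @export
write_study <- function(study, dir, format = c("nifti", "png")) {
  format <- match.arg(format)
  ext <- if (format == "nifti") ".nii.gz" else ".png"
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  manifest <- study$manifest
  manifest$image_path <- file.path("images", paste0(manifest$roi, ext))
  manifest$mask_path <- file.path(
    "masks", paste0(manifest$roi, "_", manifest$session, ext))
  for (key in names(study$images)) {
    rng <- study$spec$sequence_intensity_ranges[[
      study$manifest$sequence[match(key, study$manifest$roi)]]]
    write_array(study$images[[key]],
                file.path(dir, "images", paste0(key, ext)),
                format, max_value = rng[2])
  }
  for (sess in names(study$masks)) {
    for (key in names(study$masks[[sess]])) {
      write_array(study$masks[[sess]][[key]],
                  file.path(dir, "masks", paste0(key, "_", sess, ext)),
                  format, max_value = 1)
    }
  }
  readr::write_csv(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' Write a long feature table as CSV
#'
#' @param features Feature tibble from [extract_features()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Run configuration serialization
#'
#' A run configuration bundles the dataset spec, discretization grids,
#' feature configuration, aggregation mode, reading design thresholds,
#' perturbation config and master seed, and round-trips through YAML so a
#' run can be archived next to its outputs.
#'
#' @param spec A [dataset_spec()].
#' @param schemes Scheme table (see [discretization_grid()]).
#' @param config Feature configuration name.
#' @param aggregation Aggregation mode or `NULL` for the config default.
#' @param normalize Logical, intensity normalization before extraction.
#' @param design A [reading_design()].
#' @param perturbation A [perturbation_config()].
#' @return A `run_config` list.
#' @export
run_config <- function(spec = dataset_spec(),
                       schemes = discretization_grid(),
                       config = "full", aggregation = NULL,
                       normalize = FALSE,
                       design = reading_design(),
                       perturbation = perturbation_config()) {
  structure(
    list(spec = unclass(spec), schemes = as.data.frame(as_scheme_table(schemes)),
         config = config, aggregation = aggregation, normalize = normalize,
         design = unclass(design), perturbation = unclass(perturbation)),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param x A `run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(x, path) {
  stopifnot(inherits(x, "run_config"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- run_config(
    spec = do.call(dataset_spec, raw$spec[setdiff(names(raw$spec),
                                                  "sequence_intensity_ranges")] |>
                     c(list(sequence_intensity_ranges =
                              raw$spec$sequence_intensity_ranges))),
    schemes = dplyr::bind_rows(raw$schemes),
    config = raw$config,
    aggregation = raw$aggregation,
    normalize = isTRUE(raw$normalize),
    design = do.call(reading_design, raw$design[
      setdiff(names(raw$design), "icc_pairs")] |>
        c(list(icc_pairs = raw$design$icc_pairs))),
    perturbation = do.call(perturbation_config, raw$perturbation)
  )
  cfg
}
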