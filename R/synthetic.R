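# Synthetic study generator: textured lesion images on sequence-specific
# intensity scales, one reference delineation per ROI and two further
# reading-session masks whose Dice with the reference is tuned to the
# study's inter- and intra-observer targets.

default_sequence_ranges <- function() {
  list("wDIXON-T2" = c(0, 1500),
       "ipDIXON-T2" = c(0, 2000),
       "pc-wDIXON-T1" = c(0, 1200),
       "pc-ipDIXON-T1" = c(0, 1800),
       "T1" = c(0, 800),
       # ADC in scanner storage units (1e-6 mm^2/s), so the same absolute
       # bin sizes remain meaningful on the parametric map
       "ADC" = c(0, 3000))
}

#' Synthetic dataset specification
#'
#' Defines the structure and statistical properties of a synthetic reading
#' study: `n_patients` x `regions_per_patient` x `n_sequences` ROIs per
#' reading session, three sessions (reader 1; reader 2, sessions 1 and 2),
#' elliptical lesions with spatially correlated texture mapped into
#' sequence-specific intensity ranges, and session masks perturbed so that
#' the mean inter-reader Dice approximates `reader_dice_target` and the mean
#' intra-reader Dice approximates `intra_dice_target`.
#'
#' @param n_patients Number of patients (default 37).
#' @param regions_per_patient Regions delineated per patient (default 2).
#' @param n_sequences Number of imaging sequences (default 6).
#' @param image_size Square image side in pixels (default 128).
#' @param lesion_radius_range Ellipse semi-axis range in pixels.
#' @param texture_correlation_length Gaussian correlation length (pixels) of
#'   the lesion texture field; 0 gives per-pixel independent noise.
#' @param sequence_intensity_ranges Named list of `(low, high)` intensity
#'   bounds, one per sequence.
#' @param reader_dice_target Mean Dice between reader 1 and reader 2 masks,
#'   in (0, 1] (default 0.84).
#' @param intra_dice_target Mean Dice between reader 2's two sessions
#'   (default 0.92).
#' @param dice_tolerance Tolerated deviation of the achieved study means
#'   (default 0.03).
#' @param seed Master integer seed; fully determines the study.
#' @return A `dataset_spec` list.
#' @export
dataset_spec <- function(n_patients = 37,
                         regions_per_patient = 2,
                         n_sequences = 6,
                         image_size = 128,
                         lesion_radius_range = c(12, 22),
                         texture_correlation_length = 3,
                         sequence_intensity_ranges = NULL,
                         reader_dice_target = 0.84,
                         intra_dice_target = 0.92,
                         dice_tolerance = 0.03,
                         seed = 1L) {
  ranges <- sequence_intensity_ranges %||%
    default_sequence_ranges()[seq_len(min(n_sequences, 6))]
  if (length(ranges) < n_sequences) {
    # recycle with scale doubling for specs asking for more sequences
    extra <- lapply(seq_len(n_sequences - length(ranges)),
                    function(k) c(0, 1000 * 2^k))
    names(extra) <- paste0("seq", length(ranges) + seq_along(extra))
    ranges <- c(ranges, extra)
  }
  if (is.null(names(ranges))) names(ranges) <- paste0("seq", seq_along(ranges))
  bad <- vapply(ranges, function(r) r[1] >= r[2], TRUE)
  if (any(bad)) {
    abort("Every intensity range needs low < high.",
          class = "texrepro_error_spec")
  }
  max_r <- max(lesion_radius_range)
  if (2 * (max_r + 8) >= image_size) {
    abort("Lesion does not fit in `image_size` with placement jitter.",
          class = "texrepro_error_spec")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         regions_per_patient = as.integer(regions_per_patient),
         n_sequences = as.integer(n_sequences),
         image_size = as.integer(image_size),
         lesion_radius_range = lesion_radius_range,
         texture_correlation_length = texture_correlation_length,
         sequence_intensity_ranges = ranges,
         reader_dice_target = reader_dice_target,
         intra_dice_target = intra_dice_target,
         dice_tolerance = dice_tolerance,
         seed = as.integer(seed)),
    class = "dataset_spec"
  )
}

roi_key <- function(patient, region, sequence) {
  sprintf("p%02d_r%d_s%d", patient, region, sequence)
}

# Deterministic lesion geometry for one (patient, region): shared across the
# sequences of that region so all sequences see the same anatomy.
roi_geometry <- function(spec, patient, region) {
  with_substream(spec$seed, paste0("geom_p", patient, "_r", region), {
    n <- spec$image_size
    center <- n / 2 + runif(2, -6, 6)
    radii <- sort(runif(2, spec$lesion_radius_range[1],
                        spec$lesion_radius_range[2]), decreasing = TRUE)
    angle <- runif(1, 0, pi)
    list(center = center, radii = radii, angle = angle)
  })
}

#' Generate one textured sequence image
#'
#' Produces a 2D image containing a roughly elliptical lesion with spatially
#' correlated texture (a Gaussian random field with the spec's correlation
#' length) mapped into the sequence's intensity range, over a darker
#' background at a distinct mean intensity. Deterministic in
#' `(spec$seed, patient, region, sequence)`.
#'
#' @param spec A [dataset_spec()].
#' @param patient,region,sequence 1-based integer identifiers.
#' @return List with `image` (numeric matrix) and `lesion_mask` (the
#'   reference delineation, binary matrix).
#' @export
generate_textured_image <- function(spec, patient, region, sequence) {
  geom <- roi_geometry(spec, patient, region)
  n <- spec$image_size
  rng <- spec$sequence_intensity_ranges[[sequence]]
  span <- rng[2] - rng[1]
  lesion <- ellipse_mask(n, n, geom$center, geom$radii, geom$angle)
  with_substream(spec$seed,
                 paste0("image_", roi_key(patient, region, sequence)), {
    z <- matrix(rnorm(n * n), n, n)
    if (spec$texture_correlation_length > 0) {
      # anisotropic per-ROI scales around the spec value: lesions differ in
      # coarseness and directionality, carrying between-subject texture
      # variance that survives relative (range-normalizing) discretization
      cl_r <- spec$texture_correlation_length * runif(1, 0.5, 2)
      cl_c <- spec$texture_correlation_length * runif(1, 0.5, 2)
      z <- gaussian_blur(z, cl_r, cl_c)
      z <- (z - mean(z)) / stats::sd(z)
    }
    # per-ROI lesion sub-range inside the sequence range; the background sits
    # below it at moderate contrast, as surrounding soft tissue does, so a
    # boundary change shifts the ROI minimum without collapsing the range
    lo_f <- 0.35 + runif(1, 0, 0.20)
    hi_f <- 0.65 + runif(1, 0, 0.30)
    a <- rng[1] + lo_f * span
    b <- rng[1] + hi_f * span
    tex <- a + (b - a) * stats::pnorm(z)
    # background: moderate-contrast soft tissue with a partial-volume halo
    # whose intensity decays from the lesion edge outward, so a shallow
    # delineation excursion picks up intensities just below the lesion
    # minimum while a deep one reaches darker tissue
    base <- rng[1] + 0.25 * span
    d_out <- as.matrix(EBImage::imageData(EBImage::distmap(1L - lesion)))
    halo <- (a - base) * exp(-d_out / 8)
    bg <- base + halo + 0.01 * span * matrix(rnorm(n * n), n, n)
    img <- ifelse(lesion == 1, tex, bg)
    img <- pmin(pmax(img, rng[1]), rng[2])
    list(image = img, lesion_mask = lesion)
  })
}

# Bisection of the elastic amplitude so that dice(reference, deformed)
# approximates `target`. The displacement field is fixed, so Dice is (near-)
# monotone in the amplitude.
deform_to_dice <- function(reference, field, target,
                           a_max = 40, tol = 0.004, iters = 18) {
  if (target >= 1) return(list(mask = reference, dice = 1, amplitude = 0))
  lo <- 0; hi <- a_max
  best <- reference; best_d <- 1
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    cand <- apply_displacement(reference, field, mid)
    d <- if (sum(cand) == 0) 0 else dice(cand, reference)
    if (abs(d - target) < abs(best_d - target) && sum(cand) > 0) {
      best <- cand; best_d <- d
    }
    if (abs(d - target) <= tol) break
    if (d > target) lo <- mid else hi <- mid
  }
  list(mask = best, dice = best_d, amplitude = mid)
}

#' Generate a synthetic reading study
#'
#' Builds the full synthetic dataset: one textured image and reference mask
#' (session `R1`) per (patient, region, sequence), and two further session
#' masks (`R2a`, `R2b`, reader 2) obtained by elastic deformation of the
#' reference with per-ROI amplitudes tuned by bisection to per-ROI Dice
#' targets drawn around `reader_dice_target`. The two reader-2 sessions use
#' correlated displacement fields so their mutual Dice lands near
#' `intra_dice_target`. If either achieved study mean deviates from its
#' target by more than `dice_tolerance`, generation fails with the achieved
#' means in the error.
#'
#' @param spec A [dataset_spec()].
#' @return A `synthetic_study`: named lists `images` and `ref_masks` keyed by
#'   ROI, `masks[[session]]` keyed by ROI for sessions `R1`, `R2a`, `R2b`, a
#'   `manifest` tibble, the achieved Dice table, and the spec.
#' @export
generate_study <- function(spec = dataset_spec()) {
  stopifnot(inherits(spec, "dataset_spec"))
  n <- spec$image_size
  rho <- if (spec$reader_dice_target >= 1) 1 else
    max(0, 1 - ((1 - spec$intra_dice_target) /
                  (1 - spec$reader_dice_target))^2 / 2)
  grid <- tidyr::expand_grid(
    patient = seq_len(spec$n_patients),
    region = seq_len(spec$regions_per_patient),
    sequence = seq_len(spec$n_sequences)
  )
  images <- list(); ref_masks <- list()
  masks <- list(R1 = list(), R2a = list(), R2b = list())
  dice_rows <- vector("list", nrow(grid))
  for (idx in seq_len(nrow(grid))) {
    p <- grid$patient[idx]; r <- grid$region[idx]; s <- grid$sequence[idx]
    key <- roi_key(p, r, s)
    gen <- generate_textured_image(spec, p, r, s)
    images[[key]] <- gen$image
    ref <- gen$lesion_mask
    ref_masks[[key]] <- ref
    masks$R1[[key]] <- ref
    if (spec$reader_dice_target >= 1) {
      masks$R2a[[key]] <- ref
      masks$R2b[[key]] <- ref
      dice_rows[[idx]] <- tibble(patient = p, region = r, sequence = s,
                                 dice_r1_r2a = 1, dice_r1_r2b = 1,
                                 dice_r2a_r2b = 1)
      next
    }
    sess <- with_substream(spec$seed, paste0("readerB_", key), {
      t_a <- min(0.995, max(0.70, rnorm(1, spec$reader_dice_target, 0.025)))
      t_b <- min(0.995, max(0.70, rnorm(1, spec$reader_dice_target, 0.025)))
      fa <- random_displacement_field(n, n, 6)
      fr <- random_displacement_field(n, n, 6)
      fb <- list(u = rho * fa$u + sqrt(1 - rho^2) * fr$u,
                 v = rho * fa$v + sqrt(1 - rho^2) * fr$v)
      list(a = deform_to_dice(ref, fa, t_a),
           b = deform_to_dice(ref, fb, t_b))
    })
    masks$R2a[[key]] <- sess$a$mask
    masks$R2b[[key]] <- sess$b$mask
    dice_rows[[idx]] <- tibble(
      patient = p, region = r, sequence = s,
      dice_r1_r2a = sess$a$dice,
      dice_r1_r2b = sess$b$dice,
      dice_r2a_r2b = dice(sess$a$mask, sess$b$mask)
    )
  }
  dices <- dplyr::bind_rows(dice_rows)
  inter_mean <- mean(c(dices$dice_r1_r2a, dices$dice_r1_r2b))
  intra_mean <- mean(dices$dice_r2a_r2b)
  if (abs(inter_mean - spec$reader_dice_target) > spec$dice_tolerance ||
      abs(intra_mean - spec$intra_dice_target) > spec$dice_tolerance) {
    abort(sprintf(
      "Perturbation tuning missed the Dice targets: achieved inter %.3f (target %.2f), intra %.3f (target %.2f).",
      inter_mean, spec$reader_dice_target,
      intra_mean, spec$intra_dice_target),
      class = "texrepro_error_dice_target")
  }
  manifest <- tidyr::expand_grid(grid,
                                 session = c("R1", "R2a", "R2b")) |>
    dplyr::mutate(
      roi = roi_key(.data$patient, .data$region, .data$sequence),
      sequence_name = names(spec$sequence_intensity_ranges)[.data$sequence]
    )
  structure(
    list(images = images, ref_masks = ref_masks, masks = masks,
         manifest = manifest, dice_table = dices,
         achieved = c(inter = inter_mean, intra = intra_mean),
         spec = spec),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>", length(x$images), "ROIs x 3 sessions;",
      sprintf("mean inter-reader Dice %.3f, intra %.3f\n",
              x$achieved["inter"], x$achieved["intra"]))
  invisible(x)
}

#' Extract texture features for a whole study
#'
#' Runs [extract_roi_features()] for every ROI, session and discretization
#' scheme and returns a long tibble.
#'
#' @param study A [generate_study()] result (or compatible list).
#' @param schemes A [discretization_grid()]-style tibble, a character vector
#'   of scheme strings, or a list of schemes.
#' @param config Feature configuration (`"full"` or `"inhouse"`).
#' @param aggregation Aggregation mode; `NULL` uses the configuration's
#'   default.
#' @param sessions Sessions to extract (default all in the study).
#' @param normalize If `TRUE`, apply [normalize_intensity()] to every image
#'   except those of sequences named `"ADC"` (parametric maps keep their
#'   absolute scale).
#' @return Long tibble: `patient`, `region`, `sequence`, `roi`, `session`,
#'   `scheme`, `method`, `parameter`, `feature`, `value`.
#' @export
extract_features <- function(study, schemes = discretization_grid(),
                             config = c("full", "inhouse"),
                             aggregation = NULL,
                             sessions = NULL,
                             normalize = FALSE) {
  config <- match.arg(config)
  aggregation <- aggregation %||% default_aggregation(config)
  schemes <- as_scheme_table(schemes)
  sessions <- sessions %||% names(study$masks)
  seq_names <- names(study$spec$sequence_intensity_ranges)
  rois <- dplyr::distinct(study$manifest, .data$patient, .data$region,
                          .data$sequence, .data$roi)
  out <- vector("list", nrow(rois) * length(sessions) * nrow(schemes))
  k <- 0L
  for (i in seq_len(nrow(rois))) {
    key <- rois$roi[i]
    img <- study$images[[key]]
    is_adc <- !is.null(seq_names) &&
      identical(seq_names[rois$sequence[i]], "ADC")
    img_use <- if (normalize && !is_adc) normalize_intensity(img) else img
    for (sess in sessions) {
      mask <- study$masks[[sess]][[key]]
      for (j in seq_len(nrow(schemes))) {
        vals <- extract_roi_features(img_use, mask,
                                     discretization_scheme(schemes$method[j],
                                                           schemes$parameter[j]),
                                     config = config,
                                     aggregation = aggregation)
        k <- k + 1L
        out[[k]] <- tibble(
          patient = rois$patient[i], region = rois$region[i],
          sequence = rois$sequence[i], roi = key, session = sess,
          scheme = schemes$scheme[j], method = schemes$method[j],
          parameter = schemes$parameter[j],
          feature = names(vals), value = unname(vals)
        )
      }
    }
  }
  dplyr::bind_rows(out)
}

as_scheme_table <- function(schemes) {
  if (is.data.frame(schemes)) {
    stopifnot(all(c("method", "parameter") %in% names(schemes)))
    if (!"scheme" %in% names(schemes)) {
      schemes$scheme <- sprintf("%s:%g", schemes$method, schemes$parameter)
    }
    return(schemes)
  }
  if (is.character(schemes)) {
    schemes <- lapply(schemes, as_discretization_scheme)
  }
  if (inherits(schemes, "discretization_scheme")) schemes <- list(schemes)
  tibble(
    scheme = vapply(schemes, format, ""),
    method = vapply(schemes, function(s) s$method, ""),
    parameter = vapply(schemes, function(s) s$parameter, 0)
  )
}
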