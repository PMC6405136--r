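# Simulation of delineation variability: morphological + elastic
# perturbations of a reference binary mask, Dice computation, and selection
# of one perturbed mask per Dice stratum.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` for two binary masks of the same shape.
#'
#' @param mask_a,mask_b Binary matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @examples
#' a <- matrix(0, 5, 5); a[2:4, 2:4] <- 1
#' dice(a, a) # 1
#' @export
dice <- function(mask_a, mask_b) {
  check_mask(mask_a, "mask_a"); check_mask(mask_b, "mask_b")
  if (!all(dim(mask_a) == dim(mask_b))) {
    abort("Masks must have identical shape.", class = "texrepro_error_shape")
  }
  sa <- sum(mask_a); sb <- sum(mask_b)
  if (sa + sb == 0) {
    abort("Dice is undefined for two empty masks.",
          class = "texrepro_error_empty_roi")
  }
  2 * sum(mask_a * mask_b) / (sa + sb)
}

#' Perturbation configuration
#'
#' Parameters of the delineation-variability simulator: per candidate, a
#' binary opening and/or closing with radius drawn from the configured
#' ranges is applied in random order, followed by an elastic deformation (a
#' Gaussian-smoothed random displacement field with amplitude drawn from
#' `elastic_amplitude_range`) and nearest-neighbour re-binarization.
#'
#' Candidates are binned by their Dice coefficient with the reference in
#' intervals of `bin_width` from 1.0 down to `dice_floor`; one candidate per
#' bin below 1.0 is retained (Dice 1.0 is the untransformed reference).
#' Defaults cover the Dice range 0.65-0.95 for lesion-sized masks.
#'
#' @param n_candidates Number of perturbed candidates to draw (default 5000).
#' @param opening_radius_range,closing_radius_range Radius ranges in pixels
#'   for the morphological operations (radius 0 = skip).
#' @param elastic_amplitude_range Displacement amplitude range in pixels.
#' @param elastic_smoothing Gaussian sigma (pixels) of the displacement field.
#' @param dice_floor Lower edge of the lowest Dice bin (default 0.65).
#' @param bin_width Dice bin width (default 0.05).
#' @param area_ratio_bounds Accept candidates whose area stays within these
#'   multiples of the reference area (automatic plausibility check).
#' @param seed Integer seed for the candidate stream.
#' @return A `perturbation_config` list.
#' @export
perturbation_config <- function(n_candidates = 5000,
                                opening_radius_range = c(0, 3),
                                closing_radius_range = c(0, 3),
                                elastic_amplitude_range = c(0, 18),
                                elastic_smoothing = 6,
                                dice_floor = 0.65,
                                bin_width = 0.05,
                                area_ratio_bounds = c(0.4, 2.5),
                                seed = 1L) {
  stopifnot(
    n_candidates >= 1,
    all(opening_radius_range >= 0), all(closing_radius_range >= 0),
    all(elastic_amplitude_range >= 0), elastic_smoothing > 0,
    dice_floor > 0, dice_floor < 1, bin_width > 0
  )
  structure(
    list(n_candidates = n_candidates,
         opening_radius_range = opening_radius_range,
         closing_radius_range = closing_radius_range,
         elastic_amplitude_range = elastic_amplitude_range,
         elastic_smoothing = elastic_smoothing,
         dice_floor = dice_floor,
         bin_width = bin_width,
         area_ratio_bounds = area_ratio_bounds,
         seed = as.integer(seed)),
    class = "perturbation_config"
  )
}

# Smoothed unit-variance displacement fields for a mask shape.
random_displacement_field <- function(nr, nc, smoothing) {
  u <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), smoothing)
  v <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), smoothing)
  list(u = u / stats::sd(u), v = v / stats::sd(v))
}

# Apply displacement fields scaled by `amplitude` to a binary mask with
# nearest-neighbour lookup (re-binarization).
apply_displacement <- function(mask, field, amplitude) {
  if (amplitude == 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sr <- pmin(pmax(round(r + amplitude * field$u), 1), nr)
  sc <- pmin(pmax(round(c_ + amplitude * field$v), 1), nc)
  out <- matrix(mask[cbind(as.vector(sr), as.vector(sc))], nr, nc)
  storage.mode(out) <- "integer"
  out
}

morph_disc <- function(mask, radius, op) {
  if (radius < 1) return(mask)
  img <- EBImage::Image(mask)
  brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
  out <- if (op == "opening") EBImage::opening(img, brush) else
    EBImage::closing(img, brush)
  m <- as.matrix(EBImage::imageData(out))
  storage.mode(m) <- "integer"
  m
}

#' Perturb a reference mask once
#'
#' Draws one simulated delineation: binary opening and/or closing (random
#' order, radii drawn from the configured ranges) followed by an elastic
#' deformation. Candidates that empty the mask are discarded and resampled.
#'
#' @param reference Non-empty binary mask matrix.
#' @param config A [perturbation_config()].
#' @param seed Integer seed; the same seed reproduces the same mask.
#' @return A binary mask of the same shape.
#' @export
perturb_mask <- function(reference, config = perturbation_config(), seed = 1L) {
  check_nonempty_mask(reference, "reference")
  with_substream(seed, "perturb", {
    for (try in 1:50) {
      cand <- perturb_once(reference, config)
      if (sum(cand) > 0) return(cand)
    }
    abort("Perturbation repeatedly emptied the mask; reduce the amplitude.",
          class = "texrepro_error_perturb")
  })
}

perturb_once <- function(reference, config) {
  r_open <- round(runif(1, config$opening_radius_range[1],
                        config$opening_radius_range[2]))
  r_close <- round(runif(1, config$closing_radius_range[1],
                         config$closing_radius_range[2]))
  amp <- runif(1, config$elastic_amplitude_range[1],
               config$elastic_amplitude_range[2])
  m <- reference
  ops <- sample(c("opening", "closing"))
  for (op in ops) {
    m <- morph_disc(m, if (op == "opening") r_open else r_close, op)
  }
  field <- random_displacement_field(nrow(m), ncol(m), config$elastic_smoothing)
  apply_displacement(m, field, amp)
}

#' Select one simulated mask per Dice bin
#'
#' Bins candidate masks by Dice with the reference into half-open intervals
#' `[lo, lo + bin_width)` with lower edges from `dice_floor` up to
#' `1 - bin_width`, and draws one candidate uniformly at random per bin.
#' Dice 1.0 is reserved for the untransformed reference and is not a bin.
#'
#' @param reference Non-empty binary mask.
#' @param candidates List of candidate binary masks.
#' @param config A [perturbation_config()] (bin definition and seed).
#' @param dices Optional precomputed Dice values of `candidates`.
#' @return A `simulated_roi_set`: reference, the selected masks keyed by the
#'   bin's nominal Dice (lower edge, e.g. "0.65".."0.95"), their achieved
#'   Dice values, and the full candidate Dice vector.
#' @export
select_by_dice_bins <- function(reference, candidates,
                                config = perturbation_config(),
                                dices = NULL) {
  check_nonempty_mask(reference, "reference")
  dices <- dices %||% vapply(candidates, dice, 0, mask_b = reference)
  lo_edges <- seq(config$dice_floor, 1 - config$bin_width,
                  by = config$bin_width)
  sel <- with_substream(config$seed, "dice-bin-select", {
    lapply(lo_edges, function(lo) {
      in_bin <- which(dices >= lo & dices < lo + config$bin_width)
      if (length(in_bin) == 0) {
        abort(sprintf(
          "No candidate in Dice bin [%.2f, %.2f): increase n_candidates or widen the perturbation ranges.",
          lo, lo + config$bin_width), class = "texrepro_error_empty_bin")
      }
      pick <- in_bin[sample.int(length(in_bin), 1)]
      list(mask = candidates[[pick]], dice = dices[pick])
    })
  })
  names(sel) <- format(lo_edges, nsmall = 2)
  structure(
    list(reference = reference, selected = sel,
         achieved_dices = vapply(sel, `[[`, 0, "dice"),
         candidate_dices = dices, config = config),
    class = "simulated_roi_set"
  )
}

#' Simulate Dice-stratified delineations of a reference mask
#'
#' Generates `config$n_candidates` perturbed masks, computes their Dice
#' coefficients with the reference, and retains one mask per 0.05-wide Dice
#' bin between `dice_floor` and 1 (7 masks with the defaults). Candidates
#' violating the area plausibility bounds are discarded.
#'
#' @inheritParams select_by_dice_bins
#' @return A `simulated_roi_set` (see [select_by_dice_bins()]).
#' @export
simulate_delineations <- function(reference, config = perturbation_config()) {
  check_nonempty_mask(reference, "reference")
  ref_area <- sum(reference)
  bounds <- config$area_ratio_bounds * ref_area
  candidates <- vector("list", config$n_candidates)
  dices <- numeric(config$n_candidates)
  with_substream(config$seed, "candidates", {
    for (k in seq_len(config$n_candidates)) {
      repeat {
        cand <- perturb_once(reference, config)
        a <- sum(cand)
        if (a > 0 && a >= bounds[1] && a <= bounds[2]) break
      }
      candidates[[k]] <- cand
      dices[k] <- dice(cand, reference)
    }
  })
  select_by_dice_bins(reference, candidates, config, dices)
}

#' @export
print.simulated_roi_set <- function(x, ...) {
  cat("<simulated_roi_set>", length(x$selected), "Dice-stratified masks\n")
  print(round(x$achieved_dices, 3))
  invisible(x)
}
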