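#' Intensity normalization
#'
#' Normalizes an image the way the replication experiment prescribes:
#' center by the mean and scale by the (population) standard deviation, clip
#' values beyond three standard deviations to the +/- 3 bound, shift so the
#' minimum is zero, then rescale affinely to `range` (by default the image's
#' own pre-normalization intensity range, standing in for the common range
#' of the sequence).
#'
#' Outliers are clipped rather than dropped so the ROI geometry (run and
#' zone structure) is preserved; this is an interpretation of "excluded"
#' and is the package's documented choice.
#'
#' Not intended for parametric maps (e.g. ADC) whose values are already on
#' an absolute physical scale.
#'
#' @param image Numeric matrix with more than one distinct value.
#' @param range Length-2 numeric target range; default `range(image)`.
#' @return Normalized numeric matrix spanning `range`.
#' @examples
#' normalize_intensity(matrix(c(0, 10), 2, 2)) # unchanged up to rescaling
#' @export
normalize_intensity <- function(image, range = NULL) {
  if (!is.numeric(image)) {
    abort("`image` must be numeric.", class = "texrepro_error_input")
  }
  vals <- image[is.finite(image)]
  if (length(unique(vals)) < 2) {
    abort("Constant image: intensity normalization is undefined.",
          class = "texrepro_error_degenerate")
  }
  range <- range %||% base::range(vals)
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2)) # population SD
  z <- (image - mu) / sigma
  z <- pmin(pmax(z, -3), 3)
  z <- z - min(z, na.rm = TRUE) # non-negative
  span <- max(z, na.rm = TRUE)
  out <- range[1] + z / span * (range[2] - range[1])
  if (is.matrix(image)) dim(out) <- dim(image)
  out
}
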