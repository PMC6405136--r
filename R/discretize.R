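#' Discretization schemes
#'
#' A discretization scheme maps continuous pixel intensities inside an ROI to
#' integer gray levels before texture-matrix construction. Two conventions
#' are supported:
#'
#' * **FBS** (fixed bin size, "absolute"): a new bin every `parameter`
#'   intensity units, anchored at 0, then shifted so the lowest occupied bin
#'   is level 1. Levels depend only on absolute intensities, not on which
#'   pixels fall inside the ROI.
#' * **FBN** (fixed bin number, "relative"): the ROI's own intensity range is
#'   split into `parameter` equal bins, so levels always span 1..BN and are
#'   invariant under any increasing affine rescaling of the intensities.
#'
#' @param method `"fbs"` or `"fbn"`.
#' @param parameter Bin size in intensity units (FBS, positive) or integer
#'   bin count (FBN, at least 2).
#' @return A `discretization_scheme` object (also accepted wherever a scheme
#'   string such as `"fbs:25"` is accepted).
#' @examples
#' discretization_scheme("fbs", 25)
#' as_discretization_scheme("fbn:64")
#' @export
discretization_scheme <- function(method = c("fbs", "fbn"), parameter) {
  method <- match.arg(tolower(method), c("fbs", "fbn"))
  if (!is.numeric(parameter) || length(parameter) != 1 || !is.finite(parameter)) {
    abort("`parameter` must be a single finite number.",
          class = "texrepro_error_scheme")
  }
  if (method == "fbs" && parameter <= 0) {
    abort("FBS bin size must be > 0.", class = "texrepro_error_scheme")
  }
  if (method == "fbn" && (parameter < 2 || parameter != round(parameter))) {
    abort("FBN bin number must be an integer >= 2.",
          class = "texrepro_error_scheme")
  }
  structure(
    list(method = method, parameter = unname(parameter)),
    class = "discretization_scheme"
  )
}

#' @rdname discretization_scheme
#' @param x A scheme, or a string like `"fbs:25"` / `"fbn:64"`.
#' @export
as_discretization_scheme <- function(x) {
  if (inherits(x, "discretization_scheme")) return(x)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(x, ":", fixed = TRUE)[[1]]
    if (length(parts) == 2) {
      return(discretization_scheme(parts[1], as.numeric(parts[2])))
    }
  }
  abort("Cannot interpret `x` as a discretization scheme (use e.g. \"fbs:25\").",
        class = "texrepro_error_scheme")
}

#' @export
format.discretization_scheme <- function(x, ...) {
  sprintf("%s:%g", x$method, x$parameter)
}

#' @export
print.discretization_scheme <- function(x, ...) {
  cat("<discretization_scheme>", format(x), "\n")
  invisible(x)
}

#' Discretization grids under study
#'
#' The grids compared in the analysis: six absolute bin sizes and eight
#' relative bin numbers.
#'
#' @param fbs Numeric vector of bin sizes (default `c(1, 5, 10, 20, 25, 50)`).
#' @param fbn Integer vector of bin numbers
#'   (default `c(8, 16, 32, 64, 128, 256, 512, 1024)`).
#' @return A tibble with columns `scheme` (label), `method`, `parameter`.
#' @export
discretization_grid <- function(fbs = c(1, 5, 10, 20, 25, 50),
                                fbn = c(8, 16, 32, 64, 128, 256, 512, 1024)) {
  tibble(
    method = c(rep("fbs", length(fbs)), rep("fbn", length(fbn))),
    parameter = c(fbs, fbn)
  ) |>
    dplyr::mutate(scheme = sprintf("%s:%g", .data$method, .data$parameter),
                  .before = 1)
}

#' Fixed-bin-size (absolute) discretization
#'
#' Assigns level `ceiling(I/BS)` to every intensity, anchored at 0, then
#' shifts so the minimum occupied level is 1:
#' `ceil(I/BS) - min(ceil(I/BS)) + 1`.
#'
#' @param intensities Numeric vector (or matrix with `NA` outside the mask)
#'   of intensities of the masked pixels.
#' @param bin_size Positive bin size in intensity units.
#' @return Integer levels, same shape as the input; `NA` entries propagate.
#' @examples
#' fbs_discretize(c(12, 27, 41), 10) # 1 2 4
#' @export
fbs_discretize <- function(intensities, bin_size) {
  scheme <- discretization_scheme("fbs", bin_size)
  vals <- intensities[!is.na(intensities)]
  if (length(vals) == 0) {
    abort("No masked intensities to discretize (empty ROI).",
          class = "texrepro_error_empty_roi")
  }
  b <- ceiling(intensities / scheme$parameter)
  out <- b - min(b, na.rm = TRUE) + 1
  storage.mode(out) <- "integer"
  out
}

#' Fixed-bin-number (relative) discretization
#'
#' Splits the ROI's intensity range into `bin_number` equal bins, starting
#' from the minimum of the segmented area: the minimum maps to level 1, any
#' other intensity to `ceil(BN * (I - min) / (max - min))`. A constant ROI
#' (zero range) maps every pixel to level 1.
#'
#' @param intensities Numeric vector (or matrix with `NA` outside the mask).
#' @param bin_number Integer bin count, at least 2.
#' @return Integer levels in `1..bin_number`, same shape as input.
#' @examples
#' fbn_discretize(c(10, 20, 30), 2) # 1 1 2
#' @export
fbn_discretize <- function(intensities, bin_number) {
  scheme <- discretization_scheme("fbn", bin_number)
  bn <- scheme$parameter
  vals <- intensities[!is.na(intensities)]
  if (length(vals) == 0) {
    abort("No masked intensities to discretize (empty ROI).",
          class = "texrepro_error_empty_roi")
  }
  lo <- min(vals)
  hi <- max(vals)
  if (hi == lo) {
    out <- ifelse(is.na(intensities), NA_integer_, 1L)
    if (is.matrix(intensities)) dim(out) <- dim(intensities)
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- ifelse(intensities == lo, 1, ceiling(bn * (intensities - lo) / (hi - lo)))
  storage.mode(out) <- "integer"
  out
}

#' Discretize the masked pixels of an image
#'
#' Applies a scheme to `image` restricted to `mask`, returning an integer
#' level matrix with `NA` outside the mask — the form consumed by the
#' texture-matrix builders.
#'
#' @param image Numeric matrix of intensities.
#' @param mask Binary matrix of the same shape.
#' @param scheme A [discretization_scheme()] or string such as `"fbn:64"`.
#' @return Integer matrix of gray levels (`NA` outside the mask) with
#'   attribute `scheme`.
#' @export
discretize_roi <- function(image, mask, scheme) {
  scheme <- as_discretization_scheme(scheme)
  check_nonempty_mask(mask)
  if (!is.matrix(image) || !all(dim(image) == dim(mask))) {
    abort("`image` and `mask` must be matrices of identical shape.",
          class = "texrepro_error_shape")
  }
  masked <- image
  masked[mask == 0] <- NA_real_
  levels <- if (scheme$method == "fbs") {
    fbs_discretize(masked, scheme$parameter)
  } else {
    fbn_discretize(masked, scheme$parameter)
  }
  attr(levels, "scheme") <- scheme
  levels
}
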