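# Shared low-level helpers: deterministic substreams, Gaussian smoothing,
# mask geometry. All randomness in the package flows through substream_seed()
# so that a single integer seed reproduces a full study.

# Deterministic 31-bit sub-seed derived from a master seed and a label.
# Arithmetic stays below 2^53 so doubles are exact.
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  m <- 2147483647 # 2^31 - 1
  h <- (seed %% m)
  codes <- utf8ToInt(paste0("texrepro::", label))
  for (ch in codes) h <- (h * 48271 + ch) %% m
  as.integer(h)
}

# Evaluate expr with the global RNG seeded from (seed, label), restoring the
# caller's RNG state afterwards.
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  force(expr)
}

# Separable Gaussian smoothing via banded Toeplitz matrices, cached per
# (n, sigma). Replicated ("nearest") boundary handling keeps the field
# variance roughly uniform near edges.
.blur_cache <- new.env(parent = emptyenv())

gaussian_band <- function(n, sigma) {
  key <- paste0(n, "_", signif(sigma, 10))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half)^2) / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (d in seq(-half, half)) {
    idx <- seq_len(n)
    src <- pmin(pmax(idx + d, 1L), n)
    K[cbind(idx, src)] <- K[cbind(idx, src)] + k[d + half + 1L]
  }
  K <- K / rowSums(K)
  .blur_cache[[key]] <- K
  K
}

gaussian_blur <- function(x, sigma, sigma_col = sigma) {
  if (sigma <= 0 && sigma_col <= 0) return(x)
  out <- x
  if (sigma > 0) out <- gaussian_band(nrow(x), sigma) %*% out
  if (sigma_col > 0) out <- out %*% t(gaussian_band(ncol(x), sigma_col))
  out
}

is_binary_mask <- function(mask) {
  is.matrix(mask) && all(mask %in% c(0, 1))
}

check_mask <- function(mask, arg = "mask") {
  if (!is_binary_mask(mask)) {
    abort(sprintf("`%s` must be a matrix with values in {0, 1}.", arg),
          class = "texrepro_error_mask")
  }
  invisible(mask)
}

check_nonempty_mask <- function(mask, arg = "mask") {
  check_mask(mask, arg)
  if (sum(mask) == 0) {
    abort(sprintf("`%s` selects no pixels (empty ROI).", arg),
          class = "texrepro_error_empty_roi")
  }
  invisible(mask)
}

# Filled ellipse mask, rotated by `angle` (radians), on an nr x nc grid.
ellipse_mask <- function(nr, nc, center, radii, angle = 0) {
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  dr <- r - center[1]
  dc <- c_ - center[2]
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  m <- (u / radii[1])^2 + (v / radii[2])^2 <= 1
  storage.mode(m) <- "integer"
  m
}
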