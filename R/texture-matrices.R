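# Texture matrix construction on a discretized ROI.
#
# A discretized ROI is an integer matrix of gray levels with NA outside the
# mask (see discretize_roi()). All matrices are stored sparsely as a
# data.frame with columns i (gray level), j (second index: gray level for
# GLCM, run length for GLRLM, zone size for GLSZM, dependence size for GLDM)
# and n (count). Empty rows/columns carry no information for any of the
# implemented features, so the sparse form is exact.

# The four unique in-plane directions at distance 1, as (drow, dcol) offsets.
texture_directions <- function() {
  list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
}

direction_label <- function(off) paste0("d", off[1], "_", off[2])

sparse_counts <- function(i, j, w = NULL) {
  if (length(i) == 0) {
    return(data.frame(i = integer(), j = integer(), n = numeric()))
  }
  jmax <- max(j)
  key <- (as.numeric(i) - 1) * (jmax + 1) + as.numeric(j)
  ku <- sort(unique(key))
  idx <- match(key, ku)
  n <- if (is.null(w)) tabulate(idx, length(ku)) else
    as.numeric(rowsum(w, idx)[, 1])
  data.frame(
    i = as.integer((ku - 1) %/% (jmax + 1)) + 1L,
    j = as.integer(ku %% (jmax + 1)),
    n = as.numeric(n)
  )
}

shift_pairs <- function(levels, off) {
  nr <- nrow(levels); nc <- ncol(levels)
  dr <- off[1]; dc <- off[2]
  r0 <- seq_len(nr - abs(dr)) + max(0L, -dr)
  c0 <- seq_len(nc - abs(dc)) + max(0L, -dc)
  a <- levels[r0, c0, drop = FALSE]
  b <- levels[r0 + dr, c0 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

#' Gray-level co-occurrence matrix for one direction
#'
#' Symmetric counts of level pairs at distance 1 along `direction`; pairs
#' with either pixel outside the mask are ignored.
#'
#' @param levels Integer level matrix with `NA` outside the mask.
#' @param direction Offset `c(drow, dcol)`, one of (0,1), (1,1), (1,0), (1,-1).
#' @return Sparse count data.frame with columns `i`, `j`, `n`.
#' @export
build_glcm <- function(levels, direction = c(0L, 1L)) {
  p <- shift_pairs(levels, direction)
  # symmetric: count each ordered pair both ways
  sparse_counts(c(p$a, p$b), c(p$b, p$a))
}

# Split the matrix into traversal lines for a direction and return the list
# of level vectors (NA marks mask breaks).
direction_lines <- function(levels, off) {
  nr <- nrow(levels); nc <- ncol(levels)
  if (all(off == c(0L, 1L))) {
    return(split(as.vector(t(levels)), rep(seq_len(nr), each = nc)))
  }
  if (all(off == c(1L, 0L))) {
    return(split(as.vector(levels), rep(seq_len(nc), each = nr)))
  }
  r <- matrix(seq_len(nr), nr, nc)
  c_ <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  f <- if (all(off == c(1L, 1L))) c_ - r else c_ + r
  split(as.vector(levels), as.vector(f))
}

#' Gray-level run-length matrix for one direction
#'
#' Counts of maximal runs of identical levels along the direction; the mask
#' boundary breaks runs.
#'
#' @inheritParams build_glcm
#' @return Sparse data.frame: `i` gray level, `j` run length, `n` run count.
#' @export
build_glrlm <- function(levels, direction = c(0L, 1L)) {
  v <- if (all(direction == c(0L, 1L))) {
    as.vector(rbind(t(levels), NA_integer_))
  } else if (all(direction == c(1L, 0L))) {
    as.vector(rbind(levels, NA_integer_))
  } else {
    unlist(lapply(direction_lines(levels, direction),
                  function(x) c(x, NA_integer_)), use.names = FALSE)
  }
  # single-pass run detection: make every NA a unique sentinel so it forms
  # its own run, then keep only non-sentinel runs
  w <- ifelse(is.na(v), -seq_along(v), as.numeric(v))
  n <- length(w)
  ends <- c(which(w[-1] != w[-n]), n)
  vals <- w[ends]
  lens <- diff(c(0L, ends))
  keep <- vals > 0
  sparse_counts(as.integer(vals[keep]), as.integer(lens[keep]))
}

# 8-connected components of same-level masked pixels, via igraph.
label_zones <- function(levels) {
  idx <- which(!is.na(levels))
  if (length(idx) == 0) {
    return(data.frame(level = integer(), size = integer()))
  }
  nr <- nrow(levels)
  vid <- match(seq_len(length(levels)), idx) # linear index -> vertex id
  edges <- integer(0)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  for (off in texture_directions()) {
    nb_r <- rr + off[1]; nb_c <- cc + off[2]
    ok <- nb_r >= 1 & nb_r <= nr & nb_c >= 1 & nb_c <= ncol(levels)
    nb <- (nb_c - 1L) * nr + nb_r
    ok[ok] <- !is.na(levels[nb[ok]]) & levels[nb[ok]] == levels[idx[ok]]
    if (any(ok)) {
      edges <- c(edges, rbind(vid[idx[ok]], vid[nb[ok]]))
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)
  data.frame(
    level = levels[idx][match(seq_len(comp$no), comp$membership)],
    size = as.integer(comp$csize)
  )
}

#' Gray-level size-zone matrix
#'
#' Counts of 8-connected zones of identical gray level by (level, zone size).
#'
#' @inheritParams build_glcm
#' @return Sparse data.frame: `i` gray level, `j` zone size, `n` zone count.
#' @export
build_glszm <- function(levels) {
  z <- label_zones(levels)
  sparse_counts(z$level, z$size)
}

neighbor_stats <- function(levels) {
  nr <- nrow(levels); nc <- ncol(levels)
  eq <- matrix(0, nr, nc)    # neighbors with identical level
  nsum <- matrix(0, nr, nc)  # sum of masked neighbor levels
  ncnt <- matrix(0, nr, nc)  # number of masked neighbors
  offs <- list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
               c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))
  for (off in offs) {
    p <- matrix(NA_integer_, nr, nc)
    r_dst <- seq_len(nr - abs(off[1])) + max(0L, -off[1])
    c_dst <- seq_len(nc - abs(off[2])) + max(0L, -off[2])
    p[r_dst, c_dst] <- levels[r_dst + off[1], c_dst + off[2], drop = FALSE]
    ok <- !is.na(p)
    eq[ok] <- eq[ok] + (p[ok] == levels[ok] & !is.na(levels[ok]))
    nsum[ok] <- nsum[ok] + p[ok]
    ncnt[ok] <- ncnt[ok] + 1
  }
  list(eq = eq, nsum = nsum, ncnt = ncnt)
}

#' Gray-level dependence matrix
#'
#' For every masked pixel, the dependence size is 1 plus the number of its
#' masked 8-neighbours whose level differs by at most `alpha` (default 0).
#'
#' @inheritParams build_glcm
#' @param alpha Dependence tolerance on the level difference (default 0).
#' @return Sparse data.frame: `i` gray level, `j` dependence size, `n` count.
#' @export
build_gldm <- function(levels, alpha = 0) {
  ns <- neighbor_stats(levels)
  dep <- if (alpha == 0) {
    ns$eq
  } else {
    # generic alpha: count neighbors within tolerance (slower path)
    dep_a <- matrix(0, nrow(levels), ncol(levels))
    for (off in list(c(0L, 1L), c(0L, -1L), c(1L, 0L), c(-1L, 0L),
                     c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
      p <- matrix(NA_integer_, nrow(levels), ncol(levels))
      r_dst <- seq_len(nrow(levels) - abs(off[1])) + max(0L, -off[1])
      c_dst <- seq_len(ncol(levels) - abs(off[2])) + max(0L, -off[2])
      p[r_dst, c_dst] <- levels[r_dst + off[1], c_dst + off[2], drop = FALSE]
      ok <- !is.na(p) & !is.na(levels)
      dep_a[ok] <- dep_a[ok] + (abs(p[ok] - levels[ok]) <= alpha)
    }
    dep_a
  }
  msk <- !is.na(levels)
  sparse_counts(levels[msk], as.integer(dep[msk]) + 1L)
}

#' Neighbourhood gray-tone difference table
#'
#' For every masked pixel with at least one masked 8-neighbour, accumulates
#' per level the pixel count `n_i` and the summed absolute difference `s_i`
#' between the pixel level and the mean level of its masked neighbours.
#'
#' @inheritParams build_glcm
#' @return data.frame with columns `i` (gray level), `n`, `s`.
#' @export
build_ngtdm <- function(levels) {
  ns <- neighbor_stats(levels)
  msk <- !is.na(levels) & ns$ncnt > 0
  if (!any(msk)) {
    return(data.frame(i = integer(), n = numeric(), s = numeric()))
  }
  lv <- levels[msk]
  dif <- abs(lv - ns$nsum[msk] / ns$ncnt[msk])
  ag <- rowsum(cbind(n = rep(1, length(lv)), s = dif), lv)
  data.frame(i = as.integer(rownames(ag)), n = ag[, "n"], s = ag[, "s"])
}

#' All texture matrices of a discretized ROI
#'
#' @inheritParams build_glcm
#' @param alpha GLDM dependence tolerance.
#' @param families Character subset of
#'   `c("glcm", "glrlm", "glszm", "gldm", "ngtdm")`.
#' @return A `texture_matrix_set`: per-direction GLCM and GLRLM lists, the
#'   GLSZM, GLDM and NGTDM tables, plus pixel and level counts.
#' @export
texture_matrices <- function(levels,
                             families = c("glcm", "glrlm", "glszm", "gldm", "ngtdm"),
                             alpha = 0) {
  if (all(is.na(levels))) {
    abort("Empty ROI: no masked levels.", class = "texrepro_error_empty_roi")
  }
  families <- match.arg(families, several.ok = TRUE)
  dirs <- texture_directions()
  out <- list(
    n_pixels = sum(!is.na(levels)),
    n_levels = length(unique(levels[!is.na(levels)])),
    max_level = max(levels, na.rm = TRUE)
  )
  if ("glcm" %in% families) {
    out$glcm <- setNames(lapply(dirs, function(d) build_glcm(levels, d)),
                         vapply(dirs, direction_label, ""))
  }
  if ("glrlm" %in% families) {
    out$glrlm <- setNames(lapply(dirs, function(d) build_glrlm(levels, d)),
                          vapply(dirs, direction_label, ""))
  }
  if ("glszm" %in% families) out$glszm <- build_glszm(levels)
  if ("gldm" %in% families) out$gldm <- build_gldm(levels, alpha)
  if ("ngtdm" %in% families) out$ngtdm <- build_ngtdm(levels)
  structure(out, class = "texture_matrix_set")
}

# Weighted merge of per-direction sparse matrices: diagonal directions get
# weight sqrt(2), axis directions weight 1.
merge_directional <- function(mats) {
  w <- c(d0_1 = 1, d1_1 = sqrt(2), d1_0 = 1, `d1_-1` = sqrt(2))
  parts <- lapply(names(mats), function(nm) {
    m <- mats[[nm]]
    if (nrow(m) == 0) return(m)
    m$n <- m$n * w[[nm]]
    m
  })
  all <- do.call(rbind, parts)
  if (nrow(all) == 0) return(all)
  ag <- aggregate(n ~ i + j, data = all, FUN = sum)
  ag[order(ag$i, ag$j), , drop = FALSE]
}
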