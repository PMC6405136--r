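# Independent brute-force oracles used to validate the vectorized texture
# matrix builders and the closed-form coefficients. These deliberately use
# direct definition-level loops, not the package's code paths.

`%||%` <- function(x, y) if (is.null(x)) y else x

oracle_dims <- function(levels) {
  list(nr = nrow(levels), nc = ncol(levels),
       L = max(levels, na.rm = TRUE))
}

sparse_to_dense <- function(df, nrow_, ncol_) {
  m <- matrix(0, nrow_, ncol_)
  if (nrow(df)) m[cbind(df$i, df$j)] <- df$n
  m
}

oracle_glcm <- function(levels, off) {
  d <- oracle_dims(levels)
  M <- matrix(0, d$L, d$L)
  for (r in seq_len(d$nr)) {
    for (c in seq_len(d$nc)) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 < 1 || r2 > d$nr || c2 < 1 || c2 > d$nc) next
      a <- levels[r, c]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      M[a, b] <- M[a, b] + 1
      M[b, a] <- M[b, a] + 1
    }
  }
  M
}

oracle_glrlm <- function(levels, off) {
  d <- oracle_dims(levels)
  runs <- list()
  inside <- function(r, c) r >= 1 && r <= d$nr && c >= 1 && c <= d$nc
  val <- function(r, c) if (inside(r, c)) levels[r, c] else NA
  maxlen <- 0
  counts <- list()
  for (r in seq_len(d$nr)) {
    for (c in seq_len(d$nc)) {
      a <- levels[r, c]
      if (is.na(a)) next
      prev <- val(r - off[1], c - off[2])
      if (!is.na(prev) && prev == a) next # not a run start
      len <- 1
      while (TRUE) {
        nxt <- val(r + len * off[1], c + len * off[2])
        if (is.na(nxt) || nxt != a) break
        len <- len + 1
      }
      key <- paste(a, len)
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      maxlen <- max(maxlen, len)
    }
  }
  M <- matrix(0, d$L, max(1, maxlen))
  for (key in names(counts)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    M[ij[1], ij[2]] <- counts[[key]]
  }
  M
}

oracle_glszm <- function(levels) {
  d <- oracle_dims(levels)
  seen <- matrix(FALSE, d$nr, d$nc)
  zones <- list()
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (r in seq_len(d$nr)) {
    for (c in seq_len(d$nc)) {
      if (is.na(levels[r, c]) || seen[r, c]) next
      lv <- levels[r, c]
      stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1
        for (k in seq_len(nrow(offs))) {
          r2 <- p[1] + offs$dr[k]; c2 <- p[2] + offs$dc[k]
          if (r2 < 1 || r2 > d$nr || c2 < 1 || c2 > d$nc) next
          if (seen[r2, c2] || is.na(levels[r2, c2])) next
          if (levels[r2, c2] == lv) {
            seen[r2, c2] <- TRUE
            stack[[length(stack) + 1]] <- c(r2, c2)
          }
        }
      }
      zones[[length(zones) + 1]] <- c(lv, size)
    }
  }
  zs <- do.call(rbind, zones)
  M <- matrix(0, d$L, max(zs[, 2]))
  for (i in seq_len(nrow(zs))) {
    M[zs[i, 1], zs[i, 2]] <- M[zs[i, 1], zs[i, 2]] + 1
  }
  M
}

oracle_gldm <- function(levels, alpha = 0) {
  d <- oracle_dims(levels)
  counts <- list()
  maxdep <- 0
  for (r in seq_len(d$nr)) {
    for (c in seq_len(d$nc)) {
      a <- levels[r, c]
      if (is.na(a)) next
      dep <- 0
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > d$nr || c2 < 1 || c2 > d$nc) next
        b <- levels[r2, c2]
        if (!is.na(b) && abs(b - a) <= alpha) dep <- dep + 1
      }
      j <- dep + 1
      key <- paste(a, j)
      counts[[key]] <- (counts[[key]] %||% 0) + 1
      maxdep <- max(maxdep, j)
    }
  }
  M <- matrix(0, d$L, maxdep)
  for (key in names(counts)) {
    ij <- as.integer(strsplit(key, " ")[[1]])
    M[ij[1], ij[2]] <- counts[[key]]
  }
  M
}

oracle_ngtdm <- function(levels) {
  d <- oracle_dims(levels)
  n_i <- numeric(d$L); s_i <- numeric(d$L)
  for (r in seq_len(d$nr)) {
    for (c in seq_len(d$nc)) {
      a <- levels[r, c]
      if (is.na(a)) next
      nb <- c()
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- c + dc
        if (r2 < 1 || r2 > d$nr || c2 < 1 || c2 > d$nc) next
        b <- levels[r2, c2]
        if (!is.na(b)) nb <- c(nb, b)
      }
      if (length(nb) == 0) next
      n_i[a] <- n_i[a] + 1
      s_i[a] <- s_i[a] + abs(a - mean(nb))
    }
  }
  list(n = n_i, s = s_i)
}

# ANOVA-table ICC oracle via aov(): an independent route to the mean squares.
oracle_icc_avg <- function(x) {
  n <- nrow(x); k <- ncol(x)
  d <- data.frame(
    value = as.vector(x),
    subject = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  tab <- summary(stats::aov(value ~ subject + rater, data = d))[[1]]
  msr <- tab["subject", "Mean Sq"]
  msc <- tab["rater", "Mean Sq"]
  mse <- tab["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (msc - mse) / n)
}

# Full hypergeometric enumeration via lchoose, independent of dhyper.
oracle_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  lp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  p <- exp(lp)
  pobs <- exp(lchoose(r1, tab[1, 1]) + lchoose(r2, c1 - tab[1, 1]) -
                lchoose(n, c1))
  min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

# Random small discretized ROI: levels matrix with NA outside a random mask.
random_levels <- function(nr, nc, n_levels, p_mask = 0.8) {
  m <- matrix(sample.int(n_levels, nr * nc, replace = TRUE), nr, nc)
  msk <- matrix(stats::runif(nr * nc) < p_mask, nr, nc)
  if (!any(msk)) msk[sample.int(nr * nc, 1)] <- TRUE
  m[!msk] <- NA_integer_
  m
}
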