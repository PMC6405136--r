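# Texture feature values from sparse matrices.
#
# Feature naming follows the IBSI / pyradiomics nomenclature, prefixed by
# family (e.g. "GLCM_ClusterShade"). Two named configurations are provided:
#   full    : GLCM 23 + GLRLM 16 + GLSZM 16 + GLDM 14  = 69 features
#   inhouse : GLCM 26 + GLRLM 13 + GLSZM 13 + NGTDM 5  = 57 features
# The two aggregation conventions for directional families are
#   per_angle_average : one feature value per direction matrix, averaged
#   merged_weighted   : directions merged first (diagonals weighted sqrt(2)),
#                       features computed once from the merged matrix.

glcm_feature_names_23 <- function() {
  c("Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
    "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
    "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
    "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
    "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares")
}

glcm_feature_names_26 <- function() {
  c(glcm_feature_names_23(), "Dissimilarity", "SumVariance", "Mcc")
}

glrlm_feature_names_16 <- function() {
  c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage",
    "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
    "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
    "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis",
    "GrayLevelVariance", "RunVariance", "RunEntropy")
}

glrlm_feature_names_13 <- function() {
  setdiff(glrlm_feature_names_16(),
          c("GrayLevelNonUniformityNormalized",
            "RunLengthNonUniformityNormalized", "RunEntropy"))
}

glszm_feature_names_16 <- function() {
  c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
    "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage",
    "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
    "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis",
    "GrayLevelVariance", "ZoneVariance", "ZoneEntropy")
}

glszm_feature_names_13 <- function() {
  setdiff(glszm_feature_names_16(),
          c("GrayLevelNonUniformityNormalized",
            "SizeZoneNonUniformityNormalized", "ZoneEntropy"))
}

gldm_feature_names_14 <- function() {
  c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
    "GrayLevelNonUniformity", "DependenceNonUniformity",
    "DependenceNonUniformityNormalized", "GrayLevelVariance",
    "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
    "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
    "SmallDependenceHighGrayLevelEmphasis",
    "LargeDependenceLowGrayLevelEmphasis",
    "LargeDependenceHighGrayLevelEmphasis")
}

ngtdm_feature_names_5 <- function() {
  c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
}

#' Feature configurations
#'
#' Returns the named feature list of a configuration: `"full"` (69 features,
#' GLCM/GLRLM/GLSZM/GLDM) or `"inhouse"` (57 features,
#' GLCM/GLRLM/GLSZM/NGTDM).
#'
#' @param config `"full"` or `"inhouse"`.
#' @return Named list of character vectors, one per family.
#' @export
feature_configuration <- function(config = c("full", "inhouse")) {
  config <- match.arg(config)
  if (config == "full") {
    list(glcm = glcm_feature_names_23(),
         glrlm = glrlm_feature_names_16(),
         glszm = glszm_feature_names_16(),
         gldm = gldm_feature_names_14())
  } else {
    list(glcm = glcm_feature_names_26(),
         glrlm = glrlm_feature_names_13(),
         glszm = glszm_feature_names_13(),
         ngtdm = ngtdm_feature_names_5())
  }
}

default_aggregation <- function(config) {
  if (config == "inhouse") "merged_weighted" else "per_angle_average"
}

# ---- GLCM features from one sparse symmetric count matrix --------------------

glcm_features_one <- function(m, wanted) {
  if (nrow(m) == 0 || sum(m$n) == 0) {
    return(setNames(rep(NA_real_, length(wanted)), wanted))
  }
  p <- m$n / sum(m$n)
  i <- as.numeric(m$i); j <- as.numeric(m$j)
  px_t <- rowsum(p, i); ui <- as.numeric(rownames(px_t)); px <- px_t[, 1]
  py_t <- rowsum(p, j); uj <- as.numeric(rownames(py_t)); py <- py_t[, 1]
  Ng <- length(unique(c(ui, uj)))
  mux <- sum(px * ui); muy <- sum(py * uj)
  sigx <- sqrt(sum(px * (ui - mux)^2)); sigy <- sqrt(sum(py * (uj - muy)^2))
  dif <- abs(i - j); sm <- i + j
  pd_t <- rowsum(p, dif); kd <- as.numeric(rownames(pd_t)); pd <- pd_t[, 1]
  ps_t <- rowsum(p, sm); ks <- as.numeric(rownames(ps_t)); ps <- ps_t[, 1]
  DA <- sum(kd * pd)
  SA <- sum(ks * ps)
  HXY <- -sum(p * log2(p))
  HX <- -sum(px * log2(px)); HY <- -sum(py * log2(py))
  pxi <- px[match(i, ui)]; pyj <- py[match(j, uj)]
  HXY1 <- -sum(p * log2(pxi * pyj))
  op <- outer(px, py)
  HXY2 <- -sum(op * log2(op))
  f <- list()
  f$Autocorrelation <- sum(p * i * j)
  ctr <- i + j - mux - muy
  f$ClusterProminence <- sum(p * ctr^4)
  f$ClusterShade <- sum(p * ctr^3)
  f$ClusterTendency <- sum(p * ctr^2)
  f$Contrast <- sum(p * (i - j)^2)
  f$Correlation <- if (sigx * sigy == 0) 1 else
    (sum(p * i * j) - mux * muy) / (sigx * sigy)
  f$DifferenceAverage <- DA
  f$DifferenceEntropy <- -sum(pd * log2(pd))
  f$DifferenceVariance <- sum(pd * (kd - DA)^2)
  f$Dissimilarity <- sum(p * dif)
  f$Id <- sum(p / (1 + dif))
  f$Idm <- sum(p / (1 + dif^2))
  f$Idmn <- sum(p / (1 + (dif / Ng)^2))
  f$Idn <- sum(p / (1 + dif / Ng))
  f$Imc1 <- if (max(HX, HY) == 0) 0 else (HXY - HXY1) / max(HX, HY)
  f$Imc2 <- sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY))))
  iv <- dif > 0
  f$InverseVariance <- sum(p[iv] / dif[iv]^2)
  f$JointAverage <- mux
  f$JointEnergy <- sum(p^2)
  f$JointEntropy <- HXY
  f$MaximumProbability <- max(p)
  f$SumAverage <- SA
  f$SumEntropy <- -sum(ps * log2(ps))
  f$SumSquares <- sum(px * (ui - mux)^2)
  f$SumVariance <- sum(ps * (ks - SA)^2)
  if ("Mcc" %in% wanted) f$Mcc <- glcm_mcc(p, i, j, ui, px, uj, py)
  unlist(f)[wanted]
}

# Maximal correlation coefficient: sqrt of the second largest eigenvalue of
# Q(a,b) = sum_k p(a,k) p(b,k) / (px(a) py(k)).
glcm_mcc <- function(p, i, j, ui, px, uj, py) {
  if (length(ui) < 2) return(1)
  P <- matrix(0, length(ui), length(uj))
  P[cbind(match(i, ui), match(j, uj))] <- p
  Q <- (P / px) %*% t(P / matrix(py, length(ui), length(uj), byrow = TRUE))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(0, ev[2]))
}

# ---- shared (level, size) family features -----------------------------------

# Generic features of a sparse (gray level i, size j, count n) matrix.
# `np` is the number of masked pixels (for the percentage feature).
site_matrix_features <- function(m, np) {
  if (nrow(m) == 0 || sum(m$n) == 0) return(NULL)
  N <- sum(m$n)
  p <- m$n / N
  i <- as.numeric(m$i); j <- as.numeric(m$j)
  gi <- rowsum(m$n, i)[, 1]
  gj <- rowsum(m$n, j)[, 1]
  mui <- sum(p * i); muj <- sum(p * j)
  list(
    small = sum(m$n / j^2) / N,
    large = sum(m$n * j^2) / N,
    gln = sum(gi^2) / N,
    glnn = sum(gi^2) / N^2,
    sn = sum(gj^2) / N,
    snn = sum(gj^2) / N^2,
    pct = N / np,
    lgl = sum(m$n / i^2) / N,
    hgl = sum(m$n * i^2) / N,
    small_lgl = sum(m$n / (i^2 * j^2)) / N,
    small_hgl = sum(m$n * i^2 / j^2) / N,
    large_lgl = sum(m$n * j^2 / i^2) / N,
    large_hgl = sum(m$n * i^2 * j^2) / N,
    glv = sum(p * (i - mui)^2),
    sv = sum(p * (j - muj)^2),
    entropy = -sum(p * log2(p))
  )
}

na_features <- function(wanted) setNames(rep(NA_real_, length(wanted)), wanted)

glrlm_features_one <- function(m, np, wanted) {
  s <- site_matrix_features(m, np)
  if (is.null(s)) return(na_features(wanted))
  all <- c(ShortRunEmphasis = s$small, LongRunEmphasis = s$large,
           GrayLevelNonUniformity = s$gln,
           GrayLevelNonUniformityNormalized = s$glnn,
           RunLengthNonUniformity = s$sn,
           RunLengthNonUniformityNormalized = s$snn,
           RunPercentage = s$pct,
           LowGrayLevelRunEmphasis = s$lgl, HighGrayLevelRunEmphasis = s$hgl,
           ShortRunLowGrayLevelEmphasis = s$small_lgl,
           ShortRunHighGrayLevelEmphasis = s$small_hgl,
           LongRunLowGrayLevelEmphasis = s$large_lgl,
           LongRunHighGrayLevelEmphasis = s$large_hgl,
           GrayLevelVariance = s$glv, RunVariance = s$sv,
           RunEntropy = s$entropy)
  all[wanted]
}

glszm_features <- function(m, np, wanted) {
  s <- site_matrix_features(m, np)
  if (is.null(s)) return(na_features(wanted))
  all <- c(SmallAreaEmphasis = s$small, LargeAreaEmphasis = s$large,
           GrayLevelNonUniformity = s$gln,
           GrayLevelNonUniformityNormalized = s$glnn,
           SizeZoneNonUniformity = s$sn,
           SizeZoneNonUniformityNormalized = s$snn,
           ZonePercentage = s$pct,
           LowGrayLevelZoneEmphasis = s$lgl, HighGrayLevelZoneEmphasis = s$hgl,
           SmallAreaLowGrayLevelEmphasis = s$small_lgl,
           SmallAreaHighGrayLevelEmphasis = s$small_hgl,
           LargeAreaLowGrayLevelEmphasis = s$large_lgl,
           LargeAreaHighGrayLevelEmphasis = s$large_hgl,
           GrayLevelVariance = s$glv, ZoneVariance = s$sv,
           ZoneEntropy = s$entropy)
  all[wanted]
}

gldm_features <- function(m, np, wanted) {
  s <- site_matrix_features(m, np)
  if (is.null(s)) return(na_features(wanted))
  all <- c(SmallDependenceEmphasis = s$small,
           LargeDependenceEmphasis = s$large,
           GrayLevelNonUniformity = s$gln,
           DependenceNonUniformity = s$sn,
           DependenceNonUniformityNormalized = s$snn,
           GrayLevelVariance = s$glv, DependenceVariance = s$sv,
           DependenceEntropy = s$entropy,
           LowGrayLevelEmphasis = s$lgl, HighGrayLevelEmphasis = s$hgl,
           SmallDependenceLowGrayLevelEmphasis = s$small_lgl,
           SmallDependenceHighGrayLevelEmphasis = s$small_hgl,
           LargeDependenceLowGrayLevelEmphasis = s$large_lgl,
           LargeDependenceHighGrayLevelEmphasis = s$large_hgl)
  all[wanted]
}

ngtdm_features <- function(tbl, wanted) {
  if (nrow(tbl) == 0 || sum(tbl$n) == 0) return(na_features(wanted))
  Nvp <- sum(tbl$n)
  pi_ <- tbl$n / Nvp
  si <- tbl$s
  lv <- as.numeric(tbl$i)
  Ngp <- length(lv)
  f <- numeric(0)
  denom_coarse <- sum(pi_ * si)
  f["Coarseness"] <- if (denom_coarse == 0) 1e6 else 1 / denom_coarse
  if (Ngp == 1) {
    f["Contrast"] <- 0
    f["Busyness"] <- 0
    f["Complexity"] <- 0
    f["Strength"] <- 0
    return(f[wanted])
  }
  DI <- outer(lv, lv, "-")
  PP <- outer(pi_, pi_)
  f["Contrast"] <- (sum(PP * DI^2) / (Ngp * (Ngp - 1))) * (sum(si) / Nvp)
  bus_den <- sum(abs(outer(lv * pi_, lv * pi_, "-")))
  f["Busyness"] <- if (bus_den == 0) 0 else sum(pi_ * si) / bus_den
  PS <- outer(pi_ * si, pi_ * si, "+")
  f["Complexity"] <- sum(abs(DI) * PS / outer(pi_, pi_, "+")) / Nvp
  str_den <- sum(si)
  f["Strength"] <- if (str_den == 0) 0 else
    sum(outer(pi_, pi_, "+") * DI^2) / str_den
  f[wanted]
}

# ---- assembly ---------------------------------------------------------------

#' Texture feature values from a texture-matrix set
#'
#' @param matrices A [texture_matrices()] result.
#' @param aggregation `"per_angle_average"` (a feature value per direction
#'   matrix, then averaged over the 4 directions) or `"merged_weighted"`
#'   (directions merged with weight sqrt(2) on diagonals before feature
#'   computation). Direction-free families (GLSZM, GLDM, NGTDM) are
#'   unaffected by the choice.
#' @param config Feature configuration, `"full"` (69) or `"inhouse"` (57).
#' @return Named numeric vector of feature values, names prefixed by family.
#' @export
compute_features <- function(matrices,
                             aggregation = c("per_angle_average", "merged_weighted"),
                             config = c("full", "inhouse")) {
  aggregation <- match.arg(aggregation)
  config <- match.arg(config)
  want <- feature_configuration(config)
  np <- matrices$n_pixels
  out <- numeric(0)
  if (!is.null(want$glcm)) {
    wanted <- want$glcm
    fun <- function(m) glcm_features_one(m, wanted)
    if (aggregation == "per_angle_average") {
      vals <- sapply(matrices$glcm, fun)
      v <- rowMeans(vals)
    } else {
      v <- fun(merge_directional(matrices$glcm))
    }
    out <- c(out, setNames(v, paste0("GLCM_", wanted)))
  }
  if (!is.null(want$glrlm)) {
    wanted <- want$glrlm
    fun <- function(m) glrlm_features_one(m, np, wanted)
    if (aggregation == "per_angle_average") {
      v <- rowMeans(sapply(matrices$glrlm, fun))
    } else {
      v <- fun(merge_directional(matrices$glrlm))
    }
    out <- c(out, setNames(v, paste0("GLRLM_", wanted)))
  }
  if (!is.null(want$glszm)) {
    v <- glszm_features(matrices$glszm, np, want$glszm)
    out <- c(out, setNames(v, paste0("GLSZM_", want$glszm)))
  }
  if (!is.null(want$gldm)) {
    v <- gldm_features(matrices$gldm, np, want$gldm)
    out <- c(out, setNames(v, paste0("GLDM_", want$gldm)))
  }
  if (!is.null(want$ngtdm)) {
    v <- ngtdm_features(matrices$ngtdm, want$ngtdm)
    out <- c(out, setNames(v, paste0("NGTDM_", want$ngtdm)))
  }
  out
}

#' Extract all texture features of one ROI
#'
#' Convenience wrapper: optional intensity normalization, discretization,
#' matrix construction and feature computation in one call.
#'
#' @param image Numeric intensity matrix.
#' @param mask Binary mask matrix of the same shape.
#' @param scheme Discretization scheme (object or `"fbs:25"`-style string).
#' @param config Feature configuration (`"full"` or `"inhouse"`).
#' @param aggregation Aggregation mode; defaults to the configuration's
#'   convention (`per_angle_average` for `"full"`, `merged_weighted` for
#'   `"inhouse"`).
#' @param normalize If `TRUE`, apply [normalize_intensity()] to the image
#'   before discretization.
#' @return Named numeric vector of 69 (`full`) or 57 (`inhouse`) features.
#' @export
extract_roi_features <- function(image, mask, scheme,
                                 config = c("full", "inhouse"),
                                 aggregation = NULL,
                                 normalize = FALSE) {
  config <- match.arg(config)
  aggregation <- aggregation %||% default_aggregation(config)
  if (normalize) image <- normalize_intensity(image)
  levels <- discretize_roi(image, mask, scheme)
  fam <- names(feature_configuration(config))
  mats <- texture_matrices(levels, families = fam)
  compute_features(mats, aggregation, config)
}
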