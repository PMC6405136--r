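# Reproducibility-based feature selection: two-way random-effects
# absolute-agreement average-measures ICC, Lin's concordance correlation
# coefficient, and the selection rule combining them.

#' Two-way random-effects absolute-agreement average-measures ICC
#'
#' McGraw-Wong ICC(A,k): `(MSR - MSE) / (MSR + (MSC - MSE)/n)` where MSR,
#' MSC and MSE are the subject, rater and residual mean squares of the
#' two-way ANOVA decomposition of the `n x k` ratings matrix. The
#' single-measures form ICC(A,1) is available via `type = "single"`.
#'
#' Degenerate inputs (no subject variance, or a non-positive denominator)
#' return `NA`; an undefined coefficient counts as non-reproducible
#' downstream.
#'
#' @param ratings Numeric matrix, subjects in rows, raters/sessions in
#'   columns; at least 3 subjects, 2 raters, no missing cells.
#' @param type `"average"` (default) for ICC(A,k), `"single"` for ICC(A,1).
#' @return The ICC, or `NA_real_` when undefined.
#' @examples
#' icc_a_k(cbind(1:4, 2:5)) # consistent offset: ~0.87
#' @export
icc_a_k <- function(ratings, type = c("average", "single")) {
  type <- match.arg(type)
  x <- as.matrix(ratings)
  n <- nrow(x); k <- ncol(x)
  if (n < 3 || k < 2 || anyNA(x)) return(NA_real_)
  g <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm - g)^2) / (k - 1)
  sse <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + g)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- if (type == "average") {
    den <- msr + (msc - mse) / n
    if (den <= 0) return(NA_real_)
    (msr - mse) / den
  } else {
    den <- msr + (k - 1) * mse + k * (msc - mse) / n
    if (den <= 0) return(NA_real_)
    (msr - mse) / den
  }
  if (!is.finite(icc)) NA_real_ else icc
}

#' Lin's concordance correlation coefficient
#'
#' `2 s_xy / (s_x^2 + s_y^2 + (mean_x - mean_y)^2)` with moment (1/n)
#' variance and covariance estimators. Measures agreement of paired
#' measurements with the identity line.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return The CCC in `[-1, 1]`, or `NA_real_` when both variances are zero.
#' @examples
#' lin_ccc(1:4, 2:5) # 0.714...
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.",
          class = "texrepro_error_input")
  }
  if (anyNA(x) || anyNA(y)) return(NA_real_)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * sxy / den
}

#' Reading design
#'
#' Describes the reading sessions and the selection thresholds. The default
#' matches a two-reader design with one repeated session: sessions `R1`
#' (reader 1), `R2a` and `R2b` (reader 2, sessions 1 and 2); ICC is computed
#' on all three session pairs and Lin's CCC on the intra-observer pair
#' `(R2a, R2b)`. A feature is selected when all ICCs exceed
#' `icc_threshold` (0.8) and the CCC exceeds `ccc_threshold` (0.9), both
#' strictly.
#'
#' @param session_ids Ordered session labels.
#' @param icc_pairs List of session-id pairs for the ICC.
#' @param intra_pair The repeated-session pair for the CCC.
#' @param icc_threshold,ccc_threshold Strict selection thresholds in (0, 1).
#' @return A `reading_design` list.
#' @export
reading_design <- function(session_ids = c("R1", "R2a", "R2b"),
                           icc_pairs = NULL,
                           intra_pair = c("R2a", "R2b"),
                           icc_threshold = 0.8,
                           ccc_threshold = 0.9) {
  icc_pairs <- icc_pairs %||% utils::combn(session_ids, 2, simplify = FALSE)
  stopifnot(
    length(session_ids) >= 2,
    all(unlist(icc_pairs) %in% session_ids),
    all(intra_pair %in% session_ids),
    icc_threshold > 0, icc_threshold < 1,
    ccc_threshold > 0, ccc_threshold < 1
  )
  structure(
    list(session_ids = session_ids, icc_pairs = icc_pairs,
         intra_pair = intra_pair, icc_threshold = icc_threshold,
         ccc_threshold = ccc_threshold),
    class = "reading_design"
  )
}

#' Select reproducible features
#'
#' For every (grouping, feature) cell of a long feature table, computes the
#' pairwise ICC(A,k) over each session pair of the design and Lin's CCC over
#' the intra-observer pair, and flags the feature as selected when all ICCs
#' strictly exceed `icc_threshold` and the CCC strictly exceeds
#' `ccc_threshold`. Undefined coefficients are never selected. ROIs with
#' missing session values are dropped per feature with a warning.
#'
#' @param features Long tibble with at least columns `roi` (ROI identifier),
#'   `session`, `feature`, `value`; any additional columns named in `by`
#'   (e.g. `sequence`, `scheme`) define separate selection strata.
#' @param design A [reading_design()].
#' @param by Character vector of stratifying columns (default: those of
#'   `c("scheme", "method", "parameter", "sequence")` present in the table).
#' @return A `repro_report` tibble: one row per stratum and feature with the
#'   pairwise ICCs (`icc_<a>_<b>`), `ccc` and `selected`.
#' @export
select_reproducible <- function(features, design = reading_design(),
                                by = NULL) {
  by <- by %||% intersect(c("scheme", "method", "parameter", "sequence"),
                          names(features))
  needed <- c("roi", "session", "feature", "value")
  if (!all(needed %in% names(features))) {
    abort(paste("`features` must contain columns:",
                paste(needed, collapse = ", ")),
          class = "texrepro_error_input")
  }
  wide <- features |>
    dplyr::select(dplyr::all_of(c(by, needed))) |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  missing_sessions <- setdiff(design$session_ids, names(wide))
  if (length(missing_sessions)) {
    abort(paste("Sessions absent from the feature table:",
                paste(missing_sessions, collapse = ", ")),
          class = "texrepro_error_input")
  }
  incomplete <- !stats::complete.cases(wide[design$session_ids])
  if (any(incomplete)) {
    warn(sprintf(
      "%d ROI-feature cells have missing session values and are dropped.",
      sum(incomplete)))
  }
  pair_names <- vapply(design$icc_pairs,
                       function(p) paste0("icc_", p[1], "_", p[2]), "")
  report <- wide |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "feature")))) |>
    dplyr::group_modify(function(d, key) {
      d <- d[stats::complete.cases(d[design$session_ids]), , drop = FALSE]
      iccs <- vapply(design$icc_pairs, function(p) {
        icc_a_k(as.matrix(d[, p]))
      }, 0)
      ccc <- if (nrow(d) >= 3) {
        lin_ccc(d[[design$intra_pair[1]]], d[[design$intra_pair[2]]])
      } else {
        NA_real_
      }
      out <- as.data.frame(as.list(setNames(iccs, pair_names)))
      out$ccc <- ccc
      out$selected <- all(!is.na(iccs)) && !is.na(ccc) &&
        all(iccs > design$icc_threshold) && ccc > design$ccc_threshold
      out
    }) |>
    dplyr::ungroup()
  structure(report, class = c("repro_report", class(report)),
            design = design, by = by)
}

#' Feature selection against simulated delineations
#'
#' Experiment-4-style selection: for each feature (within strata), the
#' ICC(A,k) between the values measured on the reference masks and on the
#' simulated masks must strictly exceed `icc_threshold`; there is no CCC
#' criterion in this mode.
#'
#' @param reference_features,simulated_features Long tibbles with columns
#'   `roi`, `feature`, `value` plus any stratifying columns.
#' @param icc_threshold Strict threshold (default 0.8).
#' @param by Stratifying columns (default as in [select_reproducible()]).
#' @return Tibble with per-stratum, per-feature `icc` and `selected`.
#' @export
icc_pairwise_simulated <- function(reference_features, simulated_features,
                                   icc_threshold = 0.8, by = NULL) {
  by <- by %||% intersect(c("scheme", "method", "parameter", "sequence"),
                          names(reference_features))
  joined <- dplyr::inner_join(
    dplyr::select(reference_features,
                  dplyr::all_of(c(by, "roi", "feature")), ref = "value"),
    dplyr::select(simulated_features,
                  dplyr::all_of(c(by, "roi", "feature")), sim = "value"),
    by = c(by, "roi", "feature")
  )
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(by, "feature")))) |>
    dplyr::summarise(
      icc = icc_a_k(cbind(.data$ref, .data$sim)),
      .groups = "drop"
    ) |>
    dplyr::mutate(selected = !is.na(.data$icc) & .data$icc > icc_threshold)
}

#' @method tidy repro_report
#' @export
tidy.repro_report <- function(x, ...) {
  as_tibble(unclass(x)[names(x)])
}

#' Per-stratum selection counts
#'
#' @param x A `repro_report`.
#' @param ... Unused.
#' @return One row per stratum: number of features, number selected.
#' @method glance repro_report
#' @export
glance.repro_report <- function(x, ...) {
  by <- attr(x, "by")
  tidy(x) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_features = dplyr::n(),
                     n_selected = sum(.data$selected),
                     .groups = "drop")
}
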