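# Experiment orchestration: run the discretization grid over a study,
# count reproducible features, compare FBS vs FBN (Fisher exact), compare
# distributions across settings (chi-square), and trace reproducibility
# against delineation overlap (Dice curves).

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p-value by full hypergeometric enumeration: the sum of the
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. A zero margin returns 1 by
#' convention.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(54, 32, 15, 37), 2)) # < 0.001
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must be a 2x2 matrix of non-negative integers.",
          class = "texrepro_error_input")
  }
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  if (r1 == 0 || r2 == 0 || c1 == 0 || sum(tab[, 2]) == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(xs, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Chi-square homogeneity test of selection counts across settings
#'
#' Pearson chi-square (no continuity correction) on a `settings x
#' {selected, not selected}` count table, df = settings - 1.
#'
#' @param table Matrix with one row per setting and two columns
#'   (selected, not selected).
#' @return p-value, or `NA` when a margin is all zero.
#' @export
chisq_homogeneity <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) != 2 || any(tab < 0)) {
    abort("`table` must be a (settings >= 2) x 2 count matrix.",
          class = "texrepro_error_input")
  }
  if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) return(NA_real_)
  suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
}

count_table <- function(counts, n_features, method_) {
  d <- counts[counts$method == method_, , drop = FALSE]
  d <- d[order(d$parameter), , drop = FALSE]
  cbind(selected = d$n_selected, not = n_features - d$n_selected)
}

best_setting <- function(counts, method_) {
  d <- counts[counts$method == method_, , drop = FALSE]
  d <- d[order(-d$n_selected, d$parameter), , drop = FALSE] # tie: smaller bin
  d[1, , drop = FALSE]
}

#' Run the discretization grid experiment on a study
#'
#' Extracts features for every scheme and session, applies the
#' reproducibility selection per sequence, and summarizes per sequence: the
#' selected-feature count of every setting, the highest count per
#' discretization method, the Fisher exact comparison of the two best
#' settings (selected vs not, over the common feature set), and the
#' chi-square homogeneity of counts within each method's grid. Ties for the
#' best setting go to the smaller bin parameter.
#'
#' @param study A [generate_study()] result.
#' @param schemes Scheme table (default: the full 6 FBS + 8 FBN grid).
#' @param design A [reading_design()].
#' @param config,aggregation,normalize Passed to [extract_features()].
#' @param features Optional precomputed feature table (skips extraction).
#' @return A `texture_experiment`: `counts` (per sequence and setting),
#'   `summary` (per sequence), the selection `report`, and metadata.
#' @export
run_grid <- function(study, schemes = discretization_grid(),
                     design = reading_design(),
                     config = c("full", "inhouse"),
                     aggregation = NULL, normalize = FALSE,
                     features = NULL) {
  config <- match.arg(config)
  schemes <- as_scheme_table(schemes)
  features <- features %||%
    extract_features(study, schemes, config, aggregation,
                     normalize = normalize)
  missing_schemes <- setdiff(schemes$scheme, unique(features$scheme))
  if (length(missing_schemes)) {
    abort(paste("Feature table lacks schemes:",
                paste(missing_schemes, collapse = ", ")),
          class = "texrepro_error_input")
  }
  report <- select_reproducible(features, design)
  n_features <- length(unique(features$feature))
  counts <- glance(report) |>
    dplyr::rename(dplyr::any_of(c(n_selected = "n_selected")))
  summary <- counts |>
    dplyr::group_by(.data$sequence) |>
    dplyr::group_modify(function(d, key) {
      bf <- best_setting(d, "fbs")
      bn <- best_setting(d, "fbn")
      tab <- rbind(c(bf$n_selected, n_features - bf$n_selected),
                   c(bn$n_selected, n_features - bn$n_selected))
      tibble(
        best_fbs_scheme = bf$scheme, best_fbs = bf$n_selected,
        best_fbn_scheme = bn$scheme, best_fbn = bn$n_selected,
        fisher_p = fisher_exact_2x2(tab),
        chisq_p_fbs = if (sum(d$method == "fbs") >= 2) {
          chisq_homogeneity(count_table(d, n_features, "fbs"))
        } else {
          NA_real_
        },
        chisq_p_fbn = if (sum(d$method == "fbn") >= 2) {
          chisq_homogeneity(count_table(d, n_features, "fbn"))
        } else {
          NA_real_
        }
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      sequence_name = names(study$spec$sequence_intensity_ranges)[.data$sequence],
      .after = "sequence"
    )
  structure(
    list(counts = counts, summary = summary, report = report,
         n_features = n_features, schemes = schemes, design = design,
         config = config),
    class = "texture_experiment"
  )
}

#' @export
print.texture_experiment <- function(x, ...) {
  cat("<texture_experiment>", x$n_features, "features,",
      nrow(x$schemes), "schemes\n")
  print(x$summary)
  invisible(x)
}

#' @method tidy texture_experiment
#' @export
tidy.texture_experiment <- function(x, ...) x$counts

#' @method glance texture_experiment
#' @export
glance.texture_experiment <- function(x, ...) x$summary

#' Simulate Dice-stratified delineations for every ROI of a study
#'
#' Applies the candidate-generation and Dice-bin selection machinery of
#' [simulate_delineations()] to every reference mask of the study.
#'
#' @param study A [generate_study()] result.
#' @param config A [perturbation_config()]; its seed is combined with a
#'   per-ROI label so every ROI has its own candidate stream.
#' @return Named list (by ROI key) of `simulated_roi_set` objects.
#' @export
simulate_study_rois <- function(study, config = perturbation_config()) {
  out <- lapply(names(study$ref_masks), function(key) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, paste0("roi_", key))
    simulate_delineations(study$ref_masks[[key]], cfg)
  })
  names(out) <- names(study$ref_masks)
  out
}

#' Reproducible-feature counts against the Dice coefficient
#'
#' Experiment-4-style analysis: texture features are extracted from the
#' reference mask (Dice 1.0) and from the simulated mask of each Dice
#' stratum; per Dice level, sequence and scheme, features whose ICC between
#' the reference and simulated readings strictly exceeds the threshold are
#' counted, and the highest count per discretization method is reported
#' together with the FBS - FBN gap.
#'
#' @param study A [generate_study()] result.
#' @param sim_rois A [simulate_study_rois()] result for the same study.
#' @param schemes Scheme table.
#' @param config,aggregation Passed to [extract_features()]-style extraction.
#' @param icc_threshold Strict selection threshold (default 0.8).
#' @return A `dice_curve` tibble: `dice`, `sequence`, `method`, highest
#'   `n_selected` and `scheme`, plus the per-level `gap` table in attribute
#'   `gap` (and via [glance()]).
#' @export
dice_curve <- function(study, sim_rois, schemes = discretization_grid(),
                       config = c("full", "inhouse"), aggregation = NULL,
                       icc_threshold = 0.8) {
  config <- match.arg(config)
  aggregation <- aggregation %||% default_aggregation(config)
  schemes <- as_scheme_table(schemes)
  rois <- dplyr::distinct(study$manifest, .data$patient, .data$region,
                          .data$sequence, .data$roi)
  levels_lab <- names(sim_rois[[1]]$selected)
  extract_one <- function(mask_for) {
    out <- vector("list", nrow(rois) * nrow(schemes))
    k <- 0L
    for (i in seq_len(nrow(rois))) {
      key <- rois$roi[i]
      img <- study$images[[key]]
      mask <- mask_for(key)
      for (j in seq_len(nrow(schemes))) {
        vals <- extract_roi_features(
          img, mask,
          discretization_scheme(schemes$method[j], schemes$parameter[j]),
          config = config, aggregation = aggregation)
        k <- k + 1L
        out[[k]] <- tibble(
          sequence = rois$sequence[i], roi = key,
          scheme = schemes$scheme[j], method = schemes$method[j],
          parameter = schemes$parameter[j],
          feature = names(vals), value = unname(vals))
      }
    }
    dplyr::bind_rows(out)
  }
  ref_features <- extract_one(function(key) study$ref_masks[[key]])
  per_level <- lapply(levels_lab, function(lab) {
    sim_features <- extract_one(function(key) sim_rois[[key]]$selected[[lab]]$mask)
    sel <- icc_pairwise_simulated(ref_features, sim_features,
                                  icc_threshold = icc_threshold)
    sel |>
      dplyr::group_by(.data$sequence, .data$method, .data$scheme,
                      .data$parameter) |>
      dplyr::summarise(n_selected = sum(.data$selected), .groups = "drop") |>
      dplyr::mutate(dice = as.numeric(lab))
  })
  # Dice 1.0: reference against itself; every well-defined feature selected
  top <- icc_pairwise_simulated(ref_features, ref_features,
                                icc_threshold = icc_threshold) |>
    dplyr::group_by(.data$sequence, .data$method, .data$scheme,
                    .data$parameter) |>
    dplyr::summarise(n_selected = sum(.data$selected), .groups = "drop") |>
    dplyr::mutate(dice = 1.0)
  all_counts <- dplyr::bind_rows(c(per_level, list(top)))
  best <- all_counts |>
    dplyr::group_by(.data$dice, .data$sequence, .data$method) |>
    dplyr::arrange(dplyr::desc(.data$n_selected), .data$parameter,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  gap <- best |>
    dplyr::select("dice", "sequence", "method", "n_selected") |>
    tidyr::pivot_wider(names_from = "method", values_from = "n_selected") |>
    dplyr::mutate(gap = .data$fbs - .data$fbn)
  structure(best, class = c("dice_curve", class(best)),
            gap = gap, counts = all_counts)
}

#' @method glance dice_curve
#' @export
glance.dice_curve <- function(x, ...) attr(x, "gap")
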