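# ggplot2 visualizations of experiment results.

#' @importFrom ggplot2 ggplot aes geom_col geom_line geom_point facet_wrap
#'   labs position_dodge scale_x_reverse
NULL

#' Plot highest reproducible-feature counts per sequence and method
#'
#' @param object A `texture_experiment` from [run_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot texture_experiment
#' @export
autoplot.texture_experiment <- function(object, ...) {
  d <- object$summary |>
    tidyr::pivot_longer(cols = c("best_fbs", "best_fbn"),
                        names_to = "method", values_to = "n_selected") |>
    dplyr::mutate(method = toupper(sub("best_", "", .data$method)))
  ggplot(d, aes(x = factor(.data$sequence_name,
                           levels = unique(.data$sequence_name)),
                y = .data$n_selected, fill = .data$method)) +
    geom_col(position = position_dodge()) +
    labs(x = "Sequence", y = "Highest number of reproducible features",
         fill = "Discretization")
}

#' Plot reproducible-feature counts against the Dice coefficient
#'
#' @param object A `dice_curve` from [dice_curve()].
#' @param ... Unused.
#' @return A ggplot, one panel per sequence, Dice decreasing left to right.
#' @method autoplot dice_curve
#' @export
autoplot.dice_curve <- function(object, ...) {
  d <- as_tibble(object)
  ggplot(d, aes(x = .data$dice, y = .data$n_selected,
                colour = toupper(.data$method))) +
    geom_line() + geom_point() +
    scale_x_reverse() +
    facet_wrap(~sequence) +
    labs(x = "Dice coefficient", y = "Reproducible features",
         colour = "Discretization")
}

#' Plot per-setting selection counts
#'
#' Selected-feature counts for every discretization setting, per sequence.
#'
#' @param experiment A `texture_experiment`.
#' @return A ggplot.
#' @export
plot_selection_counts <- function(experiment) {
  d <- experiment$counts
  ggplot(d, aes(x = factor(.data$parameter), y = .data$n_selected,
                fill = toupper(.data$method))) +
    geom_col() +
    facet_wrap(~ .data$method + .data$sequence, scales = "free_x") +
    labs(x = "Bin size / bin number", y = "Selected features",
         fill = "Discretization")
}
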