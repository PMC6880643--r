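#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected attribute subset
#'
#' One row per selected attribute with its selection rank (1 = highest
#' weight), gain-ratio rank value and normalized weight.
#'
#' @param x A `dgs_result`.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `attribute`, `weight`.
#' @method tidy dgs_result
#' @export
tidy.dgs_result <- function(x, ...) {
  w <- x$weights[x$weights$attribute %in% x$selected, ]
  tibble::tibble(rank = seq_len(nrow(w)), attribute = w$attribute,
                 weight = w$weight)
}

#' One-row summary of a selection run
#'
#' @param x A `dgs_result`.
#' @param ... Unused.
#' @return A tibble with `best_accuracy`, `n_selected`, `best_fitness`,
#'   `generations`, `final_T`, `termination`.
#' @method glance dgs_result
#' @export
glance.dgs_result <- function(x, ...) {
  tibble::tibble(
    best_accuracy = x$best$AC,
    n_selected = x$best$s,
    best_fitness = x$best$f,
    generations = nrow(x$log),
    final_T = x$log$T[nrow(x$log)],
    termination = x$termination
  )
}

#' @export
print.dgs_result <- function(x, ...) {
  cat("Deep gene selection run\n")
  cat(sprintf("  generations: %d (%s)\n", nrow(x$log), x$termination))
  cat(sprintf("  best fitness: %.4f  (accuracy %.4f, %d attributes)\n",
              x$best$f, x$best$AC, x$best$s))
  cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Plot the trajectory of a selection run
#'
#' Two stacked panels over generations: the terminal-set size `T` (the
#' shrinking search space, log scale) and the generation-best fitness and
#' accuracy.
#'
#' @param object A `dgs_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dgs_result
#' @export
autoplot.dgs_result <- function(object, ...) {
  log <- object$log
  long <- dplyr::bind_rows(
    tibble::tibble(generation = log$generation, panel = "search space",
                   metric = "terminal set size", value = log$T),
    tibble::tibble(generation = log$generation, panel = "score",
                   metric = "best fitness", value = log$best_f),
    tibble::tibble(generation = log$generation, panel = "score",
                   metric = "best accuracy", value = log$best_AC)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
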