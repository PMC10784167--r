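#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an optimizer result
#'
#' One row per iteration with the best fitness so far.
#'
#' @param x A `fox_result`.
#' @param ... Unused.
#' @return A tibble with columns `iteration`, `best_fitness`, `algorithm`.
#' @export
tidy.fox_result <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$best_history),
    best_fitness = x$best_history,
    algorithm = x$algorithm
  )
}

#' One-row summary of an optimizer result
#'
#' @param x A `fox_result`.
#' @param ... Unused.
#' @return A tibble with `algorithm`, `best_fitness`, `n_evals`,
#'   `n_iterations`.
#' @export
glance.fox_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    best_fitness = x$best_fitness,
    n_evals = x$n_evals,
    n_iterations = length(x$best_history)
  )
}

#' Tidy repeated-trial statistics
#'
#' One row per run with its final best fitness.
#'
#' @param x A `trial_stats` object.
#' @param ... Unused.
#' @return A tibble with `fn`, `algorithm`, `run`, `final_best`.
#' @export
tidy.trial_stats <- function(x, ...) {
  tibble::tibble(
    fn = x$function_name,
    algorithm = x$algo_name,
    run = seq_along(x$per_run_finals),
    final_best = x$per_run_finals
  )
}

#' One-row Best/Mean/StD summary of repeated trials
#'
#' @param x A `trial_stats` object.
#' @param ... Unused.
#' @return A tibble with `fn`, `algorithm`, `n_runs`, `best`, `mean`, `std`.
#' @export
glance.trial_stats <- function(x, ...) {
  tibble::tibble(
    fn = x$function_name, algorithm = x$algo_name,
    n_runs = x$n_runs, best = x$best, mean = x$mean, std = x$std
  )
}

#' Tidy a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble of counts and metrics.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' One-row summary of a metrics report
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return A tibble with accuracy and the headline/macro metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy, precision = x$precision,
    sensitivity = x$sensitivity, f1 = x$f1,
    macro_precision = x$macro_precision,
    macro_sensitivity = x$macro_sensitivity,
    macro_f1 = x$macro_f1
  )
}

#' Convergence plot for an optimizer result
#'
#' Best-so-far fitness against iteration, on a log10 fitness scale when all
#' values are positive.
#'
#' @param object A `fox_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fox_result <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration,
                                        y = .data$best_fitness)) +
    ggplot2::geom_line(color = "#2166ac") +
    ggplot2::labs(x = "iteration", y = "best fitness",
                  title = sprintf("%s convergence", object$algorithm)) +
    ggplot2::theme_minimal()
  if (all(df$best_fitness > 0)) p <- p + ggplot2::scale_y_log10()
  p
}

#' Distribution plot of per-run final fitnesses
#'
#' @param object A `trial_stats` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_stats <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$algorithm, y = .data$final_best)) +
    ggplot2::geom_boxplot(fill = "#d1e5f0") +
    ggplot2::labs(y = "final best fitness", x = NULL,
                  title = sprintf("%s: %d runs", object$function_name,
                                  object$n_runs)) +
    ggplot2::theme_minimal()
}

#' Raster plot of a grayscale image
#'
#' @param img Numeric matrix (intensities).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_gray_image <- function(img, title = NULL) {
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.numeric(img)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom ggplot2 .data
NULL
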