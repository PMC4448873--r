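#' Tidy a null distribution
#'
#' @param x A `null_distribution`.
#' @param ... Unused.
#' @return Tibble: `bin`, `observed`, `lower`, `upper`, `range_lo`,
#'   `range_hi`.
#' @export
tidy.null_distribution <- function(x, ...) {
  dplyr::mutate(x$envelope, observed = as.numeric(x$observed),
                .after = "bin")
}

#' @rdname tidy.null_distribution
#' @export
glance.null_distribution <- function(x, ...) {
  tibble::tibble(name = x$name, n_samples = nrow(x$samples),
                 n_iterations = x$n_iterations,
                 sampling_interval = x$sampling_interval,
                 n_bins = ncol(x$samples))
}

#' Plot a null distribution against the observed statistic
#'
#' Scalar statistics get a histogram of permuted values with the observed
#' value as a vertical line; per-bin statistics get an envelope ribbon with
#' the observed profile.
#'
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.null_distribution <- function(object, ...) {
  if (ncol(object$samples) == 1) {
    df <- tibble::tibble(value = object$samples[, 1])
    ggplot2::ggplot(df, ggplot2::aes(x = .data$value)) +
      ggplot2::geom_histogram(bins = 30, fill = "grey70",
                              colour = "grey40") +
      ggplot2::geom_vline(xintercept = as.numeric(object$observed),
                          colour = "red", linewidth = 1) +
      ggplot2::labs(x = object$name, y = "permutations",
                    title = sprintf("%s: observed vs null", object$name))
  } else {
    df <- tidy(object)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$bin)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = "steelblue", alpha = 0.4) +
      ggplot2::geom_line(ggplot2::aes(y = .data$observed), colour = "black",
                         linewidth = 1) +
      ggplot2::labs(x = "bin", y = object$name,
                    title = sprintf("%s: observed vs 95%% null envelope",
                                    object$name))
  }
}

#' Plot a stability curve (optionally with its permuted reference)
#'
#' @param object A `stability_curve` tibble.
#' @param permuted Optional permuted-curve tibble to overlay as a ratio.
#' @param ... Unused.
#' @return A ggplot on a log-lag axis.
#' @export
autoplot.stability_curve <- function(object, permuted = NULL, ...) {
  if (is.null(permuted)) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_mid, y = .data$s)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "time gap between groups (s, log scale)",
                    y = "mean stability S")
  } else {
    df <- stability_ratio(object, permuted)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_mid, y = .data$ratio)) +
      ggplot2::geom_hline(yintercept = 1, linetype = 2) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "time gap between groups (s, log scale)",
                    y = "observed / permuted stability")
  }
}

#' Plot a saturation fit
#'
#' Data with the fitted linear and logistic curves; the logistic asymptote
#' is drawn as a dashed horizontal line.
#'
#' @param object A `saturation_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble::tibble(x = seq(min(df$x), max(df$x), length.out = 200))
  grid$linear <- predict(object$linear, newdata = grid)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$linear, colour = "linear")) +
    ggplot2::labs(x = "local population size",
                  y = sprintf("%s group size", object$response),
                  colour = "model")
  if (object$converged) {
    grid$logistic <- predict(object$logistic, newdata = grid)
    p <- p +
      ggplot2::geom_line(data = grid,
                         ggplot2::aes(y = .data$logistic,
                                      colour = "logistic")) +
      ggplot2::geom_hline(yintercept = coef(object$logistic)["K"],
                          linetype = 2, colour = "grey40")
  }
  p
}
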