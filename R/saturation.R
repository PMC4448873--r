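#' Local population and group-size table
#'
#' For every (feeder, sampling period) stratum: the number of unique
#' individuals recorded there, and the mean and maximum group size.
#'
#' @param matrix A [group_matrix()].
#' @return Tibble: `feeder_id`, `sampling_period`, `local_population`,
#'   `mean_group_size`, `max_group_size`, `n_groups`.
#' @export
local_population_table <- function(matrix) {
  stopifnot(inherits(matrix, "group_matrix"))
  inc <- matrix$incidence
  meta <- matrix$meta
  sz <- rowSums(inc)
  key <- paste(meta$feeder_id, meta$sampling_period, sep = "\r")
  purrr::map_dfr(split(seq_len(nrow(meta)), key), function(rows) {
    tibble::tibble(
      feeder_id = meta$feeder_id[rows[1]],
      sampling_period = meta$sampling_period[rows[1]],
      local_population = sum(colSums(inc[rows, , drop = FALSE]) > 0),
      mean_group_size = mean(sz[rows]),
      max_group_size = max(sz[rows]),
      n_groups = length(rows)
    )
  }) |>
    dplyr::arrange(.data$sampling_period, .data$feeder_id)
}

logistic3 <- function(x, K, x0, s) K / (1 + exp(-(x - x0) / s))

#' Fit and compare linear vs logistic models of group size
#'
#' Least-squares fits of `y = a + b x` and of the three-parameter logistic
#' `y = K / (1 + exp(-(x - x0)/s))` of group size on local population size,
#' compared by Gaussian-likelihood AIC. A positive `delta_aic`
#' (`AIC_linear - AIC_logistic`) supports saturation of group size with
#' local density; the fitted `K` is the saturation asymptote.
#'
#' @param records Tibble from [local_population_table()] (or any tibble
#'   with `local_population` plus the response columns).
#' @param response `"mean"` or `"max"` group size.
#' @return An object of class `saturation_fit`: list with `linear` (lm),
#'   `logistic` (nls or NULL on non-convergence), `delta_aic`, `response`,
#'   `converged`, `diagnostics`.
#' @export
fit_saturation <- function(records, response = c("mean", "max")) {
  response <- match.arg(response)
  ycol <- paste0(response, "_group_size")
  stopifnot(all(c("local_population", ycol) %in% names(records)))
  x <- records$local_population
  y <- records[[ycol]]
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5 || length(unique(x)) < 3) {
    stop("fit_saturation: need >= 5 records over >= 3 distinct population sizes",
         call. = FALSE)
  }
  df <- data.frame(x = x, y = y)
  linear <- lm(y ~ x, data = df)

  logistic <- NULL
  diagnostics <- character()
  starts <- list(
    c(K = max(y) * 1.05, x0 = median(x), s = sd(x) / 2),
    c(K = max(y) * 1.2, x0 = mean(x), s = sd(x)),
    c(K = max(y), x0 = stats::quantile(x, 0.25, names = FALSE),
      s = sd(x) / 4)
  )
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ K / (1 + exp(-(x - x0) / s)), data = df,
                        start = as.list(st),
                        lower = c(K = 1e-8, x0 = -Inf, s = 1e-8),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        diagnostics <<- c(diagnostics, conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) break
  }
  if (stats::var(y) <= .Machine$double.eps) {
    diagnostics <- c(diagnostics, "constant response: logistic degenerate")
    logistic <- NULL
  } else {
    logistic <- fit
  }
  delta_aic <- if (!is.null(logistic)) AIC(linear) - AIC(logistic) else NA_real_
  structure(list(linear = linear, logistic = logistic,
                 delta_aic = delta_aic, response = response,
                 converged = !is.null(logistic),
                 diagnostics = diagnostics,
                 data = tibble::as_tibble(df)),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("<saturation_fit> response: %s group size\n", x$response))
  if (x$converged) {
    p <- coef(x$logistic)
    cat(sprintf("  logistic: K = %.2f, x0 = %.2f, s = %.2f\n",
                p["K"], p["x0"], p["s"]))
    cat(sprintf("  delta AIC (linear - logistic) = %.2f (%s preferred)\n",
                x$delta_aic,
                if (x$delta_aic > 0) "logistic" else "linear"))
  } else {
    cat("  logistic fit did not converge:",
        paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @rdname fit_saturation
#' @param x A `saturation_fit`.
#' @param ... Unused.
#' @export
tidy.saturation_fit <- function(x, ...) {
  lin <- tibble::tibble(model = "linear",
                        term = c("intercept", "slope"),
                        estimate = unname(coef(x$linear)))
  if (x$converged) {
    log_ <- tibble::tibble(model = "logistic",
                           term = c("K", "x0", "s"),
                           estimate = unname(coef(x$logistic)))
    dplyr::bind_rows(lin, log_)
  } else {
    lin
  }
}

#' @rdname fit_saturation
#' @export
glance.saturation_fit <- function(x, ...) {
  tibble::tibble(
    response = x$response,
    n = nrow(x$data),
    aic_linear = AIC(x$linear),
    aic_logistic = if (x$converged) AIC(x$logistic) else NA_real_,
    delta_aic = x$delta_aic,
    asymptote = if (x$converged) unname(coef(x$logistic)["K"]) else NA_real_,
    preferred = dplyr::case_when(
      !x$converged ~ "linear",
      x$delta_aic > 0 ~ "logistic",
      TRUE ~ "linear")
  )
}

#' Descriptive week-effect check on residual group size
#'
#' Fixed-effects linear regression of the linear-model residuals of group
#' size (after controlling for local population size) on sampling period.
#' This is a descriptive check only; it is not a mixed model and makes no
#' allowance for repeated measures of the same feeder.
#'
#' @param records Tibble from [local_population_table()].
#' @param response `"mean"` or `"max"`.
#' @return Tidy tibble of the period coefficient.
#' @export
week_effect_check <- function(records, response = c("mean", "max")) {
  response <- match.arg(response)
  ycol <- paste0(response, "_group_size")
  base_fit <- lm(stats::reformulate("local_population", ycol),
                 data = records)
  fit <- lm(stats::resid(base_fit) ~ records$sampling_period)
  sm <- summary(fit)$coefficients
  tibble::tibble(term = "sampling_period",
                 estimate = sm[2, 1], std_error = sm[2, 2],
                 t_value = sm[2, 3], p_value = sm[2, 4])
}
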