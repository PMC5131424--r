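#' Tidy mortality-model objects
#'
#' Broom-style views: `tidy()` returns one row per parameter or component,
#' `glance()` one row of fit summaries.
#'
#' @param x A `code_params`, `siler_params`, `code_fit`, `code_fit_series`,
#'   `e0_decomposition` or `compression_gain` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.code_params <- function(x, ...) {
  tibble::tibble(term = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' @rdname tidiers
#' @export
tidy.siler_params <- function(x, ...) {
  tibble::tibble(term = names(unclass(x)),
                 value = unlist(unclass(x), use.names = FALSE))
}

#' @rdname tidiers
#' @export
tidy.code_fit <- function(x, ...) {
  tb <- tidy(x$params)
  names(tb)[2] <- "estimate"
  tb
}

#' @rdname tidiers
#' @export
glance.code_fit <- function(x, ...) {
  tibble::tibble(model = x$model, objective = x$objective,
                 r2_logq = x$r2_logq, r2_d = x$r2_d, r2_avg = x$r2_avg,
                 converged = x$converged, n_evals = x$n_evals)
}

#' @rdname tidiers
#' @export
tidy.code_fit_series <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidiers
#' @export
glance.code_fit_series <- function(x, ...) {
  ok <- !is.na(x$objective)
  tibble::tibble(n_years = nrow(x), n_failed = sum(!ok),
                 mean_r2_avg = mean(x$r2_avg[ok]),
                 min_r2_avg = if (any(ok)) min(x$r2_avg[ok]) else NA_real_,
                 delay_pace = if (sum(ok) >= 2)
                   delay_pace(x[ok, ]) else NA_real_)
}

#' @rdname tidiers
#' @export
tidy.e0_decomposition <- function(x, ...) {
  tb <- tibble::tibble(
    component = c("young_age", "delay_of_mortality", "middle_age",
                  "above_modal_age"),
    years = c(x$delta_young, x$delta_delay, x$delta_middle, x$delta_old))
  if (!is.null(x$unexplained)) {
    tb <- dplyr::bind_rows(tb, tibble::tibble(component = "unexplained",
                                              years = x$unexplained))
  }
  tb
}

#' @rdname tidiers
#' @export
tidy.compression_gain <- function(x, ...) {
  tibble::tibble(
    source = c("total", "young_age", "below_mode_slopes", "above_mode_slope",
               "interaction"),
    gain = c(x$total, x$young, x$middle, x$old, x$interaction))
}
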