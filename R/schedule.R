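#' Mortality schedules
#'
#' A mortality schedule is a tibble with one row per single year of age and
#' columns `age` and `value`, carrying as attributes whether the values are
#' death probabilities q(x) or central death rates m(x), and population
#' metadata. Ages label one-year intervals `[x, x + 1)`.
#'
#' @param age Integer age grid: strictly increasing, unit-spaced.
#' @param value Per-age death probabilities (in `[0, 1]`) or rates (>= 0);
#'   `NA` marks a gap (tolerated on input, rejected by fits).
#' @param kind `"probability"` or `"rate"`.
#' @param population,year,sex Optional metadata.
#' @return A tibble of class `mortality_schedule`.
#' @export
mortality_schedule <- function(age, value, kind = c("probability", "rate"),
                               population = NA_character_, year = NA_integer_,
                               sex = NA_character_) {
  kind <- match.arg(kind)
  if (length(age) == 0L) stop_input("age grid must be non-empty")
  if (length(age) != length(value)) {
    stop_input("`age` and `value` must have the same length")
  }
  if (any(!is.finite(age)) || any(age < 0)) {
    stop_input("ages must be finite and non-negative")
  }
  if (length(age) > 1L && any(diff(age) != 1)) {
    stop_input("ages must be strictly increasing and unit-spaced")
  }
  ok <- is.na(value) | (value >= 0 & (kind == "rate" | value <= 1))
  if (!all(ok)) {
    stop_domain(sprintf(
      "%s values must lie in %s; %d offending entries",
      kind, if (kind == "probability") "[0, 1]" else "[0, Inf)", sum(!ok)))
  }
  out <- tibble::tibble(age = as.numeric(age), value = as.numeric(value))
  attr(out, "value_kind") <- kind
  attr(out, "population") <- population
  attr(out, "year") <- year
  attr(out, "sex") <- sex
  class(out) <- c("mortality_schedule", class(out))
  out
}

#' @rdname mortality_schedule
#' @param x An object.
#' @export
is_mortality_schedule <- function(x) inherits(x, "mortality_schedule")

#' @rdname mortality_schedule
#' @param s A mortality schedule.
#' @export
schedule_kind <- function(s) attr(s, "value_kind") %||% "probability"

#' @rdname mortality_schedule
#' @export
schedule_meta <- function(s) {
  tibble::tibble(population = attr(s, "population") %||% NA_character_,
                 year = attr(s, "year") %||% NA_integer_,
                 sex = attr(s, "sex") %||% NA_character_,
                 kind = schedule_kind(s))
}

as_schedule <- function(x, kind = "probability") {
  if (is_mortality_schedule(x)) return(x)
  if (is.data.frame(x) && all(c("age", "value") %in% names(x))) {
    return(mortality_schedule(x$age, x$value, kind = kind))
  }
  stop_input("expected a mortality_schedule or a data frame with columns age, value")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  m <- schedule_meta(x)
  cat(sprintf("<mortality_schedule: %s, ages %g-%g%s>\n",
              m$kind, min(x$age), max(x$age),
              if (!is.na(m$year)) sprintf(", %s %s %s", m$population, m$sex, m$year) else ""))
  NextMethod()
}

#' Plot a mortality schedule on the log scale
#'
#' @param object A [mortality_schedule()].
#' @param ... Unused.
#' @return A ggplot object of log10 value against age.
#' @export
autoplot.mortality_schedule <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "age",
                  y = if (schedule_kind(object) == "probability") "q(x)" else "m(x)") +
    ggplot2::theme_minimal()
}
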