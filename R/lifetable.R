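#' Build a period life table from a death-probability schedule
#'
#' Standard single-year period life-table construction with radix 1:
#' `l(x + 1) = l(x) (1 - q(x))`, deaths `d(x) = l(x) q(x)`, person-years
#' `L(x) = l(x + 1) + a(x) d(x)` where `a(x)` is the average fraction of the
#' interval lived by those dying in it, and remaining life expectancy
#' `e(x) = sum(L(y), y >= x) / l(x)`. With radix 1 the `d` column is directly
#' the age-at-death distribution.
#'
#' Closure policies: `"terminal-one"` forces q = 1 at the last age so the
#' table is closed and `d` sums to 1; `"none"` leaves the schedule as data,
#' so `sum(d) + l(end + 1) = 1` and `e` is the truncated expectancy within
#' the observed span. For model schedules use [code_life_table()], which
#' extends the fitted curve to a high closing age first.
#'
#' @param data A probability [mortality_schedule()] (or a data frame with
#'   columns `age`, `value`).
#' @param closure `"terminal-one"` (default) or `"none"`.
#' @param a_frac Average fraction of the year lived by those dying, applied
#'   at all ages except age 0. Default 0.5.
#' @param a_frac_infant Separation factor for age 0, where deaths concentrate
#'   early in the interval. Default 0.14; exposed because the exact
#'   infant-separation rule is a protocol choice, not a model quantity.
#' @return A tibble of class `life_table` with columns `age`, `q`, `a_frac`,
#'   `l`, `d`, `L`, `e`; attribute `closure` records the policy and
#'   `open_survivorship` the mass beyond the last age (0 for closed tables).
#' @examples
#' lt <- life_table(code_schedule(0:100, code_preset("late")))
#' lt$e[1] # life expectancy at birth
#' @export
life_table <- function(data, closure = c("terminal-one", "none"),
                       a_frac = 0.5, a_frac_infant = 0.14) {
  closure <- match.arg(closure)
  s <- as_schedule(data)
  if (schedule_kind(s) != "probability") {
    stop_domain("life tables require a probability schedule; convert rates with mx_to_qx()")
  }
  if (anyNA(s$value)) stop_input("schedule contains gaps (NA values); life table undefined")
  q <- s$value
  n <- length(q)
  if (closure == "terminal-one") q[n] <- 1
  af <- rep(a_frac, n)
  if (s$age[1] == 0) af[1] <- a_frac_infant
  l <- cumprod(c(1, 1 - q))[seq_len(n)]
  d <- l * q
  l_next <- c(l[-1], l[n] * (1 - q[n]))
  L <- l_next + af * d
  e <- rev(cumsum(rev(L))) / l
  e[!is.finite(e)] <- 0 # ages reached by nobody
  out <- tibble::tibble(age = s$age, q = q, a_frac = af, l = l, d = d, L = L, e = e)
  attr(out, "closure") <- closure
  attr(out, "open_survivorship") <- l[n] * (1 - q[n])
  attr(out, "meta") <- schedule_meta(s)
  class(out) <- c("life_table", class(out))
  out
}

#' Model-extended life table for a CoDe parameter set
#'
#' Evaluates the fitted curve on `0:max_age`, closes the table by forcing
#' q = 1 at `max_age` (default 120, well beyond observed data so closure
#' artifacts are negligible), and builds the life table. All decomposition
#' quantities use this closure so components are comparable across parameter
#' sets.
#'
#' @param p A [code_params()] object.
#' @param max_age Closing age (default 120).
#' @inheritParams life_table
#' @return A `life_table` tibble.
#' @export
code_life_table <- function(p, max_age = 120, a_frac = 0.5, a_frac_infant = 0.14) {
  s <- withCallingHandlers(
    code_schedule(0:max_age, p),
    codemort_clip_warning = function(w) invokeRestart("muffleWarning"))
  life_table(s, closure = "terminal-one",
             a_frac = a_frac, a_frac_infant = a_frac_infant)
}

#' Life expectancy at birth implied by a CoDe parameter set
#'
#' @inheritParams code_life_table
#' @return e0 in years, from the model-extended closed life table.
#' @export
code_e0 <- function(p, max_age = 120) {
  life_table_e0(code_life_table(p, max_age = max_age))
}

#' @rdname code_e0
#' @param lt A `life_table`.
#' @export
life_table_e0 <- function(lt) lt$e[lt$age == min(lt$age)]

#' Age-at-death distribution of a schedule
#'
#' Projects the `d` column of the life table: `d(x) = l(x) q(x)`. With
#' `closure = "none"` the table is left open and `sum(d)` falls short of 1 by
#' the survivorship beyond the last age (recorded in the `open_survivorship`
#' attribute).
#'
#' @inheritParams life_table
#' @return A tibble with columns `age`, `d` and the same attributes as the
#'   life table.
#' @export
dx_from_q <- function(data, closure = c("terminal-one", "none"),
                      a_frac = 0.5, a_frac_infant = 0.14) {
  lt <- life_table(data, closure = match.arg(closure),
                   a_frac = a_frac, a_frac_infant = a_frac_infant)
  out <- tibble::tibble(age = lt$age, d = lt$d)
  attr(out, "closure") <- attr(lt, "closure")
  attr(out, "open_survivorship") <- attr(lt, "open_survivorship")
  out
}

#' Modal age at death of an age-at-death distribution
#'
#' Returns the age of the maximum of `d(x)` restricted to ages at or above
#' `min_age` (excluding the infant peak); ties are broken toward the oldest
#' age. Used to validate fitted modal ages against the adult mode of the
#' distribution.
#'
#' @param data A tibble with columns `age` and `d` (e.g. from
#'   [dx_from_q()]), or a bare numeric vector of deaths taken to start at
#'   age 0.
#' @param min_age Youngest age considered (default 5).
#' @return The modal age (single number).
#' @export
empirical_mode <- function(data, min_age = 5) {
  if (is.numeric(data) && is.null(dim(data))) {
    data <- tibble::tibble(age = seq_along(data) - 1, d = data)
  }
  if (!all(c("age", "d") %in% names(data))) {
    stop_input("expected columns `age` and `d`")
  }
  keep <- data$age >= min_age
  if (!any(keep)) stop_input("no ages at or above `min_age`")
  d <- data$d[keep]
  age <- data$age[keep]
  if (all(d == 0)) stop_input("distribution is all zero above `min_age`")
  mx <- max(d)
  max(age[d == mx]) # tie-break toward the older age
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("<life_table: ages %g-%g, closure %s, e0 = %.3f>\n",
              min(x$age), max(x$age), attr(x, "closure"), life_table_e0(x)))
  NextMethod()
}

#' Plot the age-at-death distribution of a life table
#'
#' @param object A `life_table`.
#' @param ... Unused.
#' @return A ggplot of `d(x)` against age.
#' @export
autoplot.life_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age, y = .data$d)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age", y = "d(x)") +
    ggplot2::theme_minimal()
}
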