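#' CoDe model parameters
#'
#' Constructs and validates the ten-parameter set of the CoDe death-probability
#' model. The curve is the sum of five additive components: an inverse-age
#' infant/childhood term `A / (x + B)`, a logistic accident-hump term with
#' plateau `a` (background mortality) centred at `m_hump`, and three
#' Kannisto-type logistic terms with slopes `b1`, `b2`, `b3` acting below
#' `M - h`, between `M - h` and `M`, and above the modal age at death `M`,
#' joined continuously by the constants returned by [continuity_constants()].
#'
#' @param A Infant-mortality level (> 0, dimensionless).
#' @param B Childhood-decline offset in years (> 0); larger `B` flattens the
#'   decline of mortality after infancy.
#' @param a Background-mortality level, the plateau of the accident-hump
#'   logistic (probability, >= 0).
#' @param b1,b2,b3 Slopes (per year, > 0) of the logistic terms in young
#'   adulthood (ages up to `M - h`), late adulthood (`M - h` to `M`), and old
#'   age (above `M`).
#' @param M Modal age at death in years, in `[40, 110]`.
#' @param h Width of the late-adulthood window in years; default 30, so with
#'   `M` near 80 the three adult regimes cover roughly ages up to 50, 50--80,
#'   and 80+. Must satisfy `h < M`.
#' @param g Old-age asymptote of the logistic terms (probability in `(0, 1]`);
#'   default 0.7, the death-probability bound implied by capping death rates
#'   at 1. Exposed so sensitivity runs (e.g. `g = 0.5`) are possible.
#' @param m_hump Centre of the adolescent rise in years; default 16.
#'
#' @return An object of class `code_params`: a named list of the ten values.
#' @seealso [code_q()], [continuity_constants()], [code_preset()]
#' @examples
#' p <- code_params(A = 0.003, B = 1, a = 2e-4,
#'                  b1 = 0.10, b2 = 0.14, b3 = 0.18, M = 90)
#' code_q(c(0, 50, 90, 100), p)
#' @export
code_params <- function(A, B, a, b1, b2, b3, M, h = 30, g = 0.7, m_hump = 16) {
  p <- structure(
    list(A = A, B = B, a = a, b1 = b1, b2 = b2, b3 = b3,
         M = M, h = h, g = g, m_hump = m_hump),
    class = "code_params"
  )
  validate_code_params(p)
  p
}

#' @rdname code_params
#' @param p A `code_params` object.
#' @export
validate_code_params <- function(p) {
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) {
      stop_domain(sprintf("parameter `%s` must be a single finite number", nm))
    }
  }
  for (nm in c("A", "B", "b1", "b2", "b3")) {
    if (p[[nm]] <= 0) {
      stop_domain(sprintf("parameter `%s` must be strictly positive (got %g)",
                          nm, p[[nm]]))
    }
  }
  if (p$a < 0) stop_domain(sprintf("parameter `a` must be >= 0 (got %g)", p$a))
  if (p$g <= 0 || p$g > 1) {
    stop_domain(sprintf("parameter `g` must lie in (0, 1] (got %g)", p$g))
  }
  if (p$M < 40 || p$M > 110) {
    stop_domain(sprintf("parameter `M` must lie in [40, 110] (got %g)", p$M))
  }
  if (p$h <= 0 || p$h >= p$M) {
    stop_domain(sprintf(
      "parameter `h` must satisfy 0 < h < M so the breakpoint M - h is a positive age (got h = %g, M = %g)",
      p$h, p$M))
  }
  invisible(p)
}

#' @export
print.code_params <- function(x, ...) {
  cat("<code_params>\n")
  cat(sprintf("  infant:      A = %.6g, B = %.6g\n", x$A, x$B))
  cat(sprintf("  background:  a = %.6g (hump centred at %.6g)\n", x$a, x$m_hump))
  cat(sprintf("  slopes:      b1 = %.6g, b2 = %.6g, b3 = %.6g\n", x$b1, x$b2, x$b3))
  cat(sprintf("  modal age:   M = %.6g  (window h = %.6g, asymptote g = %.6g)\n",
              x$M, x$h, x$g))
  invisible(x)
}

# Kannisto-type logistic term: b e^{b z} / (1 + (b/g) e^{b z}), z = x - M.
# Written with the exponential in the denominator for large z so it cannot
# overflow: the term increases monotonically from 0 to g.
kannisto_term <- function(b, g, z) {
  ez <- exp(b * z)
  out <- ifelse(is.infinite(ez), g, b * ez / (1 + (b / g) * ez))
  out
}

#' Continuity constants of the CoDe curve
#'
#' The three adult logistic terms would jump at the breakpoints `M - h` and
#' `M` if their slopes differ; two level offsets restore continuity. `c1` is
#' added on `(M - h, M]` and equals the gap between the `b1` and `b2`
#' logistics at `x = M - h`; `c2` is added above `M` and equals the gap
#' between the (offset) `b2` logistic and the `b3` logistic at `x = M`.
#' Both vanish when the slopes coincide.
#'
#' @param p A [code_params()] object.
#' @return A one-row tibble with columns `c1` and `c2` (probability units).
#' @examples
#' continuity_constants(code_preset("equal_slopes")) # both zero
#' @export
continuity_constants <- function(p) {
  validate_code_params(p)
  cc <- continuity_constants_(p$b1, p$b2, p$b3, p$g, p$h)
  tibble::tibble(c1 = cc[[1]], c2 = cc[[2]])
}

# bare numeric version used in hot loops
continuity_constants_ <- function(b1, b2, b3, g, h) {
  c1 <- kannisto_term(b1, g, -h) - kannisto_term(b2, g, -h)
  c2 <- b2 / (1 + b2 / g) + c1 - b3 / (1 + b3 / g)
  c(c1, c2)
}

# unvalidated vectorised evaluation of the full curve; the workhorse behind
# code_q(), code_schedule() and the fitting objective
code_q_ <- function(x, A, B, a, b1, b2, b3, M, h, g, m_hump) {
  cc <- continuity_constants_(b1, b2, b3, g, h)
  infant <- A / (x + B)
  eh <- exp(x - m_hump)
  background <- ifelse(is.infinite(eh), a, a * eh / (1 + eh))
  z <- x - M
  regime <- ifelse(
    x <= M - h, kannisto_term(b1, g, z),
    ifelse(x <= M,
           kannisto_term(b2, g, z) + cc[[1]],
           kannisto_term(b3, g, z) + cc[[2]]))
  infant + background + regime
}

#' Evaluate the CoDe death-probability curve
#'
#' Returns the model death probability `q(x)` at (possibly non-integer) ages
#' `x`. Exactly one of the three adult logistic regimes contributes at each
#' age, selected by real-valued comparison of `x` against `M - h` and `M`
#' (ages on a boundary belong to the left-closed side). The raw five-term sum
#' is returned unclipped; see [code_schedule()] for the capped schedule.
#'
#' @param x Vector of ages in years (>= 0).
#' @param p A [code_params()] object.
#' @return Numeric vector of death probabilities (raw sums, >= 0).
#' @export
code_q <- function(x, p) {
  validate_code_params(p)
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_domain("ages must be finite numbers")
  }
  if (any(x < 0)) stop_domain("ages must be non-negative")
  code_q_(x, p$A, p$B, p$a, p$b1, p$b2, p$b3, p$M, p$h, p$g, p$m_hump)
}

#' Decompose the CoDe curve into its five additive components
#'
#' Mainly a plotting and diagnostics aid: evaluates each component separately
#' (with the regime indicator and continuity constant applied) so their sum
#' equals [code_q()].
#'
#' @inheritParams code_q
#' @return A tibble with columns `age`, `infant`, `background`,
#'   `young_adult`, `late_adult`, `old_age`, `q`.
#' @export
code_terms <- function(x, p) {
  validate_code_params(p)
  if (any(x < 0)) stop_domain("ages must be non-negative")
  cc <- continuity_constants_(p$b1, p$b2, p$b3, p$g, p$h)
  eh <- exp(x - p$m_hump)
  z <- x - p$M
  in1 <- x <= p$M - p$h
  in2 <- !in1 & x <= p$M
  in3 <- x > p$M
  tb <- tibble::tibble(
    age = x,
    infant = p$A / (x + p$B),
    background = ifelse(is.infinite(eh), p$a, p$a * eh / (1 + eh)),
    young_adult = ifelse(in1, kannisto_term(p$b1, p$g, z), 0),
    late_adult = ifelse(in2, kannisto_term(p$b2, p$g, z) + cc[[1]], 0),
    old_age = ifelse(in3, kannisto_term(p$b3, p$g, z) + cc[[2]], 0)
  )
  tb$q <- tb$infant + tb$background + tb$young_adult + tb$late_adult + tb$old_age
  tb
}

#' Old-age limit of the CoDe curve
#'
#' As age grows the infant term vanishes, the background logistic approaches
#' `a`, and the old-age logistic approaches its asymptote `g`, so the curve
#' levels off at `a + g + c2`.
#'
#' @inheritParams continuity_constants
#' @return A single probability.
#' @export
code_asymptote <- function(p) {
  validate_code_params(p)
  cc <- continuity_constants_(p$b1, p$b2, p$b3, p$g, p$h)
  p$a + p$g + cc[[2]]
}

#' Evaluate the CoDe model on an age grid as a mortality schedule
#'
#' Vectorises [code_q()] over a contiguous integer age grid and wraps the
#' result as a probability [mortality_schedule()]. Sums exceeding 1 (possible
#' for extreme parameters since the background and continuity offsets are
#' additive) are clipped to 1 with a warning, so downstream life tables stay
#' valid.
#'
#' @param ages Integer age grid (contiguous, unit-spaced, non-negative).
#' @param p A [code_params()] object.
#' @param population,year,sex Optional metadata carried on the schedule.
#' @return A [mortality_schedule()] tibble with `value_kind = "probability"`.
#' @export
code_schedule <- function(ages, p, population = NA_character_,
                          year = NA_integer_, sex = NA_character_) {
  if (length(ages) == 0L) stop_input("age grid must be non-empty")
  q <- code_q(ages, p)
  if (any(q > 1)) {
    warn(sprintf("%d model death probabilities exceeded 1 and were clipped",
                 sum(q > 1)), class = "codemort_clip_warning")
    q <- pmin(q, 1)
  }
  mortality_schedule(ages, q, kind = "probability",
                     population = population, year = year, sex = sex)
}

#' Siler comparison model
#'
#' The five-parameter Siler death-rate curve used as the comparison model:
#' `m(x) = a1 exp(-a2 x) + c + b exp(b (x - M))` -- an exponential infant
#' decline, a Makeham background constant, and a Gompertz senescent term
#' re-parametrised through the modal age at death `M`. Unlike the CoDe model
#' it has a single adult slope `b`, so it cannot separate compression below
#' and above the mode.
#'
#' @param a1 Infant mortality level at age 0 (> 0).
#' @param a2 Childhood decline rate per year (> 0).
#' @param c Background mortality rate (>= 0).
#' @param b Senescent slope per year (> 0).
#' @param M Modal age at death in years.
#' @return An object of class `siler_params`.
#' @export
siler_params <- function(a1, a2, c, b, M) {
  s <- structure(list(a1 = a1, a2 = a2, c = c, b = b, M = M),
                 class = "siler_params")
  validate_siler_params(s)
  s
}

#' @rdname siler_params
#' @param s A `siler_params` object.
#' @export
validate_siler_params <- function(s) {
  for (nm in names(s)) {
    v <- s[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_domain(sprintf("parameter `%s` must be a single finite number", nm))
    }
  }
  for (nm in c("a1", "a2", "b")) {
    if (s[[nm]] <= 0) {
      stop_domain(sprintf("parameter `%s` must be strictly positive", nm))
    }
  }
  if (s$c < 0) stop_domain("parameter `c` must be >= 0")
  invisible(s)
}

#' @export
print.siler_params <- function(x, ...) {
  cat("<siler_params>\n")
  cat(sprintf("  a1 = %.6g, a2 = %.6g, c = %.6g, b = %.6g, M = %.6g\n",
              x$a1, x$a2, x$c, x$b, x$M))
  invisible(x)
}

siler_m_ <- function(x, a1, a2, c, b, M) {
  a1 * exp(-a2 * x) + c + b * exp(b * (x - M))
}

#' Evaluate the Siler death-rate curve
#'
#' @param x Vector of ages in years (>= 0).
#' @param s A [siler_params()] object.
#' @return Numeric vector of central death rates.
#' @export
siler_m <- function(x, s) {
  validate_siler_params(s)
  if (any(x < 0)) stop_domain("ages must be non-negative")
  siler_m_(x, s$a1, s$a2, s$c, s$b, s$M)
}

#' Evaluate the Siler model on an age grid
#'
#' @inheritParams code_schedule
#' @param s A [siler_params()] object.
#' @return A [mortality_schedule()] with `value_kind = "rate"`.
#' @export
siler_schedule <- function(ages, s, population = NA_character_,
                           year = NA_integer_, sex = NA_character_) {
  if (length(ages) == 0L) stop_input("age grid must be non-empty")
  mortality_schedule(ages, siler_m(ages, s), kind = "rate",
                     population = population, year = year, sex = sex)
}
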