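# substitution groups of the decomposition, keyed by component name
decomp_groups <- list(
  young = c("A", "a"),    # infant + background mortality
  delay = "M",            # shift of the adult schedule
  middle = c("b1", "b2"), # slopes below the modal age
  old = "b3"              # slope above the modal age
)

#' Decompose a change in life expectancy into delay and compression parts
#'
#' Sequential parameter substitution between two fitted parameter sets:
#' starting from `p_start`, the parameter groups are replaced one group at a
#' time by their `p_end` values -- by default young-age mortality (`A`, `a`),
#' then the modal age `M` (delay), then the slopes below the mode (`b1`,
#' `b2`), then the slope above the mode (`b3`). Each component is the change
#' in model life expectancy at birth between consecutive substituted life
#' tables (model-extended closure at `max_age`), so the four components
#' telescope exactly to the full model-based change. Components are path
#' dependent (a different `order` changes the split, never the total);
#' `average_orders = TRUE` averages each component over all 24 orders.
#'
#' The childhood-decline offset `B` belongs to no component: it is one of
#' the near-constant parameters, and its leverage on e0 is an order of
#' magnitude below `A`'s (see [param_sensitivity()]). The substitution chain
#' therefore ends at `p_end` with `B` (and the structural constants) held at
#' their start values, and `e0_end_model` is the life expectancy of that
#' final model.
#'
#' When observed life expectancies are supplied, the part of the observed
#' change that the substituted model does not reproduce -- fit discrepancy
#' in both years plus any drift in `B` -- is reported as `unexplained`.
#'
#' @param p_start,p_end Fitted [code_params()] for the two periods; their
#'   structural constants `h`, `g`, `m_hump` must match.
#' @param e0_obs Optional numeric length 2: observed e0 in the start and end
#'   period.
#' @param order Substitution order, a permutation of
#'   `c("young", "delay", "middle", "old")`.
#' @param average_orders Average components over all substitution orders
#'   (default `FALSE`).
#' @param max_age Closing age of the model life tables (default 120).
#' @return An object of class `e0_decomposition` with fields `e0_start`,
#'   `e0_end_model`, `delta_young`, `delta_delay`, `delta_middle`,
#'   `delta_old`, `unexplained` (NULL without observed values),
#'   `e0_obs_change`, `order`. [tidy()] gives a component table.
#' @examples
#' dec <- decompose_e0(code_preset("early"), code_preset("late"))
#' tidy(dec)
#' @export
decompose_e0 <- function(p_start, p_end, e0_obs = NULL,
                         order = c("young", "delay", "middle", "old"),
                         average_orders = FALSE, max_age = 120) {
  validate_code_params(p_start)
  validate_code_params(p_end)
  for (nm in c("h", "g", "m_hump")) {
    if (p_start[[nm]] != p_end[[nm]]) {
      stop_config(sprintf(
        "structural constant `%s` differs between the two parameter sets (%g vs %g); decomposition requires matching constants",
        nm, p_start[[nm]], p_end[[nm]]))
    }
  }
  if (!setequal(order, names(decomp_groups)) || length(order) != 4L) {
    stop_config("`order` must be a permutation of young, delay, middle, old")
  }
  if (!is.null(e0_obs) && length(e0_obs) != 2L) {
    stop_input("`e0_obs` must be length 2 (start, end)")
  }

  components_for <- function(ord) {
    p_cur <- p_start
    e_prev <- code_e0(p_cur, max_age = max_age)
    e_first <- e_prev
    comp <- setNames(numeric(4), ord)
    for (gname in ord) {
      for (fld in decomp_groups[[gname]]) p_cur[[fld]] <- p_end[[fld]]
      e_new <- code_e0(p_cur, max_age = max_age)
      comp[gname] <- e_new - e_prev
      e_prev <- e_new
    }
    list(comp = comp, e0_start = e_first, e0_end = e_prev)
  }

  if (average_orders) {
    perms <- all_permutations(names(decomp_groups))
    runs <- lapply(perms, components_for)
    comp <- Reduce(`+`, lapply(runs, function(r) r$comp[names(decomp_groups)])) /
      length(runs)
    base <- runs[[1]]
    e0_start <- base$e0_start
    e0_end <- base$e0_end
    order_used <- "average of all orders"
  } else {
    run <- components_for(order)
    comp <- run$comp[names(decomp_groups)]
    e0_start <- run$e0_start
    e0_end <- run$e0_end
    order_used <- order
  }

  out <- list(
    e0_start = e0_start, e0_end_model = e0_end,
    delta_young = unname(comp["young"]), delta_delay = unname(comp["delay"]),
    delta_middle = unname(comp["middle"]), delta_old = unname(comp["old"]),
    unexplained = if (is.null(e0_obs)) NULL else
      (e0_obs[2] - e0_obs[1]) - (e0_end - e0_start),
    e0_obs_change = if (is.null(e0_obs)) NULL else e0_obs[2] - e0_obs[1],
    order = order_used)
  class(out) <- "e0_decomposition"
  out
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

#' @export
print.e0_decomposition <- function(x, ...) {
  cat("<e0_decomposition>\n")
  cat(sprintf("  model e0: %.3f -> %.3f (change %.3f years)\n",
              x$e0_start, x$e0_end_model, x$e0_end_model - x$e0_start))
  cat(sprintf("  delay of mortality (M):        %+.3f\n", x$delta_delay))
  cat(sprintf("  young-age mortality (A, a):    %+.3f\n", x$delta_young))
  cat(sprintf("  middle-age mortality (b1, b2): %+.3f\n", x$delta_middle))
  cat(sprintf("  above modal age (b3):          %+.3f\n", x$delta_old))
  if (!is.null(x$unexplained)) {
    cat(sprintf("  unexplained (observed - model): %+.3f\n", x$unexplained))
  }
  invisible(x)
}

#' Pace of mortality delay from a fitted modal-age series
#'
#' The average speed at which the modal age at death moves to older ages:
#' ten times the least-squares slope of `M` on calendar year, in years of
#' age per decade.
#'
#' @param data A data frame with the year and modal-age columns (e.g. a
#'   [fit_series()] result).
#' @param year,M Column names (tidy-eval; defaults `year`, `M`).
#' @return Years per decade (single number).
#' @export
delay_pace <- function(data, year = year, M = M) {
  yr <- rlang::eval_tidy(rlang::enquo(year), data)
  m <- rlang::eval_tidy(rlang::enquo(M), data)
  keep <- is.finite(yr) & is.finite(m)
  yr <- yr[keep]; m <- m[keep]
  if (length(yr) < 2L) stop_input("need at least two years of fitted modal ages")
  10 * unname(coef(lm(m ~ yr))[2])
}

#' Shift-only age-at-death distribution
#'
#' The distribution that results from moving the modal age of `p_start` to
#' `M_new` while leaving every shape parameter unchanged -- a pure delay
#' (shift) of adult mortality with no compression.
#'
#' @param p_start A [code_params()] object.
#' @param M_new New modal age in years (must keep the parameter set valid:
#'   within `[40, 110]` and above `h`).
#' @param max_age Closing age (default 120).
#' @return A tibble with columns `age`, `d` (closed distribution).
#' @export
shift_only_distribution <- function(p_start, M_new, max_age = 120) {
  validate_code_params(p_start)
  p <- p_start
  p$M <- M_new
  validate_code_params(p)
  lt <- code_life_table(p, max_age = max_age)
  tibble::tibble(age = lt$age, d = lt$d)
}

#' Compression gain around the modal age
#'
#' Measures how much larger the share of deaths near the modal age is under
#' the fitted end-period distribution than under a pure shift of the
#' start-period distribution to the end-period modal age: the integral of
#' the positive part of `d_end(x) - d_shift(x)`, as a fraction of total
#' deaths. The total is split by source by substituting each shape group --
#' young age (`A`, `a`), below-mode slopes (`b1`, `b2`), above-mode slope
#' (`b3`) -- one at a time on top of the shift-only baseline; the split
#' terms sum to the total up to an interaction residual, reported
#' separately.
#'
#' @inheritParams decompose_e0
#' @param max_age Closing age (default 120).
#' @return An object of class `compression_gain`: fields `total`, `young`,
#'   `middle`, `old` (fractions of deaths), `interaction`, and `M_shift`.
#' @export
compression_gain <- function(p_start, p_end, max_age = 120) {
  validate_code_params(p_start)
  validate_code_params(p_end)
  for (nm in c("h", "g", "m_hump")) {
    if (p_start[[nm]] != p_end[[nm]]) {
      stop_config(sprintf("structural constant `%s` differs between the parameter sets", nm))
    }
  }
  d_shift <- shift_only_distribution(p_start, p_end$M, max_age = max_age)$d
  lt_end <- code_life_table(p_end, max_age = max_age)
  total <- sum(pmax(lt_end$d - d_shift, 0))

  gain_from <- function(fields) {
    p <- p_start
    p$M <- p_end$M
    for (fld in fields) p[[fld]] <- p_end[[fld]]
    dk <- code_life_table(p, max_age = max_age)$d
    sum(pmax(dk - d_shift, 0))
  }
  young <- gain_from(c("A", "a"))
  middle <- gain_from(c("b1", "b2"))
  old <- gain_from("b3")

  structure(list(total = total, young = young, middle = middle, old = old,
                 interaction = total - (young + middle + old),
                 M_shift = p_end$M - p_start$M),
            class = "compression_gain")
}

#' @export
print.compression_gain <- function(x, ...) {
  cat("<compression_gain>\n")
  cat(sprintf("  total gain around the mode: %.1f%% of deaths\n", 100 * x$total))
  cat(sprintf("  young age (A, a): %.1f%%  below-mode slopes (b1, b2): %.1f%%  above mode (b3): %.1f%%\n",
              100 * x$young, 100 * x$middle, 100 * x$old))
  cat(sprintf("  interaction residual: %.2f%%  (modal shift %.1f years)\n",
              100 * x$interaction, x$M_shift))
  invisible(x)
}

#' Life-expectancy sensitivity to a single parameter
#'
#' The change in model life expectancy at birth when one parameter is
#' multiplied by `factor`, all else unchanged. Useful for contrasting the
#' leverage of parameters (e.g. scaling `A` depresses e0 far more than
#' scaling `B` raises it).
#'
#' @param p A [code_params()] object.
#' @param name Parameter name (one of A, B, a, b1, b2, b3, M).
#' @param factor Positive multiplier.
#' @param max_age Closing age (default 120).
#' @return Signed change in e0, years.
#' @export
param_sensitivity <- function(p, name, factor, max_age = 120) {
  validate_code_params(p)
  if (!name %in% c("A", "B", "a", "b1", "b2", "b3", "M")) {
    stop_input(sprintf("unknown parameter `%s`", name))
  }
  p2 <- p
  p2[[name]] <- p2[[name]] * factor
  validate_code_params(p2)
  code_e0(p2, max_age = max_age) - code_e0(p, max_age = max_age)
}

#' Decomposition component bar chart
#'
#' @param object An `e0_decomposition`.
#' @param ... Unused.
#' @return A ggplot bar chart of the components in years.
#' @export
autoplot.e0_decomposition <- function(object, ...) {
  tb <- tidy(object)
  tb$component <- factor(tb$component, levels = tb$component)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$component, y = .data$years)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "contribution to Δe0 (years)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Compare the fitted end distribution with a pure shift
#'
#' Plots the start-period distribution, the shift-only distribution at the
#' end-period modal age, and the fitted end distribution; the area where
#' the fitted end curve exceeds the shifted one is the compression gain.
#'
#' @inheritParams compression_gain
#' @return A ggplot object.
#' @export
plot_compression <- function(p_start, p_end, max_age = 120) {
  d0 <- code_life_table(p_start, max_age = max_age)
  d1 <- code_life_table(p_end, max_age = max_age)
  ds <- shift_only_distribution(p_start, p_end$M, max_age = max_age)
  long <- dplyr::bind_rows(
    tibble::tibble(age = d0$age, d = d0$d, curve = "start"),
    tibble::tibble(age = ds$age, d = ds$d, curve = "shift only"),
    tibble::tibble(age = d1$age, d = d1$d, curve = "end (fitted)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$d,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age", y = "d(x)", colour = NULL) +
    ggplot2::theme_minimal()
}
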