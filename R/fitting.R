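#' Options controlling model fitting
#'
#' @param age_range Inclusive fit range in years (default `c(0, 100)`).
#' @param fixed Named list of parameters held at given values during
#'   optimization (e.g. `list(b1 = 0.1)`). The structural constants `h`,
#'   `g`, `m_hump` are always fixed and set here.
#' @param bounds Named list of `c(lower, upper)` box bounds per free
#'   parameter; `NULL` uses the defaults below.
#' @param n_starts Number of Latin-hypercube multi-start initial points
#'   (default 8); a data-driven heuristic start is always added.
#' @param seed Integer seed making the multi-start (and hence the whole fit)
#'   reproducible.
#' @param zero_q_policy How observed ages with q = 0 enter the log-q error:
#'   `"exclude"` (default) drops them from the log-q term only, `"floor"`
#'   replaces them by `q_floor`. They always remain in the d term.
#' @param q_floor Floor used under `zero_q_policy = "floor"`.
#' @param h,g,m_hump Structural constants of the CoDe curve (defaults 30,
#'   0.7, 16).
#'
#' @details Default bounds: `A` in (1e-6, 0.5), `B` in (0.01, 10), `a` in
#'   (1e-8, 0.05), each slope in (0.02, 0.5), `M` in (60, 105); for the Siler
#'   model `a1` in (1e-6, 1), `a2` in (0.01, 5), `c` in (1e-9, 0.05), `b` in
#'   (0.02, 0.5), `M` in (60, 105). Positive parameters are optimized on the
#'   log scale; `M` on the natural scale.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(age_range = c(0, 100), fixed = list(), bounds = NULL,
                        n_starts = 8, seed = 1,
                        zero_q_policy = c("exclude", "floor"), q_floor = 1e-6,
                        h = 30, g = 0.7, m_hump = 16) {
  zero_q_policy <- match.arg(zero_q_policy)
  if (n_starts < 1) stop_input("n_starts must be >= 1")
  structure(list(age_range = age_range, fixed = fixed, bounds = bounds,
                 n_starts = as.integer(n_starts), seed = as.integer(seed),
                 zero_q_policy = zero_q_policy, q_floor = q_floor,
                 h = h, g = g, m_hump = m_hump),
            class = "fit_options")
}

default_bounds_code <- function() {
  list(A = c(1e-6, 0.5), B = c(0.01, 10), a = c(1e-8, 0.05),
       b1 = c(0.02, 0.5), b2 = c(0.02, 0.5), b3 = c(0.02, 0.5),
       M = c(60, 105))
}

default_bounds_siler <- function() {
  list(a1 = c(1e-6, 1), a2 = c(0.01, 5), c = c(1e-9, 0.05),
       b = c(0.02, 0.5), M = c(60, 105))
}

# Observed-data summary entering the objective. Variances are population
# variances (denominator n) across the fitted ages, computed once from the
# observed schedule and treated as fixed weights during optimization, so
# objective = 1 - mean(R^2) holds exactly.
objective_data <- function(s, opts) {
  s <- as_schedule(s)
  if (schedule_kind(s) != "probability") s <- schedule_to_qx(s)
  keep <- s$age >= opts$age_range[1] & s$age <= opts$age_range[2]
  age <- s$age[keep]
  q <- s$value[keep]
  if (anyNA(q)) {
    stop_input(sprintf("schedule has gaps at ages %s inside the fit range; fill or exclude them",
                       paste(age[is.na(q)], collapse = ", ")))
  }
  mask <- if (opts$zero_q_policy == "exclude") q > 0 else rep(TRUE, length(q))
  q_log <- if (opts$zero_q_policy == "floor") pmax(q, opts$q_floor) else q
  obs_logq <- log(q_log[mask])
  l <- cumprod(c(1, 1 - q))[seq_along(q)]
  obs_d <- l * q
  var_logq <- mean((obs_logq - mean(obs_logq))^2)
  var_d <- mean((obs_d - mean(obs_d))^2)
  if (!is.finite(var_logq) || var_logq == 0 || var_d == 0) {
    stop_numeric("observed schedule is degenerate (zero variance in log q or d); the weighted objective is undefined. Supply a schedule with age variation.")
  }
  list(age = age, q = q, mask = mask, obs_logq = obs_logq, obs_d = obs_d,
       var_logq = var_logq, var_d = var_d)
}

# weighted combined error for a model q vector on the prepared data:
# (MSE[log q]/var[log q] + MSE[d]/var[d]) / 2
objective_value <- function(model_q, dat) {
  model_q <- pmin(pmax(model_q, 1e-300), 1)
  mse_logq <- mean((log(model_q[dat$mask]) - dat$obs_logq)^2)
  l <- cumprod(c(1, 1 - model_q))[seq_along(model_q)]
  mse_d <- mean((l * model_q - dat$obs_d)^2)
  r2_logq <- 1 - mse_logq / dat$var_logq
  r2_d <- 1 - mse_d / dat$var_d
  list(objective = (mse_logq / dat$var_logq + mse_d / dat$var_d) / 2,
       r2_logq = r2_logq, r2_d = r2_d, r2_avg = (r2_logq + r2_d) / 2)
}

#' Weighted combined fitting objective
#'
#' The estimation criterion: the average of the variance-normalized mean
#' squared errors of `log q(x)` and of the age-at-death distribution `d(x)`
#' over the fit range,
#' `(MSE[log q]/var[log q] + MSE[d]/var[d]) / 2`.
#' The log-q half weights relative errors (young ages), the d half weights
#' errors around the modal age; each half equals `1 - R^2`, so the objective
#' equals `1 - (R^2_logq + R^2_d)/2` and minimizing it maximizes average
#' R-squared. Variances are computed across ages of the observed data.
#'
#' @param data An observed probability [mortality_schedule()].
#' @param params A [code_params()] or [siler_params()] object to score.
#' @param options A [fit_options()] object.
#' @return A one-row tibble with `objective`, `r2_logq`, `r2_d`, `r2_avg`.
#' @export
fit_objective <- function(data, params, options = fit_options()) {
  dat <- objective_data(data, options)
  model_q <- model_q_for(params, dat$age)
  res <- objective_value(model_q, dat)
  tibble::as_tibble(res)
}

model_q_for <- function(params, age) {
  if (inherits(params, "code_params")) {
    validate_code_params(params)
    code_q_(age, params$A, params$B, params$a, params$b1, params$b2,
            params$b3, params$M, params$h, params$g, params$m_hump)
  } else if (inherits(params, "siler_params")) {
    validate_siler_params(params)
    af <- rep(0.5, length(age))
    af[age == 0] <- 0.14
    mx_to_qx(siler_m_(age, params$a1, params$a2, params$c, params$b, params$M), af)
  } else {
    stop_input("expected code_params or siler_params")
  }
}

# ---- internal optimizer ----------------------------------------------------

# minimize fn over a box with nlminb from several starts (rows of `starts`,
# already in the transformed space); returns the polished best
multistart_nlminb <- function(fn, starts, lower, upper) {
  ctrl <- list(eval.max = 4000, iter.max = 2000, rel.tol = 1e-14,
               x.tol = 1.5e-12)
  n_evals <- 0L
  runs <- apply(starts, 1, function(st) {
    r <- tryCatch(nlminb(st, fn, lower = lower, upper = upper, control = ctrl),
                  error = function(e) NULL)
    r
  })
  runs <- Filter(Negate(is.null), runs)
  if (length(runs) == 0L) {
    stop_convergence("optimizer failed from every start")
  }
  objs <- vapply(runs, function(r) r$objective, numeric(1))
  n_evals <- sum(vapply(runs, function(r) r$evaluations[["function"]], numeric(1)))
  best <- runs[[which.min(objs)]]
  # polish: restart from the incumbent until no further improvement
  for (i in 1:3) {
    r2 <- tryCatch(nlminb(best$par, fn, lower = lower, upper = upper, control = ctrl),
                   error = function(e) NULL)
    if (is.null(r2)) break
    n_evals <- n_evals + r2$evaluations[["function"]]
    if (r2$objective < best$objective - 1e-16) best <- r2 else {
      if (r2$objective <= best$objective) best <- r2
      break
    }
  }
  # PORT codes 3-7 ("relative/X/singular convergence") terminate at a
  # stationary point; only limit hits and false convergence count as failure
  ok <- best$convergence == 0 ||
    (grepl("convergence", best$message %||% "") &&
       !grepl("false convergence", best$message %||% ""))
  list(par = best$par, objective = best$objective,
       converged = ok, n_evals = n_evals,
       start_objectives = objs)
}

# transformed (log for positive parameters, natural for M) <-> natural
to_theta <- function(x, names) ifelse(names == "M", x, log(x))
from_theta <- function(theta, names) ifelse(names == "M", theta, exp(theta))

lhs_starts <- function(n, lower_t, upper_t, seed) {
  k <- length(lower_t)
  u <- withr::with_seed(seed, lhs::randomLHS(n, k))
  sweep(sweep(u, 2, upper_t - lower_t, "*"), 2, lower_t, "+")
}

# crude data-driven start: infant level from q(0), background from the
# floor of adult q, modal age from the adult mode of d, slopes at 0.1
heuristic_start_code <- function(dat, free, bounds, opts) {
  q <- dat$q; age <- dat$age
  clamp <- function(v, b) min(max(v, b[1] * 1.0000001), b[2] * 0.9999999)
  d <- dat$obs_d
  M0 <- tryCatch(empirical_mode(tibble::tibble(age = age, d = d), min_age = 40),
                 error = function(e) 80)
  adult <- q[age >= 25 & age <= 35 & q > 0]
  st <- c(A = max(q[age == min(age)], 1e-5), B = 1,
          a = if (length(adult)) stats::median(adult) else 3e-4,
          b1 = 0.1, b2 = 0.1, b3 = 0.12, M = M0)
  vapply(free, function(nm) clamp(st[[nm]], bounds[[nm]]), numeric(1))
}

heuristic_start_siler <- function(dat, free, bounds, opts) {
  q <- dat$q; age <- dat$age
  clamp <- function(v, b) min(max(v, b[1] * 1.0000001), b[2] * 0.9999999)
  M0 <- tryCatch(empirical_mode(tibble::tibble(age = age, d = dat$obs_d), min_age = 40),
                 error = function(e) 80)
  adult <- q[age >= 25 & age <= 35 & q > 0]
  st <- c(a1 = max(q[age == min(age)], 1e-5), a2 = 0.5,
          c = if (length(adult)) stats::median(adult) else 3e-4,
          b = 0.1, M = M0)
  vapply(free, function(nm) clamp(st[[nm]], bounds[[nm]]), numeric(1))
}

fit_engine <- function(data, options, model = c("code", "siler")) {
  model <- match.arg(model)
  dat <- objective_data(data, options)
  if (model == "code") {
    if (max(dat$age) < 90 || min(dat$age) > 5) {
      stop_input("schedule must cover ages from early childhood to at least 90 so all five components are identified")
    }
    all_names <- c("A", "B", "a", "b1", "b2", "b3", "M")
    bounds <- modifyList(default_bounds_code(), options$bounds %||% list())
  } else {
    if (length(dat$age) < 30 || max(dat$age) < 90) {
      stop_input("schedule too short to identify the Siler parameters; supply ages spanning childhood to at least 90")
    }
    all_names <- c("a1", "a2", "c", "b", "M")
    bounds <- modifyList(default_bounds_siler(), options$bounds %||% list())
  }
  fixed <- options$fixed
  bad <- setdiff(names(fixed), all_names)
  if (length(bad)) stop_input(sprintf("unknown fixed parameter(s): %s", paste(bad, collapse = ", ")))
  free <- setdiff(all_names, names(fixed))
  if (length(free) == 0L) stop_input("no free parameters to fit")
  for (nm in free) {
    if (bounds[[nm]][1] >= bounds[[nm]][2]) {
      stop_input(sprintf("bounds for `%s` are empty", nm))
    }
  }

  build_params <- if (model == "code") {
    function(vals) {
      full <- modifyList(as.list(vals), fixed)
      code_params(A = full$A, B = full$B, a = full$a, b1 = full$b1,
                  b2 = full$b2, b3 = full$b3, M = full$M,
                  h = options$h, g = options$g, m_hump = options$m_hump)
    }
  } else {
    function(vals) {
      full <- modifyList(as.list(vals), fixed)
      siler_params(a1 = full$a1, a2 = full$a2, c = full$c, b = full$b, M = full$M)
    }
  }

  age <- dat$age
  af <- rep(0.5, length(age)); af[age == 0] <- 0.14
  fn <- if (model == "code") {
    fx <- modifyList(setNames(as.list(rep(NA_real_, length(all_names))), all_names), fixed)
    function(theta) {
      v <- from_theta(theta, free)
      full <- fx
      full[free] <- as.list(v)
      q <- code_q_(age, full$A, full$B, full$a, full$b1, full$b2, full$b3,
                   full$M, options$h, options$g, options$m_hump)
      ov <- objective_value(q, dat)$objective
      if (!is.finite(ov)) 1e12 else ov
    }
  } else {
    fx <- modifyList(setNames(as.list(rep(NA_real_, length(all_names))), all_names), fixed)
    function(theta) {
      v <- from_theta(theta, free)
      full <- fx
      full[free] <- as.list(v)
      m <- siler_m_(age, full$a1, full$a2, full$c, full$b, full$M)
      ov <- objective_value(mx_to_qx(m, af), dat)$objective
      if (!is.finite(ov)) 1e12 else ov
    }
  }

  lower_t <- to_theta(vapply(free, function(nm) bounds[[nm]][1], numeric(1)), free)
  upper_t <- to_theta(vapply(free, function(nm) bounds[[nm]][2], numeric(1)), free)
  starts <- lhs_starts(options$n_starts, lower_t, upper_t, options$seed)
  heur <- if (model == "code") heuristic_start_code(dat, free, bounds, options)
          else heuristic_start_siler(dat, free, bounds, options)
  starts <- rbind(to_theta(heur, free), starts)

  run <- multistart_nlminb(fn, starts, lower_t, upper_t)
  params <- build_params(setNames(as.list(from_theta(run$par, free)), free))
  score <- objective_value(model_q_for(params, age), dat)

  res <- tibble::tibble(
    age = age, obs_q = dat$q, fit_q = model_q_for(params, age))
  res$obs_d <- dat$obs_d
  l <- cumprod(c(1, 1 - res$fit_q))[seq_len(nrow(res))]
  res$fit_d <- l * res$fit_q

  structure(list(model = model, params = params,
                 objective = score$objective,
                 r2_logq = score$r2_logq, r2_d = score$r2_d,
                 r2_avg = score$r2_avg,
                 converged = run$converged, n_evals = run$n_evals,
                 start_objectives = run$start_objectives,
                 age_range = options$age_range, seed = options$seed,
                 residuals = res, options = options),
            class = "code_fit")
}

#' Fit the CoDe model to an observed mortality schedule
#'
#' Estimates the free parameters (by default `A`, `B`, `a`, `b1`, `b2`,
#' `b3`, `M`; the constants `h`, `g`, `m_hump` are fixed) by minimizing
#' [fit_objective()] with a bounded quasi-Newton search from `n_starts`
#' Latin-hypercube initial points plus one data-driven start; the best local
#' optimum is polished and returned. Deterministic given `options$seed`.
#'
#' @param data An observed [mortality_schedule()]; rates are converted to
#'   probabilities first.
#' @param options A [fit_options()] object.
#' @return An object of class `code_fit` with elements `params`,
#'   `objective`, `r2_logq`, `r2_d`, `r2_avg`, `converged`, `n_evals`, and a
#'   `residuals` tibble of per-age observed and fitted q and d. Use
#'   [tidy()] / [glance()] for tabular views.
#' @examples
#' s <- generate(code_preset("late"), ages = 0:100)
#' fit <- fit_code(s, fit_options(n_starts = 4, seed = 1))
#' glance(fit)
#' @export
fit_code <- function(data, options = fit_options()) {
  fit_engine(data, options, model = "code")
}

#' Fit the Siler comparison model
#'
#' Same objective machinery as [fit_code()], applied to the Siler death-rate
#' curve. Model rates are converted to probabilities (standard interval
#' conversion, infant separation factor 0.14) before scoring, so the two
#' models are compared on a common scale.
#'
#' @inheritParams fit_code
#' @return A `code_fit` with `model = "siler"` and [siler_params()] inside.
#' @export
fit_siler <- function(data, options = fit_options()) {
  fit_engine(data, options, model = "siler")
}

#' Fit the CoDe model to a series of annual schedules
#'
#' Fits each year in calendar order. From the second year on, a warm start
#' at the previous year's solution is run alongside the cold multi-start and
#' the better objective wins, so the warm start can never degrade a year's
#' fit. Per-year failures are caught, flagged in the `error` column, and do
#' not abort the series.
#'
#' @param data A named list of [mortality_schedule()] objects (names or
#'   metadata give the years), or a long tibble with columns `year`, `age`,
#'   `value`.
#' @param options A [fit_options()] object (shared across years).
#' @return A tibble of class `code_fit_series`: one row per year with the
#'   fitted parameters, `objective`, `r2_logq`, `r2_d`, `r2_avg`,
#'   `converged` and `error`; the full `code_fit` objects are in
#'   `attr(, "fits")`.
#' @export
fit_series <- function(data, options = fit_options()) {
  schedules <- series_schedules(data)
  years <- as.integer(names(schedules))
  ord <- order(years)
  schedules <- schedules[ord]
  years <- years[ord]

  fits <- vector("list", length(years))
  errors <- rep(NA_character_, length(years))
  prev <- NULL
  for (i in seq_along(years)) {
    fit <- tryCatch(fit_engine(schedules[[i]], options, model = "code"),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errors[i] <- conditionMessage(fit)
      fits[i] <- list(NULL)
      next
    }
    if (!is.null(prev)) {
      warm <- tryCatch(
        refit_from(schedules[[i]], options, prev$params),
        error = function(e) NULL)
      if (!is.null(warm) && warm$objective < fit$objective) fit <- warm
    }
    fits[[i]] <- fit
    prev <- fit
  }

  rows <- purrr::map2(fits, years, function(f, y) {
    if (is.null(f)) {
      tibble::tibble(year = y, A = NA_real_, B = NA_real_, a = NA_real_,
                     b1 = NA_real_, b2 = NA_real_, b3 = NA_real_, M = NA_real_,
                     objective = NA_real_, r2_logq = NA_real_, r2_d = NA_real_,
                     r2_avg = NA_real_, converged = FALSE)
    } else {
      p <- f$params
      tibble::tibble(year = y, A = p$A, B = p$B, a = p$a, b1 = p$b1,
                     b2 = p$b2, b3 = p$b3, M = p$M,
                     objective = f$objective, r2_logq = f$r2_logq,
                     r2_d = f$r2_d, r2_avg = f$r2_avg, converged = f$converged)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$error <- errors
  attr(out, "fits") <- setNames(fits, years)
  class(out) <- c("code_fit_series", class(out))
  out
}

# single local optimization warm-started at `params` (all free parameters)
refit_from <- function(s, options, params) {
  opts <- options
  dat <- objective_data(s, opts)
  free <- setdiff(c("A", "B", "a", "b1", "b2", "b3", "M"), names(opts$fixed))
  bounds <- modifyList(default_bounds_code(), opts$bounds %||% list())
  start <- vapply(free, function(nm) {
    min(max(params[[nm]], bounds[[nm]][1]), bounds[[nm]][2])
  }, numeric(1))
  age <- dat$age
  fn <- function(theta) {
    v <- setNames(from_theta(theta, free), free)
    full <- modifyList(as.list(v), opts$fixed)
    q <- code_q_(age, full$A, full$B, full$a, full$b1, full$b2, full$b3,
                 full$M, opts$h, opts$g, opts$m_hump)
    ov <- objective_value(q, dat)$objective
    if (!is.finite(ov)) 1e12 else ov
  }
  lower_t <- to_theta(vapply(free, function(nm) bounds[[nm]][1], numeric(1)), free)
  upper_t <- to_theta(vapply(free, function(nm) bounds[[nm]][2], numeric(1)), free)
  run <- multistart_nlminb(fn, matrix(to_theta(start, free), nrow = 1),
                           lower_t, upper_t)
  vals <- setNames(as.list(from_theta(run$par, free)), free)
  full <- modifyList(vals, opts$fixed)
  params_new <- code_params(A = full$A, B = full$B, a = full$a, b1 = full$b1,
                            b2 = full$b2, b3 = full$b3, M = full$M,
                            h = opts$h, g = opts$g, m_hump = opts$m_hump)
  score <- objective_value(model_q_for(params_new, age), dat)
  res <- tibble::tibble(age = age, obs_q = dat$q,
                        fit_q = model_q_for(params_new, age))
  res$obs_d <- dat$obs_d
  l <- cumprod(c(1, 1 - res$fit_q))[seq_len(nrow(res))]
  res$fit_d <- l * res$fit_q
  structure(list(model = "code", params = params_new,
                 objective = score$objective, r2_logq = score$r2_logq,
                 r2_d = score$r2_d, r2_avg = score$r2_avg,
                 converged = run$converged, n_evals = run$n_evals,
                 start_objectives = run$start_objectives,
                 age_range = opts$age_range, seed = opts$seed,
                 residuals = res, options = opts),
            class = "code_fit")
}

# accept a named list of schedules or a long (year, age, value) tibble
series_schedules <- function(data) {
  if (is.data.frame(data)) {
    if (!all(c("year", "age", "value") %in% names(data))) {
      stop_input("series data frame needs columns year, age, value")
    }
    sp <- split(data, data$year)
    return(lapply(sp, function(dd) mortality_schedule(dd$age, dd$value,
                                                      year = dd$year[1])))
  }
  if (!is.list(data) || !all(vapply(data, is_mortality_schedule, logical(1)))) {
    stop_input("expected a list of mortality_schedule objects or a long data frame")
  }
  nms <- names(data)
  if (is.null(nms) || any(!nzchar(nms))) {
    yrs <- vapply(data, function(s) as.integer(schedule_meta(s)$year), integer(1))
    if (anyNA(yrs)) stop_input("schedules must be named by year or carry year metadata")
    nms <- as.character(yrs)
  }
  setNames(data, nms)
}

#' @export
print.code_fit <- function(x, ...) {
  cat(sprintf("<code_fit: %s model, objective %.3e, R2(log q) %.5f, R2(d) %.5f%s>\n",
              x$model, x$objective, x$r2_logq, x$r2_d,
              if (x$converged) "" else ", NOT converged"))
  print(x$params)
  invisible(x)
}

#' Observed against fitted curves
#'
#' @param object A `code_fit`.
#' @param ... Unused.
#' @return A ggplot with two facets: log10 q(x) and d(x), observed (points)
#'   and fitted (line).
#' @export
autoplot.code_fit <- function(object, ...) {
  r <- object$residuals
  long <- dplyr::bind_rows(
    tibble::tibble(age = r$age, value = log10(pmax(r$obs_q, 1e-12)),
                   fitted = log10(pmax(r$fit_q, 1e-12)), measure = "log10 q(x)"),
    tibble::tibble(age = r$age, value = r$obs_d, fitted = r$fit_d,
                   measure = "d(x)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value), size = 0.6,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::facet_wrap(~measure, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "age", y = NULL) +
    ggplot2::theme_minimal()
}
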