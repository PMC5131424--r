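#' Preset CoDe parameter fixtures
#'
#' Three fully specified parameter sets spanning the qualitative range seen
#' in post-war low-mortality countries, for simulation and testing without
#' any external data. `"early"` resembles a mid-century schedule (high
#' infant and background mortality, modal age near 80, moderate slopes);
#' `"late"` a recent one (low young-age mortality, modal age near 90,
#' steeper compression slopes above and below the mode); `"equal_slopes"`
#' has `b1 = b2 = b3`, collapsing the three adult terms to a single
#' logistic. The young-adult slope is near 0.10 throughout, the empirically
#' near-constant value, and the slopes are balanced so the adult mode of
#' each preset's d(x) falls within a year of `M`, preserving the
#' interpretation of `M` as the modal age at death. The numbers are package
#' fixtures, not estimates.
#'
#' @param name `"early"`, `"late"` or `"equal_slopes"`.
#' @return A [code_params()] object.
#' @export
code_preset <- function(name = c("early", "late", "equal_slopes")) {
  name <- tryCatch(match.arg(name),
                   error = function(e) stop_input(sprintf(
                     "unknown preset '%s' (use early, late or equal_slopes)",
                     paste(name, collapse = ", "))))
  switch(name,
    early = code_params(A = 0.04, B = 1.2, a = 8e-4,
                        b1 = 0.10, b2 = 0.10, b3 = 0.11, M = 80),
    late = code_params(A = 0.003, B = 1.0, a = 2e-4,
                       b1 = 0.10, b2 = 0.14, b3 = 0.16, M = 90),
    equal_slopes = code_params(A = 0.01, B = 1.0, a = 4e-4,
                               b1 = 0.11, b2 = 0.11, b3 = 0.11, M = 82))
}

#' Generate a mortality schedule with known truth
#'
#' Evaluates a CoDe (or Siler) truth on an age grid and optionally adds
#' binomial sampling noise: with finite `exposure` the observed deaths at
#' each age are drawn independently as `Binomial(exposure, q(x))` and the
#' schedule holds `deaths / exposure`, emulating the random fluctuation of
#' unsmoothed data from a finite population. `exposure = Inf` (default)
#' returns the model schedule exactly. Deterministic given `seed`. The truth
#' and generator settings are recorded in attributes so recovery tests can
#' compare against them.
#'
#' @param p A [code_params()] or [siler_params()] truth. Siler truths are
#'   converted from rates to probabilities before sampling so all schedules
#'   are on the probability scale.
#' @param ages Integer age grid (default `0:100`).
#' @param exposure Persons per age; `Inf` means noise-free.
#' @param seed Integer seed (required for finite exposure).
#' @param replicates Number of independent schedules to draw; if > 1 a list
#'   is returned and replicate r uses `seed + r - 1`.
#' @param population,year,sex Metadata for the schedule(s).
#' @return A probability [mortality_schedule()] with attributes `truth`,
#'   `exposure`, `seed`; or a list of them when `replicates > 1`.
#' @export
generate <- function(p, ages = 0:100, exposure = Inf, seed = NULL,
                     replicates = 1, population = "synthetic",
                     year = NA_integer_, sex = NA_character_) {
  if (replicates < 1) stop_input("replicates must be >= 1")
  if (is.finite(exposure) && exposure <= 0) stop_input("exposure must be positive")
  if (is.finite(exposure) && is.null(seed)) {
    stop_input("a seed is required for noisy generation")
  }
  q <- if (inherits(p, "siler_params")) {
    model_q_for(p, ages)
  } else {
    code_schedule(ages, p)$value
  }
  if (any(q > 1 | q < 0)) stop_input("truth yields death probabilities outside [0, 1]")

  one <- function(rep_seed) {
    v <- if (is.infinite(exposure)) q else {
      withr::with_seed(rep_seed,
        rbinom(length(q), size = as.integer(exposure), prob = q) / exposure)
    }
    s <- mortality_schedule(ages, v, kind = "probability",
                            population = population, year = year, sex = sex)
    attr(s, "truth") <- p
    attr(s, "exposure") <- exposure
    attr(s, "seed") <- rep_seed
    s
  }
  if (replicates == 1) one(seed) else {
    lapply(seq_len(replicates), function(r) one(seed + r - 1L))
  }
}

#' Generate an annual series of schedules with drifting parameters
#'
#' Builds one schedule per calendar year from a base parameter set plus
#' linear per-year drifts -- emulating the observed secular trends (rising
#' modal age, steepening late-adulthood and old-age slopes, near-constant
#' young-adult slope). Year `t` (0-based within `years`) uses
#' `p0[[k]] + t * drift[[k]]`, validated each year.
#'
#' @param p0 Base [code_params()] (the first year).
#' @param drifts Named numeric vector/list of per-year additive drifts,
#'   e.g. `c(M = 0.2, b2 = 5e-4)`.
#' @param years Integer vector of calendar years.
#' @param exposure,seed As in [generate()]; with finite exposure year i uses
#'   `seed + i - 1`.
#' @return A named list of schedules (one per year) with attribute `truth`:
#'   a tibble of the per-year true parameters.
#' @export
generate_series <- function(p0, drifts = c(M = 0), years, exposure = Inf,
                            seed = NULL) {
  validate_code_params(p0)
  drifts <- unlist(drifts)
  bad <- setdiff(names(drifts), c("A", "B", "a", "b1", "b2", "b3", "M"))
  if (length(bad)) stop_input(sprintf("unknown drift parameter(s): %s",
                                      paste(bad, collapse = ", ")))
  if (is.finite(exposure) && is.null(seed)) {
    stop_input("a seed is required for noisy generation")
  }
  out <- vector("list", length(years))
  truth_rows <- vector("list", length(years))
  for (i in seq_along(years)) {
    p <- p0
    for (nm in names(drifts)) p[[nm]] <- p0[[nm]] + (i - 1) * drifts[[nm]]
    ok <- tryCatch({validate_code_params(p); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop_input(sprintf("drift drives parameters out of domain in year %d: %s",
                         years[i], ok))
    }
    out[[i]] <- generate(p, exposure = exposure,
                         seed = if (is.null(seed)) NULL else seed + i - 1L,
                         year = years[i])
    truth_rows[[i]] <- tibble::tibble(year = years[i], A = p$A, B = p$B,
                                      a = p$a, b1 = p$b1, b2 = p$b2,
                                      b3 = p$b3, M = p$M)
  }
  names(out) <- years
  attr(out, "truth") <- dplyr::bind_rows(truth_rows)
  out
}
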