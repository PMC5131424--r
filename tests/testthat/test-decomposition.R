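test_that("identical parameter sets decompose to zero everywhere", {
  p <- code_preset("late")
  dec <- decompose_e0(p, p)
  expect_equal(dec$delta_young, 0)
  expect_equal(dec$delta_delay, 0)
  expect_equal(dec$delta_middle, 0)
  expect_equal(dec$delta_old, 0)
  expect_null(dec$unexplained)
})

test_that("a modal-age-only change loads entirely on the delay component", {
  p0 <- code_preset("early")
  p1 <- p0
  p1$M <- p0$M + 8
  dec <- decompose_e0(p0, p1)
  total <- dec$e0_end_model - dec$e0_start
  expect_equal(dec$delta_delay, total, tolerance = 1e-12)
  expect_equal(dec$delta_young, 0)
  expect_equal(dec$delta_middle, 0)
  expect_equal(dec$delta_old, 0)
})

test_that("components telescope to the model e0 change for every order", {
  pars <- random_params(10, seed = 21)
  orders <- list(c("young", "delay", "middle", "old"),
                 c("old", "middle", "delay", "young"),
                 c("delay", "young", "old", "middle"))
  for (i in seq(1, 9, by = 2)) {
    p0 <- pars[[i]]
    p1 <- pars[[i + 1]]
    # the substitution endpoint keeps the non-component offset B at its
    # start value; compute its e0 independently
    p_final <- p1
    p_final$B <- p0$B
    total <- code_e0(p_final) - code_e0(p0)
    for (ord in orders) {
      dec <- decompose_e0(p0, p1, order = ord)
      expect_equal(dec$delta_young + dec$delta_delay + dec$delta_middle +
                     dec$delta_old, total, tolerance = 1e-9)
    }
  }
})

test_that("fixture components match an independent brute-force substitution", {
  p0 <- code_preset("early")
  p1 <- code_preset("late")
  dec <- decompose_e0(p0, p1)

  # oracle: build each substituted life table from scratch with the
  # term-by-term curve oracle and the explicit-loop table oracle
  e0_of <- function(p) {
    q <- oracle_q(0:120, p)
    q[121] <- 1
    oracle_lifetable(q, a_frac = c(0.14, rep(0.5, 120)))$e0
  }
  p_y <- p0; p_y$A <- p1$A; p_y$a <- p1$a
  p_m <- p_y; p_m$M <- p1$M
  p_b <- p_m; p_b$b1 <- p1$b1; p_b$b2 <- p1$b2
  p_o <- p_b; p_o$b3 <- p1$b3
  e <- c(e0_of(p0), e0_of(p_y), e0_of(p_m), e0_of(p_b), e0_of(p_o))
  expect_equal(dec$e0_start, e[1], tolerance = 1e-10)
  expect_equal(dec$delta_young, e[2] - e[1], tolerance = 1e-10)
  expect_equal(dec$delta_delay, e[3] - e[2], tolerance = 1e-10)
  expect_equal(dec$delta_middle, e[4] - e[3], tolerance = 1e-10)
  expect_equal(dec$delta_old, e[5] - e[4], tolerance = 1e-10)
  expect_equal(dec$e0_end_model, e[5], tolerance = 1e-10)

  # observed values feed the unexplained remainder
  dec2 <- decompose_e0(p0, p1, e0_obs = c(63.0, 83.5))
  expect_equal(dec2$unexplained,
               (83.5 - 63.0) - (dec2$e0_end_model - dec2$e0_start),
               tolerance = 1e-12)
})

test_that("averaging over all substitution orders preserves the total", {
  p0 <- code_preset("early")
  p1 <- code_preset("late")
  dec <- decompose_e0(p0, p1, average_orders = TRUE)
  p_final <- p1
  p_final$B <- p0$B
  total <- code_e0(p_final) - code_e0(p0)
  expect_equal(dec$delta_young + dec$delta_delay + dec$delta_middle +
                 dec$delta_old, total, tolerance = 1e-9)
})

test_that("mismatched structural constants are a configuration error", {
  p0 <- code_preset("early")
  p1 <- code_preset("late")
  p1$g <- 0.5
  expect_error(decompose_e0(p0, p1), "`g`", class = "codemort_config_error")
  expect_error(compression_gain(p0, p1), class = "codemort_config_error")
})

test_that("with negligible young mortality the delay component tracks the shift", {
  p0 <- code_params(A = 1e-6, B = 1, a = 1e-8,
                    b1 = 0.1, b2 = 0.12, b3 = 0.13, M = 80)
  p1 <- p0
  p1$M <- 88
  dec <- decompose_e0(p0, p1)
  expect_lt(abs(dec$delta_delay - 8), 0.5)
})

test_that("delay_pace recovers constructed and noisy linear trends", {
  tb <- tibble::tibble(year = 1950:2010, M = 70 + 0.23 * (1950:2010 - 1950))
  expect_equal(delay_pace(tb), 2.3, tolerance = 1e-12)

  const <- tibble::tibble(year = 1950:2010, M = rep(80, 61))
  expect_equal(delay_pace(const), 0)

  noisy <- withr::with_seed(77, tibble::tibble(
    year = 1950:2010,
    M = 70 + 0.17 * (1950:2010 - 1950) + rnorm(61, sd = 0.3)))
  expect_lt(abs(delay_pace(noisy) - 1.7), 0.03)

  expect_error(delay_pace(tb[1, ]), class = "codemort_input_error")
})

test_that("shift_only_distribution shifts the adult mode without reshaping", {
  p <- code_preset("early")
  same <- shift_only_distribution(p, p$M)
  expect_equal(same$d, code_life_table(p)$d, tolerance = 1e-14)

  p_clean <- code_params(A = 1e-6, B = 1, a = 1e-8,
                         b1 = 0.1, b2 = 0.12, b3 = 0.13, M = 80)
  d0 <- dx_from_q(code_schedule(0:120, p_clean))
  d10 <- shift_only_distribution(p_clean, 90)
  expect_lte(abs((empirical_mode(d10) - empirical_mode(d0)) - 10), 0.5)

  expect_error(shift_only_distribution(p, 25), class = "codemort_domain_error")
})

test_that("compression gain vanishes for pure shifts and splits by source", {
  p <- code_preset("early")
  for (M_new in c(72, 80, 88, 95)) {
    p_shift <- p
    p_shift$M <- M_new
    g <- compression_gain(p, p_shift)
    expect_lt(abs(g$total), 1e-9)
  }

  # only A changes (plus a shift): the young-age source carries the gain
  p_end <- p
  p_end$M <- 88
  p_end$A <- p$A / 4
  g2 <- compression_gain(p, p_end)
  expect_gt(g2$total, 0)
  expect_equal(g2$young, g2$total, tolerance = 1e-12)
  expect_equal(g2$middle, 0, tolerance = 1e-12)
  expect_equal(g2$old, 0, tolerance = 1e-12)

  # fixture pair against a direct numeric integration oracle
  p1 <- code_preset("late")
  g3 <- compression_gain(p, p1)
  d_shift <- {
    ps <- p; ps$M <- p1$M
    q <- oracle_q(0:120, ps); q[121] <- 1
    oracle_lifetable(q, c(0.14, rep(0.5, 120)))$d
  }
  d_end <- {
    q <- oracle_q(0:120, p1); q[121] <- 1
    oracle_lifetable(q, c(0.14, rep(0.5, 120)))$d
  }
  expect_equal(g3$total, sum(pmax(d_end - d_shift, 0)), tolerance = 1e-10)
  expect_equal(g3$total, g3$young + g3$middle + g3$old + g3$interaction,
               tolerance = 1e-12)
})

test_that("e0 responds far more to scaling A than to scaling B", {
  p <- code_preset("late")
  expect_equal(param_sensitivity(p, "A", 1), 0)
  expect_lt(param_sensitivity(p, "A", 3), 0)
  dA <- abs(param_sensitivity(p, "A", 10))
  dB <- abs(param_sensitivity(p, "B", 10))
  expect_gt(dA, dB)
  expect_error(param_sensitivity(p, "Z", 2), class = "codemort_input_error")
  expect_error(param_sensitivity(p, "M", 3), class = "codemort_domain_error")
})

test_that("decomposition results serialize and tidy", {
  dec <- decompose_e0(code_preset("early"), code_preset("late"),
                      e0_obs = c(63, 83.5))
  path <- withr::local_tempfile(fileext = ".json")
  write_decomposition(dec, path)
  back <- read_decomposition(path)
  expect_equal(back$delta_delay, dec$delta_delay)
  expect_equal(back$unexplained, dec$unexplained)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_decomposition(dec, csv, format = "csv")
  row <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(row$delay_of_mortality, dec$delta_delay)
  expect_equal(row$unexplained, dec$unexplained)

  td <- tidy(dec)
  expect_identical(nrow(td), 5L)
  expect_equal(sum(td$years[td$component != "unexplained"]),
               dec$e0_end_model - dec$e0_start, tolerance = 1e-9)
})
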