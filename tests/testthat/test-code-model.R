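test_that("continuity constants match the closed forms and collapse cases", {
  # equal first two slopes: the two terms in c1 coincide
  p <- code_params(A = 0.01, B = 1, a = 1e-4, b1 = 0.1, b2 = 0.1, b3 = 0.15, M = 85)
  cc <- continuity_constants(p)
  expect_identical(cc$c1, 0)

  # all slopes equal: full collapse to a single logistic
  p <- code_preset("equal_slopes")
  cc <- continuity_constants(p)
  expect_identical(cc$c1, 0)
  expect_identical(cc$c2, 0)

  # frozen high-precision evaluation of the printed closed forms
  p <- code_params(A = 0.01, B = 1, a = 1e-4,
                   b1 = 0.10, b2 = 0.12, b3 = 0.14, M = 90)
  cc <- continuity_constants(p)
  expect_equal(cc$c1, 0.001679986208362935, tolerance = 1e-14)
  expect_equal(cc$c2, -0.012547656068059854, tolerance = 1e-14)
})

test_that("code_q matches trivial closed forms and the term-by-term oracle", {
  # equal slopes, no infant/background: at x = M the curve is b/(1 + b/g)
  p <- code_params(A = 1e-12, B = 1, a = 0,
                   b1 = 0.1, b2 = 0.1, b3 = 0.1, M = 80)
  expect_equal(code_q(80, p), 0.1 / (1 + 0.1 / 0.7), tolerance = 1e-10)

  # infant term alone: A/(x+B) with slopes pushed to a negligible level
  p <- code_params(A = 0.01, B = 1, a = 0,
                   b1 = 1e-12, b2 = 1e-12, b3 = 1e-12, M = 80)
  expect_equal(code_q(0, p), 0.01, tolerance = 1e-8)
  expect_equal(code_q(1, p), 0.005, tolerance = 1e-8)

  # full preset at key ages against the independent oracle
  for (nm in c("early", "late", "equal_slopes")) {
    p <- code_preset(nm)
    xs <- c(0, p$m_hump, p$M - p$h, p$M, 100)
    expect_equal(code_q(xs, p), oracle_q(xs, p), tolerance = 1e-13)
  }

  expect_error(code_q(-1, code_preset("late")), class = "codemort_domain_error")
})

test_that("the curve is continuous at both regime boundaries", {
  eps <- 1e-9
  for (p in random_params(200, seed = 42)) {
    q1 <- code_q(c(p$M - p$h - eps, p$M - p$h + eps), p)
    q2 <- code_q(c(p$M - eps, p$M + eps), p)
    expect_lt(abs(diff(q1)), 1e-9)
    expect_lt(abs(diff(q2)), 1e-9)
  }
})

test_that("equal slopes collapse the adult terms to a single logistic", {
  for (seed in 1:5) {
    b <- withr::with_seed(seed, runif(1, 0.05, 0.25))
    p <- code_params(A = 0.02, B = 1.5, a = 3e-4, b1 = b, b2 = b, b3 = b, M = 85)
    x <- seq(0, 110, by = 0.25)
    single <- p$A / (x + p$B) +
      p$a * exp(x - p$m_hump) / (1 + exp(x - p$m_hump)) +
      b * exp(b * (x - p$M)) / (1 + (b / p$g) * exp(b * (x - p$M)))
    expect_equal(code_q(x, p), single, tolerance = 1e-12)
  }
})

test_that("regime terms are positive, bounded by g, and increasing in age", {
  for (p in random_params(20, seed = 7)) {
    tb <- code_terms(seq(0, 115, by = 0.5), p)
    regime <- tb$young_adult + tb$late_adult + tb$old_age
    cc <- continuity_constants(p)
    # raw logistic parts (offsets removed) lie in (0, g)
    raw <- regime - ifelse(tb$late_adult > 0 | tb$old_age > 0,
                           ifelse(tb$old_age > 0, cc$c2, cc$c1), 0)
    expect_true(all(raw > 0 & raw < p$g))
    # each regime term increases with age within its regime
    for (col in c("young_adult", "late_adult", "old_age")) {
      v <- tb[[col]][tb[[col]] != 0]
      if (length(v) > 1) expect_true(all(diff(v) > 0))
    }
    # background term increases toward its plateau a (up to float rounding)
    expect_true(all(diff(tb$background) >= -1e-15))
    expect_lt(abs(tb$background[nrow(tb)] - p$a), 1e-8)
    # terms sum to the curve
    expect_equal(tb$q, code_q(tb$age, p), tolerance = 1e-14)
  }
})

test_that("code_schedule is element-wise code_q, clips above 1, and handles edges", {
  p <- code_preset("late")
  s <- code_schedule(0:100, p)
  expect_s3_class(s, "mortality_schedule")
  expect_identical(nrow(s), 101L)
  expect_equal(s$value[s$age == 80], code_q(80, p))
  expect_identical(schedule_kind(s), "probability")

  s1 <- code_schedule(0, p)
  expect_identical(nrow(s1), 1L)

  # monotone non-decreasing over adult ages for the late preset
  s2 <- code_schedule(0:120, p)
  adult <- s2$value[s2$age >= 30]
  expect_true(all(diff(adult) >= 0))

  expect_error(code_schedule(numeric(0), p), class = "codemort_input_error")

  # extreme background forces sums above 1 -> clipped with a warning
  p_hot <- code_params(A = 30, B = 1, a = 0.9, b1 = 0.3, b2 = 0.3, b3 = 0.3,
                       M = 45, g = 1)
  expect_warning(sh <- code_schedule(0:100, p_hot),
                 class = "codemort_clip_warning")
  expect_true(all(sh$value <= 1))
})

test_that("parameter validation names the offending field", {
  expect_error(code_params(A = -1, B = 1, a = 0, b1 = .1, b2 = .1, b3 = .1, M = 80),
               "`A`", class = "codemort_domain_error")
  expect_error(code_params(A = 1, B = 1, a = 0, b1 = .1, b2 = .1, b3 = .1, M = 30),
               "`M`", class = "codemort_domain_error")
  expect_error(code_params(A = 1, B = 1, a = 0, b1 = .1, b2 = .1, b3 = .1,
                           M = 80, h = 85),
               "`h`", class = "codemort_domain_error")
  expect_error(code_params(A = 1, B = 1, a = 0, b1 = .1, b2 = .1, b3 = .1,
                           M = 80, g = 1.4),
               "`g`", class = "codemort_domain_error")
})

test_that("siler_m matches closed forms and the arithmetic oracle", {
  s <- siler_params(a1 = 1e-9, a2 = 1, c = 0, b = 0.1, M = 80)
  expect_equal(siler_m(80, s), 0.1, tolerance = 1e-7)

  s <- siler_params(a1 = 0.05, a2 = 0.2, c = 0, b = 1e-12, M = 80)
  expect_equal(siler_m(0, s), 0.05, tolerance = 1e-8)

  s <- siler_params(a1 = 0.05, a2 = 0.2, c = 0.001, b = 0.1, M = 80)
  expect_equal(siler_m(60, s), 0.014533835534278937, tolerance = 1e-14)

  expect_error(siler_params(a1 = 0, a2 = 1, c = 0, b = .1, M = 80),
               class = "codemort_domain_error")
})

test_that("the curve levels off at a + g + c2", {
  p <- code_preset("equal_slopes")
  expect_equal(code_asymptote(p), p$a + 0.7)

  p <- code_params(A = 0.01, B = 1, a = 0.01, b1 = .1, b2 = .1, b3 = .1, M = 80)
  expect_equal(code_asymptote(p), 0.71)

  # far enough out that the infant term A/(x+B) is below the tolerance
  for (nm in c("early", "late")) {
    p <- code_preset(nm)
    expect_lt(abs(code_q(1e10, p) - code_asymptote(p)), 1e-9)
  }
})

test_that("parameters serialize to flat JSON and round-trip", {
  p <- code_preset("late")
  path <- withr::local_tempfile(fileext = ".json")
  write_params(p, path)
  x <- jsonlite::read_json(path)
  expect_setequal(names(x), c("model", names(unclass(p))))
  expect_equal(read_params(path), p)

  s <- siler_params(a1 = 0.05, a2 = 0.2, c = 0.001, b = 0.1, M = 80)
  write_params(s, path)
  expect_equal(read_params(path), s)
})
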