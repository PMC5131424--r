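# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every quantity from first principles
# (term-by-term sums, explicit loops) rather than calling package internals.

# five-term curve evaluated term by term
oracle_q <- function(x, p) {
  kan <- function(b, z) b * exp(b * z) / (1 + (b / p$g) * exp(b * z))
  c1 <- kan(p$b1, -p$h) - kan(p$b2, -p$h)
  c2 <- p$b2 / (1 + p$b2 / p$g) + c1 - p$b3 / (1 + p$b3 / p$g)
  vapply(x, function(xx) {
    t1 <- p$A / (xx + p$B)
    t2 <- p$a * exp(xx - p$m_hump) / (1 + exp(xx - p$m_hump))
    t3 <- if (xx <= p$M - p$h) kan(p$b1, xx - p$M)
          else if (xx <= p$M) kan(p$b2, xx - p$M) + c1
          else kan(p$b3, xx - p$M) + c2
    t1 + t2 + t3
  }, numeric(1))
}

# explicit-loop life table; returns list(l, d, L, e0)
oracle_lifetable <- function(q, a_frac) {
  n <- length(q)
  if (length(a_frac) == 1L) a_frac <- rep(a_frac, n)
  l <- numeric(n)
  l[1] <- 1
  for (i in seq_len(n - 1)) l[i + 1] <- l[i] * (1 - q[i])
  d <- l * q
  L <- numeric(n)
  for (i in seq_len(n)) {
    l_next <- if (i < n) l[i + 1] else l[n] * (1 - q[n])
    L[i] <- l_next + a_frac[i] * d[i]
  }
  list(l = l, d = d, L = L, e0 = sum(L))
}

# from-scratch weighted objective on a common age grid (q > 0 assumed)
oracle_objective <- function(obs_q, model_q) {
  d_of <- function(q) {
    l <- numeric(length(q)); l[1] <- 1
    for (i in seq_along(q)[-1]) l[i] <- l[i - 1] * (1 - q[i - 1])
    l * q
  }
  obs_logq <- log(obs_q)
  obs_d <- d_of(obs_q)
  mse_logq <- mean((log(model_q) - obs_logq)^2)
  mse_d <- mean((d_of(model_q) - obs_d)^2)
  vr <- function(v) mean((v - mean(v))^2)
  (mse_logq / vr(obs_logq) + mse_d / vr(obs_d)) / 2
}

# random valid parameter sets for property tests
random_params <- function(n, seed) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      code_params(
        A = exp(runif(1, log(1e-4), log(0.1))),
        B = runif(1, 0.1, 5),
        a = exp(runif(1, log(1e-6), log(0.01))),
        b1 = runif(1, 0.03, 0.3),
        b2 = runif(1, 0.03, 0.3),
        b3 = runif(1, 0.03, 0.3),
        M = runif(1, 65, 100))
    })
  })
}

# a small HMD-style 1x1 fixture written to a temp file
write_hmd_fixture <- function(lines, eol = "\n") {
  path <- withr::local_tempfile(fileext = ".txt",
                                .local_envir = parent.frame())
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = eol)
  close(con)
  path
}
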