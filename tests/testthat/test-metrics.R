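test_that("EI matches the linear-Gaussian closed form", {
  ## Y = A X + eps, X ~ U([-L,L]^n): EI = n ln(2L) + ln|det A| - sum ln(sigma sqrt(2 pi e))
  set.seed(31)
  for (n in 1:4) {
    A <- matrix(rnorm(n * n), n, n)
    sig <- runif(n, 0.05, 0.5)
    L <- runif(1, 0.5, 3)
    ei <- ei_continuous(function(x) as.numeric(A %*% x), sig, n = n, L = L,
                        n_mc = 200, seed = 1)
    closed <- n * log(2 * L) +
      as.numeric(determinant(A, logarithm = TRUE)$modulus) -
      sum(log(sig * sqrt(2 * pi * exp(1))))
    ## constant Jacobian: the MC term is exact up to finite-difference error
    expect_equal(ei$value, closed, tolerance = 1e-6)
    expect_equal(ei$value, ei$volume_term + ei$jacobian_term - ei$noise_term)
  }
})

test_that("EI shifts by ln 2 when the map doubles", {
  e1 <- ei_continuous(function(x) x, 0.1, n = 1, n_mc = 200, seed = 2)
  e2 <- ei_continuous(function(x) 2 * x, 0.1, n = 1, n_mc = 200, seed = 2)
  expect_equal(e2$value - e1$value, log(2), tolerance = 1e-6)
})

test_that("a constant map is degenerate with EI 0", {
  ei <- ei_continuous(function(x) c(1, 2), c(0.1, 0.1), n = 2, n_mc = 150,
                      seed = 3)
  expect_true(ei$degenerate)
  expect_equal(ei$value, 0)
})

test_that("EI approaches the exact channel MI as the noise shrinks", {
  ## quadrature oracle for Y = X + eps, X ~ U(-L, L): the EI formula is a
  ## small-noise approximation whose edge bias is O(sigma/L)
  mi_quad <- function(sigma, L) {
    fy <- function(y) (pnorm((L - y) / sigma) - pnorm((-L - y) / sigma)) /
      (2 * L)
    hY <- integrate(function(y) {
      f <- fy(y); ifelse(f > 0, -f * log(f), 0)
    }, -L - 8 * sigma, L + 8 * sigma, rel.tol = 1e-10)$value
    hY - 0.5 * log(2 * pi * exp(1) * sigma^2)
  }
  err <- vapply(c(0.1, 0.01), function(s) {
    ei <- ei_continuous(function(x) x, s, n = 1, n_mc = 150, seed = 4)
    abs(ei$value - mi_quad(s, 1))
  }, numeric(1))
  expect_lt(err[2], 0.02)        # inside the approximation regime
  expect_lt(err[2], err[1] / 5)  # bias shrinks linearly with sigma
})

test_that("dEI divides by the dimension and propagates the SE", {
  ei <- ei_continuous(function(x) x, c(0.1, 0.1), n = 2, n_mc = 150, seed = 5)
  d <- dEI(ei, 2)
  expect_equal(as.numeric(d), ei$value / 2)
  expect_equal(attr(d, "se"), ei$se / 2)
  expect_equal(dEI(4, 2), 2)
  expect_equal(dEI(3, 1), 3)
  expect_error(dEI(1, 0), "n must")
})

test_that("dCE subtracts dimension-averaged EIs and is zero for f vs f", {
  f <- function(x) c(tanh(x[1]) + 0.3 * x[2], x[2] - 0.2 * x[1])
  r <- dce(f, c(0.2, 0.3), 2, f, c(0.2, 0.3), 2, n_mc = 150, seed = 6)
  expect_equal(r$value, 0)
  expect_equal(r$value, r$dEI_macro - r$dEI_micro)
})

test_that("dCE agrees with the direct Jacobian/sigma expression", {
  ## macro 2y in 1-dim vs micro identity in 2-dim, unit sigma: both routes
  macro <- function(y) 2 * y
  micro <- function(x) x
  r <- dce(macro, 1, 1, micro, c(1, 1), 2, L = 1, n_mc = 150, seed = 7)
  ## direct: (1/nM) E ln|det J_M| - (1/nm) E ln|det J_m|
  ##         - (1/nM) sum ln sigma_M + (1/nm) sum ln sigma_m
  direct <- log(2) / 1 - 0 - 0 + 0
  expect_equal(r$value, direct, tolerance = 1e-6)
})

test_that("dCE is invariant to the hypercube half-width L on linear systems", {
  ## the ln(2L) terms cancel exactly; for linear maps the Jacobian term is
  ## constant, so the invariance is exact up to finite-difference error
  set.seed(8)
  for (trial in 1:3) {
    AM <- matrix(rnorm(1), 1, 1)
    Am <- matrix(rnorm(4), 2, 2)
    fM <- function(y) as.numeric(AM %*% y)
    fm <- function(x) as.numeric(Am %*% x)
    r1 <- dce(fM, 0.3, 1, fm, c(0.4, 0.5), 2, L = 1, n_mc = 150, seed = 9)
    r10 <- dce(fM, 0.3, 1, fm, c(0.4, 0.5), 2, L = 10, n_mc = 150, seed = 10)
    expect_equal(r1$value, r10$value, tolerance = 1e-6)
  }
})

test_that("Monte-Carlo SE shrinks with the sample count", {
  f <- function(x) tanh(2 * x)
  e_small <- ei_continuous(f, 0.1, n = 1, n_mc = 400, seed = 11)
  e_big <- ei_continuous(f, 0.1, n = 1, n_mc = 6400, seed = 11)
  expect_lt(e_big$se, e_small$se * 0.5)
  expect_gt(e_small$se, 0)
})

test_that("discrete EI attains its extremes and matches brute force", {
  ## permutation matrix: deterministic bijection, EI = ln N
  Pperm <- diag(5)[c(2, 3, 4, 5, 1), ]
  expect_equal(ei_discrete(Pperm), log(5))
  ## identical rows: output independent of input, EI = 0
  Puni <- matrix(1 / 6, 6, 6)
  expect_equal(ei_discrete(Puni), 0)
  ## the 8-state benchmark chain: independent double-sum oracle
  P <- markov_transition_matrix()
  py <- colMeans(P)
  acc <- 0
  for (i in 1:8) for (j in 1:8) if (P[i, j] > 0)
    acc <- acc + (1 / 8) * P[i, j] * log(P[i, j] / py[j])
  expect_equal(ei_discrete(P), acc)
  expect_gt(acc, 0)
  expect_lt(acc, log(8))
  expect_error(ei_discrete(matrix(1, 2, 2)), "stochastic")
})

test_that("knn MI estimator recovers known values", {
  set.seed(12)
  n <- 4000
  x <- rnorm(n)
  expect_lt(abs(mi_estimate(x, rnorm(n), method = "knn")), 0.05)
  rho <- 0.9
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  expect_lt(abs(mi_estimate(x, y, method = "knn") -
                  (-0.5 * log(1 - rho^2))), 0.05)
  expect_error(mi_estimate(rnorm(10), rnorm(10), method = "knn"),
               "at least 50")
})

test_that("discrete plug-in MI handles one-hot states exactly", {
  set.seed(13)
  s <- sample.int(8, 5000, replace = TRUE)
  X <- diag(8)[s, ]
  expect_equal(mi_estimate(X, X, method = "discrete_plugin"),
               -sum(tabulate(s, 8) / 5000 * log(tabulate(s, 8) / 5000)))
  ## independent: MI near 0 (plug-in bias is positive but small here)
  s2 <- sample.int(8, 5000, replace = TRUE)
  expect_lt(mi_estimate(diag(8)[s, ], diag(8)[s2, ],
                        method = "discrete_plugin"), 0.02)
})

test_that("mi_with_se produces a usable uncertainty", {
  set.seed(14)
  x <- rnorm(800); y <- x + rnorm(800)
  r <- mi_with_se(x, y, n_blocks = 8)
  expect_gt(r$se, 0)
  expect_equal(length(r$blocks), 8L)
  expect_lt(abs(r$value - 0.5 * log(2)), 0.1)
})
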