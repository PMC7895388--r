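dp_example <- function(k_plus_0 = 2, k_plus_delta = 4, k_minus = 1,
                       mu = 0.5, delta = 1) {
  dim_params(alpha = 1, mu = mu, k_minus = k_minus, k_plus_0 = k_plus_0,
             k_plus_delta = k_plus_delta, delta = delta, beta = 1,
             gamma = 0.5, pi = 1, D = 0.2, Theta1 = 2, Theta2 = 1)
}

test_that("nondimensionalization reproduces the dimensionless groups", {
  p <- dp_example()                     # K0 = 2, K = 4
  q <- nondimensionalize(p)
  expect_equal(q$kappa, 4 / 3)
  expect_equal(q$eta, 2)
  expect_true(is_admissible(q))
  # mu_hat = delta_hat and K0 = 1 give mu = 2
  p2 <- dp_example(k_plus_0 = 1, k_plus_delta = 1, mu = 1, delta = 1)
  expect_equal(nondimensionalize(p2)$mu, 2)
  # no protein-induced binding: kappa = eta = 0
  p3 <- dp_example(k_plus_delta = 0)
  q3 <- nondimensionalize(p3)
  expect_equal(q3$kappa, 0)
  expect_equal(q3$eta, 0)
  expect_false(is_admissible(q3))
  # full Table-2 formulas at a generic point
  expect_equal(q$mu, p$mu * 3 / p$delta)
  expect_equal(q$pi, p$pi * 3 / p$delta)
  expect_equal(q$epsilon, p$D * 3 / p$delta)
  expect_equal(q$gamma, p$gamma / p$beta)
  expect_equal(q$theta1, p$Theta1 * p$delta^2 / (p$alpha * p$beta * 2 * 3))
})

test_that("rapid-equilibrium reduction sums bound and unbound mRNA", {
  p <- dp_example()                     # K0 = 2, K = 4
  s <- c(1, 0, 0, 0, 0, 0)              # u1 = 1, p1 = 0
  expect_equal(reduce_rapid_equilibrium(s, p)[1], 3)   # factor 1 + K0
  s2 <- c(1, 0, 0, 0, 1e9, 0)           # saturated switch
  expect_equal(reduce_rapid_equilibrium(s2, p)[1], 7, tolerance = 1e-6)
  expect_equal(reduce_rapid_equilibrium(rep(0, 6), p)[1], 0)
})

test_that("scaled right-hand side matches its defining structure", {
  p <- worked_params()
  expect_equal(rhs_scaled(c(0, 0, 0, 0), p), c(1, 1, 0, 0))
  # exchange symmetry on random states
  set.seed(1)
  for (i in 1:25) {
    s <- runif(4, 0, 4)
    sw <- s[c(2, 1, 4, 3)]
    expect_equal(rhs_scaled(sw, p), rhs_scaled(s, p)[c(2, 1, 4, 3)])
  }
  # heaviside limit: the domain-0 affine fixed point is an equilibrium
  q <- dimless_params(mu = 0.5, pi = 2, epsilon = 0.3, gamma = 1,
                      theta1 = 6, theta2 = 4, kappa = 0.2, eta = 0.9)
  s0 <- c(1 / q$mu, 1 / q$mu, 1 / (q$mu * q$pi), 1 / (q$mu * q$pi))
  expect_true(all(s0[3:4] < q$theta2))
  expect_equal(rhs_scaled(s0, q, heaviside = TRUE), rep(0, 4),
               tolerance = 1e-12)
})

test_that("full 6-D system production terms and symmetry are correct", {
  p <- dp_example()
  d <- rhs_full(rep(0, 6), p)
  expect_equal(d[1:2], rep(p$alpha, 2))
  expect_equal(d[3:6], rep(0, 4))
  set.seed(2)
  s <- runif(6, 0, 2)
  sw <- s[c(2, 1, 4, 3, 6, 5)]
  expect_equal(rhs_full(sw, p), rhs_full(s, p)[c(2, 1, 4, 3, 6, 5)])
})

test_that("trajectories of the reduced system rescale onto the scaled system", {
  p <- dp_example(mu = 0.3, delta = 2)
  q <- nondimensionalize(p)
  y0 <- c(0.5, 1.2, 0.8, 0.1)
  f_red <- function(t, y, parms) list(rhs_reduced(y, p))
  f_sc <- function(t, y, parms) list(rhs_scaled(y, q))
  tau_end <- 5
  out_r <- deSolve::lsoda(y0, c(0, tau_end), f_red, NULL,
                          rtol = 1e-10, atol = 1e-12)
  Y0 <- scale_state(y0, p)
  out_s <- deSolve::lsoda(Y0, c(0, tau_end * time_scale(p)), f_sc, NULL,
                          rtol = 1e-10, atol = 1e-12)
  expect_equal(unname(scale_state(out_r[2, 2:5], p)),
               unname(out_s[2, 2:5]), tolerance = 1e-6)
})

test_that("fast binding collapses the 6-D system onto the reduced one", {
  # the rapid-equilibrium error is first order in 1/k_minus: the residual
  # of the reduced equations at the mapped 6-D steady state shrinks
  # proportionally as binding and unbinding speed up
  p_slow <- dp_example()
  res <- vapply(c(1e3, 1e4), function(f) {
    p_fast <- dp_example(k_plus_0 = 2 * f, k_plus_delta = 4 * f,
                         k_minus = f)      # same K0, K; binding f-times faster
    f6 <- function(t, y, parms) list(rhs_full(y, p_fast))
    y0 <- c(0.5, 0.1, 0, 0, 0.2, 0.3)
    out <- deSolve::lsoda(y0, c(0, 500), f6, NULL, rtol = 1e-10,
                          atol = 1e-12)
    yT <- out[2, 2:7]
    st <- c(yT[1] + yT[3], yT[2] + yT[4], yT[5], yT[6])   # u,b -> m
    max(abs(rhs_reduced(st, p_slow)))
  }, 0)
  expect_lt(res[1], 5e-4)
  expect_lt(res[2], 5e-5)
  expect_equal(res[1] / res[2], 10, tolerance = 0.05)
})

test_that("analytic Jacobian matches finite differences", {
  p <- worked_params()
  set.seed(3)
  for (i in 1:5) {
    y <- runif(4, 0.05, 3)
    J <- jacobian_scaled(y, p)
    Jn <- matrix(0, 4, 4)
    f0 <- rhs_scaled(y, p)
    for (k in 1:4) {
      h <- 1e-7 * max(abs(y[k]), 1e-3)
      y2 <- y; y2[k] <- y[k] + h
      Jn[, k] <- (rhs_scaled(y2, p) - f0) / h
    }
    expect_equal(J, Jn, tolerance = 1e-4)
  }
})

test_that("toy right-hand side has the stated equilibria", {
  tp <- toy_params(0.4, 1.5, 0.8, n = Inf)
  expect_equal(rhs_toy(0.4 / 0.8, tp), 0)          # f0 = b/gamma below theta
  expect_equal(rhs_toy(1.4 / 0.8, tp), 0)          # f1 = (b+1)/gamma above
  expect_equal(rhs_toy(0, tp), 0.4)
})

test_that("parameter JSON round trip preserves the groups", {
  p <- worked_params()
  path <- tempfile(fileext = ".json")
  write_params(p, path)
  q <- read_params(path)
  expect_equal(unclass(q), unclass(p))
})
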