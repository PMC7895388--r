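test_that("phase space decomposes into nine domains (two for the toy)", {
  for (ord in threshold_order()) {
    d <- enumerate_domains(ord)
    expect_equal(nrow(d), 9L)
    expect_setequal(d$index, 0:8)
    d0 <- d[d$index == 0, ]
    expect_equal(c(d0$s1, d0$s2), c(0, 0))
    lo <- if (ord == "theta2_lt_theta1") "theta2" else "theta1"
    expect_equal(d0$p1_interval, sprintf("(0,%s)", lo))
  }
  expect_equal(nrow(enumerate_toy_domains()), 2L)
  # 3 intervals per switching axis, squared
  expect_equal(3^2, nrow(enumerate_domains("theta2_lt_theta1")))
})

test_that("affine subsystems substitute the Heaviside levels correctly", {
  p <- dimless_params(mu = 0.7, pi = 1.3, epsilon = 0.4, gamma = 0.6,
                      theta1 = 3, theta2 = 1, kappa = 0.5, eta = 1.1)
  a0 <- affine_subsystem(0, 0, "theta2_lt_theta1", p)
  # domain 0: dM1/dt = 1 - mu M1 - M1 + M2
  expect_equal(a0$A[1, ], c(-(p$mu + 1), 1, 0, 0))
  expect_equal(a0$c, c(1, 1, 0, 0))
  a8 <- affine_subsystem(2, 2, "theta2_lt_theta1", p)
  # domain 8 protein production coefficient (1+gamma)(1+eta)/(1+kappa)
  expect_equal(a8$A[3, 1],
               (1 + p$gamma) * (1 + p$eta) / (1 + p$kappa))
  # consistency with the heaviside right-hand side at an interior state
  s <- c(0.4, 0.8, 2 * p$theta1, 2 * p$theta1)   # both cells in zone 2
  expect_equal(as.vector(a8$A %*% s + a8$c),
               rhs_scaled(s, p, heaviside = TRUE))
})

test_that("domain fixed points are closed-form solutions", {
  p <- dimless_params(mu = 0.7, pi = 1.3, epsilon = 0.4, gamma = 0.6,
                      theta1 = 3, theta2 = 1, kappa = 0.5, eta = 1.1)
  f0 <- domain_fixed_point(0, 0, "theta2_lt_theta1", p)
  expect_equal(unname(f0), c(1 / p$mu, 1 / p$mu, 1 / (p$mu * p$pi),
                             1 / (p$mu * p$pi)))
  f8 <- domain_fixed_point(2, 2, "theta2_lt_theta1", p)
  w <- (1 + p$gamma) * (1 + p$eta) / (1 + p$kappa)
  expect_equal(unname(f8[3:4]), rep(w / (p$mu * p$pi), 2))
  # A f + c = 0 and mRNA balance for every domain, both orderings
  set.seed(4)
  df <- random_params(10, 5)
  for (i in 1:10) {
    pp <- as_params(df, i)
    ord <- threshold_order(pp)
    for (s2 in 0:2) for (s1 in 0:2) {
      sub <- affine_subsystem(s1, s2, ord, pp)
      f <- domain_fixed_point(s1, s2, ord, pp)
      expect_lt(max(abs(sub$A %*% f + sub$c)), 1e-10)
      expect_equal(unname(f[1] + f[2]), 2 / pp$mu, tolerance = 1e-12)
      expect_true(all(f > 0))
    }
  }
})

test_that("every domain's affine matrix is Hurwitz on random parameters", {
  df <- random_params(150, 6, admissible = FALSE)   # holds on all of R^8_+
  for (i in seq_len(nrow(df))) {
    pp <- as_params(df, i)
    ord <- threshold_order(pp)
    for (s2 in 0:2) for (s1 in 0:2) {
      A <- affine_subsystem(s1, s2, ord, pp)$A
      expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 0)
    }
  }
})

test_that("the domain-0 attractor condition is 1 < mu*pi*theta2", {
  cond <- attractor_condition(0, "theta2_lt_theta1")
  expect_equal(cond$inequalities, "1 < mu*pi*theta2")
  # randomized identity check: condition truth equals the inequality
  df <- random_params(200, 7, admissible = FALSE)
  for (i in seq_len(nrow(df))) {
    if (df$theta2[i] >= df$theta1[i]) next
    pp <- as_params(df, i)
    expect_equal(condition_holds(cond, pp),
                 1 < pp$mu * pp$pi * pp$theta2)
  }
})

test_that("toy attractor conditions give the three regions", {
  expect_equal(toy_region(toy_params(2, 1, 1)), "D1")      # b > gamma*theta
  expect_equal(toy_region(toy_params(0.5, 1.2, 1)), "D2")
  expect_equal(toy_region(toy_params(0.1, 3, 1)), "D3")    # b+1 < gamma*theta
  expect_equal(nrow(toy_regions()), 3L)
  # no parameters yield zero attracting intervals: b/gamma > theta and
  # (b+1)/gamma < theta contradict each other
  set.seed(8)
  for (i in 1:200) {
    b <- 10^runif(1, -2, 2); g <- 10^runif(1, -2, 2); th <- 10^runif(1, -2, 2)
    A0 <- b / g < th
    A1 <- (b + 1) / g > th
    expect_true(A0 || A1)
  }
})

test_that("conjugate domains have identical attractor conditions", {
  for (ord in threshold_order()) {
    for (pr in list(c(1, 3), c(2, 6), c(5, 7))) {
      ca <- attractor_condition(pr[1], ord)
      cb <- attractor_condition(pr[2], ord)
      expect_identical(ca$inequalities, cb$inequalities)
    }
  }
  # hence the attracting set is closed under the swap
  df <- random_params(100, 9, admissible = FALSE)
  conj <- c(0, 3, 6, 1, 4, 7, 2, 5, 8)   # index map under P1 <-> P2
  for (i in seq_len(nrow(df))) {
    s <- attracting_domains(as_params(df, i))
    expect_setequal(s, conj[s + 1])
  }
})

test_that("symbolic attracting sets agree with brute-force linear solves", {
  df <- random_params(250, 10, admissible = FALSE)
  for (i in seq_len(nrow(df))) {
    pp <- as_params(df, i)
    expect_equal(attracting_domains(pp), attracting_domains_bruteforce(pp))
  }
})

test_that("admissible parameter sets always retain a symmetric attractor", {
  df <- random_params(300, 11, admissible = TRUE)
  for (i in seq_len(nrow(df))) {
    s <- attracting_domains(as_params(df, i))
    expect_true(length(intersect(s, c(0, 4, 8))) >= 1)
  }
})
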