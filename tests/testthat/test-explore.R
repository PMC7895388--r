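test_that("the initial-condition grid has 34 starts covering all domains", {
  p <- worked_params()
  ic <- default_ic_grid(p)
  expect_equal(dim(ic), c(34L, 4L))
  zone <- function(x) (x >= p$theta2) + (x >= p$theta1)
  doms <- unique(zone(ic[, 3]) + 3 * zone(ic[, 4]))
  expect_setequal(doms, 0:8)
})

test_that("the worked parameter set yields only an asymmetric swap pair", {
  ss <- find_stable_steady_states(worked_params())
  expect_equal(nrow(ss$states), 2L)
  expect_equal(classify_states(ss), "asymmetric_only")
  expect_equal(unname(ss$states[1, c(2, 1, 4, 3)]),
               unname(ss$states[2, ]), tolerance = 1e-6)
  expect_lt(max(abs(rhs_scaled(ss$states[1, ], worked_params()))), 1e-9)
})

test_that("reported steady states satisfy swap closure and mRNA balance", {
  sets <- sample_parameters(12, seed = 17)
  for (i in seq_len(nrow(sets))) {
    p <- as_params(sets[, c("mu", "gamma", "eta", "kappa", "pi", "epsilon",
                            "theta1", "theta2")], i)
    ss <- find_stable_steady_states(p)
    if (is.null(ss$states)) next
    for (k in seq_len(nrow(ss$states))) {
      y <- ss$states[k, ]
      expect_equal(unname(y[1] + y[2]), 2 / p$mu, tolerance = 1e-6)
      sw <- y[c(2, 1, 4, 3)]
      dmin <- min(apply(ss$states, 1, function(z) max(abs(z - sw))))
      expect_lt(dmin, 1e-4 * max(abs(sw)))
      # symmetric mRNA iff symmetric protein
      expect_equal(unname(abs(y[1] - y[2]) < 1e-5 * max(y[1:2])),
                   unname(abs(y[3] - y[4]) <
                            1e-5 * max(y[3:4], p$theta2 * 1e-3)))
    }
  }
})

test_that("classification distinguishes the three symmetry classes", {
  # deep in the low-state region: single symmetric state
  p_sym <- dimless_params(mu = 1, pi = 1, epsilon = 0.5, gamma = 0.5,
                          theta1 = 50, theta2 = 20, kappa = 0.2, eta = 0.5,
                          n = 10, nu = 10)
  ss <- find_stable_steady_states(p_sym)
  expect_equal(classify_states(ss), "symmetric_only")
  expect_equal(classify_states(find_stable_steady_states(worked_params())),
               "asymmetric_only")
  pp <- phase_portrait(worked_params())
  expect_equal(pp$class, "asymmetric_only")
})

test_that("toy stable states match the bistable example", {
  tp <- toy_params(0.5, 1.2, 1, n = 20)
  st <- toy_stable_states(tp)
  expect_equal(length(st), 2L)
  expect_equal(st[1], 0.5, tolerance = 1e-3)       # near b/gamma
  expect_equal(st[2], 1.5, tolerance = 0.05)       # near (b+1)/gamma
  expect_true(toy_configuration_match(tp))
})

test_that("scan-based and integration-based toy finders agree", {
  set.seed(18)
  for (i in 1:150) {
    tp <- toy_params(10^runif(1, -1.5, 0.5), 10^runif(1, -1, 0.5),
                     10^runif(1, -1, 0.5), n = sample(c(5, 10, 20), 1))
    a <- toy_stable_states(tp)
    b <- toy_stable_states_ode(tp)
    expect_equal(length(a), length(b))
    if (length(a)) expect_equal(a, b, tolerance = 1e-4)
  }
})

test_that("bistable toy region preservation sharpens monotonically in n", {
  tt <- toy_preservation_table(250, c(5, 10, 20), seed = 19)
  expect_equal(tt["D1", ], data.frame(n5 = 1, n10 = 1, n20 = 1,
                                      row.names = "D1"))
  expect_equal(tt["D3", ], data.frame(n5 = 1, n10 = 1, n20 = 1,
                                      row.names = "D3"))
  expect_true(all(diff(as.numeric(tt["D2", ])) >= 0))
  expect_true(all(as.numeric(tt["D2", ]) < 1))
})

test_that("rejection sampling respects the box and region filters", {
  s <- sample_parameters(10, seed = 20)
  expect_equal(nrow(s), 10L)
  expect_true(all(s >= 0.01 & s <= 3))
  s16 <- sample_parameters(25, region = in_selection_chain, seed = 21)
  expect_true(all(in_selection_chain(s16)))
  # accepted points satisfy mu*pi*theta2 < 1 (part of the chain)
  expect_true(all(s16$mu * s16$pi * s16$theta2 < 1))
  # toy-like filter on a catalog region predicate: D1 analogue
  cat0 <- main_catalog()
  regfun <- function(df) !is.na(region_membership(cat0, df)) &
    region_membership(cat0, df) == cat0$regions$label[1]
  expect_error(sample_parameters(5, region = function(df)
    rep(FALSE, nrow(df)), seed = 1, max_draw = 1e4), "budget")
})

test_that("deep sharp-limit parameter sets keep their configuration at
           n = nu = 50", {
  # sample base points, place thresholds in wide slots only (all ratio
  # gaps > 10^0.3), so every inequality has large slack
  set.seed(22)
  tested <- 0L; matched <- 0L
  while (tested < 60L) {
    lg <- function() 10^runif(1, -1.5, 1.5)
    mu <- lg(); gamma <- lg(); K0 <- lg(); K <- lg(); pi_ <- lg(); eps <- lg()
    eta <- K / K0; kappa <- K / (1 + K0)
    q <- sort(canonical_quantities("theta2_lt_theta1",
      data.frame(mu = mu, gamma = gamma, eta = eta, kappa = kappa,
                 pi = pi_, epsilon = eps))[1, ])
    lq <- log10(q)
    slot <- function(k) c(if (k == 0) lq[1] - 0.7 else lq[k],
                          if (k == 9) lq[9] + 0.7 else lq[k + 1])
    i <- sample(0:9, 1); j <- sample(i:9, 1)
    si <- slot(i); sj <- slot(j)
    if (i == j) {
      if (diff(si) < 0.9) next
      tlo <- 10^(si[1] + diff(si) / 3); thi <- 10^(si[1] + 2 * diff(si) / 3)
    } else {
      if (diff(si) < 0.6 || diff(sj) < 0.6) next
      tlo <- 10^mean(si); thi <- 10^mean(sj)
    }
    p <- dimless_params(mu = mu, pi = pi_, epsilon = eps, gamma = gamma,
                        theta1 = thi / (mu * pi_), theta2 = tlo / (mu * pi_),
                        kappa = kappa, eta = eta, n = 50, nu = 50)
    att <- attracting_domains(p)
    if (!length(att)) next
    tested <- tested + 1L
    ss <- find_stable_steady_states(p)
    zone <- function(x) (x >= p$theta2) + (x >= p$theta1)
    doms <- if (is.null(ss$states)) integer(0) else
      sort(unique(apply(ss$states, 1, function(y)
        zone(y[3]) + 3L * zone(y[4]))))
    if (identical(doms, sort(att))) matched <- matched + 1L
  }
  expect_gte(matched / tested, 0.95)
})
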