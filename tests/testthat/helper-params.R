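# shared fixtures for the test suite

# the worked asymmetric-selection parameter set (theta1, theta2, mu, gamma,
# eta, kappa, pi, epsilon) = (1.4, 0.9, 0.8, 0.2, 2.3, 2.5, 1.2, 0.1)
worked_params <- function(n = 10, nu = 10) {
  dimless_params(mu = 0.8, pi = 1.2, epsilon = 0.1, gamma = 0.2,
                 theta1 = 1.4, theta2 = 0.9, kappa = 2.5, eta = 2.3,
                 n = n, nu = nu)
}

# random positive dimensionless parameter sets; admissible = TRUE derives
# kappa and eta from binding constants so that eta > kappa exactly
random_params <- function(n_sets, seed, admissible = TRUE, log_range = 2,
                          order = NULL) {
  set.seed(seed)
  lg <- function() 10 ^ runif(n_sets, -log_range, log_range)
  mu <- lg(); gamma <- lg(); pi <- lg(); eps <- lg()
  if (admissible) {
    K0 <- lg(); K <- lg()
    eta <- K / K0; kappa <- K / (1 + K0)
  } else {
    eta <- lg(); kappa <- lg()
  }
  th_a <- lg(); th_b <- th_a * (1 + runif(n_sets))
  if (is.null(order)) {
    swap <- runif(n_sets) < 0.5
  } else swap <- rep(order == "theta1_lt_theta2", n_sets)
  theta1 <- ifelse(swap, th_a, th_b)
  theta2 <- ifelse(swap, th_b, th_a)
  data.frame(mu = mu, gamma = gamma, eta = eta, kappa = kappa, pi = pi,
             epsilon = eps, theta1 = theta1, theta2 = theta2)
}

as_params <- function(df, i, n = 10, nu = 10) {
  dimless_params(mu = df$mu[i], pi = df$pi[i], epsilon = df$epsilon[i],
                 gamma = df$gamma[i], theta1 = df$theta1[i],
                 theta2 = df$theta2[i], kappa = df$kappa[i],
                 eta = df$eta[i], n = n, nu = nu)
}

# the catalog is deterministic and cached inside the package, so repeated
# calls across test files are free after the first
main_catalog <- function() decompose_regions("theta2_lt_theta1")
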