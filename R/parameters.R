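#' Dimensional parameters of the two-cell oocyte-selection model
#'
#' The full model tracks unbound mRNA, fusome-bound mRNA and protein in each
#' of the two central cells of the germline cyst. All rates are first order
#' except transcription; the two Hill switches describe protein-induced mRNA
#' binding (threshold `Theta1`) and protein-induced translation (threshold
#' `Theta2`).
#'
#' @param alpha mRNA transcription rate (concentration/time).
#' @param mu mRNA degradation rate constant (1/time).
#' @param k_minus mRNA unbinding rate constant (1/time).
#' @param k_plus_0 basal mRNA binding rate constant (1/time).
#' @param k_plus_delta protein-induced increment of the binding rate
#'   constant (1/time).
#' @param delta intercellular mRNA exchange rate constant (1/time).
#' @param beta basal translation rate constant (1/time).
#' @param gamma protein-induced increment of the translation rate constant
#'   (1/time).
#' @param pi protein degradation rate constant (1/time).
#' @param D intercellular protein exchange rate constant (1/time).
#' @param Theta1 protein threshold for induced mRNA binding (concentration).
#' @param Theta2 protein threshold for induced translation (concentration).
#' @param n Hill exponent for binding (> 1).
#' @param nu Hill exponent for translation (> 1).
#' @return An object of class `dim_params`.
#' @seealso [nondimensionalize()]
#' @export
dim_params <- function(alpha, mu, k_minus, k_plus_0, k_plus_delta, delta,
                       beta, gamma, pi, D, Theta1, Theta2, n = 10, nu = 10) {
  p <- list(alpha = alpha, mu = mu, k_minus = k_minus, k_plus_0 = k_plus_0,
            k_plus_delta = k_plus_delta, delta = delta, beta = beta,
            gamma = gamma, pi = pi, D = D, Theta1 = Theta1, Theta2 = Theta2,
            n = n, nu = nu)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals[setdiff(names(vals), "k_plus_delta")] <= 0) ||
      p$k_plus_delta < 0) {
    stop("all dimensional parameters must be positive (k_plus_delta >= 0)",
         call. = FALSE)
  }
  if (p$n <= 1 || p$nu <= 1) stop("Hill exponents must exceed 1", call. = FALSE)
  structure(p, class = "dim_params")
}

#' Equilibrium binding constants
#'
#' Under the rapid-equilibrium approximation for mRNA binding/unbinding, the
#' bound fraction is governed by the dimensionless constants
#' `K0 = k_plus_0 / k_minus` and `K = k_plus_delta / k_minus`.
#'
#' @param p A [dim_params()] object.
#' @return Named numeric vector `c(K0, K)`.
#' @export
binding_constants <- function(p) {
  stopifnot(inherits(p, "dim_params"))
  c(K0 = p$k_plus_0 / p$k_minus, K = p$k_plus_delta / p$k_minus)
}

#' Dimensionless parameters of the rescaled model
#'
#' The rescaled two-cell model has eight dimensionless groups plus the two
#' Hill exponents. `mu` and `pi` compare mRNA and protein degradation to the
#' maximal mRNA transport rate, `epsilon` compares protein to mRNA
#' transport, `gamma` is the relative strength of autocatalytic translation,
#' `theta1`/`theta2` are the rescaled switching thresholds, and
#' `kappa = K/(1+K0)`, `eta = K/K0` measure protein-induced mRNA binding
#' against the basal binding equilibrium.
#'
#' Because `kappa` and `eta` derive from the same binding constants,
#' parameter sets arising from a physical model always satisfy
#' `eta > kappa` (see [is_admissible()]). The constructor accepts any
#' positive values so that sampling boxes can be explored freely; the
#' sharp-switch catalog is built over the admissible set.
#'
#' @param mu,pi,epsilon,gamma,theta1,theta2,kappa,eta Positive dimensionless
#'   groups.
#' @param n,nu Hill exponents (> 1; `Inf` marks the sharp-switch limit).
#' @return An object of class `dimless_params` (a named list).
#' @export
dimless_params <- function(mu, pi, epsilon, gamma, theta1, theta2,
                           kappa, eta, n = 10, nu = 10) {
  p <- list(mu = mu, pi = pi, epsilon = epsilon, gamma = gamma,
            theta1 = theta1, theta2 = theta2, kappa = kappa, eta = eta,
            n = n, nu = nu)
  vals <- unlist(p[1:6])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("dimensionless groups must be positive and finite", call. = FALSE)
  }
  if (!is.finite(kappa) || !is.finite(eta) || kappa < 0 || eta < 0) {
    stop("kappa and eta must be nonnegative and finite", call. = FALSE)
  }
  if (theta1 == theta2) {
    stop("theta1 == theta2 lies on the measure-zero threshold-order boundary",
         call. = FALSE)
  }
  if ((is.finite(p$n) && p$n <= 1) || (is.finite(p$nu) && p$nu <= 1)) {
    stop("Hill exponents must exceed 1", call. = FALSE)
  }
  structure(p, class = "dimless_params")
}

#' @export
print.dimless_params <- function(x, ...) {
  cat("<dimless_params>\n")
  cat(sprintf("  mu=%.4g pi=%.4g epsilon=%.4g gamma=%.4g\n",
              x$mu, x$pi, x$epsilon, x$gamma))
  cat(sprintf("  theta1=%.4g theta2=%.4g kappa=%.4g eta=%.4g  (n=%g, nu=%g)\n",
              x$theta1, x$theta2, x$kappa, x$eta, x$n, x$nu))
  cat(sprintf("  threshold order: %s; admissible (eta > kappa): %s\n",
              threshold_order(x), is_admissible(x)))
  invisible(x)
}

#' Nondimensionalize the two-cell model
#'
#' Maps dimensional parameters to the eight dimensionless groups of the
#' rescaled model. Time is rescaled by the maximal intercellular mRNA
#' transport rate `delta/(1+K0)`, mRNA by `alpha (1+K0)/delta`, protein by
#' `alpha beta K0 (1+K0)/delta^2`.
#'
#' @param p A [dim_params()] object.
#' @return A [dimless_params()] object.
#' @export
nondimensionalize <- function(p) {
  stopifnot(inherits(p, "dim_params"))
  kc <- binding_constants(p)
  K0 <- kc[["K0"]]; K <- kc[["K"]]
  theta_scale <- p$delta^2 / (p$alpha * p$beta * K0 * (1 + K0))
  dimless_params(
    mu      = p$mu * (1 + K0) / p$delta,
    pi      = p$pi * (1 + K0) / p$delta,
    epsilon = p$D * (1 + K0) / p$delta,
    gamma   = p$gamma / p$beta,
    theta1  = p$Theta1 * theta_scale,
    theta2  = p$Theta2 * theta_scale,
    kappa   = K / (1 + K0),
    eta     = K / K0,
    n = p$n, nu = p$nu
  )
}

#' Threshold ordering of a parameter set
#'
#' The sharp-switch decomposition is carried out separately for the two
#' generic orderings of the switching thresholds; the hypersurface
#' `theta1 == theta2` has zero volume and is excluded.
#'
#' @param p A [dimless_params()] object, or nothing to list the valid
#'   ordering labels.
#' @return `"theta2_lt_theta1"` or `"theta1_lt_theta2"`.
#' @export
threshold_order <- function(p) {
  if (missing(p)) return(c("theta2_lt_theta1", "theta1_lt_theta2"))
  stopifnot(inherits(p, "dimless_params"))
  if (p$theta2 < p$theta1) "theta2_lt_theta1" else "theta1_lt_theta2"
}

#' Physical admissibility of a dimensionless parameter set
#'
#' `eta = K/K0` always exceeds `kappa = K/(1+K0)` when the groups descend
#' from binding constants `K, K0 > 0`; conversely any `0 < kappa < eta` is
#' realized by `K0 = kappa/(eta - kappa)`, `K = eta K0`. The sharp-switch
#' region catalog is defined over this admissible set.
#'
#' @param p A [dimless_params()] object.
#' @return Logical.
#' @export
is_admissible <- function(p) {
  stopifnot(inherits(p, "dimless_params"))
  p$eta > p$kappa
}

#' Toy model parameters
#'
#' One autocatalytic species `X` with basal production `b`, self-activation
#' above threshold `theta` with Hill exponent `n`, and linear degradation
#' `gamma`.
#'
#' @param b Basal production rate.
#' @param theta Self-activation threshold.
#' @param gamma Degradation rate constant.
#' @param n Hill exponent (> 1; `Inf` for the sharp switch).
#' @return An object of class `toy_params`.
#' @export
toy_params <- function(b, theta, gamma, n = 10) {
  if (any(c(b, theta, gamma) <= 0)) stop("b, theta, gamma must be positive",
                                         call. = FALSE)
  if (is.finite(n) && n <= 1) stop("n must exceed 1", call. = FALSE)
  structure(list(b = b, theta = theta, gamma = gamma, n = n),
            class = "toy_params")
}

#' Read / write dimensionless parameter sets as JSON
#'
#' Parameter sets are stored as a flat JSON object keyed by the ASCII group
#' names `"mu","pi","epsilon","gamma","theta1","theta2","kappa","eta","n",
#' "nu"`.
#'
#' @param p A [dimless_params()] object.
#' @param path File path.
#' @return `read_params()` returns a [dimless_params()] object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(p, path) {
  stopifnot(inherits(p, "dimless_params"))
  jsonlite::write_json(p[c("mu", "pi", "epsilon", "gamma", "theta1",
                           "theta2", "kappa", "eta", "n", "nu")],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(dimless_params, as.list(x))
}

# internal: dimless_params -> named numeric vector in canonical column order
param_vec <- function(p) {
  c(mu = p$mu, gamma = p$gamma, eta = p$eta, kappa = p$kappa,
    pi = p$pi, epsilon = p$epsilon, theta1 = p$theta1, theta2 = p$theta2,
    n = p$n, nu = p$nu)
}
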