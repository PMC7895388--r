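#' Right-hand side of the full six-dimensional model
#'
#' Unbound mRNA `u`, bound mRNA `b` and protein `p` in each of the two
#' cells, in dimensional units. Bound mRNA does not exchange between cells;
#' unbound mRNA and protein exchange symmetrically. Provided as a
#' consistency oracle for the reduced and rescaled systems; all analysis in
#' the package operates on the rescaled model.
#'
#' @param state Numeric vector `c(u1, u2, b1, b2, p1, p2)`.
#' @param p A [dim_params()] object.
#' @param spec A [switch_spec()] for the binding switch; by default the
#'   finite Hill functions with the exponents stored in `p`.
#' @return Numeric 6-vector of time derivatives.
#' @export
rhs_full <- function(state, p, spec = NULL) {
  stopifnot(inherits(p, "dim_params"), length(state) == 6L)
  u <- state[1:2]; b <- state[3:4]; pr <- pmax(state[5:6], 0)
  sb <- spec %||% switch_spec("finite", p$n)
  st <- if (is.null(spec)) switch_spec("finite", p$nu) else spec
  h1 <- hill(pr, p$Theta1, sb)
  h2 <- hill(pr, p$Theta2, st)
  kplus <- p$k_plus_0 + p$k_plus_delta * h1
  du <- p$alpha - p$mu * u + p$k_minus * b - kplus * u + p$delta * (rev(u) - u)
  db <- kplus * u - p$k_minus * b - p$mu * b
  dp <- (p$beta + p$gamma * h2) * b - p$pi * pr + p$D * (rev(pr) - pr)
  c(du, db, dp)
}

#' Rapid-equilibrium reduction of the mRNA pools
#'
#' When binding and unbinding are fast, the bound and unbound pools
#' equilibrate and the total mRNA `m_i = u_i + b_i` satisfies
#' `m_i = u_i (1 + K0 + K hill(p_i, Theta1, n))`.
#'
#' @param state Numeric vector `c(u1, u2, b1, b2, p1, p2)` (the bound
#'   components are ignored; the reduction recomputes them from `u` and
#'   protein).
#' @param p A [dim_params()] object.
#' @return Numeric vector `c(m1, m2, p1, p2)`.
#' @export
reduce_rapid_equilibrium <- function(state, p) {
  stopifnot(inherits(p, "dim_params"), length(state) == 6L)
  kc <- binding_constants(p)
  u <- state[1:2]; pr <- pmax(state[5:6], 0)
  h <- hill(pr, p$Theta1, switch_spec("finite", p$n))
  m <- u * (1 + kc[["K0"]] + kc[["K"]] * h)
  c(m, state[5:6])
}

#' Right-hand side of the reduced four-dimensional model
#'
#' Total mRNA `m_i` and protein `p_i` per cell, dimensional units, after
#' eliminating the fast binding equilibrium.
#'
#' @param state Numeric vector `c(m1, m2, p1, p2)`.
#' @param p A [dim_params()] object.
#' @return Numeric 4-vector of time derivatives.
#' @export
rhs_reduced <- function(state, p) {
  stopifnot(inherits(p, "dim_params"), length(state) == 4L)
  kc <- binding_constants(p)
  K0 <- kc[["K0"]]; K <- kc[["K"]]
  m <- state[1:2]; pr <- pmax(state[3:4], 0)
  h1 <- hill(pr, p$Theta1, switch_spec("finite", p$n))
  h2 <- hill(pr, p$Theta2, switch_spec("finite", p$nu))
  denom <- 1 + K0 + K * h1
  transp <- p$delta / denom
  dm <- p$alpha - p$mu * m - transp * m + rev(transp * m)
  dp <- (p$beta + p$gamma * h2) * ((K0 + K * h1) / denom) * m -
    p$pi * pr + p$D * (rev(pr) - pr)
  c(dm, dp)
}

#' Right-hand side of the rescaled (dimensionless) model
#'
#' The rescaled two-cell model in state `(M1, M2, P1, P2)`:
#' \deqn{\dot M_i = 1 - \mu M_i - \frac{M_i}{1+\kappa H_1(P_i)} +
#'       \frac{M_j}{1+\kappa H_1(P_j)}}
#' \deqn{\dot P_i = (1+\gamma H_2(P_i))\,
#'       \frac{1+\eta H_1(P_i)}{1+\kappa H_1(P_i)}\, M_i - \pi P_i +
#'       \epsilon (P_j - P_i)}
#' where \eqn{H_1} switches at `theta1` with exponent `n` and \eqn{H_2} at
#' `theta2` with exponent `nu`. This pure-R evaluator is the reference
#' implementation; time integration uses the identical compiled version.
#'
#' @param state Numeric vector `c(M1, M2, P1, P2)`.
#' @param p A [dimless_params()] object.
#' @param heaviside If `TRUE`, evaluate the sharp-switch limit instead of
#'   the finite Hill functions.
#' @return Numeric 4-vector of time derivatives.
#' @export
rhs_scaled <- function(state, p, heaviside = FALSE) {
  stopifnot(inherits(p, "dimless_params"), length(state) == 4L)
  M <- state[1:2]; P <- pmax(state[3:4], 0)
  if (heaviside) {
    s1 <- switch_spec("heaviside"); s2 <- s1
  } else {
    s1 <- switch_spec("finite", p$n); s2 <- switch_spec("finite", p$nu)
  }
  h1 <- hill(P, p$theta1, s1)
  h2 <- hill(P, p$theta2, s2)
  transp <- 1 / (1 + p$kappa * h1)
  dM <- 1 - p$mu * M - transp * M + rev(transp * M)
  dP <- (1 + p$gamma * h2) * (1 + p$eta * h1) / (1 + p$kappa * h1) * M -
    p$pi * P + p$epsilon * (rev(P) - P)
  c(dM, dP)
}

#' Analytic Jacobian of the rescaled model (finite Hill)
#'
#' Used for Newton polishing of steady-state candidates and for linear
#' stability classification.
#'
#' @param state Numeric vector `c(M1, M2, P1, P2)`.
#' @param p A [dimless_params()] object (finite exponents).
#' @return A 4x4 numeric matrix.
#' @export
jacobian_scaled <- function(state, p) {
  stopifnot(inherits(p, "dimless_params"), length(state) == 4L)
  M <- state[1:2]; P <- pmax(state[3:4], 0)
  s1 <- switch_spec("finite", p$n); s2 <- switch_spec("finite", p$nu)
  h1 <- hill(P, p$theta1, s1)
  h2 <- hill(P, p$theta2, s2)
  # d/dP hill(P, theta, n) = n h (1-h) / P  (P > 0)
  dh1 <- ifelse(P > 0, p$n * h1 * (1 - h1) / P, 0)
  dh2 <- ifelse(P > 0, p$nu * h2 * (1 - h2) / P, 0)
  transp <- 1 / (1 + p$kappa * h1)
  dtr <- -p$kappa * transp^2 * dh1            # d transp_i / d P_i
  Bfac <- (1 + p$gamma * h2) * (1 + p$eta * h1) * transp
  dB <- p$gamma * dh2 * (1 + p$eta * h1) * transp +
    (1 + p$gamma * h2) * (p$eta * dh1 * transp + (1 + p$eta * h1) * dtr)
  J <- matrix(0, 4, 4)
  # dM1': -mu M1 - T1 M1 + T2 M2
  J[1, 1] <- -p$mu - transp[1]
  J[1, 2] <- transp[2]
  J[1, 3] <- -dtr[1] * M[1]
  J[1, 4] <- dtr[2] * M[2]
  J[2, 1] <- transp[1]
  J[2, 2] <- -p$mu - transp[2]
  J[2, 3] <- dtr[1] * M[1]
  J[2, 4] <- -dtr[2] * M[2]
  # dP1': B(P1) M1 - pi P1 + eps (P2 - P1)
  J[3, 1] <- Bfac[1]
  J[3, 3] <- dB[1] * M[1] - p$pi - p$epsilon
  J[3, 4] <- p$epsilon
  J[4, 2] <- Bfac[2]
  J[4, 3] <- p$epsilon
  J[4, 4] <- dB[2] * M[2] - p$pi - p$epsilon
  J
}

#' Right-hand side of the one-dimensional toy model
#'
#' `dX/dt = b + s(X) - gamma X` where `s` is the self-activation switch at
#' threshold `theta` (Hill in finite mode, Heaviside step in the sharp
#' limit).
#'
#' @param X Nonnegative numeric vector of states.
#' @param p A [toy_params()] object.
#' @param spec Optional [switch_spec()]; defaults to the mode implied by
#'   `p$n` (`Inf` means Heaviside).
#' @return Derivatives, same length as `X`.
#' @export
rhs_toy <- function(X, p, spec = NULL) {
  stopifnot(inherits(p, "toy_params"))
  if (is.null(spec)) {
    spec <- if (is.finite(p$n)) switch_spec("finite", p$n) else
      switch_spec("heaviside")
  }
  b_term <- hill(pmax(X, 0), p$theta, spec)
  p$b + b_term - p$gamma * X
}

#' Map a reduced-model state to the rescaled state
#'
#' Applies the nondimensionalizing substitutions: `M_i = delta m_i /
#' (alpha (1+K0))`, `P_i = delta^2 p_i / (alpha beta K0 (1+K0))`, `t =
#' delta tau / (1+K0)`. Used to check that trajectories of the reduced
#' dimensional system reproduce trajectories of the rescaled system.
#'
#' @param state Numeric vector `c(m1, m2, p1, p2)` (dimensional).
#' @param p A [dim_params()] object.
#' @return Numeric vector `c(M1, M2, P1, P2)`.
#' @export
scale_state <- function(state, p) {
  stopifnot(inherits(p, "dim_params"), length(state) == 4L)
  K0 <- binding_constants(p)[["K0"]]
  Mf <- p$delta / (p$alpha * (1 + K0))
  Pf <- p$delta^2 / (p$alpha * p$beta * K0 * (1 + K0))
  c(state[1:2] * Mf, state[3:4] * Pf)
}

#' @rdname scale_state
#' @export
time_scale <- function(p) {
  stopifnot(inherits(p, "dim_params"))
  p$delta / (1 + binding_constants(p)[["K0"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
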