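#' Switching domains of the sharp-switch phase space
#'
#' In the Heaviside limit the two protein coordinates are each partitioned
#' by the two thresholds into three intervals, tiling the positive
#' `(P1, P2)` quadrant into nine open domains on which both switches are
#' constant and the dynamics are affine. Domains are indexed
#' `i = s1 + 3 s2` where `s_j` in `{0, 1, 2}` is the interval of `P_j`
#' (below both thresholds, between, above both). The conjugate pairs
#' (1,3), (2,6), (5,7) are exchanged by swapping the two cells.
#'
#' @param order Threshold ordering, see [threshold_order()].
#' @return A data frame with one row per domain: `index`, `s1`, `s2`,
#'   interval labels for each protein coordinate, and the Heaviside levels
#'   of both switches in each cell.
#' @export
enumerate_domains <- function(order = c("theta2_lt_theta1", "theta1_lt_theta2")) {
  order <- match.arg(order)
  lo <- if (order == "theta2_lt_theta1") "theta2" else "theta1"
  hi <- if (order == "theta2_lt_theta1") "theta1" else "theta2"
  iv <- c(sprintf("(0,%s)", lo), sprintf("(%s,%s)", lo, hi),
          sprintf("(%s,Inf)", hi))
  g <- expand.grid(s1 = 0:2, s2 = 0:2)
  h1 <- vapply(seq_len(9), function(i)
    switch_levels(g$s1[i], order)[["h1"]], 0)
  h2 <- vapply(seq_len(9), function(i)
    switch_levels(g$s1[i], order)[["h2"]], 0)
  data.frame(index = g$s1 + 3L * g$s2, s1 = g$s1, s2 = g$s2,
             p1_interval = iv[g$s1 + 1L], p2_interval = iv[g$s2 + 1L],
             h1_cell1 = h1, h2_cell1 = h2)
}

#' @rdname enumerate_domains
#' @return `enumerate_toy_domains()`: the two phase-space intervals of the
#'   toy model.
#' @export
enumerate_toy_domains <- function() {
  data.frame(index = 0:1, interval = c("(0,theta)", "(theta,Inf)"),
             H = c(0, 1))
}

# Heaviside levels (h1 = binding/transport switch at theta1, h2 =
# translation switch at theta2) as a function of the protein interval s and
# the threshold ordering. For theta2 < theta1 the low threshold is the
# translation one; for theta1 < theta2 it is the binding one.
switch_levels <- function(s, order) {
  stopifnot(s %in% 0:2)
  if (order == "theta2_lt_theta1") {
    c(h1 = as.numeric(s == 2), h2 = as.numeric(s >= 1))
  } else {
    c(h1 = as.numeric(s >= 1), h2 = as.numeric(s == 2))
  }
}

# per-interval production factor B(s) = (1+gamma h2)(1+eta h1)/(1+kappa h1)
# and transport factor T(s) = 1/(1+kappa h1); vectorized over parameter rows
production_factor <- function(s, order, gamma, eta, kappa) {
  h <- switch_levels(s, order)
  (1 + gamma * h[["h2"]]) * (1 + eta * h[["h1"]]) / (1 + kappa * h[["h1"]])
}
transport_factor <- function(s, order, kappa) {
  h <- switch_levels(s, order)
  1 / (1 + kappa * h[["h1"]])
}

#' Affine subsystem of one switching domain
#'
#' Substituting the constant Heaviside levels of a domain into the rescaled
#' equations gives a linear system `dx/dt = A x + c` with
#' `c = (1, 1, 0, 0)`. The `A` matrix is block lower-triangular (mRNA block
#' feeding the protein block), with mRNA eigenvalues strictly negative and
#' protein eigenvalues `-pi`, `-pi - 2 epsilon`: it is Hurwitz for every
#' positive parameter set, so each domain owns a unique attracting fixed
#' point of its affine flow.
#'
#' @param s1,s2 Protein interval of cell 1 and cell 2 (each in `0:2`).
#' @param order Threshold ordering.
#' @param p A [dimless_params()] object.
#' @return List with components `A` (4x4 matrix) and `c` (length-4 vector).
#' @export
affine_subsystem <- function(s1, s2, order = c("theta2_lt_theta1",
                                               "theta1_lt_theta2"), p) {
  order <- match.arg(order)
  stopifnot(inherits(p, "dimless_params"))
  T1 <- transport_factor(s1, order, p$kappa)
  T2 <- transport_factor(s2, order, p$kappa)
  B1 <- production_factor(s1, order, p$gamma, p$eta, p$kappa)
  B2 <- production_factor(s2, order, p$gamma, p$eta, p$kappa)
  A <- rbind(c(-(p$mu + T1), T2, 0, 0),
             c(T1, -(p$mu + T2), 0, 0),
             c(B1, 0, -(p$pi + p$epsilon), p$epsilon),
             c(0, B2, p$epsilon, -(p$pi + p$epsilon)))
  list(A = A, c = c(1, 1, 0, 0))
}

#' Closed-form fixed point of a switching domain
#'
#' Solving the affine system of domain `(s1, s2)` gives, with
#' `T_i` the transport factors and `B_i` the production factors,
#' \deqn{\mu M_1 = \frac{\mu + 2 T_2}{\mu + T_1 + T_2}, \quad
#'       \mu M_2 = \frac{\mu + 2 T_1}{\mu + T_1 + T_2},}
#' \deqn{\mu\pi P_1 = \frac{(\pi+\epsilon) B_1 \mu M_1 +
#'       \epsilon B_2 \mu M_2}{\pi + 2\epsilon},}
#' and symmetrically for `P_2`. `M1 + M2 = 2/mu` always; `M1 = M2 = 1/mu`
#' exactly when the two cells share the same transport state.
#'
#' @inheritParams affine_subsystem
#' @return Numeric vector `c(M1, M2, P1, P2)`.
#' @export
domain_fixed_point <- function(s1, s2, order = c("theta2_lt_theta1",
                                                 "theta1_lt_theta2"), p) {
  order <- match.arg(order)
  stopifnot(inherits(p, "dimless_params"))
  q <- domain_q(s1, s2, order, p$mu, p$gamma, p$eta, p$kappa, p$pi, p$epsilon)
  T1 <- transport_factor(s1, order, p$kappa)
  T2 <- transport_factor(s2, order, p$kappa)
  den <- p$mu + T1 + T2
  c(M1 = (p$mu + 2 * T2) / (p$mu * den),
    M2 = (p$mu + 2 * T1) / (p$mu * den),
    P1 = q[[1]] / (p$mu * p$pi),
    P2 = q[[2]] / (p$mu * p$pi))
}

# mu*pi*(P1*, P2*) of domain (s1,s2); vectorized over parameter vectors.
# These rational functions, compared against mu*pi*theta_low and
# mu*pi*theta_high, are the entire content of the attractor conditions.
domain_q <- function(s1, s2, order, mu, gamma, eta, kappa, pi, epsilon) {
  T1 <- transport_factor(s1, order, kappa)
  T2 <- transport_factor(s2, order, kappa)
  B1 <- production_factor(s1, order, gamma, eta, kappa)
  B2 <- production_factor(s2, order, gamma, eta, kappa)
  den <- mu + T1 + T2
  m1 <- (mu + 2 * T2) / den            # = mu * M1
  m2 <- (mu + 2 * T1) / den
  p2e <- pi + 2 * epsilon
  list(q1 = ((pi + epsilon) * B1 * m1 + epsilon * B2 * m2) / p2e,
       q2 = (epsilon * B1 * m1 + (pi + epsilon) * B2 * m2) / p2e)
}

# canonical q-set for the zone machinery: 9 rational functions of the six
# non-threshold parameters. Columns: sym0, sym1, sym2 (symmetric domains),
# then (q1, q2) for the pairs (0,1), (0,2), (1,2).
q_names <- c("sym0", "sym1", "sym2", "p01_1", "p01_2", "p02_1", "p02_2",
             "p12_1", "p12_2")

q_matrix <- function(order, mu, gamma, eta, kappa, pi, epsilon) {
  n <- length(mu)
  out <- matrix(NA_real_, n, 9, dimnames = list(NULL, q_names))
  for (s in 0:2) {
    out[, s + 1L] <- rep_len(production_factor(s, order, gamma, eta, kappa), n)
  }
  pairs <- list(c(0, 1), c(0, 2), c(1, 2))
  for (k in seq_along(pairs)) {
    q <- domain_q(pairs[[k]][1], pairs[[k]][2], order, mu, gamma, eta,
                  kappa, pi, epsilon)
    out[, 2L + 2L * k] <- q$q1
    out[, 3L + 2L * k] <- q$q2
  }
  out
}

# zone requirements per domain: which q columns must sit in which zone
# (0 = below mu*pi*theta_low, 1 = between, 2 = above mu*pi*theta_high)
domain_zone_requirements <- function(index) {
  s1 <- index %% 3L
  s2 <- index %/% 3L
  if (s1 == s2) {
    list(cols = paste0("sym", s1), zones = s1)
  } else {
    a <- min(s1, s2); b <- max(s1, s2)
    nm <- sprintf("p%d%d", a, b)
    # domain (s1,s2): P1 in zone s1, P2 in zone s2; for the reflected
    # domain the fixed point components swap, giving identical conditions
    list(cols = paste0(nm, c("_1", "_2")), zones = c(a, b))
  }
}

#' Attractor-membership condition of a switching domain
#'
#' Domain `i` is attracting exactly when its affine fixed point lies inside
#' the domain, which reduces to strict inequalities between rational
#' functions of the six non-threshold parameters and the rescaled
#' thresholds `mu*pi*theta_low`, `mu*pi*theta_high`. Conjugate domains
#' (swap of the two cells) yield identical conditions.
#'
#' @param index Domain index `0:8`.
#' @param order Threshold ordering.
#' @return An object of class `attractor_condition` with the elementary
#'   inequalities (as strings and as an evaluable predicate).
#' @examples
#' cond <- attractor_condition(0, "theta2_lt_theta1")
#' print(cond)   # 1 < mu*pi*theta2
#' @export
attractor_condition <- function(index, order = c("theta2_lt_theta1",
                                                 "theta1_lt_theta2")) {
  order <- match.arg(order)
  stopifnot(index %in% 0:8)
  req <- domain_zone_requirements(index)
  lo <- if (order == "theta2_lt_theta1") "theta2" else "theta1"
  hi <- if (order == "theta2_lt_theta1") "theta1" else "theta2"
  ineq <- list()
  for (k in seq_along(req$cols)) {
    qs <- q_string(req$cols[k], order)
    z <- req$zones[k]
    if (z == 0) {
      ineq[[length(ineq) + 1L]] <- sprintf("%s < mu*pi*%s", qs, lo)
    } else if (z == 1) {
      ineq[[length(ineq) + 1L]] <- sprintf("mu*pi*%s < %s", lo, qs)
      ineq[[length(ineq) + 1L]] <- sprintf("%s < mu*pi*%s", qs, hi)
    } else {
      ineq[[length(ineq) + 1L]] <- sprintf("mu*pi*%s < %s", hi, qs)
    }
  }
  structure(list(index = index, order = order, cols = req$cols,
                 zones = req$zones, inequalities = unlist(ineq)),
            class = "attractor_condition")
}

#' @export
print.attractor_condition <- function(x, ...) {
  cat(sprintf("<attractor_condition> domain %d (%s)\n", x$index, x$order))
  for (s in x$inequalities) cat(" ", s, "\n")
  invisible(x)
}

#' Evaluate an attractor condition at a parameter set
#'
#' @param cond An [attractor_condition()].
#' @param p A [dimless_params()] object whose threshold ordering matches
#'   the condition's.
#' @return Logical: is the domain attracting at `p`?
#' @export
condition_holds <- function(cond, p) {
  stopifnot(inherits(cond, "attractor_condition"), inherits(p, "dimless_params"))
  if (threshold_order(p) != cond$order) {
    stop("parameter set has the opposite threshold ordering", call. = FALSE)
  }
  Q <- q_matrix(cond$order, p$mu, p$gamma, p$eta, p$kappa, p$pi, p$epsilon)
  tau <- sort(c(p$mu * p$pi * p$theta1, p$mu * p$pi * p$theta2))
  all(vapply(seq_along(cond$cols), function(k) {
    v <- Q[1, cond$cols[k]]
    switch(cond$zones[k] + 1L, v < tau[1], v > tau[1] && v < tau[2],
           v > tau[2])
  }, TRUE))
}

#' Attracting-domain set of a parameter point (sharp-switch limit)
#'
#' Evaluates all nine attractor conditions. This is the "symbolic" route;
#' [attracting_domains_bruteforce()] recomputes the same set by numerically
#' solving each domain's affine system and testing interval membership, and
#' the two must agree everywhere off the boundary hypersurfaces.
#'
#' @param p A [dimless_params()] object.
#' @return Integer vector of attracting domain indices (subset of `0:8`).
#' @export
attracting_domains <- function(p) {
  ord <- threshold_order(p)
  idx <- 0:8
  keep <- vapply(idx, function(i)
    condition_holds(attractor_condition(i, ord), p), TRUE)
  idx[keep]
}

#' @rdname attracting_domains
#' @export
attracting_domains_bruteforce <- function(p) {
  ord <- threshold_order(p)
  tlo <- min(p$theta1, p$theta2); thi <- max(p$theta1, p$theta2)
  zone <- function(x) if (x < tlo) 0L else if (x < thi) 1L else 2L
  out <- integer(0)
  for (s2 in 0:2) for (s1 in 0:2) {
    sub <- affine_subsystem(s1, s2, ord, p)
    f <- solve(sub$A, -sub$c)
    if (zone(f[3]) == s1 && zone(f[4]) == s2) {
      out <- c(out, s1 + 3L * s2)
    }
  }
  sort(out)
}

# human-readable algebraic string for a canonical q column
q_string <- function(col, order) {
  h <- list(); Bs <- character(3); Ts <- character(3)
  for (s in 0:2) {
    hl <- switch_levels(s, order)
    b <- "1"
    if (hl[["h2"]] == 1) b <- "(1+gamma)"
    if (hl[["h1"]] == 1) {
      b <- if (b == "1") "(1+eta)/(1+kappa)" else
        paste0(b, "*(1+eta)/(1+kappa)")
    }
    Bs[s + 1L] <- b
    Ts[s + 1L] <- if (hl[["h1"]] == 1) "1/(1+kappa)" else "1"
  }
  if (col %in% c("sym0", "sym1", "sym2")) {
    return(Bs[as.integer(substring(col, 4)) + 1L])
  }
  a <- as.integer(substring(col, 2, 2)); b <- as.integer(substring(col, 3, 3))
  comp <- substring(col, 5)          # "1" or "2"
  B1 <- Bs[a + 1L]; B2 <- Bs[b + 1L]; T1 <- Ts[a + 1L]; T2 <- Ts[b + 1L]
  if (T1 == T2) {
    # equal transport: mu*M_i = 1
    w1 <- "(pi+epsilon)"; w2 <- "epsilon"
    if (comp == "2") { w1 <- "epsilon"; w2 <- "(pi+epsilon)" }
    sprintf("(%s*%s + %s*%s)/(pi+2*epsilon)", w1, B1, w2, B2)
  } else {
    # mixed transport (T1=1, T2=1/(1+kappa)); clear (1+kappa) throughout
    m1 <- "(2+mu*(1+kappa))"; m2 <- "(1+kappa)*(2+mu)"
    den <- "((1+mu)*(1+kappa)+1)*(pi+2*epsilon)"
    t1 <- sprintf("%s*%s", B1, m1); t2 <- sprintf("%s*%s", B2, m2)
    t1 <- sub("^1\\*", "", t1); t2 <- sub("^1\\*", "", t2)
    # B2 carries a 1/(1+kappa) that cancels against m2's (1+kappa)
    t2 <- gsub("\\*\\(1\\+eta\\)/\\(1\\+kappa\\)\\*\\(1\\+kappa\\)",
               "*(1+eta)", t2)
    t2 <- sub("^\\(1\\+eta\\)/\\(1\\+kappa\\)\\*\\(1\\+kappa\\)",
              "(1+eta)", t2)
    w1 <- "(pi+epsilon)"; w2 <- "epsilon"
    if (comp == "2") { w1 <- "epsilon"; w2 <- "(pi+epsilon)" }
    sprintf("(%s*%s + %s*%s)/(%s)", w1, t1, w2, t2, den)
  }
}

#' Toy-model attractor conditions and parameter regions
#'
#' The toy model has two phase-space intervals with fixed points `b/gamma`
#' (switch off) and `(b+1)/gamma` (switch on). The interval below the
#' threshold attracts iff `b < gamma*theta`; the interval above iff
#' `b + 1 > gamma*theta`; both cannot fail at once, so parameter space
#' splits into exactly three regions:
#' `D1 = {b > gamma*theta}` (high state only),
#' `D2 = {b < gamma*theta < b+1}` (bistable), and
#' `D3 = {b + 1 < gamma*theta}` (low state only).
#'
#' @param p A [toy_params()] object.
#' @return `toy_region()`: `"D1"`, `"D2"` or `"D3"` (boundary points return
#'   `NA`). `toy_regions()`: a data frame cataloguing the three regions.
#' @export
toy_region <- function(p) {
  stopifnot(inherits(p, "toy_params"))
  gt <- p$gamma * p$theta
  if (p$b > gt) return("D1")
  if (p$b + 1 < gt) return("D3")
  if (p$b < gt && gt < p$b + 1) return("D2")
  NA_character_
}

#' @rdname toy_region
#' @export
toy_regions <- function() {
  data.frame(
    label = c("D1", "D2", "D3"),
    defining = c("b > gamma*theta", "b < gamma*theta < b + 1",
                 "b + 1 < gamma*theta"),
    attractors = c("high", "low+high", "low"),
    n_stable_states = c(1L, 2L, 1L))
}
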