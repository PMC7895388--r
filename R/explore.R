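#' Default initial-condition grid for steady-state searches
#'
#' A 5x5 Cartesian grid over the protein plane at
#' `{0.2*th_lo, th_lo, (th_lo+th_hi)/2, th_hi, 2*th_hi}` per coordinate
#' (with `th_lo`, `th_hi` the ordered thresholds) and `M1 = M2 = 1/mu`,
#' plus the nine sharp-switch domain fixed points as seeds: 34 starts.
#' The grid places starts in every switching domain; the fixed-point seeds
#' make discovery of each attracting state robust.
#'
#' @param p A [dimless_params()] object.
#' @return A 34x4 matrix of initial states.
#' @export
default_ic_grid <- function(p) {
  stopifnot(inherits(p, "dimless_params"))
  th_lo <- min(p$theta1, p$theta2); th_hi <- max(p$theta1, p$theta2)
  pv <- c(0.2 * th_lo, th_lo, (th_lo + th_hi) / 2, th_hi, 2 * th_hi)
  g <- as.matrix(expand.grid(P1 = pv, P2 = pv))
  grid <- cbind(M1 = 1 / p$mu, M2 = 1 / p$mu, g)
  ord <- threshold_order(p)
  seeds <- t(vapply(0:8, function(i)
    domain_fixed_point(i %% 3L, i %/% 3L, ord, p), numeric(4)))
  colnames(seeds) <- colnames(grid)
  unname(rbind(grid, seeds))
}

#' Find the stable steady states of the rescaled model
#'
#' Integrates the finite-Hill rescaled equations (compiled right-hand
#' side, stiff-capable `lsoda`) from each initial condition until the
#' vector field norm falls below `rhs_tol` (horizon `t_max` rescaled time
#' units), polishes each endpoint by damped Newton iteration with the
#' analytic Jacobian to residual `polish_tol`, deduplicates at relative
#' tolerance `dedup_tol` (max norm), certifies stability by the Jacobian
#' eigenvalue real parts, and closes the result under the cell swap.
#'
#' @param p A [dimless_params()] object with finite exponents.
#' @param ic Matrix of initial states; default [default_ic_grid()].
#' @param rhs_tol Convergence threshold on the sup-norm of the vector
#'   field (per unit rescaled time).
#' @param t_max Integration horizon.
#' @param polish_tol Newton residual target.
#' @param dedup_tol Relative deduplication tolerance.
#' @return Object of class `steady_states`: list with `states` (k x 4
#'   matrix), `symmetric` (logical per state), `params`, `n_failed_ic`.
#' @export
find_stable_steady_states <- function(p, ic = default_ic_grid(p),
                                      rhs_tol = 1e-8, t_max = 1e4,
                                      polish_tol = 1e-10,
                                      dedup_tol = 1e-4) {
  stopifnot(inherits(p, "dimless_params"), is.finite(p$n), is.finite(p$nu))
  parms <- c(p$theta1, p$theta2, p$mu, p$gamma, p$eta, p$kappa, p$pi,
             p$epsilon, p$n, p$nu)
  times <- c(0, 100, 250, 600, 1500, 4000, t_max)
  cand <- list(); n_failed <- 0L
  for (s in seq_len(nrow(ic))) {
    y <- pmax(ic[s, ], 0)
    out <- deSolve::lsoda(y, times, func = "sm_derivs", parms = parms,
                          dllname = "switchmap", initfunc = "sm_init",
                          rtol = 1e-8, atol = 1e-10)
    conv <- FALSE
    for (r in 2:nrow(out)) {
      yr <- pmax(out[r, 2:5], 0)
      if (max(abs(rhs_scaled(yr, p))) < rhs_tol) { conv <- TRUE; y <- yr; break }
    }
    if (!conv) { n_failed <- n_failed + 1L; next }
    y <- newton_polish(y, p, polish_tol)
    if (is.null(y)) { n_failed <- n_failed + 1L; next }
    cand[[length(cand) + 1L]] <- y
  }
  states <- dedup_states(cand, dedup_tol)
  # swap closure: the equations are exchange-symmetric, so the swap of a
  # steady state is one too; enforce closure, then re-deduplicate
  if (!is.null(states)) {
    swapped <- states[, c(2, 1, 4, 3), drop = FALSE]
    states <- dedup_states(c(split_rows(states), split_rows(swapped)),
                           dedup_tol)
  }
  # keep only linearly stable states
  if (!is.null(states)) {
    stable <- apply(states, 1, function(y)
      max(Re(eigen(jacobian_scaled(y, p), only.values = TRUE)$values)) <
        -1e-8)
    states <- states[stable, , drop = FALSE]
    if (nrow(states) == 0L) states <- NULL
  }
  sym <- if (is.null(states)) logical(0) else
    abs(states[, 3] - states[, 4]) <=
      1e-3 * pmax(states[, 3], pmax(states[, 4], p$theta2))
  structure(list(states = states, symmetric = sym, params = p,
                 n_failed_ic = n_failed), class = "steady_states")
}

split_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

dedup_states <- function(cand, tol) {
  if (!length(cand)) return(NULL)
  S <- do.call(rbind, cand)
  keep <- rep(TRUE, nrow(S))
  for (i in seq_len(nrow(S))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(S))) {
      if (j > i && keep[j] &&
          max(abs(S[i, ] - S[j, ])) < tol * max(abs(S[i, ]), 1e-8)) {
        keep[j] <- FALSE
      }
    }
  }
  m <- S[keep, , drop = FALSE]
  colnames(m) <- c("M1", "M2", "P1", "P2")
  m
}

newton_polish <- function(y, p, tol, max_iter = 30L) {
  for (it in seq_len(max_iter)) {
    f <- rhs_scaled(y, p)
    if (max(abs(f)) < tol) return(y)
    step <- tryCatch(solve(jacobian_scaled(y, p), f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    y <- pmax(y - step, 0)
  }
  if (max(abs(rhs_scaled(y, p))) < 1e-6) y else NULL
}

#' @export
print.steady_states <- function(x, ...) {
  k <- if (is.null(x$states)) 0L else nrow(x$states)
  cat(sprintf("<steady_states> %d stable state(s); class %s\n", k,
              classify_states(x)))
  if (k) print(round(x$states, 5))
  invisible(x)
}

#' Classify a set of stable steady states by symmetry
#'
#' A state is asymmetric when `|P1 - P2| > 1e-3 * max(P1, P2, theta2)`
#' (scale-aware, far below the separation of genuine symmetry-broken
#' branches). A parameter set whose stable states are all asymmetric
#' guarantees oocyte selection from any initial condition.
#'
#' @param ss A `steady_states` object from [find_stable_steady_states()].
#' @return `"symmetric_only"`, `"mixed"`, `"asymmetric_only"`; error when
#'   no stable state was found.
#' @export
classify_states <- function(ss) {
  stopifnot(inherits(ss, "steady_states"))
  if (is.null(ss$states) || nrow(ss$states) == 0L) {
    stop("no stable steady state found; cannot classify", call. = FALSE)
  }
  if (all(ss$symmetric)) return("symmetric_only")
  if (all(!ss$symmetric)) return("asymmetric_only")
  "mixed"
}

#' Phase-portrait summary of one parameter set
#'
#' @param p A [dimless_params()] object.
#' @param ... Passed to [find_stable_steady_states()].
#' @return List with `params`, `states`, `class`.
#' @export
phase_portrait <- function(p, ...) {
  ss <- find_stable_steady_states(p, ...)
  list(params = p, states = ss, class = classify_states(ss))
}

#' Sample parameter sets from a box, optionally restricted to a region
#'
#' Uniform sampling over a per-coordinate box in the order
#' `(theta1, theta2, mu, gamma, eta, kappa, pi, epsilon)`, with rejection
#' against an optional region predicate.
#'
#' @param n Number of accepted parameter sets.
#' @param box Length-2 interval applied to every coordinate (default
#'   `c(0.01, 3)`), or an 8x2 matrix of per-coordinate bounds.
#' @param region `NULL`, or a predicate taking the data frame of sampled
#'   sets and returning a logical vector (e.g. [in_selection_chain()], or
#'   a closure built from a catalog region).
#' @param seed Seed for the sampler.
#' @param max_draw Rejection-sampling budget; exceeded budget with a low
#'   acceptance rate is an error naming the region.
#' @return Data frame of `n` accepted parameter sets.
#' @export
sample_parameters <- function(n, box = c(0.01, 3), region = NULL,
                              seed = 1L, max_draw = 2e7) {
  stopifnot(n >= 1)
  if (is.null(dim(box))) box <- matrix(rep(box, each = 8), 8, 2)
  stopifnot(all(box > 0), all(box[, 2] > box[, 1]))
  cols <- c("theta1", "theta2", "mu", "gamma", "eta", "kappa", "pi",
            "epsilon")
  acc <- NULL; drawn <- 0L; chunk <- max(1000L, min(2e5L, n * 20L))
  with_seed(seed, {
    while (is.null(acc) || nrow(acc) < n) {
      if (drawn >= max_draw) {
        stop(sprintf(
          "rejection sampling budget exhausted (%d draws, %d accepted) %s",
          drawn, if (is.null(acc)) 0L else nrow(acc),
          if (is.null(region)) "" else "for the requested region"),
          call. = FALSE)
      }
      X <- matrix(stats::runif(8L * chunk, rep(box[, 1], each = chunk),
                               rep(box[, 2], each = chunk)), ncol = 8)
      colnames(X) <- cols
      df <- as.data.frame(X)
      drawn <- drawn + chunk
      keep <- if (is.null(region)) rep(TRUE, chunk) else region(df)
      keep <- keep & df$theta1 != df$theta2
      if (any(keep)) acc <- rbind(acc, df[keep, , drop = FALSE])
    }
  })
  out <- utils::head(acc, n)
  rownames(out) <- NULL
  attr(out, "acceptance_rate") <- n / drawn
  out
}

#' Symmetry-breaking density of a sampling region
#'
#' Samples parameter sets, enumerates their stable steady states at finite
#' Hill exponents, classifies each set, and reports the proportion whose
#' stable states are all asymmetric (the class that guarantees oocyte
#' selection).
#'
#' @inheritParams sample_parameters
#' @param exponents `c(n, nu)` Hill exponents (default 10, 10).
#' @param label Label stored in the report (e.g. the region name).
#' @param progress Print a progress line every 100 parameter sets.
#' @return Object of class `density_estimate`: counts per class, the
#'   proportion of `asymmetric_only` sets, seed and sampling metadata, and
#'   the per-sample results data frame.
#' @export
density_study <- function(n, box = c(0.01, 3), region = NULL,
                          exponents = c(10, 10), seed = 1L,
                          label = if (is.null(region)) "box" else "region",
                          progress = FALSE, max_draw = 2e7) {
  sets <- sample_parameters(n, box, region, seed, max_draw)
  cls <- character(n); nst <- integer(n); maxasym <- numeric(n)
  failed <- logical(n)
  for (i in seq_len(n)) {
    p <- dimless_params(mu = sets$mu[i], pi = sets$pi[i],
                        epsilon = sets$epsilon[i], gamma = sets$gamma[i],
                        theta1 = sets$theta1[i], theta2 = sets$theta2[i],
                        kappa = sets$kappa[i], eta = sets$eta[i],
                        n = exponents[1], nu = exponents[2])
    ss <- find_stable_steady_states(p)
    if (is.null(ss$states)) {
      failed[i] <- TRUE; cls[i] <- NA_character_; next
    }
    cls[i] <- classify_states(ss)
    nst[i] <- nrow(ss$states)
    maxasym[i] <- max(abs(ss$states[, 3] - ss$states[, 4]))
    if (progress && i %% 100L == 0L) {
      message(sprintf("  %d/%d classified (asym-only so far: %d)", i, n,
                      sum(cls == "asymmetric_only", na.rm = TRUE)))
    }
  }
  ok <- !failed
  counts <- table(factor(cls[ok], levels = c("symmetric_only", "mixed",
                                             "asymmetric_only")))
  structure(list(
    label = label, n_sampled = n, n_evaluated = sum(ok),
    n_failed = sum(failed), counts = as.list(counts),
    n_asymmetric_only = unname(counts[["asymmetric_only"]]),
    proportion = unname(counts[["asymmetric_only"]]) / sum(ok),
    exponents = exponents, box = box, seed = seed,
    samples = cbind(sets, class = cls, n_states = nst,
                    max_asymmetry = maxasym)),
    class = "density_estimate")
}

#' @export
print.density_estimate <- function(x, ...) {
  cat(sprintf("<density_estimate> %s: %d/%d asymmetric-only (prop %.4f)\n",
              x$label, x$n_asymmetric_only, x$n_evaluated, x$proportion))
  cat(sprintf("  exponents n=%g nu=%g, seed %d, box [%g, %g]^8\n",
              x$exponents[1], x$exponents[2], x$seed, x$box[1], x$box[2]))
  invisible(x)
}

# ---- toy model -----------------------------------------------------------

#' Stable fixed points of the toy model
#'
#' `toy_stable_states()` enumerates the stable zeros of
#' `b + hill(X) - gamma*X` by a fine sign-change scan with bisection
#' refinement (stability from the derivative sign).
#' `toy_stable_states_ode()` is the independent integration-based route:
#' relax a spread of initial conditions to equilibrium and deduplicate the
#' endpoints.
#'
#' @param p A [toy_params()] object (finite exponent).
#' @param grid_n Scan resolution.
#' @return Sorted numeric vector of stable fixed points.
#' @export
toy_stable_states <- function(p, grid_n = 1200L) {
  stopifnot(inherits(p, "toy_params"), is.finite(p$n))
  f <- function(x) rhs_toy(x, p)
  hi <- 1.05 * (p$b + 1) / p$gamma
  xs <- seq(0, hi, length.out = grid_n)
  # refine near the threshold where the switch is steep
  xs <- sort(unique(c(xs, p$theta * seq(0.8, 1.25, length.out = 200L))))
  fv <- f(xs)
  roots <- numeric(0)
  sgn <- sign(fv)
  for (i in which(sgn[-1] * sgn[-length(sgn)] < 0)) {
    r <- stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root
    roots <- c(roots, r)
  }
  roots <- c(roots, xs[which(fv == 0)])
  if (!length(roots)) return(numeric(0))
  h <- 1e-6 * max(1, roots)
  stable <- vapply(roots, function(r) (f(r + h) - f(r - h)) < 0, TRUE)
  sort(unique(round(roots[stable], 10)))
}

#' @rdname toy_stable_states
#' @param n_starts Number of initial conditions for the integration route.
#' @export
toy_stable_states_ode <- function(p, n_starts = 13L) {
  stopifnot(inherits(p, "toy_params"), is.finite(p$n))
  hi <- 1.2 * (p$b + 1) / p$gamma
  f_ode <- function(t, y, parms) list(rhs_toy(max(y, 0), p))
  ends <- vapply(seq(0, hi, length.out = n_starts), function(x0) {
    out <- deSolve::lsoda(x0, c(0, 200, 1000), f_ode, NULL,
                          rtol = 1e-10, atol = 1e-12)
    x <- max(out[nrow(out), 2], 0)
    for (i in 1:50) {              # Newton polish on the scalar field
      fx <- rhs_toy(x, p)
      if (abs(fx) < 1e-12) break
      d <- (rhs_toy(x + 1e-7, p) - rhs_toy(x - 1e-7, p)) / 2e-7
      if (d >= 0) break
      x <- max(x - fx / d, 0)
    }
    x
  }, 0)
  sort(unique(round(ends, 6)))
}

#' Does a finite-Hill toy parameter set preserve its sharp-switch
#' configuration?
#'
#' Compares the stable fixed points of the finite-`n` toy model with the
#' sharp-switch prediction of the parameter's region: `D1` expects exactly
#' one stable state above the threshold, `D3` one below, `D2` one on each
#' side.
#'
#' @param p A [toy_params()] object (`p$n` finite is used as the exponent).
#' @return Logical.
#' @export
toy_configuration_match <- function(p) {
  reg <- toy_region(p)
  if (is.na(reg)) return(NA)
  st <- toy_stable_states(p)
  lo <- sum(st < p$theta); hi <- sum(st > p$theta)
  switch(reg,
         D1 = lo == 0L && hi == 1L,
         D2 = lo == 1L && hi == 1L,
         D3 = lo == 1L && hi == 0L)
}

#' Sharp-switch preservation proportions for the toy model
#'
#' For each toy region and each Hill exponent, samples parameter sets
#' uniformly from the box restricted to the region and reports the
#' proportion whose finite-`n` steady-state configuration matches the
#' sharp-switch prediction. The bistable region `D2` shrinks as `n`
#' decreases; `D1` and `D3` are preserved exactly.
#'
#' @param n_per_region Accepted samples per region and exponent.
#' @param exponents Hill exponents to test.
#' @param box Sampling interval applied to `(b, gamma, theta)`.
#' @param seed Sampler seed.
#' @return Data frame: one row per region, one column per exponent.
#' @export
toy_preservation_table <- function(n_per_region = 1000L,
                                   exponents = c(5, 10, 20),
                                   box = c(0.01, 3), seed = 1L) {
  regions <- c("D1", "D2", "D3")
  out <- matrix(NA_real_, 3L, length(exponents),
                dimnames = list(regions, paste0("n", exponents)))
  for (ri in seq_along(regions)) {
    sets <- with_seed(seed + ri, {
      acc <- NULL
      while (is.null(acc) || nrow(acc) < n_per_region) {
        X <- matrix(stats::runif(3L * 20000L, box[1], box[2]), ncol = 3)
        colnames(X) <- c("b", "gamma", "theta")
        gt <- X[, "gamma"] * X[, "theta"]
        keep <- switch(regions[ri],
                       D1 = X[, "b"] > gt,
                       D2 = X[, "b"] < gt & gt < X[, "b"] + 1,
                       D3 = X[, "b"] + 1 < gt)
        acc <- rbind(acc, X[keep, , drop = FALSE])
      }
      acc[seq_len(n_per_region), , drop = FALSE]
    })
    for (ei in seq_along(exponents)) {
      match_ok <- vapply(seq_len(n_per_region), function(i) {
        toy_configuration_match(toy_params(sets[i, "b"], sets[i, "theta"],
                                           sets[i, "gamma"],
                                           exponents[ei]))
      }, TRUE)
      out[ri, ei] <- mean(match_ok)
    }
  }
  as.data.frame(out)
}
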