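# Sharp-switch decomposition of parameter space.
#
# Every attractor condition compares one of the nine canonical rational
# functions q_k(mu, gamma, eta, kappa, pi, epsilon) against the rescaled
# thresholds tau_lo = mu*pi*theta_low and tau_hi = mu*pi*theta_high, and the
# thresholds appear nowhere else. A maximal open cell of the induced
# parameter-space arrangement is therefore a "zone vector"
# z in {0,1,2}^9 assigning each q_k to (below tau_lo | between | above
# tau_hi); its feasible set is {base point : max(zone0 q) < min(zone1 q),
# max(zone1 q) < min(zone2 q)} x (an open box of thresholds). Cell
# feasibility and wall feasibility are ordered-grouping queries over the
# six base parameters, decided by a shared witness pool plus budgeted slack
# maximization. Enumeration is restricted to the physically admissible set
# eta > kappa (see is_admissible()).

.sm_cache <- new.env(parent = emptyenv())

POW3 <- 3L^(0:8)

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# log-uniform admissible base pool; kappa and eta derived from binding
# constants so that eta > kappa holds exactly
sample_base_pool <- function(n, seed, log_range) {
  with_seed(seed, {
    lg <- function() 10 ^ stats::runif(n, -log_range, log_range)
    mu <- lg(); gamma <- lg(); K0 <- lg(); K <- lg(); pi <- lg(); eps <- lg()
    cbind(mu = mu, gamma = gamma, eta = K / K0, kappa = K / (1 + K0),
          pi = pi, epsilon = eps)
  })
}

# provably-true strict orderings among the q columns over the admissible
# set, used to reject roundoff-corrupted pool rows and invalid zone vectors
proven_q_order <- function(order) {
  base <- list(c("sym0", "sym1"), c("sym1", "sym2"),
               c("p01_1", "p01_2"), c("p02_1", "p02_2"), c("p12_1", "p12_2"))
  if (order == "theta2_lt_theta1") {
    base <- c(base, list(c("sym0", "p01_1"), c("p01_2", "sym1"),
                         c("p02_1", "p12_1"), c("p02_2", "p12_2")))
  }
  base
}

# drop rows whose computed q-vector violates a proven ordering or has any
# relative gap below tol: both are double-precision cancellation artifacts
# (the q's are generically distinct; ties have measure zero)
pool_q <- function(P, order, gap_tol = 1e-7) {
  Q <- q_matrix(order, P[, "mu"], P[, "gamma"], P[, "eta"], P[, "kappa"],
                P[, "pi"], P[, "epsilon"])
  ok <- rep(TRUE, nrow(Q))
  for (pr in proven_q_order(order)) ok <- ok & (Q[, pr[1]] < Q[, pr[2]])
  for (a in 1:8) for (b in (a + 1):9) {
    ok <- ok & abs(Q[, a] - Q[, b]) > gap_tol * (Q[, a] + Q[, b])
  }
  list(P = P[ok, , drop = FALSE], Q = Q[ok, , drop = FALSE])
}

rank_matrix <- function(Q) {
  R <- matrix(1L, nrow(Q), ncol(Q))
  for (a in seq_len(ncol(Q))) for (b in seq_len(ncol(Q))) {
    if (a != b) R[, a] <- R[, a] + (Q[, b] < Q[, a])
  }
  R
}

zone_vector <- function(id) as.integer((id %/% POW3) %% 3L)
zone_id <- function(z) sum(as.integer(z) * POW3)

zone_vector_valid <- function(z, order) {
  names(z) <- q_names
  all(vapply(proven_q_order(order),
             function(pr) z[[pr[1]]] <= z[[pr[2]]], TRUE))
}

# attracting-domain bitmask of a zone vector
config_bitmask <- function(z) {
  names(z) <- q_names
  bits <- 0L
  for (i in 0:8) {
    req <- domain_zone_requirements(i)
    if (all(z[req$cols] == req$zones)) bits <- bits + as.integer(2^i)
  }
  bits
}

attractor_set <- function(bitmask) (0:8)[bitwAnd(bitmask, 2L^(0:8)) > 0L]

# every zone vector realized by some pool row and some threshold placement:
# for each row, cutting its q-order at positions i <= j realizes one cell
witnessed_cells <- function(Q, R) {
  seen <- new.env(parent = emptyenv())
  for (i in 0:9) for (j in i:9) {
    ids <- as.vector(((R > i) + (R > j)) %*% POW3)
    first <- which(!duplicated(ids))
    for (k in first) {
      key <- as.character(ids[k])
      if (is.null(seen[[key]])) seen[[key]] <- k
    }
  }
  ids <- sort(as.integer(ls(seen)))
  wit <- vapply(as.character(ids), function(k) seen[[k]], 0L)
  list(ids = ids, witness = unname(wit))
}

rowmax <- function(M) {
  if (ncol(M) == 0L) return(rep(-Inf, nrow(M)))
  do.call(pmax, as.data.frame(M))
}
rowmin <- function(M) {
  if (ncol(M) == 0L) return(rep(Inf, nrow(M)))
  do.call(pmin, as.data.frame(M))
}

# min relative slack, per pool row, of the ordered grouping
# groups = list of q-column index vectors, consecutive nonempty groups
# must be strictly separated
grouping_slack_rows <- function(Q, groups) {
  groups <- Filter(length, groups)
  slack <- rep(Inf, nrow(Q))
  if (length(groups) < 2L) return(slack)
  for (g in seq_len(length(groups) - 1L)) {
    a <- rowmax(Q[, groups[[g]], drop = FALSE])
    b <- rowmin(Q[, groups[[g + 1L]], drop = FALSE])
    slack <- pmin(slack, (b - a) / (b + a))
  }
  slack
}

cell_groups <- function(z) {
  lapply(0:2, function(lev) which(z == lev))
}

# wall between cell z and its neighbour with q_k moved from zone lev to
# lev-1: q_k pinned at the separating threshold, strictly between the
# remaining members of the two zones
wall_groups <- function(z, k, lev) {
  if (lev == 1L) {
    list(setdiff(which(z == 0L), k), k, setdiff(which(z == 1L), k),
         which(z == 2L))
  } else {
    list(which(z == 0L), setdiff(which(z == 1L), k), k,
         setdiff(which(z == 2L), k))
  }
}

# budgeted slack maximization over log10 base parameters (Nelder-Mead,
# multi-start); returns the best min-relative-slack found
slack_optimize <- function(order, groups, pool, n_starts = 6L,
                           maxit = 400L) {
  groups <- Filter(length, groups)
  if (length(groups) < 2L) return(Inf)
  obj <- function(x) {
    if (any(abs(x) > 8)) return(1)           # keep the search bounded
    v <- 10 ^ x
    eta <- v[4] / v[3]; kappa <- v[4] / (1 + v[3])   # x = log10(mu,gamma,K0,K,pi,eps)
    Q1 <- q_matrix(order, v[1], v[2], eta, kappa, v[5], v[6])
    s <- Inf
    for (g in seq_len(length(groups) - 1L)) {
      a <- max(Q1[1, groups[[g]]]); b <- min(Q1[1, groups[[g + 1L]]])
      s <- min(s, (b - a) / (b + a))
    }
    -s
  }
  # deterministic starts: best pool rows under this objective, plus jitter
  sl <- grouping_slack_rows(pool$Q, groups)
  top <- order(sl, decreasing = TRUE)[seq_len(min(3L, length(sl)))]
  starts <- lapply(top, function(r) {
    p <- pool$P[r, ]
    K0 <- p[["kappa"]] / (p[["eta"]] - p[["kappa"]])
    log10(c(p[["mu"]], p[["gamma"]], K0, p[["eta"]] * K0, p[["pi"]],
            p[["epsilon"]]))
  })
  seed <- sum(vapply(groups, function(g) sum(g * seq_along(g)), 0)) + 7L
  extra <- with_seed(seed, lapply(seq_len(max(0L, n_starts - length(starts))),
                                  function(i) stats::runif(6, -2, 2)))
  best <- -Inf
  for (x0 in c(starts, extra)) {
    r <- stats::optim(x0, obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
    best <- max(best, -r$value)
    if (best > 1e-4) break
  }
  best
}

#' Decompose parameter space in the sharp-switch limit
#'
#' Enumerates the maximal open cells of the parameter-space arrangement
#' induced by the nine attractor-membership conditions, maps each cell to
#' its configuration (the set of simultaneously attracting switching
#' domains), and glues cells of equal configuration across feasible
#' codimension-1 walls into connected parameter regions. The enumeration
#' runs over the physically admissible dimensionless space (`eta > kappa`,
#' thresholds free and positive, excluding the measure-zero boundary
#' hypersurfaces).
#'
#' Feasibility of cells and walls is decided by a fixed-seed log-uniform
#' witness pool spanning `10^[-log_range, log_range]` per base coordinate,
#' with budgeted Nelder-Mead slack maximization for candidates the pool
#' does not witness; the catalog is deterministic for fixed settings.
#' Candidates whose best slack lands between `flag_tol` and `slack_tol` are
#' flagged inconclusive (and treated as infeasible); the flag count is
#' reported in `meta` and is zero at the default settings.
#'
#' @param order Threshold ordering.
#' @param pool_n Witness pool size.
#' @param pool_seed Internal pool seed (part of the deterministic
#'   algorithm configuration, not a statistical seed).
#' @param log_range Half-width of the pool's log10 sampling box.
#' @param refine Run the budgeted-optimization sweep over unwitnessed
#'   one-flip neighbours of feasible cells.
#' @param slack_tol Minimum relative slack for a feasibility declaration.
#' @param flag_tol Slack below which a candidate is cleanly infeasible.
#' @param cache Reuse a previously computed catalog with identical
#'   settings.
#' @return An object of class `region_catalog`.
#' @seealso [enumerate_configurations()], [build_region_graph()],
#'   [region_membership()]
#' @export
decompose_regions <- function(order = c("theta2_lt_theta1",
                                        "theta1_lt_theta2"),
                              pool_n = 1e5, pool_seed = 20210208L,
                              log_range = 3, refine = TRUE,
                              slack_tol = 1e-6, flag_tol = 1e-8,
                              cache = TRUE) {
  order <- match.arg(order)
  key <- paste(order, pool_n, pool_seed, log_range, refine, slack_tol,
               sep = "|")
  if (cache && !is.null(.sm_cache[[key]])) return(.sm_cache[[key]])
  t0 <- proc.time()[["elapsed"]]

  P <- sample_base_pool(pool_n, pool_seed, log_range)
  pool <- pool_q(P, order)
  R <- rank_matrix(pool$Q)
  wc <- witnessed_cells(pool$Q, R)
  ids <- wc$ids
  witness <- wc$witness
  status <- new.env(parent = emptyenv())   # id -> "feasible"/"infeasible"/"flagged"
  for (id in ids) status[[as.character(id)]] <- "feasible"
  n_flagged <- 0L

  if (refine) {
    # budgeted completeness sweep: every unwitnessed one-flip neighbour of
    # a feasible cell gets a slack-maximization test
    frontier <- ids
    while (length(frontier)) {
      nxt <- integer(0)
      for (id in frontier) {
        z <- zone_vector(id)
        for (k in 1:9) for (dz in c(-1L, 1L)) {
          z2 <- z; z2[k] <- z[k] + dz
          if (z2[k] < 0L || z2[k] > 2L) next
          if (!zone_vector_valid(z2, order)) next
          id2 <- zone_id(z2); key2 <- as.character(id2)
          if (!is.null(status[[key2]])) next
          s <- slack_optimize(order, cell_groups(z2), pool)
          if (s > slack_tol) {
            status[[key2]] <- "feasible"
            ids <- c(ids, id2); witness <- c(witness, NA_integer_)
            nxt <- c(nxt, id2)
          } else if (s > flag_tol) {
            status[[key2]] <- "flagged"; n_flagged <- n_flagged + 1L
          } else status[[key2]] <- "infeasible"
        }
      }
      frontier <- nxt
    }
    o <- order(ids); ids <- ids[o]; witness <- witness[o]
  }

  zs <- lapply(ids, zone_vector)
  cfg <- vapply(zs, config_bitmask, 0L)

  # walls between feasible one-flip neighbours
  idx <- seq_along(ids); names(idx) <- as.character(ids)
  wall <- list()
  for (a in idx) {
    z <- zs[[a]]
    for (k in 1:9) if (z[k] > 0L) {
      z2 <- z; z2[k] <- z[k] - 1L
      b <- idx[as.character(zone_id(z2))]
      if (is.na(b)) next
      gw <- wall_groups(z, k, z[k])
      feas <- any(grouping_slack_rows(pool$Q, gw) > 0)
      if (!feas) {
        s <- slack_optimize(order, gw, pool)
        feas <- s > slack_tol
        if (!feas && s > flag_tol) n_flagged <- n_flagged + 1L
      }
      if (feas) {
        wall[[length(wall) + 1L]] <-
          data.frame(cell_a = ids[a], cell_b = ids[b], q = q_names[k],
                     boundary = if (z[k] == 1L) "low" else "high",
                     same_config = cfg[a] == cfg[b])
      }
    }
  }
  walls <- if (length(wall)) do.call(rbind, wall) else
    data.frame(cell_a = integer(0), cell_b = integer(0), q = character(0),
               boundary = character(0), same_config = logical(0))

  # glue same-configuration cells into regions
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  sc <- walls[walls$same_config, , drop = FALSE]
  if (nrow(sc)) {
    g <- igraph::add_edges(g, rbind(idx[as.character(sc$cell_a)],
                                    idx[as.character(sc$cell_b)]))
  }
  comp <- igraph::components(g)$membership

  cfg_sorted <- sort(unique(cfg))
  cfg_ord <- match(cfg, cfg_sorted)
  # component numbering within a configuration: by smallest member cell id
  region_of <- character(length(ids))
  regions <- list()
  for (ci in seq_along(cfg_sorted)) {
    in_cfg <- which(cfg_ord == ci)
    comps <- split(in_cfg, comp[in_cfg])
    comps <- comps[order(vapply(comps, function(m) min(ids[m]), 0))]
    for (k in seq_along(comps)) {
      lab <- if (length(comps) == 1L) as.character(ci) else
        sprintf("%d:%d", ci, k)
      region_of[comps[[k]]] <- lab
      regions[[length(regions) + 1L]] <-
        list(label = lab, config = cfg_sorted[ci], config_id = ci,
             component = k, n_components = length(comps),
             cells = ids[comps[[k]]])
    }
  }

  # representative interior point per cell (thresholds placed mid-slot)
  reps <- lapply(seq_along(ids), function(a) {
    r <- witness[a]
    if (is.na(r)) {
      # refined cell: recover a witness by one more optimization
      gz <- cell_groups(zs[[a]])
      xb <- best_witness(order, gz, pool)
      list(P = xb$P, q = xb$q)
    } else list(P = pool$P[r, ], q = pool$Q[r, ])
  })
  cell_rep <- t(vapply(seq_along(ids), function(a) {
    representative_point(zs[[a]], reps[[a]]$P, reps[[a]]$q, order)
  }, numeric(8)))

  cells <- data.frame(id = ids, zones = vapply(zs, paste, "", collapse = ""),
                      config = cfg, region = region_of,
                      stringsAsFactors = FALSE)
  cells <- cbind(cells, as.data.frame(cell_rep))

  configurations <- data.frame(
    config_id = seq_along(cfg_sorted), bitmask = cfg_sorted,
    attractors = vapply(cfg_sorted, function(b)
      paste(attractor_set(b), collapse = ","), ""),
    n_attractors = vapply(cfg_sorted, function(b)
      length(attractor_set(b)), 0L),
    n_symmetric = vapply(cfg_sorted, function(b)
      sum(attractor_set(b) %in% c(0L, 4L, 8L)), 0L),
    n_asymmetric = vapply(cfg_sorted, function(b)
      sum(!attractor_set(b) %in% c(0L, 4L, 8L)), 0L),
    n_components = vapply(cfg_sorted, function(b)
      sum(vapply(regions, function(r) r$config == b, TRUE)), 0L))

  regions_df <- do.call(rbind, lapply(regions, function(r) {
    first <- match(min(r$cells), cells$id)
    cbind(data.frame(label = r$label, config_id = r$config_id,
                     bitmask = r$config,
                     attractors = paste(attractor_set(r$config),
                                        collapse = ","),
                     n_symmetric = sum(attractor_set(r$config) %in%
                                         c(0L, 4L, 8L)),
                     n_asymmetric = sum(!attractor_set(r$config) %in%
                                          c(0L, 4L, 8L)),
                     component = r$component, n_cells = length(r$cells),
                     stringsAsFactors = FALSE),
          cells[first, names(as.data.frame(cell_rep))])
  }))
  rownames(regions_df) <- NULL

  out <- structure(list(
    order = order, cells = cells, configurations = configurations,
    regions = regions_df, walls = walls,
    meta = list(pool_n = pool_n, pool_seed = pool_seed,
                pool_kept = nrow(pool$Q), log_range = log_range,
                refine = refine, slack_tol = slack_tol,
                n_flagged = n_flagged,
                elapsed_s = proc.time()[["elapsed"]] - t0)),
    class = "region_catalog")
  if (cache) .sm_cache[[key]] <- out
  out
}

best_witness <- function(order, groups, pool) {
  sl <- grouping_slack_rows(pool$Q, groups)
  r <- which.max(sl)
  list(P = pool$P[r, ], q = pool$Q[r, ])
}

# place the two thresholds inside the open slots of a cell's q-order
representative_point <- function(z, p6, q, order) {
  pick <- function(a, b) {
    if (a <= 0 && !is.finite(b)) return(1)
    if (a <= 0) return(b / 2)
    if (!is.finite(b)) return(2 * a)
    sqrt(a * b)
  }
  la <- suppressWarnings(max(0, q[z == 0L]))
  lb <- suppressWarnings(min(Inf, q[z >= 1L]))
  ha <- suppressWarnings(max(0, q[z <= 1L]))
  hb <- suppressWarnings(min(Inf, q[z == 2L]))
  tau_hi <- pick(ha, hb)
  tau_lo <- pick(la, min(lb, tau_hi))
  th_lo <- tau_lo / (p6[["mu"]] * p6[["pi"]])
  th_hi <- tau_hi / (p6[["mu"]] * p6[["pi"]])
  if (order == "theta2_lt_theta1") {
    c(mu = p6[["mu"]], gamma = p6[["gamma"]], eta = p6[["eta"]],
      kappa = p6[["kappa"]], pi = p6[["pi"]], epsilon = p6[["epsilon"]],
      theta1 = th_hi, theta2 = th_lo)
  } else {
    c(mu = p6[["mu"]], gamma = p6[["gamma"]], eta = p6[["eta"]],
      kappa = p6[["kappa"]], pi = p6[["pi"]], epsilon = p6[["epsilon"]],
      theta1 = th_lo, theta2 = th_hi)
  }
}

#' @export
print.region_catalog <- function(x, ...) {
  cat(sprintf("<region_catalog> %s\n", x$order))
  cat(sprintf("  %d cells, %d configurations, %d regions (%d flagged tests)\n",
              nrow(x$cells), nrow(x$configurations), nrow(x$regions),
              x$meta$n_flagged))
  cat(sprintf("  pool: %d kept of %d (seed %d, 10^[-%g,%g]); %.1f s\n",
              x$meta$pool_kept, x$meta$pool_n, x$meta$pool_seed,
              x$meta$log_range, x$meta$log_range, x$meta$elapsed_s))
  invisible(x)
}

#' Enumerate realizable steady-state configurations
#'
#' A configuration is the set of switching domains that attract
#' simultaneously; it is closed under the cell swap (conjugate domains
#' enter together) and, over the admissible parameter set, always contains
#' at least one symmetric (diagonal) domain.
#'
#' @inheritParams decompose_regions
#' @param ... Passed to [decompose_regions()].
#' @return The configuration table of the catalog.
#' @export
enumerate_configurations <- function(order = c("theta2_lt_theta1",
                                               "theta1_lt_theta2"), ...) {
  decompose_regions(match.arg(order), ...)$configurations
}

#' Locate a parameter set in the region catalog
#'
#' Computes the q-vector and threshold zones of `p` and looks the resulting
#' cell up in the catalog. Points on boundary hypersurfaces or outside the
#' admissible set return `NA`.
#'
#' @param catalog A [decompose_regions()] catalog.
#' @param p A [dimless_params()] object (matching the catalog's threshold
#'   ordering), or a data frame with the eight group columns.
#' @return Region label(s), `NA` where not locatable.
#' @export
region_membership <- function(catalog, p) {
  stopifnot(inherits(catalog, "region_catalog"))
  if (inherits(p, "dimless_params")) {
    p <- as.data.frame(t(param_vec(p)[1:8]))
  }
  Q <- q_matrix(catalog$order, p$mu, p$gamma, p$eta, p$kappa, p$pi,
                p$epsilon)
  tau_lo <- p$mu * p$pi * pmin(p$theta1, p$theta2)
  tau_hi <- p$mu * p$pi * pmax(p$theta1, p$theta2)
  Z <- (Q > tau_lo) + (Q > tau_hi)
  idv <- as.vector(Z %*% POW3)
  ord_ok <- if (catalog$order == "theta2_lt_theta1")
    p$theta2 < p$theta1 else p$theta1 < p$theta2
  lab <- catalog$cells$region[match(idv, catalog$cells$id)]
  lab[!ord_ok | p$eta <= p$kappa] <- NA_character_
  lab
}

#' Canonical fixed-point quantities of the sharp-switch decomposition
#'
#' The nine rational functions `mu*pi*P*` (one per symmetric domain, two
#' per conjugate asymmetric pair) whose positions relative to
#' `mu*pi*theta_low` and `mu*pi*theta_high` determine the attracting-domain
#' set. Exposed for inspection of region inequalities.
#'
#' @param order Threshold ordering.
#' @param p A [dimless_params()] object or a data frame with columns
#'   `mu, gamma, eta, kappa, pi, epsilon`.
#' @return Matrix with one row per parameter set, columns `sym0, sym1,
#'   sym2, p01_1, p01_2, p02_1, p02_2, p12_1, p12_2`.
#' @export
canonical_quantities <- function(order = c("theta2_lt_theta1",
                                           "theta1_lt_theta2"), p) {
  order <- match.arg(order)
  if (inherits(p, "dimless_params")) p <- as.data.frame(t(param_vec(p)[1:8]))
  q_matrix(order, p$mu, p$gamma, p$eta, p$kappa, p$pi, p$epsilon)
}

#' The bistable-selection region of the two-cell model
#'
#' For `theta2 < theta1`, the parameter region whose sharp-switch
#' configuration couples the symmetric mid-level attractor (domain 4) with
#' the high/low asymmetric pair (domains 2 and 6) is the natural candidate
#' for robust oocyte selection. Its compact defining inequality chain is
#' \deqn{L_A < \pi\mu\theta_2 < 1, \qquad
#'       1 < \frac{(1+\gamma)(1+\eta)}{1+\kappa} < \pi\mu\theta_1 < L_B,}
#' with \eqn{L_A, L_B} the `mu*pi*(P1*, P2*)` components of the (0,2)
#' domain's fixed point. The chain is necessary for the configuration; the
#' complete derived description additionally requires the (1,2)-pair fixed
#' point component `C1` to avoid the mid zone (see the package vignette),
#' and the catalog region carries that full description.
#'
#' `in_selection_chain()` evaluates the chain on a data frame of
#' parameter sets (used verbatim as the sampling region of the density studies);
#' `selection_chain_strings()` returns the chain in readable form.
#'
#' @param p A data frame with columns `mu, gamma, eta, kappa, pi, epsilon,
#'   theta1, theta2`, or a [dimless_params()] object.
#' @return Logical vector.
#' @export
in_selection_chain <- function(p) {
  if (inherits(p, "dimless_params")) {
    p <- as.data.frame(t(param_vec(p)[1:8]))
  }
  q <- domain_q(0, 2, "theta2_lt_theta1", p$mu, p$gamma, p$eta, p$kappa,
                p$pi, p$epsilon)
  w <- (1 + p$gamma) * (1 + p$eta) / (1 + p$kappa)
  t1 <- p$mu * p$pi * p$theta1
  t2 <- p$mu * p$pi * p$theta2
  q$q1 < t2 & t2 < 1 & 1 < w & w < t1 & t1 < q$q2
}

#' @rdname in_selection_chain
#' @export
selection_chain_strings <- function() {
  c(sprintf("%s < mu*pi*theta2", q_string("p02_1", "theta2_lt_theta1")),
    "mu*pi*theta2 < 1",
    "1 < (1+gamma)*(1+eta)/(1+kappa)",
    "(1+gamma)*(1+eta)/(1+kappa) < mu*pi*theta1",
    sprintf("mu*pi*theta1 < %s", q_string("p02_2", "theta2_lt_theta1")))
}
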