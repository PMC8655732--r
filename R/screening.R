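#' Smallest penalty that zeroes every group
#'
#' `lambda_max = max_g ||sum_i (X_g^i)' y^i||_2 / w_g`.  For every
#' `lambda >= lambda_max` the all-zero coefficient vector is optimal, so the
#' relative regularization grid is anchored at this value.  Computed by
#' aggregating per-site `p_g`-length partials only.
#'
#' @param shards List of `institution_shard`s.
#' @param groups Groups table.
#' @return The value, with attributes `argmax_group` (the achieving group
#'   id) and `degenerate` (`TRUE` when `y` is all zero, in which case 0 is
#'   returned and the path is flagged).
#' @export
lambda_max <- function(shards, groups) {
  check_shards(shards, groups)
  corr <- numeric(sum(groups$size))
  for (s in shards) corr <- corr + as.vector(crossprod(s$X, s$y))
  gid <- group_ids_per_column(groups)
  ratios <- group_norms(corr, gid) / groups$weight
  lam <- max(ratios)
  degenerate <- all(vapply(shards, function(s) all(s$y == 0), logical(1)))
  if (degenerate) {
    warning("response is identically zero: lambda_max = 0, path degenerate")
    lam <- 0
  }
  structure(lam, argmax_group = groups$group_id[which.max(ratios)],
            degenerate = degenerate)
}

#' Uniform relative regularization grid
#'
#' @param from,to Endpoints of the relative grid (defaults 1.0 down to 0.1).
#' @param length Number of values (default 100).
#' @return Strictly decreasing numeric vector, first `from`, last `to`.
#' @export
#' @examples
#' g <- lambda_grid()     # 100 values from 1.0 to 0.1
#' c(g[1], g[100])
lambda_grid <- function(from = 1, to = 0.1, length = 100L) {
  if (!(from > to)) stop("'from' must exceed 'to'")
  if (from > 1 || to <= 0) stop("relative grid must lie in (0, 1]")
  seq(from, to, length.out = as.integer(length))
}

# Screening state: everything the sequential dual-polytope test needs about
# the previous path point.  theta is stored as per-site slices; lipschitz
# caches the per-group Gram eigenvalues so spectral norms come for free.
make_screening_state <- function(shards, groups, lambda, beta, lipschitz,
                                 lambda_max_value, kkt = 0, stale = FALSE) {
  gid <- group_ids_per_column(groups)
  # at (or above) lambda_max the exact solution is identically zero; snap
  # away any solver dust so the dual anchor theta = y/lambda is exact
  if (lambda >= as.numeric(lambda_max_value) * (1 - 1e-10))
    beta <- numeric(length(beta))
  theta <- lapply(shards, function(s)
    (s$y - as.vector(s$X %*% beta)) / lambda)
  # rescale into the dual-feasible polytope (exact duals are feasible;
  # numerically approximate ones can poke out slightly)
  corr <- numeric(length(gid))
  for (i in seq_along(shards))
    corr <- corr + as.vector(crossprod(shards[[i]]$X, theta[[i]]))
  sfac <- max(group_norms(corr, gid) / groups$weight)
  if (is.finite(sfac) && sfac > 1)
    theta <- lapply(theta, function(t) t / sfac)
  structure(list(lambda = lambda, beta = beta, theta = theta,
                 lambda_max = as.numeric(lambda_max_value),
                 argmax_group = attr(lambda_max_value, "argmax_group"),
                 lipschitz = lipschitz, kkt = kkt, stale = stale),
            class = "screening_state")
}

#' Safe screening of inactive groups before a path step
#'
#' Sequential dual-polytope-projection (EDPP-family) test for the group
#' LASSO, assembled federatedly: all inner products and per-group statistics
#' are sums of per-site terms, so only aggregates cross site boundaries.
#' With `theta0` the dual point at the previous value `lambda0`, the test
#' builds `v1` (the feasible direction at `lambda0`; at `lambda0 =
#' lambda_max` it is the gradient of the single active dual constraint),
#' `v2 = y/lambda_new - theta0`, the projection residual
#' `v2_perp = v2 - (<v1,v2>/||v1||^2) v1`, and discards group `g` when
#'
#' `|| X_g' (theta0 + v2_perp/2) ||_2 < w_g - ||v2_perp||_2 ||X_g||_2 / 2`.
#'
#' Discarded groups are provably zero in the exact solution at
#' `lambda_new`; the returned retained set is therefore a superset of the
#' true active set.  Groups active at `lambda0` are always retained.  When
#' the state is stale (its solution did not satisfy the optimality
#' conditions at `lambda0` to tolerance), screening is skipped with a
#' warning and every group is retained.
#'
#' @param state A screening state from [solve_path()] internals (previous
#'   exact solution).
#' @param lambda_new New absolute regularization value,
#'   `lambda_new <= state$lambda`.
#' @param shards,groups Design pieces.
#' @param slack Relative numerical safety margin subtracted from the discard
#'   threshold (default 1e-6 of `w_g`); guards against a slightly inexact
#'   previous dual point.
#' @return Integer vector of retained group ids (sorted).
#' @export
screen_groups <- function(state, lambda_new, shards, groups, slack = 1e-6) {
  stopifnot(inherits(state, "screening_state"))
  if (lambda_new > state$lambda)
    stop("lambda_new must not exceed the state's lambda (decreasing path)")
  if (isTRUE(state$stale)) {
    warning("screening state stale (previous solution not optimal to tolerance); retaining all groups")
    return(groups$group_id)
  }
  gid <- group_ids_per_column(groups)
  lam0 <- state$lambda
  at_max <- lam0 >= state$lambda_max * (1 - 1e-10)

  # v1, v2 as per-site slices
  if (at_max) {
    gstar <- state$argmax_group
    row <- groups[groups$group_id == gstar, ]
    cols <- row$start + seq_len(row$size) - 1L
    cg <- numeric(row$size)
    for (s in shards) cg <- cg + as.vector(crossprod(s$X[, cols, drop = FALSE], s$y))
    v1 <- lapply(shards, function(s)
      as.vector(s$X[, cols, drop = FALSE] %*% cg))
  } else {
    v1 <- mapply(function(s, th) s$y / lam0 - th, shards, state$theta,
                 SIMPLIFY = FALSE)
  }
  v2 <- mapply(function(s, th) s$y / lambda_new - th, shards, state$theta,
               SIMPLIFY = FALSE)
  v1v1 <- sum(vapply(v1, function(v) sum(v * v), numeric(1)))
  v1v2 <- sum(mapply(function(a, b) sum(a * b), v1, v2))
  coef <- if (v1v1 > 0) v1v2 / v1v1 else 0
  v2p <- mapply(function(a, b) b - coef * a, v1, v2, SIMPLIFY = FALSE)
  nv2p <- sqrt(sum(vapply(v2p, function(v) sum(v * v), numeric(1))))

  corr <- numeric(length(gid))
  for (i in seq_along(shards)) {
    u <- state$theta[[i]] + v2p[[i]] / 2
    corr <- corr + as.vector(crossprod(shards[[i]]$X, u))
  }
  lhs <- group_norms(corr, gid)
  spec <- sqrt(pmax(state$lipschitz, 0))
  rhs <- groups$weight - 0.5 * nv2p * spec - slack * groups$weight
  discard <- lhs < rhs
  active_prev <- group_norms(state$beta, gid) > 0
  sort(groups$group_id[!discard | active_prev])
}

#' Solve a full regularization path with federated screening
#'
#' For each value of a strictly decreasing relative grid: screen groups
#' against the previous exact solution, run [fbcd_solve()] on the retained
#' groups only (warm-started from the previous solution, with screened-out
#' groups zeroed -- they are provably zero at the new optimum), and embed the
#' solution into full p-space.  The anchor of the sequential screening is
#' always `lambda_max` itself, where the solution is exactly zero.
#'
#' @param shards List of `institution_shard`s.
#' @param groups Groups table.
#' @param lambdas_rel Strictly decreasing relative grid in (0, 1] (see
#'   [lambda_grid()]).
#' @param config A [solver_config()] (its `lambda_rel` field is ignored;
#'   the grid governs).
#' @param screen Logical; `FALSE` disables screening (every group retained
#'   at every value), used for path-equivalence checks.
#' @param slack Passed to [screen_groups()].
#' @return A `lambda_path` with `lambdas_rel`, `lambda_max`, sparse `beta`
#'   (p x kappa, `Matrix::dgCMatrix`), `objectives`, `retained_counts`,
#'   `active_counts`, `kkt_gaps`, `n_updates` (per value) and
#'   `n_updates_total`.
#' @export
solve_path <- function(shards, groups, lambdas_rel = lambda_grid(),
                       config = solver_config(), screen = TRUE,
                       slack = 1e-6) {
  p <- check_shards(shards, groups)
  lambdas_rel <- as.numeric(lambdas_rel)
  if (length(lambdas_rel) < 1L) stop("empty lambda grid")
  if (any(lambdas_rel <= 0) || any(lambdas_rel > 1))
    stop("relative lambdas must lie in (0, 1]")
  if (any(diff(lambdas_rel) >= 0))
    stop("lambda grid must be strictly decreasing")
  lam_max <- lambda_max(shards, groups)
  if (isTRUE(attr(lam_max, "degenerate")))
    stop("degenerate path: response is identically zero")
  lipschitz <- cpp_group_lipschitz(lapply(shards, `[[`, "X"),
                                   as.integer(groups$start - 1L),
                                   as.integer(groups$size))
  gid <- group_ids_per_column(groups)
  kappa <- length(lambdas_rel)
  objectives <- numeric(kappa)
  kkts <- numeric(kappa)
  retained_counts <- integer(kappa)
  retained_sets <- vector("list", kappa)
  active_counts <- integer(kappa)
  updates <- numeric(kappa)
  tri_i <- list(); tri_j <- list(); tri_x <- list()

  state <- make_screening_state(shards, groups, as.numeric(lam_max),
                                numeric(p), lipschitz, lam_max)
  beta_warm <- numeric(p)
  for (k in seq_len(kappa)) {
    lam <- lambdas_rel[k] * as.numeric(lam_max)
    retained <- if (screen && lambdas_rel[k] < 1) {
      screen_groups(state, lam, shards, groups, slack = slack)
    } else groups$group_id
    retained_counts[k] <- length(retained)
    retained_sets[[k]] <- retained
    # zero screened-out groups in the warm start (they are provably zero)
    if (length(retained) < nrow(groups)) {
      drop_cols <- gid %in% setdiff(groups$group_id, retained)
      beta_warm[drop_cols] <- 0
    }
    sol <- tryCatch(
      fbcd_solve(shards, groups, config = config, lambda = lam,
                 warm_start = list(beta = beta_warm),
                 active_groups = retained, lipschitz = lipschitz),
      error = function(e)
        stop(sprintf("path failed at lambda_rel = %.4g: %s",
                     lambdas_rel[k], conditionMessage(e))))
    objectives[k] <- sol$objective
    kkts[k] <- sol$kkt_gap
    updates[k] <- sol$n_updates
    nz <- which(sol$beta != 0)
    active_counts[k] <- length(unique(gid[nz]))
    tri_i[[k]] <- nz; tri_j[[k]] <- rep.int(k, length(nz)); tri_x[[k]] <- sol$beta[nz]
    beta_warm <- sol$beta
    # staleness guard: the next screening step needs an (almost) exact dual
    stale <- !sol$converged || sol$kkt_gap > 1e-3 * as.numeric(lam_max)
    state <- make_screening_state(shards, groups, lam, sol$beta, lipschitz,
                                  lam_max, kkt = sol$kkt_gap, stale = stale)
  }
  beta <- Matrix::sparseMatrix(i = unlist(tri_i), j = unlist(tri_j),
                               x = unlist(tri_x), dims = c(p, kappa))
  structure(list(lambdas_rel = lambdas_rel,
                 lambda_max = as.numeric(lam_max),
                 beta = beta,
                 objectives = objectives,
                 kkt_gaps = kkts,
                 retained_counts = retained_counts,
                 retained = retained_sets,
                 active_counts = active_counts,
                 n_updates = updates,
                 n_updates_total = sum(updates),
                 screened = screen,
                 groups = groups),
            class = "lambda_path")
}

#' @export
print.lambda_path <- function(x, ...) {
  cat(sprintf(
    "<lambda_path> %d values in [%.3g, %.3g] x lambda_max = %.4g; screening %s\n",
    length(x$lambdas_rel), min(x$lambdas_rel), max(x$lambdas_rel),
    x$lambda_max, if (x$screened) "on" else "off"))
  cat(sprintf("  retained groups: %d .. %d; active at last value: %d; %g group updates\n",
              min(x$retained_counts), max(x$retained_counts),
              x$active_counts[length(x$active_counts)], x$n_updates_total))
  invisible(x)
}

#' Write the per-lambda path summary as delimited text
#'
#' @param path A `lambda_path`.
#' @param file Output TSV path.
#' @return The file path, invisibly.
#' @export
write_path_summary <- function(path, file) {
  df <- data.frame(lambda_rel = path$lambdas_rel,
                   objective = path$objectives,
                   retained_groups = path$retained_counts,
                   active_groups = path$active_counts)
  data.table::fwrite(df, file, sep = "\t")
  invisible(file)
}
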