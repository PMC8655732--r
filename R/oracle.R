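#' Centralized proximal-gradient reference solver
#'
#' A plain (accelerated) proximal-gradient solver for the group-LASSO
#' objective on the pooled design.  It shares no code with the federated
#' block coordinate descent path and serves as an independent reference in
#' verification: both solvers minimize the same convex objective, so their
#' objective values must agree to tight tolerance.
#'
#' @param X Pooled feature matrix (subjects x features).
#' @param y Response vector.
#' @param groups Groups table (`group_id`, `start`, `size`, `weight`).
#' @param lambda Absolute regularization value.
#' @param tol Relative objective-change tolerance (default 1e-10).
#' @param max_iter Iteration cap.
#' @param warm_start Optional initial coefficient vector.
#' @param L Optional Lipschitz constant `||X||_2^2`; computed by SVD when
#'   omitted.
#' @return List with `beta`, `objective`, `iterations`, `converged`.
#' @export
prox_glasso <- function(X, y, groups, lambda, tol = 1e-10,
                        max_iter = 50000L, warm_start = NULL, L = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(groups$size) != p) stop("groups do not cover X columns")
  gid <- group_ids_per_column(groups)
  w <- groups$weight
  if (is.null(L)) L <- svd(X, nu = 0, nv = 0)$d[1]^2
  if (L <= 0) stop("degenerate design: zero spectral norm")
  step <- 1 / L

  prox <- function(z, t) {
    # groupwise soft threshold, vectorized over groups
    ng <- group_norms(z, gid)
    scale <- pmax(0, 1 - (t * w) / pmax(ng, 1e-300))
    z * scale[gid]
  }
  obj <- function(b) {
    r <- y - as.vector(X %*% b)
    0.5 * sum(r * r) + lambda * sum(w * group_norms(b, gid))
  }

  beta <- if (is.null(warm_start)) numeric(p) else as.numeric(warm_start)
  zvec <- beta
  tk <- 1
  f_prev <- obj(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- as.vector(crossprod(X, as.vector(X %*% zvec) - y))
    beta_new <- prox(zvec - step * grad, step * lambda)
    f_new <- obj(beta_new)
    if (f_new > f_prev) {
      # monotone restart: fall back to a plain proximal step from beta
      grad <- as.vector(crossprod(X, as.vector(X %*% beta) - y))
      beta_new <- prox(beta - step * grad, step * lambda)
      f_new <- obj(beta_new)
      tk <- 1
      zvec <- beta_new
    } else {
      t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
      zvec <- beta_new + ((tk - 1) / t_next) * (beta_new - beta)
      tk <- t_next
    }
    rel <- abs(f_prev - f_new) / max(abs(f_prev), 1e-300)
    beta <- beta_new
    if (rel < tol && it > 1L) {
      f_prev <- f_new
      converged <- TRUE
      break
    }
    f_prev <- f_new
  }
  list(beta = beta, objective = f_prev, iterations = it, converged = converged)
}

#' Unscreened reference path on the pooled design
#'
#' Solves the group LASSO at each value of a decreasing relative grid with
#' [prox_glasso()] and warm starts, without any screening.  Used as the
#' oracle when certifying that the safe-screening rule never discards an
#' active group.
#'
#' @param X,y,groups As in [prox_glasso()].
#' @param lambdas_rel Strictly decreasing relative grid in (0, 1].
#' @param tol,max_iter Passed to [prox_glasso()].
#' @return List with `lambdas_rel`, `lambda_max`, `beta` (p x length(grid)
#'   matrix), `objectives`.
#' @export
prox_glasso_path <- function(X, y, groups, lambdas_rel, tol = 1e-10,
                             max_iter = 50000L) {
  gid <- group_ids_per_column(groups)
  lam_max <- max(group_norms(as.vector(crossprod(X, y)), gid) / groups$weight)
  L <- svd(X, nu = 0, nv = 0)$d[1]^2
  p <- ncol(X)
  B <- matrix(0, p, length(lambdas_rel))
  objs <- numeric(length(lambdas_rel))
  warm <- NULL
  for (k in seq_along(lambdas_rel)) {
    fit <- prox_glasso(X, y, groups, lambdas_rel[k] * lam_max,
                       tol = tol, max_iter = max_iter,
                       warm_start = warm, L = L)
    B[, k] <- fit$beta
    objs[k] <- fit$objective
    warm <- fit$beta
  }
  list(lambdas_rel = lambdas_rel, lambda_max = lam_max, beta = B,
       objectives = objs)
}
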