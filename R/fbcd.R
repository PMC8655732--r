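#' Solver configuration
#'
#' @param lambda_rel Regularization strength relative to `lambda_max`
#'   (in (0, 1]).
#' @param tol Relative objective-change convergence tolerance.
#' @param max_epochs Maximum number of full cycles over the groups.
#' @param group_order `"fixed"` (ascending group id, the default, for
#'   determinism) or `"shuffled"` (seeded permutation).
#' @param seed Seed used when `group_order = "shuffled"`.
#' @return A `solver_config` list.
#' @export
solver_config <- function(lambda_rel = 0.1, tol = 1e-8, max_epochs = 1000L,
                          group_order = c("fixed", "shuffled"), seed = 1L) {
  group_order <- match.arg(group_order)
  if (!is.numeric(lambda_rel) || lambda_rel <= 0 || lambda_rel > 1)
    stop("lambda_rel must be in (0, 1]")
  if (tol <= 0) stop("tol must be > 0")
  max_epochs <- as.integer(max_epochs)
  if (max_epochs < 1L) stop("max_epochs must be >= 1")
  structure(list(lambda_rel = lambda_rel, tol = tol,
                 max_epochs = max_epochs, group_order = group_order,
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Per-site partial gradient for one group
#'
#' Computes the institution's contribution `(X_g^i)' (X^i beta - y^i)` to the
#' global gradient of the least-squares loss with respect to the group's
#' coefficients.  Only this `p_g`-length aggregate leaves the site; raw rows
#' of `X^i` or `y^i` are never transmitted.
#'
#' @param shard An `institution_shard`.
#' @param beta Current full coefficient vector (length p).
#' @param group One row of the groups table (with `group_id`, `start`,
#'   `size`), or a group id together with `groups`.
#' @param groups Optional groups table when `group` is an id.
#' @return A `gradient_message` with `site_id`, `group_id`,
#'   `partial_gradient`.
#' @export
local_gradient <- function(shard, beta, group, groups = NULL) {
  if (length(group) == 1L && is.numeric(group)) {
    stopifnot(!is.null(groups))
    group <- groups[groups$group_id == as.integer(group), , drop = FALSE]
  }
  if (length(beta) != ncol(shard$X))
    stop(sprintf("beta has length %d but shard has %d columns",
                 length(beta), ncol(shard$X)))
  cols <- group$start + seq_len(group$size) - 1L
  r <- as.vector(shard$X %*% beta) - shard$y
  g <- as.vector(crossprod(shard$X[, cols, drop = FALSE], r))
  structure(list(site_id = shard$site_id,
                 group_id = as.integer(group$group_id),
                 partial_gradient = g),
            class = "gradient_message")
}

#' Aggregate per-site gradient messages
#'
#' Master-side sum of the per-institution partial gradients for one group,
#' in ascending `site_id` order so that floating-point results are
#' reproducible run to run.
#'
#' @param messages List of `gradient_message`s, one per site, all for the
#'   same group.
#' @param expected_sites Optional integer vector of site ids that must be
#'   present; a missing site raises a protocol error naming it.
#' @return Numeric vector: the aggregated gradient for the group.
#' @export
aggregate_gradients <- function(messages, expected_sites = NULL) {
  if (length(messages) == 0L) stop("no messages to aggregate")
  gids <- vapply(messages, function(m) m$group_id, integer(1))
  if (length(unique(gids)) != 1L)
    stop("messages mix different groups")
  sids <- vapply(messages, function(m) m$site_id, integer(1))
  if (anyDuplicated(sids)) stop("duplicate site in messages")
  if (!is.null(expected_sites)) {
    missing <- setdiff(expected_sites, sids)
    if (length(missing) > 0L)
      stop(sprintf("protocol error: missing gradient from site %s",
                   paste(missing, collapse = ", ")))
  }
  ord <- order(sids)
  lens <- vapply(messages, function(m) length(m$partial_gradient), integer(1))
  if (length(unique(lens)) != 1L) stop("message length mismatch")
  out <- numeric(lens[1])
  for (i in ord) out <- out + messages[[i]]$partial_gradient
  out
}

#' Group soft-threshold (shrinkage) operator
#'
#' The proximal map of the Euclidean-norm penalty:
#' `S_t(z) = z * max(0, 1 - t / ||z||_2)`, returning the zero vector when
#' `||z||_2 <= t`.
#'
#' @param z Numeric vector.
#' @param t Non-negative threshold.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' group_soft_threshold(c(3, 4), 2.5)  # (1.5, 2): ||z|| = 5, factor 0.5
group_soft_threshold <- function(z, t) {
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0)
    stop("t must be a non-negative scalar")
  nz <- sqrt(sum(z^2))
  if (nz <= t || nz == 0) return(numeric(length(z)))
  z * (1 - t / nz)
}

#' Group-LASSO objective from per-site pieces
#'
#' `0.5 * sum_i ||y^i - X^i beta||^2 + lambda * sum_g w_g ||beta_g||_2`,
#' assembled from per-site partial residual norms only.
#'
#' @param shards List of `institution_shard`s.
#' @param beta Coefficient vector (length p).
#' @param lambda Absolute regularization parameter.
#' @param groups Groups table (`start`, `size`, `weight`).
#' @return The objective value (scalar).
#' @export
gl_objective <- function(shards, beta, lambda, groups) {
  p <- check_shards(shards, groups)
  if (length(beta) != p) stop("beta length does not match design columns")
  quad <- 0
  for (s in shards) {
    r <- s$y - as.vector(s$X %*% beta)
    quad <- quad + sum(r * r)
  }
  gid <- group_ids_per_column(groups)
  pen <- sum(groups$weight * group_norms(beta, gid))
  0.5 * quad + lambda * pen
}

# Euclidean norm of each contiguous group slice of v; gid must be the
# per-column group id vector (sorted 1..G blocks).
group_norms <- function(v, gid) {
  sqrt(as.vector(rowsum(as.vector(v)^2, gid, reorder = TRUE)))
}

#' Federated block coordinate descent for the group LASSO
#'
#' Cycles over groups; for each group the master aggregates the per-site
#' partial gradients and takes a proximal step
#' `beta_g <- S_{lambda w_g / L_g}(beta_g - grad_g / L_g)` with `L_g` the
#' largest eigenvalue of the aggregated group Gram matrix (the blockwise
#' Lipschitz constant, which guarantees monotone descent).  Stops when the
#' relative objective change over one epoch falls below `tol`.
#'
#' @param shards List of `institution_shard`s (row partition of one design).
#' @param groups Groups table (`group_id`, `start`, `size`, `weight`).
#' @param config A [solver_config()].
#' @param lambda Absolute regularization value; when `NULL`, computed as
#'   `config$lambda_rel * lambda_max(shards, groups)`.
#' @param warm_start Optional previous solution (its `beta` is reused).
#' @param active_groups Optional integer vector of group ids to cycle over
#'   (e.g. the retained set after screening); all others keep their
#'   warm-start values (zero them beforehand if they were screened out).
#' @param lipschitz Optional precomputed per-group Lipschitz constants.
#' @param transport `"fast"` (compiled path) or `"logged"` (pure-R
#'   master/worker message exchange that records every transmitted message;
#'   same arithmetic, used to audit the privacy contract).
#' @return An `fmfs_solution` with `beta`, `objective`, `epochs_run`,
#'   `converged`, `kkt_gap`, `n_updates`, `lambda`, and (logged transport
#'   only) `message_log`.
#' @export
fbcd_solve <- function(shards, groups, config = solver_config(),
                       lambda = NULL, warm_start = NULL,
                       active_groups = NULL, lipschitz = NULL,
                       transport = c("fast", "logged")) {
  transport <- match.arg(transport)
  p <- check_shards(shards, groups)
  G <- nrow(groups)
  if (is.null(lambda)) {
    lambda <- config$lambda_rel * as.numeric(lambda_max(shards, groups))
  }
  lambda <- as.numeric(lambda)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be finite and >= 0")
  beta0 <- if (is.null(warm_start)) numeric(p) else as.numeric(warm_start$beta)
  if (length(beta0) != p) stop("warm start has wrong length")
  if (is.null(lipschitz))
    lipschitz <- cpp_group_lipschitz(lapply(shards, `[[`, "X"),
                                     as.integer(groups$start - 1L),
                                     as.integer(groups$size))
  active <- if (is.null(active_groups)) groups$group_id else sort(as.integer(active_groups))
  if (length(active) > 0L && (min(active) < 1L || max(active) > G))
    stop("active_groups out of range")
  order_idx <- active
  if (config$group_order == "shuffled")
    order_idx <- with_seed(config$seed, sample(active))

  if (transport == "fast") {
    res <- cpp_bcd_solve(lapply(shards, `[[`, "X"),
                         lapply(shards, `[[`, "y"),
                         beta0,
                         as.integer(groups$start - 1L),
                         as.integer(groups$size),
                         as.numeric(groups$weight),
                         as.numeric(lipschitz),
                         as.integer(order_idx - 1L),
                         lambda, config$tol, config$max_epochs)
    message_log <- NULL
  } else {
    res <- r_bcd_solve_logged(shards, groups, beta0, lipschitz, order_idx,
                              lambda, config$tol, config$max_epochs)
    message_log <- res$message_log
  }
  kkt <- kkt_gap(shards, groups, res$beta, lambda)
  structure(list(beta = as.numeric(res$beta),
                 objective = res$objective,
                 epochs_run = res$epochs_run,
                 converged = res$converged,
                 kkt_gap = kkt,
                 n_updates = res$n_updates,
                 trace = res$trace,
                 lambda = lambda,
                 active_groups = active,
                 message_log = message_log),
            class = "fmfs_solution")
}

#' @export
print.fmfs_solution <- function(x, ...) {
  cat(sprintf(
    "<fmfs_solution> lambda %.4g, objective %.6g, %d epochs (%s), kkt gap %.3g, %d nonzero\n",
    x$lambda, x$objective, x$epochs_run,
    if (x$converged) "converged" else "max epochs", x$kkt_gap,
    sum(x$beta != 0)))
  invisible(x)
}

# Pure-R federated BCD with an explicit master/worker message exchange.
# Mirrors the compiled path arithmetic (same site order, same updates) while
# recording every message that crosses a site boundary, so tests can assert
# that only p_g-length aggregates are ever transmitted.
r_bcd_solve_logged <- function(shards, groups, beta, lipschitz, order_idx,
                               lambda, tol, max_epochs) {
  I <- length(shards)
  # worker state: residual r_i = X_i beta - y_i, kept locally
  resid <- vector("list", I)
  for (i in seq_len(I))
    resid[[i]] <- as.vector(shards[[i]]$X %*% beta) - shards[[i]]$y
  log_env <- new.env(parent = emptyenv())
  log_env$messages <- list()
  send <- function(site_id, group_id, payload, kind) {
    log_env$messages[[length(log_env$messages) + 1L]] <-
      list(site_id = site_id, group_id = group_id, kind = kind,
           length = length(payload))
    payload
  }
  objective <- function() {
    quad <- 0
    for (i in seq_len(I)) {
      # sites report a scalar partial residual norm
      quad <- quad + send(i, NA_integer_, sum(resid[[i]]^2), "residual_norm")
    }
    gid <- group_ids_per_column(groups)
    0.5 * quad + lambda * sum(groups$weight * group_norms(beta, gid))
  }
  obj_prev <- objective()
  trace <- obj_prev
  updates <- 0
  converged <- FALSE
  epochs <- 0L
  for (epoch in seq_len(max_epochs)) {
    for (g in order_idx) {
      row <- groups[g, ]
      cols <- row$start + seq_len(row$size) - 1L
      updates <- updates + 1
      if (lipschitz[g] <= 0) next
      grad <- numeric(row$size)
      for (i in seq_len(I)) {  # ascending site order
        part <- as.vector(crossprod(shards[[i]]$X[, cols, drop = FALSE], resid[[i]]))
        grad <- grad + send(i, g, part, "partial_gradient")
      }
      bg <- beta[cols]
      z <- bg - grad / lipschitz[g]
      bnew <- group_soft_threshold(z, lambda * row$weight / lipschitz[g])
      delta <- bnew - bg
      if (any(delta != 0)) {
        # master broadcasts the p_g-length update; workers adjust residuals
        for (i in seq_len(I)) {
          send(0L, g, delta, "broadcast_update")
          resid[[i]] <- resid[[i]] +
            as.vector(shards[[i]]$X[, cols, drop = FALSE] %*% delta)
        }
        beta[cols] <- bnew
      }
    }
    epochs <- epoch
    obj <- objective()
    trace <- c(trace, obj)
    if (!is.finite(obj)) stop(sprintf("objective diverged at epoch %d", epoch))
    if (abs(obj_prev - obj) / max(abs(obj_prev), 1e-300) < tol) {
      converged <- TRUE
      obj_prev <- obj
      break
    }
    obj_prev <- obj
  }
  list(beta = beta, objective = obj_prev, epochs_run = epochs,
       converged = converged, n_updates = updates, trace = trace,
       message_log = log_env$messages)
}

#' KKT optimality gap of the group-LASSO objective
#'
#' Maximum over groups of the violation of the stationarity conditions:
#' for active groups `| ||X_g'(y - X beta)|| - lambda w_g |`, for inactive
#' groups the positive part of `||X_g'(y - X beta)|| - lambda w_g`.
#' Correlations are assembled from per-site partials.
#'
#' @param shards List of `institution_shard`s.
#' @param groups Groups table.
#' @param beta Coefficient vector.
#' @param lambda Absolute regularization value.
#' @return The gap (scalar, 0 at an exact optimum).
#' @export
kkt_gap <- function(shards, groups, beta, lambda) {
  corr <- numeric(sum(groups$size))
  for (s in shards) {
    r <- s$y - as.vector(s$X %*% beta)
    corr <- corr + as.vector(crossprod(s$X, r))
  }
  gid <- group_ids_per_column(groups)
  cn <- group_norms(corr, gid)
  bn <- group_norms(beta, gid)
  act <- bn > 0
  gap_active <- if (any(act)) max(abs(cn[act] - lambda * groups$weight[act])) else 0
  gap_inactive <- if (any(!act)) max(0, cn[!act] - lambda * groups$weight[!act]) else 0
  max(gap_active, gap_inactive)
}
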