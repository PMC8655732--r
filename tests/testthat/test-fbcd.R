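test_that("local gradients match hand computation and sum to the global one", {
  sh <- structure(list(site_id = 1L, X = matrix(c(1, 2), 1), y = 1,
                       rows = 1L), class = "institution_shard")
  grp <- data.frame(group_id = 1L, start = 1L, size = 2L, weight = sqrt(2))
  msg <- local_gradient(sh, c(1, 1), grp[1, ])
  expect_equal(msg$partial_gradient, c(2, 4))   # residual 2, X' * 2

  inst <- make_instance(12, N = 30, G = 5)
  beta <- rnorm(sum(inst$groups$size))
  # beta = 0 gives -X_g' y
  for (g in c(1, 4)) {
    row <- inst$groups[g, ]
    cols <- row$start + seq_len(row$size) - 1
    m0 <- local_gradient(inst$shards[[1]], numeric(length(beta)), row)
    expect_equal(m0$partial_gradient,
                 -as.vector(crossprod(inst$shards[[1]]$X[, cols, drop = FALSE],
                                      inst$shards[[1]]$y)))
    # sum over shards equals the centralized gradient
    msgs <- lapply(inst$shards, local_gradient, beta = beta, group = row)
    total <- aggregate_gradients(msgs)
    cen <- as.vector(crossprod(inst$X[, cols, drop = FALSE],
                               as.vector(inst$X %*% beta) - inst$y))
    expect_equal(total, cen, tolerance = 1e-10)
  }
  expect_error(local_gradient(inst$shards[[1]], numeric(3), inst$groups[1, ]),
               "length")
})

test_that("gradient aggregation is ordered, checked, and linear", {
  mk <- function(site, g, v)
    structure(list(site_id = site, group_id = g, partial_gradient = v),
              class = "gradient_message")
  expect_equal(aggregate_gradients(list(mk(1L, 1L, c(1, 2)))), c(1, 2))
  expect_equal(aggregate_gradients(list(mk(1L, 1L, c(1, -3)),
                                        mk(2L, 1L, c(-1, 3)))), c(0, 0))
  set.seed(4)
  vs <- replicate(3, rnorm(4), simplify = FALSE)
  msgs <- lapply(1:3, function(i) mk(i, 2L, vs[[i]]))
  expect_equal(aggregate_gradients(msgs), Reduce(`+`, vs))
  expect_error(aggregate_gradients(msgs[1:2], expected_sites = 1:3),
               "site 3")
  expect_error(aggregate_gradients(list(mk(1L, 1L, 1:2), mk(2L, 2L, 1:2))),
               "mix")
})

test_that("the group soft-threshold operator shrinks as specified", {
  expect_equal(group_soft_threshold(c(3, 4), 2.5), c(1.5, 2.0))
  expect_equal(group_soft_threshold(c(1, 1), 5), c(0, 0))    # full shrinkage
  z <- rnorm(6)
  expect_equal(group_soft_threshold(z, 0), z)                # no penalty
  expect_equal(group_soft_threshold(numeric(3), 1), numeric(3))
  expect_error(group_soft_threshold(c(1, 2), -1), "non-negative")
})

test_that("the objective decomposes over sites and matches hand values", {
  sh <- structure(list(site_id = 1L, X = matrix(c(1, 0), 1), y = 2,
                       rows = 1L), class = "institution_shard")
  grp <- data.frame(group_id = 1L, start = 1L, size = 2L, weight = 1)
  expect_equal(gl_objective(list(sh), c(1, 0), 1, grp), 1.5)
  expect_equal(gl_objective(list(sh), c(0, 0), 1, grp), 0.5 * 4)

  inst <- make_instance(9, N = 40, G = 6)
  beta <- rnorm(sum(inst$groups$size))
  for (I in c(1, 4)) {
    shI <- partition_rows(inst$design, I, seed = 2)
    expect_equal(gl_objective(shI, beta, 3, inst$groups),
                 gl_objective(as_single_shard(inst$design), beta, 3,
                              inst$groups),
                 tolerance = 1e-10)
  }
})

test_that("lambda_rel = 1 returns the zero solution within two epochs", {
  for (s in 1:5) {
    inst <- make_instance(40 + s)
    sol <- fbcd_solve(inst$shards, inst$groups,
                      solver_config(lambda_rel = 1))
    expect_equal(sol$beta, numeric(length(sol$beta)))
    expect_lte(sol$epochs_run, 2)
    expect_true(sol$converged)
  }
})

test_that("orthonormal single-group designs hit the closed-form solution", {
  set.seed(6)
  X <- qr.Q(qr(matrix(rnorm(40 * 5), 40)))   # orthonormal columns
  y <- rnorm(40)
  grp <- data.frame(group_id = 1L, start = 1L, size = 5L, weight = 1)
  d <- grouped_design(X, y, grp)
  lam <- 0.4 * sqrt(sum(crossprod(X, y)^2))
  sol <- fbcd_solve(as_single_shard(d), grp, solver_config(tol = 1e-12),
                    lambda = lam)
  expect_equal(sol$beta, group_soft_threshold(as.vector(crossprod(X, y)), lam),
               tolerance = 1e-10)
})

test_that("the objective descends monotonically and satisfies the KKT system", {
  for (s in 1:10) {
    inst <- make_instance(60 + s, N = 50, G = 10)
    sol <- fbcd_solve(inst$shards, inst$groups,
                      solver_config(lambda_rel = 0.3, tol = 1e-10))
    expect_true(all(diff(sol$trace) <= 1e-10 * pmax(1, abs(sol$trace[-1]))))
    # inactive groups respect the dual constraint
    gid <- rep(inst$groups$group_id, inst$groups$size)
    corr <- as.vector(crossprod(inst$X, inst$y - inst$X %*% sol$beta))
    cn <- sqrt(as.vector(rowsum(corr^2, gid)))
    bn <- sqrt(as.vector(rowsum(sol$beta^2, gid)))
    lam <- sol$lambda
    expect_true(all(cn[bn == 0] <= lam * inst$groups$weight[bn == 0] * (1 + 1e-6)))
    # the objective-change stopping rule certifies the objective, not the
    # gradient; the residual stationarity violation stays small on the
    # lambda_max scale
    lam_max_val <- as.numeric(lambda_max(inst$shards, inst$groups))
    expect_lt(sol$kkt_gap, 1e-3 * lam_max_val)
  }
})

test_that("federated BCD matches the centralized oracle on random instances", {
  for (s in 1:10) {
    inst <- make_instance(80 + s, N = 60, G = 4, sizes = rep(6, 4))
    cfg <- solver_config(lambda_rel = runif(1, 0.15, 0.8), tol = 1e-10,
                         max_epochs = 5000)
    sol <- fbcd_solve(inst$shards, inst$groups, cfg)
    orc <- prox_glasso(inst$X, inst$y, inst$groups, sol$lambda, tol = 1e-12,
                       max_iter = 100000)
    expect_lt(abs(sol$objective - orc$objective), 1e-6)
  }
})

test_that("solutions are invariant to the institutional partition", {
  inst <- make_instance(7, N = 60, G = 8, n_sites = 1)
  ref <- NULL
  for (I in c(1, 3, 5)) {
    sh <- partition_rows(inst$design, I, seed = 5)
    sol <- fbcd_solve(sh, inst$groups,
                      solver_config(lambda_rel = 0.25, tol = 1e-10,
                                    max_epochs = 5000))
    if (is.null(ref)) ref <- sol
    expect_lt(abs(sol$objective - ref$objective), 1e-8)
    expect_lt(max(abs(sol$beta - ref$beta)), 1e-6)
  }
})

test_that("the logged transport matches the fast path and never leaks rows", {
  inst <- make_instance(17, N = 45, G = 6, n_sites = 3)
  cfg <- solver_config(lambda_rel = 0.3, tol = 1e-9)
  fast <- fbcd_solve(inst$shards, inst$groups, cfg)
  logged <- fbcd_solve(inst$shards, inst$groups, cfg, transport = "logged")
  expect_equal(logged$beta, fast$beta, tolerance = 1e-12)
  expect_equal(logged$objective, fast$objective, tolerance = 1e-12)
  # privacy contract: only per-group aggregates and scalars cross sites
  lens <- vapply(logged$message_log, `[[`, numeric(1), "length")
  expect_true(length(lens) > 0)
  expect_lte(max(lens), max(inst$groups$size))
  n_rows <- min(vapply(inst$shards, function(s) nrow(s$X), numeric(1)))
  expect_true(all(lens < n_rows))
})

test_that("shuffled group order still reaches the same optimum", {
  inst <- make_instance(23, N = 50, G = 10)
  a <- fbcd_solve(inst$shards, inst$groups,
                  solver_config(lambda_rel = 0.3, tol = 1e-11,
                                max_epochs = 5000))
  b <- fbcd_solve(inst$shards, inst$groups,
                  solver_config(lambda_rel = 0.3, tol = 1e-11,
                                max_epochs = 5000,
                                group_order = "shuffled", seed = 99))
  expect_lt(abs(a$objective - b$objective), 1e-8)
  expect_lt(max(abs(a$beta - b$beta)), 1e-5)
})

test_that("degenerate inputs raise informative errors", {
  inst <- make_instance(2)
  empty <- inst$shards
  empty[[1]]$X <- empty[[1]]$X[0, , drop = FALSE]
  empty[[1]]$y <- numeric(0)
  expect_error(fbcd_solve(empty, inst$groups, solver_config()), "empty")
  expect_error(solver_config(lambda_rel = 0), "lambda_rel")
  expect_error(solver_config(tol = -1), "tol")
})
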