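# Small random grouped-regression instances for solver/screening tests.
make_instance <- function(seed, N = 60, G = 8, sizes = NULL, n_sites = 3,
                          nsig = 2, noise = 0.5) {
  set.seed(seed)
  if (is.null(sizes)) sizes <- sample(2:6, G, replace = TRUE)
  G <- length(sizes)
  p <- sum(sizes)
  X <- matrix(rnorm(N * p), N)
  groups <- data.frame(group_id = seq_len(G),
                       start = cumsum(c(1L, sizes[-G])),
                       size = sizes, weight = sqrt(sizes))
  beta <- numeric(p)
  for (g in sample(G, nsig)) {
    r <- groups[g, ]
    beta[r$start + seq_len(r$size) - 1] <- rnorm(r$size)
  }
  y <- as.vector(X %*% beta) + rnorm(N, 0, noise)
  design <- grouped_design(X, y, groups)
  shards <- partition_rows(design, n_sites, seed = seed)
  list(design = design, shards = shards, groups = groups,
       beta_true = beta, X = X, y = y)
}

# A small grid-structured cohort for stability-pipeline tests.
tiny_cohort <- function(seed, n_subjects = 100, rows = 10, cols = 15,
                        n_true = 3, effect = 1, noise = 1, sites = 3,
                        hemispheres = c("left", "right")) {
  generate_cohort(n_subjects = n_subjects, grid_rows = rows, grid_cols = cols,
                  hemispheres = hemispheres, n_true_patches = n_true,
                  effect_scale = effect, noise_sd = noise, smoothness = 0.75,
                  n_sites = sites, seed = seed)
}

# Build a lambda_path shell with a prescribed sparse coefficient matrix,
# for unit-testing the stability counting without running the solver.
fake_path <- function(beta_matrix, lambdas_rel, groups) {
  structure(list(lambdas_rel = lambdas_rel,
                 lambda_max = 1,
                 beta = Matrix::Matrix(beta_matrix, sparse = TRUE),
                 objectives = rep(0, length(lambdas_rel)),
                 kkt_gaps = rep(0, length(lambdas_rel)),
                 retained_counts = rep(nrow(groups), length(lambdas_rel)),
                 retained = rep(list(groups$group_id), length(lambdas_rel)),
                 active_counts = rep(0L, length(lambdas_rel)),
                 n_updates = rep(0, length(lambdas_rel)),
                 n_updates_total = 0,
                 screened = FALSE,
                 groups = groups),
            class = "lambda_path")
}
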