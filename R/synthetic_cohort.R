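# 1-D Gaussian smoothing matrix with symmetric (reflecting) boundaries,
# rows normalized to sum 1.  sigma is the kernel sd in vertex units.
gaussian_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  h <- as.integer(ceiling(3 * sigma))
  W <- matrix(0, n, n)
  i <- seq_len(n)
  for (d in -h:h) {
    wgt <- exp(-d^2 / (2 * sigma^2))
    p <- i + d
    # symmetric reflection with edge duplication
    m <- (p - 1L) %% (2L * n)
    m[m < 0L] <- m[m < 0L] + 2L * n
    j <- ifelse(m < n, m + 1L, 2L * n - m)
    W[cbind(i, j)] <- W[cbind(i, j)] + wgt
  }
  W / rowSums(W)
}

# Smooth an n x (rows*cols) matrix of vectorized fields (row-major vertex
# order, column index fastest) with separable 1-D smoothers.
smooth_fields <- function(M, rows, cols, sigma) {
  if (sigma <= 0) return(M)
  n <- nrow(M)
  Wr <- gaussian_smoother(rows, sigma)
  Wc <- gaussian_smoother(cols, sigma)
  A <- array(M, dim = c(n, cols, rows))          # col index varies fastest
  M1 <- matrix(aperm(A, c(2, 1, 3)), nrow = cols)
  A2 <- array(Wc %*% M1, dim = c(cols, n, rows))
  M2 <- matrix(aperm(A2, c(3, 2, 1)), nrow = rows)
  A3 <- array(Wr %*% M2, dim = c(rows, n, cols))
  matrix(aperm(A3, c(2, 3, 1)), nrow = n)
}

#' Generate a synthetic multi-site morphometry cohort
#'
#' Emulates the structure of registered surface-morphometry data: each
#' subject carries spatially smooth per-vertex fields (one per hemisphere
#' and feature type, Gaussian random fields smoothed with a separable
#' isotropic kernel on the grid, reflecting boundaries), Z-scored within
#' subject per feature type.  A small set of planted patches carries the
#' signal: their RD and TBM groups receive constant coefficients of
#' magnitude `effect_scale / sqrt(p_g)`, and
#' `y = X beta_true + Normal(0, noise_sd^2)` noise.  Subjects are then
#' partitioned across simulated institutions.  One root seed drives
#' independent named streams for field, support, noise, and partition, so
#' identical seeds give bit-identical cohorts.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param grid_rows,grid_cols Grid dimensions per hemisphere (default
#'   100 x 150).
#' @param hemispheres Character vector, subset of `c("left", "right")`.
#' @param patch_rows,patch_cols Patch tiling (default 2 x 3).
#' @param feature_types Feature types per vertex (default RD and TBM).
#' @param n_true_patches Number of planted predictive patch groups (each is
#'   one feature type on one patch).
#' @param effect_scale Signal magnitude; per-coefficient value is
#'   `effect_scale / sqrt(p_g)`.
#' @param noise_sd Standard deviation of the additive response noise.
#' @param smoothness Spatial correlation length (kernel sd, in vertices).
#' @param n_sites Number of simulated institutions.
#' @param seed Root seed.
#' @param layout Optional precomputed [morphometry_layout()] (saves rebuilding
#'   the group tables when many cohorts share one geometry).
#' @return List with `design` ([grouped_design()]), `shards`
#'   (institution list), and `truth` (`synthetic_truth`: `support` group
#'   ids, `beta_true`, planted `patches`, `noise_sd`, `smoothness`,
#'   `seed`).
#' @export
generate_cohort <- function(n_subjects = 200L,
                            grid_rows = 100L, grid_cols = 150L,
                            hemispheres = c("left", "right"),
                            patch_rows = 2L, patch_cols = 3L,
                            feature_types = c("RD", "TBM"),
                            n_true_patches = 10L,
                            effect_scale = 0.15,
                            noise_sd = 1,
                            smoothness = 0.75,
                            n_sites = 5L,
                            seed = 1L,
                            layout = NULL) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(layout)) {
    grids <- lapply(hemispheres, function(h)
      surface_grid(grid_rows, grid_cols, h))
    layout <- morphometry_layout(grids, patch_rows, patch_cols, feature_types)
  } else {
    grids <- layout$grids
    hemispheres <- vapply(grids, function(g) g$hemisphere, character(1))
    feature_types <- unique(layout$feature_index$feature_type)
  }
  groups <- layout$groups
  fi <- layout$feature_index

  if (n_true_patches > nrow(groups))
    stop(sprintf("n_true_patches (%d) exceeds available patch groups (%d)",
                 n_true_patches, nrow(groups)))

  # --- smooth per-vertex fields, stream "field"
  p <- nrow(fi)
  X <- matrix(0, n_subjects, p)
  with_seed(derive_seed(seed, 1L), {
    for (h in hemispheres) {
      g <- grids[[match(h, hemispheres)]]
      for (ft in feature_types) {
        E <- matrix(rnorm(n_subjects * g$rows * g$cols), n_subjects)
        Fm <- smooth_fields(E, g$rows, g$cols, smoothness)
        sel <- fi$hemisphere == h & fi$feature_type == ft
        # Fm columns are in vertex order; map to group-major design columns
        X[, which(sel)] <- Fm[, fi$vertex[sel] + 1L, drop = FALSE]
      }
    }
  })
  X <- zscore_by_subject(X, fi$feature_type)

  # --- planted support, stream "support": each planted patch is one group
  # (one feature type on one 2x3 patch), drawn without replacement
  support <- sort(with_seed(derive_seed(seed, 2L),
                            sample(groups$group_id, n_true_patches)))
  planted <- groups[support, c("hemisphere", "feature_type",
                               "patch_row", "patch_col")]
  rownames(planted) <- NULL
  beta_true <- numeric(p)
  for (g in support) {
    row <- groups[g, ]
    cols <- row$start + seq_len(row$size) - 1L
    beta_true[cols] <- effect_scale / sqrt(row$size)
  }

  # --- response, stream "noise"
  y <- as.vector(X %*% beta_true)
  if (noise_sd > 0)
    y <- y + with_seed(derive_seed(seed, 3L),
                       rnorm(n_subjects, 0, noise_sd))

  design <- grouped_design(X, y, layout)
  shards <- partition_rows(design, n_sites, seed = derive_seed(seed, 4L))
  truth <- structure(list(support = support, beta_true = beta_true,
                          patches = planted, noise_sd = noise_sd,
                          effect_scale = effect_scale,
                          smoothness = smoothness, seed = seed),
                     class = "synthetic_truth")
  list(design = design, shards = shards, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d planted patch groups, effect %.3g, noise sd %.3g, seed %d\n",
    length(x$support), x$effect_scale, x$noise_sd, x$seed))
  invisible(x)
}

#' Write a cohort fixture directory
#'
#' Emits the full file set in the package's text formats: feature matrix
#' (`matrix.tsv` or packed binary `matrix.bin` + `matrix.json` sidecar),
#' group index (`groups.tsv`), response (`response.tsv`), site assignment
#' (`sites.tsv`), and planted truth (`truth.tsv`: group_id, coefficient).
#' The set round-trips through [read_fixture()].
#'
#' @param cohort List from [generate_cohort()].
#' @param directory Output directory (created if needed).
#' @param matrix_format `"tsv"` or `"bin"`.
#' @return The directory, invisibly.
#' @export
write_fixture <- function(cohort, directory, matrix_format = c("tsv", "bin")) {
  matrix_format <- match.arg(matrix_format)
  design <- cohort$design
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE))
    stop(sprintf("cannot create directory '%s'", directory))
  mfile <- file.path(directory,
                     if (matrix_format == "tsv") "matrix.tsv" else "matrix.bin")
  write_feature_matrix(design$X, mfile,
                       feature_ids = design$feature_index$feature_id)
  write_group_index(design, file.path(directory, "groups.tsv"))
  ids <- sprintf("s%04d", seq_len(nrow(design$X)))
  write_response(design$y, ids, file.path(directory, "response.tsv"))
  site_of <- integer(nrow(design$X))
  for (s in cohort$shards) site_of[s$rows] <- s$site_id
  write_sites(site_of, ids, file.path(directory, "sites.tsv"))
  truth <- cohort$truth
  coef_of_group <- vapply(truth$support, function(g) {
    row <- design$groups[g, ]
    truth$beta_true[row$start]
  }, numeric(1))
  data.table::fwrite(data.frame(group_id = truth$support,
                                coefficient = coef_of_group),
                     file.path(directory, "truth.tsv"), sep = "\t")
  invisible(directory)
}

#' Read a cohort fixture directory
#'
#' @param directory Directory written by [write_fixture()] (or assembled in
#'   the same formats).
#' @return List with `design`, `shards`, and (when `truth.tsv` is present)
#'   `truth` (support ids and coefficients).
#' @export
read_fixture <- function(directory) {
  mfile <- file.path(directory, "matrix.tsv")
  if (!file.exists(mfile)) mfile <- file.path(directory, "matrix.bin")
  if (!file.exists(mfile))
    stop(sprintf("no matrix.tsv or matrix.bin under '%s'", directory))
  X <- read_feature_matrix(mfile)
  gi <- read_group_index(file.path(directory, "groups.tsv"))
  resp <- read_response(file.path(directory, "response.tsv"))
  design <- grouped_design(X, resp$value, gi)
  sites <- read_sites(file.path(directory, "sites.tsv"))
  if (nrow(sites) != nrow(X))
    stop("site file rows do not match the feature matrix")
  shards <- lapply(sort(unique(sites$site_id)), function(i) {
    rows <- which(sites$site_id == i)
    structure(list(site_id = as.integer(i),
                   X = design$X[rows, , drop = FALSE],
                   y = design$y[rows], rows = rows),
              class = "institution_shard")
  })
  out <- list(design = design, shards = shards)
  tf <- file.path(directory, "truth.tsv")
  if (file.exists(tf)) {
    tr <- data.table::fread(tf, sep = "\t", data.table = FALSE)
    out$truth <- list(support = tr$group_id, coefficients = tr$coefficient)
  }
  out
}
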