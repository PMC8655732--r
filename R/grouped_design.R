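#' Surface grid descriptor
#'
#' A registered morphometry surface is represented as a regular grid of
#' vertices; every subject's surface carries the same grid, so a vertex index
#' identifies the same anatomical location across subjects.  Vertex indices
#' are 0-based and row-major: vertex `v` sits at grid row `v %/% cols`,
#' column `v %% cols`.
#'
#' @param rows Number of vertices along the first grid axis (default 100).
#' @param cols Number of vertices along the second grid axis (default 150).
#' @param hemisphere `"left"` or `"right"`.
#' @return An object of class `surface_grid`.
#' @export
#' @examples
#' g <- surface_grid()           # the default 100 x 150 hemisphere grid
#' g$rows * g$cols               # 15,000 vertices
surface_grid <- function(rows = 100L, cols = 150L, hemisphere = "left") {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || rows < 1L) stop("grid rows must be >= 1")
  if (is.na(cols) || cols < 1L) stop("grid cols must be >= 1")
  hemisphere <- match.arg(hemisphere, c("left", "right"))
  structure(list(rows = rows, cols = cols, hemisphere = hemisphere),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %s hemisphere, %d x %d (%d vertices)\n",
              x$hemisphere, x$rows, x$cols, x$rows * x$cols))
  invisible(x)
}

#' Tile a surface grid into patch groups
#'
#' Partitions the vertex grid into non-overlapping rectangular patches and
#' builds one feature group per patch and feature type.  All features of one
#' type inside a patch form a group for the group-LASSO penalty, so entire
#' patches enter or leave the model together.  The default group weight is
#' `sqrt(p_g)`, the standard group-LASSO convention that puts groups of
#' different sizes on a comparable penalty scale.
#'
#' @param grid A [surface_grid()].
#' @param patch_rows,patch_cols Patch dimensions (default 2 x 3). The grid
#'   dimensions must be divisible by the patch dimensions.
#' @param feature_types Character vector of per-vertex feature types, e.g.
#'   `c("RD", "TBM")`.
#' @param weight Optional fixed group weight; default `sqrt(p_g)`.
#' @return A data.frame with one row per group: `group_id`, `hemisphere`,
#'   `feature_type`, `patch_row`, `patch_col` (0-based patch coordinates),
#'   `size`, `weight`, and a list column `vertex_ids` of 0-based row-major
#'   member vertex indices (row-major within the patch).  Groups of the same
#'   patch but different feature types share `vertex_ids`.  Group order is
#'   feature-type major, patches row-major within a type.
#' @export
#' @examples
#' pg <- build_patch_groups(surface_grid(), 2, 3, c("RD", "TBM"))
#' nrow(pg)  # 5,000 groups: 2,500 patches per feature type
build_patch_groups <- function(grid, patch_rows = 2L, patch_cols = 3L,
                               feature_types = c("RD", "TBM"),
                               weight = NULL) {
  stopifnot(inherits(grid, "surface_grid"))
  patch_rows <- as.integer(patch_rows); patch_cols <- as.integer(patch_cols)
  if (grid$rows %% patch_rows != 0L)
    stop(sprintf("grid rows (%d) not divisible by patch rows (%d)",
                 grid$rows, patch_rows))
  if (grid$cols %% patch_cols != 0L)
    stop(sprintf("grid cols (%d) not divisible by patch cols (%d)",
                 grid$cols, patch_cols))
  if (length(feature_types) < 1L) stop("need at least one feature type")
  npr <- grid$rows %/% patch_rows
  npc <- grid$cols %/% patch_cols
  n_patch <- npr * npc
  p_g <- patch_rows * patch_cols

  # vertex ids of patch (pr, pc), row-major within the patch, 0-based
  patch_vertices <- function(pr, pc) {
    out <- integer(p_g)
    k <- 1L
    for (dr in 0:(patch_rows - 1L)) for (dc in 0:(patch_cols - 1L)) {
      out[k] <- (pr * patch_rows + dr) * grid$cols + (pc * patch_cols + dc)
      k <- k + 1L
    }
    out
  }
  pr <- rep(seq_len(npr) - 1L, each = npc)
  pc <- rep(seq_len(npc) - 1L, times = npr)
  vids <- mapply(patch_vertices, pr, pc, SIMPLIFY = FALSE)

  out <- data.frame(
    group_id = seq_len(n_patch * length(feature_types)),
    hemisphere = grid$hemisphere,
    feature_type = rep(feature_types, each = n_patch),
    patch_row = rep(pr, times = length(feature_types)),
    patch_col = rep(pc, times = length(feature_types)),
    size = p_g,
    weight = if (is.null(weight)) sqrt(p_g) else weight,
    stringsAsFactors = FALSE
  )
  out$vertex_ids <- rep(vids, times = length(feature_types))
  out
}

#' Build the full grouped feature layout over one or two hemispheres
#'
#' Enumerates patch groups over a list of surface grids and fixes the column
#' layout of the feature matrix: columns are group-major (all columns of
#' group 1, then group 2, ...), vertices row-major within each patch.  This
#' is the documented export convention for all file formats in the package.
#'
#' @param grids List of [surface_grid()] objects (typically left and right).
#' @param patch_rows,patch_cols,feature_types,weight As in
#'   [build_patch_groups()].
#' @return A list with `groups` (data.frame with `group_id`, `start` 1-based
#'   first column, `size`, `weight`, patch metadata) and `feature_index`
#'   (data.frame mapping each feature column to `feature_id`, `group_id`,
#'   `hemisphere`, `row`, `col`, `vertex`, `feature_type`, `weight`).
#' @export
morphometry_layout <- function(grids, patch_rows = 2L, patch_cols = 3L,
                               feature_types = c("RD", "TBM"),
                               weight = NULL) {
  if (inherits(grids, "surface_grid")) grids <- list(grids)
  gl <- lapply(grids, build_patch_groups, patch_rows = patch_rows,
               patch_cols = patch_cols, feature_types = feature_types,
               weight = weight)
  groups <- do.call(rbind, gl)
  groups$group_id <- seq_len(nrow(groups))
  groups$start <- cumsum(c(1L, groups$size[-nrow(groups)]))

  ncol_total <- sum(groups$size)
  col_hemi <- rep(groups$hemisphere, groups$size)
  col_type <- rep(groups$feature_type, groups$size)
  col_gid <- rep(groups$group_id, groups$size)
  col_w <- rep(groups$weight, groups$size)
  col_vertex <- unlist(groups$vertex_ids, use.names = FALSE)
  cols_by_hemi <- vapply(grids, function(g) g$cols, integer(1))
  names(cols_by_hemi) <- vapply(grids, function(g) g$hemisphere, character(1))
  col_row <- col_vertex %/% cols_by_hemi[col_hemi]
  col_col <- col_vertex %% cols_by_hemi[col_hemi]
  feature_index <- data.frame(
    column = seq_len(ncol_total),
    feature_id = sprintf("%s_%s_r%03d_c%03d",
                         substr(col_hemi, 1, 1), col_type, col_row, col_col),
    group_id = col_gid,
    hemisphere = col_hemi,
    row = as.integer(col_row),
    col = as.integer(col_col),
    vertex = col_vertex,
    feature_type = col_type,
    weight = col_w,
    stringsAsFactors = FALSE
  )
  list(groups = groups, feature_index = feature_index, grids = grids)
}

#' Grouped design container
#'
#' Bundles the feature matrix, response, and the group structure.  Groups
#' must exactly partition the columns into contiguous blocks (group-major
#' column layout).
#'
#' @param X Numeric matrix, subjects x features; all entries finite.
#' @param y Numeric response vector of length `nrow(X)`.
#' @param groups Data.frame with columns `group_id` (1..G), `start` (1-based
#'   first column), `size`, `weight` (> 0); or the list returned by
#'   [morphometry_layout()], in which case `feature_index` and `grids` are
#'   taken from it.
#' @param feature_index Optional data.frame mapping columns to grid
#'   locations (see [morphometry_layout()]).
#' @param grids Optional list of [surface_grid()]s behind the layout.
#' @return An object of class `grouped_design`.
#' @export
grouped_design <- function(X, y, groups, feature_index = NULL, grids = NULL) {
  if (is.list(groups) && !is.data.frame(groups) && !is.null(groups$groups)) {
    feature_index <- feature_index %||% groups$feature_index
    grids <- grids %||% groups$grids
    groups <- groups$groups
  }
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (!is.numeric(X)) stop("X must be numeric")
  if (nrow(X) < 1L) stop("X must have at least one subject row")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  if (!all(is.finite(y))) stop("y contains non-finite entries")
  req <- c("group_id", "start", "size", "weight")
  if (!all(req %in% names(groups)))
    stop("groups must have columns: ", paste(req, collapse = ", "))
  groups <- groups[order(groups$group_id), , drop = FALSE]
  if (!identical(as.integer(groups$group_id), seq_len(nrow(groups))))
    stop("group_id must be 1..G")
  expected_start <- cumsum(c(1L, groups$size[-nrow(groups)]))
  if (!identical(as.integer(groups$start), as.integer(expected_start)))
    stop("groups must be contiguous column blocks in group_id order")
  if (sum(groups$size) != ncol(X))
    stop(sprintf("groups cover %d columns but X has %d",
                 sum(groups$size), ncol(X)))
  if (any(groups$weight <= 0)) stop("group weights must be > 0")
  structure(list(X = X, y = y, groups = groups,
                 feature_index = feature_index, grids = grids),
            class = "grouped_design")
}

#' @export
print.grouped_design <- function(x, ...) {
  cat(sprintf("<grouped_design> %d subjects x %d features in %d groups\n",
              nrow(x$X), ncol(x$X), nrow(x$groups)))
  if (!is.null(x$grids))
    for (g in x$grids)
      cat(sprintf("  grid: %s %d x %d\n", g$hemisphere, g$rows, g$cols))
  invisible(x)
}

# per-column group id vector (length p)
group_ids_per_column <- function(groups) {
  rep.int(groups$group_id, groups$size)
}

#' Z-score features within each subject
#'
#' Standardizes each subject's row separately over each feature type so that
#' the two morphometry measures live on a common scale: within a row, the
#' values of one type get mean 0 and sample standard deviation 1 (n-1
#' divisor).  A row block with zero variance is set to all zeros with a
#' warning.
#'
#' @param X Numeric subjects x features matrix.
#' @param feature_type_mask Character vector of length `ncol(X)` labelling
#'   each column's feature type.
#' @return Matrix of the same shape.
#' @export
#' @examples
#' zscore_by_subject(matrix(c(1, 2, 3), 1), rep("RD", 3))  # -1 0 1
zscore_by_subject <- function(X, feature_type_mask) {
  X <- as.matrix(X)
  if (length(feature_type_mask) != ncol(X))
    stop("feature_type_mask must have one label per column")
  if (!all(is.finite(X))) stop("X contains non-finite entries")
  out <- X
  n_degenerate <- 0L
  for (ft in unique(feature_type_mask)) {
    idx <- which(feature_type_mask == ft)
    if (length(idx) < 2L)
      stop(sprintf("feature type '%s' has fewer than 2 columns", ft))
    B <- X[, idx, drop = FALSE]
    m <- rowMeans(B)
    ss <- rowSums(B * B) - length(idx) * m * m
    s <- sqrt(pmax(ss, 0) / (length(idx) - 1L))
    zero <- s < 1e-12
    s[zero] <- 1
    out[, idx] <- (B - m) / s
    if (any(zero)) {
      out[zero, idx] <- 0
      n_degenerate <- n_degenerate + sum(zero)
    }
  }
  if (n_degenerate > 0L)
    warning(sprintf("%d subject/type blocks had zero variance; set to zeros",
                    n_degenerate))
  out
}

#' Partition subjects across institutions
#'
#' Randomly assigns subject rows to `n_sites` disjoint shards whose sizes
#' differ by at most one, reproducibly for a fixed seed.  Each shard plays
#' the role of one institution's private data in the federated solver.
#'
#' @param design A [grouped_design()].
#' @param n_sites Number of institutions, `1 <= n_sites <= N`.
#' @param seed Integer seed for the assignment permutation.
#' @return List of `institution_shard` objects, each with `site_id`, `X`,
#'   `y`, and `rows` (the original row indices).
#' @export
partition_rows <- function(design, n_sites, seed = 1L) {
  stopifnot(inherits(design, "grouped_design"))
  n_sites <- as.integer(n_sites)
  N <- nrow(design$X)
  if (is.na(n_sites) || n_sites < 1L) stop("n_sites must be >= 1")
  if (n_sites > N)
    stop(sprintf("n_sites (%d) exceeds number of subjects (%d)", n_sites, N))
  perm <- with_seed(seed, sample.int(N))
  base <- N %/% n_sites
  sizes <- base + as.integer(seq_len(n_sites) <= N %% n_sites)
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_len(n_sites), function(i) {
    rows <- sort(perm[starts[i]:ends[i]])
    structure(list(site_id = i,
                   X = design$X[rows, , drop = FALSE],
                   y = design$y[rows],
                   rows = rows),
              class = "institution_shard")
  })
}

#' @export
print.institution_shard <- function(x, ...) {
  cat(sprintf("<institution_shard> site %d: %d subjects x %d features\n",
              x$site_id, nrow(x$X), ncol(x$X)))
  invisible(x)
}

# validate a shard list against a group table; returns ncol
check_shards <- function(shards, groups) {
  if (length(shards) < 1L) stop("need at least one shard")
  p <- sum(groups$size)
  for (s in shards) {
    if (!inherits(s, "institution_shard")) stop("shards must be institution_shard objects")
    if (nrow(s$X) < 1L) stop(sprintf("shard %d is empty", s$site_id))
    if (ncol(s$X) != p)
      stop(sprintf("shard %d has %d columns but groups cover %d",
                   s$site_id, ncol(s$X), p))
    if (length(s$y) != nrow(s$X)) stop(sprintf("shard %d: y length mismatch", s$site_id))
  }
  invisible(p)
}

#' Treat a full design as a single institution
#'
#' @param design A [grouped_design()].
#' @return A one-element shard list (the centralized special case).
#' @export
as_single_shard <- function(design) {
  list(structure(list(site_id = 1L, X = design$X, y = design$y,
                      rows = seq_len(nrow(design$X))),
                 class = "institution_shard"))
}
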