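#' Stability-selection frequency map over the surface grid
#'
#' Counts, for every vertex, the number of (lambda, feature type) pairs
#' whose coefficient is nonzero along the solved path (coefficients with
#' absolute value below `1e-12` count as zero), and normalizes the count to
#' the 0-100 scale: `100 * raw / (2 kappa)` when RD and TBM counts are
#' summed (the default), `100 * raw / kappa` when merged by maximum.
#'
#' @param path A `lambda_path` from [solve_path()].
#' @param design The [grouped_design()] the path was solved on (its feature
#'   index maps columns to vertices).
#' @param merge `"sum"` (count RD and TBM selections on a vertex together)
#'   or `"max"`.
#' @param zero_tol Magnitude below which a coefficient counts as zero.
#' @return A `frequency_map`: `grids`, per-hemisphere `raw` and
#'   `normalized` matrices (rows x cols), `smoothed = NULL` until
#'   [smooth_map()] is applied, `kappa`, and the design's feature index.
#' @export
count_selection <- function(path, design, merge = c("sum", "max"),
                            zero_tol = 1e-12) {
  merge <- match.arg(merge)
  stopifnot(inherits(path, "lambda_path"), inherits(design, "grouped_design"))
  if (is.null(design$feature_index) || is.null(design$grids))
    stop("design carries no grid feature index")
  kappa <- length(path$lambdas_rel)
  if (kappa < 1L) stop("empty path")
  if (nrow(path$beta) != ncol(design$X))
    stop("path was not solved on this design")
  fi <- design$feature_index
  nz_per_col <- Matrix::rowSums(abs(path$beta) > zero_tol)

  types <- unique(fi$feature_type)
  denom <- if (merge == "sum") length(types) * kappa else kappa
  raw <- list(); normalized <- list()
  for (h in vapply(design$grids, function(g) g$hemisphere, character(1))) {
    g <- design$grids[[match(h, vapply(design$grids, function(x) x$hemisphere,
                                       character(1)))]]
    counts_by_type <- vapply(types, function(ft) {
      sel <- fi$hemisphere == h & fi$feature_type == ft
      out <- numeric(g$rows * g$cols)
      out[fi$vertex[sel] + 1L] <- nz_per_col[sel]
      out
    }, numeric(g$rows * g$cols))
    v <- if (merge == "sum") rowSums(counts_by_type) else
      apply(counts_by_type, 1, max)
    raw[[h]] <- matrix(v, g$rows, g$cols, byrow = TRUE)
    normalized[[h]] <- 100 * raw[[h]] / denom
  }
  structure(list(grids = design$grids, raw = raw, normalized = normalized,
                 smoothed = NULL, kappa = kappa, merge = merge,
                 feature_index = fi),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  cat(sprintf("<frequency_map> kappa = %d, merge = %s%s\n", x$kappa, x$merge,
              if (is.null(x$smoothed)) "" else ", smoothed"))
  for (h in names(x$normalized))
    cat(sprintf("  %s: max normalized %.1f\n", h, max(x$normalized[[h]])))
  invisible(x)
}

#' Smooth a frequency map with a small averaging filter
#'
#' Each vertex's smoothed value is the mean of the normalized values inside
#' a `filter_rows x filter_cols` window anchored at the vertex: window rows
#' extend forward from the vertex row (`r .. r + filter_rows - 1`), window
#' columns are centred on the vertex column.  Windows are clipped at grid
#' boundaries and the mean is taken over the surviving cells, so the output
#' stays within [0, 100].
#'
#' @param map A `frequency_map` (normalized).
#' @param filter_rows,filter_cols Window size (default 2 x 3).
#' @return The map with `smoothed` filled in.
#' @export
smooth_map <- function(map, filter_rows = 2L, filter_cols = 3L) {
  stopifnot(inherits(map, "frequency_map"))
  filter_rows <- as.integer(filter_rows); filter_cols <- as.integer(filter_cols)
  dr <- 0:(filter_rows - 1L)
  dc <- seq_len(filter_cols) - 1L - (filter_cols - 1L) %/% 2L
  map$smoothed <- lapply(map$normalized, function(M) {
    R <- nrow(M); C <- ncol(M)
    if (filter_rows > R || filter_cols > C)
      stop(sprintf("filter (%d x %d) larger than grid (%d x %d)",
                   filter_rows, filter_cols, R, C))
    S <- matrix(0, R, C)
    Cnt <- matrix(0, R, C)
    for (a in dr) for (b in dc) {
      rs <- max(1L, 1L - a):min(R, R - a)      # rows whose r + a is in range
      cs <- max(1L, 1L - b):min(C, C - b)
      S[rs, cs] <- S[rs, cs] + M[rs + a, cs + b]
      Cnt[rs, cs] <- Cnt[rs, cs] + 1
    }
    S / Cnt
  })
  map
}

#' Rank vertices and select the top-k ROI features
#'
#' Vertices are sorted by smoothed frequency, descending, ties broken by
#' ascending global vertex order (hemisphere order as listed in the map,
#' row-major within a hemisphere), which makes the selection deterministic.
#' The selected features are the RD and TBM columns of the top `top_k`
#' vertices.
#'
#' @param map A smoothed `frequency_map`.
#' @param top_k Number of vertices to keep (`1 <= top_k <=` vertex count).
#' @return An `roi_selection`: `ranked_vertices` (data.frame with
#'   `hemisphere`, `row`, `col`, `vertex`, `value` in rank order), `top_k`,
#'   `selected_features` (integer design columns, `2 * top_k` of them), and
#'   `feature_ids`.
#' @export
rank_and_select <- function(map, top_k) {
  stopifnot(inherits(map, "frequency_map"))
  if (is.null(map$smoothed)) stop("map must be smoothed first (smooth_map)")
  hemis <- names(map$smoothed)
  tabs <- lapply(hemis, function(h) {
    M <- map$smoothed[[h]]
    g <- map$grids[[match(h, vapply(map$grids, function(x) x$hemisphere,
                                    character(1)))]]
    data.frame(hemisphere = h,
               row = rep(0:(g$rows - 1L), each = g$cols),
               col = rep(0:(g$cols - 1L), times = g$rows),
               vertex = 0:(g$rows * g$cols - 1L),
               value = as.vector(t(M)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  n_vertex <- nrow(tab)
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L || top_k > n_vertex)
    stop(sprintf("top_k must be in 1..%d", n_vertex))
  ord <- order(-tab$value, seq_len(n_vertex))
  ranked <- tab[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  keep <- ranked[seq_len(top_k), , drop = FALSE]
  fi <- map$feature_index
  types <- unique(fi$feature_type)
  # per-type column lookup, then interleave so each vertex contributes one
  # column per feature type, in rank order
  per_type <- lapply(types, function(ft) {
    sel <- fi$feature_type == ft
    match(paste(keep$hemisphere, keep$vertex),
          paste(fi$hemisphere[sel], fi$vertex[sel]))
  })
  cols_mat <- vapply(seq_along(types), function(t)
    fi$column[fi$feature_type == types[t]][per_type[[t]]], integer(top_k))
  cols_mat <- matrix(cols_mat, nrow = top_k)
  sel_cols <- as.integer(t(cols_mat))
  sel_ids <- fi$feature_id[sel_cols]
  structure(list(ranked_vertices = ranked, top_k = top_k,
                 selected_features = sel_cols, feature_ids = sel_ids),
            class = "roi_selection")
}

#' @export
print.roi_selection <- function(x, ...) {
  cat(sprintf("<roi_selection> top %d vertices -> %d features\n",
              x$top_k, length(x$selected_features)))
  invisible(x)
}

#' Frequency-weighted ROI scalar per subject
#'
#' For each subject, the selected vertices' RD values are weighted by the
#' smoothed selection frequency and summed (`s_RD`), likewise for TBM
#' (`s_TBM`); the two-column table over subjects is then reduced to its
#' first principal component score.  The component sign is fixed so that
#' the `s_RD` loading is non-negative.
#'
#' @param design The [grouped_design()].
#' @param map The smoothed `frequency_map` used for the weights.
#' @param selection An [rank_and_select()] result.
#' @return Data.frame with `s_rd`, `s_tbm`, and `score` (PC1) per subject.
#' @export
roi_scalar <- function(design, map, selection) {
  stopifnot(inherits(selection, "roi_selection"))
  if (is.null(map$smoothed)) stop("map must be smoothed first")
  if (length(selection$selected_features) == 0L) stop("empty selection")
  fi <- map$feature_index
  keep <- selection$ranked_vertices[seq_len(selection$top_k), , drop = FALSE]
  wts <- keep$value
  sums <- list()
  for (ft in unique(fi$feature_type)) {
    sel <- fi$feature_type == ft
    idx <- match(paste(keep$hemisphere, keep$vertex),
                 paste(fi$hemisphere[sel], fi$vertex[sel]))
    cols <- fi$column[sel][idx]
    sums[[ft]] <- as.vector(design$X[, cols, drop = FALSE] %*% wts)
  }
  tab <- data.frame(s_rd = sums[[1]], s_tbm = sums[[2]])
  if (sd(tab$s_rd) < 1e-300 || sd(tab$s_tbm) < 1e-300)
    stop("degenerate PCA: an ROI summary column has zero variance")
  pc <- prcomp(tab, center = TRUE, scale. = TRUE)
  score <- pc$x[, 1]
  if (pc$rotation[1, 1] < 0) score <- -score
  tab$score <- as.numeric(score)
  tab
}

#' Mean stability frequency per patch
#'
#' Averages the normalized (unsmoothed) frequency over the vertices of each
#' patch, giving a patch-level ranking used in recovery checks.
#'
#' @param map A `frequency_map`.
#' @param design The design whose groups define the patches.
#' @return Data.frame with `hemisphere`, `patch_row`, `patch_col`,
#'   `frequency`, sorted descending.
#' @export
patch_frequency <- function(map, design) {
  groups <- design$groups
  if (is.null(groups$vertex_ids))
    stop("design groups carry no patch vertex lists")
  sub <- groups[groups$feature_type == groups$feature_type[1], , drop = FALSE]
  vecs <- lapply(map$normalized, function(M) as.vector(t(M)))
  freq <- vapply(seq_len(nrow(sub)), function(i)
    mean(vecs[[sub$hemisphere[i]]][sub$vertex_ids[[i]] + 1L]),
    numeric(1))
  out <- data.frame(hemisphere = sub$hemisphere, patch_row = sub$patch_row,
                    patch_col = sub$patch_col, frequency = freq,
                    stringsAsFactors = FALSE)
  out[order(-out$frequency), ]
}

#' Export a frequency map
#'
#' `"tsv"` writes one line per vertex (`hemisphere`, `row`, `col`,
#' `value`); `"ply"` writes one ASCII PLY mesh per hemisphere with the grid
#' triangulated regularly (two triangles per grid cell) and the smoothed
#' value as a per-vertex `quality` property.  Values are written with 9
#' significant digits, so text round-trips are faithful well past 1e-6.
#'
#' @param map A smoothed `frequency_map`.
#' @param path Output path; for `"ply"` with two hemispheres the hemisphere
#'   name is inserted before the extension.
#' @param format `"tsv"` or `"ply"`.
#' @return Character vector of the files written, invisibly.
#' @export
export_map <- function(map, path, format = c("tsv", "ply")) {
  if (!is.character(format) || !all(format %in% c("tsv", "ply")))
    stop(sprintf("unknown export format '%s'", paste(format, collapse = ",")))
  format <- match.arg(format)
  if (is.null(map$smoothed)) stop("map must be smoothed first")
  hemis <- names(map$smoothed)
  if (format == "tsv") {
    rowsl <- lapply(hemis, function(h) {
      M <- map$smoothed[[h]]
      data.frame(hemisphere = h,
                 row = rep(0:(nrow(M) - 1L), each = ncol(M)),
                 col = rep(0:(ncol(M) - 1L), times = nrow(M)),
                 value = sprintf("%.9g", as.vector(t(M))),
                 stringsAsFactors = FALSE)
    })
    data.table::fwrite(do.call(rbind, rowsl), path, sep = "\t")
    return(invisible(path))
  }
  files <- character(0)
  for (h in hemis) {
    M <- map$smoothed[[h]]
    R <- nrow(M); C <- ncol(M)
    f <- if (length(hemis) == 1L) path else
      sprintf("%s_%s.ply", sub("\\.ply$", "", path), h)
    vals <- as.vector(t(M))  # row-major vertex order
    vx <- rep(0:(C - 1L), times = R)
    vy <- rep(0:(R - 1L), each = C)
    header <- c("ply", "format ascii 1.0",
                sprintf("comment %s hemisphere stability frequency", h),
                sprintf("element vertex %d", R * C),
                "property float x", "property float y", "property float z",
                "property float quality",
                sprintf("element face %d", 2L * (R - 1L) * (C - 1L)),
                "property list uchar int vertex_indices", "end_header")
    vtx <- sprintf("%d %d 0 %.9g", vx, vy, vals)
    # two triangles per grid cell; vertex v(r,c) = r*C + c
    r0 <- rep(0:(R - 2L), each = C - 1L)
    c0 <- rep(0:(C - 2L), times = R - 1L)
    a <- r0 * C + c0; b <- a + 1L; d <- a + C; e <- d + 1L
    faces <- c(sprintf("3 %d %d %d", a, b, e),
               sprintf("3 %d %d %d", a, e, d))
    writeLines(c(header, vtx, faces), f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read back a TSV frequency-map export
#'
#' @param path File written by [export_map()] with `format = "tsv"`.
#' @return Data.frame with `hemisphere`, `row`, `col`, `value`.
#' @export
read_map_tsv <- function(path) {
  df <- read_checked_tsv(path, 4L, "frequency map")
  df$value <- as.numeric(df$value)
  df
}
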