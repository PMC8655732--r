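# A 2x3-patch single-hemisphere layout used to exercise the counting rules.
stab_layout <- function(rows = 4, cols = 6) {
  morphometry_layout(list(surface_grid(rows, cols, "left")))
}

stab_design <- function(rows = 4, cols = 6, n = 5, seed = 1) {
  lay <- stab_layout(rows, cols)
  set.seed(seed)
  p <- nrow(lay$feature_index)
  grouped_design(matrix(rnorm(n * p), n), rnorm(n), lay)
}

test_that("selection counts normalize to the 0-100 scale", {
  d <- stab_design()
  p <- ncol(d$X)
  kappa <- 4
  B <- matrix(0, p, kappa)
  # all-zero path -> all zeros
  m0 <- count_selection(fake_path(B, seq(1, 0.4, length.out = kappa),
                                  d$groups), d)
  expect_true(all(m0$normalized$left == 0))

  # vertex 0: RD nonzero at 3 lambdas, TBM at 1 -> 100 * 4 / 8 = 50
  fi <- d$feature_index
  rd0 <- fi$column[fi$vertex == 0 & fi$feature_type == "RD"]
  tbm0 <- fi$column[fi$vertex == 0 & fi$feature_type == "TBM"]
  B[rd0, 1:3] <- 1; B[tbm0, 2] <- -0.5
  # vertex 7: both types at every lambda -> 100
  rd7 <- fi$column[fi$vertex == 7 & fi$feature_type == "RD"]
  tbm7 <- fi$column[fi$vertex == 7 & fi$feature_type == "TBM"]
  B[c(rd7, tbm7), ] <- 2
  m <- count_selection(fake_path(B, seq(1, 0.4, length.out = kappa),
                                 d$groups), d)
  expect_equal(m$normalized$left[1, 1], 50)
  expect_equal(m$normalized$left[2, 2], 100)   # vertex 7 = row 1, col 1 (0-based)
  expect_equal(m$raw$left[1, 1], 4)
  # merge = "max" counts the dominating type against kappa
  mx <- count_selection(fake_path(B, seq(1, 0.4, length.out = kappa),
                                  d$groups), d, merge = "max")
  expect_equal(mx$normalized$left[1, 1], 75)   # max(3, 1) / 4
  # numerical dust below the threshold is not counted
  B2 <- matrix(0, p, kappa); B2[rd0, 1] <- 1e-14
  m2 <- count_selection(fake_path(B2, seq(1, 0.4, length.out = kappa),
                                  d$groups), d)
  expect_true(all(m2$raw$left == 0))
})

test_that("map smoothing averages a clipped window anchored at the vertex", {
  d <- stab_design(6, 9)
  kappa <- 2
  B <- matrix(0, ncol(d$X), kappa)
  m <- count_selection(fake_path(B, c(1, 0.5), d$groups), d)

  # constant map is unchanged
  m$normalized$left[] <- 42
  sm <- smooth_map(m)
  expect_true(all(abs(sm$smoothed$left - 42) < 1e-12))

  # a single interior spike spreads as 100/6 over the windows that cover it
  m$normalized$left[] <- 0
  m$normalized$left[4, 5] <- 100   # vertex (row 3, col 4), 0-based
  sm <- smooth_map(m)
  covered <- sm$smoothed$left > 0
  expect_equal(sum(covered), 6)    # r in {2,3}, c in {3,4,5} (0-based)
  expect_true(all(abs(sm$smoothed$left[covered] - 100 / 6) < 1e-12))
  expect_equal(sm$smoothed$left[4, 5], 100 / 6)

  # bottom-right corner: window clips to 1x2 cells
  m$normalized$left[] <- 0
  m$normalized$left[6, 9] <- 60
  m$normalized$left[6, 8] <- 30
  sm <- smooth_map(m)
  expect_equal(sm$smoothed$left[6, 9], mean(c(60, 30)))

  expect_error(smooth_map(m, filter_rows = 7), "larger than grid")
})

test_that("vertex ranking is deterministic with row-major tie-breaking", {
  d <- stab_design(4, 6)
  B <- matrix(0, ncol(d$X), 2)
  m <- smooth_map(count_selection(fake_path(B, c(1, 0.5), d$groups), d))
  m$smoothed$left[] <- 0
  m$smoothed$left[1, 2] <- 5   # vertex 1
  m$smoothed$left[2, 1] <- 5   # vertex 6: same value, higher row-major index
  sel <- rank_and_select(m, 3)
  expect_equal(sel$ranked_vertices$vertex[1:2], c(1L, 6L))
  expect_length(sel$selected_features, 6)      # one RD + one TBM per vertex

  # top_k = vertex count selects every feature
  all_sel <- rank_and_select(m, 24)
  expect_equal(sort(all_sel$selected_features), seq_len(ncol(d$X)))
  expect_error(rank_and_select(m, 0), "top_k")
  expect_error(rank_and_select(m, 25), "top_k")
})

test_that("the ROI scalar weights features by frequency and reduces by PCA", {
  d <- stab_design(2, 3, n = 4, seed = 9)   # single patch, 6 vertices
  B <- matrix(0, ncol(d$X), 2)
  m <- smooth_map(count_selection(fake_path(B, c(1, 0.5), d$groups), d))
  m$smoothed$left[] <- 0
  m$smoothed$left[1, 1] <- 50
  m$smoothed$left[1, 2] <- 100
  sel <- rank_and_select(m, 2)
  expect_equal(sel$ranked_vertices$vertex[1:2], c(1L, 0L))  # 100 before 50

  fi <- d$feature_index
  X <- d$X
  rd <- fi$column[fi$feature_type == "RD"]
  tbm <- fi$column[fi$feature_type == "TBM"]
  # subject 1: RD (1, 2) and TBM (0, 1) on vertices (0, 1)
  X[1, rd[fi$vertex[rd] %in% c(0, 1)]] <- c(1, 2)
  X[1, tbm[fi$vertex[tbm] %in% c(0, 1)]] <- c(0, 1)
  d2 <- grouped_design(X, d$y, list(groups = d$groups, feature_index = fi,
                                    grids = d$grids))
  sc <- roi_scalar(d2, m, sel)
  expect_equal(sc$s_rd[1], 50 * 1 + 100 * 2)
  expect_equal(sc$s_tbm[1], 50 * 0 + 100 * 1)

  # rank-1 case: PC1 score proportional to either column, positive on RD
  X2 <- d$X
  X2[, rd[1]] <- 2 * X2[, tbm[1]]
  d3 <- grouped_design(X2, d$y, list(groups = d$groups, feature_index = fi,
                                     grids = d$grids))
  m1 <- m; m1$smoothed$left[] <- 0; m1$smoothed$left[1, 1] <- 80
  sel1 <- rank_and_select(m1, 1)
  sc1 <- roi_scalar(d3, m1, sel1)
  expect_equal(abs(cor(sc1$score, sc1$s_rd)), 1, tolerance = 1e-12)
  expect_gt(cor(sc1$score, sc1$s_rd), 0)

  # zero-variance column -> degenerate PCA error
  X3 <- d$X; X3[, rd] <- 1
  d4 <- grouped_design(X3, d$y, list(groups = d$groups, feature_index = fi,
                                     grids = d$grids))
  expect_error(roi_scalar(d4, m1, sel1), "zero variance")
})

test_that("frequency maps stay in bounds and are reproducible end to end", {
  co <- tiny_cohort(71, n_subjects = 60, n_true = 2, effect = 1)
  pth <- solve_path(co$shards, co$design$groups, lambda_grid(1, 0.2, 6),
                    solver_config(tol = 1e-9))
  m <- smooth_map(count_selection(pth, co$design))
  for (h in names(m$normalized)) {
    expect_true(all(m$normalized[[h]] >= 0 & m$normalized[[h]] <= 100))
    expect_true(all(m$smoothed[[h]] >= 0 & m$smoothed[[h]] <= 100))
  }
  m2 <- smooth_map(count_selection(pth, co$design))
  expect_identical(m$smoothed, m2$smoothed)
  sel <- rank_and_select(m, 10)
  sel2 <- rank_and_select(m2, 10)
  expect_identical(sel$selected_features, sel2$selected_features)
})

test_that("permuting the response collapses support-vertex frequencies", {
  support_freq <- function(design, shards, support, grid) {
    pth <- solve_path(shards, design$groups, grid, solver_config(tol = 1e-8))
    m <- count_selection(pth, design)
    vec <- as.vector(t(m$normalized$left))
    vids <- unique(unlist(design$groups$vertex_ids[support]))
    mean(vec[vids + 1])
  }
  signal <- numeric(5); null <- numeric(5)
  grid <- lambda_grid(1, 0.3, 8)
  for (s in 1:5) {
    co <- tiny_cohort(500 + s, n_subjects = 120, n_true = 2, effect = 1.5,
                      hemispheres = "left")
    signal[s] <- support_freq(co$design, co$shards, co$truth$support, grid)
    set.seed(900 + s)
    dperm <- grouped_design(co$design$X, sample(co$design$y),
                            list(groups = co$design$groups,
                                 feature_index = co$design$feature_index,
                                 grids = co$design$grids))
    null[s] <- support_freq(dperm, partition_rows(dperm, 3, seed = s),
                            co$truth$support, grid)
  }
  expect_gt(mean(signal), mean(null) * 1.25)
})

test_that("map exports round-trip and triangulate the grid", {
  co <- tiny_cohort(81, n_subjects = 40, rows = 6, cols = 9)
  pth <- solve_path(co$shards, co$design$groups, lambda_grid(1, 0.3, 4),
                    solver_config(tol = 1e-8))
  m <- smooth_map(count_selection(pth, co$design))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_map(m, tsv, "tsv")
  back <- read_map_tsv(tsv)
  expect_equal(nrow(back), 2 * 6 * 9)
  left <- back[back$hemisphere == "left", ]
  expect_equal(matrix(left$value[order(left$row * 9 + left$col)], 6, 9,
                      byrow = TRUE),
               m$smoothed$left, tolerance = 1e-6)

  ply <- file.path(withr::local_tempdir(), "map.ply")
  files <- export_map(m, ply, "ply")
  expect_length(files, 2)
  lines <- readLines(files[1])
  expect_equal(lines[grep("element vertex", lines)], "element vertex 54")
  expect_equal(lines[grep("element face", lines)],
               sprintf("element face %d", 2 * 5 * 8))
  idx_end <- which(lines == "end_header")
  n_face_lines <- length(lines) - idx_end - 54   # lines after the vertices
  expect_equal(n_face_lines, 2 * 5 * 8)

  expect_error(export_map(m, tsv, "vtk"), "format")
})

test_that("a single standard hemisphere exports 15,000 PLY vertices", {
  lay <- morphometry_layout(list(surface_grid(100, 150, "left")))
  M <- matrix(0, 100, 150)
  map <- structure(list(grids = lay$grids, raw = list(left = M),
                        normalized = list(left = M),
                        smoothed = list(left = M), kappa = 1L,
                        merge = "sum", feature_index = lay$feature_index),
                   class = "frequency_map")
  f <- file.path(withr::local_tempdir(), "hemi.ply")
  export_map(map, f, "ply")
  lines <- readLines(f, n = 12)
  expect_true("element vertex 15000" %in% lines)
  expect_true(sprintf("element face %d", 2 * 99 * 149) %in% lines)
})
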