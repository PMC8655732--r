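# File dialects
# --------------
# matrix.tsv   : subjects x features, tab separated, header row of feature ids
# matrix.bin   : packed little-endian float64, row-major (subject rows
#                contiguous), with a JSON sidecar <file>.json holding
#                {rows, cols, dtype, order, byte_order, feature_ids}
# groups.tsv   : feature_id, group_id, hemisphere, row, col, feature_type,
#                weight -- one line per feature column, in column order
# response.tsv : subject_id, value
# sites.tsv    : subject_id, site_id
# Vertex indices are 0-based row-major on a rows x cols grid; columns are
# group-major (all columns of group 1 first), vertices row-major within a
# patch.

# line-wise field-count validation for the small TSVs; returns data.frame
read_checked_tsv <- function(path, expected_cols, what) {
  if (!file.exists(path)) stop(sprintf("%s file '%s' not found", what, path))
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop(sprintf("parse error in %s file '%s': no data rows", what, path))
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != nf[1])
  if (length(bad) > 0L)
    stop(sprintf("parse error in %s file '%s' at line %d: expected %d fields, found %d",
                 what, path, bad[1], nf[1], nf[bad[1]]))
  if (nf[1] != expected_cols)
    stop(sprintf("parse error in %s file '%s': expected %d columns, found %d",
                 what, path, expected_cols, nf[1]))
  data.table::fread(path, sep = "\t", data.table = FALSE)
}

#' Write a feature matrix
#'
#' Delimited text (`.tsv`, header row of feature ids) or documented packed
#' binary (`.bin`: little-endian float64, row-major, JSON sidecar with the
#' shape and layout).  Binary round-trips are bit-exact.
#'
#' @param X Numeric matrix, subjects x features.
#' @param path Output path ending in `.tsv` or `.bin`.
#' @param feature_ids Optional column ids (default `f000001`, ...).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(X, path, feature_ids = NULL) {
  X <- as.matrix(X)
  if (is.null(feature_ids)) feature_ids <- sprintf("f%06d", seq_len(ncol(X)))
  if (length(feature_ids) != ncol(X)) stop("feature_ids length mismatch")
  if (grepl("\\.bin$", path)) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(X)), con, size = 8L, endian = "little")
    jsonlite::write_json(
      list(rows = nrow(X), cols = ncol(X), dtype = "float64",
           order = "row-major", byte_order = "little",
           feature_ids = feature_ids),
      paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    dt <- data.table::as.data.table(X)
    data.table::setnames(dt, feature_ids)
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#'
#' @param path `.tsv` or `.bin` path.
#' @return Numeric matrix with feature ids as column names.
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("matrix file '%s' not found", path))
  if (grepl("\\.bin$", path)) {
    side <- paste0(path, ".json")
    if (!file.exists(side)) stop(sprintf("missing sidecar '%s'", side))
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!identical(meta$dtype, "float64") || !identical(meta$order, "row-major"))
      stop("unsupported binary layout in sidecar")
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = meta$rows * meta$cols, size = 8L,
                 endian = "little")
    if (length(v) != meta$rows * meta$cols)
      stop(sprintf("truncated binary matrix: expected %d values, read %d",
                   meta$rows * meta$cols, length(v)))
    X <- matrix(v, nrow = meta$rows, ncol = meta$cols, byrow = TRUE)
    colnames(X) <- meta$feature_ids
    X
  } else {
    dt <- data.table::fread(path, sep = "\t", header = TRUE)
    X <- as.matrix(dt)
    if (!is.numeric(X)) stop(sprintf("non-numeric entries in '%s'", path))
    X
  }
}

#' Write the group index
#'
#' One line per feature column, in column order: `feature_id`, `group_id`,
#' `hemisphere`, `row`, `col`, `feature_type`, `weight`.
#'
#' @param design A [grouped_design()] with a feature index.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_group_index <- function(design, path) {
  fi <- design$feature_index
  if (is.null(fi)) stop("design has no feature index")
  data.table::fwrite(
    fi[, c("feature_id", "group_id", "hemisphere", "row", "col",
           "feature_type", "weight")],
    path, sep = "\t")
  invisible(path)
}

#' Read a group index file into a design layout
#'
#' Reconstructs the groups table (contiguous blocks in file order) and the
#' feature index; validates that group ids form contiguous runs.
#'
#' @param path Group-index TSV.
#' @return A layout list (`groups`, `feature_index`, `grids`) accepted by
#'   [grouped_design()].
#' @export
read_group_index <- function(path) {
  fi <- read_checked_tsv(path, 7L, "group index")
  need <- c("feature_id", "group_id", "hemisphere", "row", "col",
            "feature_type", "weight")
  if (!identical(names(fi), need))
    stop(sprintf("group index '%s' must have columns: %s",
                 path, paste(need, collapse = ", ")))
  fi$column <- seq_len(nrow(fi))
  r <- rle(fi$group_id)
  if (anyDuplicated(r$values))
    stop(sprintf("group index '%s': group ids are not contiguous blocks", path))
  groups <- data.frame(group_id = r$values,
                       size = r$lengths,
                       stringsAsFactors = FALSE)
  groups <- groups[order(groups$group_id), ]
  if (!identical(as.integer(groups$group_id), seq_len(nrow(groups))))
    stop(sprintf("group index '%s': group ids must be 1..G", path))
  groups$start <- cumsum(c(1L, groups$size[-nrow(groups)]))
  first <- fi[match(groups$group_id, fi$group_id), ]
  groups$weight <- first$weight
  groups$hemisphere <- first$hemisphere
  groups$feature_type <- first$feature_type
  grids <- lapply(unique(fi$hemisphere), function(h) {
    sel <- fi$hemisphere == h
    surface_grid(max(fi$row[sel]) + 1L, max(fi$col[sel]) + 1L, h)
  })
  names(grids) <- NULL
  cols_by_hemi <- vapply(grids, function(g) g$cols, integer(1))
  names(cols_by_hemi) <- vapply(grids, function(g) g$hemisphere, character(1))
  fi$vertex <- as.integer(fi$row * cols_by_hemi[fi$hemisphere] + fi$col)
  list(groups = groups, feature_index = fi, grids = grids)
}

#' Write / read a response or site-assignment table
#'
#' Two-column delimited text: `subject_id` and the value.
#'
#' @param values Numeric (response) or integer (site) vector.
#' @param subject_ids Character ids, same length.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_response <- function(values, subject_ids, path) {
  stopifnot(length(values) == length(subject_ids))
  data.table::fwrite(data.frame(subject_id = subject_ids, value = values),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_response
#' @export
read_response <- function(path) {
  df <- read_checked_tsv(path, 2L, "response")
  if (!identical(names(df), c("subject_id", "value")))
    stop(sprintf("response file '%s' must have columns subject_id, value", path))
  if (!is.numeric(df$value))
    stop(sprintf("non-numeric response values in '%s'", path))
  df
}

#' @rdname write_response
#' @param site_ids Integer site assignment per subject.
#' @export
write_sites <- function(site_ids, subject_ids, path) {
  stopifnot(length(site_ids) == length(subject_ids))
  data.table::fwrite(data.frame(subject_id = subject_ids,
                                site_id = as.integer(site_ids)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_response
#' @export
read_sites <- function(path) {
  df <- read_checked_tsv(path, 2L, "site")
  if (!identical(names(df), c("subject_id", "site_id")))
    stop(sprintf("site file '%s' must have columns subject_id, site_id", path))
  df$site_id <- as.integer(df$site_id)
  if (anyNA(df$site_id)) stop(sprintf("non-integer site ids in '%s'", path))
  df
}
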