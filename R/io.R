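#' Read an adjacency matrix file
#'
#' Reads a square weighted adjacency matrix from disk. Two dialects are
#' supported: `"labelled-csv"` (comma-separated, identical row and column
#' headers) and `"plain-whitespace"` (headerless square block, BrainNet
#' `.edge`-compatible). Input is symmetrized by averaging with its transpose;
#' asymmetry beyond `1e-6` is reported via a message. The diagonal is forced
#' to zero.
#'
#' @param path file path.
#' @param dialect `"labelled-csv"` or `"plain-whitespace"`.
#' @param subject_id,group metadata to attach.
#' @return a `connectivity_matrix` with `state = "raw"`.
#' @export
read_matrix <- function(path, dialect = c("labelled-csv", "plain-whitespace"),
                        subject_id = "", group = "control") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "labelled-csv") {
    d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    w <- as.matrix(d)
    if (nrow(w) != ncol(w)) {
      stop("non-square matrix block: ", nrow(w), "x", ncol(w))
    }
    if (!identical(rownames(w), colnames(w))) {
      stop("row and column headers differ")
    }
    labels <- rownames(w)
  } else {
    rows <- readLines(path)
    rows <- rows[nzchar(trimws(rows))]
    parsed <- lapply(rows, function(r) strsplit(trimws(r), "[ \t]+")[[1]])
    ncols <- unique(vapply(parsed, length, integer(1)))
    if (length(ncols) != 1 || ncols != length(parsed)) {
      stop("non-square matrix block in ", path)
    }
    w <- matrix(NA_real_, length(parsed), ncols)
    for (i in seq_along(parsed)) {
      v <- suppressWarnings(as.numeric(parsed[[i]]))
      bad <- which(is.na(v) & parsed[[i]] != "NA")
      if (length(bad)) {
        stop(sprintf("non-numeric cell at row %d, col %d: '%s'",
                     i, bad[1], parsed[[i]][bad[1]]))
      }
      w[i, ] <- v
    }
    labels <- paste0("R", seq_len(nrow(w)))
  }
  storage.mode(w) <- "double"
  if (anyNA(w)) {
    idx <- which(is.na(w), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row %d, col %d", idx[1], idx[2]))
  }
  connectivity_matrix(w, labels = labels, subject_id = subject_id,
                      group = group, state = "raw", symmetrize = TRUE)
}

#' Write an adjacency matrix file
#'
#' Inverse of [read_matrix()]; values are written with 6 decimals so a
#' round-trip reproduces weights to 1e-6.
#'
#' @param m a `connectivity_matrix`.
#' @param path output path.
#' @param dialect `"labelled-csv"` or `"plain-whitespace"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, dialect = c("labelled-csv", "plain-whitespace")) {
  dialect <- match.arg(dialect)
  w <- m$weights
  fmt <- matrix(sprintf("%.6f", w), nrow(w))
  if (dialect == "labelled-csv") {
    d <- as.data.frame(fmt)
    colnames(d) <- m$labels
    d <- cbind(data.frame(region = m$labels), d)
    utils::write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  } else {
    writeLines(apply(fmt, 1, paste, collapse = " "), path)
  }
  invisible(path)
}

#' Write BrainNet Viewer node/edge files
#'
#' Emits `<prefix>.node` (six whitespace-separated columns: x, y, z, color,
#' size, label) and `<prefix>.edge` (square whitespace-separated weight
#' matrix). The color column is the module id when the atlas carries one (or
#' `module` is supplied), else 1; the size column is a nodal quantifier
#' rescaled to \[1, 10\] (degree by default).
#'
#' @param m a `connectivity_matrix`.
#' @param atlas a `region_atlas` of the same size.
#' @param prefix output path prefix (without extension).
#' @param size optional numeric nodal values for the size column.
#' @param module optional integer module ids for the color column.
#' @return character vector of the two file paths, invisibly.
#' @export
write_brainnet_files <- function(m, atlas, prefix, size = NULL, module = NULL) {
  n <- n_regions(m)
  if (n != nrow(atlas)) {
    stop("matrix has ", n, " regions but atlas has ", nrow(atlas))
  }
  if (is.null(module)) {
    module <- if ("module" %in% names(atlas)) atlas$module else rep(1L, n)
  }
  if (is.null(size)) size <- rowSums(m$weights != 0)
  size <- rescale_1_10(size)

  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  node <- sprintf("%.3f %.3f %.3f %d %.3f %s",
                  atlas$x, atlas$y, atlas$z, as.integer(module), size,
                  gsub("[[:space:]]", "_", atlas$label))
  writeLines(node, node_path)
  write_matrix(m, edge_path, dialect = "plain-whitespace")
  invisible(c(node = node_path, edge = edge_path))
}

# internal: affine rescale to [1, 10]; constant input maps to 1
rescale_1_10 <- function(v) {
  rng <- range(v)
  if (rng[2] == rng[1]) return(rep(1, length(v)))
  1 + 9 * (v - rng[1]) / (rng[2] - rng[1])
}

#' Classify connections as long- or short-range
#'
#' Labels every present edge by the Euclidean distance between its endpoint
#' coordinates: `long` if the distance exceeds `cutoff_mm`, else `short`. The
#' cutoff has no canonical value; the default is the median pairwise atlas
#' distance.
#'
#' @param m a thresholded or binarized `connectivity_matrix`.
#' @param atlas a `region_atlas`.
#' @param cutoff_mm positive cutoff in mm; default median pairwise distance.
#' @return list with `edges` (data frame: `from`, `to`, `distance_mm`,
#'   `class`) and `counts` (named vector `long`, `short`).
#' @export
connection_length_classes <- function(m, atlas, cutoff_mm = NULL) {
  if (!m$state %in% c("thresholded", "binarized")) {
    stop("matrix must be thresholded or binarized")
  }
  if (nrow(atlas) != n_regions(m)) stop("atlas/matrix size mismatch")
  if (anyNA(atlas[, c("x", "y", "z")])) stop("atlas has missing coordinates")
  d <- atlas_distances(atlas)
  if (is.null(cutoff_mm)) cutoff_mm <- stats::median(d[upper.tri(d)])
  if (cutoff_mm <= 0) stop("cutoff_mm must be positive")
  idx <- which(upper.tri(m$weights) & m$weights != 0, arr.ind = TRUE)
  dist_mm <- d[idx]
  cls <- ifelse(dist_mm > cutoff_mm, "long", "short")
  edges <- data.frame(from = m$labels[idx[, 1]], to = m$labels[idx[, 2]],
                      distance_mm = dist_mm, class = cls,
                      stringsAsFactors = FALSE)
  list(edges = edges,
       counts = c(long = sum(cls == "long"), short = sum(cls == "short")),
       cutoff_mm = cutoff_mm)
}
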