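#' Construct a region atlas
#'
#' A region atlas carries, for each node of the connectome, a unique label, a
#' hemisphere assignment and a 3-D coordinate in mm atlas space. It supports
#' bilateral pairing checks, distance-based connection classification and
#' BrainNet Viewer export.
#'
#' @param label character vector of unique region labels. Bilateral regions
#'   are expected to share a stem and end in `_L` / `_R`.
#' @param hemisphere character vector in `c("L", "R", "midline")`.
#' @param x,y,z numeric coordinates (mm). Larger `y` = more anterior.
#' @param module optional integer module assignment per region.
#'
#' @return a `region_atlas` data frame with columns `region_index` (0-based,
#'   contiguous), `label`, `hemisphere`, `x`, `y`, `z` and optionally `module`.
#' @export
region_atlas <- function(label, hemisphere, x, y, z, module = NULL) {
  n <- length(label)
  stopifnot(length(hemisphere) == n, length(x) == n, length(y) == n, length(z) == n)
  if (anyDuplicated(label)) stop("atlas labels must be unique")
  if (!all(hemisphere %in% c("L", "R", "midline"))) {
    stop("hemisphere must be one of 'L', 'R', 'midline'")
  }
  a <- data.frame(region_index = seq_len(n) - 1L, label = label,
                  hemisphere = hemisphere, x = x, y = y, z = z,
                  stringsAsFactors = FALSE)
  if (!is.null(module)) {
    stopifnot(length(module) == n)
    a$module <- as.integer(module)
  }
  class(a) <- c("region_atlas", "data.frame")
  a
}

#' Pair left-hemisphere regions with their right partners
#'
#' For each `L` region, looks for an `R` region whose label shares the same
#' stem (label minus a trailing `_L` / `_R`).
#'
#' @param atlas a `region_atlas`.
#' @return data frame with columns `left`, `right` (labels; `right` is `NA`
#'   for unpaired left regions).
#' @export
bilateral_pairs <- function(atlas) {
  stem <- sub("_(L|R)$", "", atlas$label)
  left <- which(atlas$hemisphere == "L")
  right <- which(atlas$hemisphere == "R")
  partner <- match(stem[left], stem[right])
  data.frame(left = atlas$label[left],
             right = ifelse(is.na(partner), NA_character_,
                            atlas$label[right][partner]),
             stringsAsFactors = FALSE)
}

#' Read / write an atlas TSV
#'
#' The interchange format is a tab-separated table with columns
#' `label`, `hemisphere`, `x`, `y`, `z` and optionally `module`.
#'
#' @param path file path.
#' @return `read_atlas` returns a `region_atlas`.
#' @export
read_atlas <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "hemisphere", "x", "y", "z")
  if (!all(need %in% names(d))) {
    stop("atlas file must have columns: ", paste(need, collapse = ", "))
  }
  region_atlas(d$label, d$hemisphere, d$x, d$y, d$z,
               module = if ("module" %in% names(d)) d$module else NULL)
}

#' @rdname read_atlas
#' @param atlas a `region_atlas` to serialize.
#' @export
write_atlas <- function(atlas, path) {
  keep <- setdiff(names(atlas), "region_index")
  utils::write.table(as.data.frame(atlas)[, keep], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise Euclidean distances between atlas coordinates
#' @param atlas a `region_atlas`.
#' @return n x n distance matrix in mm.
#' @export
atlas_distances <- function(atlas) {
  xyz <- as.matrix(atlas[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(atlas$label, atlas$label)
  d
}
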