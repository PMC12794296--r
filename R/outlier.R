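#' Detect outlier cells in a spatial feature map
#'
#' Flags cells whose value lies outside `mean +/- k * sd`, where mean and
#' (sample) standard deviation are computed over all cells of this single
#' feature map. A constant map yields no flags.
#'
#' @param map 16 x 4 numeric matrix (or any matrix).
#' @param k Criterion multiplier (default 2).
#' @return Logical matrix of the same shape, `TRUE` = outlier.
#' @export
detect_outliers <- function(map, k = 2) {
  stopifnot(is.matrix(map), all(is.finite(map)))
  m <- mean(map)
  s <- sd(as.vector(map))
  if (!is.finite(s) || s == 0) {
    return(matrix(FALSE, nrow(map), ncol(map)))
  }
  map < m - k * s | map > m + k * s
}

#' Reconstruct flagged cells from nearest valid neighbours
#'
#' Replaces each flagged cell by the mean of its valid (unflagged)
#' 4-neighbours; if a cell has no valid rook neighbour, the neighbourhood
#' expands by Euclidean grid distance until at least one valid cell is
#' found, averaging all equidistant valid cells. All replacements use the
#' original pre-repair values (single pass); unflagged cells are untouched.
#'
#' @param map Numeric matrix (16 x 4 feature map).
#' @param mask Logical matrix of the same shape (`TRUE` = repair).
#' @param wrap Treat the first (circumferential) dimension as circular.
#'   Off by default: the flexor and extensor arrays are physically
#'   separated around the arm.
#' @return Repaired map.
#' @export
reconstruct_outliers <- function(map, mask, wrap = FALSE) {
  stopifnot(identical(dim(map), dim(mask)))
  if (all(mask)) stop("all cells flagged; cannot repair")
  if (!any(mask)) return(map)
  nr <- nrow(map); nc <- ncol(map)
  valid <- which(!mask, arr.ind = TRUE)
  vals <- map[!mask]
  out <- map
  for (idx in which(mask)) {
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    dr <- abs(valid[, 1] - r)
    if (wrap) dr <- pmin(dr, nr - dr)
    d2 <- dr^2 + (valid[, 2] - c)^2
    out[r, c] <- mean(vals[d2 <= min(d2) + 1e-12])
  }
  out
}

#' Repair the eight feature maps of one window
#'
#' Applies [detect_outliers()] and [reconstruct_outliers()] to each
#' feature's 16 x 4 spatial map independently, as the maps are screened
#' per feature.
#'
#' @param F channels x features matrix (64 x 8) in region raster order.
#' @param k Criterion multiplier.
#' @param wrap Circumferential wrap flag.
#' @return Repaired 64 x 8 matrix.
#' @export
repair_feature_maps <- function(F, k = 2, wrap = FALSE) {
  stopifnot(nrow(F) == 64)
  for (j in seq_len(ncol(F))) {
    map <- region_map(F[, j])
    mask <- detect_outliers(map, k)
    if (any(mask)) F[, j] <- as.vector(reconstruct_outliers(map, mask, wrap))
  }
  F
}
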