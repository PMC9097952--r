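# 26-connected component containing seed_idx within a logical mask.
# Vectorized frontier expansion on linear indices.
connected_component <- function(mask, seed_idx) {
  d <- dim(mask)
  if (!mask[seed_idx]) stop("seed voxel is outside the mask")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- array(FALSE, d)
  comp[seed_idx] <- TRUE
  frontier <- matrix(arrayInd(seed_idx, d), ncol = 3)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * d[1] + (nb[, 3] - 1) * d[1] * d[2]
    lin <- unique(lin[mask[lin] & !comp[lin]])
    if (!length(lin)) break
    comp[lin] <- TRUE
    frontier <- matrix(arrayInd(lin, d), ncol = 3)
  }
  comp
}

#' Isocontour lesion segmentation at 41% of maximum
#'
#' Automated lesion delineation: the 26-connected component containing the
#' seed of voxels at or above 41% of the component's own maximum, iterated
#' to a fixed point (the threshold is recomputed from the current component
#' maximum until the region stabilises, at most `max_iter` rounds).
#'
#' @param map 3D map (e.g. the MR_FDG map).
#' @param seed_voxel integer voxel coordinates `c(i, j, k)` inside the
#'   lesion, or a linear index.
#' @param threshold fraction of the component maximum (default 0.41).
#' @param max_iter iteration cap for the fixed point.
#' @return a logical VOI mask (class `voi`, kind `"threshold41"`).
#' @export
segment_threshold41 <- function(map, seed_voxel, threshold = 0.41, max_iter = 20) {
  d <- dim(map)
  seed_idx <- if (length(seed_voxel) == 3) {
    seed_voxel[1] + (seed_voxel[2] - 1) * d[1] + (seed_voxel[3] - 1) * d[1] * d[2]
  } else {
    as.integer(seed_voxel)
  }
  if (!is.finite(map[seed_idx]) || map[seed_idx] <= 0) {
    stop("seed voxel must lie on a positive, finite map value")
  }
  curmax <- map[seed_idx]
  comp <- NULL
  for (iter in seq_len(max_iter)) {
    mask <- is.finite(map) & map >= threshold * curmax
    comp <- connected_component(mask, seed_idx)
    newmax <- max(map[comp])
    # re-anchor on the component's hottest voxel so the seed cannot fall
    # below the updated threshold on the next round
    seed_idx <- which(comp & map == newmax)[1]
    if (newmax <= curmax) break
    curmax <- newmax
  }
  structure(comp, kind = "threshold41", threshold = threshold,
            class = c("voi", class(comp)))
}

#' Fixed-diameter spherical VOI
#'
#' Voxels whose centers lie within `diameter_mm / 2` of the center voxel's
#' center — the fixed-diameter sphere used for normal-organ VOIs.
#'
#' @param center integer voxel coordinates `c(i, j, k)`.
#' @param diameter_mm sphere diameter, mm.
#' @param dim integer grid dimensions.
#' @param voxel_mm isotropic voxel size, mm.
#' @return a logical VOI mask (class `voi`, kind `"fixed_sphere"`).
#' @export
sphere_voi <- function(center, diameter_mm, dim, voxel_mm) {
  stopifnot(length(center) == 3, length(dim) == 3, diameter_mm > 0)
  r2 <- (diameter_mm / 2)^2
  dx2 <- ((seq_len(dim[1]) - center[1]) * voxel_mm)^2
  dy2 <- ((seq_len(dim[2]) - center[2]) * voxel_mm)^2
  dz2 <- ((seq_len(dim[3]) - center[3]) * voxel_mm)^2
  mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= r2
  if (!any(mask)) stop("sphere does not intersect the grid")
  structure(mask, kind = "fixed_sphere", diameter_mm = diameter_mm,
            class = c("voi", class(mask)))
}

# voxel offsets of a 1-cm^3 sphere (the PERCIST-style peak neighborhood)
peak_offsets <- function(voxel_mm) {
  r <- (3 * 1000 / (4 * pi))^(1 / 3)  # mm; sphere of 1 ml
  k <- floor(r / voxel_mm)
  off <- as.matrix(expand.grid(dx = -k:k, dy = -k:k, dz = -k:k))
  off[rowSums(off^2) * voxel_mm^2 <= r^2, , drop = FALSE]
}

#' Max / mean / peak statistics over a VOI
#'
#' `max` and `mean` are taken over the VOI voxels; `peak` is the highest
#' mean of a 1-cm³ spherical neighborhood centered on any VOI voxel
#' (neighborhoods are clipped at the grid boundary; `NaN` voxels are
#' ignored). Returns an invalid marker if the VOI holds no finite values.
#'
#' @param map 3D map.
#' @param voi logical VOI mask from [sphere_voi()] or
#'   [segment_threshold41()].
#' @param voxel_mm voxel size, mm (for the peak neighborhood).
#' @return list with `max`, `mean`, `peak`, `min`, `n_voxels`, `valid`.
#' @export
region_stats <- function(map, voi, voxel_mm) {
  d <- dim(map)
  idx <- which(voi)
  if (!length(idx)) stop("VOI is empty")
  vals <- map[idx]
  if (all(!is.finite(vals))) {
    return(list(max = NA_real_, mean = NA_real_, peak = NA_real_,
                min = NA_real_, n_voxels = length(idx), valid = FALSE))
  }
  off <- peak_offsets(voxel_mm)
  ctr <- matrix(arrayInd(idx, d), ncol = 3)
  sums <- numeric(length(idx))
  cnts <- numeric(length(idx))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(ctr, 2, off[r, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * d[1] + (nb[ok, 3] - 1) * d[1] * d[2]
    v <- map[lin]
    fin <- is.finite(v)
    sums[ok][fin] <- sums[ok][fin] + v[fin]
    cnts[ok][fin] <- cnts[ok][fin] + 1
  }
  peaks <- ifelse(cnts > 0, sums / cnts, NA_real_)
  list(max = max(vals, na.rm = TRUE),
       mean = mean(vals, na.rm = TRUE),
       peak = max(peaks, na.rm = TRUE),
       min = min(vals, na.rm = TRUE),
       n_voxels = length(idx), valid = TRUE)
}
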